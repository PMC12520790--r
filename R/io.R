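# Configuration files, scenario presets, table writers and the
# command-line front end.

# Keys accepted in a scenario YAML file (all others are rejected).
.config_keys <- c("k", "dominance", "costs", "benefits", "ec50_wt", "kappa",
                  "xi", "egg_mated", "egg_selfed", "mu", "ladder",
                  "escalation_threshold", "census_size", "max_generations",
                  "drug_degradation_rate", "replicates", "base_seed",
                  "mode", "record_compartments", "stop_when_fixed")

#' Load a scenario configuration from a YAML file
#'
#' Unknown keys are rejected by name; defaults (e.g. `egg_mated = 1000`,
#' `egg_selfed = 300`, `mu = 1e-4`) fill in anything omitted.
#'
#' @param path Path to a YAML file.
#' @return A validated [scenario_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(scenario_config, raw)
}

#' Write a scenario configuration to a YAML file
#'
#' Round-trips with [load_config()].
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(.config_as_list(config), path)
  invisible(path)
}

.config_as_list <- function(config) {
  list(
    k = config$k,
    dominance = config$dominance,
    costs = config$effects$costs,
    benefits = config$effects$benefits,
    ec50_wt = config$pd$ec50_wt,
    kappa = config$pd$kappa,
    xi = config$ms$xi,
    egg_mated = config$ms$egg_mated,
    egg_selfed = config$ms$egg_selfed,
    mu = config$mu,
    ladder = config$passage$ladder,
    escalation_threshold = config$passage$escalation_threshold,
    census_size = config$passage$census_size,
    max_generations = config$passage$max_generations,
    drug_degradation_rate = config$passage$drug_degradation_rate,
    replicates = config$replicates,
    base_seed = config$base_seed,
    mode = config$mode,
    record_compartments = config$record_compartments,
    stop_when_fixed = config$stop_when_fixed
  )
}

#' Stable short hash of a scenario configuration
#'
#' 32-bit FNV-1a over the canonical YAML serialization; used to tag
#' output files so sweep results are self-describing.
#'
#' @param config A [scenario_config()].
#' @return 8-character lowercase hex string.
#' @export
scenario_hash <- function(config) {
  s <- yaml::as.yaml(.config_as_list(config))
  bytes <- utf8ToInt(s) %% 256
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit multiply by the FNV prime without exceeding 2^53:
    # split h into 16-bit halves
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  # h fits in 32 bits; render as hex from two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# ---- presets ---------------------------------------------------------------

.preset_grid <- function() {
  expand.grid(
    architecture = c("loci2", "loci6"),
    dominance = c("recessive", "dominant"),
    N = c(200L, 2000L, 20000L, 200000L),
    xi = seq(0, 1, by = 0.1),
    stringsAsFactors = FALSE
  )
}

.preset_name <- function(architecture, dominance, N, xi) {
  sprintf("%s_%s_N%d_xi%.1f", architecture, dominance, N, xi)
}

#' Built-in scenario presets
#'
#' The full grid of simulated scenarios: two genetic architectures
#' (2 small-effect loci: cost 0.05, benefit 0.5 nM each; or 6 loci,
#' three small-effect plus three large-effect: cost 0.10, benefit 3 nM),
#' all-recessive or all-dominant, census sizes 200/2000/20000/200000,
#' and mating fractions xi from 0 to 1 in steps of 0.1.
#'
#' @return Data frame of preset names and their grid coordinates.
#' @export
builtin_presets <- function() {
  g <- .preset_grid()
  g$name <- .preset_name(g$architecture, g$dominance, g$N, g$xi)
  g[, c("name", "architecture", "dominance", "N", "xi")]
}

#' Retrieve one preset as a full configuration
#'
#' @param name A preset name as listed by [builtin_presets()].
#' @param ... Overrides passed to [scenario_config()] (e.g. `replicates`,
#'   `base_seed`, `max_generations`).
#' @return A [scenario_config()].
#' @examples
#' cfg <- preset("loci6_recessive_N2000_xi0.5", replicates = 2)
#' @export
preset <- function(name, ...) {
  g <- builtin_presets()
  i <- match(name, g$name)
  if (is.na(i)) {
    stop("unknown preset '", name, "'; see builtin_presets() for the ",
         nrow(g), " available names", call. = FALSE)
  }
  if (g$architecture[i] == "loci2") {
    k <- 2L; costs <- rep(0.05, 2); benefits <- rep(0.5, 2)
  } else {
    k <- 6L
    costs <- c(rep(0.05, 3), rep(0.10, 3))
    benefits <- c(rep(0.5, 3), rep(3, 3))
  }
  dom <- if (g$dominance[i] == "dominant") 1L else 0L
  args <- list(k = k, dominance = dom, costs = costs, benefits = benefits,
               xi = g$xi[i], census_size = g$N[i])
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_config, args)
}

# ---- writers ---------------------------------------------------------------

#' Write trajectory tables and a metadata sidecar
#'
#' Writes, into `out_dir`: a long-format tab-separated trajectory table
#' (one row per generation per replicate), an optional sparse
#' compartment table, and a YAML metadata sidecar carrying the full
#' configuration, seeds and package version. File names embed the
#' scenario hash and base seed, so identical runs produce byte-identical
#' files.
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the files written.
#' @export
write_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  stem <- sprintf("%s_seed%d", result$scenario_hash, cfg$base_seed)

  traj <- do.call(rbind, lapply(result$records, function(r) {
    tr <- r$trajectory
    tr$replicate <- r$replicate
    tr$seed <- r$seed
    tr
  }))
  traj_path <- file.path(out_dir, paste0(stem, "_trajectories.tsv"))
  utils::write.table(traj, traj_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(trajectories = traj_path)

  comps <- lapply(result$records, function(r) {
    if (is.null(r$compartments)) return(NULL)
    cc <- r$compartments
    cc$replicate <- r$replicate
    cc
  })
  comps <- do.call(rbind, comps)
  if (!is.null(comps)) {
    comp_path <- file.path(out_dir, paste0(stem, "_compartments.tsv"))
    utils::write.table(comps, comp_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, compartments = comp_path)
  }

  meta <- list(
    scenario_hash = result$scenario_hash,
    config = .config_as_list(cfg),
    replicate_seeds = vapply(result$records, function(r) r$seed, numeric(1)),
    extinct_replicates = vapply(result$records, function(r) r$extinct,
                                logical(1)),
    package = "androsim",
    version = as.character(utils::packageVersion("androsim"))
  )
  meta_path <- file.path(out_dir, paste0(stem, "_metadata.yaml"))
  yaml::write_yaml(meta, meta_path)
  c(paths, metadata = meta_path)
}

#' Write a scenario summary as tab-separated tables
#'
#' @param summary A `scenario_summary` from [summarize_scenario()].
#' @param out_dir Output directory.
#' @param stem File-name stem.
#' @return Named character vector of the files written.
#' @export
write_summary_tables <- function(summary, out_dir, stem = "summary") {
  stopifnot(inherits(summary, "scenario_summary"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in c("per_generation", "concentration_snapshots", "fixation")) {
    p <- file.path(out_dir, sprintf("%s_%s.tsv", stem, nm))
    utils::write.table(summary[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[nm] <- p
  }
  paths
}

# ---- command line ----------------------------------------------------------

#' Command-line entry point
#'
#' Subcommands: `simulate` (one scenario to trajectory tables), `sweep`
#' (a set of presets), `summarize` (aggregate written trajectories) and
#' `presets` (list built-ins). Invoked by the `inst/cli/androsim`
#' script: `Rscript androsim simulate --preset NAME --replicates 5
#' --seed 1 --out-dir runs/`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: androsim <simulate|sweep|summarize|presets> [options]",
    "  simulate  --preset NAME | --config FILE  [--replicates R]",
    "            [--seed S] [--generations G] [--out-dir DIR]",
    "            [--store-compartments]",
    "  sweep     --presets NAME,NAME,...  [--replicates R] [--seed S]",
    "            [--generations G] [--out-dir DIR]",
    "  summarize --in DIR [--snapshot-generations 10,25,100,250,500]",
    "            [--out-dir DIR]",
    "  presets", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opts <- .parse_cli_opts(args[-1L])
  status <- tryCatch({
    switch(cmd,
      presets = { print(builtin_presets()); 0L },
      simulate = .cli_simulate(opts),
      sweep = .cli_sweep(opts),
      summarize = .cli_summarize(opts),
      { message("unknown subcommand '", cmd, "'\n", usage); 1L }
    )
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  flags <- c("store-compartments")
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3L)
    if (key %in% flags) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("missing value for --", key, call. = FALSE)
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

.cli_config_from_opts <- function(opts) {
  over <- list()
  if (!is.null(opts$replicates)) over$replicates <- as.integer(opts$replicates)
  if (!is.null(opts$seed)) over$base_seed <- as.integer(opts$seed)
  if (!is.null(opts$generations)) {
    over$max_generations <- as.integer(opts$generations)
  }
  if (isTRUE(opts$`store-compartments`)) over$record_compartments <- TRUE
  if (!is.null(opts$preset)) {
    do.call(preset, c(list(name = opts$preset), over))
  } else if (!is.null(opts$config)) {
    cfg <- load_config(opts$config)
    if (length(over)) {
      args <- .config_as_list(cfg)
      args[names(over)] <- over
      cfg <- do.call(scenario_config, args)
    }
    cfg
  } else {
    stop("one of --preset or --config is required", call. = FALSE)
  }
}

.cli_simulate <- function(opts) {
  cfg <- .cli_config_from_opts(opts)
  out_dir <- if (is.null(opts$`out-dir`)) "." else opts$`out-dir`
  res <- run_scenario(cfg)
  paths <- write_tables(res, out_dir)
  message("wrote: ", paste(paths, collapse = ", "))
  0L
}

.cli_sweep <- function(opts) {
  if (is.null(opts$presets)) stop("--presets is required", call. = FALSE)
  names <- strsplit(opts$presets, ",", fixed = TRUE)[[1L]]
  out_dir <- if (is.null(opts$`out-dir`)) "." else opts$`out-dir`
  for (nm in names) {
    o <- opts
    o$preset <- nm
    cfg <- .cli_config_from_opts(o)
    res <- run_scenario(cfg)
    write_tables(res, out_dir)
    message("completed preset ", nm)
  }
  0L
}

.cli_summarize <- function(opts) {
  if (is.null(opts$`in`)) stop("--in is required", call. = FALSE)
  snaps <- if (is.null(opts$`snapshot-generations`)) c(10, 25, 100, 250, 500)
           else as.numeric(strsplit(opts$`snapshot-generations`, ",")[[1L]])
  files <- list.files(opts$`in`, pattern = "_trajectories\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) stop("no trajectory tables under ", opts$`in`,
                           call. = FALSE)
  out_dir <- if (is.null(opts$`out-dir`)) opts$`in` else opts$`out-dir`
  for (f in files) {
    long <- utils::read.delim(f)
    records <- lapply(split(long, long$replicate), function(d) {
      structure(list(trajectory = d[order(d$generation), ],
                     replicate = d$replicate[1L],
                     extinct = FALSE,
                     extinction_generation = NA_integer_),
                class = "trajectory_record")
    })
    sm <- summarize_scenario(records, at_generations = snaps)
    stem <- sub("_trajectories\\.tsv$", "", basename(f))
    write_summary_tables(sm, out_dir, stem = stem)
    message("summarized ", basename(f))
  }
  0L
}
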