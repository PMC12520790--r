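# Replicate orchestration: scenario configuration, initialization,
# the per-generation loop, seeding and trajectory recording.

#' Full scenario configuration
#'
#' Bundles genetics, pharmacodynamics, mating system, passage protocol,
#' mutation rate and replication settings for one simulated scenario.
#'
#' @param k Number of resistance loci.
#' @param dominance Dominance vector (length k, 0/1) or a single 0/1
#'   recycled to all loci.
#' @param costs,benefits Per-locus effect sizes (see [effect_sizes()]).
#' @param ec50_wt,kappa Pharmacodynamics (see [pd_params()]).
#' @param xi,egg_mated,egg_selfed Mating system (see [mating_system()]).
#' @param mu Per-genome single-step mutation probability per offspring.
#' @param ladder,escalation_threshold,census_size,max_generations,
#'   drug_degradation_rate Passage protocol (see [passage_config()]).
#' @param replicates Number of replicate simulations.
#' @param base_seed Base RNG seed; replicate `r` uses `base_seed + r`.
#' @param mode `"stochastic"` (Poisson mutation, multinomial dilution) or
#'   `"expectation"` (fully deterministic real-valued dynamics).
#' @param record_compartments Store full per-generation compartment
#'   counts (sparse) in each trajectory record.
#' @param stop_when_fixed Stop a replicate once any locus's mutant-allele
#'   frequency first reaches 0.95 (useful for fixation-time sweeps).
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(k,
                            dominance,
                            costs,
                            benefits,
                            ec50_wt = 1,
                            kappa = 3,
                            xi = 0.5,
                            egg_mated = 1000,
                            egg_selfed = 300,
                            mu = 1e-4,
                            ladder = default_ladder(),
                            escalation_threshold = 20,
                            census_size = 2000,
                            max_generations = 500,
                            drug_degradation_rate = 0,
                            replicates = 100,
                            base_seed = 1,
                            mode = c("stochastic", "expectation"),
                            record_compartments = FALSE,
                            stop_when_fixed = FALSE) {
  mode <- match.arg(mode)
  if (length(dominance) == 1L) dominance <- rep(dominance, k)
  effects <- effect_sizes(costs, benefits)
  pd <- pd_params(ec50_wt = ec50_wt, kappa = kappa)
  ms <- mating_system(xi = xi, egg_mated = egg_mated, egg_selfed = egg_selfed)
  pc <- passage_config(ladder = ladder,
                       escalation_threshold = escalation_threshold,
                       census_size = census_size,
                       max_generations = max_generations,
                       drug_degradation_rate = drug_degradation_rate)
  stopifnot(mu >= 0, mu < 1, replicates >= 1)
  profiles <- build_strain_profiles(k, dominance, effects, pd)
  cfg <- structure(list(
    k = as.integer(k), dominance = as.integer(dominance),
    effects = effects, pd = pd, ms = ms, passage = pc,
    mu = mu, replicates = as.integer(replicates),
    base_seed = as.integer(base_seed), mode = mode,
    record_compartments = isTRUE(record_compartments),
    stop_when_fixed = isTRUE(stop_when_fixed),
    profiles = profiles
  ), class = "scenario_config")
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$k, "loci,",
      if (all(x$dominance == 1)) "dominant" else
        if (all(x$dominance == 0)) "recessive" else "mixed dominance",
      "| xi =", x$ms$xi, "| N =", x$passage$census_size,
      "| mu =", x$mu, "| kappa =", x$pd$kappa, "\n")
  cat("  ladder:", paste(x$passage$ladder, collapse = ", "), "nM\n")
  cat("  ", x$replicates, "replicates x", x$passage$max_generations,
      "generations, mode:", x$mode, "\n")
  invisible(x)
}

#' Initial population state
#'
#' All individuals wild-type (no mutant alleles), half of them male
#' (floor rule), at the drug-free start of the ladder.
#'
#' @param config A [scenario_config()].
#' @return A [population_state()].
#' @export
initialize_population <- function(config) {
  g <- 3^config$k
  herm <- numeric(g)
  male <- numeric(g)
  n <- config$passage$census_size
  male[1L] <- floor(n / 2)
  herm[1L] <- n - floor(n / 2)
  population_state(herm, male, concentration = config$passage$ladder[1L],
                   generation = 0L)
}

# Scalar observables of a (post-regulation) state.
.state_observables <- function(state, config) {
  total <- sum(state$herm) + sum(state$male)
  if (total <= 0) {
    return(c(n_total = 0, n_herm = 0, n_male = 0, male_fraction = NA_real_,
             stats::setNames(rep(NA_real_, config$k),
                             paste0("freq", seq_len(config$k))),
             mean_hom_loci = NA_real_, shannon = NA_real_))
  }
  freqs <- allele_frequencies(state, config$profiles)
  c(n_total = total, n_herm = sum(state$herm), n_male = sum(state$male),
    male_fraction = sum(state$male) / total,
    stats::setNames(freqs, paste0("freq", seq_len(config$k))),
    mean_hom_loci = mean_homozygous_loci(state, config$profiles),
    shannon = shannon_diversity(state))
}

#' Advance the simulation by one generation
#'
#' Applies, in order: reproduction (selfing + mating egg laying),
#' single-step mutation of offspring, dilution to the census size, and
#' the escalation check (the new concentration applies from the next
#' generation). Observables are computed on the post-regulation
#' population actually passaged.
#'
#' @param state Current [population_state()].
#' @param ls Current [ladder_state()].
#' @param config A [scenario_config()].
#' @return List with `state`, `ladder` (updated), `observables` (named
#'   numeric vector incl. mean egg count), and `extinct`.
#' @export
sim_step <- function(state, ls, config) {
  stochastic <- config$mode == "stochastic"
  off <- reproduce(state, config$profiles, config$ms)
  mean_eggs <- mean_egg_count(state, off$total_eggs)
  off <- apply_mutation(off, config$mu, config$profiles,
                        stochastic = stochastic)
  reg <- regulate(off, config$passage$census_size, stochastic = stochastic)
  gen <- state$generation + 1L
  old_conc <- ls$concentration
  ls <- maybe_escalate(ls, mean_eggs, config$passage, generation = gen)
  if (config$passage$drug_degradation_rate > 0 &&
      ls$concentration == old_conc) {
    # no passage into a fresh rung: the drug decays within the vessel
    ls$concentration <- ls$concentration *
      (1 - config$passage$drug_degradation_rate)
  }
  # offspring experience the (possibly escalated) concentration
  new_state <- population_state(reg$herm, reg$male,
                                concentration = ls$concentration,
                                generation = gen)
  obs <- c(.state_observables(new_state, config), mean_eggs = mean_eggs)
  list(state = new_state, ladder = ls, observables = obs,
       extinct = reg$extinct)
}

#' Run one replicate
#'
#' Deterministic given `(base_seed, replicate_id)`: replicate `r` seeds
#' the generator with `base_seed + r` and all stochastic draws consume
#' it in a fixed order.
#'
#' @param config A [scenario_config()].
#' @param replicate_id Integer replicate index (1-based).
#' @return A `trajectory_record`: list with `trajectory` (data frame, one
#'   row per generation, generation 0 included), `replicate`, `seed`,
#'   `extinct`, `extinction_generation`, `escalations`, `mating_skipped_any`,
#'   and (optionally) `compartments`, a sparse long data frame.
#' @export
run_replicate <- function(config, replicate_id = 1L) {
  seed <- (config$base_seed + as.integer(replicate_id)) %% 2147483647L
  set.seed(seed)
  state <- initialize_population(config)
  ls <- ladder_state(config$passage)
  maxg <- config$passage$max_generations
  k <- config$k

  ncol_obs <- length(.state_observables(state, config)) + 1L
  rows <- matrix(NA_real_, nrow = maxg + 1L, ncol = ncol_obs + 2L)
  obs0 <- c(.state_observables(state, config), mean_eggs = NA_real_)
  colnames(rows) <- c("generation", "concentration", names(obs0))
  rows[1L, ] <- c(0, state$concentration, obs0)
  comp <- if (config$record_compartments) vector("list", maxg + 1L) else NULL
  if (config$record_compartments) comp[[1L]] <- .sparse_compartments(state)

  extinct <- FALSE
  extinction_generation <- NA_integer_
  mating_skipped_any <- FALSE
  last <- 1L
  for (gen in seq_len(maxg)) {
    res <- sim_step(state, ls, config)
    state <- res$state
    ls <- res$ladder
    rows[gen + 1L, ] <- c(gen, state$concentration, res$observables)
    if (config$record_compartments) {
      comp[[gen + 1L]] <- .sparse_compartments(state)
    }
    last <- gen + 1L
    if (res$extinct) {
      extinct <- TRUE
      extinction_generation <- gen
      break
    }
    if (config$stop_when_fixed) {
      fr <- res$observables[paste0("freq", seq_len(k))]
      if (any(fr >= 0.95, na.rm = TRUE)) break
    }
  }
  traj <- as.data.frame(rows[seq_len(last), , drop = FALSE])
  rec <- structure(list(
    trajectory = traj,
    replicate = as.integer(replicate_id),
    seed = seed,
    extinct = extinct,
    extinction_generation = extinction_generation,
    escalations = ls$escalation_generations,
    concentration_final = ls$concentration,
    k = k
  ), class = "trajectory_record")
  if (config$record_compartments) {
    rec$compartments <- do.call(rbind, comp[seq_len(last)])
  }
  rec
}

.sparse_compartments <- function(state) {
  ih <- which(state$herm > 0)
  im <- which(state$male > 0)
  data.frame(
    generation = state$generation,
    sex = c(rep("hermaphrodite", length(ih)), rep("male", length(im))),
    genotype_code = c(ih, im) - 1L,
    count = c(state$herm[ih], state$male[im])
  )
}

#' @export
print.trajectory_record <- function(x, ...) {
  ngen <- nrow(x$trajectory) - 1L
  cat("Trajectory record: replicate", x$replicate, "| seed", x$seed,
      "|", ngen, "generations recorded\n")
  if (x$extinct) cat("  EXTINCT at generation", x$extinction_generation, "\n")
  cat("  final concentration:", x$concentration_final, "nM\n")
  invisible(x)
}

#' Run all replicates of a scenario
#'
#' Replicate `r` is seeded `base_seed + r`; results are identical
#' whether replicates run serially or not.
#'
#' @param config A [scenario_config()].
#' @param replicates Optional override of `config$replicates`.
#' @return A `scenario_result`: list of `trajectory_record`s with the
#'   config and its hash attached.
#' @export
run_scenario <- function(config, replicates = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  n <- if (is.null(replicates)) config$replicates else as.integer(replicates)
  records <- lapply(seq_len(n), function(r) run_replicate(config, r))
  structure(list(records = records, config = config,
                 scenario_hash = scenario_hash(config)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario result:", length(x$records), "replicates | hash",
      x$scenario_hash, "\n")
  ext <- sum(vapply(x$records, function(r) r$extinct, logical(1)))
  cat("  extinct replicates:", ext, "\n")
  invisible(x)
}
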