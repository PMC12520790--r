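# Summary statistics over states and trajectories: allele frequencies,
# homozygous-locus counts, Shannon diversity, fixation times,
# concentration reached, and scenario-level aggregates.

#' Mutant-allele frequencies per locus
#'
#' `freq_j = sum_i count_i * g_ij / (2 * total)`, pooled over sexes.
#'
#' @param state A [population_state()].
#' @param profiles A `strain_profiles` object (supplies the genotype
#'   matrix).
#' @return Numeric k-vector of allele frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(state, profiles) {
  counts <- state$herm + state$male
  total <- sum(counts)
  if (total <= 0) stop("empty population: allele frequencies undefined",
                       call. = FALSE)
  as.vector(counts %*% profiles$genotypes) / (2 * total)
}

#' Mean number of homozygous-mutant loci per individual
#'
#' @param state A [population_state()].
#' @param profiles A `strain_profiles` object.
#' @return Population mean of `#\{j : g_j = 2\}`.
#' @export
mean_homozygous_loci <- function(state, profiles) {
  counts <- state$herm + state$male
  total <- sum(counts)
  if (total <= 0) stop("empty population", call. = FALSE)
  hom <- rowSums(profiles$genotypes == 2L)
  sum(counts * hom) / total
}

#' Shannon diversity of genotype classes
#'
#' `H = -sum f_i ln f_i` over genotype classes with positive frequency,
#' sexes pooled; natural log (nats). `H = 0` when a single genotype is
#' present; the maximum is `ln(3^k)`.
#'
#' @param state A [population_state()].
#' @return Shannon index in nats.
#' @export
shannon_diversity <- function(state) {
  counts <- state$herm + state$male
  total <- sum(counts)
  if (total <= 0) stop("empty population", call. = FALSE)
  f <- counts[counts > 0] / total
  -sum(f * log(f))
}

#' Per-locus fixation times from a trajectory
#'
#' Fixation is defined as the mutant-allele frequency first reaching
#' 0.95 at a locus. Ties between loci crossing in the same generation
#' are broken by locus index.
#'
#' @param record A `trajectory_record` (or its trajectory data frame
#'   with `generation` and `freq*` columns).
#' @param threshold Frequency threshold (default 0.95).
#' @return A `fixation_report` list: `fixation_generation` (k-vector,
#'   `NA` where never crossed), `first_fixation_generation`,
#'   `first_fixed_locus`.
#' @export
fixation_report <- function(record, threshold = 0.95) {
  traj <- if (inherits(record, "trajectory_record")) record$trajectory
          else record
  fcols <- grep("^freq[0-9]+$", names(traj), value = TRUE)
  k <- length(fcols)
  if (k == 0L) stop("trajectory has no allele-frequency columns",
                    call. = FALSE)
  gens <- vapply(fcols, function(cn) {
    i <- which(traj[[cn]] >= threshold)[1L]
    if (is.na(i)) NA_real_ else traj$generation[i]
  }, numeric(1))
  names(gens) <- fcols
  first <- if (all(is.na(gens))) NA_real_ else min(gens, na.rm = TRUE)
  locus <- if (is.na(first)) NA_integer_ else unname(which(gens == first)[1L])
  structure(list(fixation_generation = gens,
                 first_fixation_generation = first,
                 first_fixed_locus = locus,
                 threshold = threshold),
            class = "fixation_report")
}

#' Concentration in force at queried generations
#'
#' Reports the ladder concentration the population experienced at each
#' queried generation: the concentration at which it could survive but
#' (as yet) not produce enough eggs to escalate further.
#'
#' @param record A `trajectory_record`.
#' @param at_generations Generations to query.
#' @return Data frame with `generation`, `concentration` (`NA` if the
#'   replicate ended before that generation) and `extinct_before`.
#' @export
concentration_reached <- function(record,
                                  at_generations = c(10, 25, 100, 250, 500)) {
  traj <- record$trajectory
  out <- data.frame(generation = at_generations,
                    concentration = NA_real_,
                    extinct_before = FALSE)
  for (i in seq_along(at_generations)) {
    g <- at_generations[i]
    row <- which(traj$generation == g)
    if (length(row)) {
      out$concentration[i] <- traj$concentration[row]
    } else if (isTRUE(record$extinct) &&
               !is.na(record$extinction_generation) &&
               record$extinction_generation <= g) {
      out$extinct_before[i] <- TRUE
    }
  }
  out
}

# Box-plot statistics: median, quartiles (linear interpolation between
# order statistics, quantile type 7) and whiskers at 1.5 x IQR.
.box_stats <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    return(c(n = 0, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
             whisker_low = NA_real_, whisker_high = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  wl <- min(x[x >= q[1] - 1.5 * iqr])
  wh <- max(x[x <= q[3] + 1.5 * iqr])
  c(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = wl, whisker_high = wh)
}

#' Aggregate replicate trajectories of one scenario
#'
#' Per-generation mean and standard deviation across surviving
#' replicates of each scalar observable (extinct replicates drop out of
#' the averages after their extinction generation and are counted
#' separately), plus box-plot statistics of first-fixation times and of
#' the concentration reached at snapshot generations.
#'
#' @param result A `scenario_result` or list of `trajectory_record`s.
#' @param at_generations Snapshot generations (default
#'   `c(10, 25, 100, 250, 500)`).
#' @return A `scenario_summary` list with data frames `per_generation`,
#'   `concentration_snapshots`, `fixation`, and the count of extinct
#'   replicates.
#' @export
summarize_scenario <- function(result,
                               at_generations = c(10, 25, 100, 250, 500)) {
  records <- if (inherits(result, "scenario_result")) result$records
             else result
  stopifnot(length(records) >= 1L)
  n_extinct <- sum(vapply(records, function(r) isTRUE(r$extinct), logical(1)))

  long <- do.call(rbind, lapply(records, function(r) {
    tr <- r$trajectory
    tr$replicate <- r$replicate
    tr
  }))
  scalar_cols <- setdiff(names(long), c("generation", "replicate"))
  per_gen <- do.call(rbind, lapply(split(long, long$generation), function(d) {
    out <- data.frame(generation = d$generation[1L],
                      n_replicates = nrow(d))
    for (cn in scalar_cols) {
      v <- d[[cn]]
      out[[paste0(cn, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(cn, "_sd")]] <- stats::sd(v, na.rm = TRUE)
    }
    out
  }))
  per_gen <- per_gen[order(per_gen$generation), ]
  rownames(per_gen) <- NULL

  conc <- do.call(rbind, lapply(records, function(r) {
    cr <- concentration_reached(r, at_generations)
    cr$replicate <- r$replicate
    cr
  }))
  snaps <- do.call(rbind, lapply(split(conc, conc$generation), function(d) {
    bs <- .box_stats(d$concentration)
    data.frame(generation = d$generation[1L],
               extinct_before = sum(d$extinct_before),
               t(bs))
  }))
  rownames(snaps) <- NULL

  fix_times <- vapply(records, function(r) {
    fixation_report(r)$first_fixation_generation
  }, numeric(1))
  fixation <- data.frame(t(.box_stats(fix_times)))
  fixation$n_never_fixed <- sum(is.na(fix_times))

  structure(list(per_generation = per_gen,
                 concentration_snapshots = snaps,
                 fixation = fixation,
                 first_fixation_times = fix_times,
                 n_replicates = length(records),
                 n_extinct = n_extinct),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("Scenario summary over", x$n_replicates, "replicates (",
      x$n_extinct, "extinct )\n")
  cat("Concentration reached at snapshot generations:\n")
  print(x$concentration_snapshots)
  cat("First-fixation time (generations):\n")
  print(x$fixation)
  invisible(x)
}
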