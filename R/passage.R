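# Serial-passage protocol: concentration ladder, escalation rule,
# census regulation (dilution) and extinction detection.

#' Default drug-concentration ladder (nM)
#'
#' Starts drug-free and rises gently enough that wild-type populations
#' survive the early steps; includes the concentrations at which
#' qualitatively distinct plateaus occur under the six-locus effect
#' sizes (10, 24 and 28 nM). The ladder is a first-class configuration
#' input, so any published or experimental escalation sequence can be
#' substituted.
#'
#' @return Numeric vector of concentrations, strictly increasing from 0.
#' @export
default_ladder <- function() {
  c(0, 0.5, 1, 2, 4, 6, 8, 10, 12, 16, 20, 24, 28, 32)
}

#' Serial-passage configuration
#'
#' @param ladder Strictly increasing concentration ladder starting at 0.
#' @param escalation_threshold Mean eggs per individual required to move
#'   one ladder step up (default 20).
#' @param census_size Population size maintained by dilution.
#' @param max_generations Number of generations to simulate.
#' @param drug_degradation_rate Per-generation fractional decay of the
#'   concentration within a passage (default 0: each passage starts at
#'   the nominal ladder concentration).
#' @return A `passage_config` list.
#' @export
passage_config <- function(ladder = default_ladder(),
                           escalation_threshold = 20,
                           census_size = 2000,
                           max_generations = 500,
                           drug_degradation_rate = 0) {
  if (length(ladder) < 1L || ladder[1L] != 0) {
    stop("the concentration ladder must start at 0", call. = FALSE)
  }
  if (any(diff(ladder) <= 0)) {
    stop("the concentration ladder must be strictly increasing", call. = FALSE)
  }
  stopifnot(escalation_threshold > 0, census_size >= 2,
            max_generations >= 1, drug_degradation_rate >= 0,
            drug_degradation_rate < 1)
  structure(list(ladder = as.numeric(ladder),
                 escalation_threshold = escalation_threshold,
                 census_size = as.integer(census_size),
                 max_generations = as.integer(max_generations),
                 drug_degradation_rate = drug_degradation_rate),
            class = "passage_config")
}

#' Ladder state
#'
#' Tracks the current rung of the escalation ladder for one replicate.
#'
#' @param pc A [passage_config()].
#' @return A `ladder_state` list with `step` (1-based rung index),
#'   `concentration`, `escalation_generations`, and `at_ceiling`.
#' @export
ladder_state <- function(pc) {
  structure(list(step = 1L, concentration = pc$ladder[1L],
                 escalation_generations = integer(0),
                 at_ceiling = length(pc$ladder) == 1L),
            class = "ladder_state")
}

#' Mean egg count per adult
#'
#' Eggs laid this generation divided by the number of adults that laid
#' them, with males counted in the denominator (they lay no eggs). This
#' is the quantity the escalation rule compares against its threshold.
#'
#' @param state Parental [population_state()].
#' @param total_eggs Total eggs laid this generation.
#' @return Eggs per adult individual.
#' @export
mean_egg_count <- function(state, total_eggs) {
  adults <- sum(state$herm) + sum(state$male)
  if (adults <= 0) stop("empty population: no adults to average over",
                        call. = FALSE)
  total_eggs / adults
}

#' Escalate the drug concentration when the population is adapted
#'
#' Moves one ladder step up when the mean egg count reaches the
#' escalation threshold and the ladder top has not been reached. The new
#' concentration applies from the next generation.
#'
#' @param ls A [ladder_state()].
#' @param mean_eggs Mean eggs per individual this generation.
#' @param pc A [passage_config()].
#' @param generation Generation at which the check is made (recorded when
#'   an escalation happens).
#' @return Updated `ladder_state`.
#' @export
maybe_escalate <- function(ls, mean_eggs, pc, generation = NA_integer_) {
  stopifnot(inherits(ls, "ladder_state"), inherits(pc, "passage_config"))
  if (mean_eggs >= pc$escalation_threshold && ls$step < length(pc$ladder)) {
    ls$step <- ls$step + 1L
    ls$concentration <- pc$ladder[ls$step]
    ls$escalation_generations <- c(ls$escalation_generations,
                                   as.integer(generation))
  }
  ls$at_ceiling <- ls$step == length(pc$ladder)
  ls
}

#' Dilute offspring to the census size
#'
#' The offspring generation replaces the parental one. When the total
#' exceeds the census size `N`, `N` survivors are drawn multinomially
#' with probabilities proportional to compartment totals; otherwise
#' real-valued expected counts are rounded stochastically (floor plus a
#' Bernoulli on the fractional part), preserving expectations.
#'
#' @param offspring List with `herm` and `male` count vectors.
#' @param N Census size.
#' @param stochastic If `FALSE`, scale deterministically to total `N`
#'   (expectation mode; counts stay real-valued).
#' @return List with integer (or real, expectation mode) `herm`/`male`
#'   vectors and `extinct` flag.
#' @export
regulate <- function(offspring, N, stochastic = TRUE) {
  herm <- offspring$herm
  male <- offspring$male
  total <- sum(herm) + sum(male)
  if (total <= 0) {
    return(list(herm = herm * 0, male = male * 0, extinct = TRUE))
  }
  if (!stochastic) {
    if (total > N) {
      sc <- N / total
      herm <- herm * sc
      male <- male * sc
    }
    return(list(herm = herm, male = male, extinct = FALSE))
  }
  g <- length(herm)
  pool <- c(herm, male)
  if (total > N) {
    counts <- as.numeric(stats::rmultinom(1L, N, pool)[, 1L])
  } else {
    base <- floor(pool)
    frac <- pool - base
    counts <- base + (stats::runif(length(pool)) < frac)
  }
  herm <- counts[seq_len(g)]
  male <- counts[g + seq_len(g)]
  extinct <- sum(counts) == 0
  list(herm = herm, male = male, extinct = extinct)
}
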