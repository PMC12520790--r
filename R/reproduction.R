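# One generation of reproduction in the compartment model.
#
# A fraction xi of hermaphrodites outcrosses with males (when any are
# present); the rest self. Egg numbers scale with the parent's
# pharmacodynamic fitness phi_i(A): egg_selfed * phi when selfing,
# egg_mated * phi when mated. Outcrossed offspring are half male, half
# hermaphrodite; selfed offspring are all hermaphrodite. Drug acts only
# through hermaphrodite egg output; male fitness is not modelled.

#' Mating-system parameters
#'
#' @param xi Fraction of hermaphrodites that reproduce by mating rather
#'   than selfing, in `[0, 1]`. 0 = purely selfing (hermaphroditic),
#'   1 = obligate outcrossing (dioecious), in between = androdioecious.
#' @param egg_mated Mean eggs laid by a mated hermaphrodite at zero drug.
#' @param egg_selfed Mean eggs laid by a selfing hermaphrodite at zero drug.
#' @return A `mating_system` list.
#' @export
mating_system <- function(xi, egg_mated = 1000, egg_selfed = 300) {
  stopifnot(is.numeric(xi), length(xi) == 1L, xi >= 0, xi <= 1,
            egg_mated > 0, egg_selfed > 0)
  structure(list(xi = xi, egg_mated = egg_mated, egg_selfed = egg_selfed),
            class = "mating_system")
}

#' Equilibrium male fraction
#'
#' With males generated only by outcrossing, the expected male fraction
#' among offspring is
#' `f_m = 0.5 * xi * egg_mated / (xi * egg_mated + (1 - xi) * egg_selfed)`,
#' independent of the parental male fraction (as long as males exist).
#'
#' @param ms A [mating_system()] object.
#' @return Expected male fraction in `[0, 0.5]`.
#' @examples
#' expected_male_fraction(mating_system(xi = 1))    # 0.5
#' expected_male_fraction(mating_system(xi = 0.5))  # 0.3846...
#' @export
expected_male_fraction <- function(ms) {
  stopifnot(inherits(ms, "mating_system"))
  denom <- ms$xi * ms$egg_mated + (1 - ms$xi) * ms$egg_selfed
  if (denom <= 0) {
    stop("degenerate mating system: no eggs laid by either route",
         call. = FALSE)
  }
  0.5 * ms$xi * ms$egg_mated / denom
}

#' Expected egg output of one individual
#'
#' @param profiles A `strain_profiles` object.
#' @param code Genotype code of the egg layer.
#' @param A Drug concentration (nM).
#' @param mode `"selfing"` or `"mated"`.
#' @param ms A [mating_system()] object.
#' @return Expected eggs: `egg_selfed * phi_i(A)` or `egg_mated * phi_i(A)`.
#' @export
egg_output <- function(profiles, code, A, mode = c("selfing", "mated"),
                       ms = mating_system(xi = 0.5)) {
  mode <- match.arg(mode)
  base <- if (mode == "selfing") ms$egg_selfed else ms$egg_mated
  base * fitness_at(profiles, A, code = code)
}

#' Population state
#'
#' Counts per (sex x genotype) compartment plus the drug concentration in
#' force. Counts may be real-valued (expected counts, pre-regulation) or
#' integers (post-regulation census).
#'
#' @param herm,male Numeric vectors of length `3^k` over genotype codes.
#' @param concentration Drug concentration (nM).
#' @param generation Generation index.
#' @return A `population_state` list.
#' @export
population_state <- function(herm, male, concentration = 0, generation = 0L) {
  stopifnot(length(herm) == length(male), all(herm >= 0), all(male >= 0))
  structure(list(herm = as.numeric(herm), male = as.numeric(male),
                 concentration = concentration,
                 generation = as.integer(generation)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("Population state at generation", x$generation,
      "| A =", x$concentration, "nM\n")
  cat("  hermaphrodites:", round(sum(x$herm), 2),
      " males:", round(sum(x$male), 2),
      " occupied compartments:", sum(x$herm > 0) + sum(x$male > 0), "\n")
  invisible(x)
}

#' Genotype distribution of the male subpopulation
#'
#' Mating is random with respect to male genotype: a hermaphrodite mates
#' with a male of genotype j with probability equal to j's frequency
#' among males.
#'
#' @param state A [population_state()].
#' @return Normalized frequency vector over genotype codes, or `NULL`
#'   when no males are present (the "no-males" condition; the caller
#'   decides what the mating fraction then does).
#' @export
male_genotype_distribution <- function(state) {
  tot <- sum(state$male)
  if (tot <= 0) return(NULL)
  state$male / tot
}

#' Expected offspring of one generation
#'
#' Selfing: each hermaphrodite class contributes
#' `(1 - xi) * N_i * egg_selfed * phi_i(A)` eggs, distributed over
#' genotypes by Mendelian selfing, all hermaphrodite. Mating: each class
#' contributes `xi * N_i * egg_mated * phi_i(A)` eggs whose genotypes
#' combine one gamete from the egg-weighted hermaphrodite pool with one
#' from a random male (Punnett-square kernels, unlinked loci), split
#' 50/50 male/hermaphrodite. If no males are present the mating fraction
#' contributes nothing that generation.
#'
#' @param state A [population_state()].
#' @param profiles A `strain_profiles` object.
#' @param ms A [mating_system()] object.
#' @return List with `herm` and `male` expected offspring count vectors,
#'   `total_eggs` laid, and `mating_skipped` (TRUE when xi > 0 but no
#'   males were available).
#' @export
reproduce <- function(state, profiles, ms) {
  stopifnot(inherits(state, "population_state"),
            inherits(profiles, "strain_profiles"),
            inherits(ms, "mating_system"))
  tab <- .k_tables(profiles$k)
  phi <- fitness_at(profiles, state$concentration)

  self_w <- (1 - ms$xi) * state$herm * ms$egg_selfed * phi
  herm_off <- if (sum(self_w) > 0) .selfing_offspring(self_w, tab) else
    numeric(length(self_w))

  mate_w <- ms$xi * state$herm * ms$egg_mated * phi
  male_dist <- male_genotype_distribution(state)
  mating_skipped <- FALSE
  male_off <- numeric(length(self_w))
  tot_mate <- sum(mate_w)
  if (tot_mate > 0) {
    if (is.null(male_dist)) {
      mating_skipped <- TRUE
      tot_mate <- 0
    } else {
      hg <- .gamete_distribution(mate_w / tot_mate, tab)
      mg <- .gamete_distribution(male_dist, tab)
      cross <- tot_mate * .combine_gametes(hg, mg, tab)
      herm_off <- herm_off + cross / 2
      male_off <- cross / 2
    }
  }
  list(herm = herm_off, male = male_off,
       total_eggs = sum(self_w) + tot_mate,
       mating_skipped = mating_skipped)
}

#' Apply single-step mutation to offspring counts
#'
#' Immediately after fertilization each offspring mutates with
#' probability `mu`, changing exactly one locus by one allele
#' (0 -> 1, 1 -> 0, 1 -> 2, 2 -> 1). Per (sex x genotype) compartment
#' with `N_i` offspring, the number of mutants is Poisson(`mu * N_i`)
#' capped at `N_i`; mutants are distributed equally (multinomially)
#' among the one-step neighbour genotypes. Totals and sexes conserved.
#'
#' @param offspring List with `herm` and `male` count vectors.
#' @param mu Per-genome mutation probability in `[0, 1)`.
#' @param profiles A `strain_profiles` object.
#' @param stochastic If `FALSE`, move the expected number `mu * N_i`
#'   deterministically with equal fractions to each neighbour
#'   (expectation mode).
#' @return The offspring list with mutated `herm`/`male` counts.
#' @export
apply_mutation <- function(offspring, mu, profiles, stochastic = TRUE) {
  stopifnot(mu >= 0, mu < 1)
  if (mu == 0) return(offspring)
  tab <- .k_tables(profiles$k)
  for (sex in c("herm", "male")) {
    n <- offspring[[sex]]
    active <- which(n > 0)
    if (!length(active)) next
    if (stochastic) {
      m <- stats::rpois(length(active), mu * n[active])
      m <- pmin(m, floor(n[active]))
    } else {
      m <- mu * n[active]
    }
    moved <- which(m > 0)
    if (!length(moved)) next
    for (ii in moved) {
      i <- active[ii]
      nb <- tab$neighbors[[i]]
      n[i] <- n[i] - m[ii]
      if (stochastic) {
        gains <- stats::rmultinom(1L, m[ii], rep(1, length(nb)))[, 1L]
      } else {
        gains <- rep(m[ii] / length(nb), length(nb))
      }
      n[nb] <- n[nb] + gains
    }
    offspring[[sex]] <- n
  }
  offspring
}
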