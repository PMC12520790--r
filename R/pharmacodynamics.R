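# Additive cost/benefit genetics and Hill-type dose-response fitness.
#
# Each expressed mutant locus j adds a fitness cost c_j (drug-free) and an
# EC50 increment b_j (nM). Fitness at drug concentration A follows
#   phi_i(A) = (1 - C_i) * (1 - (A/EC50_i)^kappa / ((A/EC50_i)^kappa + 1)),
# a sigmoid that equals 1 - C_i at A = 0 and half of that at A = EC50_i.

#' Per-locus effect sizes
#'
#' @param costs Numeric k-vector of drug-free fitness costs (fractions) of
#'   an expressed mutant locus.
#' @param benefits Numeric k-vector of EC50 increments (nM) of an
#'   expressed mutant locus.
#' @return An `effect_sizes` list.
#' @export
effect_sizes <- function(costs, benefits) {
  if (length(costs) != length(benefits)) {
    stop("`costs` and `benefits` must have the same length", call. = FALSE)
  }
  if (any(costs < 0) || any(benefits < 0)) {
    stop("costs and benefits must be non-negative", call. = FALSE)
  }
  if (sum(costs) >= 1) {
    stop("total cost across all loci must be < 1 (fitness would be <= 0 ",
         "for the fully expressed genotype)", call. = FALSE)
  }
  structure(list(costs = as.numeric(costs), benefits = as.numeric(benefits)),
            class = "effect_sizes")
}

#' Pharmacodynamic parameters
#'
#' @param ec50_wt EC50 of the sensitive wild-type (nM).
#' @param kappa Hill steepness coefficient (dimensionless). The default of
#'   3 is calibrated so that, with the default concentration ladder and
#'   the six-locus effect sizes, wild-type populations cannot persist at
#'   10 nM without prior adaptation while fully selfing populations
#'   plateau at 24 nM and outcrossing populations at 28 nM; see the
#'   methods vignette.
#' @return A `pd_params` list.
#' @export
pd_params <- function(ec50_wt = 1, kappa = 3) {
  stopifnot(is.numeric(ec50_wt), length(ec50_wt) == 1L, ec50_wt > 0,
            is.numeric(kappa), length(kappa) == 1L, kappa > 0)
  structure(list(ec50_wt = ec50_wt, kappa = kappa), class = "pd_params")
}

#' Strain profiles for every genotype
#'
#' Derives, for each of the `3^k` genotypes, the phenotype under the
#' dominance vector, the total cost `C_i = p_i . c`, total benefit
#' `B_i = p_i . b`, `EC50_i = EC50_wt + B_i`, and drug-free fitness
#' `1 - C_i`. Effects are strictly additive (no epistasis).
#'
#' @param k Number of loci.
#' @param d Dominance vector (0 recessive, 1 dominant per locus).
#' @param effects An [effect_sizes()] object.
#' @param pd A [pd_params()] object.
#' @return A `strain_profiles` list with elements `genotypes` (matrix),
#'   `phenotypes` (matrix), `cost`, `benefit`, `ec50`, `fitness0`
#'   (vectors over genotype codes), plus `k`, `d`, `effects`, `pd`.
#' @examples
#' eff <- effect_sizes(costs = rep(0.05, 2), benefits = rep(0.5, 2))
#' pr <- build_strain_profiles(2, d = c(0, 0), eff, pd_params())
#' as.data.frame(pr)
#' @export
build_strain_profiles <- function(k, d, effects, pd = pd_params()) {
  stopifnot(inherits(effects, "effect_sizes"), inherits(pd, "pd_params"))
  if (length(effects$costs) != k || length(d) != k) {
    stop("`d` and effect-size vectors must have length `k`", call. = FALSE)
  }
  g <- enumerate_genotypes(k)
  p <- phenotype_of(g, d)
  cost <- as.vector(p %*% effects$costs)
  benefit <- as.vector(p %*% effects$benefits)
  if (any(cost >= 1)) {
    stop("an expressed cost combination reaches 1; fitness would be <= 0",
         call. = FALSE)
  }
  structure(list(
    k = k, d = as.integer(d), effects = effects, pd = pd,
    genotypes = g, phenotypes = p,
    cost = cost, benefit = benefit,
    ec50 = pd$ec50_wt + benefit,
    fitness0 = 1 - cost
  ), class = "strain_profiles")
}

#' @export
as.data.frame.strain_profiles <- function(x, ...) {
  data.frame(
    code = seq_len(nrow(x$genotypes)) - 1L,
    genotype = apply(x$genotypes, 1L, paste, collapse = ""),
    cost = x$cost, benefit = x$benefit,
    ec50 = x$ec50, fitness0 = x$fitness0
  )
}

#' @export
print.strain_profiles <- function(x, ...) {
  cat("Strain profiles:", nrow(x$genotypes), "genotypes over", x$k,
      "loci (kappa =", x$pd$kappa, ", wild-type EC50 =", x$pd$ec50_wt,
      "nM)\n")
  df <- as.data.frame(x)
  print(utils::head(df, 10L))
  if (nrow(df) > 10L) cat("...", nrow(df) - 10L, "more genotypes\n")
  invisible(x)
}

#' Fitness at a drug concentration
#'
#' Evaluates the Hill-type dose-response curve for one or all genotypes.
#'
#' @param profiles A `strain_profiles` object.
#' @param A Drug concentration (nM), scalar, `>= 0`.
#' @param code Optional genotype code(s); default all genotypes.
#' @return Numeric vector of fitness values in `[0, 1 - C_i]`.
#' @export
fitness_at <- function(profiles, A, code = NULL) {
  stopifnot(inherits(profiles, "strain_profiles"),
            is.numeric(A), length(A) == 1L)
  if (A < 0) stop("drug concentration must be non-negative", call. = FALSE)
  ec50 <- profiles$ec50
  f0 <- profiles$fitness0
  if (!is.null(code)) {
    ec50 <- ec50[code + 1L]
    f0 <- f0[code + 1L]
  }
  r <- (A / ec50)^profiles$pd$kappa
  f0 * (1 - r / (r + 1))
}
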