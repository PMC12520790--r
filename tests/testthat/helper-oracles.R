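# Independent oracles used across tests.

# Brute-force offspring genotype distribution by enumerating, per parent,
# every way of picking one allele per locus (2^k equally likely gametes
# per parent, 4^k gamete pairs). Parent locus state s carries alleles
# (0,0), (0,1) or (1,1).
oracle_offspring_distribution <- function(parent_a, parent_b) {
  k <- length(parent_a)
  alleles <- function(s) switch(s + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  picks <- as.matrix(expand.grid(rep(list(1:2), k)))
  gametes <- function(parent) {
    out <- matrix(0L, nrow(picks), k)
    for (j in seq_len(k)) {
      out[, j] <- alleles(parent[j])[picks[, j]]
    }
    out
  }
  ga <- gametes(parent_a)
  gb <- gametes(parent_b)
  out <- numeric(3^k)
  for (i in seq_len(nrow(ga))) {
    for (j in seq_len(nrow(gb))) {
      code <- genotype_code(ga[i, ] + gb[j, ])
      out[code + 1L] <- out[code + 1L] + 1
    }
  }
  out / sum(out)
}

# Small helper: the six-locus effect sizes used throughout (three
# small-effect loci then three large-effect loci).
six_locus_effects <- function() {
  effect_sizes(costs = c(rep(0.05, 3), rep(0.10, 3)),
               benefits = c(rep(0.5, 3), rep(3, 3)))
}

six_locus_profiles <- function(dominance = 0, kappa = 3) {
  build_strain_profiles(6, rep(dominance, 6), six_locus_effects(),
                        pd_params(ec50_wt = 1, kappa = kappa))
}

# Final-generation row of a trajectory record.
last_row <- function(record) {
  record$trajectory[nrow(record$trajectory), ]
}
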