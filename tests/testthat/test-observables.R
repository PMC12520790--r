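test_that("allele frequencies pool sexes and count mutant alleles", {
  pr <- build_strain_profiles(2, c(0, 0),
                              effect_sizes(rep(0.05, 2), rep(0.5, 2)),
                              pd_params())
  g <- enumerate_genotypes(2)
  # all wild-type
  st <- population_state(herm = c(100, rep(0, 8)), male = c(100, rep(0, 8)))
  expect_equal(allele_frequencies(st, pr), c(0, 0))
  # everyone homozygous mutant at locus 1
  herm <- numeric(9); herm[genotype_code(c(2, 0)) + 1L] <- 50
  male <- numeric(9); male[genotype_code(c(2, 0)) + 1L] <- 50
  expect_equal(allele_frequencies(population_state(herm, male), pr), c(1, 0))
  # half (0,0), half (2,0): frequency one half at locus 1
  herm2 <- numeric(9); herm2[1] <- 50; herm2[genotype_code(c(2, 0)) + 1L] <- 50
  expect_equal(allele_frequencies(population_state(herm2, numeric(9)), pr),
               c(0.5, 0))
  # heterozygotes count one allele; sexes pooled
  herm3 <- numeric(9); herm3[genotype_code(c(1, 1)) + 1L] <- 10
  male3 <- numeric(9); male3[1] <- 10
  expect_equal(allele_frequencies(population_state(herm3, male3), pr),
               c(0.25, 0.25))
  expect_error(allele_frequencies(population_state(numeric(9), numeric(9)), pr),
               "empty population")
})

test_that("mean homozygous-locus count is the population mean of g_j = 2", {
  pr <- six_locus_profiles()
  G <- 3^6
  full <- genotype_code(rep(2L, 6)) + 1L
  herm <- numeric(G); herm[full] <- 100
  expect_equal(mean_homozygous_loci(population_state(herm, numeric(G)), pr), 6)
  # half with 2 homozygous loci, half with 4: mean 3
  g2 <- genotype_code(c(2L, 2L, 0L, 0L, 0L, 0L)) + 1L
  g4 <- genotype_code(c(2L, 2L, 2L, 2L, 0L, 0L)) + 1L
  herm <- numeric(G); herm[g2] <- 50; herm[g4] <- 50
  expect_equal(mean_homozygous_loci(population_state(herm, numeric(G)), pr), 3)
  # consistency with per-locus homozygote fractions
  set.seed(13)
  counts <- rpois(G, 0.1)
  st <- population_state(counts, rpois(G, 0.05))
  tot <- st$herm + st$male
  frac2 <- colSums((pr$genotypes == 2L) * tot) / sum(tot)
  expect_equal(mean_homozygous_loci(st, pr), sum(frac2))
  expect_lte(mean_homozygous_loci(st, pr), 6)
})

test_that("Shannon diversity spans 0 to ln(3^k) with the right landmarks", {
  G <- 9
  one <- numeric(G); one[4] <- 123
  expect_equal(shannon_diversity(population_state(one, numeric(G))), 0)
  expect_equal(shannon_diversity(population_state(rep(5, G), numeric(G))),
               log(9))
  two <- numeric(G); two[c(2, 7)] <- 50
  expect_equal(shannon_diversity(population_state(two, numeric(G))), log(2))
  # sexes pooled: same genotype split across sexes is one class
  h <- numeric(G); h[1] <- 30
  m <- numeric(G); m[1] <- 70
  expect_equal(shannon_diversity(population_state(h, m)), 0)
  set.seed(9)
  r <- population_state(runif(G), runif(G))
  expect_gte(shannon_diversity(r), 0)
  expect_lte(shannon_diversity(r), log(9))
})

test_that("fixation report finds the first 95% crossing with locus-index ties", {
  traj <- data.frame(
    generation = 0:5,
    freq1 = c(0, 0.2, 0.5, 0.96, 0.97, 1),
    freq2 = c(0, 0.1, 0.2, 0.4, 0.5, 0.9),
    freq3 = c(0, 0.3, 0.96, 0.2, 0.96, 1)
  )
  fr <- fixation_report(traj)
  expect_equal(unname(fr$fixation_generation), c(3, NA, 2))
  expect_equal(fr$first_fixation_generation, 2)
  expect_equal(fr$first_fixed_locus, 3L)
  # tie on the same generation resolves to the lower locus index
  tie <- data.frame(generation = 0:2,
                    freq1 = c(0, 0.5, 0.96), freq2 = c(0, 0.6, 0.99))
  ft <- fixation_report(tie)
  expect_equal(ft$first_fixed_locus, 1L)
  expect_equal(unname(ft$fixation_generation), c(2, 2))
  # never crossing yields an empty report
  flat <- data.frame(generation = 0:3, freq1 = c(0, 0.5, 0.8, 0.9))
  expect_true(is.na(fixation_report(flat)$first_fixation_generation))
  # invariant to subsampling finer than the crossing generation
  sub <- traj[c(1, 3, 4, 6), ]
  expect_equal(fixation_report(sub)$fixation_generation[["freq1"]], 3)
})

test_that("concentration reached reports the rung in force, extinction flagged", {
  rec <- structure(list(
    trajectory = data.frame(generation = 0:12,
                            concentration = c(0, 0, 0.5, 1, 1, 2, 2, 2, 4,
                                              4, 4, 4, 4)),
    extinct = TRUE, extinction_generation = 12L
  ), class = "trajectory_record")
  cr <- concentration_reached(rec, at_generations = c(0, 5, 10, 25))
  expect_equal(cr$concentration, c(0, 2, 4, NA))
  expect_equal(cr$extinct_before, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("scenario summaries aggregate replicates with box statistics", {
  # box stats of 1..100 under the linear-interpolation quantile rule
  bs <- androsim:::.box_stats(1:100)
  expect_equal(unname(bs["median"]), 50.5)
  expect_equal(unname(bs["q1"]), 25.75)
  expect_equal(unname(bs["q3"]), 75.25)
  # identical replicates give zero spread
  cfg <- preset("loci2_recessive_N2000_xi0.5", replicates = 1, base_seed = 3,
                max_generations = 12)
  rec <- run_replicate(cfg, 1)
  sm <- summarize_scenario(list(rec, rec), at_generations = c(5, 10))
  expect_true(all(sm$per_generation$n_total_sd == 0))
  expect_equal(sm$n_replicates, 2)
  expect_equal(sm$n_extinct, 0)
  expect_equal(sm$concentration_snapshots$generation, c(5, 10))
  expect_true(all(sm$concentration_snapshots$n == 2))
  # default snapshots are the five canonical generations
  sm2 <- summarize_scenario(list(rec, rec))
  expect_equal(sm2$concentration_snapshots$generation,
               c(10, 25, 100, 250, 500))
})
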