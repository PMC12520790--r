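test_that("expected male fraction follows the androdioecy formula", {
  expect_equal(expected_male_fraction(mating_system(xi = 1)), 0.5)
  expect_equal(expected_male_fraction(mating_system(xi = 0)), 0)
  expect_equal(expected_male_fraction(mating_system(xi = 0.5)),
               0.5 * 0.5 * 1000 / (0.5 * 1000 + 0.5 * 300))  # 0.384615...
  # monotone in xi, bounded by 1/2
  fms <- vapply(seq(0, 1, 0.1),
                function(x) expected_male_fraction(mating_system(x)),
                numeric(1))
  expect_true(all(diff(fms) > 0))
  expect_true(all(fms >= 0 & fms <= 0.5))
})

test_that("egg output scales fecundity by pharmacodynamic fitness", {
  pr <- six_locus_profiles()
  ms <- mating_system(xi = 0.5)
  expect_equal(egg_output(pr, 0L, A = 0, mode = "mated", ms = ms), 1000)
  expect_equal(egg_output(pr, 0L, A = 0, mode = "selfing", ms = ms), 300)
  # at the genotype's EC50, mated output is half the drug-free maximum
  code <- 728L
  expect_equal(egg_output(pr, code, A = pr$ec50[code + 1L], mode = "mated",
                          ms = ms),
               1000 * pr$fitness0[code + 1L] / 2)
})

test_that("male genotype distribution normalizes counts and flags no males", {
  st <- population_state(herm = c(10, 0, 0), male = c(30, 70, 0))
  expect_equal(male_genotype_distribution(st), c(0.3, 0.7, 0))
  st0 <- population_state(herm = c(10, 0, 0), male = c(0, 0, 0))
  expect_null(male_genotype_distribution(st0))
})

test_that("reproduction splits outcrossed offspring 50/50 and selfed all-hermaphrodite", {
  pr <- build_strain_profiles(2, c(0, 0),
                              effect_sizes(rep(0.05, 2), rep(0.5, 2)),
                              pd_params())
  wt <- population_state(herm = c(100, rep(0, 8)), male = c(100, rep(0, 8)))
  # obligate outcrossing at zero drug: 1000 eggs per hermaphrodite
  off <- reproduce(wt, pr, mating_system(xi = 1))
  expect_equal(sum(off$male), 0.5 * 1000 * 100)
  expect_equal(sum(off$herm), 0.5 * 1000 * 100)
  expect_equal(off$herm[1], 50000)  # all wild-type
  expect_equal(off$total_eggs, 1e5)
  # pure selfing: 300 eggs per hermaphrodite, no males produced
  offs <- reproduce(wt, pr, mating_system(xi = 0))
  expect_equal(sum(offs$male), 0)
  expect_equal(sum(offs$herm), 300 * 100)
  # single heterozygous selfing hermaphrodite, k = 1: Mendelian 1:2:1
  pr1 <- build_strain_profiles(1, 0, effect_sizes(0.05, 0.5), pd_params())
  st1 <- population_state(herm = c(0, 1, 0), male = c(0, 0, 0))
  off1 <- reproduce(st1, pr1, mating_system(xi = 0))
  expect_equal(off1$herm, c(75, 150, 75))
})

test_that("mating fraction lays nothing when no males are present", {
  pr <- build_strain_profiles(1, 0, effect_sizes(0.05, 0.5), pd_params())
  st <- population_state(herm = c(10, 0, 0), male = c(0, 0, 0))
  off <- reproduce(st, pr, mating_system(xi = 0.4))
  expect_true(off$mating_skipped)
  # only the selfing fraction contributes
  expect_equal(off$total_eggs, 0.6 * 10 * 300)
  expect_equal(sum(off$male), 0)
})

test_that("expected crossing offspring equal the pairwise Punnett average", {
  # random mixed population, k = 2: compare the engine's pooled-gamete
  # computation against explicit enumeration over all parent pairs
  set.seed(11)
  pr <- build_strain_profiles(2, c(1, 0),
                              effect_sizes(c(0.05, 0.1), c(0.5, 3)),
                              pd_params())
  g <- enumerate_genotypes(2)
  herm <- runif(9, 0, 50)
  male <- runif(9, 0, 20)
  A <- 2
  st <- population_state(herm, male, concentration = A)
  ms <- mating_system(xi = 1)
  off <- reproduce(st, pr, ms)
  phi <- fitness_at(pr, A)
  w <- herm * 1000 * phi
  fm <- male / sum(male)
  expected <- numeric(9)
  for (i in 1:9) {
    for (j in 1:9) {
      expected <- expected +
        w[i] * fm[j] * offspring_distribution(g[i, ], g[j, ], "crossing")
    }
  }
  expect_equal(off$herm + off$male, expected, tolerance = 1e-10)
  expect_equal(off$herm, off$male)  # 50/50 sex split class by class
})

test_that("offspring follow Hardy-Weinberg under obligate outcrossing", {
  # no drug, no mutation: per-locus offspring genotype frequencies are
  # p^2, 2pq, q^2 for matched parental allele frequencies in both sexes
  pr <- build_strain_profiles(2, c(0, 0),
                              effect_sizes(c(0, 0), c(0.5, 3)), pd_params())
  g <- enumerate_genotypes(2)
  set.seed(5)
  comp <- runif(9); comp <- comp / sum(comp)
  st <- population_state(herm = comp * 1000, male = comp * 500)
  off <- reproduce(st, pr, mating_system(xi = 1))
  tot <- off$herm + off$male
  freq <- tot / sum(tot)
  p <- allele_frequencies(st, pr)
  for (j in 1:2) {
    obs <- vapply(0:2, function(s) sum(freq[g[, j] == s]), numeric(1))
    expect_equal(obs, c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2),
                 tolerance = 1e-12)
  }
})

test_that("selfing halves heterozygosity each generation in expectation", {
  # classic selfing decay: all-heterozygous start, no drug, no cost
  pr <- build_strain_profiles(2, c(0, 0),
                              effect_sizes(c(0, 0), c(0.5, 3)), pd_params())
  g <- enumerate_genotypes(2)
  herm <- numeric(9)
  herm[genotype_code(c(1, 1)) + 1L] <- 1000
  st <- population_state(herm, numeric(9))
  ms <- mating_system(xi = 0)
  for (t in 1:10) {
    off <- reproduce(st, pr, ms)
    reg <- regulate(off, 1000, stochastic = FALSE)
    st <- population_state(reg$herm, reg$male)
    freq <- st$herm / sum(st$herm)
    for (j in 1:2) {
      het <- sum(freq[g[, j] == 1L])
      expect_equal(het, 0.5^t, tolerance = 1e-12)
    }
    # allele frequency itself is conserved at 1/2
    expect_equal(allele_frequencies(st, pr), c(0.5, 0.5), tolerance = 1e-12)
  }
})

test_that("mutation conserves totals per sex and feeds neighbour classes", {
  pr <- build_strain_profiles(2, c(0, 0),
                              effect_sizes(rep(0.05, 2), rep(0.5, 2)),
                              pd_params())
  off <- list(herm = c(1e6, rep(0, 8)), male = c(5e5, rep(0, 8)))
  # mu = 0 leaves counts untouched
  expect_identical(apply_mutation(off, 0, pr), off)
  set.seed(3)
  mut <- apply_mutation(off, 1e-4, pr, stochastic = TRUE)
  expect_equal(sum(mut$herm), 1e6)
  expect_equal(sum(mut$male), 5e5)
  # mutants only reach one-step neighbours of the wild type
  nb <- genotype_code(mutation_neighbors(c(0L, 0L))) + 1L
  touched <- which(mut$herm > 0)
  expect_true(all(touched %in% c(1L, nb)))
  expect_gt(sum(mut$herm[nb]), 0)
  # Poisson mean: with lambda = mu * N = 100 expect roughly 100 movers
  moved <- 1e6 - mut$herm[1]
  expect_gt(moved, 50); expect_lt(moved, 170)
  # expectation mode: exact equal split among the two neighbours
  mexp <- apply_mutation(off, 1e-4, pr, stochastic = FALSE)
  expect_equal(mexp$herm[nb], c(50, 50))
  expect_equal(mexp$herm[1], 1e6 - 100)
})

test_that("realized male fraction converges to the analytic expectation", {
  cfg <- scenario_config(k = 2, dominance = 0, costs = rep(0.05, 2),
                         benefits = rep(0.5, 2), xi = 0.5,
                         census_size = 2000, max_generations = 40,
                         mu = 0, replicates = 1, base_seed = 99)
  rec <- run_replicate(cfg, 1)
  mf <- rec$trajectory$male_fraction[-(1:6)]  # discard burn-in
  expect_equal(mean(mf), expected_male_fraction(cfg$ms), tolerance = 0.02)
})
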