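test_that("mutation-rate estimates match a brute-force Hamming oracle", {
  # hand-checked example
  g <- c(0L, 0L, 0L, 0L)
  off <- rbind(c(0L, 0L, 0L, 1L), c(0L, 0L, 1L, 1L))
  est <- estimate_mutation_rate(g, off)
  expect_equal(est$mu, 1.5)
  # per-site: a site mutated in 3 of 10 offspring has rate 0.3
  off2 <- matrix(0L, 10, 4)
  off2[1:3, 2] <- 1L
  expect_equal(estimate_mutation_rate(g, off2)$per_site[2], 0.3)
  # oracle equivalence on random sets: summed distances agree exactly
  set.seed(19)
  for (rep in 1:10) {
    k <- sample(5:40, 1)
    n <- sample(5:50, 1)
    gr <- rbinom(k, 1, 0.5)
    om <- matrix(rbinom(n * k, 1, 0.3), n, k)
    brute <- sum(vapply(seq_len(n), function(i) sum(om[i, ] != gr), numeric(1)))
    est <- estimate_mutation_rate(gr, om)
    expect_equal(est$mu * n, brute)
    expect_equal(est$mu, sum(est$per_site), tolerance = 1e-9)
    expect_lte(est$mu, k)
  }
  # empty offspring set flags an undefined estimate
  empty <- estimate_mutation_rate(g, matrix(integer(0), 0, 4))
  expect_true(empty$undefined)
  expect_true(is.na(empty$mu))
})

test_that("survival rate is the fraction of buildable decodes", {
  codec <- smoke_codec()
  scaf <- tiny_scaffold()
  g <- encode_genotype(codec, tiny_corpus()[1])
  off <- matrix(rep(g, 6), 6, codec$k, byrow = TRUE)
  v1 <- estimate_survival_rate(off, codec, scaf)
  expect_equal(v1, 1)  # exact copies of a valid encode decode validly
  v2 <- estimate_survival_rate(off, codec, scaf)
  expect_identical(v1, v2)  # deterministic on a fixed offspring set
})

test_that("fitness-effect classes follow the mutant/parent ratio", {
  pairs <- data.frame(
    W_parent = c(0.8, 0.8, 0.8, 0.5, 0),
    W_mutant = c(0, 0.8, 0.9, 0.3, 0.2),
    generation = c(0, 0, 0, 1500, 2)
  )
  dfe <- fitness_effects_dfe(pairs, window_size = 1000L)
  expect_identical(attr(dfe, "n_excluded"), 1L)
  expect_equal(nrow(dfe), 4L)
  w0 <- dfe[dfe$window == 0, ]
  expect_setequal(w0$class, c("lethal", "neutral", "beneficial"))
  expect_equal(sort(w0$effect), c(0, 1, 1.125))
  expect_identical(dfe$class[dfe$window == 1], "deleterious")
  # class proportions sum to one within each window
  for (w in unique(dfe$window)) {
    expect_equal(sum(prop.table(table(dfe$class[dfe$window == w]))), 1)
  }
})

test_that("mutational robustness matches the weighted formula and endpoints", {
  # optimal genotype, all mutants lethal: lambda = 0
  expect_equal(as.numeric(mutational_robustness(1, c(0, 0, 0), c(2, 1, 5))), 0)
  # all mutations neutral: lambda = 1
  expect_equal(as.numeric(mutational_robustness(0.7, rep(0.7, 4), c(1, 2, 3, 4))), 1)
  # weighted evaluation by hand
  expect_equal(as.numeric(mutational_robustness(0.8, c(0.8, 0.3), c(3, 1))),
               1 - 0.5 / 4)
  # no recorded mutants: flagged undefined
  none <- mutational_robustness(0.5, numeric(0), integer(0))
  expect_true(is.na(none))
  expect_true(attr(none, "undefined"))
})

test_that("epistasis fits equal the least-squares oracle", {
  set.seed(33)
  h <- 150L; k <- 6L
  G <- matrix(rbinom(h * k, 1, 0.5), h, k)
  Fv <- 0.6 + 0.03 * G[, 1] - 0.02 * G[, 4] + 0.04 * G[, 2] * G[, 3] +
    rnorm(h, 0, 0.02)
  scan <- epistasis_scan(G, Fv)
  for (pair in list(c(1L, 2L), c(2L, 3L), c(5L, 6L), c(4L, 1L))) {
    i <- pair[1]; j <- pair[2]
    full <- stats::lm(Fv ~ G[, i] * G[, j])
    red <- stats::lm(Fv ~ G[, i] + G[, j])
    row <- scan[scan$i == i & scan$j == j, ]
    expect_lt(abs(row$a_ij - stats::coef(full)[4]), 1e-8)
    expect_lt(abs(row$logLik_full - as.numeric(stats::logLik(full))), 1e-6)
    lrt_oracle <- 2 * (as.numeric(stats::logLik(full)) -
                         as.numeric(stats::logLik(red)))
    expect_lt(abs(row$lrt - lrt_oracle), 1e-6)
  }
  # the scan enumerates ordered pairs, symmetric in the model
  expect_identical(nrow(scan), k * (k - 1L))
  both <- merge(scan, scan, by.x = c("i", "j"), by.y = c("j", "i"))
  expect_equal(both$a_ij.x, both$a_ij.y, tolerance = 1e-10)
})

test_that("the LRT is invariant to affine rescaling of fertility", {
  set.seed(35)
  h <- 120L
  G <- matrix(rbinom(h * 5, 1, 0.5), h, 5)
  Fv <- 0.5 + 0.05 * G[, 1] * G[, 2] + rnorm(h, 0, 0.03)
  s1 <- epistasis_scan(G, Fv)
  s2 <- epistasis_scan(G, 100 * Fv + 7)
  expect_equal(s1$lrt, s2$lrt, tolerance = 1e-8)
  expect_equal(s1$p, s2$p, tolerance = 1e-8)
})

test_that("monomorphic and singular designs are skipped with reasons", {
  set.seed(37)
  G <- matrix(rbinom(60 * 4, 1, 0.5), 60, 4)
  G[, 2] <- 1L                      # monomorphic
  G[, 4] <- G[, 3]                  # duplicate site: singular interaction fit
  Fv <- rnorm(60, 0.8, 0.02)
  scan <- epistasis_scan(G, Fv)
  expect_true(all(scan$skip_reason[scan$i == 2 | scan$j == 2] ==
                    "monomorphic site"))
  r34 <- scan[scan$i == 3 & scan$j == 4, ]
  expect_identical(r34$skip_reason, "singular design")
  expect_identical(attr(scan, "n_tests"), sum(scan$skip_reason == ""))
})

test_that("a planted interaction is recovered and the null is calibrated", {
  # recovery: a_12 = 0.05 at n = 5000, sigma = 0.01
  set.seed(41)
  h <- 5000L; k <- 5L
  G <- matrix(rbinom(h * k, 1, 0.5), h, k)
  Fv <- 0.7 + 0.02 * G[, 1] + 0.01 * G[, 2] + 0.05 * G[, 1] * G[, 2] +
    rnorm(h, 0, 0.01)
  scan <- epistasis_scan(G, Fv)
  r12 <- scan[scan$i == 1 & scan$j == 2, ]
  expect_lt(abs(r12$a_ij - 0.05), 0.01)
  expect_lt(r12$q, 0.05)

  # calibration: under a purely additive model the q < 0.05 discovery
  # fraction stays at or below the FDR level
  set.seed(43)
  n_disc <- 0L; n_tests <- 0L
  for (sim in 1:200) {
    Gn <- matrix(rbinom(200 * 6, 1, 0.5), 200, 6)
    Fn <- 0.6 + Gn %*% rnorm(6, 0, 0.01) + rnorm(200, 0, 0.02)
    sc <- epistasis_scan(Gn, as.numeric(Fn))
    n_disc <- n_disc + sum(sc$q < 0.05, na.rm = TRUE)
    n_tests <- n_tests + attr(sc, "n_tests")
  }
  expect_lte(n_disc / n_tests, 0.05)
})

test_that("trajectories report frequencies, fixation times and richness", {
  # hand-built log: site 1 goes 0.2 -> 0.6 -> 1.0
  mk <- function(freq, n = 10L) {
    ones <- round(freq * n)
    c(rep("100", ones), rep("000", n - ones))
  }
  run <- list(genotypes = list(mk(0.2), mk(0.6), mk(1.0)),
              specs = list(rep("a", 10), rep("a", 10), rep("a", 10)))
  # ancestral allele at site 1 is the generation-0 majority (0)
  tr <- trajectories_and_fixation(run)
  expect_equal(tr$freq[, 1], c(0.2, 0.6, 1.0))
  expect_identical(tr$fixation_time[1], 2L)
  expect_identical(tr$fixation_time_90[1], 2L)
  expect_true(all(is.na(tr$fixation_time[2:3])))

  # perfect replication: derived frequencies stay 0, richness constant
  be <- stub_backend(F = 0.9, V = 1, flip_p = 0, k = 8L)
  pop <- founding_population("x", 12L, codec = NULL, k = 8L)
  run2 <- run_experiment(pop, be, G = 4L, seed = 2L)
  tr2 <- trajectories_and_fixation(run2)
  expect_true(all(tr2$freq == 0))
  expect_true(all(tr2$richness$genotype_richness == 1L))

  # all-distinct genotypes: richness equals N
  distinct <- list(genotypes = list(sprintf("%03d", 1:10)),
                   specs = list(as.character(1:10)))
  expect_identical(
    trajectories_and_fixation(distinct)$richness$genotype_richness, 10L)
})

test_that("repeated evaluation is unbiased and zero-variance for stubs", {
  stub <- stub_individual(F = 0.83, V = 0.9, flip_p = 0.01, k = 16L)
  cyc <- repeated_evaluation(stub, cycles = 12L, seed = 3L)
  expect_equal(cyc$sd_F, 0)
  expect_equal(cyc$sd_V, 0)
  expect_equal(cyc$mean_F, 0.83)
  expect_equal(cyc$mean_W, 0.83 * 0.9)
  expect_equal(cyc$cycles, 12L)
})

test_that("the permutation test is calibrated under the independence null", {
  set.seed(47)
  pvals <- replicate(120, {
    v <- rnorm(25); w <- rnorm(25)
    variation_fitness_test(v, w, n_perm = 199L)$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))  # discrete p ties
  expect_gt(ks$p.value, 0.01)
})

test_that("mutagen comparison recovers planted condition effects", {
  k <- 30L
  X <- array(0, c(400, 4, 4))
  inds <- lapply(1:6, function(i) stub_individual(flip_p = 0, k = k))
  # identical deterministic conditions: ratio exactly 1, t = 0
  same <- mutagen_comparison(inds, X, X,
                             stub_rates = list(a = rep(1, 6), b = rep(1, 6)))
  expect_equal(same$ratio, 1)
  expect_equal(same$t, 0)
  set.seed(51)
  # doubled flip rate under condition B: ratio approximately 2
  mc <- mutagen_comparison(inds, X, X,
                           stub_rates = list(a = rep(0.05, 6),
                                             b = rep(0.10, 6)))
  expect_lt(abs(mc$ratio - 2), 0.2)
  expect_lt(mc$p, 0.05)
  # paired differences sum to mean difference times count
  expect_equal(sum(mc$diff), mean(mc$diff) * length(mc$diff))
  expect_error(mutagen_comparison(inds[1], X, X), "at least 2")
})

test_that("run-level mutation pairs feed a coherent DFE and VMR", {
  be <- stub_backend(F = 0.9, V = 0.9, flip_p = 0.03, k = 16L)
  pop <- founding_population("x", 20L, codec = NULL, k = 16L)
  run <- run_experiment(pop, be, G = 8L, seed = 9L)
  mp <- run_mutation_pairs(run)
  expect_identical(nrow(mp$pairs), 8L * 20L)
  expect_true(all(mp$pairs$n_mutations >= 0))
  expect_identical(nrow(mp$vmr), 8L)
  dfe <- fitness_effects_dfe(stats::na.omit(mp$pairs), window_size = 10L)
  expect_true(all(dfe$effect >= 0))
  expect_true(all(dfe$class %in% c("lethal", "deleterious", "neutral",
                                   "beneficial")))
})
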