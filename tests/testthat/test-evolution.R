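test_that("relative fertility normalizes and rejects degenerate populations", {
  expect_equal(relative_fertility(rep(0.8, 5)), rep(0.2, 5))
  expect_equal(relative_fertility(c(0.9, 0.1)), c(0.9, 0.1))
  set.seed(6)
  F <- runif(50)
  expect_equal(sum(relative_fertility(F)), 1)
  expect_error(relative_fertility(rep(0, 4)), class = "serann_degenerate")
})

test_that("offspring counts are multinomial with the right support and mean", {
  f <- c(0.5, 0.3, 0.2)
  set.seed(8)
  draws <- t(replicate(10000, sample_offspring_counts(f, 20L)))
  expect_true(all(rowSums(draws) == 20L))
  se <- sqrt(20 * f * (1 - f) / 10000)
  expect_true(all(abs(colMeans(draws) - 20 * f) <= 3 * se))
  expect_identical(sample_offspring_counts(c(1, 0, 0), 7L), c(7L, 0L, 0L))
})

test_that("fitness definitions agree with their closed forms", {
  expect_equal(absolute_fitness(1, 0.73), 0.73)
  expect_equal(absolute_fitness(0, 0.9), 0)
  expect_equal(absolute_fitness(0.063, 0.96), 0.06048)
  expect_equal(relative_fitness(1, 0.5, 0.5), 1)
  expect_equal(relative_fitness(1, 0.8, 0.4), 2)
})

test_that("relative fitness predicts expected next-generation frequencies", {
  set.seed(12)
  N <- 40L
  F <- runif(N, 0.2, 1)
  V <- runif(N)
  f <- relative_fertility(F)
  w <- relative_fitness(V, F, mean(F))
  # resampling oracle: simulate newborn multinomial + binomial survival,
  # measure each parent's expected surviving offspring
  sims <- replicate(4000, {
    n_i <- sample_offspring_counts(f, N)
    rbinom(N, n_i, V)
  })
  emp <- rowMeans(sims)
  se <- apply(sims, 1, sd) / sqrt(ncol(sims))
  # E[Ntilde_i] = N V_i f_i = w_i * p_i * N with p_i = 1/N
  expect_true(all(abs(emp - w) <= 3 * se + 0.01))
})

test_that("surviving offspring obey the law of total expectation N*V*f", {
  F <- c(0.9, 0.6, 0.3, 0.9)
  V <- c(1, 0.5, 0.8, 0.2)
  be <- stub_backend(F = F, V = V, flip_p = 0, k = 8L)
  pop <- founding_population("x", 4L, codec = NULL, k = 8L)
  reps <- 3000L
  sums <- matrix(0, reps, 4L)
  for (r in seq_len(reps)) {
    ev <- serann:::backend_evaluate(be, pop, seed = r, gen = 1L,
                                    pool_size = 20L)
    set.seed(derive_seed(r, 31L))
    nxt <- produce_next_generation(ev, be, 4L)
    sums[r, ] <- nxt$record$Ntilde_i
  }
  f <- F / sum(F)
  expected <- 4 * V * f
  se <- apply(sums, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(sums) - expected) <= 3 * se))
})

test_that("population size and frequency mass are conserved every generation", {
  be <- stub_backend(F = 0.9, V = 0.95, flip_p = 0.02, k = 16L)
  pop <- founding_population("x", 24L, codec = NULL, k = 16L)
  run <- run_experiment(pop, be, G = 15L, seed = 3L)
  for (rec in run$records) {
    expect_equal(sum(rec$f), 1, tolerance = 1e-9)
    expect_identical(sum(rec$N_i), 24L)
    expect_true(all(rec$Ntilde_i >= 0 & rec$Ntilde_i <= rec$N_i))
  }
  expect_true(all(vapply(run$genotypes, length, integer(1)) == 24L))
})

test_that("zero-mutation stubs copy parent genotypes exactly", {
  set.seed(21)
  g0 <- rbinom(16L, 1L, 0.5)
  be <- stub_backend(F = 0.8, V = 1, flip_p = 0, k = 16L)
  pop <- founding_population("x", 10L, codec = NULL, k = 16L)
  for (i in seq_along(pop$individuals)) pop$individuals[[i]]$genotype <- g0
  run <- run_experiment(pop, be, G = 5L, seed = 13L)
  anc <- paste(g0, collapse = "")
  for (gen in run$genotypes) expect_true(all(gen == anc))
})

test_that("site frequencies drift without bias when mutation is off", {
  # two genotypes at frequency 1/2; mean final frequency over replicates
  # stays at the initial frequency
  # a quick property check here; the full 2,000-replicate version runs with
  # the acceptance suites
  N <- 16L
  reps <- 500L
  finals <- numeric(reps)
  be <- stub_backend(F = 0.9, V = 1, flip_p = 0, k = 4L)
  half <- c(rep(0L, 4)); alt <- c(rep(1L, 4))
  for (r in seq_len(reps)) {
    pop <- founding_population("x", N, codec = NULL, k = 4L)
    for (i in seq_len(N))
      pop$individuals[[i]]$genotype <- if (i <= N / 2) half else alt
    run <- run_experiment(pop, be, G = 5L, seed = derive_seed(1000L, r))
    finals[r] <- mean(substr(run$genotypes[[6L]], 1L, 1L) == "1")
  }
  se <- sd(finals) / sqrt(reps)
  expect_lt(abs(mean(finals) - 0.5), 3 * se + 0.01)
})

test_that("runs are seed-reproducible and isogenic at generation zero", {
  be <- stub_backend(F = 0.9, V = 0.9, flip_p = 0.05, k = 12L)
  pop <- founding_population("x", 16L, codec = NULL, k = 12L)
  r1 <- run_experiment(pop, be, G = 10L, seed = 5L)
  r2 <- run_experiment(pop, be, G = 10L, seed = 5L)
  expect_identical(r1$genotypes, r2$genotypes)
  expect_identical(length(unique(r1$genotypes[[1L]])), 1L)
  expect_identical(r1$G, 10L)
  expect_length(r1$records, 10L)
})

test_that("ancestor selection prefers candidates with viable descendants", {
  # stub candidates differing in survival: selection must favor the viable one
  be_lo <- stub_backend(F = 0.9, V = 0, flip_p = 0, k = 8L)
  be_hi <- stub_backend(F = 0.9, V = 1, flip_p = 0, k = 8L)
  # a backend whose survival depends on the candidate index is emulated by
  # scoring candidates under their own backends through the same utility
  s_lo <- select_ancestor("a", be_lo, N = 8L, G = 2L, seed = 3L)
  s_hi <- select_ancestor("a", be_hi, N = 8L, G = 2L, seed = 3L)
  expect_equal(s_lo$scores, 0)        # extinct run scores zero
  expect_gt(s_hi$scores, s_lo$scores) # viable descendants win
  expect_identical(s_hi$best, 1L)
})

test_that("impossible survival triggers an extinction error", {
  be <- stub_backend(F = 0.9, V = 0, flip_p = 0, k = 8L)
  pop <- founding_population("x", 8L, codec = NULL, k = 8L)
  expect_error(run_experiment(pop, be, G = 2L, seed = 1L),
               class = "serann_extinction")
})
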