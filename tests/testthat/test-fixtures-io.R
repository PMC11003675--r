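test_that("synthetic images are balanced, bounded and seed-reproducible", {
  cfg <- synthetic_image_config(n_classes = 10L, shape = c(12L, 12L),
                                n_train = 200L, n_eval = 100L)
  d1 <- make_synthetic_images(cfg, seed = 5L)
  d2 <- make_synthetic_images(cfg, seed = 5L)
  expect_identical(d1, d2)
  expect_true(all(d1$train$X >= 0 & d1$train$X <= 1))
  expect_identical(dim(d1$train$X), c(200L, 12L, 12L))
  # sizes divisible by L give exactly balanced label histograms
  expect_true(all(table(d1$train$y) == 20L))
  expect_true(all(table(d1$eval$y) == 10L))
  expect_error(synthetic_image_config(templates = rep(digit_font()[1], 2),
                                      n_classes = 2L),
               "distinct")
})

test_that("a linear classifier separates the glyph classes above chance", {
  cfg <- synthetic_image_config(n_train = 500L, n_eval = 200L)
  data <- make_synthetic_images(cfg, seed = 7L)
  # nearest-centroid classifier (linear decision boundaries)
  n <- dim(data$train$X)[1]
  flat <- matrix(data$train$X, n, 144)
  centroids <- do.call(rbind, lapply(0:9, function(c)
    colMeans(flat[data$train$y == c, , drop = FALSE])))
  ev <- matrix(data$eval$X, dim(data$eval$X)[1], 144)
  d2 <- outer(rowSums(ev^2), rep(1, 10)) - 2 * ev %*% t(centroids) +
    outer(rep(1, nrow(ev)), rowSums(centroids^2))
  pred <- max.col(-d2) - 1L
  acc <- mean(pred == data$eval$y)
  expect_gt(acc, 1 / 10 + 0.2)
})

test_that("IDX image and label files round-trip through write/read", {
  set.seed(9)
  X <- array(runif(2 * 28 * 28), c(2, 28, 28))
  y <- c(3L, 7L)
  img <- withr::local_tempfile(); lab <- withr::local_tempfile()
  write_idx_images(X, img, y, lab)
  back <- read_idx_images(img, lab)
  expect_identical(dim(back$X), c(2L, 28L, 28L))
  expect_equal(back$X, X, tolerance = 1 / 254)  # byte quantization
  expect_identical(back$y, y)
})

test_that("corrupted IDX headers raise format errors", {
  path <- withr::local_tempfile()
  con <- file(path, "wb")
  writeBin(1234L, con, size = 4L, endian = "big")
  writeBin(rep(0L, 10), con, size = 4L)
  close(con)
  expect_error(read_idx_images(path), "magic number mismatch")
})

test_that("population state round-trips with integrity checking", {
  scaf <- tiny_scaffold()
  pop <- founding_population("input ; dense 1 6 ; merge ; alpha 0 . 1 0 0 0 ; output",
                             6L, codec = NULL, scaffold = scaf, k = 24L)
  pop$seed <- 5L
  path <- withr::local_tempfile()
  save_population(pop, path)
  back <- load_population(path, scaf)
  expect_identical(back$generation, pop$generation)
  expect_identical(
    vapply(back$individuals, function(i) paste(i$genotype, collapse = ""), ""),
    vapply(pop$individuals, function(i) paste(i$genotype, collapse = ""), ""))
  # tampering is detected: flip bits inside a stored genotype
  txt <- readLines(path)
  writeLines(sub("000000", "101010", txt, fixed = TRUE), path)
  expect_error(load_population(path, scaf), "checksum mismatch")
})

test_that("resuming a checkpointed run reproduces the uninterrupted run", {
  be <- stub_backend(F = 0.9, V = 0.95, flip_p = 0.03, k = 12L)
  pop <- founding_population("x", 12L, codec = NULL, k = 12L)
  full <- run_experiment(pop, be, G = 8L, seed = 21L)

  dir <- withr::local_tempdir()
  part <- run_experiment(pop, be, G = 4L, seed = 21L, out_dir = dir)
  resumed_pop <- load_population(file.path(dir, "population.json"),
                                 tiny_scaffold())
  # stub runs rebuild stub individuals from genotypes
  for (i in seq_along(resumed_pop$individuals)) {
    g <- resumed_pop$individuals[[i]]$genotype
    resumed_pop$individuals[[i]] <- stub_individual(F = 0.9, V = 0.95,
                                                    flip_p = 0.03,
                                                    k = 12L, genotype = g)
  }
  rest <- run_experiment(resumed_pop, be, G = 4L, seed = 21L)
  expect_identical(rest$genotypes[[5L]], full$genotypes[[9L]])
  # per-generation logs validate against the schema
  log <- read_generation_log(file.path(dir, "generations.jsonl"))
  expect_true(all(log$schema_version == 1L))
  expect_true(all(c("parent_id", "F", "f", "N_i", "Ntilde_i", "W",
                    "generation") %in% names(log)))
})

test_that("genotype FASTA export writes one record per individual", {
  g <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  path <- withr::local_tempfile()
  write_genotypes_fasta(g, generation = 3L, path)
  lines <- readLines(path)
  expect_length(lines, 4L)
  expect_identical(lines[1], ">ind_1 gen_3")
  expect_identical(lines[2], "01")
  expect_identical(lines[4], "10")
})
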