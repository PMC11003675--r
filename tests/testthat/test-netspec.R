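test_that("tokenize/detokenize round-trips and pads to exactly d", {
  v <- default_vocab()
  set.seed(101)
  for (rep in 1:20) {
    spec <- sample_architecture(scaffold = tiny_scaffold(), d = 64L)
    toks <- tokenize(spec$text, v, 64L)
    expect_length(toks$ids, 64L)
    expect_true(all(toks$ids >= 0 & toks$ids < v$r))
    # trailing positions after content are the padding id
    if (toks$content_length < 64L)
      expect_true(all(toks$ids[(toks$content_length + 1L):64L] == v$pad_id))
    expect_identical(detokenize(toks, v), spec$text)
    # tokenize(detokenize(ids)) is also the identity on the id domain
    expect_identical(tokenize(detokenize(toks, v), v, 64L)$ids, toks$ids)
  }
})

test_that("tokenizer rejects unknown lexemes and over-budget content", {
  v <- default_vocab()
  expect_error(tokenize("input ; blob ; output", v, 64L), "unknown lexeme")
  expect_error(tokenize(paste(rep("pool", 30), collapse = " "), v, 16L),
               "exceeds token budget")
})

test_that("vocabulary invariants and plain-text serialization hold", {
  v <- default_vocab()
  expect_gte(v$r, 2L)
  expect_identical(sum(v$tokens == "<pad>"), 1L)
  expect_identical(anyDuplicated(v$tokens), 0L)
  path <- withr::local_tempfile()
  write_vocab(v, path)
  v2 <- read_vocab(path)
  expect_identical(v2$tokens, v$tokens)
  expect_identical(v2$pad_id, v$pad_id)
  expect_error(serann_vocab(c("a", "b")), "padding")
  expect_error(serann_vocab(c("a", "a", "<pad>")), "distinct")
})

test_that("parameter counts match an independent per-layer hand count", {
  scaf <- default_scaffold(image_shape = c(12L, 12L), n_classes = 10L,
                           k = 24L, post_merge_units = 32L)
  # independent oracle: recompute layer by layer with explicit shape algebra
  hand_count <- function(spec, scaf) {
    h <- 12L; w <- 12L; c <- 1L; flat <- NA; total <- 0
    for (l in spec$layers) {
      if (l$type == "conv") {
        total <- total + (3 * 3 * c + 1) * l$filters
        c <- l$filters
      } else if (l$type == "pool") {
        h <- floor(h / 2); w <- floor(w / 2)
      } else {
        n_in <- if (is.na(flat)) h * w * c else flat
        total <- total + (n_in + 1) * l$units
        flat <- l$units
      }
    }
    himg <- if (is.na(flat)) h * w * c else flat
    total + (himg + 24 + 1) * 32 + (32 + 1) * 10 + (32 + 1) * 24
  }
  set.seed(7)
  for (rep in 1:25) {
    spec <- sample_architecture(scaffold = scaf, d = 64L)
    expect_identical(build_network(spec, scaf)$parameter_count,
                     hand_count(spec, scaf))
  }
  # single fully-connected layer with a inputs and b units adds b*(a+1)
  base <- build_network("input ; merge ; alpha 0 . 5 0 0 0 ; output", scaf)
  one <- build_network("input ; dense 1 7 ; merge ; alpha 0 . 5 0 0 0 ; output",
                       scaf)
  a <- 12 * 12
  extra_dense <- 17 * (a + 1)
  # the dense layer changes the merge input width from 144 to 17
  merge_delta <- (17 + 24 + 1) * 32 - (144 + 24 + 1) * 32
  expect_equal(one$parameter_count - base$parameter_count,
               extra_dense + merge_delta)
})

test_that("build_network encodes all failures in the report", {
  scaf <- default_scaffold(image_shape = c(12L, 12L), k = 24L)
  miss_merge <- build_network("input ; conv 4 ; alpha 0 . 1 0 0 0 ; output",
                              scaf)
  expect_false(miss_merge$valid)
  expect_identical(miss_merge$error_kind, "scaffold-violation")

  bad_shape <- build_network(
    "input ; pool ; pool ; pool ; pool ; merge ; alpha 0 . 1 0 0 0 ; output",
    scaf)
  expect_identical(bad_shape$error_kind, "shape-mismatch")

  over_cap <- build_network(
    "input ; dense 9 9 9 9 9 ; merge ; alpha 0 . 1 0 0 0 ; output", scaf)
  expect_identical(over_cap$error_kind, "parameter-cap-exceeded")
  expect_gt(over_cap$parameter_count, 2e6)

  garbled <- build_network("input ; conv x ; merge ; alpha 0 . 1 0 0 0 ; output",
                           scaf)
  expect_identical(garbled$error_kind, "parse-error")
  expect_true(is.na(garbled$parameter_count))

  ok <- build_network("input ; conv 4 ; merge ; alpha 0 . 1 0 0 0 ; output",
                      scaf)
  expect_true(ok$valid)
  expect_identical(ok$error_kind, "none")
})

test_that("build_network is deterministic and pure", {
  scaf <- tiny_scaffold()
  txt <- "input ; conv 8 ; pool ; dense 3 0 ; merge ; alpha 0 . 2 5 0 0 ; output"
  r1 <- build_network(txt, scaf)
  r2 <- build_network(txt, scaf)
  expect_identical(r1, r2)
})

test_that("alpha is parsed at 1e-4 precision and range-checked", {
  sp <- parse_netspec("input ; merge ; alpha 0 . 1 0 2 6 ; output")
  expect_equal(sp$alpha, 0.1026)
  expect_identical(format_netspec(sp), "input ; merge ; alpha 0 . 1 0 2 6 ; output")
  bad <- build_network("input ; merge ; alpha 5 . 0 0 0 0 ; output",
                       tiny_scaffold())
  expect_false(bad$valid)
})
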