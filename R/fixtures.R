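# Synthetic classification data, IDX input, and run-state persistence.
# The glyph generator stands in for the handwritten-digit dataset so the
# whole framework runs and tests offline: noisy digit-glyph templates with
# learnable class structure on a small grayscale grid.

#' Built-in 7x5 digit glyph templates
#'
#' @return list of ten 7x5 binary matrices, one per digit class.
#' @export
digit_font <- function() {
  rows <- c(
    "01110 10001 10011 10101 11001 10001 01110",  # 0
    "00100 01100 00100 00100 00100 00100 01110",  # 1
    "01110 10001 00001 00010 00100 01000 11111",  # 2
    "11111 00010 00100 00010 00001 10001 01110",  # 3
    "00010 00110 01010 10010 11111 00010 00010",  # 4
    "11111 10000 11110 00001 00001 10001 01110",  # 5
    "00110 01000 10000 11110 10001 10001 01110",  # 6
    "11111 00001 00010 00100 01000 01000 01000",  # 7
    "01110 10001 10001 01110 10001 10001 01110",  # 8
    "01110 10001 10001 01111 00001 00010 01100"   # 9
  )
  lapply(rows, function(s) {
    m <- do.call(rbind, lapply(strsplit(s, " ")[[1]], function(r)
      as.integer(strsplit(r, "")[[1]])))
    m  # 7 x 5
  })
}

#' Configuration for the synthetic glyph image generator
#'
#' @param n_classes number of classes L (2..10; templates are digit glyphs).
#' @param shape integer c(rows, cols), at least 9 x 7.
#' @param noise pixel Gaussian noise standard deviation.
#' @param n_train,n_eval set sizes.
#' @param templates optional list of L binary template matrices (pairwise
#'   distinct); defaults to 7x5 digit glyphs.
#' @return list of class `serann_image_config`.
#' @export
synthetic_image_config <- function(n_classes = 10L, shape = c(12L, 12L),
                                   noise = 0.15, n_train = 500L,
                                   n_eval = 200L, templates = NULL) {
  stopifnot(n_classes >= 2, all(shape >= c(9L, 7L)))
  if (is.null(templates)) templates <- digit_font()[seq_len(n_classes)]
  stopifnot(length(templates) == n_classes)
  key <- vapply(templates, function(t) paste(t, collapse = ""), character(1))
  if (anyDuplicated(key)) stop("glyph templates must be pairwise distinct")
  structure(list(n_classes = as.integer(n_classes), shape = as.integer(shape),
                 noise = noise, n_train = as.integer(n_train),
                 n_eval = as.integer(n_eval), templates = templates),
            class = "serann_image_config")
}

render_glyphs <- function(labels, config) {
  m <- config$shape[1]; n <- config$shape[2]
  X <- array(0, c(length(labels), m, n))
  th <- nrow(config$templates[[1]]); tw <- ncol(config$templates[[1]])
  r0 <- (m - th) %/% 2L; c0 <- (n - tw) %/% 2L
  dr <- sample(-1:1, length(labels), replace = TRUE)
  dc <- sample(-1:1, length(labels), replace = TRUE)
  for (i in seq_along(labels)) {
    tpl <- config$templates[[labels[i] + 1L]]
    ri <- r0 + dr[i]; ci <- c0 + dc[i]
    ri <- min(max(ri, 0L), m - th); ci <- min(max(ci, 0L), n - tw)
    X[i, (ri + 1):(ri + th), (ci + 1):(ci + tw)] <- 0.9 * tpl
  }
  X <- X + array(stats::rnorm(length(X), 0, config$noise), dim(X))
  clamp(X, 0, 1)
}

#' Generate synthetic train/eval image sets
#'
#' Labels are exactly balanced whenever the set size is divisible by the
#' class count; images are noisy, jittered glyph templates with values in
#' `[0, 1]`.  Train and eval sets are drawn independently (disjoint noise
#' realizations).
#'
#' @param config a [synthetic_image_config()].
#' @param seed integer seed; the same seed reproduces identical arrays.
#' @return list with `train` and `eval`, each `list(X = array(n, m, n_cols),
#'   y = integer 0-based labels)`.
#' @export
make_synthetic_images <- function(config = synthetic_image_config(), seed = 1L) {
  set.seed(seed)
  bal <- function(n) {
    y <- rep(seq_len(config$n_classes) - 1L, length.out = n)
    sample(y)
  }
  y_tr <- bal(config$n_train); y_ev <- bal(config$n_eval)
  list(train = list(X = render_glyphs(y_tr, config), y = y_tr),
       eval  = list(X = render_glyphs(y_ev, config), y = y_ev))
}

# -- IDX format (optional real-dataset input) --------------------------------

read_idx_header <- function(con, expect_magic) {
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (!identical(magic, expect_magic))
    stop("IDX magic number mismatch: got ", magic, ", expected ", expect_magic)
  magic
}

#' Read images (and optionally labels) in IDX binary format
#'
#' The standard container of the handwritten-digit dataset: big-endian
#' 32-bit header (magic, counts, dimensions) followed by unsigned bytes.
#' Pixel values are scaled to `[0, 1]`.
#'
#' @param image_path path to an IDX3 image file (magic 2051).
#' @param label_path optional path to an IDX1 label file (magic 2049).
#' @return list with `X` (array n x rows x cols) and `y` (integer labels or
#'   NULL).
#' @export
read_idx_images <- function(image_path, label_path = NULL) {
  con <- file(image_path, "rb"); on.exit(close(con), add = TRUE)
  read_idx_header(con, 2051L)
  dims <- readBin(con, "integer", 3L, size = 4L, endian = "big")
  n_px <- prod(dims)
  raw <- readBin(con, "integer", n_px, size = 1L, signed = FALSE)
  if (length(raw) < n_px) stop("IDX image file truncated")
  X <- aperm(array(raw / 255, dim = rev(dims)), 3:1)
  y <- NULL
  if (!is.null(label_path)) {
    lcon <- file(label_path, "rb"); on.exit(close(lcon), add = TRUE)
    read_idx_header(lcon, 2049L)
    n <- readBin(lcon, "integer", 1L, size = 4L, endian = "big")
    y <- readBin(lcon, "integer", n, size = 1L, signed = FALSE)
    if (length(y) < n) stop("IDX label file truncated")
  }
  list(X = X, y = y)
}

#' Write images (and optionally labels) in IDX binary format
#'
#' @param X array `(n, rows, cols)` with values in `[0, 1]`.
#' @param image_path output path for the IDX3 image file.
#' @param y optional integer labels; written to `label_path`.
#' @param label_path output path for the IDX1 label file.
#' @export
write_idx_images <- function(X, image_path, y = NULL, label_path = NULL) {
  dims <- dim(X)
  con <- file(image_path, "wb"); on.exit(close(con), add = TRUE)
  writeBin(2051L, con, size = 4L, endian = "big")
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  bytes <- as.integer(round(aperm(X, 3:1) * 255))
  writeBin(as.raw(bytes), con)
  if (!is.null(y)) {
    lcon <- file(label_path, "wb"); on.exit(close(lcon), add = TRUE)
    writeBin(2049L, lcon, size = 4L, endian = "big")
    writeBin(length(y), lcon, size = 4L, endian = "big")
    writeBin(as.raw(as.integer(y)), lcon)
  }
  invisible(image_path)
}

# -- run-state persistence ----------------------------------------------------

POP_SCHEMA_VERSION <- 1L

#' Save / load population state as checksummed JSON
#'
#' The container records the schema version, the generation index, each
#' individual's genotype and spec, and the full R RNG state, so a run can be
#' resumed mid-stream and reproduce the same subsequent generations.  A
#' polynomial checksum over the payload detects tampering or truncation.
#'
#' @param state a `serann_population` (see [run_experiment()]).
#' @param path file path (JSON).
#' @export
save_population <- function(state, path) {
  payload <- jsonlite::toJSON(list(
    schema_version = POP_SCHEMA_VERSION,
    generation = state$generation,
    n = length(state$individuals),
    genotypes = vapply(state$individuals, function(i)
      paste(i$genotype, collapse = ""), character(1)),
    spec_texts = vapply(state$individuals, function(i)
      i$spec_text %||% "", character(1)),
    parent = state$parent %||% integer(0),
    seed = state$seed,
    rng_state = state$rng_state %||% integer(0)
  ), auto_unbox = TRUE, digits = NA)
  obj <- list(payload = as.character(payload),
              checksum = text_checksum(as.character(payload)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_population
#' @param scaffold scaffold used to rebuild the individuals.
#' @export
load_population <- function(path, scaffold = default_scaffold()) {
  obj <- jsonlite::fromJSON(readLines(path))
  if (!identical(text_checksum(obj$payload), obj$checksum))
    stop("population container checksum mismatch (tampered or truncated)")
  p <- jsonlite::fromJSON(obj$payload)
  if (p$schema_version != POP_SCHEMA_VERSION)
    stop("population container schema version ", p$schema_version,
         " not supported")
  individuals <- lapply(seq_len(p$n), function(i) {
    g <- as.integer(strsplit(p$genotypes[i], "")[[1]])
    serann_individual(g, p$spec_texts[i], scaffold)
  })
  structure(list(individuals = individuals, generation = p$generation,
                 parent = as.integer(p$parent), seed = p$seed,
                 rng_state = as.integer(p$rng_state)),
            class = "serann_population")
}

#' Export a generation's genotypes as FASTA-style records over {0,1}
#'
#' Header lines carry the individual index and generation; sequence lines
#' the genotype bits as characters, for interoperability with sequence
#' tools.
#'
#' @param genotypes integer matrix (individuals x sites).
#' @param generation generation index recorded in the headers.
#' @param path output file.
#' @export
write_genotypes_fasta <- function(genotypes, generation, path) {
  lines <- character(2L * nrow(genotypes))
  for (i in seq_len(nrow(genotypes))) {
    lines[2L * i - 1L] <- sprintf(">ind_%d gen_%d", i, generation)
    lines[2L * i] <- paste(genotypes[i, ], collapse = "")
  }
  writeLines(lines, path)
  invisible(path)
}
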