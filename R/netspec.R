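# The phenotype dialect: a constrained network-specification language.
#
# A specification is a single line of whitespace-separated tokens describing
# the variable part of an individual's architecture.  The scaffold markers
# `input`, `merge` and `output` must each appear exactly once and in order;
# between `input` and `merge` lies the hidden-layer chain; the `alpha`
# statement (between `merge` and `output`) carries the heritable loss weight
# as digit tokens with fixed 1e-4 precision.  Example:
#
#   input ; conv 1 2 ; pool ; dense 6 4 ; merge ; alpha 0 . 1 0 2 6 ; output
#
# Numbers are tokenized digit by digit so that the whole dialect fits in a
# small closed vocabulary, and a replication error in any single token yields
# either a nearby spec or a parse failure ("lethal" mutation).

PAD_TOKEN <- "<pad>"

#' Construct a token vocabulary
#'
#' @param tokens character vector of distinct tokens; must contain exactly one
#'   padding token (`"<pad>"`).
#' @return an object of class `serann_vocab` with fields `tokens` (character),
#'   `r` (vocabulary size) and `pad_id` (0-based id of the padding token).
#' @details Token ids are 0-based: token `tokens[i]` has id `i - 1`, matching
#'   the on-disk format where line number minus one is the id.
#' @export
serann_vocab <- function(tokens) {
  stopifnot(is.character(tokens), length(tokens) >= 2)
  if (anyDuplicated(tokens)) stop("vocabulary tokens must be distinct")
  if (sum(tokens == PAD_TOKEN) != 1L)
    stop("vocabulary must contain exactly one padding token '<pad>'")
  structure(
    list(tokens = tokens, r = length(tokens),
         pad_id = which(tokens == PAD_TOKEN) - 1L),
    class = "serann_vocab"
  )
}

#' @export
print.serann_vocab <- function(x, ...) {
  cat("<serann_vocab> ", x$r, " tokens, padding id ", x$pad_id, "\n", sep = "")
  invisible(x)
}

#' The default specification vocabulary
#'
#' Layer keywords, scaffold markers, digits, punctuation and the padding
#' token. The vocabulary is configuration: any vocabulary covering the
#' dialect's lexemes can be supplied instead.
#'
#' @return a `serann_vocab`.
#' @export
default_vocab <- function() {
  serann_vocab(c(
    "input", "merge", "output", "conv", "pool", "dense", "alpha",
    ";", ".", as.character(0:9), PAD_TOKEN
  ))
}

#' Write / read a vocabulary as plain text, one token per line
#'
#' Line `i` of the file holds the token with integer id `i - 1`.
#'
#' @param vocab a `serann_vocab`.
#' @param path file path.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) serann_vocab(readLines(path))

#' Tokenize a specification string to a fixed-length id sequence
#'
#' Splits on whitespace (one token per lexeme; whitespace is canonical and not
#' significant), maps lexemes to 0-based vocabulary ids, and right-pads with
#' the padding token to exactly `d` ids.
#'
#' @param text specification string.
#' @param vocab a `serann_vocab`.
#' @param d token budget; the returned id vector has length exactly `d`.
#' @return an object of class `serann_tokens`: list with `ids` (integer, length
#'   `d`, values in `[0, r)`), `text` (canonical string) and `content_length`.
#' @export
tokenize <- function(text, vocab, d) {
  stopifnot(inherits(vocab, "serann_vocab"), d >= 1)
  lex <- strsplit(trimws(text), "\\s+")[[1]]
  lex <- lex[nzchar(lex)]
  idx <- match(lex, vocab$tokens)
  if (anyNA(idx)) {
    stop("unknown lexeme(s): ", paste(unique(lex[is.na(idx)]), collapse = " "),
         call. = FALSE)
  }
  if (length(lex) > d) {
    stop("content length ", length(lex), " exceeds token budget d = ", d,
         call. = FALSE)
  }
  ids <- c(idx - 1L, rep(vocab$pad_id, d - length(lex)))
  structure(list(ids = as.integer(ids), text = paste(lex, collapse = " "),
                 content_length = length(lex)),
            class = "serann_tokens")
}

#' Detokenize an id sequence back to a specification string
#'
#' Content stops at the first padding token; remaining ids are ignored.
#'
#' @param ids integer vector of 0-based token ids (or a `serann_tokens`).
#' @param vocab a `serann_vocab`.
#' @return the specification string with canonical single-space separators.
#' @export
detokenize <- function(ids, vocab) {
  if (inherits(ids, "serann_tokens")) ids <- ids$ids
  stopifnot(all(ids >= 0), all(ids < vocab$r))
  first_pad <- match(vocab$pad_id, ids)
  if (!is.na(first_pad)) ids <- ids[seq_len(first_pad - 1L)]
  paste(vocab$tokens[ids + 1L], collapse = " ")
}

# -- parsing ------------------------------------------------------------------

read_number_tokens <- function(lex) {
  # consume leading digit tokens; returns list(value, rest); NULL if none
  n <- 0L
  while (n < length(lex) && grepl("^[0-9]$", lex[n + 1L])) n <- n + 1L
  if (n == 0L) return(NULL)
  list(value = as.integer(paste(lex[seq_len(n)], collapse = "")),
       rest = lex[-seq_len(n)])
}

#' Parse a specification string into a structured network description
#'
#' @param text specification string in the layer dialect.
#' @return an object of class `serann_netspec`: list with `layers` (list of
#'   `list(type, ...)` descriptors for the hidden chain), `alpha` (loss weight
#'   in `[0, 1]`) and `text`; or `NULL` with attribute `error` describing the
#'   failure (use [build_network()] for a structured report).
#' @export
parse_netspec <- function(text) {
  fail <- function(kind, msg) {
    structure(list(NULL), class = "serann_parse_failure",
              error_kind = kind, message_text = msg)
  }
  lex <- strsplit(trimws(text), "\\s+")[[1]]
  lex <- lex[nzchar(lex)]
  stmts <- split(lex, cumsum(lex == ";"))
  stmts <- lapply(stmts, function(s) s[s != ";"])
  stmts <- stmts[vapply(stmts, length, 1L) > 0L]
  kinds <- vapply(stmts, `[`, "", 1L)

  scaffold <- c("input", "merge", "output", "alpha")
  for (s in scaffold) {
    if (sum(kinds == s) != 1L)
      return(fail("scaffold-violation", paste0("'", s, "' must appear exactly once")))
  }
  pos <- match(scaffold, kinds)
  if (!(pos[1] == 1L && pos[2] < pos[4] && pos[4] < pos[3] &&
        pos[3] == length(stmts)))
    return(fail("scaffold-violation", "scaffold markers out of order"))
  if (pos[4] != pos[2] + 1L)
    return(fail("scaffold-violation", "'alpha' must directly follow 'merge'"))

  # alpha: digit '.' digit digit digit digit  (fixed 1e-4 precision)
  a <- stmts[[pos[4]]][-1L]
  if (length(a) != 6L || a[2] != "." ||
      !all(grepl("^[0-9]$", a[-2])))
    return(fail("parse-error", "alpha must be d.dddd in digit tokens"))
  alpha <- as.numeric(paste0(a[1], ".", paste(a[3:6], collapse = "")))
  if (alpha > 1) return(fail("scaffold-violation", "alpha outside [0, 1]"))

  layers <- list()
  hidden <- stmts[seq(2L, pos[2] - 1L)][seq_len(max(0L, pos[2] - 2L))]
  for (st in hidden) {
    type <- st[1]
    rest <- st[-1L]
    if (type == "conv") {
      num <- read_number_tokens(rest)
      if (is.null(num) || length(num$rest))
        return(fail("parse-error", "conv expects one integer (filters)"))
      if (num$value < 1L) return(fail("parse-error", "conv filters must be >= 1"))
      layers[[length(layers) + 1L]] <- list(type = "conv", filters = num$value)
    } else if (type == "dense") {
      num <- read_number_tokens(rest)
      if (is.null(num) || length(num$rest))
        return(fail("parse-error", "dense expects one integer (units)"))
      if (num$value < 1L) return(fail("parse-error", "dense units must be >= 1"))
      layers[[length(layers) + 1L]] <- list(type = "dense", units = num$value)
    } else if (type == "pool") {
      if (length(rest)) return(fail("parse-error", "pool takes no arguments"))
      layers[[length(layers) + 1L]] <- list(type = "pool")
    } else {
      return(fail("parse-error", paste0("unknown layer keyword '", type, "'")))
    }
  }
  structure(list(layers = layers, alpha = alpha, text = paste(lex, collapse = " ")),
            class = "serann_netspec")
}

#' @export
print.serann_netspec <- function(x, ...) {
  cat("<serann_netspec> alpha =", format(x$alpha), "\n")
  for (l in x$layers) {
    extra <- setdiff(names(l), "type")
    cat("  ", l$type,
        if (length(extra)) paste0(" (", paste(extra, "=", unlist(l[extra]),
                                              collapse = ", "), ")"), "\n",
        sep = "")
  }
  invisible(x)
}

#' Render a structured network description back to its canonical spec string
#'
#' @param spec a `serann_netspec` or a list with `layers` and `alpha`.
#' @return the canonical single-line specification string.
#' @export
format_netspec <- function(spec) {
  digits_of <- function(v) paste(strsplit(as.character(v), "")[[1]], collapse = " ")
  parts <- c("input")
  for (l in spec$layers) {
    parts <- c(parts, ";", switch(l$type,
      conv  = paste("conv", digits_of(l$filters)),
      pool  = "pool",
      dense = paste("dense", digits_of(l$units))
    ))
  }
  a <- sprintf("%.4f", spec$alpha)
  parts <- c(parts, ";", "merge", ";",
             paste("alpha", digits_of(substr(a, 1, 1)), ".",
                   paste(strsplit(substr(a, 3, 6), "")[[1]], collapse = " ")),
             ";", "output")
  paste(parts, collapse = " ")
}

# -- building -----------------------------------------------------------------

#' Default architecture scaffold configuration
#'
#' The fixed parts of every individual: image input shape, number of classes,
#' genotype length, width of the fixed post-merge layer, and the trainable
#' parameter cap.
#'
#' @param image_shape integer c(rows, cols) of the grayscale input.
#' @param n_classes number of image classes L.
#' @param k genotype length in bits.
#' @param post_merge_units width of the fixed fully-connected layer after the
#'   merge of the image and genotype branches.
#' @param parameter_cap maximum trainable parameter count; networks above the
#'   cap are flagged `parameter-cap-exceeded`.
#' @return a list of class `serann_scaffold`.
#' @export
default_scaffold <- function(image_shape = c(28L, 28L), n_classes = 10L,
                             k = 100L, post_merge_units = 32L,
                             parameter_cap = 2e6) {
  structure(list(image_shape = as.integer(image_shape),
                 n_classes = as.integer(n_classes), k = as.integer(k),
                 post_merge_units = as.integer(post_merge_units),
                 parameter_cap = parameter_cap),
            class = "serann_scaffold")
}

#' Validate a specification and count its trainable parameters
#'
#' Walks the layer chain, propagating tensor shapes: `conv` is a 3x3
#' same-padded convolution (valid only on a spatial representation), `pool` a
#' 2x2 average pooling (valid only when both spatial extents are at least 2),
#' and `dense` flattens any spatial representation. After the chain the image
#' branch is flattened and concatenated with the k-bit genotype (the merge),
#' followed by the fixed post-merge layer and the two output heads
#' (classification softmax over L classes, replication sigmoid over k bits),
#' whose parameters are included in the count.
#'
#' All failures are encoded in the report, never raised: `parse-error`,
#' `scaffold-violation`, `shape-mismatch`, `parameter-cap-exceeded`, `none`.
#'
#' @param spec a `serann_netspec`, or a specification string (parsed first).
#' @param scaffold a [default_scaffold()] list.
#' @param cap parameter cap; defaults to the scaffold's.
#' @return a list of class `serann_build_report`: `valid` (logical),
#'   `parameter_count` (NA if the spec did not parse) and `error_kind`.
#' @export
build_network <- function(spec, scaffold = default_scaffold(), cap = scaffold$parameter_cap) {
  report <- function(valid, count, kind) {
    structure(list(valid = valid, parameter_count = count, error_kind = kind),
              class = "serann_build_report")
  }
  if (is.character(spec)) spec <- parse_netspec(spec)
  if (inherits(spec, "serann_parse_failure")) {
    return(report(FALSE, NA_real_, attr(spec, "error_kind")))
  }
  stopifnot(inherits(spec, "serann_netspec"))

  shape <- c(scaffold$image_shape, 1L)  # h, w, channels
  spatial <- TRUE
  params <- 0
  for (l in spec$layers) {
    if (l$type == "conv") {
      if (!spatial) return(report(FALSE, NA_real_, "shape-mismatch"))
      params <- params + l$filters * (9 * shape[3] + 1)
      shape[3] <- l$filters
    } else if (l$type == "pool") {
      if (!spatial || min(shape[1:2]) < 2)
        return(report(FALSE, NA_real_, "shape-mismatch"))
      shape[1:2] <- shape[1:2] %/% 2L
    } else if (l$type == "dense") {
      n_in <- if (spatial) prod(shape) else shape[1]
      params <- params + l$units * (n_in + 1)
      shape <- l$units
      spatial <- FALSE
    }
  }
  h_img <- if (spatial) prod(shape) else shape[1]
  p <- scaffold$post_merge_units
  params <- params + p * (h_img + scaffold$k + 1)          # merge -> post layer
  params <- params + scaffold$n_classes * (p + 1)          # classification head
  params <- params + scaffold$k * (p + 1)                  # replication head
  if (params > cap) return(report(FALSE, params, "parameter-cap-exceeded"))
  report(TRUE, params, "none")
}

#' @export
print.serann_build_report <- function(x, ...) {
  cat("<serann_build_report> valid =", x$valid,
      "| parameters =", format(x$parameter_count),
      "| error =", x$error_kind, "\n")
  invisible(x)
}
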