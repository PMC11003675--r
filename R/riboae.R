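# The ribosomal autoencoder ("RiboAE"): the genotype-phenotype codec.  The
# encoder (embedding, three convolutional stages, fully-connected head) maps a
# d-token specification to k Bernoulli parameters phi; during training the
# decoder receives a relaxed Bernoulli sample of phi (reparameterized uniform
# noise through a logistic), at inference the hardened 0/1 genotype.  The
# decoder (fully-connected head, one convolutional layer) emits d score
# vectors over the r vocabulary tokens; softmax rows give the token
# posterior.  The training loss is the negative log-likelihood of the input
# sequence; there is no latent prior / KL term.

#' Relaxed Bernoulli sample (reparameterized, temperature 1)
#'
#' Computes `logistic(log(phi) + log(u) - log(1 - u))` elementwise: a
#' differentiable surrogate for sampling `Bernoulli(phi)`, with the uniform
#' draw `u` supplying the randomness.  `phi = 0` is handled as the limit
#' (output 0); there is no temperature parameter, which is the temperature-1
#' special case of the usual concrete distribution.
#'
#' @param phi numeric vector in `[0, 1]`.
#' @param u numeric vector in `(0, 1)`, same length.
#' @return numeric vector of soft genotype values in `[0, 1)`.
#' @export
concrete_relax <- function(phi, u) {
  stopifnot(length(phi) == length(u), all(phi >= 0), all(phi <= 1),
            all(u > 0), all(u < 1))
  z <- log(phi) + log(u) - log1p(-u)   # log(0) = -Inf gives sigmoid(-Inf) = 0
  sigmoid(z)
}

#' Harden Bernoulli parameters to a binary genotype
#'
#' Bit i is 1 exactly when `phi[i] > 0.5`; the boundary value 0.5 maps to 0.
#'
#' @param phi numeric vector in `[0, 1]`.
#' @return integer vector of 0/1 bits, same length.
#' @export
harden <- function(phi) as.integer(phi > 0.5)

#' Negative log-likelihood of a token sequence under a token posterior
#'
#' `-sum_i log P(s_i | g)`, additive over positions.  Probabilities are
#' clamped below at 1e-12 so a zero posterior at the true token yields a large
#' finite penalty rather than infinity.
#'
#' @param ids integer vector of 0-based true token ids (length d), or a
#'   `serann_tokens`.
#' @param probs numeric d x r matrix of row-stochastic token posteriors.
#' @return non-negative scalar.
#' @export
reconstruction_nll <- function(ids, probs) {
  if (inherits(ids, "serann_tokens")) ids <- ids$ids
  stopifnot(length(ids) == nrow(probs), all(ids >= 0), all(ids < ncol(probs)))
  p <- probs[cbind(seq_along(ids), ids + 1L)]
  -sum(log(pmax(p, 1e-12)))
}

riboae_init_params <- function(r, d, k, emb, ch, dch) {
  d8 <- d %/% 8L
  list(
    Emb = glorot_init(r, emb, c(r, emb)),
    W1 = glorot_init(3 * emb, ch), b1 = numeric(ch),
    W2 = glorot_init(3 * ch, ch),  b2 = numeric(ch),
    W3 = glorot_init(3 * ch, ch),  b3 = numeric(ch),
    We = glorot_init(d8 * ch, k),  be = numeric(k),
    Wd = glorot_init(k, d * dch),  bd = numeric(d * dch),
    Wo = glorot_init(3 * dch, r),  bo = numeric(r)
  )
}

riboae_encode_phi <- function(params, S, d) {
  # S: B x d matrix of 1-based token ids
  B <- nrow(S)
  emb <- ncol(params$Emb)
  x0 <- array(params$Emb[as.vector(S), ], c(B, d, emb))
  c1 <- conv1d_fwd(x0, params$W1, params$b1); h1 <- relu(c1$y); p1 <- pool1d_fwd(h1)
  c2 <- conv1d_fwd(p1, params$W2, params$b2); h2 <- relu(c2$y); p2 <- pool1d_fwd(h2)
  c3 <- conv1d_fwd(p2, params$W3, params$b3); h3 <- relu(c3$y); p3 <- pool1d_fwd(h3)
  flat <- matrix(p3, B, length(p3) / B)
  philog <- sweep(flat %*% params$We, 2L, params$be, `+`)
  list(phi = sigmoid(philog), flat = flat,
       c1 = c1, h1 = h1, c2 = c2, h2 = h2, c3 = c3, h3 = h3, x0 = x0)
}

riboae_decode_scores <- function(params, G, d) {
  # G: B x k matrix of genotype values (hard or relaxed)
  B <- nrow(G)
  dch <- length(params$bd) / d
  hpre <- sweep(G %*% params$Wd, 2L, params$bd, `+`)
  hd <- relu(hpre)
  co <- conv1d_fwd(array(hd, c(B, d, dch)), params$Wo, params$bo)
  list(scores = co$y, hd = hd, hpre = hpre, xc = co$xc)
}

#' Train the ribosomal autoencoder on a specification corpus
#'
#' Mini-batch Adam on the reconstruction negative log-likelihood, in three
#' phases:
#'
#' 1. *Warm-up* (`warmup_epochs`): the uniform draw is held at its median
#'    (`u = 1/2`), so the relaxation is deterministic (`g = phi / (1 + phi)`)
#'    and an input-dependent code can form before noise is introduced.
#' 2. *Stochastic* (the remaining epochs): a fresh relaxed Bernoulli sample
#'    ([concrete_relax()]) of the encoder output feeds the decoder at every
#'    forward pass; replication noise during this phase is what makes the
#'    learned genetic code robust to mutations.
#' 3. *Sharpening* (`sharpen_epochs`, encoder frozen): the decoder alone is
#'    tuned on hardened 0/1 genotypes, the exact representation it receives
#'    at inference.
#'
#' A small L2 penalty (`logit_l2`) on the encoder's pre-sigmoid outputs keeps
#' the Bernoulli parameters off the hard 0/1 boundary during phases 1-2,
#' where the one-sided `log(phi)` relaxation would otherwise trap the encoder
#' in a saturated state with vanishing gradients.
#'
#' Padding positions are included in the loss by default (`mask_padding =
#' TRUE` restricts it to content positions).
#'
#' @param corpus character vector of specification strings.
#' @param vocab a [serann_vocab()].
#' @param k genotype length in bits.
#' @param d padded token-sequence length; must be a multiple of 8 (three
#'   halving pool stages).
#' @param epochs total epochs across all three phases.
#' @param warmup_epochs,sharpen_epochs lengths of phases 1 and 3.
#' @param batch,lr mini-batch size and Adam learning rate.
#' @param logit_l2 L2 coefficient on encoder logits during phases 1-2.
#' @param emb,channels,dec_channels architecture widths (embedding size,
#'   encoder convolution channels, decoder convolution channels).
#' @param mask_padding exclude padding positions from the loss.
#' @param seed integer seed; fixes initialization, shuffling and the uniform
#'   relaxation draws, making the loss trace reproducible.
#' @param verbose print the per-epoch mean NLL.
#' @return an object of class `serann_codec`: parameters, architecture
#'   configuration, the vocabulary, a per-epoch mean-NLL `loss_trace`, and a
#'   vocabulary digest checked on [load_codec()].
#' @export
train_codec <- function(corpus, vocab = default_vocab(), k = 100L, d = 352L,
                        epochs = 450L, warmup_epochs = 150L,
                        sharpen_epochs = 80L, batch = 32L, lr = 3e-3,
                        logit_l2 = 1e-3,
                        emb = 16L, channels = 48L, dec_channels = 48L,
                        mask_padding = FALSE, seed = 1L, verbose = FALSE) {
  stopifnot(d %% 8L == 0L, length(corpus) >= 1,
            warmup_epochs + sharpen_epochs <= epochs)
  set.seed(seed)
  r <- vocab$r
  toks <- lapply(corpus, tokenize, vocab = vocab, d = d)
  S <- do.call(rbind, lapply(toks, function(t) t$ids)) + 1L  # 1-based
  n <- nrow(S)
  params <- riboae_init_params(r, d, k, emb, channels, dec_channels)
  opt <- adam_new(params)
  eps <- 1e-7
  dec_names <- c("Wd", "bd", "Wo", "bo")
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    phase <- if (ep <= warmup_epochs) "warm"
             else if (ep > epochs - sharpen_epochs) "sharpen"
             else "stochastic"
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      Sb <- S[idx, , drop = FALSE]
      B <- nrow(Sb)
      enc <- riboae_encode_phi(params, Sb, d)
      phi <- clamp(enc$phi, eps, 1 - eps)
      if (phase == "sharpen") {
        G <- matrix(as.numeric(enc$phi > 0.5), B, k)
      } else {
        u <- if (phase == "warm") matrix(0.5, B, k)
             else matrix(clamp(stats::runif(B * k), eps, 1 - eps), B, k)
        G <- sigmoid(log(phi) + log(u) - log1p(-u))
      }
      dec <- riboae_decode_scores(params, G, d)
      P <- row_softmax(matrix(dec$scores, B * d, r))
      tgt <- cbind(seq_len(B * d), as.vector(Sb))
      if (mask_padding) {
        w <- as.numeric(as.vector(Sb) != vocab$pad_id + 1L)
      } else w <- rep(1, B * d)
      tot <- tot + sum(-log(pmax(P[tgt], 1e-12)) * w) / n
      # backward
      dS <- P
      dS[tgt] <- dS[tgt] - 1
      dS <- dS * (w / B)
      bo_ <- conv1d_bwd(array(dS, c(B, d, r)), dec$xc, params$Wo)
      dhd <- matrix(bo_$dx, B, length(params$bd)) * (dec$hpre > 0)
      grads <- list(
        Wo = bo_$dW, bo = bo_$db,
        Wd = crossprod(G, dhd), bd = colSums(dhd)
      )
      if (phase == "sharpen") {
        upd <- adam_step(params[dec_names], grads[dec_names],
                         list(m = opt$m[dec_names], v = opt$v[dec_names],
                              t = opt$t), lr = lr)
        params[dec_names] <- upd$params
        opt$m[dec_names] <- upd$state$m
        opt$v[dec_names] <- upd$state$v
        opt$t <- upd$state$t
      } else {
        dG <- dhd %*% t(params$Wd)
        dphi <- dG * G * (1 - G) / phi
        dphilog <- dphi * enc$phi * (1 - enc$phi) +
          (2 * logit_l2 / B) * stats::qlogis(phi)
        grads$We <- crossprod(enc$flat, dphilog)
        grads$be <- colSums(dphilog)
        dflat <- dphilog %*% t(params$We)
        dp3 <- array(dflat, c(B, d %/% 8L, channels))
        dh3 <- pool1d_bwd(dp3, d %/% 4L) * (enc$c3$y > 0)
        b3_ <- conv1d_bwd(dh3, enc$c3$xc, params$W3)
        grads$W3 <- b3_$dW; grads$b3 <- b3_$db
        dh2 <- pool1d_bwd(b3_$dx, d %/% 2L) * (enc$c2$y > 0)
        b2_ <- conv1d_bwd(dh2, enc$c2$xc, params$W2)
        grads$W2 <- b2_$dW; grads$b2 <- b2_$db
        dh1 <- pool1d_bwd(b2_$dx, d) * (enc$c1$y > 0)
        b1_ <- conv1d_bwd(dh1, enc$c1$xc, params$W1)
        grads$W1 <- b1_$dW; grads$b1 <- b1_$db
        dx0 <- matrix(b1_$dx, B * d, emb)
        grads$Emb <- matrix(0, r, emb)
        acc <- rowsum(dx0, group = as.vector(Sb))
        grads$Emb[as.integer(rownames(acc)), ] <- acc
        if (!all(vapply(grads, function(g) all(is.finite(g)), TRUE)))
          stop("train_codec: non-finite gradient (divergent training)")
        upd <- adam_step(params, grads, opt, lr = lr)
        params <- upd$params
        opt <- upd$state
      }
    }
    if (!is.finite(tot)) stop("train_codec: non-finite loss (divergent training)")
    trace[ep] <- tot
    if (verbose) cat(sprintf("epoch %3d [%s]  mean NLL %.4f\n", ep, phase, tot))
  }
  structure(list(params = params, vocab = vocab, k = k, d = d, r = r,
                 emb = emb, channels = channels, dec_channels = dec_channels,
                 mask_padding = mask_padding, epochs = epochs, seed = seed,
                 loss_trace = trace,
                 vocab_digest = text_checksum(vocab$tokens)),
            class = "serann_codec")
}

#' @export
print.serann_codec <- function(x, ...) {
  cat("<serann_codec> k =", x$k, "bits | d =", x$d, "tokens | r =", x$r,
      "\n  trained", x$epochs, "epochs; final mean NLL",
      format(utils::tail(x$loss_trace, 1), digits = 4), "\n")
  invisible(x)
}

#' Encode a specification to a hardened k-bit genotype
#'
#' Deterministic at inference: the Bernoulli parameters are hardened at 0.5,
#' no uniform sampling is involved.
#'
#' @param codec a trained `serann_codec`.
#' @param spec a specification string or a `serann_tokens`.
#' @return integer vector of k bits in `{0, 1}`.
#' @export
encode_genotype <- function(codec, spec) {
  toks <- if (inherits(spec, "serann_tokens")) spec
          else tokenize(spec, codec$vocab, codec$d)
  if (length(toks$ids) != codec$d)
    stop("token sequence length ", length(toks$ids),
         " does not match codec d = ", codec$d)
  S <- matrix(toks$ids + 1L, 1L)
  enc <- riboae_encode_phi(codec$params, S, codec$d)
  harden(as.vector(enc$phi))
}

#' Token posterior of a genotype under the decoder
#'
#' @param codec a trained `serann_codec`.
#' @param g integer vector of k bits (or a matrix, one genotype per row).
#' @return a d x r row-stochastic matrix (or a list of them for a matrix
#'   input): entry (i, l) is the softmax probability of token l at position i.
#' @export
decode_posterior <- function(codec, g) {
  G <- if (is.matrix(g)) g else matrix(g, 1L)
  stopifnot(ncol(G) == codec$k)
  dec <- riboae_decode_scores(codec$params, G, codec$d)
  out <- lapply(seq_len(nrow(G)), function(i) {
    row_softmax(matrix(dec$scores[i, , ], codec$d, codec$r))
  })
  if (is.matrix(g)) out else out[[1L]]
}

#' Decode a genotype to a specification string
#'
#' Takes the argmax token at each of the d positions and truncates the
#' sequence at the first padding token.
#'
#' @param codec a trained `serann_codec`.
#' @param g integer vector of k bits, or a matrix (one genotype per row).
#' @return a specification string (character vector for a matrix input).  The
#'   string is not guaranteed to parse: invalid decodes are how lethal
#'   mutations arise.
#' @export
decode_genotype <- function(codec, g) {
  G <- if (is.matrix(g)) g else matrix(g, 1L)
  stopifnot(ncol(G) == codec$k)
  dec <- riboae_decode_scores(codec$params, G, codec$d)
  out <- vapply(seq_len(nrow(G)), function(i) {
    sc <- matrix(dec$scores[i, , ], codec$d, codec$r)
    ids <- max.col(sc, ties.method = "first") - 1L
    detokenize(ids, codec$vocab)
  }, character(1))
  if (is.matrix(g)) out else out[[1L]]
}

#' Save / load a codec
#'
#' The container embeds a digest of the vocabulary; [load_codec()] refuses to
#' load when the supplied vocabulary does not match the one the codec was
#' trained with.
#'
#' @param codec a `serann_codec`.
#' @param path file path.
#' @param vocab optional vocabulary to check the container against.
#' @export
save_codec <- function(codec, path) {
  saveRDS(codec, path)
  invisible(path)
}

#' @rdname save_codec
#' @export
load_codec <- function(path, vocab = NULL) {
  codec <- readRDS(path)
  if (!inherits(codec, "serann_codec")) stop("not a codec container")
  if (!identical(codec$vocab_digest, text_checksum(codec$vocab$tokens)))
    stop("codec container digest mismatch")
  if (!is.null(vocab) &&
      !identical(text_checksum(vocab$tokens), codec$vocab_digest))
    stop("codec was trained under a different vocabulary")
  codec
}

#' Fraction of single-bit mutants that decode to buildable specifications
#'
#' For each supplied specification, encodes it, flips every bit in turn, and
#' decodes each mutant; reports the fraction of mutants whose decode parses
#' and builds.  A descriptive robustness metric of the learned genetic code.
#'
#' @param codec a trained `serann_codec`.
#' @param specs character vector of specification strings.
#' @param scaffold a [default_scaffold()] for the build check.
#' @return scalar in `[0, 1]`.
#' @export
single_bit_viability <- function(codec, specs, scaffold = default_scaffold()) {
  ok <- 0L; tot <- 0L
  for (s in specs) {
    g <- encode_genotype(codec, s)
    M <- matrix(rep(g, codec$k), codec$k, codec$k, byrow = TRUE)
    diag(M) <- 1L - diag(M)
    dec <- decode_genotype(codec, M)
    ok <- ok + sum(vapply(dec, function(t) build_network(t, scaffold)$valid, TRUE))
    tot <- tot + codec$k
  }
  ok / tot
}
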