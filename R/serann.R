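# The individual replicator: a network built from its specification that is
# trained jointly on image classification (fertility task) and on copying
# genotypes (replication task).  The image branch is the spec's hidden-layer
# chain; its flattened output is concatenated with the k-bit genotype input
# (the merge), passed through the fixed post-merge layer, and read out by two
# heads: a softmax over the L classes and a sigmoid over the k genotype bits.

#' Weighted two-task training loss
#'
#' `alpha * l_X + (1 - alpha) * l_g`, where `l_X` is the categorical cross
#' entropy `-sum_i y_i log(yhat_i)` and `l_g` the mean squared error
#' `(1/k) sum_j (g_j - gprime_j)^2`.  `alpha` is the heritable loss weight:
#' large values favor classification, small values favor replication
#' fidelity (and hence a low mutation rate).
#'
#' @param y one-hot true label vector (length L).
#' @param yhat predicted probability vector (length L); entries at the true
#'   class are clamped below at 1e-12 before the log.
#' @param g,gprime genotype and replicated genotype (length k, values in
#'   `[0, 1]`; `gprime` may be continuous).
#' @param alpha loss weight in `[0, 1]`.
#' @return scalar loss.
#' @export
combined_loss <- function(y, yhat, g, gprime, alpha) {
  stopifnot(length(y) == length(yhat), length(g) == length(gprime),
            alpha >= 0, alpha <= 1)
  l_x <- -sum(y * log(pmax(yhat, 1e-12)))
  l_g <- mean((g - gprime)^2)
  alpha * l_x + (1 - alpha) * l_g
}

# -- network construction -----------------------------------------------------

serann_net_init <- function(spec, scaffold) {
  rep_ <- build_network(spec, scaffold)
  if (!rep_$valid && rep_$error_kind != "parameter-cap-exceeded")
    stop("cannot initialize network: ", rep_$error_kind)
  shape <- c(scaffold$image_shape, 1L)
  spatial <- TRUE
  params <- list()
  meta <- list()
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    nm <- paste0("L", i)
    if (l$type == "conv") {
      params[[paste0(nm, "_W")]] <- glorot_init(9 * shape[3], 9 * l$filters,
                                                c(9 * shape[3], l$filters))
      params[[paste0(nm, "_b")]] <- numeric(l$filters)
      meta[[i]] <- list(type = "conv", in_shape = shape)
      shape[3] <- l$filters
    } else if (l$type == "pool") {
      meta[[i]] <- list(type = "pool", in_shape = shape)
      shape[1:2] <- shape[1:2] %/% 2L
    } else {
      n_in <- if (spatial) prod(shape) else shape[1]
      params[[paste0(nm, "_W")]] <- glorot_init(n_in, l$units)
      params[[paste0(nm, "_b")]] <- numeric(l$units)
      meta[[i]] <- list(type = "dense", in_shape = shape, spatial_in = spatial)
      shape <- l$units
      spatial <- FALSE
    }
  }
  h_img <- if (spatial) prod(shape) else shape[1]
  k <- scaffold$k; L <- scaffold$n_classes; p <- scaffold$post_merge_units
  params$Wp <- glorot_init(h_img + k, p); params$bp <- numeric(p)
  params$Wy <- glorot_init(p, L);         params$by <- numeric(L)
  params$Wg <- glorot_init(p, k);         params$bg <- numeric(k)
  list(params = params, meta = meta, h_img = h_img, scaffold = scaffold,
       alpha = spec$alpha, out_spatial = spatial, out_shape = shape)
}

serann_net_fwd <- function(net, X, G, keep_cache = FALSE) {
  # X: array (B, m, n); G: matrix (B, k)
  B <- dim(X)[1]
  x <- array(X, c(dim(X), 1L))
  cache <- list()
  params <- net$params
  for (i in seq_along(net$meta)) {
    m <- net$meta[[i]]
    nm <- paste0("L", i)
    if (m$type == "conv") {
      maps <- get_conv_index(B, m$in_shape[1], m$in_shape[2])
      cf <- conv2d_fwd(x, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]],
                       maps = maps)
      if (keep_cache) cache[[nm]] <- list(xc = cf$xc, pre = cf$y)
      x <- relu(cf$y)
    } else if (m$type == "pool") {
      x <- pool2d_fwd(x)
    } else {
      xm <- if (m$spatial_in) matrix(x, B, prod(m$in_shape)) else x
      pre <- sweep(xm %*% params[[paste0(nm, "_W")]], 2L,
                   params[[paste0(nm, "_b")]], `+`)
      if (keep_cache) cache[[nm]] <- list(xin = xm, pre = pre)
      x <- relu(pre)
    }
  }
  himg <- if (net$out_spatial) matrix(x, B, net$h_img) else x
  Z <- cbind(himg, G)
  hp_pre <- sweep(Z %*% params$Wp, 2L, params$bp, `+`)
  Hp <- relu(hp_pre)
  ylog <- sweep(Hp %*% params$Wy, 2L, params$by, `+`)
  yhat <- row_softmax(ylog)
  gpre <- sweep(Hp %*% params$Wg, 2L, params$bg, `+`)
  gprime <- sigmoid(gpre)
  out <- list(yhat = yhat, gprime = gprime)
  if (keep_cache) {
    out$cache <- cache
    out$Z <- Z; out$Hp <- Hp; out$hp_pre <- hp_pre; out$gprime_s <- gprime
  }
  out
}

serann_net_bwd <- function(net, fwd, X, G, Y, alpha) {
  B <- nrow(Y)
  k <- ncol(G)
  params <- net$params
  dy <- alpha * (fwd$yhat - Y) / B
  dgpre <- (1 - alpha) * (2 / k) * (fwd$gprime - G) * fwd$gprime *
    (1 - fwd$gprime) / B
  grads <- list(
    Wy = crossprod(fwd$Hp, dy), by = colSums(dy),
    Wg = crossprod(fwd$Hp, dgpre), bg = colSums(dgpre)
  )
  dHp <- (dy %*% t(params$Wy) + dgpre %*% t(params$Wg)) * (fwd$hp_pre > 0)
  grads$Wp <- crossprod(fwd$Z, dHp)
  grads$bp <- colSums(dHp)
  dZ <- dHp %*% t(params$Wp)
  dh <- dZ[, seq_len(net$h_img), drop = FALSE]
  dx <- if (net$out_spatial) {
    array(dh, c(B, net$out_shape))
  } else dh
  for (i in rev(seq_along(net$meta))) {
    m <- net$meta[[i]]
    nm <- paste0("L", i)
    if (m$type == "conv") {
      cc <- fwd$cache[[nm]]
      dx <- dx * (cc$pre > 0)
      maps <- get_conv_index(B, m$in_shape[1], m$in_shape[2])
      bb <- conv2d_bwd(dx, cc$xc, params[[paste0(nm, "_W")]], maps)
      grads[[paste0(nm, "_W")]] <- bb$dW
      grads[[paste0(nm, "_b")]] <- bb$db
      dx <- array(bb$dx, c(B, m$in_shape))
    } else if (m$type == "pool") {
      dx <- pool2d_bwd(dx, m$in_shape[1], m$in_shape[2])
    } else {
      cc <- fwd$cache[[nm]]
      dxm <- dx * (cc$pre > 0)
      grads[[paste0(nm, "_W")]] <- crossprod(cc$xin, dxm)
      grads[[paste0(nm, "_b")]] <- colSums(dxm)
      dx <- dxm %*% t(params[[paste0(nm, "_W")]])
      if (m$spatial_in) dx <- array(dx, c(B, m$in_shape))
    }
  }
  grads
}

# -- individuals --------------------------------------------------------------

#' Construct an (untrained) individual from a genotype and its decoded spec
#'
#' @param genotype integer vector of k bits (may be NULL for a founding
#'   individual specified directly by text).
#' @param spec_text the decoded specification string.
#' @param scaffold a [default_scaffold()].
#' @return an object of class `serann_individual` with the parsed spec, its
#'   build report, the heritable loss weight `alpha`, and empty slots for the
#'   trained network, fertility `F`, survival `V` and fitness `W`.
#' @export
serann_individual <- function(genotype, spec_text, scaffold = default_scaffold()) {
  spec <- parse_netspec(spec_text)
  rep_ <- build_network(if (inherits(spec, "serann_netspec")) spec else spec_text,
                        scaffold)
  structure(list(
    genotype = genotype, spec_text = spec_text,
    spec = if (inherits(spec, "serann_netspec")) spec else NULL,
    build = rep_,
    alpha = if (inherits(spec, "serann_netspec")) spec$alpha else NA_real_,
    net = NULL, F = NA_real_, V = NA_real_, W = NA_real_,
    scaffold = scaffold
  ), class = "serann_individual")
}

#' @export
print.serann_individual <- function(x, ...) {
  cat("<serann_individual>",
      if (!is.null(x$genotype)) paste0(" genotype[", length(x$genotype), "]"),
      " valid=", x$build$valid,
      " alpha=", format(x$alpha),
      " F=", format(x$F), " V=", format(x$V), "\n", sep = "")
  invisible(x)
}

#' Stub individual with fixed fertility, survival and flip rate
#'
#' A non-training replicator used to exercise the evolutionary engine in
#' isolation: fertility is the constant `F`, each offspring survives with
#' probability `V`, and replication flips each genotype bit independently
#' with probability `flip_p` (0 = perfect replication).
#'
#' @param F fertility in `[0, 1]`.
#' @param V offspring survival probability in `[0, 1]`.
#' @param flip_p per-bit flip probability of the replication stub.
#' @param k genotype length.
#' @param genotype optional explicit genotype (defaults to all zeros).
#' @return an object of class `c("serann_stub", "serann_individual")`.
#' @export
stub_individual <- function(F = 0.9, V = 1, flip_p = 0, k = 24L,
                            genotype = integer(k)) {
  structure(list(genotype = as.integer(genotype), F = F, V = V,
                 flip_p = flip_p, alpha = NA_real_,
                 spec_text = "<stub>", build = NULL, net = NULL,
                 W = NA_real_),
            class = c("serann_stub", "serann_individual"))
}

#' Train an individual on the joint classification + replication task
#'
#' Builds the network from the individual's spec (Glorot initialization),
#' pairs each training image with a genotype from the pool (recycled), and
#' runs mini-batch Adam on the combined loss for the configured number of
#' epochs.  If the spec does not build, the individual is returned marked
#' invalid with fertility 0.
#'
#' @param ind a `serann_individual`.
#' @param images array `(n, m, n_cols)` of training images in `[0, 1]`.
#' @param labels integer vector of 0-based class labels (length n).
#' @param genotype_pool matrix `(n_pool, k)` of 0/1 genotypes used as
#'   replication training targets.
#' @param epochs number of passes (conventional default 5).
#' @param batch,lr mini-batch size and Adam learning rate.
#' @param seed integer seed controlling initialization and shuffling.
#' @return the individual with a trained `net` and a `loss_trace` attribute
#'   on the net (per-epoch mean combined loss).
#' @export
train_individual <- function(ind, images, labels, genotype_pool,
                             epochs = 5L, batch = 32L, lr = 2e-3, seed = 1L) {
  stopifnot(inherits(ind, "serann_individual"))
  if (inherits(ind, "serann_stub")) return(ind)
  if (is.null(ind$spec) || !ind$build$valid) {
    if (is.null(ind$spec) ||
        ind$build$error_kind != "parameter-cap-exceeded") {
      ind$F <- 0; ind$net <- NULL
      return(ind)
    }
    # cap-exceeded individuals are sterile but structurally buildable;
    # skip training, fertility is forced to 0
    ind$F <- 0
    return(ind)
  }
  set.seed(seed)
  scaffold <- ind$scaffold
  n <- dim(images)[1]
  k <- scaffold$k; L <- scaffold$n_classes
  G_all <- genotype_pool[((seq_len(n) - 1L) %% nrow(genotype_pool)) + 1L, ,
                         drop = FALSE]
  Y_all <- matrix(0, n, L)
  Y_all[cbind(seq_len(n), labels + 1L)] <- 1
  net <- serann_net_init(ind$spec, scaffold)
  opt <- adam_new(net$params)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      Xb <- images[idx, , , drop = FALSE]
      Gb <- G_all[idx, , drop = FALSE]
      Yb <- Y_all[idx, , drop = FALSE]
      fwd <- serann_net_fwd(net, Xb, Gb, keep_cache = TRUE)
      B <- length(idx)
      l_x <- -sum(log(pmax(fwd$yhat[cbind(seq_len(B), labels[idx] + 1L)],
                           1e-12))) / B
      l_g <- mean((Gb - fwd$gprime)^2)
      tot <- tot + (ind$alpha * l_x + (1 - ind$alpha) * l_g) * B / n
      grads <- serann_net_bwd(net, fwd, Xb, Gb, Yb, ind$alpha)
      upd <- adam_step(net$params, grads, opt, lr = lr)
      net$params <- upd$params
      opt <- upd$state
    }
    trace[ep] <- tot
  }
  attr(net, "loss_trace") <- trace
  ind$net <- net
  ind
}

#' Fertility: classification accuracy on an evaluation set
#'
#' @param ind a trained `serann_individual` (stubs return their fixed `F`).
#' @param images array `(E, m, n)` of evaluation images.
#' @param labels integer vector of 0-based labels.
#' @return accuracy in `[0, 1]`; the fraction of argmax predictions matching
#'   the labels.  Invariant to the order of the evaluation set.
#' @export
evaluate_fertility <- function(ind, images, labels) {
  if (inherits(ind, "serann_stub")) return(ind$F)
  if (is.null(ind$net)) return(0)
  E <- dim(images)[1]
  G0 <- matrix(rep(ind$genotype, each = E), E, ind$scaffold$k)
  fwd <- serann_net_fwd(ind$net, images, G0)
  mean(max.col(fwd$yhat, ties.method = "first") - 1L == labels)
}

#' Self-replication: one offspring genotype per evaluation image
#'
#' The trained individual receives its own genotype paired with each
#' evaluation image and emits a continuous replicated genotype per image,
#' hardened at 0.5 into the offspring pool.  Replication output depends on
#' the paired image because the two tasks share layers, so unusual image
#' inputs act as mutagens.
#'
#' @param ind a trained `serann_individual` (stubs flip bits at their fixed
#'   rate, one offspring per image).
#' @param images array `(E, m, n)` of paired classification inputs.
#' @return integer matrix `(E, k)` of 0/1 offspring genotypes.
#' @export
self_replicate <- function(ind, images) {
  E <- dim(images)[1]
  k <- length(ind$genotype)
  if (inherits(ind, "serann_stub")) {
    flips <- matrix(stats::rbinom(E * k, 1L, ind$flip_p), E, k)
    return(abs(matrix(ind$genotype, E, k, byrow = TRUE) - flips))
  }
  if (is.null(ind$net)) stop("self_replicate: individual is not trained")
  G0 <- matrix(rep(ind$genotype, each = E), E, k)
  fwd <- serann_net_fwd(ind$net, images, G0)
  matrix(as.integer(fwd$gprime > 0.5), E, k)
}
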