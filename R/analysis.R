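# Estimators and statistics over runs: mutation rate and spectrum, offspring
# survival, the distribution of fitness effects, mutational robustness,
# pairwise epistasis, allele-frequency trajectories, repeated evaluation of
# individuals, and the random-image mutagen comparison.

#' Mutation rate as mean Hamming distance to offspring
#'
#' `mu_g = (1/N_g) * sum_j H(g, g'_j)`, with the per-site spectrum the
#' fraction of offspring differing at each site.  By construction `mu_g`
#' equals the sum of the per-site rates.
#'
#' @param g integer parent genotype (k bits).
#' @param offspring integer matrix (N_g x k) of offspring genotypes.
#' @return list of class `serann_mutation_spectrum`: `mu`, `per_site`
#'   (length k), `n_offspring`.  An empty offspring set yields `mu = NA`
#'   with `undefined = TRUE`.
#' @export
estimate_mutation_rate <- function(g, offspring) {
  k <- length(g)
  if (is.null(offspring) || nrow(offspring) == 0L) {
    return(structure(list(mu = NA_real_, per_site = rep(NA_real_, k),
                          n_offspring = 0L, undefined = TRUE),
                     class = "serann_mutation_spectrum"))
  }
  stopifnot(ncol(offspring) == k)
  diff <- offspring != matrix(g, nrow(offspring), k, byrow = TRUE)
  structure(list(mu = mean(rowSums(diff)), per_site = colMeans(diff),
                 n_offspring = nrow(offspring), undefined = FALSE),
            class = "serann_mutation_spectrum")
}

#' @export
print.serann_mutation_spectrum <- function(x, ...) {
  cat("<serann_mutation_spectrum> mu =", format(x$mu),
      "over", x$n_offspring, "offspring\n")
  invisible(x)
}

#' Offspring survival rate
#'
#' The fraction of replicated genotypes that decode to buildable
#' specifications.
#'
#' @param offspring integer matrix of offspring genotypes.
#' @param codec a trained codec.
#' @param scaffold build scaffold (with its parameter cap).
#' @return survival rate V in `[0, 1]`.
#' @export
estimate_survival_rate <- function(offspring, codec,
                                   scaffold = default_scaffold()) {
  stopifnot(nrow(offspring) >= 1)
  texts <- decode_genotype(codec, offspring)
  mean(vapply(texts, function(t) build_network(t, scaffold)$valid, TRUE))
}

#' Distribution of fitness effects of new mutations
#'
#' Fitness effects are the ratio of mutant to parent absolute fitness:
#' 0 is lethal, below 1 deleterious, 1 neutral, above 1 beneficial.  Pairs
#' are sampled per generation window (conventionally 5,000 pairs per
#' 1,000-generation window when data suffice); pairs with zero parent
#' fitness cannot define a ratio and are excluded but counted.
#'
#' @param pairs data.frame with columns `W_parent`, `W_mutant` and
#'   `generation`.
#' @param window_size generations per window.
#' @param per_window maximum sampled pairs per window.
#' @return data.frame of class `serann_dfe` with `effect`, `class`
#'   (lethal/deleterious/neutral/beneficial) and `window`; attribute
#'   `n_excluded` counts zero-parent-fitness pairs.
#' @export
fitness_effects_dfe <- function(pairs, window_size = 1000L,
                                per_window = 5000L) {
  stopifnot(all(c("W_parent", "W_mutant", "generation") %in% names(pairs)))
  excluded <- sum(pairs$W_parent <= 0 | is.na(pairs$W_parent) |
                    is.na(pairs$W_mutant))
  ok <- pairs[!(pairs$W_parent <= 0 | is.na(pairs$W_parent) |
                  is.na(pairs$W_mutant)), , drop = FALSE]
  ok$window <- ok$generation %/% window_size
  out <- do.call(rbind, lapply(split(ok, ok$window), function(w) {
    if (nrow(w) > per_window) w <- w[sample.int(nrow(w), per_window), ]
    w
  }))
  effect <- out$W_mutant / out$W_parent
  cls <- ifelse(effect == 0, "lethal",
         ifelse(effect < 1, "deleterious",
         ifelse(effect == 1, "neutral", "beneficial")))
  res <- data.frame(effect = effect, class = cls, window = out$window,
                    row.names = NULL)
  attr(res, "n_excluded") <- excluded
  class(res) <- c("serann_dfe", "data.frame")
  res
}

#' Mutational robustness of a genotype
#'
#' `lambda(g) = 1 - sum_g' |W_g' - W_g| * M_{g->g'} / sum_g' M_{g->g'}`:
#' one minus the multiplicity-weighted mean absolute fitness change across
#' the genotype's observed mutants.  0 for an optimal genotype (W = 1) whose
#' mutants are all lethal (W = 0); 1 when every mutation is neutral.
#'
#' @param W_g parent absolute fitness.
#' @param W_mutants numeric vector of mutant fitnesses.
#' @param M integer vector of mutant multiplicities (times each mutant was
#'   observed), same length.
#' @return robustness lambda; `NA` with attribute `undefined` when there are
#'   no recorded mutants.
#' @export
mutational_robustness <- function(W_g, W_mutants, M = rep(1L, length(W_mutants))) {
  stopifnot(length(W_mutants) == length(M), all(M >= 0))
  if (length(W_mutants) == 0L || sum(M) == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  1 - sum(abs(W_mutants - W_g) * M) / sum(M)
}

# -- epistasis ----------------------------------------------------------------

#' Pairwise epistasis scan over genotype sites
#'
#' For every ordered pair of distinct sites (i, j), fits the linear model
#' `F = b + a_i g_i + a_j g_j + a_ij g_i g_j` by maximum likelihood under a
#' normal error model (equivalently least squares), refits with the
#' interaction fixed at zero, and tests `a_ij = 0` with a likelihood-ratio
#' test against chi-squared with 1 degree of freedom.  P-values are adjusted
#' across all performed tests with the Benjamini-Hochberg FDR procedure.
#' With 100 polymorphic sites this is 9,900 tests.  The model is symmetric
#' in (i, j); ordered enumeration is the bookkeeping convention.
#'
#' Pairs where either site is monomorphic, or whose four-combination design
#' is singular, are skipped with a reason and excluded from the FDR family.
#'
#' Implementation: all sufficient statistics (site sums, cross tallies,
#' fertility cross products) are precomputed once, so each fit reduces to a
#' 4x4 (or 3x3) normal-equation solve.
#'
#' @param genotypes integer matrix (h x k) of 0/1 genotypes (h > 10).
#' @param fertility numeric vector of length h.
#' @return data.frame of class `serann_epistasis`, one row per ordered pair:
#'   coefficients (`b`, `a_i`, `a_j`, `a_ij`), residual scale `sigma_F`,
#'   log-likelihoods, `lrt`, `p`, `q`, and `skip_reason` (`""` for performed
#'   tests).  Attribute `n_tests` is the number of LRTs performed.
#' @export
epistasis_scan <- function(genotypes, fertility) {
  h <- nrow(genotypes); k <- ncol(genotypes)
  stopifnot(h > 10, length(fertility) == h,
            all(genotypes %in% c(0L, 1L)))
  G <- genotypes
  storage.mode(G) <- "double"
  Fv <- as.numeric(fertility)
  S <- colSums(G)                 # site sums
  Sij <- crossprod(G)             # co-occurrence tallies
  TF <- as.numeric(crossprod(G, Fv))
  Tij <- crossprod(G * Fv, G)     # sum F g_i g_j
  sumF <- sum(Fv); sumF2 <- sum(Fv * Fv)
  poly <- S > 0 & S < h

  n_pairs <- k * (k - 1L)
  ii <- integer(n_pairs); jj <- integer(n_pairs)
  bb <- ai <- aj <- aij <- sg <- ll1 <- ll0 <- lrt <- pv <- rep(NA_real_, n_pairs)
  skip <- character(n_pairs)
  ll <- function(rss) -h / 2 * (log(2 * pi * rss / h) + 1)
  row <- 0L
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      row <- row + 1L
      ii[row] <- i; jj[row] <- j
      if (!poly[i] || !poly[j]) {
        skip[row] <- "monomorphic site"
        next
      }
      si <- S[i]; sj <- S[j]; sij <- Sij[i, j]
      # full design: columns (1, gi, gj, gi*gj)
      XtX <- matrix(c(h,   si,  sj,  sij,
                      si,  si,  sij, sij,
                      sj,  sij, sj,  sij,
                      sij, sij, sij, sij), 4, 4)
      Xty <- c(sumF, TF[i], TF[j], Tij[i, j])
      beta <- tryCatch(solve(XtX, Xty, tol = 1e-12), error = function(e) NULL)
      if (is.null(beta)) {
        skip[row] <- "singular design"
        next
      }
      rss1 <- max(sumF2 - sum(beta * Xty), 0)
      beta0 <- solve(XtX[1:3, 1:3], Xty[1:3])
      rss0 <- max(sumF2 - sum(beta0 * Xty[1:3]), 0)
      bb[row] <- beta[1]; ai[row] <- beta[2]; aj[row] <- beta[3]
      aij[row] <- beta[4]
      sg[row] <- sqrt(rss1 / h)
      ll1[row] <- ll(rss1); ll0[row] <- ll(rss0)
      lrt[row] <- max(2 * (ll1[row] - ll0[row]), 0)
    }
  }
  done <- !nzchar(skip)
  pv[done] <- stats::pchisq(lrt[done], df = 1, lower.tail = FALSE)
  qv <- rep(NA_real_, n_pairs)
  qv[done] <- stats::p.adjust(pv[done], method = "BH")
  res <- data.frame(i = ii, j = jj, b = bb, a_i = ai, a_j = aj, a_ij = aij,
                    sigma_F = sg, logLik_full = ll1, logLik_reduced = ll0,
                    lrt = lrt, p = pv, q = qv, skip_reason = skip)
  attr(res, "n_tests") <- sum(done)
  class(res) <- c("serann_epistasis", "data.frame")
  res
}

#' @export
print.serann_epistasis <- function(x, ...) {
  cat("<serann_epistasis>", attr(x, "n_tests"), "LRTs over",
      nrow(x), "ordered site pairs;",
      sum(x$q < 0.05, na.rm = TRUE), "pairs at q < 0.05\n")
  invisible(x)
}

# -- trajectories -------------------------------------------------------------

#' Allele-frequency trajectories, fixation times, and richness
#'
#' The ancestral allele at each site is the (first) generation-0 majority
#' state; the derived-allele frequency per site per generation, the first
#' generation at which each site reaches the fixation threshold, and the
#' per-generation genotype and phenotype richness are reported.
#'
#' @param run a `serann_run` (or a list with `genotypes` and `specs`
#'   per-generation character vectors).
#' @param threshold fixation threshold on the derived-allele frequency
#'   (default 1.0; 0.9 is a common reporting alternative and is always
#'   exported alongside).
#' @return list of class `serann_trajectories`: `freq` (generations x sites
#'   matrix of derived-allele frequencies), `fixation_time` (per site; NA if
#'   never fixed at `threshold`), `fixation_time_90` (0.9 threshold),
#'   `richness` (per-generation data.frame with genotype and phenotype
#'   counts).
#' @export
trajectories_and_fixation <- function(run, threshold = 1.0) {
  gens <- run$genotypes
  stopifnot(length(gens) >= 1)
  bit_mat <- function(v) {
    do.call(rbind, lapply(strsplit(v, ""), as.integer))
  }
  g0 <- bit_mat(gens[[1L]])
  ancestral <- as.integer(colMeans(g0) > 0.5)
  freq <- do.call(rbind, lapply(gens, function(v) {
    m <- bit_mat(v)
    colMeans(m != matrix(ancestral, nrow(m), ncol(m), byrow = TRUE))
  }))
  fix_at <- function(th) {
    apply(freq, 2L, function(col) {
      w <- which(col >= th)
      if (length(w)) w[1L] - 1L else NA_integer_
    })
  }
  richness <- data.frame(
    generation = seq_along(gens) - 1L,
    genotype_richness = vapply(gens, function(v) length(unique(v)), integer(1)),
    phenotype_richness = vapply(run$specs, function(v)
      length(unique(v)), integer(1))
  )
  structure(list(freq = freq, fixation_time = fix_at(threshold),
                 fixation_time_90 = fix_at(0.9), richness = richness,
                 ancestral = ancestral, threshold = threshold),
            class = "serann_trajectories")
}

#' Mutation counts and parent-offspring fitness pairs from a run
#'
#' Joins each offspring to its parent across consecutive generations,
#' yielding per-transition Hamming distances (mutation counts) and
#' parent/mutant absolute fitness pairs for mutated offspring (inputs to the
#' DFE); also reports the per-generation variance-to-mean ratio of mutation
#' counts.
#'
#' @param run a `serann_run`.
#' @return list with `pairs` (data.frame: `generation`, `parent_id`,
#'   `n_mutations`, `W_parent`, `W_mutant`) and `vmr` (per-generation
#'   variance-to-mean ratio of mutation counts; NA where the mean is 0).
#' @export
run_mutation_pairs <- function(run) {
  G <- length(run$records)
  out <- list()
  vmr <- data.frame(generation = integer(0), vmr = numeric(0))
  for (t in seq_len(G)) {
    par_idx <- run$parent[[t]]
    g_par <- run$genotypes[[t]][par_idx]
    g_off <- run$genotypes[[t + 1L]]
    nm <- mapply(function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, g_par, g_off, USE.NAMES = FALSE)
    m <- mean(nm)
    vmr <- rbind(vmr, data.frame(generation = t - 1L,
                                 vmr = if (m > 0) stats::var(nm) / m else NA_real_))
    W_par <- run$records[[t]]$W[par_idx]
    W_off <- if (t < G) run$records[[t + 1L]]$W else rep(NA_real_, length(g_off))
    out[[t]] <- data.frame(generation = t - 1L, parent_id = par_idx,
                           n_mutations = nm, W_parent = W_par,
                           W_mutant = W_off)
  }
  list(pairs = do.call(rbind, out), vmr = vmr)
}

# -- repeated evaluation ------------------------------------------------------

#' Repeated initialize-train-evaluate cycles for one individual
#'
#' Each cycle re-initializes the network from the random scheme, trains it,
#' evaluates fertility on the evaluation set, and replicates the
#' individual's own genotype to estimate offspring survival; cycles use
#' distinct seed substreams.  The cycle spread (SD of fertility, SD of
#' survival) quantifies phenotypic variation due to developmental noise.
#'
#' @param ind a `serann_individual` (stubs are deterministic: zero spread).
#' @param backend a [serann_backend()] supplying data, codec and schedule
#'   (ignored for stubs).
#' @param cycles number of cycles (>= 1).
#' @param seed integer seed.
#' @return list of class `serann_eval_cycles`: per-cycle `F` and `V`,
#'   summary means and SDs, and the per-cycle mutation rate `mu`.
#' @export
repeated_evaluation <- function(ind, backend = NULL, cycles = 10L, seed = 1L) {
  stopifnot(cycles >= 1)
  if (inherits(ind, "serann_stub")) {
    Fs <- rep(ind$F, cycles); Vs <- rep(ind$V, cycles)
    mus <- rep(length(ind$genotype) * ind$flip_p, cycles)
  } else {
    stopifnot(inherits(backend, "serann_backend"))
    Fs <- Vs <- mus <- numeric(cycles)
    ev <- backend$data$eval
    for (c in seq_len(cycles)) {
      tr <- train_individual(ind, backend$data$train$X, backend$data$train$y,
                             backend$genotype_pool, epochs = backend$epochs,
                             batch = backend$batch, lr = backend$lr,
                             seed = derive_seed(seed, c))
      Fs[c] <- evaluate_fertility(tr, ev$X, ev$y)
      if (is.null(tr$net)) {
        Vs[c] <- 0; mus[c] <- NA_real_
        next
      }
      off <- self_replicate(tr, ev$X)
      val <- backend_validate(backend, off, rep(1L, nrow(off)))
      Vs[c] <- mean(val$valid)
      mus[c] <- estimate_mutation_rate(ind$genotype, off)$mu
    }
  }
  structure(list(F = Fs, V = Vs, mu = mus,
                 mean_F = mean(Fs), sd_F = stats::sd(Fs),
                 mean_V = mean(Vs), sd_V = stats::sd(Vs),
                 mean_W = mean(Fs) * mean(Vs), cycles = cycles),
            class = "serann_eval_cycles")
}

#' @export
print.serann_eval_cycles <- function(x, ...) {
  cat("<serann_eval_cycles>", x$cycles, "cycles | F =",
      round(x$mean_F, 4), "+/-", round(x$sd_F, 4), "| V =",
      round(x$mean_V, 4), "+/-", round(x$sd_V, 4), "\n")
  invisible(x)
}

#' Permutation test for correlation between variation and fitness
#'
#' Pearson correlation between a per-genotype variation measure (e.g. the SD
#' of fertility across evaluation cycles) and mean absolute fitness, with a
#' permutation null for the p-value.
#'
#' @param variation numeric vector (one value per genotype).
#' @param fitness numeric vector, same length.
#' @param n_perm number of permutations.
#' @return list with `rho` (observed correlation) and `p` (two-sided
#'   permutation p-value).
#' @export
variation_fitness_test <- function(variation, fitness, n_perm = 1000L) {
  stopifnot(length(variation) == length(fitness), length(variation) >= 3)
  rho <- stats::cor(variation, fitness)
  perm <- replicate(n_perm, stats::cor(sample(variation), fitness))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p = p)
}

#' Mutagen comparison: mutation rate under two image conditions
#'
#' Replicates the same trained individuals under two input-image conditions
#' (e.g. in-distribution glyphs vs random-pixel images), estimates the
#' mutation rate per condition per individual, and compares them with a
#' paired t-test.  Because the classification and replication tasks share
#' layers, out-of-distribution images act as mutagens.
#'
#' @param individuals list of trained `serann_individual`s (length >= 2), or
#'   stubs with condition-dependent flip rates given via `stub_rates`.
#' @param images_a,images_b arrays of paired images for the two conditions.
#' @param stub_rates optional list with `a` and `b` per-individual flip
#'   rates for stub individuals.
#' @return list of class `serann_mutagen`: per-individual `mu_a`, `mu_b`,
#'   their paired differences, `ratio` of means (b over a), and the paired
#'   t-test (`t`, `p`).
#' @export
mutagen_comparison <- function(individuals, images_a, images_b,
                               stub_rates = NULL) {
  n <- length(individuals)
  if (n < 2) stop("mutagen_comparison needs at least 2 individuals")
  mu_a <- mu_b <- numeric(n)
  for (i in seq_len(n)) {
    ind <- individuals[[i]]
    if (inherits(ind, "serann_stub")) {
      k <- length(ind$genotype)
      E <- dim(images_a)[1]
      ia <- ind; ia$flip_p <- stub_rates$a[[i]]
      ib <- ind; ib$flip_p <- stub_rates$b[[i]]
      mu_a[i] <- estimate_mutation_rate(ind$genotype,
                                        self_replicate(ia, images_a))$mu
      mu_b[i] <- estimate_mutation_rate(ind$genotype,
                                        self_replicate(ib, images_b))$mu
    } else {
      mu_a[i] <- estimate_mutation_rate(ind$genotype,
                                        self_replicate(ind, images_a))$mu
      mu_b[i] <- estimate_mutation_rate(ind$genotype,
                                        self_replicate(ind, images_b))$mu
    }
  }
  d <- mu_b - mu_a
  tt <- if (stats::sd(d) == 0) list(statistic = 0, p.value = 1)
        else stats::t.test(mu_b, mu_a, paired = TRUE)
  structure(list(mu_a = mu_a, mu_b = mu_b, diff = d,
                 ratio = mean(mu_b) / mean(mu_a),
                 t = unname(tt$statistic), p = tt$p.value),
            class = "serann_mutagen")
}

#' @export
print.serann_mutagen <- function(x, ...) {
  cat("<serann_mutagen> rate ratio (B/A) =", round(x$ratio, 3),
      "| paired t =", round(x$t, 3), " p =", format.pval(x$p), "\n")
  invisible(x)
}
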