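# The Wright-Fisher engine: fertility selection, multinomial drift, offspring
# drawn from each parent's replicated-genotype pool, decoding, and survival
# filtering of offspring whose specs fail to build.  Population size N is
# constant and generations do not overlap.  Invalid offspring are replaced by
# conditional resampling (redraw a parent proportional to relative fertility
# and one member of its pool) within a retry budget of 50 * N draws, which
# preserves E[surviving offspring of i] proportional to V_i * f_i.

#' Relative fertility
#'
#' `f_i = F_i / sum(F)`.  All-zero fertility is a degenerate population and
#' halts with an error rather than returning NaN.
#'
#' @param F numeric vector of non-negative fertilities.
#' @return probability vector summing to 1.
#' @export
relative_fertility <- function(F) {
  stopifnot(all(F >= 0))
  s <- sum(F)
  if (s <= 0)
    stop(serann_condition("serann_degenerate",
                          "all fertilities are zero: degenerate population"))
  F / s
}

#' Multinomial offspring counts
#'
#' `N_i ~ Multinomial(N, f)`: the newborn count of each parent before
#' survival filtering.
#'
#' @param f probability vector of relative fertilities.
#' @param N population size.
#' @return integer vector of non-negative counts summing to `N`.
#' @export
sample_offspring_counts <- function(f, N) {
  stopifnot(abs(sum(f) - 1) < 1e-9)
  as.integer(stats::rmultinom(1L, N, f))
}

#' Absolute and relative fitness
#'
#' Absolute fitness is `W = V * F` (survival times fertility), comparable
#' across generations.  Relative fitness `w = V * F / Fbar` is the expected
#' change in frequency due to selection, where `Fbar` is the population mean
#' fertility.
#'
#' @param V offspring survival rate in `[0, 1]`.
#' @param F fertility in `[0, 1]`.
#' @param Fbar population mean fertility (> 0).
#' @return numeric fitness value(s).
#' @export
absolute_fitness <- function(V, F) {
  stopifnot(all(V >= 0 & V <= 1 | is.na(V)), all(F >= 0 & F <= 1 | is.na(F)))
  V * F
}

#' @rdname absolute_fitness
#' @export
relative_fitness <- function(V, F, Fbar) {
  stopifnot(Fbar > 0)
  V * F / Fbar
}

serann_condition <- function(class, msg, ...) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-1), ...))
}

# -- backends -----------------------------------------------------------------

#' Evaluation backends for the evolutionary engine
#'
#' A backend supplies the three operations the engine needs per generation:
#' evaluating parents (fertility + offspring genotype pools), validating
#' offspring genotypes (decode + build), and constructing next-generation
#' individuals.
#'
#' `serann_backend()` is the full model: individuals are built from their
#' specs, trained on the joint task, evaluated on a shared evaluation set
#' (fixed within a generation), and their offspring decoded through the
#' codec.  `stub_backend()` replaces the networks with fixed-parameter stubs
#' (constant fertility, Bernoulli survival, independent per-bit flips) so the
#' population-genetic machinery can be exercised and calibrated in isolation.
#'
#' @param codec a trained [train_codec()] codec.
#' @param data train/eval image sets as from [make_synthetic_images()].
#' @param scaffold a [default_scaffold()].
#' @param genotype_pool matrix of genotypes used as replication training
#'   targets (defaults to encodings of a generated corpus).
#' @param epochs,batch,lr per-individual training schedule.
#' @return a backend object.
#' @export
serann_backend <- function(codec, data, scaffold, genotype_pool,
                           epochs = 5L, batch = 32L, lr = 3e-3) {
  structure(list(codec = codec, data = data, scaffold = scaffold,
                 genotype_pool = genotype_pool, epochs = epochs,
                 batch = batch, lr = lr),
            class = c("serann_backend", "serann_engine_backend"))
}

#' @rdname serann_backend
#' @param F,V,flip_p stub fertility, survival probability and per-bit flip
#'   rate; scalars or per-individual vectors (recycled).
#' @param k genotype length.
#' @export
stub_backend <- function(F = 0.9, V = 1, flip_p = 0, k = 24L) {
  structure(list(F = F, V = V, flip_p = flip_p, k = as.integer(k)),
            class = c("serann_stub_backend", "serann_engine_backend"))
}

backend_evaluate <- function(backend, pop, seed, gen, pool_size) {
  UseMethod("backend_evaluate")
}

#' @export
backend_evaluate.serann_backend <- function(backend, pop, seed, gen, pool_size) {
  inds <- pop$individuals
  Fv <- numeric(length(inds))
  pools <- vector("list", length(inds))
  ev <- backend$data$eval
  for (i in seq_along(inds)) {
    ind <- train_individual(inds[[i]], backend$data$train$X,
                            backend$data$train$y, backend$genotype_pool,
                            epochs = backend$epochs, batch = backend$batch,
                            lr = backend$lr,
                            seed = derive_seed(seed, gen, i))
    Fv[i] <- evaluate_fertility(ind, ev$X, ev$y)
    if (!is.null(ind$build) && !ind$build$valid) Fv[i] <- 0
    pools[[i]] <- if (!is.null(ind$net)) self_replicate(ind, ev$X)
                  else matrix(ind$genotype, 1L, length(ind$genotype))
    ind$F <- Fv[i]
    inds[[i]] <- ind
  }
  list(individuals = inds, F = Fv, pools = pools)
}

#' @export
backend_evaluate.serann_stub_backend <- function(backend, pop, seed, gen,
                                                 pool_size) {
  n <- length(pop$individuals)
  Fv <- rep_len(backend$F, n)
  flip <- rep_len(backend$flip_p, n)
  set.seed(derive_seed(seed, gen, 1L))
  pools <- lapply(seq_len(n), function(i) {
    g <- pop$individuals[[i]]$genotype
    k <- length(g)
    if (flip[i] == 0) {
      matrix(g, pool_size, k, byrow = TRUE)
    } else {
      flips <- matrix(stats::rbinom(pool_size * k, 1L, flip[i]), pool_size, k)
      abs(matrix(g, pool_size, k, byrow = TRUE) - flips)
    }
  })
  for (i in seq_len(n)) pop$individuals[[i]]$F <- Fv[i]
  list(individuals = pop$individuals, F = Fv, pools = pools)
}

backend_validate <- function(backend, genotypes, parent_idx) {
  UseMethod("backend_validate")
}

#' @export
backend_validate.serann_backend <- function(backend, genotypes, parent_idx) {
  texts <- decode_genotype(backend$codec, genotypes)
  valid <- vapply(texts, function(t) {
    r <- build_network(t, backend$scaffold)
    r$valid || r$error_kind == "parameter-cap-exceeded"
  }, TRUE, USE.NAMES = FALSE)
  list(texts = texts, valid = valid)
}

#' @export
backend_validate.serann_stub_backend <- function(backend, genotypes, parent_idx) {
  V <- rep_len(backend$V, max(parent_idx))
  list(texts = rep("<stub>", nrow(genotypes)),
       valid = stats::rbinom(nrow(genotypes), 1L, V[parent_idx]) == 1L)
}

backend_new_individual <- function(backend, genotype, text) {
  UseMethod("backend_new_individual")
}

#' @export
backend_new_individual.serann_backend <- function(backend, genotype, text) {
  serann_individual(genotype, text, backend$scaffold)
}

#' @export
backend_new_individual.serann_stub_backend <- function(backend, genotype, text) {
  stub_individual(F = backend$F[1], V = backend$V[1],
                  flip_p = backend$flip_p[1], k = length(genotype),
                  genotype = genotype)
}

# -- one generation -----------------------------------------------------------

#' Produce the next generation from evaluated parents
#'
#' Draws offspring counts `N_i ~ Multinomial(N, f)`, samples each parent's
#' newborns from its offspring-genotype pool (with replacement), decodes and
#' validates them, and replaces invalid offspring by conditional resampling
#' until `N` valid offspring exist or the retry budget (`50 * N` draws) is
#' exhausted (extinction).
#'
#' @param eval_result list from a backend's evaluate step (`F`, `pools`,
#'   `individuals`).
#' @param backend an engine backend.
#' @param N population size.
#' @return list with `individuals` (length N, untrained), `parent` (parent
#'   index per offspring), and `record`: per-parent data.frame with `F`,
#'   `f`, newborn `N_i`, surviving `Ntilde_i`, realized survival `V`
#'   (NA when `N_i = 0`), absolute `W` and relative `w` fitness, and the
#'   replacement count used to restore constant N.
#' @export
produce_next_generation <- function(eval_result, backend, N) {
  Fv <- eval_result$F
  pools <- eval_result$pools
  f <- relative_fertility(Fv)
  counts <- sample_offspring_counts(f, N)
  parent_idx <- rep(seq_along(f), counts)
  drawn <- lapply(seq_along(f), function(i) {
    if (counts[i] == 0L) return(NULL)
    rows <- sample.int(nrow(pools[[i]]), counts[i], replace = TRUE)
    pools[[i]][rows, , drop = FALSE]
  })
  genotypes <- do.call(rbind, drawn)
  val <- backend_validate(backend, genotypes, parent_idx)
  surv_by_parent <- vapply(seq_along(f), function(i)
    sum(val$valid[parent_idx == i]), integer(1))

  keep <- which(val$valid)
  out_g <- genotypes[keep, , drop = FALSE]
  out_t <- val$texts[keep]
  out_p <- parent_idx[keep]
  replacements <- 0L
  budget <- 50L * N
  while (nrow(out_g) < N) {
    need <- N - nrow(out_g)
    if (replacements + need > budget)
      stop(serann_condition("serann_extinction",
        paste0("survival too low: retry budget ", budget, " exhausted")))
    j <- sample.int(length(f), need, replace = TRUE, prob = f)
    g_new <- do.call(rbind, lapply(j, function(jj) {
      pools[[jj]][sample.int(nrow(pools[[jj]]), 1L), , drop = FALSE]
    }))
    v_new <- backend_validate(backend, g_new, j)
    ok <- which(v_new$valid)
    replacements <- replacements + need
    if (length(ok)) {
      out_g <- rbind(out_g, g_new[ok, , drop = FALSE])
      out_t <- c(out_t, v_new$texts[ok])
      out_p <- c(out_p, j[ok])
    }
  }
  out_g <- out_g[seq_len(N), , drop = FALSE]
  out_t <- out_t[seq_len(N)]
  out_p <- out_p[seq_len(N)]

  V_real <- ifelse(counts > 0, surv_by_parent / counts, NA_real_)
  Fbar <- mean(Fv)
  record <- data.frame(
    parent_id = seq_along(f), F = Fv, f = f,
    N_i = counts, Ntilde_i = surv_by_parent, V = V_real,
    W = absolute_fitness(V_real, Fv),
    w = ifelse(is.na(V_real), NA_real_, relative_fitness(V_real, Fv, Fbar))
  )
  individuals <- lapply(seq_len(N), function(i)
    backend_new_individual(backend, as.integer(out_g[i, ]), out_t[i]))
  list(individuals = individuals, parent = out_p, record = record,
       replacements = replacements)
}

# -- full runs ----------------------------------------------------------------

#' Founding (isogenic) population from a single ancestor spec
#'
#' @param spec_text ancestor specification string.
#' @param N population size.
#' @param codec codec used to encode the ancestor genotype (NULL for stub
#'   runs: genotype defaults to all zeros of length `k`).
#' @param scaffold a [default_scaffold()].
#' @param k genotype length when `codec` is NULL.
#' @return a `serann_population` at generation 0.
#' @export
founding_population <- function(spec_text, N, codec = NULL,
                                scaffold = default_scaffold(), k = scaffold$k) {
  g <- if (is.null(codec)) integer(k) else encode_genotype(codec, spec_text)
  individuals <- lapply(seq_len(N), function(i)
    if (is.null(codec)) stub_individual(k = length(g), genotype = g)
    else serann_individual(g, spec_text, scaffold))
  structure(list(individuals = individuals, generation = 0L,
                 parent = integer(0), seed = NA_integer_),
            class = "serann_population")
}

#' @export
print.serann_population <- function(x, ...) {
  cat("<serann_population> N =", length(x$individuals),
      "| generation", x$generation, "\n")
  invisible(x)
}

#' Run a full evolutionary experiment
#'
#' Repeats train-evaluate-replicate-select-decode for `G` generations from a
#' founding population.  All randomness derives from `seed` via per-
#' generation and per-individual substreams, so a run is exactly reproducible
#' and can be resumed from a checkpoint.
#'
#' @param pop founding `serann_population` (see [founding_population()]).
#' @param backend an engine backend ([serann_backend()] or [stub_backend()]).
#' @param G number of generations to advance.
#' @param seed integer run seed.
#' @param out_dir optional directory: per-generation records are appended as
#'   line-delimited JSON and the population checkpointed after each
#'   generation.
#' @param progress print a line per generation.
#' @return an object of class `serann_run`: `records` (one data.frame per
#'   completed generation, see [produce_next_generation()]), `genotypes`
#'   (per-generation character matrix of bit strings), `specs`
#'   (per-generation spec texts), `parent` (per-generation parent indices),
#'   `final` population, `seed`, `G`.
#' @export
run_experiment <- function(pop, backend, G, seed = 1L, out_dir = NULL,
                           progress = FALSE) {
  N <- length(pop$individuals)
  records <- vector("list", G)
  genotypes <- vector("list", G + 1L)
  specs <- vector("list", G + 1L)
  parents <- vector("list", G)
  genotypes[[1L]] <- vapply(pop$individuals, function(i)
    paste(i$genotype, collapse = ""), character(1))
  specs[[1L]] <- vapply(pop$individuals, function(i)
    i$spec_text %||% "", character(1))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  g0 <- pop$generation
  for (t in seq_len(G)) {
    gen <- g0 + t
    ev <- backend_evaluate(backend, pop, seed, gen,
                           pool_size = default_pool_size(backend))
    set.seed(derive_seed(seed, gen, 0L))
    nxt <- produce_next_generation(ev, backend, N)
    rec <- nxt$record
    rec$generation <- gen - 1L  # record describes the parental generation
    records[[t]] <- rec
    parents[[t]] <- nxt$parent
    pop <- structure(list(individuals = nxt$individuals, generation = gen,
                          parent = nxt$parent, seed = seed,
                          rng_state = integer(0)),
                     class = "serann_population")
    genotypes[[t + 1L]] <- vapply(pop$individuals, function(i)
      paste(i$genotype, collapse = ""), character(1))
    specs[[t + 1L]] <- vapply(pop$individuals, function(i)
      i$spec_text %||% "", character(1))
    if (!is.null(out_dir)) {
      write_generation_log(rec, file.path(out_dir, "generations.jsonl"),
                           append = t > 1L || g0 > 0L)
      save_population(pop, file.path(out_dir, "population.json"))
    }
    if (progress)
      cat(sprintf("generation %d: mean F %.3f mean W %.3f\n", gen,
                  mean(rec$F), mean(rec$W, na.rm = TRUE)))
  }
  structure(list(records = records, genotypes = genotypes, specs = specs,
                 parent = parents, final = pop, seed = seed, G = G,
                 start_generation = g0),
            class = "serann_run")
}

default_pool_size <- function(backend) {
  if (inherits(backend, "serann_backend")) dim(backend$data$eval$X)[1] else 50L
}

#' @export
print.serann_run <- function(x, ...) {
  cat("<serann_run>", x$G, "generations | N =",
      length(x$final$individuals), "| seed", x$seed, "\n")
  last <- x$records[[length(x$records)]]
  cat("  final parental generation: mean F =", round(mean(last$F), 4),
      "mean W =", round(mean(last$W, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' @export
summary.serann_run <- function(object, ...) {
  df <- do.call(rbind, lapply(object$records, function(r) {
    data.frame(generation = r$generation[1], mean_F = mean(r$F),
               mean_W = mean(r$W, na.rm = TRUE),
               richness = NA_real_)
  }))
  for (i in seq_len(nrow(df)))
    df$richness[i] <- length(unique(object$genotypes[[i]]))
  class(df) <- c("summary.serann_run", "data.frame")
  df
}

#' Append a generation record as line-delimited JSON (one object per parent)
#'
#' @param record per-parent data.frame from [produce_next_generation()].
#' @param path output file.
#' @param append append to an existing log.
#' @export
write_generation_log <- function(record, path, append = FALSE) {
  lines <- vapply(seq_len(nrow(record)), function(i)
    as.character(jsonlite::toJSON(c(list(schema_version = 1L),
                                    as.list(record[i, ])),
                                  auto_unbox = TRUE, digits = NA, na = "null")),
    character(1))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Read a line-delimited generation log
#'
#' @param path file written by [write_generation_log()].
#' @return data.frame with one row per parent per generation.
#' @export
read_generation_log <- function(path) {
  jsonlite::stream_in(file(path), verbose = FALSE)
}

#' Select an ancestor by short-run descendant viability
#'
#' Runs each candidate spec as an isogenic founding population for a small
#' number of generations and keeps the candidate whose run attains the
#' highest cumulative offspring survival (ties broken by mean fitness).
#' Candidates whose runs go extinct score zero.
#'
#' @param candidates character vector of candidate ancestor specs.
#' @param backend an engine backend.
#' @param N,G population size and number of generations per candidate run.
#' @param seed integer seed (one substream per candidate).
#' @param codec codec for genotype encoding (NULL for stub backends).
#' @param scaffold scaffold for individual construction.
#' @return list with `best` (index), `spec` (winning text) and `scores`.
#' @export
select_ancestor <- function(candidates, backend, N = 16L, G = 3L, seed = 1L,
                            codec = NULL, scaffold = default_scaffold()) {
  scores <- vapply(seq_along(candidates), function(i) {
    pop <- founding_population(candidates[i], N, codec, scaffold)
    run <- tryCatch(
      run_experiment(pop, backend, G, seed = derive_seed(seed, i)),
      serann_extinction = function(e) NULL,
      serann_degenerate = function(e) NULL)
    if (is.null(run)) return(0)
    sum(vapply(run$records, function(r) sum(r$Ntilde_i), numeric(1))) +
      mean(run$records[[G]]$W, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)
  list(best = best, spec = candidates[best], scores = scores)
}
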