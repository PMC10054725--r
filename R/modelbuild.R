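## Variable subset selection (all-subset + genetic algorithm) and the
## outlier-removal / recalibration workflow.

#' GA configuration
#'
#' @param model_size descriptors per candidate model.
#' @param population chromosomes per generation.
#' @param generations number of generations.
#' @param mutation_rate per-child probability of a gene swap.
#' @param elitism top chromosomes copied unchanged each generation.
#' @param fitness `"Q2LOO"` (default), `"R2"` or `"Q2LMO"`.
#' @param seed integer seed; the whole run is reproducible for a given seed.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(model_size = 7L, population = 100L, generations = 500L,
                      mutation_rate = 0.2, elitism = 2L,
                      fitness = c("Q2LOO", "R2", "Q2LMO"), seed = 1L) {
  fitness <- match.arg(fitness)
  stopifnot(model_size >= 1L, population >= 2L,
            mutation_rate > 0, mutation_rate < 1)
  structure(list(model_size = as.integer(model_size),
                 population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 fitness = fitness, seed = as.integer(seed)),
            class = "ga_config")
}

# fitness of a column subset; -Inf (discarded) on rank deficiency
subset_fitness <- function(X, y, cols, fitness = "Q2LOO") {
  f <- tryCatch(qsar_mlr.default(X[, cols, drop = FALSE], y),
                error = function(e) NULL)
  if (is.null(f)) return(-Inf)
  v <- switch(fitness,
              Q2LOO = tryCatch(q2_loo_fit(f), error = function(e) -Inf),
              R2 = f$r2,
              Q2LMO = q2_lmo(X[, cols, drop = FALSE], y, iterations = 100L))
  if (!is.finite(v)) -Inf else v
}

new_population <- function(members, fitness_name) {
  ord <- order(vapply(members, `[[`, numeric(1), "fitness"),
               decreasing = TRUE)
  structure(list(models = members[ord], fitness = fitness_name),
            class = "model_population")
}

#' @export
print.model_population <- function(x, ...) {
  cat(sprintf("<model_population> %d models ranked by %s\n",
              length(x$models), x$fitness))
  for (m in utils::head(x$models, 5))
    cat(sprintf("  %.4f  {%s}\n", m$fitness, paste(m$subset, collapse = ", ")))
  invisible(x)
}

#' Best descriptor subset of a model population
#' @param pop a `model_population`.
#' @param rank which ranked model to return (1 = best).
#' @return character vector of descriptor names.
#' @export
best_subset <- function(pop, rank = 1L) pop$models[[rank]]$subset

#' Exhaustive all-subset model search
#'
#' Fits every descriptor subset of size 1..`max_size` and ranks them by the
#' chosen fitness.  Guarded by a budget on the number of candidate models;
#' an over-budget pool must be searched with [ga_vss()] instead.
#'
#' @param pool descriptor data.frame.
#' @param y response.
#' @param max_size largest subset size.
#' @param fitness fitness statistic (see [ga_config()]).
#' @param budget maximum number of subsets fitted (default 2e5).
#' @return a `model_population` (subsets, fitted fitness, ranked).
#' @export
all_subset_search <- function(pool, y, max_size, fitness = "Q2LOO",
                              budget = 2e5) {
  pool <- as.data.frame(pool, check.names = FALSE)
  p <- ncol(pool)
  stopifnot(p >= max_size)
  total <- sum(choose(p, seq_len(max_size)))
  if (total > budget)
    stop(sprintf(
      "all-subset search would fit %.0f models (budget %.0f); use ga_vss()",
      total, budget))
  X <- as.matrix(pool)
  members <- vector("list", total)
  t <- 0L
  for (size in seq_len(max_size)) {
    combos <- utils::combn(p, size)
    for (cidx in seq_len(ncol(combos))) {
      cols <- combos[, cidx]
      t <- t + 1L
      members[[t]] <- list(subset = names(pool)[cols],
                           fitness = subset_fitness(X, y, cols, fitness))
    }
  }
  new_population(members, fitness)
}

#' Genetic-algorithm variable subset selection (GA-VSS)
#'
#' Generational GA over fixed-size descriptor subsets: tournament selection
#' (size 3), uniform crossover (children sample from the union of their
#' parents' genes), per-child gene-swap mutation, and elitism.  Fitness is
#' the leave-one-out Q2 of the OLS fit by default.  Runs are reproducible
#' for a given seed; rank-deficient subsets receive fitness `-Inf` and die
#' out.
#'
#' @param pool descriptor data.frame (more columns than `model_size`).
#' @param y response.
#' @param cfg a [ga_config()].
#' @param init optional list of starting subsets (descriptor-name or column
#'   index vectors) preloaded into the initial population, e.g. the best
#'   model of an all-subset search.
#' @return a `model_population` with the unique subsets of the final
#'   population (plus the best-ever subset), ranked by fitness.
#' @export
ga_vss <- function(pool, y, cfg = ga_config(), init = NULL) {
  pool <- as.data.frame(pool, check.names = FALSE)
  p <- ncol(pool)
  m <- cfg$model_size
  if (p <= m) stop("pool must have more columns than model_size")
  X <- as.matrix(pool)
  with_seed(cfg$seed, {
    chrom <- replicate(cfg$population, sort(sample.int(p, m)),
                       simplify = FALSE)
    if (!is.null(init)) {
      init <- lapply(init, function(s) {
        cols <- if (is.character(s)) match(s, names(pool)) else as.integer(s)
        if (anyNA(cols) || length(cols) != m)
          stop("init subsets must name ", m, " pool columns")
        sort(cols)
      })
      chrom[seq_along(init)] <- init
    }
    fit <- vapply(chrom, function(cols)
      subset_fitness(X, y, cols, cfg$fitness), numeric(1))
    best <- list(cols = chrom[[which.max(fit)]], fitness = max(fit))
    tournament <- function() {
      cand <- sample.int(cfg$population, 3L)
      cand[which.max(fit[cand])]
    }
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fit, decreasing = TRUE)
      nxt <- chrom[ord[seq_len(min(cfg$elitism, cfg$population))]]
      while (length(nxt) < cfg$population) {
        u <- union(chrom[[tournament()]], chrom[[tournament()]])
        child <- sort(u[sample.int(length(u), m)])
        if (stats::runif(1) < cfg$mutation_rate) {
          outside <- setdiff(seq_len(p), child)
          child[sample.int(m, 1L)] <- outside[sample.int(length(outside), 1L)]
          child <- sort(child)
        }
        nxt[[length(nxt) + 1L]] <- child
      }
      chrom <- nxt
      fit <- vapply(chrom, function(cols)
        subset_fitness(X, y, cols, cfg$fitness), numeric(1))
      if (max(fit) > best$fitness)
        best <- list(cols = chrom[[which.max(fit)]], fitness = max(fit))
    }
    keys <- vapply(chrom, paste, character(1), collapse = ",")
    keep <- !duplicated(keys)
    members <- Map(function(cols, f) list(subset = names(pool)[cols],
                                          fitness = f),
                   chrom[keep], fit[keep])
    bk <- paste(best$cols, collapse = ",")
    if (!bk %in% keys[keep])
      members[[length(members) + 1L]] <-
        list(subset = names(pool)[best$cols], fitness = best$fitness)
    new_population(members, cfg$fitness)
  })
}

#' Chemicals repeatedly mispredicted across the best models
#'
#' Refits each of the `top_k` ranked subsets of a model population and flags
#' chemicals that are response outliers (|standardized residual| > 2.5) or
#' high leverage (h > h*) in a majority of those models.
#'
#' @param pop a `model_population` from [ga_vss()] or [all_subset_search()].
#' @param pool descriptor data.frame used for the population.
#' @param y response.
#' @param top_k number of top models inspected.
#' @param id optional chemical identifiers.
#' @return data.frame of flagged chemicals with per-model evidence counts
#'   (`n_outlier`, `n_high_leverage` out of `top_k`).
#' @export
detect_recurrent_outliers <- function(pop, pool, y, top_k = 10L, id = NULL) {
  top_k <- min(top_k, length(pop$models))
  pool <- as.data.frame(pool, check.names = FALSE)
  n <- length(y)
  n_out <- n_lev <- integer(n)
  for (r in seq_len(top_k)) {
    fit <- qsar_mlr.default(pool[, best_subset(pop, r), drop = FALSE], y)
    ad <- williams(fit)
    n_out <- n_out + as.integer(ad$response_outlier)
    n_lev <- n_lev + as.integer(ad$high_leverage)
  }
  flag <- (n_out > top_k / 2) | (n_lev > top_k / 2)
  data.frame(id = if (is.null(id)) which(flag) else id[flag],
             index = which(flag),
             n_outlier = n_out[flag], n_high_leverage = n_lev[flag],
             top_k = rep(top_k, sum(flag)))
}

#' Recalibrate a model's descriptor set on new data
#'
#' Refits the descriptor set of an existing model by OLS on the supplied
#' data (typically training and prediction sets pooled) and returns a new
#' frozen [qsar_model()] with the refitted coefficients and standard
#' errors.  Recalibrating on the original training data reproduces the
#' original coefficients.
#'
#' @param m a [qsar_model()] or [qsar_mlr()] fit (defines the term set).
#' @param x descriptor data covering the model terms.
#' @param y responses.
#' @param model_id label of the recalibrated model.
#' @return a [qsar_model()].
#' @export
recalibrate <- function(m, x, y, model_id = "recalibrated") {
  terms <- if (inherits(m, "qsar_model")) m$terms$name else m$term_names
  x <- as.data.frame(x, check.names = FALSE)
  miss <- setdiff(terms, names(x))
  if (length(miss)) stop("data lacks descriptor(s): ",
                         paste(miss, collapse = ", "))
  fit <- qsar_mlr.default(x[, terms, drop = FALSE], y)
  qsar_model(intercept = unname(fit$coefficients[1L]),
             intercept_se = unname(fit$se[1L]),
             terms = data.frame(name = terms,
                                coefficient = unname(fit$coefficients[-1L]),
                                se = unname(fit$se[-1L])),
             training_n = fit$n, model_id = model_id)
}
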