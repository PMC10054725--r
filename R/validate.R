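## Splitting scheme and internal/external validation statistics.

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Response-ordered train/prediction split
#'
#' Records are sorted by increasing response; every record whose 1-based
#' sorted position is a multiple of `stride` joins the prediction set,
#' except the global minimum and maximum, which always stay in training.
#' With the default `stride = 4` this reproduces training/prediction sizes
#' of 115/37 on a 152-record set and 194/64 on a 258-record set.
#'
#' @param y numeric response vector, or a [bmf_dataset()].
#' @param stride take every `stride`-th sorted record (>= 2).
#' @return for a numeric `y`, a list with integer index vectors `train` and
#'   `test` (into the original ordering); for a dataset, a list of two
#'   [bmf_dataset()]s with the index vectors attached as attribute
#'   `"indices"`.
#' @export
split_by_response <- function(y, stride = 4L) {
  if (inherits(y, "bmf_dataset")) {
    idx <- split_by_response(y$records$log_bmf_l, stride)
    out <- list(train = dataset_subset(y, idx$train),
                test = dataset_subset(y, idx$test))
    attr(out, "indices") <- idx
    return(out)
  }
  stride <- as.integer(stride)
  if (stride < 2L) stop("stride must be >= 2")
  n <- length(y)
  if (n < stride + 2L) stop("need at least stride + 2 records")
  ord <- order(y)                     # stable: ties keep original order
  pos <- seq_len(n)
  test_pos <- pos[pos %% stride == 0L & pos != 1L & pos != n]
  list(train = sort(ord[setdiff(pos, test_pos)]),
       test = sort(ord[test_pos]))
}

#' Fitting statistics: R2, RMSE, MAE
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return list with elements `r2` (computed against the mean of `y`),
#'   `rmse` and `mae`.
#' @export
basic_stats <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2L)
    stop("y and yhat must have equal length >= 2")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero variance in y: R2 undefined")
  res <- y - yhat
  list(r2 = 1 - sum(res^2) / tss,
       rmse = sqrt(mean(res^2)),
       mae = mean(abs(res)))
}

#' Leave-one-out cross-validated Q2
#'
#' Predictive squared correlation \eqn{1 - PRESS/TSS}; PRESS is obtained
#' from a single fit through the OLS identity \eqn{e_i/(1-h_i)} rather than
#' n refits.
#'
#' @param x descriptor matrix/data.frame (no intercept column).
#' @param y response.
#' @return Q2_LOO.
#' @export
q2_loo <- function(x, y) q2_loo_fit(qsar_mlr.default(x, y))

#' Leave-many-out cross-validated Q2
#'
#' Repeatedly leaves out a random fraction of the records, refits on the
#' remainder and evaluates \eqn{1 - PRESS_{out}/TSS_{out}} (the held-out
#' total sum of squares is taken around the retained-set mean); returns the
#' mean over iterations.  Seed-reproducible.
#'
#' @param x descriptor matrix/data.frame.
#' @param y response.
#' @param leave_fraction fraction left out each iteration (0 < f <= 0.5).
#' @param iterations number of random deletions (default 1000).
#' @param seed integer seed.
#' @return Q2_LMO.
#' @export
q2_lmo <- function(x, y, leave_fraction = 0.3, iterations = 1000L,
                   seed = 1L) {
  if (leave_fraction <= 0 || leave_fraction > 0.5)
    stop("leave_fraction must be in (0, 0.5]")
  X <- as.matrix(as.data.frame(x, check.names = FALSE))
  n <- nrow(X)
  n_out <- max(1L, round(leave_fraction * n))
  if (n - n_out <= ncol(X) + 1L) stop("retained set too small to fit")
  with_seed(seed, {
    vals <- vapply(seq_len(iterations), function(it) {
      out <- sample.int(n, n_out)
      fit <- qsar_mlr.default(X[-out, , drop = FALSE], y[-out])
      pred <- predict(fit, X[out, , drop = FALSE])
      press <- sum((y[out] - pred)^2)
      tss <- sum((y[out] - mean(y[-out]))^2)
      1 - press / tss
    }, numeric(1))
    mean(vals)
  })
}

#' External predictivity Q2-F3
#'
#' \deqn{Q^2_{F3} = 1 - \frac{\sum (\hat y_{ext} - y_{ext})^2 / n_{ext}}
#'                          {\sum (y_{tr} - \bar y_{tr})^2 / n_{tr}}}
#'
#' @param y_train training responses (defines the reference variance).
#' @param y_ext external observed responses.
#' @param yhat_ext external predictions.
#' @return Q2-F3.
#' @export
q2_f3 <- function(y_train, y_ext, yhat_ext) {
  if (!length(y_train) || !length(y_ext)) stop("empty set")
  if (length(y_ext) != length(yhat_ext)) stop("length mismatch")
  tss <- sum((y_train - mean(y_train))^2) / length(y_train)
  if (tss == 0) stop("zero training variance")
  1 - (sum((yhat_ext - y_ext)^2) / length(y_ext)) / tss
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = \frac{2\,cov(y, \hat y)}{var(y) + var(\hat y) + (\bar y - \bar{\hat y})^2}}
#' using population moments (denominator n).
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return CCC in [-1, 1].
#' @export
ccc <- function(y, yhat) {
  n <- length(y)
  if (n < 2L || length(yhat) != n) stop("need equal lengths >= 2")
  my <- mean(y); mp <- mean(yhat)
  vy <- mean((y - my)^2); vp <- mean((yhat - mp)^2)
  cv <- mean((y - my) * (yhat - mp))
  den <- vy + vp + (my - mp)^2
  if (den == 0) stop("CCC undefined: zero variances and equal means")
  2 * cv / den
}

#' k-fold cross-validation with per-fold variable selection
#'
#' Records are sorted by increasing response and dealt into `k` folds
#' venetian-blind style (sorted position p goes to fold ((p-1) mod k) + 1),
#' so every fold spans the response range.  For each fold a fresh GA
#' variable selection of `model_size` descriptors is run on the retained
#' records, an OLS model is fitted, and RMSE/MAE are evaluated on the
#' held-out fold.  Selection frequencies of the descriptors across folds
#' are tallied.  With `ga = NULL` the descriptor set is re-used as given
#' (no selection), which makes `k = n` reduce to leave-one-out.
#'
#' @param y response vector.
#' @param pool descriptor matrix/data.frame (the selection pool).
#' @param k number of folds (default 5).
#' @param model_size descriptors per fold model (default 7).
#' @param ga a [ga_config()] driving the per-fold selection, or `NULL` to
#'   fit the pool as-is.
#' @param folds `"venetian"` (deterministic, default) or `"random"`.
#' @param seed seed for random fold assignment and the GA.
#' @return an object of class `kfold_cv`: per-fold table, means, and the
#'   descriptor selection-frequency table.
#' @export
kfold_cv <- function(y, pool, k = 5L, model_size = 7L, ga = NULL,
                     folds = c("venetian", "random"), seed = 1L) {
  folds <- match.arg(folds)
  pool <- as.data.frame(pool, check.names = FALSE)
  n <- length(y)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("k must be in [2, n]")
  if (!is.null(ga) && ncol(pool) < model_size)
    stop("descriptor pool smaller than model_size")
  fold_id <- integer(n)
  ord <- order(y)
  fold_id[ord] <- if (folds == "venetian") ((seq_len(n) - 1L) %% k) + 1L
                  else with_seed(seed, sample(((seq_len(n) - 1L) %% k) + 1L))
  per <- data.frame(fold = seq_len(k), n_test = NA_integer_,
                    rmse_test = NA_real_, mae_test = NA_real_)
  sel_count <- stats::setNames(numeric(ncol(pool)), names(pool))
  fold_terms <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold_id != f; te <- !tr
    if (!is.null(ga)) {
      cfg <- ga
      cfg$model_size <- model_size
      cfg$seed <- ga$seed + f
      sel <- ga_vss(pool[tr, , drop = FALSE], y[tr], cfg)
      terms <- best_subset(sel)
    } else terms <- names(pool)
    fit <- qsar_mlr.default(pool[tr, terms, drop = FALSE], y[tr])
    pred <- predict(fit, pool[te, terms, drop = FALSE])
    res <- y[te] - pred
    per$n_test[f] <- sum(te)
    per$rmse_test[f] <- sqrt(mean(res^2))
    per$mae_test[f] <- mean(abs(res))
    sel_count[terms] <- sel_count[terms] + 1
    fold_terms[[f]] <- terms
  }
  structure(list(per_fold = per,
                 rmse_mean = mean(per$rmse_test),
                 mae_mean = mean(per$mae_test),
                 frequency = sort(sel_count[sel_count > 0], decreasing = TRUE),
                 fold_terms = fold_terms, k = k),
            class = "kfold_cv")
}

#' @export
print.kfold_cv <- function(x, ...) {
  cat(sprintf("<kfold_cv> k = %d\n", x$k))
  print(transform(x$per_fold, rmse_test = round(rmse_test, 3),
                  mae_test = round(mae_test, 3)))
  cat(sprintf("  mean RMSE_test = %.3f, mean MAE_test = %.3f\n",
              x$rmse_mean, x$mae_mean))
  if (length(x$frequency)) {
    cat("  selection frequencies:\n")
    print(utils::head(x$frequency, 10))
  }
  invisible(x)
}

#' Full validation report for a split model
#'
#' Bundles training statistics, leave-one-out and leave-many-out Q2, and
#' external statistics (RMSE/MAE/R2 on the prediction set, Q2-F3, CCC) in
#' one object.
#'
#' @param x_train,y_train training descriptors and response.
#' @param x_test,y_test external set (optional).
#' @param lmo_iterations,lmo_fraction,seed leave-many-out settings.
#' @return list of class `validation_report`.
#' @export
validation_report <- function(x_train, y_train, x_test = NULL, y_test = NULL,
                              lmo_iterations = 1000L, lmo_fraction = 0.3,
                              seed = 1L) {
  fit <- qsar_mlr.default(x_train, y_train)
  tr <- basic_stats(y_train, fit$fitted)
  out <- list(fit = fit,
              r2 = tr$r2, rmse_tr = tr$rmse, mae_tr = tr$mae,
              q2_loo = q2_loo_fit(fit),
              q2_lmo = q2_lmo(x_train, y_train, lmo_fraction,
                              lmo_iterations, seed))
  if (!is.null(x_test)) {
    pred <- predict(fit, x_test)
    ext <- basic_stats(y_test, pred)
    out$rmse_ext <- ext$rmse
    out$mae_ext <- ext$mae
    out$r2_ext <- ext$r2
    out$q2_f3 <- q2_f3(y_train, y_test, pred)
    out$ccc_ext <- ccc(y_test, pred)
  }
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n_tr = %d%s\n", x$fit$n,
              if (!is.null(x$rmse_ext)) "" else " (no external set)"))
  cat(sprintf("  R2 = %.2f; RMSE_tr = %.2f; MAE_tr = %.2f; Q2_LOO = %.2f; Q2_LMO = %.2f\n",
              x$r2, x$rmse_tr, x$mae_tr, x$q2_loo, x$q2_lmo))
  if (!is.null(x$rmse_ext))
    cat(sprintf("  RMSE_ext = %.2f; MAE_ext = %.2f; R2_ext = %.2f; Q2-F3 = %.2f; CCC_ext = %.2f\n",
                x$rmse_ext, x$mae_ext, x$r2_ext, x$q2_f3, x$ccc_ext))
  invisible(x)
}
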