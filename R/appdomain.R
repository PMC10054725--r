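## Leverage / standardized-residual applicability domain (Williams plot)
## and the low-quality-data consistency screen.

#' Leverage cutoff h* = 3 p'/n
#'
#' @param n_train number of training chemicals.
#' @param n_descriptors number of model variables (p' is this plus one).
#' @return the warning leverage h*.
#' @examples
#' leverage_cutoff(115, 7)   # 0.2087, printed as 0.209
#' leverage_cutoff(194, 7)   # 0.1237
#' @export
leverage_cutoff <- function(n_train, n_descriptors) {
  if (n_train <= 0) stop("n_train must be positive")
  3 * (n_descriptors + 1) / n_train
}

#' Leverages of query points with respect to a training design
#'
#' \eqn{h_q = x_q^T (X^T X)^{-1} x_q} with the intercept column included.
#' A query equal to a training row reproduces that row's hat diagonal;
#' training leverages sum to p'.
#'
#' @param x_train training descriptor matrix (no intercept column).
#' @param x_query query descriptor matrix (defaults to the training set).
#' @return numeric vector of leverages.
#' @export
leverages <- function(x_train, x_query = x_train) {
  Xt <- cbind(1, as.matrix(as.data.frame(x_train, check.names = FALSE)))
  Xq <- cbind(1, as.matrix(as.data.frame(x_query, check.names = FALSE)))
  if (ncol(Xq) != ncol(Xt)) stop("query columns do not match training design")
  qx <- qr(Xt)
  if (qx$rank < ncol(Xt)) stop("rank-deficient training design")
  XtXinv <- chol2inv(qr.R(qx))
  rowSums((Xq %*% XtXinv) * Xq)
}

#' Standardized residuals
#'
#' Residuals divided by the training-fit residual standard deviation
#' \eqn{s = \sqrt{RSS/(n-p')}}.  External points are standardized with the
#' same training s so they are comparable on the Williams plot.
#'
#' @param residuals raw residuals.
#' @param s training residual standard deviation (> 0).
#' @return numeric vector.
#' @export
standardized_residuals <- function(residuals, s) {
  if (!is.finite(s) || s <= 0) stop("s must be positive")
  residuals / s
}

#' Applicability-domain report (Williams plot content)
#'
#' Combines leverages and standardized residuals into per-chemical AD flags:
#' `high_leverage` when h exceeds h* = 3p'/n (strict inequality),
#' `response_outlier` when |standardized residual| exceeds 2.5 (strict), and
#' the reported-only `strong_outlier` tier at 3 standard deviations.
#' A chemical is `in_domain` iff its leverage does not exceed h*.
#'
#' @param fit a [qsar_mlr()] training fit.
#' @param x_query optional external descriptors (default: training set).
#' @param y_query optional external responses (residual flags are `NA`
#'   without them).
#' @param id optional chemical identifiers.
#' @return data.frame of class `ad_report` with columns `id`, `h`,
#'   `std_residual`, `in_domain`, `high_leverage`, `response_outlier`,
#'   `strong_outlier`; attributes `h_star` and `s`.
#' @export
williams <- function(fit, x_query = NULL, y_query = NULL, id = NULL) {
  stopifnot(inherits(fit, "qsar_mlr"))
  h_star <- leverage_cutoff(fit$n, fit$p1 - 1L)
  Xtr <- fit$X[, -1L, drop = FALSE]
  if (is.null(x_query)) {
    h <- fit$hat
    res <- fit$residuals
  } else {
    h <- leverages(Xtr, x_query[, fit$term_names, drop = FALSE])
    res <- if (is.null(y_query)) rep(NA_real_, length(h)) else
      y_query - predict(fit, x_query)
  }
  std <- ifelse(is.na(res), NA_real_, standardized_residuals(res, fit$s))
  out <- data.frame(
    id = if (is.null(id)) seq_along(h) else id,
    h = h, std_residual = std,
    in_domain = h <= h_star,
    high_leverage = h > h_star,
    response_outlier = !is.na(std) & abs(std) > 2.5,
    strong_outlier = !is.na(std) & abs(std) > 3)
  attr(out, "h_star") <- h_star
  attr(out, "s") <- fit$s
  class(out) <- c("ad_report", class(out))
  out
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report> %d chemicals; h* = %.4f\n", nrow(x),
              attr(x, "h_star")))
  cat(sprintf("  in domain: %d; high leverage: %d; response outliers (>2.5 sd): %d; >3 sd: %d\n",
              sum(x$in_domain), sum(x$high_leverage),
              sum(x$response_outlier, na.rm = TRUE),
              sum(x$strong_outlier, na.rm = TRUE)))
  invisible(x)
}

#' Williams plot
#'
#' Hat values against standardized residuals with the h* cutoff and the
#' +/- 2.5 and 3 standard-deviation guides.
#'
#' @param x an `ad_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ad_report <- function(x, ...) {
  graphics::plot(x$h, x$std_residual, xlab = "leverage (h)",
                 ylab = "standardized residual",
                 pch = ifelse(x$in_domain, 19, 1), ...)
  graphics::abline(v = attr(x, "h_star"), lty = 2)
  graphics::abline(h = c(-2.5, 2.5), lty = 3)
  graphics::abline(h = c(-3, 3), lty = 4, col = "grey50")
  invisible(x)
}

#' Consistency screen of external (e.g. low-quality) data
#'
#' Each record with a measured response is categorized against a fitted
#' model: `outside_AD_unreliable` when its leverage exceeds h* (such data
#' cannot be judged by the model), otherwise `inconsistent_in_AD` when the
#' standardized prediction error exceeds 2.5 training standard deviations,
#' otherwise `consistent_in_AD`.  Records surviving as `consistent_in_AD`
#' are the ones eligible to be pooled with the good-quality training data
#' in a final model.
#'
#' @param fit a [qsar_mlr()] training fit (defines the AD and s).
#' @param x_query descriptor values of the screened records.
#' @param y_query their measured responses.
#' @param id optional identifiers.
#' @return data.frame of class `screen_verdicts`: `id`, `predicted`,
#'   `residual`, `h`, `std_residual`, `category`; summary counts in the
#'   `counts` attribute.
#' @export
screen_external <- function(fit, x_query, y_query, id = NULL) {
  ad <- williams(fit, x_query, y_query, id = id)
  pred <- predict(fit, x_query)
  category <- ifelse(ad$high_leverage, "outside_AD_unreliable",
                     ifelse(ad$response_outlier, "inconsistent_in_AD",
                            "consistent_in_AD"))
  out <- data.frame(id = ad$id, predicted = pred,
                    residual = y_query - pred,
                    h = ad$h, std_residual = ad$std_residual,
                    category = category)
  attr(out, "h_star") <- attr(ad, "h_star")
  attr(out, "counts") <- table(factor(category,
    levels = c("consistent_in_AD", "inconsistent_in_AD",
               "outside_AD_unreliable")))
  class(out) <- c("screen_verdicts", class(out))
  out
}

#' @export
print.screen_verdicts <- function(x, ...) {
  cat("<screen_verdicts>\n")
  print(attr(x, "counts"))
  invisible(x)
}
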