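#' Ordinary least squares fit of a descriptor model
#'
#' The central fitting function of the package: fits Log BMF_L (or any
#' response) on a set of descriptors by OLS and returns an object carrying
#' everything the validation and applicability-domain machinery needs --
#' coefficients with standard errors, residuals, the hat diagonal, and the
#' residual standard deviation \eqn{s = \sqrt{RSS/(n - p')}} with
#' \eqn{p'} the number of descriptors plus one.
#'
#' @param x descriptor data.frame/matrix (no intercept column; one is added),
#'   or a formula.
#' @param y numeric response (for the default method).
#' @param data data.frame holding the formula variables.
#' @param ... passed between methods.
#' @return an object of class `qsar_mlr` with components `coefficients`,
#'   `se`, `residuals`, `fitted`, `hat`, `s`, `r2`, `X` (design matrix with
#'   intercept), `y`, `term_names`.
#' @examples
#' X <- data.frame(a = rnorm(20), b = rnorm(20))
#' fit <- qsar_mlr(X, 1 + 2 * X$a - X$b + rnorm(20, 0, .1))
#' coef(fit)
#' @export
qsar_mlr <- function(x, ...) UseMethod("qsar_mlr")

#' @rdname qsar_mlr
#' @export
qsar_mlr.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  icpt <- which(colnames(X) == "(Intercept)")
  qsar_mlr.default(X[, -icpt, drop = FALSE], y, ...)
}

#' @rdname qsar_mlr
#' @export
qsar_mlr.default <- function(x, y, ...) {
  X0 <- as.matrix(as.data.frame(x, check.names = FALSE))
  storage.mode(X0) <- "double"
  n <- nrow(X0)
  if (length(y) != n) stop("length(y) != nrow(x)")
  p1 <- ncol(X0) + 1L
  if (n <= p1) stop("need more observations (", n, ") than parameters (", p1, ")")
  X <- cbind("(Intercept)" = 1, X0)
  qx <- qr(X)
  if (qx$rank < p1) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):p1]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- qr.coef(qx, y)
  fitted <- drop(X %*% cf)
  res <- y - fitted
  rss <- sum(res^2)
  s2 <- rss / (n - p1)
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(XtXinv) * s2)
  Q <- qr.Q(qx)
  h <- rowSums(Q^2)
  tss <- sum((y - mean(y))^2)
  structure(list(coefficients = cf, se = stats::setNames(se, names(cf)),
                 residuals = res, fitted = fitted, hat = h,
                 s = sqrt(s2), r2 = 1 - rss / tss,
                 X = X, y = y, XtXinv = XtXinv,
                 term_names = colnames(X0), n = n, p1 = p1),
            class = "qsar_mlr")
}

#' Fit an OLS model from an explicit design
#'
#' Thin alias of [qsar_mlr()] for matrix input, kept as the canonical
#' entry point of the model-building pipeline.
#'
#' @inheritParams qsar_mlr
#' @return a `qsar_mlr` object.
#' @export
fit_ols <- function(x, y) qsar_mlr.default(x, y)

#' @export
print.qsar_mlr <- function(x, ...) {
  cat(sprintf("<qsar_mlr> n = %d, descriptors = %d\n", x$n, x$p1 - 1L))
  cat(sprintf("  R2 = %.3f, s = %.3f\n", x$r2, x$s))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
coef.qsar_mlr <- function(object, ...) object$coefficients

#' @export
residuals.qsar_mlr <- function(object, ...) object$residuals

#' @export
fitted.qsar_mlr <- function(object, ...) object$fitted

#' @export
predict.qsar_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- as.matrix(as.data.frame(newdata,
                               check.names = FALSE)[, object$term_names,
                                                    drop = FALSE])
  drop(cbind(1, X) %*% object$coefficients)
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  out <- list(fit = object,
              stats = internal_stats(object),
              cutoff = leverage_cutoff(object$n, object$p1 - 1L))
  class(out) <- "summary.qsar_mlr"
  out
}

#' @export
print.summary.qsar_mlr <- function(x, ...) {
  print(x$fit)
  st <- x$stats
  cat(sprintf("  RMSE_tr = %.3f, MAE_tr = %.3f, Q2_LOO = %.3f\n",
              st$rmse, st$mae, st$q2_loo))
  cat(sprintf("  leverage cutoff h* = %.4f\n", x$cutoff))
  invisible(x)
}

#' @export
plot.qsar_mlr <- function(x, ...) {
  plot(williams(x), ...)
}

#' @export
simulate.qsar_mlr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- object$n
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(n, 0, object$s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

# training R2/RMSE/MAE/Q2loo bundle used by summary() and the GA reports
internal_stats <- function(fit) {
  bs <- basic_stats(fit$y, fit$fitted)
  list(r2 = bs$r2, rmse = bs$rmse, mae = bs$mae,
       q2_loo = q2_loo_fit(fit))
}

# Q2loo from a fitted object via the hat identity (no refits)
q2_loo_fit <- function(fit) {
  if (any(fit$hat >= 1 - 1e-12))
    stop("leave-one-out undefined: a training point is fitted exactly (h = 1)")
  press <- sum((fit$residuals / (1 - fit$hat))^2)
  tss <- sum((fit$y - mean(fit$y))^2)
  1 - press / tss
}
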