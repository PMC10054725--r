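#' Frozen MLR predictors for Log BMF_L
#'
#' `qsar_model()` builds a linear Log BMF_L predictor from an intercept and
#' named descriptor terms; `builtin_model()` returns one of the four
#' published equations with every coefficient and standard error stored at
#' printed precision (no re-derived digits).  `eq1` (split model, n = 115)
#' and its full-data recalibration `eq2` (n = 152) use autocorrelation,
#' BCUT, fingerprint and topological-charge descriptors; `eq3` (n = 194) and
#' its recalibration `eq4` (n = 258) use fingerprint, fragment-count,
#' path-ratio, polarizability, H E-state and detour descriptors.
#'
#' @param id one of `"eq1"`, `"eq2"`, `"eq3"`, `"eq4"`.
#' @param intercept,intercept_se intercept estimate and standard error.
#' @param terms data.frame with columns `name`, `coefficient`, `se`.
#' @param training_n number of training chemicals.
#' @param model_id label for the model.
#' @return an object of class `qsar_model`.
#' @examples
#' m <- builtin_model("eq4")
#' predict(m, setNames(rep(0, 7), names(coef(m))[-1]))  # intercept: -1.04
#' @export
builtin_model <- function(id = c("eq1", "eq2", "eq3", "eq4")) {
  id <- match.arg(id)
  tdf <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(name = m[, 1],
               coefficient = as.numeric(m[, 2]), se = as.numeric(m[, 3]),
               stringsAsFactors = FALSE)
  }
  spec <- switch(id,
    eq1 = list(-103.01, 25.20, 115L, tdf(
      "AATS5i",       -0.08, 0.02,
      "BCUTw-1l",      9.74, 2.03,
      "PubchemFP257", -0.88, 0.27,
      "C3SP2",        -0.15, 0.05,
      "MATS1i",        3.14, 1.50,
      "GATS5m",       -0.54, 0.40,
      "GGI5",          0.29, 0.25)),
    eq2 = list(-103.72, 22.93, 152L, tdf(
      "AATS5i",       -0.07, 0.02,
      "BCUTw-1l",      9.74, 1.85,
      "PubchemFP257", -0.83, 0.25,
      "C3SP2",        -0.15, 0.05,
      "MATS1i",        3.73, 1.36,
      "GGI5",          0.42, 0.21,
      "GATS5m",       -0.55, 0.34)),
    eq3 = list(-0.90, 0.19, 194L, tdf(
      "PubchemFP503",  1.41, 0.19,
      "SubFPC295",    -0.40, 0.07,
      "R_TpiPCTPC",   -0.06, 0.02,
      "MLFER_S",       0.56, 0.23,
      "maxHother",    -1.39, 0.60,
      "GGI5",          0.65, 0.26,
      "VE3_Dt",       -4.00e-3, 2.5e-3)),
    eq4 = list(-1.04, 0.16, 258L, tdf(
      "SubFPC295",    -0.42, 0.06,
      "PubchemFP503",  1.38, 0.18,
      "R_TpiPCTPC",   -0.06, 0.02,
      "MLFER_S",       0.57, 0.23,
      "GGI5",          0.73, 0.22,
      "maxHother",    -1.05, 0.55,
      "VE3_Dt",       -5.00e-3, 2.4e-3)))
  qsar_model(intercept = spec[[1]], intercept_se = spec[[2]],
             terms = spec[[4]], training_n = spec[[3]], model_id = id)
}

#' @rdname builtin_model
#' @export
qsar_model <- function(intercept, terms, intercept_se = NA_real_,
                       training_n = NA_integer_, model_id = "custom") {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "coefficient", "se") %in% names(terms)))
  if (anyDuplicated(terms$name)) stop("duplicated term names")
  structure(list(model_id = model_id,
                 intercept = intercept, intercept_se = intercept_se,
                 terms = terms, training_n = as.integer(training_n),
                 endpoint = "Log BMF_L (dietary)"),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model %s> endpoint: %s (n_training = %s)\n",
              x$model_id, x$endpoint,
              ifelse(is.na(x$training_n), "?", x$training_n)))
  cat(sprintf("  intercept %8.4g (+/- %.4g)\n", x$intercept, x$intercept_se))
  for (k in seq_len(nrow(x$terms)))
    cat(sprintf("  %+9.4g (+/- %.4g) * %s\n", x$terms$coefficient[k],
                x$terms$se[k], x$terms$name[k]))
  invisible(x)
}

#' @export
coef.qsar_model <- function(object, ...) {
  stats::setNames(c(object$intercept, object$terms$coefficient),
                  c("(Intercept)", object$terms$name))
}

#' Predict Log BMF_L from a descriptor vector or matrix
#'
#' @param object a `qsar_model`.
#' @param newdata named numeric vector, or data.frame/matrix with one column
#'   per model descriptor (extra columns ignored).
#' @param ... unused.
#' @return numeric vector of Log BMF_L predictions (log10 units).
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  nm <- object$terms$name
  if (is.null(dim(newdata))) {
    newdata <- as.data.frame(as.list(newdata), check.names = FALSE)
  }
  miss <- setdiff(nm, colnames(newdata))
  if (length(miss))
    stop("missing descriptor(s) for ", object$model_id, ": ",
         paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata, check.names = FALSE)[, nm, drop = FALSE])
  drop(object$intercept + X %*% object$terms$coefficient)
}

#' Biomagnification classification
#'
#' A chemical is flagged as capable of biomagnifying when its BMF exceeds 1,
#' i.e. Log BMF_L strictly greater than 0 (the boundary value 0 is classified
#' as non-biomagnifier).
#'
#' @param log_bmf_l numeric vector of Log BMF_L values.
#' @return logical vector.
#' @export
classify_biomagnifier <- function(log_bmf_l) {
  if (any(!is.finite(log_bmf_l))) stop("log_bmf_l must be finite")
  log_bmf_l > 0
}

#' Model card for a frozen predictor
#'
#' Serializable QMRF-style metadata: endpoint, coefficients at printed
#' precision, training size.  Round-trips through JSON bit-exactly because
#' coefficients are stored, never re-derived.
#'
#' @param m a `qsar_model`.
#' @return a list suitable for [jsonlite::toJSON()].
#' @export
model_card <- function(m) {
  stopifnot(inherits(m, "qsar_model"))
  list(model_id = m$model_id, endpoint = m$endpoint,
       training_n = m$training_n,
       intercept = list(estimate = m$intercept, se = m$intercept_se),
       terms = m$terms,
       software = paste0("bmfqsar ",
                         as.character(utils::packageVersion("bmfqsar"))))
}
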