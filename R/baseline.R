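# Linear-regression comparator: treatment category fitted on the six raw
# predictors by a pseudoinverse least-squares solve, no intercept, and
# classified with the same nearest-integer thresholding as the fuzzy system.

#' Fit the multiple-input regression comparator
#'
#' `TC = a1*Age + a2*VA + a3*IOP + a4*VF + a5*Drops + a6*Type`: the
#' coefficient vector is `pinv(X) %*% TC` on the raw (unnormalized)
#' predictor matrix, i.e. the minimum-norm least-squares solution, whose
#' residual is orthogonal to the column space of X. No intercept by default
#' (the model is a pure weighted sum of the six measurements); set
#' `intercept = TRUE` to append one for exploration.
#'
#' @param cohort a labeled cohort.
#' @param intercept add a constant regressor (default `FALSE`).
#' @return object of class `migs_regression`: `coefficients` (named),
#'   `intercept` flag.
#' @export
fit_regression <- function(cohort, intercept = FALSE) {
  if (nrow(cohort) == 0) stopf("cannot fit regression on an empty cohort")
  if (!is_labeled(cohort)) stopf("regression baseline needs treatment labels")
  X <- feature_matrix(cohort)
  if (intercept) X <- cbind(X, `(intercept)` = 1)
  a <- minnorm_lstsq(X, cohort$treatment)
  names(a) <- colnames(X)
  structure(list(coefficients = a, intercept = intercept),
            class = "migs_regression")
}

#' @export
print.migs_regression <- function(x, ...) {
  cat("Pseudoinverse regression comparator (treatment ~ raw predictors):\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Predict with the regression comparator
#'
#' @param object a [fit_regression()] model.
#' @param newdata a cohort or data frame with the six raw predictors.
#' @param type `"class"` for thresholded codes, `"raw"` for the continuous
#'   estimate.
#' @param n_classes number of treatment codes to clamp into.
#' @param ... unused.
#' @return numeric (`"raw"`) or integer (`"class"`) vector.
#' @export
predict.migs_regression <- function(object, newdata, type = c("class", "raw"),
                                    n_classes = 4L, ...) {
  type <- match.arg(type)
  X <- feature_matrix(as_cohort(as.data.frame(newdata)))
  if (object$intercept) X <- cbind(X, 1)
  raw <- drop(X %*% object$coefficients)
  if (type == "raw") raw else round_to_class(raw, n_classes)
}
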