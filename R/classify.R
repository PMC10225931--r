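# From crisp outputs to treatment classes, and the full multiclass
# evaluation rubric: confusion matrix, one-vs-rest TP/TN/FP/FN, the eight
# per-class ratio metrics, Pearson significance, and decision surfaces.

#' Round a crisp output to a treatment class code
#'
#' Nearest-integer thresholding with the half point rounding up (so outputs
#' in \[1.5, 2.5) map to class 2), clamped into the valid code range 1..C.
#' Monotone nondecreasing in `y`.
#'
#' @param y crisp numeric output(s).
#' @param n_classes number of classes C (>= 2).
#' @return integer class code(s) in 1..C.
#' @export
round_to_class <- function(y, n_classes = 4L) {
  if (n_classes < 2) stopf("need at least two classes")
  if (any(!is.finite(y))) stopf("cannot classify a non-finite output")
  as.integer(pmin(pmax(floor(y + 0.5), 1), n_classes))
}

#' Multiclass confusion matrix
#'
#' `counts[i, j]` = number of samples with true class i predicted as j.
#'
#' @param true_codes,pred_codes integer class codes in 1..n_classes.
#' @param n_classes number of classes.
#' @return integer matrix of class `confusion_matrix` with dimnames
#'   `true`/`predicted`.
#' @export
confusion <- function(true_codes, pred_codes, n_classes = 4L) {
  if (length(true_codes) != length(pred_codes)) {
    stopf("true and predicted code vectors differ in length")
  }
  codes <- seq_len(n_classes)
  if (!all(true_codes %in% codes) || !all(pred_codes %in% codes)) {
    stopf("class codes must lie in 1..%d", n_classes)
  }
  m <- table(factor(true_codes, levels = codes),
             factor(pred_codes, levels = codes))
  m <- matrix(as.integer(m), n_classes, n_classes,
              dimnames = list(true = codes, predicted = codes))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' One-vs-rest counts for a single class
#'
#' TP is the diagonal cell of class k; FP the rest of its predicted column;
#' FN the rest of its true row; TN everything else.
#'
#' @param m a [confusion()] matrix.
#' @param k class index.
#' @return named list `tp`, `tn`, `fp`, `fn` (summing to the matrix total).
#' @export
class_counts <- function(m, k) {
  C <- nrow(m)
  if (k < 1 || k > C) stopf("class index out of range")
  tp <- m[k, k]
  fp <- sum(m[, k]) - tp
  fn <- sum(m[k, ]) - tp
  tn <- sum(m) - tp - fp - fn
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' The eight per-class rubric metrics
#'
#' Sensitivity (TPR), specificity (TNR), precision (PPV), negative
#' predictive value (NPV), fall-out (FPR), miss rate (FNR), false discovery
#' rate (FDR) and per-class accuracy (ACC), each the plain count ratio. A
#' zero denominator yields NaN rather than an error (the indeterminate-value
#' convention for empty classes).
#'
#' @param counts a [class_counts()] list.
#' @return named numeric vector `tpr, tnr, ppv, npv, fpr, fnr, fdr, acc`.
#' @export
class_metrics <- function(counts) {
  ratio <- function(num, den) if (den == 0) NaN else num / den
  with(counts, c(
    tpr = ratio(tp, tp + fn),
    tnr = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    fpr = ratio(fp, fp + tn),
    fnr = ratio(fn, tp + fn),
    fdr = ratio(fp, tp + fp),
    acc = ratio(tp + tn, tp + fp + fn + tn)
  ))
}

#' Per-class metric table for a whole confusion matrix
#'
#' @param m a [confusion()] matrix.
#' @return data frame, one row per class, columns `class` plus the eight
#'   metrics of [class_metrics()].
#' @export
metrics_table <- function(m) {
  rows <- lapply(seq_len(nrow(m)), function(k) {
    c(class = k, class_metrics(class_counts(m, k)))
  })
  as.data.frame(do.call(rbind, rows))
}

#' NaN-skipping unweighted mean over classes
#'
#' The aggregate used when comparing classifiers: the mean of a per-class
#' metric over all classes for which it is defined.
#'
#' @param v numeric vector, possibly containing NaN.
#' @return mean of the defined entries.
#' @export
mean_defined <- function(v) mean(v[!is.nan(v)])

#' Pearson correlation and two-sided significance
#'
#' Sample Pearson r between actual and estimated outcome codes, with the
#' two-sided p-value from `t = r sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom. Perfect correlation gives p = 0.
#'
#' @param actual,estimated numeric vectors of equal length n >= 3 with
#'   nonzero variance.
#' @return list with `r` and `p`.
#' @export
pearson_significance <- function(actual, estimated) {
  n <- length(actual)
  if (length(estimated) != n) stopf("vectors differ in length")
  if (n < 3) stopf("need at least 3 paired observations")
  if (stats::var(actual) == 0 || stats::var(estimated) == 0) {
    stopf("correlation undefined: zero variance")
  }
  r <- stats::cor(actual, estimated)
  if (1 - r^2 <= 0) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p)
}

#' Pairwise decision surfaces
#'
#' Evaluates the trained system on a regular grid over every unordered pair
#' of the six inputs — choose(6, 2) = 15 surfaces — while holding the
#' remaining inputs at `fixed_values` (default: the training-set feature
#' means stored in the model). Each grid spans the feature's observed
#' training min..max. Coordinates and fixed values are on the normalized
#' feature scale the model evaluates on.
#'
#' @param model a `fis_model` built by [build_fis()] (its meta carries the
#'   training feature ranges and means).
#' @param grid_size points per axis (>= 2), default 50.
#' @param fixed_values optional named six-vector of held-constant values.
#' @return named list of 15 surfaces, each a list with `x_name`, `y_name`,
#'   `x`, `y` (axis vectors) and `z` (grid_size x grid_size output matrix).
#' @export
decision_surfaces <- function(model, grid_size = 50L, fixed_values = NULL) {
  if (grid_size < 2) stopf("grid_size must be at least 2")
  d <- ncol(model$centers)
  lo <- model$meta$feature_min
  hi <- model$meta$feature_max
  if (is.null(lo) || is.null(hi)) stopf("model meta lacks feature ranges")
  if (is.null(fixed_values)) fixed_values <- model$meta$feature_means
  fixed_values <- unlist(fixed_values)
  pairs <- utils::combn(d, 2)
  out <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    xi <- seq(lo[i], hi[i], length.out = grid_size)
    xj <- seq(lo[j], hi[j], length.out = grid_size)
    G <- matrix(fixed_values, grid_size^2, d, byrow = TRUE)
    G[, i] <- rep(xi, times = grid_size)
    G[, j] <- rep(xj, each = grid_size)
    z <- matrix(evaluate_fis(model, G), grid_size, grid_size)
    nm <- paste(model$feature_names[i], model$feature_names[j], sep = "_x_")
    out[[nm]] <- list(x_name = model$feature_names[i],
                      y_name = model$feature_names[j],
                      x = xi, y = xj, z = z)
  }
  out
}
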