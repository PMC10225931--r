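# End-to-end convenience pipeline: clean -> normalize -> split -> cluster
# -> build -> hybrid-train, and the matching evaluation report.

#' Train the treatment-selection fuzzy system on a labeled cohort
#'
#' Runs the full modelling pipeline: drop incomplete records, fit and apply
#' the abs-max normalizer, split 60/40 with a 5% validation carve-out of the
#' training share, subtractively cluster the joint normalized
#' input+output matrix (the output column scaled like an input) to extract
#' one rule per cluster, and hybrid-train the resulting Sugeno system.
#'
#' @param cohort a labeled cohort (raw clinical units).
#' @param radius radius of influence for rule extraction; default 0.15.
#' @param train_frac,val_frac_of_train split fractions, defaults 0.60 and
#'   0.05.
#' @param epochs premise training epochs; default 10.
#' @param seed RNG seed for the split.
#' @param subclust extra [subclust_params()] overrides (squash,
#'   accept_ratio, reject_ratio).
#' @param config optional [train_config()]; its `epochs`/`seed` default to
#'   this function's arguments.
#' @return list of class `migs_fit`: `model`, `history`, `split` (the three
#'   raw cohorts), `clusters`, `normalizer`.
#' @export
migs_train <- function(cohort, radius = 0.15, train_frac = 0.60,
                       val_frac_of_train = 0.05, epochs = 10L, seed = 1L,
                       subclust = NULL, config = NULL) {
  cohort <- clean_cohort(as_cohort(as.data.frame(cohort)))
  if (nrow(cohort) == 0) stopf("no usable records after cleaning")
  if (!is_labeled(cohort)) stopf("training requires treatment labels")
  # normalization precedes the random split, so one abs-max spec covers the
  # whole cohort and travels with the model for later prediction
  normalizer <- fit_normalizer(cohort)
  split <- split_cohort(cohort, train_frac, val_frac_of_train, seed)
  norm_of <- function(part) feature_matrix(apply_normalizer(part, normalizer))
  Xtr <- norm_of(split$train)
  ytr <- split$train$treatment
  params <- do.call(subclust_params, c(list(radius = radius), subclust))
  clusters <- subtractive_cluster(cbind(Xtr, treatment = ytr), params)
  model <- build_fis(clusters, Xtr, ytr, radius, normalizer = normalizer,
                     meta = list(seed = seed))
  cfg <- config %||% train_config(epochs = epochs, seed = seed)
  has_val <- nrow(split$val) > 0
  fit <- train_anfis(model, Xtr, ytr,
                     xval = if (has_val) norm_of(split$val),
                     yval = if (has_val) split$val$treatment,
                     config = cfg)
  structure(list(model = fit$model, history = fit$history, split = split,
                 clusters = clusters, normalizer = normalizer),
            class = "migs_fit")
}

#' @export
print.migs_fit <- function(x, ...) {
  cat(sprintf(
    "Trained MIGS advisor: %d rules from %d training / %d validation / %d test patients\n",
    nrow(x$model$centers), nrow(x$split$train), nrow(x$split$val),
    nrow(x$split$test)))
  invisible(x)
}

#' Evaluate a trained model on a labeled cohort
#'
#' Produces the raw and thresholded predictions, the confusion matrix, the
#' per-class eight-metric table, the Pearson correlation between actual and
#' estimated codes with its two-sided significance, and the overall
#' fraction of exact class matches.
#'
#' @param model a `fis_model` (or `migs_fit`, whose model is used).
#' @param cohort a labeled cohort in raw units.
#' @return list of class `migs_evaluation`: `raw`, `predicted`, `actual`,
#'   `confusion`, `metrics` (4 x 8 data frame), `pearson` (r, p),
#'   `accuracy`.
#' @export
migs_evaluate <- function(model, cohort) {
  if (inherits(model, "migs_fit")) model <- model$model
  cohort <- clean_cohort(as_cohort(as.data.frame(cohort)))
  if (!is_labeled(cohort)) stopf("evaluation requires treatment labels")
  raw <- predict(model, cohort, type = "raw")
  pred <- round_to_class(raw, model$n_classes)
  actual <- as.integer(cohort$treatment)
  cm <- confusion(actual, pred, model$n_classes)
  structure(list(raw = raw, predicted = pred, actual = actual,
                 confusion = cm, metrics = metrics_table(cm),
                 pearson = pearson_significance(actual, raw),
                 accuracy = mean(pred == actual)),
            class = "migs_evaluation")
}

#' @export
print.migs_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation on %d patients: accuracy %.4f, Pearson r %.4f (p %.3g)\n",
              length(x$actual), x$accuracy, x$pearson$r, x$pearson$p))
  cat("Per-class metrics (4 dp):\n")
  tab <- x$metrics
  tab[-1] <- lapply(tab[-1], function(v) formatC(round(v, 4), format = "f", digits = 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
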