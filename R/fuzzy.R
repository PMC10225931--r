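# First-order Takagi-Sugeno fuzzy inference with Gaussian premises.
#
# A model is a bank of R rules over the six normalized predictors. Rule c
# fires with strength w_c = prod_d exp(-(x_d - mu_cd)^2 / (2 sigma_cd^2))
# (product t-norm) and contributes the linear consequent
# f_c(x) = p_c . x + r_c; the crisp output is the firing-strength-weighted
# average of the consequents, i.e. the centroid of the rule outputs.
#
# Internally the rule bank is stored as three matrices (centers, sigmas:
# R x 6; consequents: R x 7, bias last) for vectorized evaluation.

SIGMA_FLOOR <- 1e-6

#' Gaussian membership degree
#'
#' `exp(-(x - center)^2 / (2 sigma^2))`: 1 at the center, symmetric, never
#' exactly zero.
#'
#' @param x numeric value(s) on the normalized feature scale.
#' @param center membership center.
#' @param sigma membership width, > 0.
#' @return membership degree(s) in (0, 1].
#' @export
mf_degree <- function(x, center, sigma) {
  if (any(sigma <= 0)) stopf("Gaussian membership sigma must be positive")
  exp(-((x - center)^2) / (2 * sigma^2))
}

new_fis_model <- function(centers, sigmas, consequents, normalizer = NULL,
                          n_classes = 4L, feature_names = migs_features,
                          meta = list()) {
  stopifnot(nrow(centers) >= 1, all(dim(centers) == dim(sigmas)),
            nrow(consequents) == nrow(centers),
            ncol(consequents) == ncol(centers) + 1)
  structure(list(centers = centers, sigmas = sigmas, consequents = consequents,
                 normalizer = normalizer, n_classes = as.integer(n_classes),
                 feature_names = feature_names, meta = meta),
            class = "fis_model")
}

#' @export
print.fis_model <- function(x, ...) {
  cat(sprintf("Sugeno fuzzy system: %d rules, %d inputs, %d output classes\n",
              nrow(x$centers), ncol(x$centers), x$n_classes))
  if (!is.null(x$meta$radius)) {
    cat(sprintf("  cluster radius %.3g; epochs trained %s\n", x$meta$radius,
                x$meta$epochs_trained %||% 0L))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

n_rules <- function(model) nrow(model$centers)

#' Rule firing strengths
#'
#' Product t-norm across the six premise memberships of every rule.
#'
#' @param model a `fis_model`.
#' @param x numeric matrix of normalized inputs (rows = samples) or a single
#'   six-vector.
#' @return matrix (n samples x R rules) of strengths in (0, 1].
#' @export
rule_firing <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  n <- nrow(X)
  R <- n_rules(model)
  W <- matrix(0, n, R)
  for (c in seq_len(R)) {
    Z <- (X - matrix(model$centers[c, ], n, ncol(X), byrow = TRUE)) /
      matrix(model$sigmas[c, ], n, ncol(X), byrow = TRUE)
    W[, c] <- exp(-0.5 * rowSums(Z^2))
  }
  W
}

# Linear consequent values f_c(x) for every sample/rule pair (n x R).
consequent_values <- function(model, X) {
  X %*% t(model$consequents[, -ncol(model$consequents), drop = FALSE]) +
    matrix(model$consequents[, ncol(model$consequents)], nrow(X),
           n_rules(model), byrow = TRUE)
}

#' Evaluate the fuzzy system
#'
#' Weighted-average defuzzification: `y = sum_c w_c f_c(x) / sum_c w_c`, a
#' convex combination of the rule consequents, so the output always lies
#' within their range at `x`.
#'
#' @param model a `fis_model`.
#' @param x normalized input matrix (rows = samples) or single six-vector.
#' @return numeric vector of crisp outputs.
#' @export
evaluate_fis <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  W <- rule_firing(model, X)
  S <- rowSums(W)
  if (any(S < 1e-300)) stopf("degenerate firing: no rule responds to an input")
  rowSums(W * consequent_values(model, X)) / S
}

#' Build the initial fuzzy system from a cluster set
#'
#' One rule per cluster (1:1 correspondence between clusters and rules):
#' premise centers are the cluster center's input coordinates; every
#' premise width is `radius * (max_d - min_d) / sqrt(8)` on the per-feature
#' training range (the classical conversion of a subtractive-clustering
#' radius into a Gaussian sigma), floored at 1e-6 on degenerate dimensions.
#' Consequents are initialized by the global least-squares solve
#' ([lse_consequents()]).
#'
#' @param clusters a [subtractive_cluster()] result on the joint
#'   input+output matrix (inputs first, output last column).
#' @param x normalized training predictor matrix (n x 6).
#' @param y numeric training targets (raw class codes 1-4).
#' @param radius radius of influence used for the sigma conversion.
#' @param normalizer optional [fit_normalizer()] spec stored for prediction.
#' @param constant_consequents use zero-order (constant) consequents.
#' @param meta extra provenance entries stored in the model.
#' @return a `fis_model`.
#' @export
build_fis <- function(clusters, x, y, radius, normalizer = NULL,
                      constant_consequents = FALSE, meta = list()) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stopf("empty training matrix")
  d_in <- ncol(x)
  centers <- clusters$centers[, seq_len(d_in), drop = FALSE]
  span <- apply(x, 2, max) - apply(x, 2, min)
  sigma_row <- pmax(radius * span / sqrt(8), SIGMA_FLOOR)
  sigmas <- matrix(sigma_row, nrow(centers), d_in, byrow = TRUE)
  consequents <- matrix(0, nrow(centers), d_in + 1)
  meta <- utils::modifyList(
    list(radius = radius, epochs_trained = 0L,
         constant_consequents = constant_consequents,
         feature_means = colMeans(x),
         feature_min = apply(x, 2, min), feature_max = apply(x, 2, max)),
    meta)
  model <- new_fis_model(centers, sigmas, consequents, normalizer = normalizer,
                         meta = meta)
  lse_consequents(model, x, y)
}

#' Predict treatment categories for new patients
#'
#' Normalizes the raw cohort with the training-time abs-max spec stored in
#' the model, evaluates the fuzzy system, and (for `type = "class"`) rounds
#' to the nearest treatment code.
#'
#' @param object a `fis_model` holding a normalizer.
#' @param newdata a cohort or data frame with the six predictor columns.
#' @param type `"raw"` for the crisp continuous output, `"class"` for
#'   treatment codes 1-4.
#' @param ... unused.
#' @return numeric vector (`"raw"`) or integer vector (`"class"`).
#' @export
predict.fis_model <- function(object, newdata, type = c("class", "raw"), ...) {
  type <- match.arg(type)
  if (is.null(object$normalizer)) {
    stopf("model carries no normalizer; evaluate with evaluate_fis() instead")
  }
  coh <- as_cohort(as.data.frame(newdata))
  X <- feature_matrix(apply_normalizer(coh, object$normalizer))
  y <- evaluate_fis(object, X)
  if (type == "raw") y else round_to_class(y, object$n_classes)
}

#' Serialize a fuzzy model to JSON
#'
#' Full double precision; the file holds the rule bank, the training
#' normalizer and provenance metadata, and round-trips losslessly through
#' [read_fis()].
#'
#' @param model a `fis_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fis <- function(model, path) {
  rules <- lapply(seq_len(n_rules(model)), function(c) {
    list(premise = lapply(seq_len(ncol(model$centers)), function(d) {
      list(center = model$centers[c, d], sigma = model$sigmas[c, d])
    }),
    consequent = model$consequents[c, ])
  })
  doc <- list(
    meta = model$meta,
    n_classes = model$n_classes,
    feature_names = model$feature_names,
    normalizer = if (!is.null(model$normalizer)) {
      as.list(model$normalizer$abs_max)
    },
    rules = rules
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Deserialize a fuzzy model written by [write_fis()]
#'
#' @param path JSON model file.
#' @return a `fis_model`.
#' @export
read_fis <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  R <- length(doc$rules)
  d_in <- length(doc$rules[[1]]$premise)
  centers <- matrix(0, R, d_in)
  sigmas <- matrix(0, R, d_in)
  consequents <- matrix(0, R, d_in + 1)
  for (c in seq_len(R)) {
    for (d in seq_len(d_in)) {
      centers[c, d] <- doc$rules[[c]]$premise[[d]]$center
      sigmas[c, d] <- doc$rules[[c]]$premise[[d]]$sigma
    }
    consequents[c, ] <- unlist(doc$rules[[c]]$consequent)
  }
  feature_names <- unlist(doc$feature_names)
  colnames(centers) <- colnames(sigmas) <- feature_names
  normalizer <- if (!is.null(doc$normalizer)) {
    structure(list(abs_max = unlist(doc$normalizer)), class = "migs_normalizer")
  }
  meta <- lapply(doc$meta, function(v) if (length(v) > 1 || is.list(v)) unlist(v) else v)
  new_fis_model(centers, sigmas, consequents, normalizer = normalizer,
                n_classes = doc$n_classes, feature_names = feature_names,
                meta = meta)
}
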