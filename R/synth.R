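# Synthetic glaucoma cohorts: truncated-normal marginals matching the
# published cohort summary statistics, plus a planted rulebook mapping
# features to the four MIGS categories so that recovery of the structure by
# the classifier can be tested end to end.

#' Default per-feature marginal parameters
#'
#' Mean and SD follow the audited cohort's summary table; bounds take the
#' reported absolute maximum as the upper limit and a clinically sensible
#' lower limit. The visual-field upper bound (+1.11 dB) is the least
#' negative observed mean deviation. Glaucoma type is categorical over the
#' six codes.
#'
#' @return named list of `c(mean, sd, min, max)` vectors for the five
#'   continuous features.
#' @export
default_marginals <- function() {
  list(
    age = c(mean = 77.36, sd = 3.819, min = 40, max = 97),
    va = c(mean = 0.3, sd = 0.25, min = 0, max = 1.4),
    iop = c(mean = 18.54, sd = 4.62, min = 6, max = 40),
    vf = c(mean = -7.65, sd = 7.2, min = -33, max = 1.11),
    drops = c(mean = 2.12, sd = 1.08, min = 0, max = 5)
  )
}

#' Construct a rulebook
#'
#' An ordered list of predicate -> class rules applied first-match-first;
#' `default_class` labels records matching no predicate, making every
#' rulebook exhaustive.
#'
#' @param rules list of `list(predicate = function(df) logical, class = k)`.
#' @param default_class class code for unmatched records.
#' @return object of class `migs_rulebook`.
#' @export
rulebook <- function(rules, default_class) {
  structure(list(rules = rules, default_class = as.integer(default_class)),
            class = "migs_rulebook")
}

#' The default planted rulebook
#'
#' Four clinically flavoured assignment rules (high pressure -> shunt,
#' advanced field loss -> XEN, poor acuity -> combined stent/ECP, otherwise
#' plain stent), with thresholds placed so that every class keeps at least
#' roughly 10% prevalence under the default marginals:
#' `iop > 23 -> 2; vf < -13 -> 3; va > 0.55 -> 1; else 4`.
#'
#' @return a [rulebook()].
#' @export
default_rulebook <- function() {
  rulebook(list(
    list(predicate = function(df) df$iop > 23, class = 2L),
    list(predicate = function(df) df$vf < -13, class = 3L),
    list(predicate = function(df) df$va > 0.55, class = 1L)
  ), default_class = 4L)
}

#' Apply a rulebook to a feature table
#'
#' @param df data frame with the six predictor columns.
#' @param rb a [rulebook()].
#' @return integer class codes (first matching rule, else the default).
#' @export
apply_rulebook <- function(df, rb) {
  labels <- rep(rb$default_class, nrow(df))
  undecided <- rep(TRUE, nrow(df))
  for (rule in rb$rules) {
    hit <- undecided & rule$predicate(df)
    labels[hit] <- rule$class
    undecided <- undecided & !hit
  }
  as.integer(labels)
}

#' Synthetic-cohort configuration
#'
#' @param n cohort size.
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   cohorts.
#' @param marginals per-feature `c(mean, sd, min, max)` list, see
#'   [default_marginals()].
#' @param gtype_probs probabilities over the six glaucoma-type codes;
#'   default uniform. `skewed_gtype_probs()` provides an alternative whose
#'   mean matches the audited cohort's 5.13.
#' @param label_noise probability in \[0, 1) that a planted label is
#'   replaced by a uniform random class.
#' @param rules a [rulebook()] planting the feature-to-class structure.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 372L, seed = 1L,
                             marginals = default_marginals(),
                             gtype_probs = rep(1 / 6, 6),
                             label_noise = 0,
                             rules = default_rulebook()) {
  if (n < 1) stopf("cohort size must be at least 1")
  if (!(label_noise >= 0 && label_noise < 1)) {
    stopf("label_noise must lie in [0, 1)")
  }
  for (nm in names(marginals)) {
    m <- marginals[[nm]]
    if (m[["max"]] < m[["min"]] || m[["sd"]] <= 0) {
      stopf("invalid marginal for '%s'", nm)
    }
  }
  if (length(gtype_probs) != 6 || any(gtype_probs < 0)) {
    stopf("gtype_probs must be six nonnegative weights")
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 marginals = marginals,
                 gtype_probs = gtype_probs / sum(gtype_probs),
                 label_noise = label_noise, rules = rules),
            class = "synthetic_config")
}

#' Glaucoma-type weights skewed toward the open-angle codes
#'
#' Mixture over codes 1..6 with mean approximately 5.13, for emulating a
#' cohort dominated by primary/secondary open-angle glaucoma.
#'
#' @return probability vector of length 6.
#' @export
skewed_gtype_probs <- function() {
  p <- c(0.03, 0.03, 0.05, 0.06, 0.25, 0.58)
  p / sum(p)
}

# Inverse-CDF truncated-normal sampler.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  stats::qnorm(stats::runif(n, plo, phi)) * sd + mean
}

#' Generate a synthetic labeled cohort
#'
#' Continuous features are truncated-normal draws with the configured
#' marginal moments and bounds; daily drop counts are rounded to integers
#' within range; glaucoma type is categorical. Labels come from the planted
#' rulebook and are then flipped to a uniform random class with probability
#' `label_noise`. Features are sampled independently (no correlation
#' structure is imposed).
#'
#' @param cfg a [synthetic_config()].
#' @return a labeled `migs_cohort` of `cfg$n` records.
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    m <- cfg$marginals
    draw <- function(nm) {
      p <- m[[nm]]
      rtruncnorm(cfg$n, p[["mean"]], p[["sd"]], p[["min"]], p[["max"]])
    }
    df <- data.frame(
      age = draw("age"),
      va = draw("va"),
      iop = draw("iop"),
      vf = draw("vf"),
      drops = pmin(pmax(round(draw("drops")), m$drops[["min"]]),
                   m$drops[["max"]]),
      gtype = sample(1:6, cfg$n, replace = TRUE, prob = cfg$gtype_probs)
    )
    labels <- apply_rulebook(df, cfg$rules)
    if (cfg$label_noise > 0) {
      flip <- stats::runif(cfg$n) < cfg$label_noise
      labels[flip] <- sample(1:4, sum(flip), replace = TRUE)
    }
    df$treatment <- labels
    as_cohort(df)
  })
}
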