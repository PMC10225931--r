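# Cohort data model: loading, cleaning, abs-max normalization, splitting.

#' Canonical predictor names for a MIGS cohort
#'
#' Six baseline clinical measurements, in fixed order: patient age (years),
#' best-corrected visual acuity (LogMAR), intraocular pressure (mmHg),
#' visual-field mean deviation (dB, typically negative), number of daily
#' IOP-lowering drops, and the glaucoma-type code (integer 1-6).
#'
#' @format Character vector of length 6.
#' @export
migs_features <- c("age", "va", "iop", "vf", "drops", "gtype")

#' Construct a cohort from a data frame
#'
#' A cohort is a plain data frame carrying the six predictor columns (see
#' [migs_features]) and optionally a `treatment` column with the surgery
#' category code (integer 1-4: 1 = iStent+ECP "ICE2", 2 = PreserFlo
#' MicroShunt, 3 = XEN, 4 = iStent inject). Row order is identity: cleaning
#' and splitting always preserve it within each output.
#'
#' @param df data frame with numeric columns `age, va, iop, vf, drops, gtype`
#'   and optionally `treatment`.
#' @return the validated data frame with class `migs_cohort` prepended.
#' @export
as_cohort <- function(df) {
  missing_cols <- setdiff(migs_features, names(df))
  if (length(missing_cols) > 0) {
    stopf("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  keep <- c(migs_features, intersect("treatment", names(df)))
  df <- as.data.frame(df)[, keep, drop = FALSE]
  for (col in keep) {
    if (!is.numeric(df[[col]])) {
      stopf("cohort column '%s' is not numeric", col)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("migs_cohort", "data.frame")
  df
}

#' @export
print.migs_cohort <- function(x, ...) {
  lab <- if (is_labeled(x)) "labeled" else "unlabeled"
  cat(sprintf("MIGS cohort: %d patients (%s)\n", nrow(x), lab))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

is_labeled <- function(cohort) "treatment" %in% names(cohort)

#' Extract the predictor matrix of a cohort
#'
#' @param cohort a [as_cohort()] cohort.
#' @return numeric matrix with one column per entry of [migs_features].
#' @export
feature_matrix <- function(cohort) {
  as.matrix(as.data.frame(cohort)[, migs_features, drop = FALSE])
}

#' Read a cohort from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and "." as the
#' decimal mark. `schema` maps canonical names to file column names when the
#' file uses different headers. A file without a treatment column is read as
#' an unlabeled prediction cohort. Any non-numeric cell in a mapped column is
#' an error naming the offending row and column; genuinely empty cells and
#' literal `NA` become missing values to be handled by [clean_cohort()].
#'
#' @param path CSV file path.
#' @param schema named character vector mapping canonical column names
#'   (`age`, ..., `treatment`) to the file's column names; defaults to the
#'   canonical names themselves.
#' @return a `migs_cohort` preserving the file's row order.
#' @seealso [write_cohort()], [clean_cohort()]
#' @export
load_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  canonical <- c(migs_features, "treatment")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) map[names(schema)] <- schema
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE, fileEncoding = "UTF-8")
  need <- migs_features
  if (map[["treatment"]] %in% names(raw)) need <- canonical
  for (col in need) {
    if (!map[[col]] %in% names(raw)) {
      stopf("column '%s' (mapped from '%s') not found in %s", map[[col]], col, path)
    }
  }
  out <- list()
  for (col in need) {
    cell <- raw[[map[[col]]]]
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) & !(is.na(cell) | cell == "" | cell == "NA"))
    if (length(bad) > 0) {
      stopf("non-numeric value '%s' in row %d, column %s", cell[bad[1]], bad[1], col)
    }
    out[[col]] <- val
  }
  as_cohort(as.data.frame(out))
}

#' Write a cohort to CSV with the canonical header
#'
#' @param cohort a cohort.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop incomplete or ambiguously coded records
#'
#' Removes every record with a missing or non-finite field, a glaucoma-type
#' code outside the integer set 1-6, or (when the cohort is labeled) a
#' treatment code outside the integer set 1-4. Records are dropped, never
#' imputed. The number of dropped rows is attached as attribute `n_dropped`.
#'
#' @param cohort a cohort.
#' @return the cleaned cohort (possibly empty), row order preserved.
#' @export
clean_cohort <- function(cohort) {
  X <- feature_matrix(cohort)
  ok <- rowSums(!is.finite(X)) == 0
  ok <- ok & X[, "gtype"] %in% 1:6
  if (is_labeled(cohort)) {
    ok <- ok & !is.na(cohort$treatment) & cohort$treatment %in% 1:4
  }
  ok[is.na(ok)] <- FALSE
  out <- as_cohort(as.data.frame(cohort)[ok, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Fit the absolute-maximum normalizer
#'
#' Per-feature scale factors: the largest absolute value observed for each
#' predictor. Dividing by them maps every feature of the fitted cohort into
#' \[-1, 1\]. Variances are deliberately not standardized; only the scale is
#' removed. Treatment codes are never normalized.
#'
#' @param cohort a nonempty cohort.
#' @return object of class `migs_normalizer`: named vector `abs_max`.
#' @export
fit_normalizer <- function(cohort) {
  if (nrow(cohort) == 0) stopf("cannot fit a normalizer on an empty cohort")
  abs_max <- apply(abs(feature_matrix(cohort)), 2, max)
  zero <- names(abs_max)[abs_max == 0]
  if (length(zero) > 0) {
    stopf("degenerate all-zero feature column(s): %s", paste(zero, collapse = ", "))
  }
  structure(list(abs_max = abs_max), class = "migs_normalizer")
}

#' @export
print.migs_normalizer <- function(x, ...) {
  cat("Abs-max normalizer:\n")
  print(x$abs_max)
  invisible(x)
}

#' Apply (or invert) an absolute-maximum normalizer
#'
#' Divides each predictor elementwise by its `abs_max`; `invert = TRUE`
#' multiplies instead, recovering the raw scale to machine precision. Values
#' outside the training range pass through unclipped. Treatment labels are
#' untouched.
#'
#' @param cohort a cohort.
#' @param normalizer a [fit_normalizer()] result.
#' @param invert reverse the mapping.
#' @return the transformed cohort.
#' @export
apply_normalizer <- function(cohort, normalizer, invert = FALSE) {
  am <- normalizer$abs_max
  if (length(am) != length(migs_features) || any(!is.finite(am)) || any(am <= 0)) {
    stopf("normalizer must hold six positive finite abs-max values")
  }
  out <- as.data.frame(cohort)
  for (col in migs_features) {
    out[[col]] <- if (invert) out[[col]] * am[[col]] else out[[col]] / am[[col]]
  }
  as_cohort(out)
}

#' Random train / validation / test partition
#'
#' Shuffles the cohort under `seed` and splits it into a training share of
#' `round(train_frac * N)` rows and a test share of the remainder; a
#' validation set of `floor(val_frac_of_train * n_train_total)` rows is then
#' carved out of the training share (the convention of holding out a small
#' fraction of the training data to checkpoint intermediate fits). The three
#' parts are disjoint, exhaustive, and identical for identical seeds.
#'
#' @param cohort a cohort.
#' @param train_frac fraction of rows assigned to training (0, 1);
#'   default 0.60.
#' @param val_frac_of_train fraction of the training share held out for
#'   validation \[0, 1); default 0.05.
#' @param seed integer RNG seed.
#' @return list with cohorts `train`, `val`, `test`; the permuted row
#'   indices of each part are attached as attribute `indices`.
#' @export
split_cohort <- function(cohort, train_frac = 0.60, val_frac_of_train = 0.05,
                         seed = 1L) {
  if (!(train_frac > 0 && train_frac < 1)) stopf("train_frac must be in (0, 1)")
  if (!(val_frac_of_train >= 0 && val_frac_of_train < 1)) {
    stopf("val_frac_of_train must be in [0, 1)")
  }
  n <- nrow(cohort)
  perm <- with_seed(seed, sample.int(n))
  n_train_total <- round(train_frac * n)
  n_val <- floor(val_frac_of_train * n_train_total)
  idx <- list(
    train = sort(perm[seq_len(n_train_total - n_val)]),
    val = sort(perm[seq_len(n_val) + (n_train_total - n_val)]),
    test = sort(perm[seq_len(n - n_train_total) + n_train_total])
  )
  df <- as.data.frame(cohort)
  out <- lapply(idx, function(i) as_cohort(df[i, , drop = FALSE]))
  attr(out, "indices") <- idx
  out
}
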