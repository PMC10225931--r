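test_that("crisp outputs round to the nearest class code, clamped to range", {
  expect_equal(round_to_class(1.5), 2L)
  expect_equal(round_to_class(2.4), 2L)
  expect_equal(round_to_class(3.0), 3L)
  expect_equal(round_to_class(5.7, 4), 4L)
  expect_equal(round_to_class(0.2, 4), 1L)
  ys <- seq(-1, 6, by = 0.01)
  expect_true(all(diff(round_to_class(ys)) >= 0)) # monotone
  expect_error(round_to_class(NaN), "finite")
  expect_error(round_to_class(2, n_classes = 1), "two classes")
})

test_that("confusion matrix tallies true-by-predicted counts", {
  perfect <- confusion(c(1, 2, 2, 3, 4, 4), c(1, 2, 2, 3, 4, 4), 4)
  expect_equal(diag(perfect), c(`1` = 1L, `2` = 2L, `3` = 1L, `4` = 2L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)

  single <- confusion(2, 3, 4)
  expect_equal(single[2, 3], 1L)
  expect_equal(sum(single), 1L)

  tru <- c(1, 1, 2, 2, 3, 3, 4, 4, 1, 2, 3, 4)
  prd <- c(1, 2, 2, 2, 3, 1, 4, 3, 1, 4, 3, 4)
  m <- confusion(tru, prd, 4)
  hand <- matrix(0L, 4, 4)
  for (i in seq_along(tru)) hand[tru[i], prd[i]] <- hand[tru[i], prd[i]] + 1L
  expect_equal(unname(unclass(m)), hand)

  expect_error(confusion(1:3, 1:2, 4), "length")
  expect_error(confusion(c(1, 5), c(1, 2), 4), "1..4")
})

test_that("one-vs-rest counts reproduce the worked class-3 example", {
  m <- worked_confusion()
  expect_equal(sum(m), 112L)
  cc <- class_counts(m, 3)
  expect_equal(cc, list(tp = 11L, tn = 92L, fp = 6L, fn = 3L))
  for (k in 1:4) {
    counts <- class_counts(m, k)
    expect_equal(Reduce(`+`, counts), 112L) # partition identity
  }
  diagm <- confusion(c(1, 2, 3, 4), c(1, 2, 3, 4), 4)
  for (k in 1:4) {
    ck <- class_counts(diagm, k)
    expect_equal(ck$fp + ck$fn, 0L)
  }
  expect_equal(sum(sapply(1:4, function(k) class_counts(m, k)$tp)),
               sum(diag(m)))
})

test_that("the eight ratio metrics match the worked example to 4 decimals", {
  got <- class_metrics(list(tp = 11, tn = 92, fp = 6, fn = 3))
  expect_equal(round(got, 4),
               c(tpr = 0.7857, tnr = 0.9388, ppv = 0.6471, npv = 0.9684,
                 fpr = 0.0612, fnr = 0.2143, fdr = 0.3529, acc = 0.9196))
})

test_that("zero denominators yield NaN, and complements sum to one", {
  empty <- class_metrics(list(tp = 0, tn = 25, fp = 0, fn = 0))
  expect_true(is.nan(empty[["tpr"]]))
  expect_true(is.nan(empty[["ppv"]]))
  expect_true(is.nan(empty[["fdr"]]))
  expect_equal(empty[["tnr"]], 1)
  expect_equal(empty[["acc"]], 1)

  for (s in 1:30) {
    counts <- withr::with_seed(200 + s,
                               as.list(stats::setNames(sample(0:20, 4, TRUE),
                                                       c("tp", "tn", "fp", "fn"))))
    v <- class_metrics(counts)
    if (!is.nan(v[["tpr"]])) expect_equal(v[["tpr"]] + v[["fnr"]], 1)
    if (!is.nan(v[["tnr"]])) expect_equal(v[["tnr"]] + v[["fpr"]], 1)
    if (!is.nan(v[["ppv"]])) expect_equal(v[["ppv"]] + v[["fdr"]], 1)
  }

  diag4 <- confusion(1:4, 1:4, 4)
  tab <- metrics_table(diag4)
  expect_equal(tab$acc, rep(1, 4))
  expect_equal(mean_defined(c(0.5, NaN, 1)), 0.75)
})

test_that("Pearson r and significance follow the t-distribution form", {
  x <- c(1, 2, 3, 4, 2, 3)
  self <- pearson_significance(x, x)
  expect_equal(self$r, 1)
  expect_equal(self$p, 0)
  anti <- pearson_significance(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(anti$r, -1)

  # cross-check against the standard test implementation
  fix <- withr::with_seed(55, list(a = rnorm(25), b = rnorm(25)))
  got <- pearson_significance(fix$a, fix$b)
  ref <- stats::cor.test(fix$a, fix$b)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  expect_error(pearson_significance(rep(1, 5), 1:5), "variance")
  expect_error(pearson_significance(1:2, 2:1), "3")
})

test_that("the analytic p-value agrees with a permutation oracle", {
  fix <- withr::with_seed(66, {
    a <- rnorm(20)
    list(a = a, b = 0.4 * a + rnorm(20))
  })
  got <- pearson_significance(fix$a, fix$b)
  perm <- withr::with_seed(67, {
    r_obs <- abs(stats::cor(fix$a, fix$b))
    hits <- replicate(1e5, abs(stats::cor(fix$a, sample(fix$b))) >= r_obs)
    mean(hits)
  })
  expect_equal(got$p, perm, tolerance = 0.01)
})

test_that("decision surfaces cover all 15 input pairs at the grid size", {
  coh <- as_cohort(tiny_cohort_df(40, seed = 21))
  fit <- migs_train(coh, radius = 0.5, epochs = 0, seed = 2)
  surf <- decision_surfaces(fit$model, grid_size = 8)
  expect_length(surf, choose(6, 2))
  expect_true(all(sapply(surf, function(s) all(dim(s$z) == c(8, 8)))))
  pair_names <- sapply(surf, function(s) paste(s$x_name, s$y_name))
  expect_equal(anyDuplicated(pair_names), 0L)

  # a single-rule constant model gives flat surfaces
  flat <- migsfis:::new_fis_model(
    matrix(0.5, 1, 6), matrix(0.3, 1, 6), matrix(c(rep(0, 6), 2.5), 1),
    meta = list(feature_min = rep(0, 6), feature_max = rep(1, 6),
                feature_means = rep(0.5, 6)))
  fs <- decision_surfaces(flat, grid_size = 4)
  expect_true(all(sapply(fs, function(s) max(abs(s$z - 2.5)) < 1e-12)))
  expect_error(decision_surfaces(flat, grid_size = 1), "grid_size")
})
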