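test_that("single-rule consequent solve reduces to ordinary least squares", {
  X <- withr::with_seed(12, matrix(runif(60, -1, 1), 10, 6))
  y <- 2 * X[, 1] + 1
  m <- migsfis:::new_fis_model(matrix(0, 1, 6), matrix(1, 1, 6),
                               matrix(0, 1, 7))
  m <- lse_consequents(m, X, y)
  expect_equal(unname(m$consequents[1, ]), c(2, 0, 0, 0, 0, 0, 1),
               tolerance = 1e-9)
  expect_error(lse_consequents(m, X[0, , drop = FALSE], numeric(0)), "one")
})

test_that("the consequent solve never increases training SSE", {
  for (s in 1:50) {
    fix <- withr::with_seed(100 + s, {
      X <- matrix(runif(24, -1, 1), 12, 2)
      y <- runif(12, 1, 4)
      cons <- matrix(rnorm(6), 2, 3)
      list(X = X, y = y, cons = cons)
    })
    m <- two_rule_truth()
    m$consequents <- fix$cons
    before <- sse_of(m, fix$X, fix$y)
    after <- sse_of(lse_consequents(m, fix$X, fix$y), fix$X, fix$y)
    expect_lte(after, before + 1e-10)
  }
})

test_that("duplicated rows solve the same problem as weighted deduplication", {
  X <- withr::with_seed(13, matrix(runif(16, -1, 1), 8, 2))
  y <- withr::with_seed(14, runif(8, 1, 4))
  m <- two_rule_truth()
  dup <- lse_consequents(m, X[rep(1:8, each = 2), ], rep(y, each = 2))
  # oracle: sqrt(weight)-scaled rows of the single-copy design matrix
  W <- rule_firing(m, X)
  Wbar <- W / rowSums(W)
  A <- cbind(Wbar[, 1] * cbind(X, 1), Wbar[, 2] * cbind(X, 1))
  theta <- qr.solve(sqrt(2) * A, sqrt(2) * y)
  expect_equal(as.vector(t(dup$consequents)), unname(theta), tolerance = 1e-8)
})

test_that("analytic premise gradients match central finite differences", {
  m <- two_rule_truth()
  fix <- withr::with_seed(15, list(X = matrix(runif(30, 0, 1), 15, 2),
                                   y = runif(15, 1, 4)))
  g <- migsfis:::premise_gradients(m, fix$X, fix$y)
  h <- 1e-6
  for (c in 1:2) {
    for (d in 1:2) {
      for (field in c("centers", "sigmas")) {
        up <- m; up[[field]][c, d] <- up[[field]][c, d] + h
        dn <- m; dn[[field]][c, d] <- dn[[field]][c, d] - h
        num <- (sse_of(up, fix$X, fix$y) - sse_of(dn, fix$X, fix$y)) / (2 * h)
        ana <- if (field == "centers") g$centers[c, d] else g$sigmas[c, d]
        expect_equal(ana, num, tolerance = 1e-5)
      }
    }
  }
})

test_that("gradient step honours step = 0 and the sigma floor", {
  m <- two_rule_truth()
  fix <- withr::with_seed(16, list(X = matrix(runif(20), 10, 2),
                                   y = runif(10, 1, 4)))
  expect_identical(premise_gradient_step(m, fix$X, fix$y, 0), m)
  m2 <- m
  m2$sigmas[] <- 1e-6 # already at the floor; a step cannot go below it
  stepped <- premise_gradient_step(m2, fix$X, fix$y, 0.5)
  expect_true(all(stepped$sigmas >= 1e-6))
  expect_error(premise_gradient_step(m, fix$X, fix$y, -1), "nonnegative")
})

test_that("epoch-0 training is exactly the least-squares initialization", {
  X <- withr::with_seed(17, matrix(runif(40, -1, 1), 20, 2))
  y <- withr::with_seed(18, runif(20, 1, 4))
  cl <- subtractive_cluster(cbind(X, y), subclust_params(radius = 0.5))
  m0 <- build_fis(cl, X, y, radius = 0.5)
  out <- train_anfis(m0, X, y, config = train_config(epochs = 0))
  expect_equal(out$model$consequents, m0$consequents, tolerance = 1e-12)
  expect_equal(out$model$centers, m0$centers)
  expect_equal(nrow(out$history), 1)
  expect_error(train_config(epochs = -1), "epochs")
})

test_that("validation checkpointing returns the recorded minimum", {
  X <- withr::with_seed(19, matrix(runif(60, -1, 1), 30, 2))
  y <- 2 + sin(3 * X[, 1]) + 0.5 * X[, 2]
  Xv <- withr::with_seed(20, matrix(runif(20, -1, 1), 10, 2))
  yv <- 2 + sin(3 * Xv[, 1]) + 0.5 * Xv[, 2]
  cl <- subtractive_cluster(cbind(X, y), subclust_params(radius = 0.7))
  m0 <- build_fis(cl, X, y, radius = 0.7)
  out <- train_anfis(m0, X, y, Xv, yv, config = train_config(epochs = 15))
  hist <- out$history
  best <- attr(hist, "best_epoch")
  expect_equal(best, hist$epoch[which.min(hist$val_rmse)])
  returned_val <- sqrt(mean((evaluate_fis(out$model, Xv) - yv)^2))
  expect_equal(returned_val, min(hist$val_rmse), tolerance = 1e-12)
  expect_lte(returned_val, hist$val_rmse[nrow(hist)]) # early-stop dominance

  rerun <- train_anfis(m0, X, y, Xv, yv, config = train_config(epochs = 15))
  expect_identical(rerun$history, hist) # fully deterministic
})

test_that("data simulated from a known two-rule system is recovered", {
  truth <- two_rule_truth()
  X <- withr::with_seed(77, matrix(runif(160), 80, 2))
  y <- evaluate_fis(truth, X)
  cl <- subtractive_cluster(cbind(X, y), subclust_params(radius = 0.5))
  m0 <- build_fis(cl, X, y, radius = 0.5)
  out <- train_anfis(m0, X, y, config = train_config(epochs = 50))
  expect_lt(min(out$history$train_rmse), 0.05)
})
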