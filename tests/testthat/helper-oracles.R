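# Independent oracles and fixture builders. Everything here is written as
# plain scalar loops, deliberately avoiding the package's vectorized code
# paths, so that agreement is a genuine cross-check.

# Brute-force subtractive clustering: the same potential/subtraction
# equations coded directly from their definitions.
oracle_subclust <- function(points, radius, squash = 1.25,
                            accept_ratio = 0.5, reject_ratio = 0.15) {
  n <- nrow(points)
  d <- ncol(points)
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  U <- points
  for (j in seq_len(d)) {
    U[, j] <- if (hi[j] > lo[j]) (points[, j] - lo[j]) / (hi[j] - lo[j]) else 0.5
  }
  alpha <- 4 / radius^2
  beta <- 4 / (squash * radius)^2
  P <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      P[i] <- P[i] + exp(-alpha * sum((U[i, ] - U[j, ])^2))
    }
  }
  P1 <- max(P)
  centers <- integer(0)
  repeat {
    k <- which.max(P)
    pk <- P[k]
    if (length(centers) > 0) {
      if (pk >= accept_ratio * P1) {
        # accept
      } else if (pk < reject_ratio * P1) {
        break
      } else {
        dmin <- Inf
        for (c in centers) dmin <- min(dmin, sqrt(sum((U[k, ] - U[c, ])^2)))
        if (dmin / radius + pk / P1 < 1) {
          P[k] <- 0
          next
        }
      }
    }
    centers <- c(centers, k)
    for (i in seq_len(n)) {
      P[i] <- P[i] - pk * exp(-beta * sum((U[i, ] - U[k, ])^2))
    }
    if (length(centers) >= n) break
  }
  centers
}

# Two tight 10-point blobs separated across the unit box.
two_blob_points <- function(seed = 11) {
  withr::with_seed(seed, {
    rbind(
      cbind(rnorm(10, 0.1, 0.02), rnorm(10, 0.1, 0.02)),
      cbind(rnorm(10, 0.9, 0.02), rnorm(10, 0.9, 0.02))
    )
  })
}

# A small hand-specified two-rule Sugeno system over two inputs.
two_rule_truth <- function() {
  migsfis:::new_fis_model(
    centers = rbind(c(0.25, 0.3), c(0.75, 0.7)),
    sigmas = rbind(c(0.15, 0.2), c(0.2, 0.15)),
    consequents = rbind(c(1.0, -0.5, 2.0), c(-0.8, 1.2, 3.0)),
    feature_names = c("x1", "x2")
  )
}

sse_of <- function(model, X, y) sum((evaluate_fis(model, X) - y)^2)

# Small labeled cohort data frame with valid codes.
tiny_cohort_df <- function(n = 8, seed = 3) {
  withr::with_seed(seed, data.frame(
    age = runif(n, 50, 90), va = runif(n, 0, 1.2),
    iop = runif(n, 10, 35), vf = runif(n, -25, 0),
    drops = sample(0:5, n, TRUE), gtype = sample(1:6, n, TRUE),
    treatment = sample(1:4, n, TRUE)
  ))
}

# Worked confusion-matrix fixture: class 3 has tp = 11, fp = 6, fn = 3 in a
# 112-sample 4-class tally.
worked_confusion <- function() {
  m <- diag(c(30L, 30L, 11L, 32L))
  m[1, 3] <- 2L; m[2, 3] <- 2L; m[4, 3] <- 2L
  m[3, 1] <- 1L; m[3, 2] <- 1L; m[3, 4] <- 1L
  dimnames(m) <- list(true = 1:4, predicted = 1:4)
  class(m) <- c("confusion_matrix", class(m))
  m
}

# The example rulebook used throughout the generator's determinism checks.
example_rulebook <- function() {
  rulebook(list(
    list(predicate = function(df) df$iop > 25, class = 2L),
    list(predicate = function(df) df$vf < -15, class = 3L),
    list(predicate = function(df) df$va > 0.8, class = 1L)
  ), default_class = 4L)
}
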