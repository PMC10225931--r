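# Internal numerical / RNG helpers shared across modules.

#' Minimum-norm least squares via the SVD pseudoinverse
#'
#' Solves `min ||A x - b||` returning the minimum-norm solution when `A` is
#' rank deficient. Singular values below `tol` (default: the usual
#' `max(dim(A)) * max(d) * eps` cutoff) are treated as zero.
#'
#' @param A numeric matrix (n x p).
#' @param b numeric vector of length n.
#' @param tol singular-value cutoff; `NULL` for the default.
#' @return numeric vector of length p.
#' @keywords internal
#' @noRd
minnorm_lstsq <- function(A, b, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) {
    tol <- max(dim(A)) * max(s$d, 0) * .Machine$double.eps
  }
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  drop(s$v %*% (dinv * crossprod(s$u, b)))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Squared Euclidean distances from each row of X to the vector v.
row_dist2 <- function(X, v) {
  rowSums((X - matrix(v, nrow(X), ncol(X), byrow = TRUE))^2)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
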