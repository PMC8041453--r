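# Independent oracles used to freeze expected values. These deliberately use
# brute force / exhaustive enumeration and share no code with the package
# internals they check.

# ESF by exhaustive enumeration of all 2^m response patterns
esf_enumerate <- function(beta) {
  m <- length(beta)
  gam <- numeric(m + 1)
  for (code in 0:(2^m - 1)) {
    x <- as.integer(intToBits(code)[1:m])
    r <- sum(x)
    gam[r + 1] <- gam[r + 1] + exp(-sum(beta * x))
  }
  gam
}

# conditional log-likelihood of a binary matrix at difficulty vector beta,
# using the enumeration ESF (extreme scores excluded)
cloglik_enumerate <- function(X, beta) {
  m <- ncol(X)
  sc <- rowSums(X)
  X <- X[sc > 0 & sc < m, , drop = FALSE]
  gam <- esf_enumerate(beta)
  sum(-X %*% beta - log(gam[rowSums(X) + 1]))
}

# two-stage grid search maximiser of the conditional likelihood (first_zero
# restriction), oracle for the CML fit on small fixtures
oracle_cml_grid <- function(X, span = 4, coarse = 0.05, fine = 5e-4) {
  m <- ncol(X)
  stopifnot(m == 3)  # lattice search is only tractable for 3 items
  best <- c(0, 0)
  bestll <- -Inf
  for (stage in 1:2) {
    step <- if (stage == 1) coarse else fine
    lo <- if (stage == 1) c(-span, -span) else best - 2 * coarse
    hi <- if (stage == 1) c(span, span) else best + 2 * coarse
    g2 <- seq(lo[1], hi[1], by = step)
    g3 <- seq(lo[2], hi[2], by = step)
    for (b2 in g2) for (b3 in g3) {
      ll <- cloglik_enumerate(X, c(0, b2, b3))
      if (ll > bestll) { bestll <- ll; best <- c(b2, b3) }
    }
  }
  list(beta = c(0, best), loglik = bestll)
}

# Gini Index via the pairwise mean-absolute-difference form
gini_pairwise <- function(d) {
  m <- length(d)
  if (sum(d) == 0) return(0)
  s <- 0
  for (i in seq_len(m - 1)) s <- s + sum(abs(d[i] - d[(i + 1):m]))
  s / (m^2 * mean(d))
}

# fixed 6-person x 3-item fixture (no extreme scores, both categories per item)
fixture_6x3 <- function() {
  matrix(c(1, 0, 0,
           1, 1, 0,
           0, 1, 0,
           1, 0, 1,
           0, 1, 1,
           1, 1, 0), nrow = 6, byrow = TRUE,
         dimnames = list(NULL, c("A", "B", "C")))
}

# simulate a Rasch dataset for one group from true difficulties
simulate_group <- function(n, beta, theta_mean = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(beta)
  theta <- rnorm(n, theta_mean, 1)
  X <- (matrix(runif(n * m), n, m) <
          plogis(outer(theta, beta, "-"))) + 0L
  colnames(X) <- paste0("Item", seq_len(m))
  X
}

# swap a 2x2 checkerboard submatrix; preserves all row and column totals
tetrad_swap <- function(X) {
  n <- nrow(X)
  for (i1 in 1:(n - 1)) for (i2 in (i1 + 1):n) {
    j1 <- which(X[i1, ] == 1 & X[i2, ] == 0)
    j2 <- which(X[i1, ] == 0 & X[i2, ] == 1)
    if (length(j1) && length(j2)) {
      X[i1, j1[1]] <- 0; X[i2, j1[1]] <- 1
      X[i1, j2[1]] <- 1; X[i2, j2[1]] <- 0
      return(X)
    }
  }
  stop("no tetrad found")
}
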