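#' Elementary symmetric functions of Rasch item parameters
#'
#' Computes the elementary symmetric functions (ESFs)
#' \eqn{\gamma_r(\epsilon) = \sum_{|x| = r} \prod_j \epsilon_j^{x_j}} of the
#' item easiness parameters \eqn{\epsilon_j = \exp(-\beta_j)}, for raw scores
#' \eqn{r = 0, \dots, m}. The ESFs are the normalising constants of the
#' conditional likelihood of the Rasch model given the person raw scores and
#' are the computational backbone of conditional maximum likelihood (CML)
#' estimation.
#'
#' The summation algorithm is used: items are folded in one at a time via
#' \eqn{\gamma_r^{(1..j)} = \gamma_r^{(1..j-1)} + \epsilon_j
#' \gamma_{r-1}^{(1..j-1)}}. For numerical stability the difficulties are
#' centred first and the scaling identity \eqn{\gamma_r(t\epsilon) = t^r
#' \gamma_r(\epsilon)} is used to restore the requested scale, so overflow
#' only occurs for pathologically spread difficulty vectors.
#'
#' First-order partials \eqn{\partial\gamma_r/\partial\epsilon_j =
#' \gamma_{r-1}^{(j)}} (ESF of all items except \eqn{j}) are obtained by the
#' backward removal recurrence, with a forward-recurrence fallback when
#' cancellation is detected. Second-order partials remove a second item the
#' same way.
#'
#' @param beta numeric vector of item difficulties (logit scale), length
#'   \eqn{m \ge 1}, all finite.
#' @param order 0, 1 or 2: highest order of partial derivatives to return.
#' @return A list with components:
#'   \item{gamma}{numeric vector of length \eqn{m + 1}, \eqn{\gamma_0, \dots,
#'     \gamma_m} on the original (uncentred) scale.}
#'   \item{log_gamma}{\eqn{\log \gamma_r}, computed without forming possibly
#'     overflowing products.}
#'   \item{gamma1}{if \code{order >= 1}: an \eqn{m \times m} matrix whose row
#'     \eqn{j} holds \eqn{\gamma^{(j)}_r} for \eqn{r = 0, \dots, m - 1}
#'     (item \eqn{j} removed), on the centred scale, with the centring factor
#'     in attribute \code{"scale"}.}
#'   \item{gamma2}{if \code{order == 2}: a list over \eqn{j} of matrices of
#'     \eqn{\gamma^{(j,k)}_r}, \eqn{r = 0, \dots, m - 2}, centred scale.}
#' @examples
#' elementary_symmetric(c(0, 0))$gamma        # binomial coefficients 1 2 1
#' elementary_symmetric(c(0.5, -0.5, 0))$gamma
#' @export
elementary_symmetric <- function(beta, order = 0) {
  if (!is.numeric(beta) || length(beta) < 1L || any(!is.finite(beta)))
    stop("'beta' must be a finite numeric vector of length >= 1")
  if (!order %in% 0:2) stop("'order' must be 0, 1 or 2")
  m <- length(beta)
  ctr <- mean(beta)
  eps <- exp(-(beta - ctr))            # centred easiness parameters
  gam <- esf_forward(eps)
  if (any(!is.finite(gam)))
    stop("elementary symmetric functions overflowed; difficulty spread too large")
  log_gamma <- log(gam) - (0:m) * ctr  # undo centring: gamma_r(t*eps) = t^r gamma_r
  out <- list(gamma = exp(log_gamma), log_gamma = log_gamma,
              eps = eps, center = ctr)
  if (order >= 1) {
    g1 <- esf_exclude_one(eps)
    attr(g1, "scale") <- ctr
    out$gamma1 <- g1
    if (order == 2) out$gamma2 <- esf_exclude_two(eps)
  }
  out
}

# forward summation algorithm: gamma_r for r = 0..m (linear domain)
esf_forward <- function(eps) {
  m <- length(eps)
  gam <- c(1, rep.int(0, m))
  for (j in seq_len(m))
    gam[2:(j + 1L)] <- gam[2:(j + 1L)] + eps[j] * gam[1:j]
  gam
}

# ESFs with one item removed, all items at once: row j = gamma^{(j)}_{0..m-1}.
# Computed by convolving prefix ESFs (items 1..j-1) with suffix ESFs (items
# j+1..m): all terms are positive sums, so there is no cancellation (the
# backward removal recurrence gamma_r - eps_j*gamma^{(j)}_{r-1} loses several
# digits for m beyond ~10, which the CML gradient cannot afford).
esf_exclude_one <- function(eps) {
  m <- length(eps)
  pre <- vector("list", m)              # pre[[j]]: ESF of items 1..j-1
  pre[[1L]] <- 1
  for (j in seq_len(m - 1L)) {
    p <- pre[[j]]
    pre[[j + 1L]] <- c(p, 0) + eps[j] * c(0, p)
  }
  suf <- vector("list", m)              # suf[[j]]: ESF of items j+1..m
  suf[[m]] <- 1
  if (m > 1L) for (j in (m - 1L):1L) {
    s <- suf[[j + 1L]]
    suf[[j]] <- c(s, 0) + eps[j + 1L] * c(0, s)
  }
  G <- matrix(0, m, m)
  for (j in seq_len(m)) {
    a <- pre[[j]]                       # length j
    b <- suf[[j]]                       # length m - j + 1
    out <- numeric(m)
    for (i in seq_along(a)) {
      idx <- i:(i + m - j)
      out[idx] <- out[idx] + a[i] * b
    }
    G[j, ] <- out
  }
  G
}

# ESFs with two items removed: element [[j]] is an m x (m-1) matrix whose row
# k holds gamma^{(j,k)}_{0..m-2} (row j itself is unused and kept at zero;
# callers index k != j).  Each reduced set reuses the cancellation-free
# exclusion routine: the backward removal recurrence is far too lossy here —
# its Hessian errors stall the Newton iteration for m beyond ~10.
esf_exclude_two <- function(eps) {
  m <- length(eps)
  lapply(seq_len(m), function(j) {
    K <- matrix(0, m, m - 1L)
    if (m > 1L) K[-j, ] <- esf_exclude_one(eps[-j])
    K
  })
}
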