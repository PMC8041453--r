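#' Conditional maximum likelihood estimation of Rasch item parameters
#'
#' Fits the Rasch model to a single group's binary response matrix by
#' conditional maximum likelihood (CML): the conditional likelihood given the
#' person raw scores is free of the person parameters, which are eliminated
#' through the elementary symmetric functions. Estimation uses Newton-Raphson
#' with the analytic gradient and observed (= conditional expected)
#' information, with step halving on non-improving steps. The conditional
#' likelihood is concave in the restricted parameterisation, so convergence is
#' fast and reliable.
#'
#' Persons with extreme raw scores (0 or \eqn{m} correct) carry no conditional
#' information and are dropped silently; the number of persons retained is
#' reported in \code{n_used}. Every item must have both a correct and an
#' incorrect response among the retained persons, otherwise its difficulty is
#' not identified and an error naming the item is raised.
#'
#' The Rasch scale has no natural origin, so one linear restriction is
#' required. \code{"sum_zero"} (the default) constrains the difficulties to
#' sum to zero and yields a covariance matrix with strictly positive diagonal
#' for every item, as needed by the item-wise Wald test; \code{"first_zero"}
#' fixes the first difficulty at zero. Fits under different restrictions
#' differ only by a constant shift of \code{beta} (and the corresponding
#' linear transformation of \code{vcov}); see [convert_restriction()].
#'
#' @param responses binary matrix (persons x items) for one group, or a
#'   \code{response_data} object restricted to one group's rows.
#' @param restriction \code{"sum_zero"} or \code{"first_zero"}.
#' @param tol convergence tolerance: maximum absolute gradient component.
#' @param maxit maximum number of Newton iterations.
#' @return An object of class \code{"rasch_cml"} with components
#'   \item{beta}{named vector of \eqn{m} difficulty estimates (logits);}
#'   \item{vcov}{\eqn{m \times m} covariance matrix of \code{beta} (rank
#'     \eqn{m - 1}: one restriction);}
#'   \item{restriction}{the restriction tag;}
#'   \item{loglik}{conditional log-likelihood at the optimum;}
#'   \item{n_used}{persons retained after extreme-score removal;}
#'   \item{n_dropped}{persons removed;}
#'   \item{iterations, gradient_norm}{convergence diagnostics.}
#' @examples
#' set.seed(1)
#' theta <- rnorm(300)
#' beta <- seq(-1.5, 1.5, length.out = 5)
#' X <- matrix(rbinom(300 * 5, 1, plogis(outer(theta, beta, "-"))), 300, 5)
#' fit <- rasch_cml(X)
#' coef(fit)
#' @export
rasch_cml <- function(responses, restriction = c("sum_zero", "first_zero"),
                      tol = 1e-8, maxit = 100L) {
  restriction <- match.arg(restriction)
  if (inherits(responses, "response_data")) responses <- responses$responses
  X <- as.matrix(responses)
  if (anyNA(X) || !all(X %in% c(0, 1)))
    stop("responses must be a binary (0/1) matrix without missing values")
  m <- ncol(X)
  if (m < 2L) stop("at least 2 items are required")
  items <- colnames(X)
  if (is.null(items)) items <- paste0("Item", seq_len(m))

  score <- rowSums(X)
  keep <- score > 0 & score < m
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  n_used <- nrow(X)
  if (n_used < 1L) stop("no persons remain after removing extreme raw scores")

  s <- colSums(X)                        # item totals
  if (any(s == 0) || any(s == n_used)) {
    j <- which(s == 0 | s == n_used)[1L]
    stop(sprintf("item '%s' has zero variance within the group (all %s); difficulty not identified",
                 items[j], if (s[j] == 0) "incorrect" else "correct"))
  }
  nr <- tabulate(rowSums(X), nbins = m - 1L)   # counts of raw scores 1..m-1

  # Newton-Raphson under the internal first_zero parameterisation
  beta <- log((n_used - s) / s)
  beta <- beta - beta[1L]
  free <- 2:m
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    gh <- cml_grad_info(beta, s, nr)
    gmax <- max(abs(gh$grad[free]))
    if (gmax < tol || iter > maxit) {
      ll_old <- gh$loglik
      break
    }
    step <- rep(0, m)
    step[free] <- solve(gh$info[free, free, drop = FALSE], gh$grad[free])
    if (gmax < 1e-3) {
      # quadratic-convergence region: log-likelihood changes are at rounding
      # level, a line search would stall; take the pure Newton step
      beta <- beta + step
      ll_old <- gh$loglik
    } else {
      lam <- 1
      repeat {
        cand <- beta + lam * step
        ll_new <- cml_loglik(cand, s, nr)
        if (is.finite(ll_new) &&
            ll_new >= gh$loglik - 1e-10 * max(1, abs(gh$loglik))) break
        lam <- lam / 2
        if (lam < 1e-10)
          stop("CML estimation failed: step halving could not improve the conditional log-likelihood (iteration ",
               iter, ", max |gradient| = ", format(gmax), ")")
      }
      beta <- cand
      ll_old <- ll_new
    }
  }
  if (iter > maxit)
    stop("CML estimation did not converge in ", maxit,
         " iterations (max |gradient| = ", format(max(abs(gh$grad[free]))), ")")

  V <- matrix(0, m, m)
  Vf <- solve(gh$info[free, free, drop = FALSE])
  V[free, free] <- (Vf + t(Vf)) / 2

  fit <- structure(list(beta = stats::setNames(beta, items), vcov = V,
                        restriction = "first_zero", loglik = ll_old,
                        n_used = n_used, n_dropped = n_dropped,
                        iterations = iter, gradient_norm = max(abs(gh$grad[free]))),
                   class = "rasch_cml")
  convert_restriction(fit, restriction)
}

# conditional log-likelihood, gradient and information (full m x m, first_zero
# internal scale).  pi[j, r] = P(x_j = 1 | raw score r).
cml_grad_info <- function(beta, s, nr) {
  m <- length(beta)
  ctr <- mean(beta)
  eps <- exp(-(beta - ctr))
  gam <- esf_forward(eps)
  if (any(!is.finite(gam))) stop("ESF overflow during CML iteration")
  G1 <- esf_exclude_one(eps)
  P <- (eps * G1[, 1:(m - 1L), drop = FALSE]) /
    rep(gam[2:m], each = m)              # pi_{jr}, r = 1..m-1
  grad <- as.vector(P %*% nr) - s
  # information = sum_r n_r Cov_r(x); off-diagonals need pairwise ESFs
  M <- matrix(0, m, m)
  if (m >= 3L) {
    G2 <- esf_exclude_two(eps)
    w <- nr[2:(m - 1L)] / gam[3:m]       # n_r / gamma_r, r = 2..m-1
    for (j in seq_len(m)) {
      K <- G2[[j]]
      M[j, ] <- eps[j] * eps * as.vector(K[, 1:(m - 2L), drop = FALSE] %*% w)
    }
  }
  diag(M) <- as.vector(P %*% nr)
  info <- M - P %*% (nr * t(P))
  info <- (info + t(info)) / 2          # exact symmetry
  loglik <- -sum(s * beta) - sum(nr * (log(gam[2:m]) - (1:(m - 1L)) * ctr))
  list(grad = grad, info = info, loglik = loglik)
}

cml_loglik <- function(beta, s, nr) {
  m <- length(beta)
  ctr <- mean(beta)
  gam <- esf_forward(exp(-(beta - ctr)))
  if (any(!is.finite(gam)) || any(gam <= 0)) return(-Inf)
  -sum(s * beta) - sum(nr * (log(gam[2:m]) - (1:(m - 1L)) * ctr))
}

#' Convert a CML fit between scale restrictions
#'
#' Re-expresses a [rasch_cml()] fit under a different identifying restriction.
#' The difficulties change only by a constant shift; the covariance matrix is
#' transformed by the corresponding linear map. The conditional log-likelihood
#' is unaffected.
#'
#' @param fit a \code{"rasch_cml"} object.
#' @param restriction \code{"sum_zero"} or \code{"first_zero"}.
#' @return The fit under the requested restriction.
#' @export
convert_restriction <- function(fit, restriction = c("sum_zero", "first_zero")) {
  stopifnot(inherits(fit, "rasch_cml"))
  restriction <- match.arg(restriction)
  if (identical(fit$restriction, restriction)) return(fit)
  m <- length(fit$beta)
  if (restriction == "sum_zero") {
    A <- diag(m) - matrix(1 / m, m, m)
  } else {
    A <- diag(m)
    A[, 1L] <- A[, 1L] - 1
  }
  fit$beta <- stats::setNames(as.vector(A %*% fit$beta), names(fit$beta))
  fit$vcov <- A %*% fit$vcov %*% t(A)
  fit$restriction <- restriction
  fit
}

#' @export
print.rasch_cml <- function(x, digits = 4, ...) {
  cat("Rasch model, conditional maximum likelihood\n")
  cat(sprintf("Items: %d   Persons used: %d (%d extreme scores dropped)\n",
              length(x$beta), x$n_used, x$n_dropped))
  cat(sprintf("Restriction: %s   Conditional log-likelihood: %.4f\n",
              x$restriction, x$loglik))
  cat("Item difficulties:\n")
  print(round(x$beta, digits))
  invisible(x)
}

#' @export
coef.rasch_cml <- function(object, ...) object$beta

#' @export
vcov.rasch_cml <- function(object, ...) object$vcov

#' @export
logLik.rasch_cml <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) - 1L,
            nobs = object$n_used, class = "logLik")
}

#' @export
summary.rasch_cml <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  tab <- cbind(Estimate = object$beta, `Std. Error` = se)
  structure(list(coefficients = tab, restriction = object$restriction,
                 loglik = object$loglik, n_used = object$n_used,
                 n_dropped = object$n_dropped), class = "summary.rasch_cml")
}

#' @export
print.summary.rasch_cml <- function(x, digits = 4, ...) {
  cat("Rasch CML fit (", x$restriction, " restriction)\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("Conditional log-likelihood: %.4f on %d persons (%d dropped)\n",
              x$loglik, x$n_used, x$n_dropped))
  invisible(x)
}
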