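#' Anchored item-wise Wald tests for DIF
#'
#' Given per-group CML fits and a scale shift \eqn{c} (the anchor point),
#' tests each item for DIF with the item-wise Wald statistic
#' \deqn{t_j = \frac{\tilde\beta_j^{(1)} - \tilde\beta_j^{(2)} - c}{\hat{se}_j},
#' \qquad \hat{se}_j = \sqrt{\widehat{Var}(\tilde\beta^{(1)})_{jj} +
#' \widehat{Var}(\tilde\beta^{(2)})_{jj}},}
#' referred to the standard normal distribution (two-sided).
#'
#' When the shift corresponds to a known anchor set \eqn{A} (always the case
#' for [anchored_wald_test()] and for anchor points, which are single-item
#' shifts), the standard errors are computed under the anchoring restriction:
#' \eqn{\hat{se}_j^2} sums, over the two groups, the variance of the contrast
#' \eqn{\tilde\beta_j - \overline{\tilde\beta}_A}, which includes the anchor
#' items' own variance and covariance terms. This makes the null distribution
#' of \eqn{t_j} standard normal for any anchor length — with a single-item
#' anchor the omitted anchor-variance term would otherwise inflate the
#' type-I error well above the nominal level. An anchor item in a
#' single-item anchor has \eqn{se = 0} and \eqn{t = 0} by construction.
#' When no anchor is supplied the per-group vcov diagonals under the
#' sum-zero restriction are used. Either way the statistics do not depend on
#' the restriction the fits were estimated under, since the shift (or the
#' contrast) absorbs any constant reparameterisation.
#'
#' No multiple-testing correction is applied by default, matching the
#' per-item false-alarm-rate convention; Bonferroni or Benjamini-Hochberg
#' adjusted flags can be requested via \code{adjust}. Uncertainty in the
#' data-driven selection of \eqn{c} (or of \eqn{A}) is not propagated.
#'
#' @param fit1,fit2 \code{rasch_cml} fits for the reference and focal group
#'   with the same items.
#' @param shift scalar anchor point \eqn{c} applied to group 2.
#' @param alpha significance level for the DIF flags.
#' @param adjust p-value adjustment for the flags: \code{"none"} (default),
#'   \code{"bonferroni"} or \code{"BH"}.
#' @param anchor optional integer vector of anchor item indices consistent
#'   with \code{shift}; used only for the anchored standard errors (see
#'   Details). \code{NULL} uses the sum-zero diagonal convention.
#' @return An object of class \code{"dif_table"}: a data frame with one row
#'   per item and columns \code{item}, \code{difference} (shifted difference
#'   \eqn{\hat\beta_j^{(1)} - \hat\beta_j^{(2)}}), \code{se},
#'   \code{statistic}, \code{p_value}, \code{flag}; the shift, anchor set (if
#'   any), \code{alpha} and \code{adjust} are stored as attributes.
#' @seealso [anchored_wald_test()] for anchoring by an item set,
#'   [anchorpoint()] for the full pipeline.
#' @export
wald_test <- function(fit1, fit2, shift = 0, alpha = 0.05,
                      adjust = c("none", "bonferroni", "BH"), anchor = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(fit1, "rasch_cml"), inherits(fit2, "rasch_cml"))
  m <- length(fit1$beta)
  if (m != length(fit2$beta))
    stop("fits must share the same number of items")
  stopifnot(is.numeric(shift), length(shift) == 1L, is.finite(shift))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  if (is.null(anchor)) {
    # sum-zero diagonal convention (restriction conversion matters here)
    se2 <- diag(convert_restriction(fit1, "sum_zero")$vcov) +
      diag(convert_restriction(fit2, "sum_zero")$vcov)
  } else {
    # variance of the contrast beta_j - mean_A(beta), per group; a contrast
    # with zero weight sum, hence invariant to the fits' restriction
    a <- numeric(m)
    a[anchor] <- 1 / length(anchor)
    anchored_var <- function(V)
      diag(V) - 2 * as.vector(V %*% a) + as.vector(a %*% V %*% a)
    se2 <- anchored_var(fit1$vcov) + anchored_var(fit2$vcov)
  }
  se <- sqrt(pmax(se2, 0))
  # differences on the scale of the fits as passed in: the shift (or anchor
  # mean) is always computed on that same scale
  diff_ <- fit1$beta - fit2$beta - shift
  degenerate <- se < 1e-12 & abs(diff_) < 1e-8   # an anchor item anchoring itself
  if (any(se < 1e-12 & !degenerate)) {
    j <- which(se < 1e-12 & !degenerate)[1L]
    stop(sprintf("item '%s' has zero standard error; Wald statistic undefined",
                 names(fit1$beta)[j]))
  }
  t_ <- ifelse(degenerate, 0, diff_ / pmax(se, .Machine$double.xmin))
  p <- 2 * stats::pnorm(-abs(t_))
  p_flag <- stats::p.adjust(p, method = if (adjust == "none") "none" else adjust)
  out <- data.frame(item = names(fit1$beta), difference = as.vector(diff_),
                    se = as.vector(se), statistic = as.vector(t_),
                    p_value = as.vector(p), flag = p_flag < alpha,
                    row.names = NULL)
  structure(out, class = c("dif_table", "data.frame"), shift = shift,
            anchor = NULL, alpha = alpha, adjust = adjust)
}

#' Wald DIF tests anchored by an item set
#'
#' Classical anchoring by a set \eqn{A} of anchor items: both groups' scales
#' are restricted so that the anchor items' parameters sum to zero, which is
#' equivalent to testing at the shift \eqn{c = \overline{\tilde\beta}_A^{(1)}
#' - \overline{\tilde\beta}_A^{(2)}} (the difference of the anchor means).
#' All \eqn{m} items are tested, including the anchor items themselves; a
#' single-item anchor \eqn{A = \{k\}} tests at the candidate shift
#' \eqn{\tilde\beta_k^{(1)} - \tilde\beta_k^{(2)}} and necessarily yields
#' \eqn{t_k = 0}. With \eqn{A} = all items this is the "equal mean"
#' anchoring.
#'
#' @inheritParams wald_test
#' @param anchor integer vector of anchor item indices (non-empty, within
#'   \code{1..m}) or an [anchor_selection] object.
#' @return A \code{"dif_table"} as in [wald_test()], with the anchor set in
#'   attribute \code{"anchor"}.
#' @export
anchored_wald_test <- function(fit1, fit2, anchor, alpha = 0.05,
                               adjust = c("none", "bonferroni", "BH")) {
  if (inherits(anchor, "anchor_selection")) anchor <- anchor$anchor
  m <- length(fit1$beta)
  anchor <- as.integer(anchor)
  if (!length(anchor)) stop("'anchor' must be a non-empty set of item indices")
  if (anyNA(anchor) || any(anchor < 1L) || any(anchor > m) || anyDuplicated(anchor))
    stop("'anchor' must be distinct item indices in 1..", m)
  shift <- mean(fit1$beta[anchor]) - mean(fit2$beta[anchor])
  out <- wald_test(fit1, fit2, shift = shift, alpha = alpha, adjust = adjust,
                   anchor = anchor)
  attr(out, "anchor") <- anchor
  out
}

# items whose single-item candidate shift equals (numerically) the selected
# anchor point: the implicit anchor set of an anchor-point analysis
matching_anchor <- function(beta1, beta2, shift, tol = 1e-10) {
  k <- which(abs(beta1 - beta2 - shift) < tol)
  if (!length(k)) NULL else k
}

#' @export
print.dif_table <- function(x, digits = 4, ...) {
  cat("Item-wise Wald DIF tests (alpha = ", attr(x, "alpha"), sep = "")
  if (!identical(attr(x, "adjust"), "none"))
    cat(", ", attr(x, "adjust"), "-adjusted flags", sep = "")
  cat(")\n")
  if (!is.null(attr(x, "anchor")))
    cat("Anchor items:", paste(attr(x, "anchor"), collapse = ", "), "-> ")
  cat("shift c =", format(attr(x, "shift"), digits = digits), "\n")
  df <- as.data.frame(x)
  df$flag <- ifelse(df$flag, "*", "")
  print(format(df, digits = digits), row.names = FALSE)
  cat(sum(x$flag), "of", nrow(x), "items flagged\n")
  invisible(x)
}
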