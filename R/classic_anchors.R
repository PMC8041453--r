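#' Classical anchor item selection heuristics
#'
#' Three established anchor-selection strategies, used as baselines against
#' anchor point selection. All return an \code{"anchor_selection"} object
#' holding the selected anchor set and the per-item auxiliary scores the
#' selection was based on; pass it to [anchored_wald_test()] for the final
#' DIF tests. All ties are broken deterministically (secondary score, then
#' lowest item index). The operationalisations of the published sketches are
#' documented in the package vignette.
#'
#' \describe{
#'   \item{\code{anchor_allother()}}{"constant all-other": each item is first
#'     tested with all other items as the preliminary anchor; the four items
#'     with the smallest absolute Wald statistics form the anchor. Simple and
#'     common, but inherits the equal-mean assumption that DIF cancels out,
#'     and is known to break down under unbalanced DIF.}
#'   \item{\code{anchor_mpt()}}{"constant four, mean p-value threshold": every
#'     item is tested with every other single item as anchor; each item
#'     collects \eqn{m - 1} p-values, the threshold is the grand mean of all
#'     collected p-values, an item's score is how many of its p-values exceed
#'     the threshold, and the four highest-scoring items (ties: larger mean
#'     p-value, then lower index) form the anchor.}
#'   \item{\code{anchor_forward()}}{"iterative forward, mean test statistic
#'     threshold": items are ranked by their mean absolute Wald statistic
#'     over all single-anchor analyses (DIF-free anchors should produce the
#'     smallest mean statistics); the anchor starts with the top-ranked item
#'     and grows along the ranking until the anchor is longer than the number
#'     of currently significant non-anchor items.}
#' }
#'
#' @param fit1,fit2 \code{rasch_cml} fits for the two groups.
#' @param alpha significance level used inside the selection (and intended
#'   for the final tests).
#' @param n_anchor anchor length for the two constant methods (default 4).
#' @return An object of class \code{"anchor_selection"}: list with
#'   \code{method}, \code{anchor} (sorted item indices), \code{scores}
#'   (per-item selection statistic), \code{alpha}.
#' @name classic_anchors
NULL

new_anchor_selection <- function(method, anchor, scores, alpha) {
  structure(list(method = method, anchor = sort(as.integer(anchor)),
                 scores = scores, alpha = alpha),
            class = "anchor_selection")
}

#' @rdname classic_anchors
#' @export
anchor_allother <- function(fit1, fit2, alpha = 0.05, n_anchor = 4L) {
  m <- length(fit1$beta)
  if (m < n_anchor + 1L)
    stop("constant all-other selection needs at least ", n_anchor + 1L, " items")
  abst <- vapply(seq_len(m), function(j) {
    tab <- anchored_wald_test(fit1, fit2, anchor = setdiff(seq_len(m), j),
                              alpha = alpha)
    abs(tab$statistic[j])
  }, numeric(1))
  sel <- order(abst, seq_len(m))[seq_len(n_anchor)]
  new_anchor_selection("allother", sel,
                       stats::setNames(abst, names(fit1$beta)), alpha)
}

# |t| and p-values from all single-anchor analyses: entry [j, k] is item j's
# result when item k is the (single) anchor; diagonal NA.
single_anchor_grid <- function(fit1, fit2, alpha) {
  m <- length(fit1$beta)
  tmat <- pmat <- matrix(NA_real_, m, m)
  for (k in seq_len(m)) {
    tab <- anchored_wald_test(fit1, fit2, anchor = k, alpha = alpha)
    tmat[, k] <- abs(tab$statistic)
    pmat[, k] <- tab$p_value
  }
  diag(tmat) <- diag(pmat) <- NA_real_
  list(t = tmat, p = pmat)
}

#' @rdname classic_anchors
#' @export
anchor_mpt <- function(fit1, fit2, alpha = 0.05, n_anchor = 4L) {
  m <- length(fit1$beta)
  if (m < n_anchor + 1L)
    stop("constant four MPT selection needs at least ", n_anchor + 1L, " items")
  p <- single_anchor_grid(fit1, fit2, alpha)$p
  threshold <- mean(p, na.rm = TRUE)
  score <- rowSums(p > threshold, na.rm = TRUE)
  meanp <- rowMeans(p, na.rm = TRUE)
  sel <- order(-score, -meanp, seq_len(m))[seq_len(n_anchor)]
  out <- new_anchor_selection("mpt4", sel,
                              stats::setNames(score, names(fit1$beta)), alpha)
  out$threshold <- threshold
  out
}

#' @rdname classic_anchors
#' @export
anchor_forward <- function(fit1, fit2, alpha = 0.05) {
  m <- length(fit1$beta)
  if (m < 3L) stop("iterative forward selection needs at least 3 items")
  meant <- rowMeans(single_anchor_grid(fit1, fit2, alpha)$t, na.rm = TRUE)
  ranking <- order(meant, seq_len(m))
  anchor <- ranking[1L]
  repeat {
    tab <- anchored_wald_test(fit1, fit2, anchor = anchor, alpha = alpha)
    n_sig <- sum(tab$flag[-anchor])
    if (length(anchor) > n_sig || length(anchor) == m) break
    anchor <- c(anchor, ranking[length(anchor) + 1L])
  }
  new_anchor_selection("forward", anchor,
                       stats::setNames(meant, names(fit1$beta)), alpha)
}

#' @export
print.anchor_selection <- function(x, ...) {
  lab <- c(allother = "constant all-other", mpt4 = "constant four MPT",
           forward = "iterative forward")[x$method]
  cat("Anchor selection (", lab, "): items ",
      paste(x$anchor, collapse = ", "), "\n", sep = "")
  invisible(x)
}
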