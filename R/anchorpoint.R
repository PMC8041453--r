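#' Anchor point selection and DIF testing between two groups
#'
#' The full pipeline: fits the Rasch model separately to the two groups by
#' conditional maximum likelihood, places the two sets of item parameter
#' estimates on a common scale — either by selecting an anchor *point* (the
#' shift maximising the Gini Index or the CLF criterion of the item-wise
#' distances over the sparse candidate grid) or by one of the classical
#' anchor *item* heuristics — and tests every item for DIF with the
#' item-wise Wald test.
#'
#' The criterion curve is always computed and stored: beyond the global
#' optimum it can reveal local optima corresponding to alternative alignments
#' (item clusters, e.g. from a DIF-inducing secondary dimension), which are
#' worth inspecting with [plot.criterion_curve()].
#'
#' @param responses a [response_data] object; or a binary matrix/data frame
#'   of responses (then \code{group} must be given); or a data frame
#'   containing the group column named by \code{group}.
#' @param group group labels (two levels), or the name of the group column
#'   when \code{responses} is a data frame containing it.
#' @param method how the scales are aligned: \code{"gini"} or \code{"clf"}
#'   (anchor point selection), \code{"allother"}, \code{"mpt4"},
#'   \code{"forward"} (classical anchor sets), or \code{"equalmean"} (anchor
#'   on all items).
#' @param alpha significance level of the Wald DIF tests.
#' @param restriction scale restriction used for reporting the per-group
#'   estimates (the DIF results are invariant to it).
#' @param resolution plotting-grid resolution of the criterion curve.
#' @param epsilon CLF smoothing constant.
#' @param adjust p-value adjustment for the DIF flags (default none).
#' @return An object of class \code{"anchorpoint"}: list with the per-group
#'   fits (\code{fit1} reference, \code{fit2} focal), the
#'   \code{criterion_curve}, the \code{method}, the selected \code{shift}
#'   (and \code{anchor} set, if a classical method), and the \code{dif}
#'   table.
#' @examples
#' d <- generate_study1(sim_design(m = 10, n_ref = 300, n_foc = 300,
#'                                 dif_items = 4, dif_size = 1, seed = 7))
#' a <- anchorpoint(d)
#' print(a)
#' @export
anchorpoint <- function(responses, group = NULL,
                        method = c("gini", "clf", "allother", "mpt4",
                                   "forward", "equalmean"),
                        alpha = 0.05,
                        restriction = c("sum_zero", "first_zero"),
                        resolution = 1001L, epsilon = 0,
                        adjust = c("none", "bonferroni", "BH")) {
  method <- match.arg(method)
  restriction <- match.arg(restriction)
  adjust <- match.arg(adjust)
  cl <- match.call()
  if (!inherits(responses, "response_data")) {
    if (is.character(group) && length(group) == 1L &&
        is.data.frame(responses) && group %in% names(responses)) {
      g <- responses[[group]]
      responses <- responses[setdiff(names(responses), group)]
    } else if (!is.null(group)) {
      g <- group
    } else stop("'group' is required when 'responses' is not a response_data object")
    responses <- response_data(responses, g)
  }
  grp <- split_groups(responses)
  fit1 <- rasch_cml(grp[[1L]], restriction = restriction)
  fit2 <- rasch_cml(grp[[2L]], restriction = restriction)
  curve <- criterion_curve(fit1, fit2,
                           criterion = if (method == "clf") "clf" else "gini",
                           resolution = resolution, epsilon = epsilon)
  anchor <- NULL
  if (method %in% c("gini", "clf")) {
    shift <- curve$global[[method]]$shift
    dif <- wald_test(fit1, fit2, shift = shift, alpha = alpha, adjust = adjust,
                     anchor = matching_anchor(fit1$beta, fit2$beta, shift))
  } else {
    anchor <- switch(method,
                     allother = anchor_allother(fit1, fit2, alpha),
                     mpt4 = anchor_mpt(fit1, fit2, alpha),
                     forward = anchor_forward(fit1, fit2, alpha),
                     equalmean = new_anchor_selection(
                       "equalmean", seq_along(fit1$beta), NULL, alpha))
    dif <- anchored_wald_test(fit1, fit2, anchor, alpha = alpha,
                              adjust = adjust)
    shift <- attr(dif, "shift")
  }
  structure(list(fit1 = fit1, fit2 = fit2, curve = curve, method = method,
                 shift = shift, anchor = anchor, dif = dif, alpha = alpha,
                 groups = levels(responses$group), call = cl),
            class = "anchorpoint")
}

#' @export
print.anchorpoint <- function(x, digits = 4, ...) {
  cat("Anchor point DIF analysis (", x$method, " method)\n", sep = "")
  cat(sprintf("Groups: %s (reference, n_used = %d) vs %s (focal, n_used = %d)\n",
              x$groups[1L], x$fit1$n_used, x$groups[2L], x$fit2$n_used))
  cat("Selected shift c =", format(x$shift, digits = digits))
  if (!is.null(x$anchor))
    cat("  (anchor items: ", paste(x$anchor$anchor, collapse = ", "), ")",
        sep = "")
  cat("\n")
  flagged <- which(x$dif$flag)
  cat("DIF flagged at alpha = ", x$alpha, ": ",
      if (length(flagged)) paste(x$dif$item[flagged], collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' @export
summary.anchorpoint <- function(object, ...) {
  structure(list(x = object), class = "summary.anchorpoint")
}

#' @export
print.summary.anchorpoint <- function(x, digits = 4, ...) {
  print(x$x, digits = digits)
  cat("\n")
  print(x$x$curve, digits = digits)
  cat("\n")
  print(x$x$dif, digits = digits)
  invisible(x)
}

#' @export
coef.anchorpoint <- function(object, ...) {
  cbind(reference = object$fit1$beta,
        focal_aligned = object$fit2$beta + object$shift)
}

#' @export
plot.anchorpoint <- function(x, ...) plot(x$curve, ...)
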