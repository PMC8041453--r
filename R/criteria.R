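#' Item-wise absolute distances on the shifted scale
#'
#' For two groups' item difficulty vectors and a scale shift \eqn{c} applied
#' to the second group, returns \eqn{d_j(c) = |\beta_{j}^{(1)} -
#' \beta_{j}^{(2)} - c|}. These distances are what the anchor-point criteria
#' (Gini Index, CLF) are evaluated on: at a well-chosen shift most distances
#' collapse to (near) zero and only DIF items stand out.
#'
#' @param beta1,beta2 numeric difficulty vectors of equal length (or
#'   \code{rasch_cml} fits).
#' @param shift scalar shift \eqn{c} (logits) applied to group 2.
#' @return numeric vector of nonnegative distances, one per item.
#' @export
shift_distances <- function(beta1, beta2, shift = 0) {
  beta1 <- item_parameters(beta1)
  beta2 <- item_parameters(beta2)
  if (length(beta1) != length(beta2))
    stop("'beta1' and 'beta2' must have the same number of items (",
         length(beta1), " vs ", length(beta2), ")")
  stopifnot(is.numeric(shift), length(shift) == 1L, is.finite(shift))
  abs(beta1 - beta2 - shift)
}

# accept either a bare difficulty vector or a rasch_cml fit
item_parameters <- function(x) {
  if (inherits(x, "rasch_cml")) x$beta
  else if (is.numeric(x)) x
  else stop("expected a numeric difficulty vector or a 'rasch_cml' fit")
}

#' Gini Index of a nonnegative distance vector
#'
#' The Gini Index is the classical inequality measure from economics, applied
#' here to the item-wise absolute distances: it is 0 when all distances are
#' equal (perfect equality — the groups can be aligned with no item singled
#' out) and reaches its maximum \eqn{1 - 1/m} when a single item carries all
#' the distance while the other \eqn{m - 1} distances are zero. Maximising it
#' over the scale shift therefore favours alignments where a small minority
#' of items shows DIF and the majority interlocks.
#'
#' Computed by the rank formula
#' \deqn{GI = \frac{2 \sum_j r_j d_j}{m \sum_j d_j} - \frac{m + 1}{m},}
#' with \eqn{r_j} the ascending rank of \eqn{d_j}. The value is invariant to
#' how ties are ordered and to positive rescaling of \code{d}. The degenerate
#' all-zero vector (perfect global alignment, i.e. no DIF anywhere) is
#' defined to have Gini Index 0, with a note.
#'
#' @param d numeric vector of nonnegative distances.
#' @return scalar in \eqn{[0, 1 - 1/m]}.
#' @examples
#' gini_index(c(1, rep(0, 9)))  # 0.9 = 1 - 1/10
#' gini_index(rep(2, 5))        # 0: perfect equality
#' @export
gini_index <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d))) stop("'d' must be finite numeric")
  if (any(d < 0)) stop("'d' must be nonnegative")
  m <- length(d)
  sd_ <- sum(d)
  if (sd_ == 0) {
    message("all distances are zero (perfect alignment); Gini Index defined as 0")
    return(0)
  }
  r <- rank(d, ties.method = "first")
  2 * sum(r * d) / (m * sd_) - (m + 1) / m
}

#' Component loss function (CLF) criterion
#'
#' The alignment criterion of the factor-analytic alignment method, translated
#' to the Rasch case: \eqn{-\sum_j \sqrt{d_j^2 + \epsilon}}. With the default
#' \eqn{\epsilon = 0} this is the simplified CLF \eqn{-\sum_j d_j} (the
#' \eqn{\epsilon} smoothing is only needed for gradient-based optimisation,
#' not for the sparse-grid search used here). Larger values (closer to 0)
#' correspond to better alignment; like the Gini Index it is maximised over
#' the shift.
#'
#' @param d numeric vector of nonnegative distances.
#' @param epsilon nonnegative smoothing constant (default 0).
#' @return scalar \eqn{\le 0}.
#' @export
clf_criterion <- function(d, epsilon = 0) {
  if (!is.numeric(d) || any(!is.finite(d))) stop("'d' must be finite numeric")
  if (any(d < 0)) stop("'d' must be nonnegative")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("'epsilon' must be a single nonnegative number")
  -sum(sqrt(d^2 + epsilon))
}

#' Search interval for the scale shift
#'
#' The interval \eqn{[c_{min}, c_{max}]} over which the second group's item
#' parameters are moved past the first group's: from the position where the
#' lowest item of group 1 meets the highest item of group 2 up to where the
#' highest item of group 1 meets the lowest item of group 2, so the parameter
#' ranges always overlap.
#'
#' @inheritParams shift_distances
#' @return numeric vector \code{c(cmin, cmax)}.
#' @export
search_interval <- function(beta1, beta2) {
  beta1 <- item_parameters(beta1)
  beta2 <- item_parameters(beta2)
  if (!length(beta1) || !length(beta2)) stop("empty difficulty vector")
  c(min(beta1) - max(beta2), max(beta1) - min(beta2))
}

#' Candidate shifts for the sparse-grid criterion search
#'
#' Both the Gini Index and the CLF criterion, as functions of the shift
#' \eqn{c}, can attain local or global optima only at the single-item shifts
#' \eqn{c = \beta_j^{(1)} - \beta_j^{(2)}} — the shifts that make one item
#' interlock exactly. The continuous search over \eqn{[c_{min}, c_{max}]}
#' therefore reduces to this sparse candidate set. Duplicate differences are
#' collapsed with tolerance \code{1e-12}.
#'
#' @inheritParams shift_distances
#' @return sorted numeric vector of unique candidate shifts.
#' @export
candidate_shifts <- function(beta1, beta2) {
  beta1 <- item_parameters(beta1)
  beta2 <- item_parameters(beta2)
  if (length(beta1) != length(beta2))
    stop("'beta1' and 'beta2' must have the same number of items")
  d <- sort(beta1 - beta2)
  d[c(TRUE, diff(d) > 1e-12)]
}

criterion_value <- function(d, criterion, epsilon = 0) {
  if (criterion == "gini") {
    m <- length(d)
    sd_ <- sum(d)
    if (sd_ == 0) return(0)
    2 * sum(rank(d, ties.method = "first") * d) / (m * sd_) - (m + 1) / m
  } else -sum(sqrt(d^2 + epsilon))
}

eval_criterion <- function(delta, shifts, criterion, epsilon = 0) {
  vapply(shifts, function(cc) criterion_value(abs(delta - cc), criterion, epsilon),
         numeric(1))
}

#' Criterion curve and anchor point selection
#'
#' Evaluates the Gini Index and the CLF criterion of the item-wise distances
#' over the search interval, selects the globally optimal shift (the anchor
#' point) for each criterion from the sparse candidate set, and locates
#' non-global local optima of the criterion curves. A dense, equally spaced
#' grid is also evaluated, but only for plotting — selection uses the
#' candidate set exclusively, where all optima are known to lie.
#'
#' When two candidates tie for the global optimum (criterion values within
#' \code{1e-10}), the one with the smaller absolute shift is designated
#' global and a warning is issued: such ties are label-switching situations
#' (two item clusters that can each be declared DIF-free) and deserve
#' inspection of the full curve.
#'
#' Local optima are local maxima of the continuous criterion curve. They can
#' only occur at candidate shifts, so each non-global candidate is probed
#' against the criterion value just to either side (offset \code{1e-3} times
#' the smallest candidate gap). Each local optimum is reported with its
#' criterion value and its prominence, defined as the value minus the higher
#' of the adjacent candidates' values (negative when the neighbouring
#' candidate — typically the global optimum — is higher).
#'
#' @param fit1,fit2 \code{rasch_cml} fits for the two groups, or bare
#'   difficulty vectors (e.g. true parameters for an illustration).
#' @param criterion which criterion drives \code{$shift}, the selected anchor
#'   point: \code{"gini"} (default) or \code{"clf"}. Both criteria are always
#'   evaluated and stored.
#' @param resolution number of grid points for the plotting grid (>= 2).
#' @param epsilon CLF smoothing constant, see [clf_criterion()].
#' @return An object of class \code{"criterion_curve"}: a list with
#'   \item{grid}{data frame \code{shift}, \code{gini}, \code{clf} (plotting
#'     grid);}
#'   \item{candidates}{data frame of candidate shifts with both criterion
#'     values;}
#'   \item{global}{per criterion, the optimal shift and value;}
#'   \item{local}{per criterion, a data frame of non-global local optima
#'     (shift, value, prominence);}
#'   \item{interval}{\code{c(cmin, cmax)};}
#'   \item{criterion, shift}{the selecting criterion and its optimal shift.}
#' @examples
#' toy <- make_toy()
#' cc <- criterion_curve(toy$beta1, toy$beta2)
#' cc$shift                      # 0: global optimum aligns the nine clean items
#' local_optima(cc)              # secondary peak at -0.75 (item 4 interlocks)
#' @export
criterion_curve <- function(fit1, fit2, criterion = c("gini", "clf"),
                            resolution = 1001L, epsilon = 0) {
  criterion <- match.arg(criterion)
  beta1 <- item_parameters(fit1)
  beta2 <- item_parameters(fit2)
  m <- length(beta1)
  if (m != length(beta2)) stop("fits must share the same number of items")
  if (m < 2L) stop("at least 2 items are required")
  if (resolution < 2L) stop("'resolution' must be >= 2")
  delta <- beta1 - beta2
  interval <- search_interval(beta1, beta2)
  cand <- candidate_shifts(beta1, beta2)

  cand_df <- data.frame(shift = cand,
                        gini = eval_criterion(delta, cand, "gini"),
                        clf  = eval_criterion(delta, cand, "clf", epsilon))
  grid_shifts <- seq(interval[1L], interval[2L], length.out = resolution)
  grid_df <- data.frame(shift = grid_shifts,
                        gini = eval_criterion(delta, grid_shifts, "gini"),
                        clf  = eval_criterion(delta, grid_shifts, "clf", epsilon))

  glob <- lapply(c(gini = "gini", clf = "clf"),
                 function(cr) select_global(cand, cand_df[[cr]], cr))

  loc <- lapply(c(gini = "gini", clf = "clf"), function(cr) {
    find_local_optima(delta, cand, cand_df[[cr]], glob[[cr]]$shift, cr, epsilon)
  })

  structure(list(grid = grid_df, candidates = cand_df, global = glob,
                 local = loc, interval = interval, criterion = criterion,
                 shift = glob[[criterion]]$shift, epsilon = epsilon, m = m),
            class = "criterion_curve")
}

# global optimum over the candidate set; ties within 1e-10 resolve to the
# smallest |shift| with a warning (label-switching situation)
select_global <- function(cand, values, label) {
  top <- which(values >= max(values) - 1e-10)
  if (length(top) > 1L) {
    warning("tied global optima for the ", label, " criterion at shifts ",
            paste(format(cand[top]), collapse = ", "),
            "; selecting the smallest |shift| (possible label switching)")
    top <- top[order(abs(cand[top]), cand[top])]
  }
  list(shift = cand[top[1L]], value = values[top[1L]],
       ties = cand[top])
}

# fast selection path used in simulations: candidate set only, no grid
anchor_shift <- function(beta1, beta2, criterion, epsilon = 0) {
  cand <- candidate_shifts(beta1, beta2)
  v <- eval_criterion(beta1 - beta2, cand, criterion, epsilon)
  select_global(cand, v, criterion)$shift
}

# local maxima of the continuous criterion curve among non-global candidates:
# the candidate value must strictly exceed the curve just to either side.
find_local_optima <- function(delta, cand, values, global_shift, criterion,
                              epsilon = 0) {
  k <- length(cand)
  empty <- data.frame(shift = numeric(0), value = numeric(0),
                      prominence = numeric(0))
  if (k < 2L) return(empty)
  h <- 1e-3 * min(diff(cand))
  keep <- logical(k)
  for (i in seq_len(k)) {
    if (abs(cand[i] - global_shift) < 1e-15) next
    side <- eval_criterion(delta, c(cand[i] - h, cand[i] + h), criterion, epsilon)
    keep[i] <- values[i] > side[1L] && values[i] > side[2L]
  }
  if (!any(keep)) return(empty)
  prom <- vapply(which(keep), function(i) {
    nb <- c(if (i > 1L) values[i - 1L], if (i < k) values[i + 1L])
    values[i] - max(nb)
  }, numeric(1))
  data.frame(shift = cand[keep], value = values[keep], prominence = prom)
}

#' Local optima of a criterion curve
#'
#' Returns the non-global local maxima located by [criterion_curve()]. A
#' pronounced secondary optimum signals a second item cluster that could
#' equally be declared DIF-free — e.g. unaccounted DIF-inducing
#' multidimensionality — and should be inspected on the criterion plot.
#'
#' @param curve a \code{"criterion_curve"} object.
#' @param criterion \code{"gini"} or \code{"clf"}; defaults to the curve's
#'   selecting criterion.
#' @return data frame with columns \code{shift}, \code{value},
#'   \code{prominence}.
#' @export
local_optima <- function(curve, criterion = NULL) {
  stopifnot(inherits(curve, "criterion_curve"))
  if (is.null(criterion)) criterion <- curve$criterion
  criterion <- match.arg(criterion, c("gini", "clf"))
  curve$local[[criterion]]
}

#' @export
print.criterion_curve <- function(x, digits = 4, ...) {
  cat("Anchor point selection over [", format(x$interval[1L], digits = digits),
      ", ", format(x$interval[2L], digits = digits), "] (",
      nrow(x$candidates), " candidate shifts, ", x$m, " items)\n", sep = "")
  for (cr in c("gini", "clf")) {
    g <- x$global[[cr]]
    cat(sprintf("  %-4s global optimum: shift = %s (value %s)",
                toupper(cr), format(g$shift, digits = digits),
                format(g$value, digits = digits)))
    lo <- x$local[[cr]]
    if (nrow(lo))
      cat("; local optima at ", paste(format(lo$shift, digits = digits),
                                      collapse = ", "), sep = "")
    cat("\n")
  }
  cat("Selected anchor point (", x$criterion, "): shift = ",
      format(x$shift, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Criterion plot
#'
#' Plots both criteria over the search interval, in the style of the standard
#' anchor-point criterion plot: the Gini Index on its natural \eqn{[0, 1]}
#' scale and the CLF criterion min-max rescaled onto the same panel (its raw
#' values are retained in the object and in text exports). Candidate shifts
#' are shown as rug marks, the global optima as filled points, local optima
#' as open points.
#'
#' @param x a \code{"criterion_curve"} object.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.criterion_curve <- function(x, ...) {
  g <- x$grid
  rng <- range(g$clf)
  clf_scaled <- if (diff(rng) > 0) (g$clf - rng[1L]) / diff(rng) else rep(0.5, nrow(g))
  graphics::plot(g$shift, g$gini, type = "l", col = "black", lwd = 1.5,
                 xlab = "shift c", ylab = "criterion value",
                 ylim = c(0, max(1 - 1 / x$m, g$gini)), ...)
  graphics::lines(g$shift, clf_scaled * max(1 - 1 / x$m), col = "grey45",
                  lty = 2, lwd = 1.5)
  graphics::rug(x$candidates$shift)
  graphics::points(x$global$gini$shift, x$global$gini$value, pch = 19)
  lo <- x$local$gini
  if (nrow(lo)) graphics::points(lo$shift, lo$value, pch = 1)
  graphics::legend("topleft", bty = "n", lwd = 1.5, lty = c(1, 2),
                   col = c("black", "grey45"),
                   legend = c("Gini Index", "CLF (rescaled)"))
  invisible(x)
}
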