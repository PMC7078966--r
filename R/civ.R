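#' Grid of clinically important values for one outcome
#'
#' The grid is declared on the oriented preference scale: positive values
#' demand a clinically important advantage, negative values express how
#' much disadvantage one is willing to tolerate. A weight-gain tolerance
#' sweep from none up to 1 SMD unit is thus
#' `civ_spec("weight_gain", from = -1, to = 0, by = 0.05)`.
#'
#' @param outcome_name outcome the grid applies to.
#' @param grid strictly increasing numeric vector of CIV values; built from
#'   `from`/`to`/`by` when omitted.
#' @param from,to,by arithmetic-sequence shortcut (default step 0.05, the
#'   granularity at which curve crossings are usually read).
#' @return An object of class `civ_spec`.
#' @export
civ_spec <- function(outcome_name = "outcome", grid = NULL,
                     from = 0, to = 0.5, by = 0.05) {
  if (is.null(grid)) grid <- seq(from, to, by = by)
  grid <- as.numeric(grid)
  if (length(grid) == 0) stop("CIV grid is empty")
  if (any(!is.finite(grid))) stop("CIV grid must be finite")
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("CIV grid must be strictly increasing")
  resolution <- if (length(grid) > 1) stats::median(diff(grid)) else NA_real_
  structure(list(outcome_name = outcome_name, grid = grid,
                 resolution = resolution),
            class = "civ_spec")
}

new_civ_curves <- function(treatments, grid, scores, outcome_name,
                           benefit = NULL) {
  dimnames(scores) <- list(treatments, format(grid, trim = TRUE))
  structure(list(treatments = treatments, grid = grid, scores = scores,
                 mean_curve = colMeans(scores),
                 crossings = .all_crossings(treatments, grid, scores),
                 outcome_name = outcome_name, benefit = benefit),
            class = "civ_curves")
}

#' P-score curves over a CIV grid
#'
#' Recomputes the analytic P-scores of every treatment at each value of a
#' CIV grid, giving the curves from which one reads how the treatment
#' hierarchy re-orders as the demanded clinical margin grows (or, for
#' negative CIVs, as a disadvantage is increasingly tolerated). Every curve
#' is non-increasing in the CIV, and the mean curve equals 0.5 at CIV = 0
#' and falls below it for positive CIVs.
#'
#' @param effects an oriented [outcome_effects] object.
#' @param spec a [civ_spec] (or numeric vector, coerced to one).
#' @return An object of class `civ_curves`: the score matrix (treatment x
#'   grid point), the per-point mean curve, and all pairwise curve
#'   crossings located by linear interpolation.
#' @seealso [find_crossings()], [benefit_risk_curves()]
#' @export
civ_curve <- function(effects, spec) {
  stopifnot(inherits(effects, "outcome_effects"))
  if (!effects$oriented) stop("effects must be oriented first; see orient()")
  if (is.numeric(spec)) spec <- civ_spec(effects$outcome_name, grid = spec)
  stopifnot(inherits(spec, "civ_spec"))
  g <- spec$grid
  sc <- vapply(g, function(cv) pscores(effects, civ = cv)$scores,
               numeric(length(effects$treatments)))
  sc <- matrix(sc, nrow = length(effects$treatments))
  new_civ_curves(effects$treatments, g, sc, effects$outcome_name)
}

# Sign changes of score_a - score_b between adjacent grid points, located
# by linear interpolation. A touch (zero at a grid point) is not a crossing.
.pair_crossings <- function(grid, sa, sb) {
  d <- sa - sb
  out <- numeric(0)
  for (k in seq_len(length(grid) - 1L)) {
    if (d[k] * d[k + 1L] < 0) {
      w <- d[k] / (d[k] - d[k + 1L])
      out <- c(out, grid[k] + w * (grid[k + 1L] - grid[k]))
    }
  }
  out
}

.all_crossings <- function(treatments, grid, scores) {
  res <- list()
  I <- length(treatments)
  if (length(grid) >= 2 && I >= 2) {
    for (a in seq_len(I - 1L)) for (b in (a + 1L):I) {
      cv <- .pair_crossings(grid, scores[a, ], scores[b, ])
      if (length(cv))
        res[[length(res) + 1L]] <-
          data.frame(treatment_a = treatments[a], treatment_b = treatments[b],
                     civ = cv)
    }
  }
  if (length(res)) do.call(rbind, res)
  else data.frame(treatment_a = character(0), treatment_b = character(0),
                  civ = numeric(0))
}

#' Locate the CIV values where two P-score curves cross
#'
#' A crossing is a sign change of the score difference between adjacent
#' grid points; its location is linearly interpolated between the two
#' bracketing points (so it is accurate to well within one grid step for
#' smooth curves). Curves that touch without changing order are not
#' reported.
#'
#' @param curves a `civ_curves` object.
#' @param pair character vector of two treatment labels.
#' @return Numeric vector of CIV values (possibly empty).
#' @export
find_crossings <- function(curves, pair) {
  stopifnot(inherits(curves, "civ_curves"), length(pair) == 2)
  miss <- setdiff(pair, curves$treatments)
  if (length(miss))
    stop("unknown treatment label(s): ", paste(miss, collapse = ", "))
  .pair_crossings(curves$grid,
                  curves$scores[pair[1L], ], curves$scores[pair[2L], ])
}

#' @export
print.civ_curves <- function(x, ...) {
  cat("P-score curves: ", x$outcome_name, ", ",
      length(x$treatments), " treatments over ", length(x$grid),
      " CIV values [", format(min(x$grid)), ", ", format(max(x$grid)),
      "]\n", sep = "")
  if (!is.null(x$benefit))
    cat("benefit outcome ", x$benefit$outcome, " at CIV = ",
        format(x$benefit$civ), "\n", sep = "")
  nc <- nrow(x$crossings)
  cat(nc, " pairwise crossing(s) on the grid\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.civ_curves <- function(x, ...) {
  data.frame(treatment = rep(x$treatments, times = length(x$grid)),
             civ = rep(x$grid, each = length(x$treatments)),
             pscore = as.vector(x$scores))
}

#' P-score curve plot
#'
#' One line per treatment with a dotted line for the mean P-score across
#' treatments at each grid point.
#'
#' @param x a `civ_curves` object.
#' @param label logical; annotate line ends with treatment labels.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.civ_curves <- function(x, label = TRUE, ...) {
  graphics::matplot(x$grid, t(x$scores), type = "l", lty = 1,
                    xlab = "CIV", ylab = "P-score", ylim = c(0, 1), ...)
  graphics::lines(x$grid, x$mean_curve, lty = 3, lwd = 2)
  if (label) {
    side <- which.max(abs(range(x$grid)))
    at <- if (side == 2) length(x$grid) else 1L
    graphics::text(x$grid[at], x$scores[, at], labels = x$treatments,
                   pos = 4, cex = 0.6, xpd = NA)
  }
  invisible(x)
}
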