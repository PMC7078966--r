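#' Relative treatment effects for one outcome of a network meta-analysis
#'
#' Container for the summary output of a single-outcome NMA: the estimated
#' relative effects of every treatment versus a common reference, together
#' with the covariance matrix of those estimates. Both representations of
#' uncertainty are kept: the full covariance `sigma` (needed to simulate
#' rank distributions) and the matrix of pairwise standard errors
#' `pairwise_se` with entries \eqn{s_{ij} = \sqrt{\sigma_{ii} + \sigma_{jj}
#' - 2\sigma_{ij}}} (all the analytic P-score machinery needs).
#'
#' The reference treatment is an ordinary member of the ranking: its effect
#' is fixed at 0 and its row/column of `sigma` are exact zeros.
#'
#' @param treatments character vector of unique treatment labels.
#' @param mu numeric vector of relative effects versus `reference`, same
#'   length and order as `treatments`; the reference entry must be 0.
#' @param sigma covariance matrix of `mu` (I x I), or `NULL` when only
#'   pairwise standard errors are available (see `pairwise_se`).
#' @param reference label of the reference treatment.
#' @param measure effect measure of the published estimates: `"SMD"`
#'   (standardized mean difference) or `"logOR"` (log odds ratio).
#' @param direction `"higher_better"` or `"lower_better"` on the published
#'   scale. Harmful outcomes (e.g. weight gain) are `"lower_better"`.
#' @param outcome_name short outcome label.
#' @param pairwise_se optional I x I matrix of pairwise standard errors;
#'   computed from `sigma` when omitted. Must be supplied if `sigma` is
#'   `NULL`.
#' @param oriented logical; `TRUE` once [orient()] has been applied so that
#'   larger `mu` is always better.
#' @return An object of class `outcome_effects`.
#' @seealso [orient()], [covariance_from_league()], [pscores()]
#' @export
outcome_effects <- function(treatments, mu, sigma = NULL,
                            reference = treatments[1L],
                            measure = c("SMD", "logOR"),
                            direction = c("higher_better", "lower_better"),
                            outcome_name = "outcome",
                            pairwise_se = NULL,
                            oriented = FALSE) {
  measure <- match.arg(measure)
  direction <- match.arg(direction)
  treatments <- as.character(treatments)
  I <- length(treatments)
  if (anyDuplicated(treatments))
    stop("duplicate treatment labels: ",
         paste(unique(treatments[duplicated(treatments)]), collapse = ", "))
  if (!reference %in% treatments)
    stop("reference treatment '", reference, "' is not among the treatments")
  if (length(mu) != I)
    stop("length(mu) = ", length(mu), " but there are ", I, " treatments")
  mu <- as.numeric(mu)
  names(mu) <- treatments
  if (abs(mu[reference]) > 1e-12)
    stop("effect of the reference treatment must be 0, got ", mu[reference])
  mu[reference] <- 0

  if (is.null(sigma) && is.null(pairwise_se))
    stop("either sigma or pairwise_se must be supplied")

  if (!is.null(sigma)) {
    sigma <- as.matrix(sigma)
    if (!all(dim(sigma) == c(I, I)))
      stop("sigma must be ", I, " x ", I)
    if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
      stop("sigma is not symmetric")
    sigma <- (sigma + t(sigma)) / 2
    if (any(diag(sigma) < -1e-12))
      stop("sigma has a negative diagonal entry")
    sigma <- .psd_clip(sigma)
    r <- match(reference, treatments)
    if (max(abs(sigma[r, ])) > 1e-10 || max(abs(sigma[, r])) > 1e-10)
      stop("reference row/column of sigma must be zero")
    sigma[r, ] <- 0
    sigma[, r] <- 0
    dimnames(sigma) <- list(treatments, treatments)
  }

  if (is.null(pairwise_se)) {
    v <- diag(sigma)
    s2 <- outer(v, v, "+") - 2 * sigma
    s2[s2 < 0] <- 0   # numerical guard; exact zeros only on the diagonal
    pairwise_se <- sqrt(s2)
  } else {
    pairwise_se <- as.matrix(pairwise_se)
    if (!all(dim(pairwise_se) == c(I, I)))
      stop("pairwise_se must be ", I, " x ", I)
    pairwise_se <- (pairwise_se + t(pairwise_se)) / 2
  }
  dimnames(pairwise_se) <- list(treatments, treatments)
  off <- pairwise_se[upper.tri(pairwise_se)]
  if (any(off <= 0))
    stop("all pairwise standard errors must be positive")

  structure(
    list(outcome_name = outcome_name, treatments = treatments,
         reference = reference, mu = mu, sigma = sigma,
         pairwise_se = pairwise_se, measure = measure,
         direction = direction, oriented = isTRUE(oriented)),
    class = "outcome_effects")
}

# Eigenvalue clip for almost-PSD matrices (league tables transcribed from
# rounded publications are often slightly inconsistent). Eigenvalues down to
# -tol * max(eigenvalue) are clipped to zero; anything lower is an error.
.psd_clip <- function(m, tol = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  lmax <- max(e$values, 0)
  lmin <- min(e$values)
  if (lmin < -tol * max(lmax, 1))
    stop("matrix is not positive semidefinite (smallest eigenvalue ",
         format(lmin), ")")
  if (lmin < 0) {
    v <- pmax(e$values, 0)
    m <- e$vectors %*% (v * t(e$vectors))
    m <- (m + t(m)) / 2
  }
  m
}

#' @export
print.outcome_effects <- function(x, ...) {
  cat("NMA summary effects: ", x$outcome_name,
      " (", length(x$treatments), " treatments, measure ", x$measure,
      ", ", x$direction, if (x$oriented) ", oriented" else "", ")\n", sep = "")
  cat("reference:", x$reference, "\n")
  print(round(x$mu, 4))
  if (is.null(x$sigma))
    cat("(pairwise standard errors only; no full covariance)\n")
  invisible(x)
}

#' Convert log odds ratios to standardized mean differences
#'
#' Rescales a log odds ratio to the SMD scale by the factor
#' \eqn{\sqrt{3}/\pi} (Chinn's conversion, based on the logistic
#' distribution's standard deviation). The conversion is linear, so the
#' standard error is rescaled by the same factor.
#'
#' @param log_or log odds ratio(s).
#' @param se_log_or standard error(s) of `log_or`, nonnegative.
#' @return List with components `smd` and `se_smd`.
#' @examples
#' or_to_smd(1, 2)   # smd ~ 0.5513, se ~ 1.1027
#' @export
or_to_smd <- function(log_or, se_log_or = 0) {
  if (any(se_log_or < 0)) stop("se_log_or must be nonnegative")
  f <- sqrt(3) / pi
  list(smd = f * log_or, se_smd = f * se_log_or)
}

#' Orient an outcome so that larger effects are better
#'
#' Downstream ranking code uniformly treats larger oriented effects as
#' preferable. For a `lower_better` outcome the effects are negated (the
#' covariance is unchanged: negating every component of a contrast vector
#' leaves contrast variances intact). Orientation is applied exactly once;
#' a second call is an error rather than a silent double negation.
#'
#' After orientation, clinically important values are interpreted on the
#' preference scale: positive CIVs demand an advantage of that size,
#' negative CIVs tolerate a disadvantage (the natural encoding for harm
#' tolerances on a `lower_better` outcome).
#'
#' @param effects an [outcome_effects] object with `oriented = FALSE`.
#' @return The oriented `outcome_effects` object.
#' @export
orient <- function(effects) {
  stopifnot(inherits(effects, "outcome_effects"))
  if (effects$oriented)
    stop("effects for '", effects$outcome_name, "' are already oriented")
  if (effects$direction == "lower_better")
    effects$mu <- -effects$mu
  effects$oriented <- TRUE
  effects
}

# Clinically important values everywhere in this package live on the
# oriented preference scale: positive values demand a clinically important
# advantage, negative values tolerate a bounded disadvantage. For a
# lower_better outcome a tolerance of 0.65 published units of harm is
# therefore civ = -0.65. This is the convention in which harm-tolerance
# grids run from 0 down to negative values.
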