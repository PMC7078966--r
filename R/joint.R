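#' Between-outcome correlation matrix
#'
#' Correlation linking the standardized pairwise contrasts of the K
#' outcomes in the joint superiority probability. It is rarely estimable
#' from published NMA output; see [correlation_strategy()] for the usual
#' ways of choosing it (ignore, expert opinion, sensitivity range).
#'
#' @param outcome_names ordered outcome labels.
#' @param rho K x K correlation matrix: symmetric, unit diagonal, entries
#'   in `[-1, 1]`, positive semidefinite.
#' @return An object of class `correlation_spec`.
#' @export
correlation_spec <- function(outcome_names, rho) {
  rho <- as.matrix(rho)
  K <- length(outcome_names)
  if (!all(dim(rho) == c(K, K)))
    stop("rho must be ", K, " x ", K)
  if (max(abs(rho - t(rho))) > 1e-10) stop("rho must be symmetric")
  rho <- (rho + t(rho)) / 2
  if (max(abs(diag(rho) - 1)) > 1e-10) stop("rho must have a unit diagonal")
  diag(rho) <- 1
  if (any(rho < -1 - 1e-12) || any(rho > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * K)
    stop("rho is not positive semidefinite (smallest eigenvalue ",
         format(min(ev)), ")")
  dimnames(rho) <- list(outcome_names, outcome_names)
  structure(list(outcome_names = as.character(outcome_names), rho = rho),
            class = "correlation_spec")
}

#' Strategies for setting the between-outcome correlation
#'
#' Three pragmatic strategies when no multivariate NMA estimate exists:
#' analyse outcomes as independent (`"zero"`), fix the matrix from expert
#' opinion (`"fixed"`), or sweep a plausible range of a single correlation
#' in a sensitivity analysis (`"range"`, two outcomes only).
#'
#' @param mode `"zero"`, `"fixed"` or `"range"`.
#' @param outcome_names outcome labels (length 2 for `"range"`).
#' @param values for `"fixed"`: the K x K matrix; for `"range"`: a vector
#'   `c(lo, hi, step)` with endpoints strictly inside (-1, 1); unused for
#'   `"zero"`.
#' @return A [correlation_spec], or a list of them for `"range"`.
#' @export
correlation_strategy <- function(mode = c("zero", "fixed", "range"),
                                 outcome_names, values = NULL) {
  mode <- match.arg(mode)
  K <- length(outcome_names)
  switch(mode,
    zero = correlation_spec(outcome_names, diag(K)),
    fixed = {
      if (is.null(values)) stop("mode 'fixed' needs a correlation matrix")
      correlation_spec(outcome_names, values)
    },
    range = {
      if (K != 2) stop("mode 'range' sweeps a single correlation (K = 2)")
      if (length(values) != 3)
        stop("mode 'range' needs values = c(lo, hi, step)")
      lo <- values[1L]; hi <- values[2L]; by <- values[3L]
      if (lo <= -1 || hi >= 1)
        stop("range endpoints must lie strictly inside (-1, 1)")
      lapply(seq(lo, hi, by = by), function(r)
        correlation_spec(outcome_names, matrix(c(1, r, r, 1), 2L)))
    })
}

#' Several outcomes of the same treatment network
#'
#' Bundles K oriented [outcome_effects] objects over the identical
#' treatment set (same labels, order and reference) with the assumed
#' between-outcome correlation, ready for joint superiority probabilities.
#'
#' @param outcomes list of oriented [outcome_effects] objects.
#' @param correlation a [correlation_spec] over the same outcomes, or
#'   `NULL` for independence.
#' @return An object of class `joint_effects`.
#' @export
joint_effects <- function(outcomes, correlation = NULL) {
  if (inherits(outcomes, "outcome_effects")) outcomes <- list(outcomes)
  stopifnot(length(outcomes) >= 1)
  if (length(outcomes) > 6)
    stop("joint ranking supports at most 6 outcomes")
  lapply(outcomes, function(o) stopifnot(inherits(o, "outcome_effects")))
  nm <- vapply(outcomes, `[[`, "", "outcome_name")
  if (anyDuplicated(nm)) stop("outcome names must be unique")
  names(outcomes) <- nm
  ref <- outcomes[[1L]]
  for (o in outcomes[-1L]) {
    if (!identical(o$treatments, ref$treatments))
      stop("outcomes disagree on the treatment set: '", o$outcome_name,
           "' differs from '", ref$outcome_name, "' (",
           paste(union(setdiff(o$treatments, ref$treatments),
                       setdiff(ref$treatments, o$treatments)),
                 collapse = ", "), ")")
    if (!identical(o$reference, ref$reference))
      stop("outcomes disagree on the reference treatment")
  }
  for (o in outcomes)
    if (!o$oriented)
      stop("outcome '", o$outcome_name, "' is not oriented; see orient()")
  K <- length(outcomes)
  if (is.null(correlation)) correlation <- correlation_spec(nm, diag(K))
  stopifnot(inherits(correlation, "correlation_spec"))
  if (length(correlation$outcome_names) != K)
    stop("correlation dimension does not match the number of outcomes")
  if (!identical(correlation$outcome_names, unname(nm))) {
    ord <- match(nm, correlation$outcome_names)
    if (any(is.na(ord)))
      stop("correlation outcome names do not match the outcomes")
    correlation <- correlation_spec(nm, correlation$rho[ord, ord])
  }
  structure(list(outcomes = outcomes, correlation = correlation,
                 treatments = ref$treatments, reference = ref$reference),
            class = "joint_effects")
}

#' @export
print.joint_effects <- function(x, ...) {
  cat("Joint NMA effects: ", length(x$outcomes), " outcome(s) [",
      paste(names(x$outcomes), collapse = ", "), "] over ",
      length(x$treatments), " treatments\n", sep = "")
  cat("between-outcome correlation:\n")
  print(x$correlation$rho)
  invisible(x)
}

# Standard multivariate normal CDF Phi_K(upper; rho).
# K = 1: closed form. K = 2, 3 nonsingular: deterministic TVPACK.
# Otherwise: Genz-Bretz quasi-Monte-Carlo run under a locally fixed RNG
# state so results are reproducible call to call.
.joint_phi <- function(upper, rho, abseps = 1e-8) {
  K <- length(upper)
  if (K == 1L) return(stats::pnorm(upper))
  if (any(!is.finite(upper))) {
    if (any(upper == -Inf)) return(0)
    fin <- is.finite(upper)
    if (!any(fin)) return(1)          # all +Inf
    return(.joint_phi(upper[fin], rho[fin, fin, drop = FALSE], abseps))
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (K <= 3L && min(ev) > 1e-10) {
    as.numeric(mvtnorm::pmvnorm(upper = upper, corr = rho,
                                algorithm = mvtnorm::TVPACK(abseps)))
  } else {
    .with_seed(171717L, as.numeric(mvtnorm::pmvnorm(
      upper = upper, corr = rho,
      algorithm = mvtnorm::GenzBretz(abseps = abseps, maxpts = 250000L))))
  }
}

#' Joint superiority probability across outcomes
#'
#' Probability that treatment i beats treatment j by more than the outcome
#' CIVs on *all* K outcomes simultaneously,
#' \deqn{P_{i>j} = \Phi_K\!\left(\frac{d^{(1)}_{ij} - c_1}{s^{(1)}_{ij}},
#' \ldots, \frac{d^{(K)}_{ij} - c_K}{s^{(K)}_{ij}};\; \rho\right),}
#' the CDF of a standard K-variate normal with the assumed between-outcome
#' correlation \eqn{\rho}. With K = 1 this is exactly [pairwise_prob()];
#' with \eqn{\rho = 0} it factorizes into the product of marginals; it can
#' never exceed the smallest marginal.
#'
#' @param je a [joint_effects] object.
#' @param i,j treatment labels.
#' @param civs length-K vector of CIVs on the oriented scales (default all
#'   zero).
#' @return A probability.
#' @export
joint_pairwise_prob <- function(je, i, j, civs = rep(0, length(je$outcomes))) {
  stopifnot(inherits(je, "joint_effects"))
  K <- length(je$outcomes)
  if (length(civs) != K) stop("civs must have one entry per outcome")
  ii <- match(i, je$treatments)
  jj <- match(j, je$treatments)
  if (is.na(ii) || is.na(jj))
    stop("unknown treatment label: ", if (is.na(ii)) i else j)
  upper <- vapply(seq_len(K), function(k) {
    o <- je$outcomes[[k]]
    s <- o$pairwise_se[ii, jj]
    if (s <= 0) stop("nonpositive pairwise SE for outcome '",
                     o$outcome_name, "'")
    (o$mu[ii] - o$mu[jj] - civs[k]) / s
  }, numeric(1))
  .joint_phi(upper, je$correlation$rho)
}

#' Multi-outcome P-scores
#'
#' The P-score average of joint superiority probabilities: the mean extent
#' of certainty that a treatment beats each competitor on all outcomes at
#' once, by at least the outcome CIVs. Scores shrink as outcomes are added
#' (the joint event is more demanding), which is why a top-efficacy
#' treatment with a poor safety profile drops down the joint ranking.
#'
#' @param je a [joint_effects] object.
#' @param civs length-K vector of CIVs on the oriented scales.
#' @return A [pscores] object with the full outcome context.
#' @export
multi_pscores <- function(je, civs = rep(0, length(je$outcomes))) {
  stopifnot(inherits(je, "joint_effects"))
  K <- length(je$outcomes)
  if (length(civs) != K) stop("civs must have one entry per outcome")
  trt <- je$treatments
  I <- length(trt)
  if (I < 2) stop("ranking needs at least two treatments")
  rho <- je$correlation$rho
  D <- lapply(je$outcomes, function(o) outer(o$mu, o$mu, "-"))
  S <- lapply(je$outcomes, `[[`, "pairwise_se")
  scores <- numeric(I)
  for (a in seq_len(I)) {
    tot <- 0
    for (b in seq_len(I)) {
      if (a == b) next
      upper <- vapply(seq_len(K), function(k)
        (D[[k]][a, b] - civs[k]) / S[[k]][a, b], numeric(1))
      tot <- tot + .joint_phi(upper, rho)
    }
    scores[a] <- tot / (I - 1)
  }
  new_pscores(scores, trt, civ = civs, outcome_context = names(je$outcomes),
              method = "analytic")
}

#' Benefit-risk P-score curves
#'
#' Fixes the clinically important benefit on one outcome and sweeps a grid
#' of harm tolerances on another, recomputing the joint P-scores at each
#' grid point. The resulting curves display the benefit-risk tradeoff: how
#' the treatment hierarchy re-orders as more harm is tolerated in exchange
#' for a required gain. Both CIVs are declared on the oriented preference
#' scale: the benefit CIV is a positive demanded margin, and harm
#' tolerances are negative, running from 0 down to the largest tolerated
#' harm.
#'
#' @param je a [joint_effects] containing both outcomes.
#' @param benefit_outcome,risk_outcome outcome names in `je`.
#' @param benefit_civ scalar CIV for the benefit outcome (oriented
#'   preference scale).
#' @param risk_grid a [civ_spec] (or numeric vector) of harm tolerances
#'   (typically nonpositive) for the risk outcome.
#' @return A `civ_curves` object over the risk grid, with the benefit
#'   context recorded in `$benefit`.
#' @export
benefit_risk_curves <- function(je, benefit_outcome, risk_outcome,
                                benefit_civ = 0, risk_grid) {
  stopifnot(inherits(je, "joint_effects"))
  if (benefit_outcome == risk_outcome)
    stop("benefit and risk outcomes must differ")
  nm <- names(je$outcomes)
  miss <- setdiff(c(benefit_outcome, risk_outcome), nm)
  if (length(miss)) stop("outcome(s) not in the joint set: ",
                         paste(miss, collapse = ", "))
  if (is.numeric(risk_grid)) risk_grid <- civ_spec(risk_outcome, risk_grid)
  stopifnot(inherits(risk_grid, "civ_spec"))

  sel <- match(c(benefit_outcome, risk_outcome), nm)
  sub <- joint_effects(je$outcomes[sel],
                       correlation_spec(nm[sel],
                                        je$correlation$rho[sel, sel]))
  g <- risk_grid$grid
  sc <- vapply(g, function(cv)
    multi_pscores(sub, civs = c(benefit_civ, cv))$scores,
    numeric(length(je$treatments)))
  sc <- matrix(sc, nrow = length(je$treatments))
  new_civ_curves(je$treatments, g, sc,
                 outcome_name = paste(benefit_outcome, "+", risk_outcome),
                 benefit = list(outcome = benefit_outcome, civ = benefit_civ,
                                risk_outcome = risk_outcome))
}
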