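#' Rank-probability distribution (rankogram data)
#'
#' `P[i, r]` is the probability that treatment i occupies rank r, with
#' rank 1 the best on the oriented scale. A valid distribution is doubly
#' stochastic: every treatment occupies exactly one rank and every rank is
#' occupied by exactly one treatment.
#'
#' @param P I x I matrix of rank probabilities; rows are treatments,
#'   columns are ranks 1..I.
#' @param treatments treatment labels (defaults to rownames of `P`).
#' @param n_samples number of simulation draws behind `P` (`NA` for
#'   distributions constructed analytically or by hand).
#' @param seed RNG seed used for the draws (`NA` if not simulated).
#' @return An object of class `rank_dist`.
#' @seealso [simulate_ranks()], [sucra()], [pbest()]
#' @export
rank_dist <- function(P, treatments = rownames(P), n_samples = NA_integer_,
                      seed = NA_integer_) {
  P <- as.matrix(P)
  I <- nrow(P)
  if (ncol(P) != I) stop("P must be square (one column per rank)")
  if (is.null(treatments)) treatments <- paste0("t", seq_len(I))
  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    stop("rank probabilities must lie in [0, 1]")
  if (max(abs(rowSums(P) - 1)) > 1e-9)
    stop("every treatment's rank probabilities must sum to 1")
  if (max(abs(colSums(P) - 1)) > 1e-9)
    stop("every rank's probabilities must sum to 1 across treatments")
  dimnames(P) <- list(treatments, seq_len(I))
  structure(list(treatments = as.character(treatments), P = P,
                 n_samples = n_samples, seed = seed),
            class = "rank_dist")
}

#' @export
print.rank_dist <- function(x, digits = 3, ...) {
  cat("Rank distribution for", length(x$treatments), "treatments")
  if (!is.na(x$n_samples))
    cat(" (", format(x$n_samples, big.mark = ","), " draws, seed ",
        x$seed, ")", sep = "")
  cat("\n")
  print(round(x$P, digits))
  invisible(x)
}

#' Simulate the rank distribution from NMA estimates
#'
#' Draws `n_samples` effect vectors from the multivariate normal
#' distribution of the estimates, ranks each draw in descending order on
#' the oriented scale, and tallies rank frequencies. This is the frequentist
#' route to rankograms and SUCRA: resampling from the estimated effects and
#' their variance-covariance matrix. Exact ties within a draw (possible
#' only with a degenerate covariance) are broken uniformly at random so the
#' tallied matrix stays doubly stochastic in expectation.
#'
#' The covariance is always singular in the reference direction (the
#' reference effect is fixed at 0), so draws use an eigendecomposition
#' rather than a Cholesky factor.
#'
#' @param effects an oriented [outcome_effects] with a full covariance
#'   (league-table loads reconstruct one via [covariance_from_league()]).
#' @param n_samples number of draws (default 1e5, Monte-Carlo error about
#'   0.0016 on any single probability).
#' @param seed RNG seed; required so runs are reproducible. The caller's
#'   RNG state is left untouched.
#' @return A [rank_dist] object.
#' @export
simulate_ranks <- function(effects, n_samples = 1e5, seed) {
  stopifnot(inherits(effects, "outcome_effects"))
  if (!effects$oriented) stop("effects must be oriented first; see orient()")
  if (is.null(effects$sigma))
    stop("no covariance matrix available for '", effects$outcome_name,
         "'; reconstruct one with covariance_from_league()")
  if (missing(seed)) stop("a seed is required for simulate_ranks()")
  if (n_samples < 1) stop("n_samples must be at least 1")
  n_samples <- as.integer(n_samples)
  I <- length(effects$treatments)

  draws <- .with_seed(seed, {
    X <- MASS::mvrnorm(n_samples, mu = effects$mu, Sigma = effects$sigma,
                       tol = 1e-6)
    if (n_samples == 1L) X <- matrix(X, nrow = 1L)
    # rank 1 = largest oriented effect; random tie-break keeps degenerate
    # covariances unbiased
    t(apply(X, 1L, function(x) rank(-x, ties.method = "random")))
  })

  P <- matrix(0, I, I)
  for (i in seq_len(I))
    P[i, ] <- tabulate(draws[, i], nbins = I) / n_samples
  rank_dist(P, treatments = effects$treatments,
            n_samples = n_samples, seed = seed)
}

#' @rdname simulate_ranks
#' @param object an [outcome_effects] object.
#' @param nsim number of draws.
#' @param ... unused.
#' @export
simulate.outcome_effects <- function(object, nsim = 1e5, seed = NULL, ...) {
  if (is.null(seed)) stop("a seed is required")
  simulate_ranks(object, n_samples = nsim, seed = seed)
}

# Evaluate expr under set.seed(seed) and restore the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Surface under the cumulative ranking curve
#'
#' \deqn{\mathrm{SUCRA}_i = \frac{1}{I-1} \sum_{r=1}^{I-1} F(i, r)} with
#' \eqn{F(i, r) = \sum_{x \le r} P_{ix}}. An intervention certain to rank
#' first scores 1, one certain to rank last scores 0, and a completely
#' uninformative (uniform) rank row scores 0.5. SUCRA is a linear function
#' of the mean rank, \eqn{\mathrm{SUCRA}_i = (I - E[\mathrm{rank}_i]) /
#' (I - 1)}; both forms are computed and checked against each other.
#'
#' @param rd a [rank_dist] object.
#' @return Named vector of SUCRA values, with the mean ranks attached as
#'   attribute `mean_rank`.
#' @export
sucra <- function(rd) {
  stopifnot(inherits(rd, "rank_dist"))
  I <- length(rd$treatments)
  if (I < 2) stop("ranking needs at least two treatments")
  FF <- t(apply(rd$P, 1L, cumsum))
  s <- rowSums(FF[, seq_len(I - 1L), drop = FALSE]) / (I - 1L)
  mr <- as.numeric(rd$P %*% seq_len(I))
  if (max(abs(s - (I - mr) / (I - 1L))) > 1e-12)
    stop("internal error: SUCRA / mean-rank identity violated")
  names(s) <- rd$treatments
  attr(s, "mean_rank") <- stats::setNames(mr, rd$treatments)
  s
}

#' Mean rank of each treatment
#'
#' @param rd a [rank_dist] object.
#' @return Named vector of expected ranks.
#' @export
mean_rank <- function(rd) {
  stopifnot(inherits(rd, "rank_dist"))
  stats::setNames(as.numeric(rd$P %*% seq_len(ncol(rd$P))), rd$treatments)
}

#' Probability of being the best treatment
#'
#' The first column of the rank distribution: the probability of occupying
#' the top rank. Taken alone it overweights one end of the distribution (an
#' imprecisely estimated treatment can have a high probability of ranking
#' first *and* last); prefer SUCRA/P-scores for a summary.
#'
#' @param rd a [rank_dist] object.
#' @return Named vector of probabilities, summing to 1 across treatments.
#' @export
pbest <- function(rd) {
  stopifnot(inherits(rd, "rank_dist"))
  stats::setNames(rd$P[, 1L], rd$treatments)
}

#' Rankogram plot
#'
#' One line per treatment of rank probabilities over ranks.
#'
#' @param x a [rank_dist] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rank_dist <- function(x, ...) {
  I <- ncol(x$P)
  graphics::matplot(seq_len(I), t(x$P), type = "b", pch = 1,
                    xlab = "Rank", ylab = "Probability",
                    main = "Rankogram", ...)
  graphics::legend("topright", legend = x$treatments, bty = "n",
                   col = seq_len(I), lty = seq_len(I), cex = 0.7)
  invisible(x)
}
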