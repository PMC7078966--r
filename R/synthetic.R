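#' Generate a synthetic treatment network with known ground truth
#'
#' Emulates the summary output of per-outcome NMA models so every ranking
#' metric can be exercised without external data. True relative effects are
#' drawn uniformly in `[-effect_spread, effect_spread]` (reference fixed at
#' 0). The covariance of the estimates follows a star-plus-noise geometry:
#' independent basic parameters versus the reference (variances from
#' squared standard errors drawn in `precision_range`) plus a small shared
#' rank-one loading, which keeps the matrix positive definite while giving
#' nonzero off-diagonal covariance. Observed estimates are the truth plus a
#' single multivariate-normal noise draw with that covariance, coupled
#' across outcomes through `rho`.
#'
#' Defaults mirror the dynamic range of antipsychotics networks (SMD spread
#' 0.6, standard errors 0.05-0.3).
#'
#' @param I number of treatments (>= 2); the first is the reference.
#' @param K number of outcomes.
#' @param effect_spread half-width of the uniform true-effect range, SMD
#'   units.
#' @param precision_range length-2 range of basic-parameter standard
#'   errors, lower end positive.
#' @param rho a [correlation_spec] over the K outcomes, or `NULL` for
#'   independence.
#' @param seed RNG seed; the generator is fully reproducible from it and
#'   leaves the caller's RNG state untouched.
#' @param directions per-outcome direction(s), recycled to length K.
#' @param outcome_names outcome labels (default `outcome1..K`).
#' @param treatments treatment labels (default `T01..T<I>`, reference
#'   `T01`).
#' @return List with components `joint` (an oriented [joint_effects]) and
#'   `truth` (treatments, per-outcome true effects and covariances, the
#'   correlation and the seed).
#' @export
generate_network <- function(I, K = 1, effect_spread = 0.6,
                             precision_range = c(0.05, 0.3), rho = NULL,
                             seed, directions = "higher_better",
                             outcome_names = NULL, treatments = NULL) {
  if (I < 2) stop("a network needs at least two treatments")
  if (K < 1) stop("K must be at least 1")
  if (missing(seed)) stop("a seed is required for generate_network()")
  if (length(precision_range) != 2 || precision_range[1L] <= 0 ||
      diff(precision_range) < 0)
    stop("precision_range must be c(lo, hi) with 0 < lo <= hi")
  if (effect_spread <= 0) stop("effect_spread must be positive")
  if (is.null(outcome_names)) outcome_names <- paste0("outcome", seq_len(K))
  if (is.null(treatments))
    treatments <- sprintf("T%02d", seq_len(I))
  directions <- rep_len(directions, K)
  if (is.null(rho)) rho <- correlation_spec(outcome_names, diag(K))
  stopifnot(inherits(rho, "correlation_spec"))
  if (length(rho$outcome_names) != K)
    stop("rho dimension does not match K")
  rho <- correlation_spec(outcome_names, rho$rho)

  out <- .with_seed(seed, {
    true_mu <- vector("list", K)
    sigma <- vector("list", K)
    L <- vector("list", K)
    for (k in seq_len(K)) {
      true_mu[[k]] <- c(0, stats::runif(I - 1L, -effect_spread, effect_spread))
      se <- stats::runif(I - 1L, precision_range[1L], precision_range[2L])
      u <- stats::runif(I - 1L, 0, 0.3 * mean(se))
      sig <- diag(se^2, I - 1L) + tcrossprod(u)
      sigma[[k]] <- sig
      L[[k]] <- t(chol(sig))
    }
    # noise coupled across outcomes: shared standard normals mixed by rho
    Z <- matrix(stats::rnorm((I - 1L) * K), I - 1L, K)
    Crho <- .psd_chol(rho$rho)
    E <- Z %*% t(Crho)
    mu_hat <- lapply(seq_len(K), function(k)
      c(0, true_mu[[k]][-1L] + as.numeric(L[[k]] %*% E[, k])))
    list(true_mu = true_mu, sigma = sigma, mu_hat = mu_hat)
  })

  outcomes <- lapply(seq_len(K), function(k) {
    full <- matrix(0, I, I)
    full[-1L, -1L] <- out$sigma[[k]]
    mu <- out$mu_hat[[k]]
    # published scale: a lower_better outcome reports the raw (unoriented)
    # effects, which orient() then negates
    eff <- outcome_effects(treatments, mu, full, reference = treatments[1L],
                           direction = directions[k],
                           outcome_name = outcome_names[k])
    orient(eff)
  })

  truth <- structure(
    list(treatments = treatments,
         true_mu = stats::setNames(out$true_mu, outcome_names),
         sigma = stats::setNames(out$sigma, outcome_names),
         rho = rho, seed = seed),
    class = "synthetic_truth")
  list(joint = joint_effects(outcomes, rho), truth = truth)
}

# lower-triangular square root valid for PSD (possibly singular) matrices
.psd_chol <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m))
}

#' Monte-Carlo oracle for the joint superiority probability
#'
#' Brute-force estimate of \eqn{P(\bigcap_k d_k + s_k Z_k - c_k > 0)} with
#' \eqn{Z \sim N(0, \rho)}: samples `n` correlated standard-normal vectors
#' and counts how often all K shifted inequalities hold. Used as an
#' independent check on the analytic multivariate-normal CDF path.
#'
#' @param d length-K vector of effect differences (oriented scale).
#' @param s length-K vector of standard errors, positive.
#' @param civs length-K vector of CIVs (oriented scale).
#' @param rho K x K correlation matrix.
#' @param n number of samples (>= 1000).
#' @param seed RNG seed (caller's RNG state preserved).
#' @return List with `estimate`, binomial `mc_se`, and `n`.
#' @export
mc_joint_prob_oracle <- function(d, s, civs = rep(0, length(d)), rho = NULL,
                                 n = 1e5, seed) {
  K <- length(d)
  if (length(s) != K || length(civs) != K)
    stop("d, s and civs must have the same length")
  if (any(s <= 0)) stop("s must be positive")
  if (n < 1000) stop("n must be at least 1000")
  if (missing(seed)) stop("a seed is required")
  if (is.null(rho)) rho <- diag(K)
  rho <- as.matrix(rho)
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * K) stop("rho is not positive semidefinite")
  n <- as.integer(n)
  hit <- .with_seed(seed, {
    Z <- matrix(stats::rnorm(n * K), n, K) %*% t(.psd_chol(rho))
    ok <- rep(TRUE, n)
    for (k in seq_len(K))
      ok <- ok & (d[k] + s[k] * Z[, k] - civs[k] > 0)
    sum(ok)
  })
  p <- hit / n
  list(estimate = p, mc_se = sqrt(p * (1 - p) / n), n = n)
}

#' Side-by-side P-score report across outcomes
#'
#' Per-outcome P-scores (as rounded percentages, the usual presentation)
#' with their ranks, plus cumulative joint columns: outcomes 1-2 combined,
#' 1-3 combined, and so on, all at CIV = 0 under the joint set's
#' correlation. Joint columns can only shrink relative to their marginals,
#' so a treatment strong on one outcome but weak on another visibly drops
#' in the combined ranking.
#'
#' @param je a [joint_effects] object.
#' @return Data frame, one row per treatment, sorted by the first outcome's
#'   rank.
#' @export
table1_style_report <- function(je) {
  stopifnot(inherits(je, "joint_effects"))
  K <- length(je$outcomes)
  nm <- names(je$outcomes)
  res <- data.frame(treatment = je$treatments)
  add_cols <- function(res, scores, label) {
    res[[paste0(label, "_pscore_pct")]] <- round(100 * scores)
    res[[paste0(label, "_rank")]] <-
      match(seq_along(scores), order(-scores, je$treatments))
    res
  }
  for (k in seq_len(K))
    res <- add_cols(res, pscores(je$outcomes[[k]])$scores, nm[k])
  if (K >= 2) {
    for (k in 2:K) {
      sel <- seq_len(k)
      sub <- joint_effects(je$outcomes[sel],
                           correlation_spec(nm[sel],
                                            je$correlation$rho[sel, sel]))
      res <- add_cols(res, multi_pscores(sub)$scores,
                      paste0("combined_", k, "_outcomes"))
    }
  }
  res[order(res[[paste0(nm[1L], "_rank")]]), , drop = FALSE]
}

#' Write / read a joint network as JSON
#'
#' Plain-text serialization of a [joint_effects] object (plus optional
#' ground truth) on the published scale, used for packaged synthetic
#' fixtures and for moving networks between the generator and the CLI.
#'
#' @param x for writing: a list with `joint` (and optionally `truth`) as
#'   returned by [generate_network()], or a bare [joint_effects].
#' @param path file path.
#' @return `read_network_json()` returns a list with `joint` (oriented) and
#'   `truth` (`NULL` unless stored).
#' @export
write_network_json <- function(x, path) {
  if (inherits(x, "joint_effects")) x <- list(joint = x)
  je <- x$joint
  stopifnot(inherits(je, "joint_effects"))
  pub <- lapply(je$outcomes, function(o) {
    mu <- o$mu
    if (o$oriented && o$direction == "lower_better") mu <- -mu
    list(outcome_name = o$outcome_name, mu = unname(mu),
         sigma = unname(o$sigma), measure = o$measure,
         direction = o$direction)
  })
  obj <- list(synthetic = TRUE,
              treatments = je$treatments, reference = je$reference,
              outcomes = unname(pub),
              correlation = list(outcome_names = names(je$outcomes),
                                 rho = unname(je$correlation$rho)))
  if (!is.null(x$truth))
    obj$truth <- list(true_mu = lapply(x$truth$true_mu, unname),
                      seed = x$truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  trt <- unlist(obj$treatments)
  as_mat <- function(rows) do.call(rbind, lapply(rows, unlist))
  outcomes <- lapply(obj$outcomes, function(o)
    orient(outcome_effects(trt, unlist(o$mu), as_mat(o$sigma),
                           reference = obj$reference, measure = o$measure,
                           direction = o$direction,
                           outcome_name = o$outcome_name)))
  rho <- correlation_spec(unlist(obj$correlation$outcome_names),
                          as_mat(obj$correlation$rho))
  truth <- if (!is.null(obj$truth))
    list(true_mu = lapply(obj$truth$true_mu, unlist),
         seed = obj$truth$seed)
  list(joint = joint_effects(outcomes, rho), truth = truth)
}

#' Packaged synthetic antipsychotics-like network
#'
#' A seed-generated synthetic stand-in for a published 16-treatment
#' antipsychotics network with three outcomes (efficacy, acceptability,
#' weight gain; the last harmful), used in examples and CLI demos. It is
#' *not* real data: effects and covariances come from
#' [generate_network()].
#'
#' @return A list with `joint` and `truth` as from [read_network_json()].
#' @export
antipsychotics_like <- function() {
  read_network_json(system.file("extdata", "antipsychotics_like.json",
                                package = "civrank", mustWork = TRUE))
}
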