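#' Pairwise superiority probability
#'
#' Probability that treatment i beats treatment j by more than a clinically
#' important value (CIV), under the normal approximation for the relative
#' effect: \eqn{P_{i>j} = \Phi((d_{ij} - \mathrm{CIV}) / s_{ij})}, where
#' \eqn{d_{ij}} is the estimated difference on the oriented (larger-better)
#' scale and \eqn{s_{ij}} its standard error. With CIV = 0 this is the plain
#' extent of certainty that i is better than j.
#'
#' @param d_ij effect difference(s) on the oriented scale.
#' @param s_ij standard error(s), strictly positive.
#' @param civ clinically important value on the oriented scale (default 0).
#' @return Probability (vectorized over the inputs).
#' @export
pairwise_prob <- function(d_ij, s_ij, civ = 0) {
  if (any(s_ij <= 0)) stop("s_ij must be strictly positive")
  stats::pnorm((d_ij - civ) / s_ij)
}

#' Analytic P-scores for a single outcome
#'
#' The P-score of treatment i is the mean extent of certainty that i beats
#' each competitor by more than `civ`, averaged with equal weights:
#' \deqn{\bar P_i = \frac{1}{I-1} \sum_{j \ne i} \Phi\!\left(\frac{d_{ij} -
#' \mathrm{CIV}}{s_{ij}}\right).}
#' At CIV = 0 the P-scores average exactly 0.5 across treatments (each
#' pairwise term and its mirror sum to 1), and they coincide with SUCRA
#' values when the rank probabilities are known exactly.
#'
#' Only the pairwise standard errors are needed, so league-table input
#' without a reconstructed covariance is sufficient.
#'
#' @param effects an oriented [outcome_effects] object.
#' @param civ scalar clinically important value on the oriented scale, or an
#'   I x I matrix of pair-specific values (`civ[i, j]` applies to the
#'   comparison of i versus j and should be antisymmetric).
#' @return An object of class `pscores`: treatments, scores in `[0, 1]`,
#'   the CIV applied, outcome context and method.
#' @examples
#' eff <- outcome_effects(c("A", "B", "C"), c(0, 0.3, 0.6),
#'                        diag(c(0, 0.04, 0.04)), oriented = TRUE)
#' pscores(eff)
#' @export
pscores <- function(effects, civ = 0) {
  stopifnot(inherits(effects, "outcome_effects"))
  if (!effects$oriented)
    stop("effects must be oriented first; see orient()")
  I <- length(effects$treatments)
  if (I < 2) stop("ranking needs at least two treatments")
  D <- outer(effects$mu, effects$mu, "-")
  S <- effects$pairwise_se
  if (is.matrix(civ)) {
    if (!all(dim(civ) == c(I, I))) stop("civ matrix must be ", I, " x ", I)
    CIV <- civ
  } else {
    CIV <- matrix(civ, I, I)
  }
  P <- stats::pnorm((D - CIV) / S)
  diag(P) <- 0
  scores <- rowSums(P) / (I - 1)
  new_pscores(scores, effects$treatments, civ = civ,
              outcome_context = effects$outcome_name, method = "analytic")
}

new_pscores <- function(scores, treatments, civ = 0, outcome_context,
                        method = c("analytic", "simulated")) {
  scores <- as.numeric(scores)
  names(scores) <- treatments
  structure(list(treatments = treatments, scores = scores, civ = civ,
                 outcome_context = outcome_context,
                 method = match.arg(method)),
            class = "pscores")
}

#' @export
print.pscores <- function(x, digits = 3, ...) {
  civ_lab <- if (is.matrix(x$civ)) "pairwise matrix" else
    paste(format(x$civ), collapse = ", ")
  cat("P-scores (", x$method, "), outcome(s): ",
      paste(x$outcome_context, collapse = " + "),
      "; CIV = ", civ_lab, "\n", sep = "")
  print(summary(x), digits = digits, ...)
  invisible(x)
}

#' Ranked table of P-scores
#'
#' Ranks are assigned by descending score; exact ties share the smallest
#' rank, are broken alphabetically for display order, and are flagged.
#'
#' @param object a [pscores] object.
#' @param ... unused.
#' @return Data frame with columns `treatment`, `pscore`, `percent`,
#'   `rank`, `tied`.
#' @export
summary.pscores <- function(object, ...) {
  s <- object$scores
  tied <- duplicated(s) | duplicated(s, fromLast = TRUE)
  ord <- order(-s, names(s))
  data.frame(treatment = names(s)[ord],
             pscore = unname(s[ord]),
             percent = round(100 * unname(s[ord])),
             rank = seq_along(s),
             tied = tied[ord],
             row.names = NULL)
}

#' @export
coef.pscores <- function(object, ...) object$scores

#' @export
as.data.frame.pscores <- function(x, ...) summary(x)
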