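#' League table of pairwise relative effects
#'
#' A league table stores the relative effect and standard error for every
#' pair of treatments, the usual tabular output of an NMA. Rows may be given
#' in either order; when both orders of a pair are present the differences
#' must be antisymmetric and the standard errors equal, and a single
#' canonical row is kept.
#'
#' @param rows data frame with columns `treatment_i`, `treatment_j`,
#'   `diff` (effect of i relative to j) and `se` (positive).
#' @param outcome_name short outcome label.
#' @return An object of class `league_table`.
#' @seealso [covariance_from_league()]
#' @export
league_table <- function(rows, outcome_name = "outcome") {
  need <- c("treatment_i", "treatment_j", "diff", "se")
  if (!all(need %in% names(rows)))
    stop("league table needs columns ", paste(need, collapse = ", "))
  rows <- as.data.frame(rows)[need]
  rows$treatment_i <- as.character(rows$treatment_i)
  rows$treatment_j <- as.character(rows$treatment_j)
  if (any(rows$treatment_i == rows$treatment_j))
    stop("league table has a self-comparison")
  if (any(rows$se <= 0)) stop("all standard errors must be positive")

  key <- ifelse(rows$treatment_i < rows$treatment_j,
                paste(rows$treatment_i, rows$treatment_j, sep = "\r"),
                paste(rows$treatment_j, rows$treatment_i, sep = "\r"))
  keep <- !duplicated(key)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    a <- rows[idx[1L], ]
    for (i in idx[-1L]) {
      b <- rows[i, ]
      flip <- b$treatment_i != a$treatment_i
      d <- if (flip) -b$diff else b$diff
      if (abs(d - a$diff) > 1e-8)
        stop("inconsistent differences for pair ", a$treatment_i, " vs ",
             a$treatment_j, ": ", a$diff, " and ", b$diff)
      if (abs(b$se - a$se) > 1e-8)
        stop("inconsistent standard errors for pair ", a$treatment_i,
             " vs ", a$treatment_j)
    }
  }
  rows <- rows[keep, , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(outcome_name = outcome_name, rows = rows),
            class = "league_table")
}

#' @export
print.league_table <- function(x, ...) {
  cat("League table:", x$outcome_name, "-", nrow(x$rows), "pairs\n")
  print(x$rows)
  invisible(x)
}

# diff and se of i vs j, or NA if the pair is absent
.league_lookup <- function(league, i, j) {
  r <- league$rows
  k <- which(r$treatment_i == i & r$treatment_j == j)
  if (length(k)) return(c(diff = r$diff[k[1L]], se = r$se[k[1L]]))
  k <- which(r$treatment_i == j & r$treatment_j == i)
  if (length(k)) return(c(diff = -r$diff[k[1L]], se = r$se[k[1L]]))
  c(diff = NA_real_, se = NA_real_)
}

#' Reconstruct basic-parameter effects and covariance from a league table
#'
#' A league table reports every pairwise contrast \eqn{\hat\mu_i -
#' \hat\mu_j} with its standard error \eqn{s_{ij}}, but not the covariance
#' of the basic parameters (effects versus the reference) that simulation
#' needs. Writing \eqn{\sigma_{ii} = s_{iR}^2} for reference R, the
#' remaining covariances follow from
#' \eqn{s_{ij}^2 = \sigma_{ii} + \sigma_{jj} - 2\sigma_{ij}}, i.e.
#' \eqn{\sigma_{ij} = (\sigma_{ii} + \sigma_{jj} - s_{ij}^2)/2}.
#' The reconstructed matrix is validated positive semidefinite (league
#' tables transcribed from rounded publications may be slightly
#' inconsistent; tiny negative eigenvalues are clipped, larger ones are an
#' error reporting the smallest eigenvalue).
#'
#' The input pairwise standard errors are stored verbatim in the result's
#' `pairwise_se`, so analytic P-scores use the published values exactly.
#'
#' @param league a [league_table].
#' @param reference label of the reference treatment.
#' @param measure,direction,outcome_name passed to [outcome_effects()].
#' @return An [outcome_effects] object with a full covariance.
#' @export
covariance_from_league <- function(league, reference,
                                   measure = c("SMD", "logOR"),
                                   direction = c("higher_better", "lower_better"),
                                   outcome_name = league$outcome_name) {
  stopifnot(inherits(league, "league_table"))
  trt <- unique(c(reference,
                  league$rows$treatment_i, league$rows$treatment_j))
  if (!reference %in% trt)
    stop("reference treatment '", reference, "' not in the league table")
  trt <- c(reference, setdiff(sort(trt), reference))
  I <- length(trt)

  mu <- numeric(I)
  S <- matrix(0, I, I, dimnames = list(trt, trt))
  for (i in trt) for (j in trt) {
    if (i == j) next
    v <- .league_lookup(league, i, j)
    if (is.na(v["se"]))
      stop("league table is missing the pair ", i, " vs ", j)
    S[i, j] <- v["se"]
    if (j == reference) mu[match(i, trt)] <- v["diff"]
  }

  sigma <- matrix(0, I, I, dimnames = list(trt, trt))
  diag(sigma) <- S[, reference]^2
  for (a in 2:I) for (b in 2:I) {
    if (a == b) next
    sigma[a, b] <- (sigma[a, a] + sigma[b, b] - S[trt[a], trt[b]]^2) / 2
  }
  sigma <- .psd_clip(sigma)
  sigma[1, ] <- 0
  sigma[, 1] <- 0

  outcome_effects(treatments = trt, mu = mu, sigma = sigma,
                  reference = reference, measure = measure,
                  direction = direction, outcome_name = outcome_name,
                  pairwise_se = S)
}
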