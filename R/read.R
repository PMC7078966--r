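#' Read one outcome's NMA estimates from CSV
#'
#' Two schemas are accepted and detected from the header:
#' \itemize{
#'   \item basic-parameter form: columns `treatment,effect` (effects versus
#'     the reference) with a companion covariance CSV — a square matrix
#'     whose first column and header row carry the treatment labels;
#'   \item league-table form: columns `treatment_i,treatment_j,diff,se`,
#'     converted through [covariance_from_league()].
#' }
#' The config entry declares what the numbers mean: the effect measure
#' (`"logOR"` estimates are rescaled to the SMD scale at load, covariance
#' included), the outcome direction, and the reference treatment.
#' Orientation is applied once here (disable with `apply_orient = FALSE`
#' to inspect the published-scale object).
#'
#' @param path CSV file (basic effects or league table).
#' @param config_entry list with `name`, `measure` (`"SMD"`/`"logOR"`),
#'   `direction` (`"higher_better"`/`"lower_better"`), `reference`, and for
#'   basic form `covariance_file` (resolved relative to `path` when not
#'   absolute).
#' @param apply_orient orient the outcome after reading (default `TRUE`).
#' @return An [outcome_effects] object.
#' @export
read_outcome <- function(path, config_entry, apply_orient = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ce <- config_entry
  for (f in c("name", "measure", "direction", "reference"))
    if (is.null(ce[[f]])) stop("config entry is missing '", f, "'")
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))

  if (all(c("treatment_i", "treatment_j", "diff", "se") %in% hdr)) {
    lg <- league_table(utils::read.csv(path), outcome_name = ce$name)
    eff <- covariance_from_league(lg, reference = ce$reference,
                                  measure = ce$measure,
                                  direction = ce$direction,
                                  outcome_name = ce$name)
  } else if (all(c("treatment", "effect") %in% hdr)) {
    if (is.null(ce$covariance_file))
      stop("basic-parameter form needs a 'covariance_file' in the config")
    cov_path <- ce$covariance_file
    if (!file.exists(cov_path))
      cov_path <- file.path(dirname(path), ce$covariance_file)
    if (!file.exists(cov_path))
      stop("covariance file not found: ", ce$covariance_file)
    tab <- utils::read.csv(path)
    cv <- utils::read.csv(cov_path, row.names = 1, check.names = FALSE)
    cv <- as.matrix(cv)
    if (!setequal(rownames(cv), tab$treatment) ||
        !setequal(colnames(cv), tab$treatment))
      stop("covariance labels do not match the effects table")
    cv <- cv[tab$treatment, tab$treatment]
    eff <- outcome_effects(tab$treatment, tab$effect, cv,
                           reference = ce$reference, measure = ce$measure,
                           direction = ce$direction, outcome_name = ce$name)
  } else {
    stop("unrecognized CSV schema in ", path,
         " (need treatment,effect or treatment_i,treatment_j,diff,se)")
  }

  if (eff$measure == "logOR") {
    f <- sqrt(3) / pi
    eff$mu <- f * eff$mu
    if (!is.null(eff$sigma)) eff$sigma <- f^2 * eff$sigma
    eff$pairwise_se <- f * eff$pairwise_se
  }
  if (apply_orient) eff <- orient(eff)
  eff
}

#' Read a run configuration
#'
#' JSON file declaring the outcomes (file, measure, direction, reference),
#' an optional `correlation` block (`"zero"` or
#' `{outcome_names, matrix}`), optional per-outcome `civ_grids`
#' (`{from, to, by}` or explicit `values`), an optional `benefit_risk`
#' block, `n_samples`, `seed` and `output_dir`.
#'
#' @param path JSON file path.
#' @return The configuration as a list, with `base_dir` recording the
#'   config's directory so relative file references resolve against it.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$outcomes) || !length(cfg$outcomes))
    stop("config declares no outcomes")
  nm <- vapply(cfg$outcomes, function(o) o$name %||% "", "")
  if (any(nm == "")) stop("every outcome needs a name")
  if (anyDuplicated(nm)) stop("outcome names must be unique")
  cfg$base_dir <- dirname(normalizePath(path))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
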