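#' Run the full ranking workflow from a configuration
#'
#' Orchestrates the load -> orient -> rank -> CIV-curve -> benefit-risk
#' workflow and writes CSV artifacts plus a `run.json` manifest (config
#' echo, seed, package version) from which every artifact is regenerable.
#' CSVs, not figures, are the contract; plots can be rebuilt from them.
#'
#' Artifacts per command:
#' \describe{
#'   \item{`pscore`}{`pscores_<outcome>.csv`: treatment, pscore, percent,
#'     rank, tied, plus the oriented direction.}
#'   \item{`rankogram`}{`rankogram_<outcome>.csv` (long format treatment,
#'     rank, probability) and `sucra_<outcome>.csv`.}
#'   \item{`civ-curve`}{`civ_curves_<outcome>.csv` (long format treatment,
#'     civ, pscore) and `crossings_<outcome>.csv`.}
#'   \item{`multi`}{`multi_pscores.csv` over all configured outcomes.}
#'   \item{`benefit-risk`}{`benefit_risk_curves.csv` (with a `benefit_civ`
#'     column) and `benefit_risk_crossings.csv`.}
#'   \item{`simulate`}{a synthetic network written as
#'     `synthetic_network.json` via [generate_network()].}
#' }
#'
#' @param config path to a JSON run config, or the list from
#'   [read_run_config()].
#' @param commands subset of `c("pscore", "rankogram", "civ-curve",
#'   "multi", "benefit-risk", "simulate")`.
#' @param output_dir overrides the config's `output_dir`.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config,
                         commands = c("pscore"),
                         output_dir = NULL) {
  allowed <- c("pscore", "rankogram", "civ-curve", "multi",
               "benefit-risk", "simulate")
  bad <- setdiff(commands, allowed)
  if (length(bad)) stop("unknown command(s): ", paste(bad, collapse = ", "))
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- output_dir %||% config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 42L)
  n_samples <- as.integer(config$n_samples %||% 1e5)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", label, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% commands) {
    stage("simulate", {
      sm <- config$simulate %||% list()
      net <- generate_network(I = as.integer(sm$I %||% 16L),
                              K = as.integer(sm$K %||% 1L),
                              effect_spread = sm$effect_spread %||% 0.6,
                              precision_range =
                                unlist(sm$precision_range %||% c(0.05, 0.3)),
                              seed = as.integer(sm$seed %||% seed),
                              directions =
                                unlist(sm$directions %||% "higher_better"))
      p <- file.path(out_dir, "synthetic_network.json")
      write_network_json(net, p)
      written <<- c(written, p)
    })
  }

  analysis <- setdiff(commands, "simulate")
  if (length(analysis)) {
    outs <- stage("load", lapply(config$outcomes, function(ce) {
      path <- ce$file
      if (!file.exists(path) && !is.null(config$base_dir))
        path <- file.path(config$base_dir, ce$file)
      read_outcome(path, ce)
    }))
    names(outs) <- vapply(outs, `[[`, "", "outcome_name")
    rho <- stage("correlation", .config_correlation(config, names(outs)))

    if ("pscore" %in% commands) stage("pscore", {
      for (o in outs) {
        df <- summary(pscores(o))
        df$direction <- o$direction
        emit(df, paste0("pscores_", .slug(o$outcome_name), ".csv"))
      }
    })

    if ("rankogram" %in% commands) stage("rankogram", {
      for (o in outs) {
        rd <- simulate_ranks(o, n_samples = n_samples, seed = seed)
        long <- data.frame(
          treatment = rep(rd$treatments, times = ncol(rd$P)),
          rank = rep(seq_len(ncol(rd$P)), each = length(rd$treatments)),
          probability = as.vector(rd$P))
        emit(long, paste0("rankogram_", .slug(o$outcome_name), ".csv"))
        su <- sucra(rd)
        emit(data.frame(treatment = names(su), sucra = as.numeric(su),
                        mean_rank = as.numeric(attr(su, "mean_rank")),
                        pbest = as.numeric(pbest(rd)),
                        direction = o$direction),
             paste0("sucra_", .slug(o$outcome_name), ".csv"))
      }
    })

    if ("civ-curve" %in% commands) stage("civ-curve", {
      for (o in outs) {
        grid <- .config_grid(config, o$outcome_name)
        cc <- civ_curve(o, grid)
        df <- as.data.frame(cc)
        df$direction <- o$direction
        emit(df, paste0("civ_curves_", .slug(o$outcome_name), ".csv"))
        emit(cc$crossings,
             paste0("crossings_", .slug(o$outcome_name), ".csv"))
      }
    })

    if ("multi" %in% commands) stage("multi", {
      if (length(outs) < 2)
        stop("the 'multi' command needs at least two outcomes")
      je <- joint_effects(outs, rho)
      df <- summary(multi_pscores(je))
      df$outcomes <- paste(names(outs), collapse = "+")
      emit(df, "multi_pscores.csv")
    })

    if ("benefit-risk" %in% commands) stage("benefit-risk", {
      br <- config$benefit_risk
      if (is.null(br))
        stop("the 'benefit-risk' command needs a benefit_risk config block")
      je <- joint_effects(outs, rho)
      grid <- .config_grid(config, br$risk,
                           default = civ_spec(br$risk, from = -1, to = 0,
                                              by = 0.05))
      cc <- benefit_risk_curves(je, br$benefit, br$risk,
                                benefit_civ = br$benefit_civ %||% 0,
                                risk_grid = grid)
      df <- as.data.frame(cc)
      df$benefit_civ <- cc$benefit$civ
      emit(df, "benefit_risk_curves.csv")
      emit(cc$crossings, "benefit_risk_crossings.csv")
    })
  }

  manifest <- list(tool = "civrank",
                   version = as.character(utils::packageVersion("civrank")),
                   seed = seed, n_samples = n_samples,
                   commands = commands,
                   config = config[setdiff(names(config), "base_dir")])
  mp <- file.path(out_dir, "run.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, mp)
  invisible(written)
}

.slug <- function(x) gsub("[^A-Za-z0-9_-]", "_", x)

.config_correlation <- function(config, outcome_names) {
  cr <- config$correlation
  if (is.null(cr) || identical(cr, "zero"))
    return(correlation_spec(outcome_names, diag(length(outcome_names))))
  nms <- unlist(cr$outcome_names)
  mat <- do.call(rbind, lapply(cr$matrix, unlist))
  sp <- correlation_spec(nms, mat)
  if (!setequal(nms, outcome_names))
    stop("correlation block names outcomes not in the config")
  sp
}

.config_grid <- function(config, outcome_name, default = NULL) {
  for (g in config$civ_grids %||% list()) {
    if (identical(g$outcome, outcome_name)) {
      if (!is.null(g$values))
        return(civ_spec(outcome_name, grid = unlist(g$values)))
      return(civ_spec(outcome_name, from = g$from %||% 0,
                      to = g$to %||% 0.5, by = g$by %||% 0.05))
    }
  }
  default %||% civ_spec(outcome_name, from = 0, to = 0.5, by = 0.05)
}
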