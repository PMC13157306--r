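#' Build a validated pipeline configuration
#'
#' Collects every knob of the analysis chain with the defaults used
#' throughout: m = 5 imputations with 10 chained iterations, LASSO
#' (`alpha = 1`) with 10-fold CV, display threshold 0.05, and bootstrap
#' defaults of 1000 replicates. Either `input` (a wide panel CSV path) or
#' `preset` (a [synthetic_preset()] name) must identify the data source.
#'
#' @param input Optional path to a wide two-wave panel CSV.
#' @param preset Optional synthetic preset name (`"desk"`,
#'   `"charls_like"`); used when `input` is `NULL`.
#' @param n Optional synthetic sample-size override.
#' @param m,iterations Imputation settings.
#' @param alpha,k,display_threshold Estimation settings.
#' @param stability Run the bootstrap stability stage? (default `FALSE`;
#'   it dominates runtime)
#' @param B_case,B_edge Bootstrap replicates when `stability` is `TRUE`.
#' @param drop_mcar_covariates Covariate columns subjected to listwise
#'   deletion before imputation (default `"education"`, treated as MCAR).
#' @param seed Master seed; every stochastic stage derives a substream.
#' @param outdir Output directory.
#' @return A validated list of class `clpn_config`.
#' @export
clpn_config <- function(input = NULL, preset = "desk", n = NULL,
                        m = 5, iterations = 10, alpha = 1, k = 10,
                        display_threshold = 0.05, stability = FALSE,
                        B_case = 1000, B_edge = 1000,
                        drop_mcar_covariates = "education",
                        seed = 1, outdir = "clpn_run") {
  assert_scalar_num(m, "m", 1, 100)
  assert_scalar_num(iterations, "iterations", 1, 100)
  assert_scalar_num(alpha, "alpha", 0, 1)
  assert_scalar_num(k, "k", 2, 100)
  assert_scalar_num(display_threshold, "display_threshold", 0, 1)
  assert_scalar_num(seed, "seed", 0, 2^31 - 1)
  if (is.null(input) && is.null(preset))
    stop("config needs either `input` or `preset`")
  structure(list(input = input, preset = preset, n = n, m = m,
                 iterations = iterations, alpha = alpha, k = k,
                 display_threshold = display_threshold,
                 stability = isTRUE(stability),
                 B_case = B_case, B_edge = B_edge,
                 drop_mcar_covariates = drop_mcar_covariates,
                 seed = as.integer(seed), outdir = outdir),
            class = "clpn_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`); keys mirror
#'   [clpn_config()] arguments.
#' @return A `clpn_config`.
#' @export
read_clpn_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; restore it
  names(vals)[names(vals) == "FALSE"] <- "n"
  do.call(clpn_config, vals)
}

#' Run the full cross-lagged network pipeline
#'
#' Chain: read or simulate -> validate -> missingness report -> listwise
#' deletion on MCAR covariates -> chained-equation imputation (m datasets)
#' -> per-imputation network estimation -> element-wise pooling -> display
#' filter -> centralities -> optional bootstrap stability. All artifacts
#' (adjacency, display adjacency, GraphML, centrality and missingness CSVs,
#' stability CSVs, and a JSON run manifest echoing the config and timings)
#' are written under `config$outdir`.
#'
#' @param config A [clpn_config()].
#' @return Invisibly, a list with `network` (pooled), `display`,
#'   `centrality`, `missingness`, `stability` (or `NULL`) and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "clpn_config"))
  t_start <- Sys.time()
  log_lines <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage: %s] %s", name, conditionMessage(e)),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf(
      "%s: %.2fs", name, as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  panel <- stage("input", {
    if (!is.null(config$input)) read_panel_csv(config$input)
    else synthetic_preset(config$preset, seed = config$seed,
                          n = config$n)$panel
  })
  log_lines <- c(log_lines, sprintf("participants in: %d",
                                    n_participants(panel)))

  mrep <- stage("missingness-report", missingness_report(panel))
  paths$missingness <- file.path(config$outdir, "missingness.csv")
  write_missingness_csv(mrep, paths$missingness,
                        file.path(config$outdir, "missingness_cor.csv"))

  panel <- stage("listwise-mcar-covariates",
                 drop_missing_covariates(panel, config$drop_mcar_covariates))
  log_lines <- c(log_lines, sprintf("participants after deletion: %d",
                                    n_participants(panel)))

  imps <- stage("imputation", {
    if (panel_complete(panel)) {
      structure(list(datasets = replicate(config$m, panel,
                                          simplify = FALSE),
                     m = config$m, iterations = config$iterations,
                     seed = config$seed),
                class = "clpn_imputation_set")
    } else impute_chained(panel, m = config$m,
                          iterations = config$iterations,
                          seed = seed_stream(config$seed, "imputation"))
  })

  nets <- stage("estimation", lapply(seq_len(imps$m), function(i)
    estimate_clpn(imps$datasets[[i]], alpha = config$alpha, k = config$k,
                  seed = seed_stream(config$seed, paste0("net-imp-", i)))))
  pooled <- stage("pooling", pool_networks(nets))
  disp <- stage("display-filter",
                filter_display(pooled, config$display_threshold))
  cent <- stage("centrality", centrality_table(pooled))

  paths$adjacency <- file.path(config$outdir, "adjacency.csv")
  write_network_csv(pooled, paths$adjacency)
  paths$adjacency_display <- file.path(config$outdir,
                                       "adjacency_display.csv")
  write_network_csv(disp, paths$adjacency_display)
  paths$graphml <- file.path(config$outdir, "network.graphml")
  write_network_graphml(pooled, paths$graphml, config$display_threshold)
  paths$centrality <- file.path(config$outdir, "centrality.csv")
  write_centrality_csv(cent, paths$centrality)

  stab <- NULL
  if (config$stability) {
    ref_data <- imps$datasets[[1]]
    est <- clpn_estimator(alpha = config$alpha, k = config$k,
                          seed = seed_stream(config$seed, "boot-estimator"))
    stab <- stage("stability",
                  stability_report(ref_data, est, B_case = config$B_case,
                                   B_edge = config$B_edge,
                                   seed = seed_stream(config$seed,
                                                      "stability")))
    paths$stability <- file.path(config$outdir, "stability")
    write_stability_csv(stab, paths$stability)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("clpnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    lambda_per_imputation = pooled$lambda_per_imp,
    log = log_lines,
    elapsed_s = as.numeric(Sys.time() - t_start, units = "secs"))
  paths$manifest <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(network = pooled, display = disp, centrality = cent,
                 missingness = mrep, stability = stab, paths = paths))
}
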