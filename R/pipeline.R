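#' Run configuration for the end-to-end analysis
#'
#' Exactly one of `synthetic`/`input` must be supplied: either a
#' [synthetic_config()] (the pipeline simulates its own data), or a named
#' list of file paths `list(exports=, imports=, covariates=, centroids=,
#' agreements=)` pointing at the CSV dialects written by this package.
#'
#' @param synthetic optional [synthetic_config()].
#' @param input optional named list of input CSV paths.
#' @param fit named list of fit settings passed to [gibbs_fit()]
#'   (`iterations`, `burn_in`, `thin`).
#' @param cluster_method partition method per year, see [cluster_years()].
#' @param robustness_coefficients coefficients to run the replacement
#'   analysis on (default `"agreement"` in the first and last year).
#' @param top_k how many top sender/receiver countries to rank.
#' @param seed integer master seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(synthetic = NULL, input = NULL,
                       fit = list(iterations = 2000L, burn_in = 500L,
                                  thin = 5L),
                       cluster_method = "greedy",
                       robustness_coefficients = "agreement",
                       top_k = 5L, seed = 1L) {
  if (is.null(synthetic) == is.null(input)) {
    stop("exactly one of synthetic config or input paths must be given")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  structure(list(synthetic = synthetic, input = input, fit = fit,
                 cluster_method = cluster_method,
                 robustness_coefficients = robustness_coefficients,
                 top_k = as.integer(top_k), seed = as.integer(seed)),
            class = "run_config")
}

load_input_data <- function(paths) {
  need <- c("exports", "covariates", "centroids", "agreements")
  if (!all(need %in% names(paths))) {
    stop("input paths must name: ", paste(need, collapse = ", "))
  }
  exports <- read_trade_matrix(paths$exports, "exporter_reported")
  imports <- if (!is.null(paths$imports)) {
    read_trade_matrix(paths$imports, "importer_reported")
  } else NULL
  merged <- merge_reported_flows(exports, imports)
  cov <- utils::read.csv(paths$covariates, stringsAsFactors = FALSE)
  cent <- utils::read.csv(paths$centroids, stringsAsFactors = FALSE)
  panel <- merge(cov, cent, by = "country")
  agr <- utils::read.csv(paths$agreements, stringsAsFactors = FALSE)
  names(agr)[names(agr) == "country_a"] <- "sender"
  names(agr)[names(agr) == "country_b"] <- "receiver"
  # symmetrize the agreement table to ordered dyads
  rev <- agr
  rev$sender <- agr$receiver
  rev$receiver <- agr$sender
  agr <- rbind(agr, rev)
  agr <- agr[!duplicated(paste(agr$sender, agr$receiver, agr$year)), ]
  countries <- sort(unique(panel$country))
  years <- sort(unique(panel$year))
  tensor <- build_trade_tensor(merged, countries, years)
  list(tensor = tensor, panel = panel, dyads = agr)
}

#' Run the yearly trade-network analysis end-to-end
#'
#' Orchestrates simulate/load, filtering, design assembly, the MCMC fit,
#' per-year community detection and the replacement-robustness analysis,
#' and collects the tables the analysis reports: per-year partitions with
#' major/minor cluster counts, the coefficient-trajectory table (mean, HPD
#' interval and significance per coefficient-year), the temporal-dependence
#' (Phi) summary table, top-k sender/receiver rankings, and robustness
#' results. Deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, each stage's tables are
#'   written (CSV/JSON) as soon as the stage completes.
#' @param verbose log stage progress to stderr.
#' @return A `report_bundle` list: `clusters`, `partitions`,
#'   `coefficients`, `phi`, `effects`, `top_senders`, `top_receivers`,
#'   `robustness`, `filter_report`, `draws`, `summary_obj`.
#' @export
run_yearly_analysis <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) {
    if (verbose) message(sprintf(paste0("[tradeflow] ", fmt), ...))
  }
  stage_write <- function(obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (is.data.frame(obj)) {
      utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    } else {
      jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  t0 <- Sys.time()
  if (!is.null(config$synthetic)) {
    say("stage simulate")
    sc <- config$synthetic
    sc$seed <- as.integer(derive_seed(config$seed, 1))
    dat <- simulate_dataset(sc)
    tensor <- dat$tensor
    panel <- dat$panel
    dyads <- dat$dyads
  } else {
    say("stage load")
    dat <- load_input_data(config$input)
    tensor <- dat$tensor
    panel <- dat$panel
    dyads <- dat$dyads
  }

  say("stage filter (%.1fs)", as.numeric(Sys.time() - t0, "secs"))
  filt <- tryCatch(filter_countries(tensor, panel),
                   error = function(e) stop("stage filter: ",
                                            conditionMessage(e)))
  tensor <- filt$tensor
  panel <- filt$panel
  stage_write(filt$report, "filter_report")

  say("stage design")
  design <- tryCatch(
    build_design_matrices(panel, dyads, tensor = tensor),
    error = function(e) stop("stage design: ", conditionMessage(e)))

  say("stage cluster")
  cl <- tryCatch(
    cluster_years(tensor, method = config$cluster_method),
    error = function(e) stop("stage cluster: ", conditionMessage(e)))
  stage_write(cl$summary, "clusters")
  partition_table <- do.call(rbind, lapply(cl$partitions, function(p) {
    data.frame(country = names(p$assignment), year = p$year,
               cluster = unname(p$assignment), method = p$method,
               stringsAsFactors = FALSE)
  }))
  stage_write(partition_table, "partitions")

  say("stage fit")
  fit_args <- c(list(design = design,
                     seed = as.integer(derive_seed(config$seed, 2))),
                config$fit)
  draws <- tryCatch(do.call(gibbs_fit, fit_args),
                    error = function(e) stop("stage fit: ",
                                             conditionMessage(e)))
  summ <- summarize_posterior(draws)
  stage_write(summ$coefficients, "coefficients")
  stage_write(summ$phi, "phi")
  stage_write(summ$effects, "effects")

  say("stage robustness")
  years <- design$years
  rb_years <- unique(c(years[1], years[length(years)]))
  n_cases <- nrow(design$dyads)
  dfree <- max(1, n_cases - length(design$columns))
  robustness <- list()
  for (cf in config$robustness_coefficients) {
    k <- match(cf, design$columns)
    if (is.na(k)) stop("stage robustness: unknown coefficient ", cf)
    for (yr in rb_years) {
      t <- match(yr, years)
      res <- rir_from_posterior(draws$beta[, k, t], df = dfree,
                                n_cases = n_cases)
      robustness[[paste(cf, yr, sep = "_")]] <- c(
        list(coefficient = cf, year = yr), unclass(res))
    }
  }
  stage_write(robustness, "robustness")

  rank_tab <- function(col, decreasing = TRUE) {
    ea <- summ$effects_avg
    ea[order(ea[[col]], decreasing = decreasing)[
      seq_len(min(config$top_k, nrow(ea)))], c("country", col)]
  }
  bundle <- list(clusters = cl$summary,
                 partitions = partition_table,
                 coefficients = summ$coefficients,
                 phi = summ$phi,
                 effects = summ$effects,
                 top_senders = rank_tab("sender"),
                 top_receivers = rank_tab("receiver"),
                 robustness = robustness,
                 filter_report = filt$report,
                 draws = draws,
                 summary_obj = summ)
  class(bundle) <- "report_bundle"
  say("done (%.1fs)", as.numeric(Sys.time() - t0, "secs"))
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n  years:",
      paste(range(x$clusters$year), collapse = "-"),
      "\n  clusters per year:",
      paste(x$clusters$n_clusters, collapse = ", "), "\n")
  print(x$phi, row.names = FALSE, digits = 3)
  invisible(x)
}
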