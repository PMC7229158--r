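# File formats and end-to-end orchestration.  Counts travel as long/tidy
# CSV (cell_id, condition, count); fits and manifests as JSON.

#' Read a per-cell count table
#'
#' Accepts CSV or TSV (sniffed from the header line) with at least the
#' columns `cell_id`, `condition` and `count`.  Counts must parse as
#' non-negative integers; offending rows are reported by number.
#'
#' @param path Path to the file.
#' @return A [count_dataset()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          stringsAsFactors = FALSE)
  need <- c("cell_id", "condition", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  raw <- df$count
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(num) | num < 0 | num != floor(num))
  if (length(bad) > 0)
    stop("invalid count at data row ", bad[1], ": '", raw[bad[1]],
         "' (counts must be non-negative integers)", call. = FALSE)
  count_dataset(df$cell_id, df$condition, as.integer(num),
                provenance = list(source = path))
}

#' Write a per-cell count table
#'
#' Canonical CSV: header `cell_id,condition,count`, comma separated, no
#' quoting, LF line endings — so [read_counts()] followed by
#' `write_counts()` reproduces the file byte for byte.
#'
#' @param data A [count_dataset()].
#' @param path Output path.
#' @param provenance_path Optional path for a JSON sidecar recording the
#'   dataset provenance (seed, generator, parameters).
#' @return `path`, invisibly.
#' @export
write_counts <- function(data, path, provenance_path = NULL) {
  stopifnot(is_count_dataset(data))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("cell_id,condition,count",
               paste(data$cell_id, data$condition, data$count, sep = ",")),
             con, sep = "\n")
  if (!is.null(provenance_path)) {
    prov <- provenance(data)
    if (is.null(prov)) prov <- list()
    jsonlite::write_json(prov, provenance_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

write_chain_csv <- function(chain, path) {
  df <- cbind(as.data.frame(chain$samples),
              log_posterior = chain$log_posteriors)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fit_to_list <- function(fit) {
  list(map = unclass(fit$map),
       intervals = apply(fit$intervals, 1, as.list),
       burst_frequency = fit$kinetics_map$burst_frequency,
       burst_size = fit$kinetics_map$burst_size,
       kinetics_intervals = apply(fit$kinetics_intervals, 1, as.list),
       n_cells_used = fit$n_cells_used,
       n_cells_filtered = fit$n_cells_filtered,
       diagnostics = list(
         acceptance_rate = fit$diagnostics$acceptance_rate,
         ess = as.list(fit$diagnostics$ess),
         split_rhat = as.list(fit$diagnostics$split_rhat),
         flags = fit$diagnostics$flags))
}

file_digest <- function(path) unname(tools::md5sum(path))

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> summarize -> fit -> predict with per-stage
#' seeds derived deterministically from the global seed.  Outputs are a
#' counts CSV, a per-condition summary CSV, one thinned-chain CSV and one
#' fit JSON per condition, theory-curve CSVs for both regimes, and a
#' manifest JSON recording seeds and md5 digests of every artifact.
#'
#' @param config A list (or path to a JSON file holding one) with elements:
#'   `seed` (global seed), `scenario` (list of condition specs as in
#'   [generate_scenario()]; alternatively `counts_file` pointing at an
#'   existing CSV), `max_count` (filter threshold, default 150), `n_boot`
#'   (bootstrap resamples, default 10000), `mcmc` (argument list for
#'   [mcmc_settings()]), `predict` (list with optional `K`, `nu`,
#'   `lambda`), `out_dir` (output directory).
#' @return The manifest, invisibly (a list; also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  stopifnot(is.list(config), !is.null(config$out_dir), !is.null(config$seed))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  max_count <- config$max_count %||% 150
  n_boot <- config$n_boot %||% 10000
  manifest <- list(package = "burstfit",
                   version = as.character(utils::packageVersion("burstfit")),
                   seed = config$seed, stages = list(), outputs = list())
  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(config$counts_file)) {
      data <- read_counts(config$counts_file)
    } else {
      spec <- lapply(config$scenario, function(s) {
        pars <- s$params
        if (!inherits(pars, c("zinb_params", "burst_model_params")) &&
            is.list(pars)) {
          pars <- if (all(c("omega", "r", "p") %in% names(pars)))
            zinb_params(pars$omega, pars$r, pars$p)
          else do.call(burst_model_params, pars)
        }
        list(condition = s$condition, params = pars, n_cells = s$n_cells)
      })
      data <- generate_scenario(spec, seed = derive_seed(config$seed, "simulate"))
    }
    counts_path <- file.path(out_dir, "counts.csv")
    write_counts(data, counts_path,
                 provenance_path = file.path(out_dir, "counts_provenance.json"))
    manifest$stages$simulate <- list(n_cells = nrow(data))
    manifest$outputs$counts <- file_digest(counts_path)

    stage <- "summarize"
    summ <- summarize_counts(data, max_count = max_count, n_boot = n_boot,
                             seed = derive_seed(config$seed, "summarize"))
    summary_path <- file.path(out_dir, "summary.csv")
    utils::write.csv(summ, summary_path, row.names = FALSE, quote = FALSE)
    manifest$stages$summarize <- list(conditions = summ$condition)
    manifest$outputs$summary <- file_digest(summary_path)

    stage <- "fit"
    mcmc_args <- config$mcmc %||% list()
    fits <- list()
    for (cond in unique(data$condition)) {
      mcmc_args$seed <- derive_seed(config$seed, paste0("fit:", cond))
      st <- do.call(mcmc_settings, mcmc_args)
      fit <- fit_condition(data[data$condition == cond, ], st,
                           max_count = max_count)
      chain_path <- file.path(out_dir, paste0("chain_", cond, ".csv"))
      write_chain_csv(fit$chain, chain_path)
      fit_path <- file.path(out_dir, paste0("fit_", cond, ".json"))
      jsonlite::write_json(fit_to_list(fit), fit_path, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      manifest$outputs[[paste0("chain_", cond)]] <- file_digest(chain_path)
      manifest$outputs[[paste0("fit_", cond)]] <- file_digest(fit_path)
      fits[[cond]] <- fit
      message(sprintf(
        "fit[%s]: acceptance %.1f%%, min ESS %.0f, burst size %.3g, frequency %.3g",
        cond, 100 * fit$diagnostics$acceptance_rate,
        min(fit$diagnostics$ess), fit$kinetics_map$burst_size,
        fit$kinetics_map$burst_frequency))
    }
    manifest$stages$fit <- list(conditions = names(fits))

    stage <- "predict"
    pr <- config$predict %||% list()
    K <- pr$K %||% 1000
    for (regime in c("frequency_regulated", "size_regulated")) {
      sc <- make_scaling_curves(regime, K = K,
                                nu = pr$nu %||% (K / 11.3),
                                lambda = pr$lambda %||% 1.89)
      curve_path <- file.path(out_dir, paste0("curve_", regime, ".csv"))
      utils::write.csv(as.data.frame(sc), curve_path, row.names = FALSE,
                       quote = FALSE)
      manifest$outputs[[paste0("curve_", regime)]] <- file_digest(curve_path)
    }
    manifest$stages$predict <- list(K = K)
    list(data = data, summary = summ, fits = fits)
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$config <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(manifest, res[c("summary", "fits")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
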