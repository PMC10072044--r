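#' Write run artifacts
#'
#' Writes two files into `out_dir`: `selected_features.tsv` (feature id,
#' Welch t, p-value, fold change, rank) and `run_report.json` (config echo,
#' metrics, per-generation fitness trace, best mask and feature ids).
#' Numbers are serialized at full double precision, so
#' [read_run_report()] reproduces the report fields exactly.
#'
#' @param report a `RunReport` with `biomarker_stats` filled in (see
#'   [run_efbdba()]).
#' @param out_dir output directory (created if absent).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  tsv_path <- file.path(out_dir, "selected_features.tsv")
  json_path <- file.path(out_dir, "run_report.json")
  stats_df <- report$biomarker_stats
  if (is.null(stats_df)) {
    stats_df <- data.frame(feature_id = report$best_feature_ids,
                           t = NA_real_, p_value = NA_real_, FC = NA_real_,
                           rank = seq_along(report$best_feature_ids),
                           stringsAsFactors = FALSE)
  }
  utils::write.table(stats_df, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  payload <- list(
    config = unclass(report$config),
    best_mask = as.integer(report$best_mask),
    best_feature_ids = as.character(report$best_feature_ids),
    best_acc = report$best_acc,
    best_num = report$best_num,
    per_generation_best_fitness = report$per_generation_best_fitness,
    best_acc_trace = report$best_acc_trace,
    pool_ids = as.character(report$pool_ids),
    metrics = as.list(report$metrics)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(tsv = tsv_path, json = json_path))
}

#' Read a run report back from JSON
#'
#' @param json_path path to a `run_report.json` written by [write_report()].
#' @return A `RunReport` (without biomarker stats; those live in the TSV).
#' @export
read_run_report <- function(json_path) {
  payload <- jsonlite::fromJSON(json_path, simplifyVector = TRUE)
  cfg <- payload$config
  cfg$G <- as.integer(cfg$G); cfg$NP <- as.integer(cfg$NP)
  structure(
    list(best_mask = as.integer(payload$best_mask),
         best_feature_ids = as.character(payload$best_feature_ids),
         best_acc = payload$best_acc,
         best_num = as.integer(payload$best_num),
         per_generation_best_fitness = as.numeric(payload$per_generation_best_fitness),
         best_acc_trace = as.numeric(payload$best_acc_trace),
         pool_ids = as.character(payload$pool_ids),
         metrics = unlist(payload$metrics),
         biomarker_stats = NULL,
         config = structure(cfg, class = "bdba_config")),
    class = "RunReport"
  )
}
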