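#' Load the transcribed reference results table
#'
#' A 210-row fixture transcribing the published per-miRNA results of the
#' motivating EV miRNA cohort (miRNA id, logFC, p, BH-adjusted p, AUC with
#' 95\% CI bounds, accuracy, sensitivity, specificity), used by the test
#' suite and the acceptance report as the printed-value reference.
#'
#' @param path Fixture path (defaults to the copy shipped with the package).
#' @return Data frame with 210 rows and 10 columns.
#' @export
load_table2_fixture <- function(path = system.file("extdata",
                                                   "table2_fixture.tsv",
                                                   package = "mirpanel")) {
  if (!nzchar(path) || !file.exists(path)) stop_("fixture not found")
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  num <- setdiff(names(d), "mirna_id")
  d[num] <- lapply(d[num], as.numeric)
  d
}

#' Assemble the per-marker results table
#'
#' Inner-joins differential-expression results with predictor statistics on
#' probe id, restricted to dysregulated probes, and sorts by `auc_mean`
#' descending with ties broken by adjusted p ascending and then probe id, so
#' the ordering is total and deterministic.
#'
#' @param de Differential-expression results (from \code{\link{run_de}} or
#'   equivalent) with columns `probe_id`, `logFC`, `p_value`, `adj_p_value`
#'   and logical `dysregulated` (when absent, all rows are taken).
#' @param stats Predictor statistics with `probe_id` and the columns of
#'   \code{\link{repeat_evaluation}}.
#' @return Data frame of class `results_table`, one row per dysregulated
#'   probe.
#' @export
assemble_results_table <- function(de, stats) {
  rows <- if ("dysregulated" %in% names(de)) de[de$dysregulated, , drop = FALSE] else de
  missing_ids <- setdiff(rows$probe_id, stats$probe_id)
  if (length(missing_ids)) {
    stop_("missing predictor stats for: ", paste(missing_ids, collapse = ", "))
  }
  out <- merge(rows, stats, by = "probe_id", sort = FALSE)
  out <- out[order(-out$auc_mean, out$adj_p_value, out$probe_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("results_table", "data.frame")
  out
}

#' Headline summary counts of a results table
#'
#' Computes the counts the analysis reports in prose: the number of
#' dysregulated probes, the up/down partition, how many exceed `auc_cut`
#' (strict), and two top-`top_k` extrema: the largest |logFC| among
#' downregulated top-k rows and the |logFC| of the k-th (lowest-AUC) row.
#'
#' @param tab Results table with columns `logFC`, `adj_p_value` and an AUC
#'   column (`auc_mean` or `auc`).
#' @param auc_cut AUC threshold (default 0.95, strict `>`).
#' @param top_k Number of top rows for the extrema (default 10).
#' @return List of class `summary_counts`: `n_dysregulated`, `n_down`,
#'   `n_up`, `n_auc_above`, `max_abs_down_logfc_topk`,
#'   `logfc_of_lowest_auc_topk`.
#' @export
table_summary_counts <- function(tab, auc_cut = 0.95, top_k = 10) {
  auc <- tab[["auc_mean"]] %||% tab[["auc"]]
  if (is.null(auc)) stop_("results table lacks an AUC column")
  if (top_k > nrow(tab)) stop_("top_k exceeds table size")
  ord <- order(-auc, tab$adj_p_value, as.character(tab[[1]]))
  top <- tab[ord[seq_len(top_k)], , drop = FALSE]
  down_top <- top$logFC[top$logFC < 0]
  structure(list(
    n_dysregulated = nrow(tab),
    n_down = sum(tab$logFC < 0),
    n_up = sum(tab$logFC > 0),
    n_auc_above = sum(auc > auc_cut),
    max_abs_down_logfc_topk = if (length(down_top)) max(abs(down_top)) else NA_real_,
    logfc_of_lowest_auc_topk = abs(top$logFC[top_k])
  ), class = "summary_counts")
}

#' @export
print.summary_counts <- function(x, ...) {
  cat(sprintf(paste0(
    "dysregulated: %d (%d down / %d up)\n",
    "AUC above cut: %d\n",
    "top-k |logFC| extrema: largest down %.2f, lowest-AUC member %.2f\n"),
    x$n_dysregulated, x$n_down, x$n_up, x$n_auc_above,
    x$max_abs_down_logfc_topk, x$logfc_of_lowest_auc_topk))
  invisible(x)
}

#' Write / read a results table at full precision
#'
#' @param tab Results table.
#' @param path File path.
#' @param display Also mirror the published display dialect (2 decimals for
#'   logFC, scientific p-values, 3 decimals for metrics) instead of full
#'   precision.
#' @return `read_results_table` returns the table (full-precision dialect
#'   round-trips losslessly at >= 10 significant digits).
#' @export
write_results_table <- function(tab, path, display = FALSE) {
  out <- as.data.frame(tab)
  if (display) {
    fmt_p <- function(p) toupper(sprintf("%.2e", p))
    out$logFC <- sprintf("%.2f", out$logFC)
    for (cl in intersect(c("p_value", "adj_p_value"), names(out))) {
      out[[cl]] <- fmt_p(out[[cl]])
    }
    met <- intersect(c("auc_mean", "auc_ci_lower", "auc_ci_upper",
                       "accuracy_mean", "sensitivity_mean",
                       "specificity_mean"), names(out))
    for (cl in met) out[[cl]] <- sprintf("%.3f", out[[cl]])
  } else {
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the full synthetic-panel pipeline
#'
#' Chains simulation, preprocessing, differential expression and predictor
#' evaluation under one master seed, returning every intermediate product.
#' This is the programmatic equivalent of the `run-all` command line.
#'
#' @param config A \code{\link{sim_config}}.
#' @param seed Master seed (overrides `config$seed`).
#' @param alpha,lfc_threshold Dysregulation thresholds.
#' @param n_repetitions Split repetitions for predictor evaluation.
#' @param max_predictors Cap on the number of dysregulated probes scored
#'   (most significant first; `Inf` scores all). Keeps synthetic end-to-end
#'   runs bounded.
#' @return List with `sim`, `pre`, `de`, `stats`, `results`, `summary`.
#' @export
run_pipeline <- function(config = sim_config(), seed = NULL,
                         alpha = 0.05, lfc_threshold = 1,
                         n_repetitions = 500, max_predictors = Inf) {
  seed <- seed %||% config$seed
  sim <- simulate_panel(config, seed = seed)
  pre <- preprocess_panel(sim$ct, sim$annotation)
  de <- run_de(pre$expr, pre$annotation, alpha, lfc_threshold)
  hits <- de[de$dysregulated, , drop = FALSE]
  hits <- hits[order(hits$adj_p_value), , drop = FALSE]
  ids <- utils::head(hits$probe_id, max_predictors)
  scheme <- split_scheme(n_repetitions = n_repetitions,
                         seed = derive_seed(seed, "splits"))
  stats_tab <- if (length(ids)) {
    evaluate_predictors(pre$expr, pre$annotation, ids, scheme)
  } else {
    data.frame()
  }
  results <- if (length(ids)) {
    assemble_results_table(de[de$probe_id %in% ids, , drop = FALSE], stats_tab)
  } else {
    data.frame()
  }
  summary <- if (nrow(results) >= 10) table_summary_counts(results) else NULL
  list(sim = sim, pre = pre, de = de, stats = stats_tab,
       results = results, summary = summary)
}
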