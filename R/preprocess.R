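#' Remove probes undetected in every sample
#'
#' Drops probes whose Ct equals the non-detection code (40) in all samples;
#' probe order is otherwise preserved.
#'
#' @param m Ct matrix (probes x samples).
#' @param ceiling Non-detection code (default 40).
#' @return Filtered Ct matrix with attribute `removed_probes`.
#' @export
filter_probes_all_undetected <- function(m, ceiling = 40) {
  validate_ct_matrix(m, ceiling)
  if (nrow(m) == 0) stop_("empty Ct matrix")
  keep <- rowSums(m < ceiling) > 0
  if (!any(keep)) stop_("all probes undetected in every sample; unusable run")
  out <- m[keep, , drop = FALSE]
  attr(out, "removed_probes") <- rownames(m)[!keep]
  out
}

#' Remove samples with excessive non-detection
#'
#' Removes samples in which the fraction of probes at or above the
#' non-detection code strictly exceeds `max_undetected_fraction` (default
#' 0.8, i.e. "more than 80% of the probes undetected"). Sample order is
#' preserved and removed ids are messaged and attached as an attribute.
#'
#' @param m Ct matrix.
#' @param max_undetected_fraction Removal threshold in (0, 1].
#' @param annotation Optional annotation; when given, an error is raised if
#'   either group loses all its samples.
#' @param ceiling Non-detection code (default 40).
#' @return Filtered Ct matrix with attribute `removed_samples`.
#' @export
filter_samples_by_detection <- function(m, max_undetected_fraction = 0.8,
                                        annotation = NULL, ceiling = 40) {
  validate_ct_matrix(m, ceiling)
  if (max_undetected_fraction <= 0 || max_undetected_fraction > 1) {
    stop_("max_undetected_fraction must be in (0, 1]")
  }
  frac_undet <- colMeans(m >= ceiling)
  keep <- frac_undet <= max_undetected_fraction
  removed <- colnames(m)[!keep]
  if (length(removed)) {
    message("removing ", length(removed), " sample(s): ",
            paste(removed, collapse = ", "))
  }
  out <- m[, keep, drop = FALSE]
  if (!is.null(annotation)) {
    validate_annotation(annotation)
    left <- annotation$group[annotation$sample_id %in% colnames(out)]
    if (!all(c("case", "control") %in% left)) {
      stop_("a group lost all of its samples during detection filtering")
    }
  }
  attr(out, "removed_samples") <- removed
  out
}

#' Select endogenous-control (normalizer) probes
#'
#' Among probes with at most `max_undetected` values at the non-detection
#' code, returns the `k` probes with the smallest interquartile range of Ct
#' across all samples (IQR computed on all values, censored 40s included,
#' with the linear-interpolation quantile definition). Ties are broken by
#' probe id in lexicographic order, making the ranking deterministic.
#'
#' @param m Ct matrix.
#' @param max_undetected Maximum number of undetected samples tolerated per
#'   candidate (default 3).
#' @param k Number of normalizers to select (default 4).
#' @param ceiling Non-detection code (default 40).
#' @return Object of class `normalizer_set`: list with `probe_ids` (the k
#'   selected, in rank order), `iqr` and `n_undetected` (named, over all
#'   eligible probes).
#' @export
select_normalizer_probes <- function(m, max_undetected = 3, k = 4,
                                     ceiling = 40) {
  validate_ct_matrix(m, ceiling)
  n_undet <- rowSums(m >= ceiling)
  eligible <- n_undet <= max_undetected
  if (sum(eligible) < k) {
    stop_("only ", sum(eligible), " probes satisfy the undetected constraint; ",
          k, " required")
  }
  cand <- m[eligible, , drop = FALSE]
  iqr <- apply(cand, 1, stats::IQR, type = 7)
  ord <- order(iqr, rownames(cand), method = "radix")
  structure(list(
    probe_ids = rownames(cand)[ord][seq_len(k)],
    iqr = iqr[ord],
    n_undetected = n_undet[eligible][ord]
  ), class = "normalizer_set")
}

#' @export
print.normalizer_set <- function(x, ...) {
  cat("normalizer set (", length(x$probe_ids), " probes):\n", sep = "")
  for (p in x$probe_ids) {
    cat(sprintf("  %s  IQR = %.4g  undetected = %d\n",
                p, x$iqr[[p]], x$n_undetected[[p]]))
  }
  invisible(x)
}

#' Delta-Ct normalization against a normalizer set
#'
#' Per sample i, the reference is the mean Ct of the normalizer probes and
#' the relative expression of probe g is \code{x[g, i] = -(Ct[g, i] -
#' reference_i)}: higher x means more abundant, on a log2-like scale, so the
#' downstream logFC sign convention matches expression. Normalizer rows are
#' retained in the output, and by construction their per-sample mean of x is
#' zero; adding any constant to all Cts of a sample leaves x unchanged.
#'
#' @param m Ct matrix.
#' @param normalizers A `normalizer_set` or character vector of probe ids
#'   present in `m`.
#' @return Numeric expression matrix (same dimnames as `m`) with attribute
#'   `reference` holding the per-sample reference Ct.
#' @export
delta_normalize <- function(m, normalizers) {
  validate_ct_matrix(m, ceiling = Inf)
  ids <- if (inherits(normalizers, "normalizer_set")) {
    normalizers$probe_ids
  } else {
    as.character(normalizers)
  }
  if (!all(ids %in% rownames(m))) {
    stop_("normalizer probes missing from matrix: ",
          paste(setdiff(ids, rownames(m)), collapse = ", "))
  }
  reference <- colMeans(m[ids, , drop = FALSE])
  x <- -sweep(m, 2, reference, "-")
  attr(x, "reference") <- reference
  x
}

#' One-call preprocessing: filter, select normalizers, delta-normalize
#'
#' @param m Raw Ct matrix.
#' @param annotation Sample annotation (used to guard group survival).
#' @param max_undetected_fraction Sample filter threshold (default 0.8).
#' @param max_undetected Normalizer eligibility threshold (default 3).
#' @param k Number of normalizers (default 4).
#' @param ceiling Non-detection code (default 40).
#' @return List with `expr` (expression matrix), `ct` (filtered Ct matrix),
#'   `annotation` (restricted to retained samples), `normalizers`.
#' @export
preprocess_panel <- function(m, annotation, max_undetected_fraction = 0.8,
                             max_undetected = 3, k = 4, ceiling = 40) {
  validate_annotation(annotation, m)
  m <- filter_probes_all_undetected(m, ceiling)
  m <- filter_samples_by_detection(m, max_undetected_fraction, annotation,
                                   ceiling)
  normalizers <- select_normalizer_probes(m, max_undetected, k, ceiling)
  expr <- delta_normalize(m, normalizers)
  ann <- annotation[match(colnames(m), annotation$sample_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(expr = expr, ct = m, annotation = ann, normalizers = normalizers)
}
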