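#' Validate a Ct matrix
#'
#' A Ct matrix is a numeric matrix of cycle-threshold values with probes in
#' rows and samples in columns, rownames/colnames carrying unique probe and
#' sample identifiers, and every value in \code{[0, ceiling]} where the
#' ceiling (40 on this platform) encodes non-detection.
#'
#' @param m Numeric matrix, probes x samples.
#' @param ceiling Non-detection code (default 40).
#' @return `m`, invisibly, after validation.
#' @export
validate_ct_matrix <- function(m, ceiling = 40) {
  if (!is.matrix(m) || !is.numeric(m)) stop_("Ct matrix must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_("Ct matrix must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(m))) stop_("duplicate probe ids")
  if (anyDuplicated(colnames(m))) stop_("duplicate sample ids")
  if (anyNA(m)) stop_("Ct matrix contains NA")
  if (any(m < 0) || any(m > ceiling)) {
    stop_("Ct values must lie in [0, ", ceiling, "]")
  }
  invisible(m)
}

#' Validate a sample annotation table
#'
#' @param ann Data frame with columns `sample_id` and `group`; `group` must
#'   only contain "case" and "control".
#' @param m Optional Ct matrix the annotation must cover exactly.
#' @return `ann`, invisibly (with `group` as character).
#' @export
validate_annotation <- function(ann, m = NULL) {
  if (!is.data.frame(ann) || !all(c("sample_id", "group") %in% names(ann))) {
    stop_("annotation needs columns sample_id and group")
  }
  ann$group <- as.character(ann$group)
  if (!all(ann$group %in% c("case", "control"))) {
    stop_("group must be 'case' or 'control'")
  }
  if (anyDuplicated(ann$sample_id)) stop_("duplicate sample_id in annotation")
  if (!is.null(m)) {
    if (!setequal(colnames(m), ann$sample_id)) {
      stop_("annotation samples do not match matrix samples")
    }
  }
  invisible(ann)
}

#' Read / write Ct or expression matrices as TSV
#'
#' The on-disk layout is one header row of sample ids, a first column of
#' probe ids, and tab-separated numeric values (probes in rows).
#'
#' @param path File path.
#' @param m Matrix to write.
#' @return `read_ct_matrix` returns a numeric matrix with dimnames.
#' @export
read_ct_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  m
}

#' @rdname read_ct_matrix
#' @export
write_ct_matrix <- function(m, path) {
  d <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_ct_matrix
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

#' @param ann Annotation data frame to write.
#' @rdname read_ct_matrix
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
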