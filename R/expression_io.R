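#' Read an expression matrix from TSV
#'
#' Expression files are tab-separated with the first row holding sample
#' identifiers (after a leading `feature_id` column header) and the first
#' column holding feature identifiers; every remaining cell must parse as a
#' finite real number. Missing or non-numeric cells are rejected with their
#' coordinates: the mutual-information estimator downstream has no
#' missing-data contract, so imputation must happen upstream.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix, features in rows and samples in columns, with
#'   `rownames()`/`colnames()` set. Row and column order follow the file.
#' @seealso [write_expression()], [align_samples()]
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression file needs a header and at least one feature row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  n_col <- length(header)
  bad <- which(vapply(rows, length, integer(1)) != n_col)
  if (length(bad) > 0L) {
    stop(sprintf("line %d has %d fields, expected %d", bad[1L] + 1L,
                 length(rows[[bad[1L]]]), n_col))
  }
  feature_ids <- vapply(rows, `[[`, character(1), 1L)
  values <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1L]))
    bad_j <- which(is.na(v) | !is.finite(v))
    if (length(bad_j) > 0L) {
      stop(sprintf(
        "non-numeric or non-finite value at feature row %d ('%s'), sample column %d ('%s')",
        i, feature_ids[i], bad_j[1L], sample_ids[bad_j[1L]]))
    }
    values[i, ] <- v
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  validate_expression(values)
}

#' Write an expression matrix to TSV
#'
#' @param x Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  x <- validate_expression(x)
  header <- paste(c("feature_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the joint data model used throughout the package: unique feature and
#' sample identifiers and all-finite real values.
#'
#' @param x Numeric matrix with dimnames.
#' @return The validated matrix (invisibly identical to the input).
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must carry feature rownames and sample colnames")
  }
  dup_f <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_f) > 0L) {
    stop("duplicated feature ids: ", paste(dup_f, collapse = ", "))
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s) > 0L) {
    stop("duplicated sample ids: ", paste(dup_s, collapse = ", "))
  }
  if (any(!is.finite(x))) stop("expression matrix contains non-finite values")
  x
}

#' Construct a miRNA-to-mRNA target network
#'
#' A target network is the prior-knowledge edge set that seeds candidate
#' enumeration: each row records that a miRNA has a binding site (a microRNA
#' response element) on an mRNA. Duplicate edges are collapsed.
#'
#' @param edges Data frame whose first two columns are miRNA and mRNA
#'   identifiers.
#' @param source_tag Short label for the provenance of the edges (for example
#'   an experimentally-validated versus a sequence-predicted interaction set).
#' @return A tibble of class `target_network` with columns `mirna`, `mrna`.
#' @export
target_network <- function(edges, source_tag = "targets") {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  out <- tibble::tibble(mirna = as.character(edges[[1L]]),
                        mrna = as.character(edges[[2L]]))
  out <- dplyr::distinct(out)
  class(out) <- c("target_network", class(out))
  attr(out, "source_tag") <- source_tag
  out
}

#' Read a target network from a two-column TSV
#'
#' The file has columns miRNA id, mRNA id; a header line is recognised when
#' its first field is `mirna`/`mirna_id` (case-insensitive). Duplicate rows
#' are collapsed and the resulting edge count is reported.
#'
#' @inheritParams target_network
#' @param path Path to a TSV file.
#' @return A `target_network` tibble.
#' @export
read_targets <- function(path, source_tag = "targets") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty target file: returning a network with 0 edges")
    return(target_network(tibble::tibble(mirna = character(), mrna = character()),
                          source_tag))
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, integer(1)) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d has %d columns, expected 2", bad[1L],
                 length(rows[[bad[1L]]])))
  }
  first <- tolower(rows[[1L]][1L])
  if (first %in% c("mirna", "mirna_id", "mir", "mirbase_id")) rows <- rows[-1L]
  net <- target_network(
    tibble::tibble(mirna = vapply(rows, `[[`, character(1), 1L),
                   mrna = vapply(rows, `[[`, character(1), 2L)),
    source_tag)
  message(sprintf("read %d unique target edges from %s", nrow(net), path))
  net
}

#' Write a target network to TSV
#' @param net A `target_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(net, path) {
  writeLines(c("mirna_id\tmrna_id", paste(net$mirna, net$mrna, sep = "\t")), path)
  invisible(path)
}

#' Union of target networks
#'
#' Set-union of edge sets, mirroring the construction of an
#' experimentally-validated interaction set from multiple databases.
#'
#' @param ... `target_network` objects (or two-column data frames).
#' @param source_tag Label for the combined network.
#' @return A `target_network` tibble.
#' @export
targets_union <- function(..., source_tag = "union") {
  nets <- lapply(list(...), function(x) tibble::tibble(mirna = as.character(x[[1L]]),
                                                       mrna = as.character(x[[2L]])))
  target_network(dplyr::distinct(dplyr::bind_rows(nets)), source_tag)
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `class_label` and optionally
#' `time_to_event` and `event_flag` (both present or both absent). Class
#' labels must be `normal`, `primary` or `metastatic`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per sample.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
  validate_metadata(tibble::as_tibble(meta))
}

#' Write sample metadata to TSV
#' @param meta Metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(meta) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample ids in metadata")
  if ("class_label" %in% names(meta)) {
    bad <- setdiff(unique(meta$class_label), c("normal", "primary", "metastatic"))
    if (length(bad) > 0L) {
      stop("unknown class labels: ", paste(bad, collapse = ", "))
    }
  }
  has_time <- "time_to_event" %in% names(meta)
  has_event <- "event_flag" %in% names(meta)
  if (has_time != has_event) {
    stop("time_to_event and event_flag must be present together")
  }
  if (has_time) {
    if (any(!is.finite(meta$time_to_event)) || any(meta$time_to_event < 0)) {
      stop("time_to_event must be nonnegative and finite")
    }
    meta$event_flag <- as.logical(meta$event_flag)
    if (any(is.na(meta$event_flag))) stop("event_flag must be logical (0/1 or TRUE/FALSE)")
  }
  tibble::as_tibble(meta)
}

#' Align paired expression matrices (and metadata) on shared samples
#'
#' Restricts the miRNA matrix, the mRNA matrix and (optionally) the sample
#' metadata to their common sample identifiers, in a single canonical
#' (lexicographic) column order so that permutation seeds reproduce across
#' runs regardless of input file ordering. This is how a joint cohort is
#' formed from platform-specific profiles measured on overlapping samples.
#'
#' @param mir miRNA expression matrix (features x samples).
#' @param mrna mRNA expression matrix (features x samples).
#' @param meta Optional metadata tibble with a `sample_id` column.
#' @return A list with elements `mir`, `mrna` and (if given) `meta`, all
#'   restricted to the shared samples.
#' @export
align_samples <- function(mir, mrna, meta = NULL) {
  mir <- validate_expression(mir)
  mrna <- validate_expression(mrna)
  shared <- intersect(colnames(mir), colnames(mrna))
  if (!is.null(meta)) {
    meta <- validate_metadata(meta)
    shared <- intersect(shared, meta$sample_id)
  }
  if (length(shared) < 2L) stop("insufficient overlapping samples")
  shared <- sort(shared)
  message(sprintf(
    "aligned on %d shared samples (dropped %d miRNA, %d mRNA samples)",
    length(shared), ncol(mir) - length(shared), ncol(mrna) - length(shared)))
  out <- list(mir = mir[, shared, drop = FALSE],
              mrna = mrna[, shared, drop = FALSE])
  if (!is.null(meta)) {
    out$meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
  }
  out
}
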