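#' Marker presence/absence matrix with per-marker metadata
#'
#' The central data container: an integer matrix of dominant marker calls
#' (rows = markers, columns = progeny; 1 = present, 0 = absent, NA =
#' missing) plus a metadata data frame with one row per marker. The call
#' rate (fraction of non-missing calls) is always recomputed from the
#' matrix.
#'
#' @param calls Integer (or logical) matrix with rownames = marker ids and
#'   colnames = progeny ids; values in \{0, 1, NA\}.
#' @param meta Optional data frame with a `marker` column matching the
#'   rownames of `calls`; typical columns are `system` (DArT, AFLP, SSR,
#'   SNP, RFLP, RAPD), `enzyme` (PTB/PTH/PTP/none), `family` (multi-allelic
#'   locus family id) and `quality` (0-100). Missing metadata columns are
#'   filled with NA.
#' @return An object of class `marker_matrix`: list with elements `calls`
#'   and `meta` (the latter gains a `call_rate` column).
#' @export
marker_matrix <- function(calls, meta = NULL) {
  if (is.logical(calls)) {
    mode(calls) <- "integer"
  }
  if (!is.matrix(calls) || !is.numeric(calls)) {
    stop("`calls` must be a numeric matrix", call. = FALSE)
  }
  bad <- !is.na(calls) & !(calls %in% c(0L, 1L))
  if (any(bad)) {
    stop("`calls` must contain only 0, 1 or NA", call. = FALSE)
  }
  if (is.null(rownames(calls))) {
    dimnames(calls) <- list(sprintf("M%05d", seq_len(nrow(calls))),
                            colnames(calls))
  }
  if (anyDuplicated(rownames(calls))) {
    stop("marker ids (rownames of `calls`) must be unique", call. = FALSE)
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("P%03d", seq_len(ncol(calls)))
  }
  storage.mode(calls) <- "integer"

  ids <- rownames(calls)
  if (is.null(ids)) ids <- character(0)   # zero-row matrices lose dimnames
  if (is.null(meta)) {
    meta <- data.frame(marker = ids, stringsAsFactors = FALSE)
  }
  if (!"marker" %in% names(meta)) {
    stop("`meta` must contain a `marker` column", call. = FALSE)
  }
  if (!setequal(meta$marker, ids)) {
    stop("`meta$marker` must match the rownames of `calls`", call. = FALSE)
  }
  meta <- meta[match(ids, meta$marker), , drop = FALSE]
  for (col in c("system", "enzyme", "family")) {
    if (!col %in% names(meta)) meta[[col]] <- rep(NA_character_, nrow(meta))
  }
  if (!"quality" %in% names(meta)) meta$quality <- rep(NA_real_, nrow(meta))
  meta$call_rate <- rowMeans(!is.na(calls))
  rownames(meta) <- NULL

  structure(list(calls = calls, meta = meta), class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$calls), "markers x", ncol(x$calls),
      "progeny;", sprintf("%.1f%%", 100 * mean(is.na(x$calls))),
      "missing calls\n")
  sys <- table(x$meta$system, useNA = "ifany")
  if (length(sys)) {
    cat("  systems:", paste(names(sys), sys, sep = "=", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Subset a marker matrix by marker ids
#'
#' @param mm A [marker_matrix()].
#' @param markers Character vector of marker ids to keep.
#' @return A `marker_matrix` restricted to `markers`, in the given order.
#' @export
subset_markers <- function(mm, markers) {
  stopifnot(inherits(mm, "marker_matrix"))
  missing <- setdiff(markers, rownames(mm$calls))
  if (length(missing)) {
    stop("unknown markers: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  marker_matrix(mm$calls[markers, , drop = FALSE],
                mm$meta[match(markers, mm$meta$marker), , drop = FALSE])
}
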