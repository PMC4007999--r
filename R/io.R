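#' Read a genotype matrix (and metadata sidecar) from disk
#'
#' The genotype file is CSV with a `marker` id column followed by one
#' column per progeny, cells 1/0/NA. The optional metadata sidecar is TSV
#' with columns `marker`, `system`, `enzyme`, `family`, `quality`.
#' Malformed cells are reported with their line number.
#'
#' @param path Genotype CSV path.
#' @param meta_path Optional metadata TSV path.
#' @return A [marker_matrix()].
#' @export
read_genotypes <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("empty or malformed genotype file: ", path, call. = FALSE)
  }
  if (names(df)[1] != "marker") {
    stop("first column of ", path, " must be `marker`", call. = FALSE)
  }
  calls <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.na(calls) & !(calls %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid genotype call at line ", bad[1, 1] + 1L, ", column ",
         colnames(calls)[bad[1, 2]], " of ", path,
         " (expected 0, 1 or NA)", call. = FALSE)
  }
  storage.mode(calls) <- "integer"
  rownames(calls) <- df$marker
  meta <- if (!is.null(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  }
  marker_matrix(calls, meta)
}

#' Write a genotype matrix (and metadata sidecar) to disk
#'
#' @param mm A [marker_matrix()].
#' @param path Genotype CSV path.
#' @param meta_path Optional metadata TSV path.
#' @param truth Optional truth table (written as TSV next to the matrix,
#'   e.g. from [generate_population()]).
#' @param truth_path Path for the truth table when `truth` is given.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(mm, path, meta_path = NULL, truth = NULL,
                            truth_path = NULL) {
  stopifnot(inherits(mm, "marker_matrix"))
  df <- data.frame(marker = rownames(mm$calls), mm$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  if (!is.null(meta_path)) {
    utils::write.table(mm$meta, meta_path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
  }
  if (!is.null(truth)) {
    if (is.null(truth_path)) stop("`truth_path` required with `truth`",
                                  call. = FALSE)
    utils::write.table(truth, truth_path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "NA")
  }
  invisible(path)
}

#' Write a genetic map as TSV
#'
#' Columns: `lg`, `marker`, `position` (cM) and, when metadata is given,
#' `system`.
#'
#' @param map A `genetic_map` or map data frame.
#' @param path Output path.
#' @param meta Optional marker metadata to add the `system` column.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path, meta = NULL) {
  mapdf <- if (inherits(map, "genetic_map")) map$map else map
  if (!is.null(meta)) {
    mapdf$system <- meta$system[match(mapdf$marker, meta$marker)]
  }
  utils::write.table(mapdf, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a genetic map TSV
#'
#' Validates that positions are non-negative and non-decreasing within
#' each linkage group; violations are rejected with the offending line
#' number.
#'
#' @param path Map TSV path (columns `lg`, `marker`, `position`).
#' @return Map data frame.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lg", "marker", "position")
  if (!all(need %in% names(df))) {
    stop("map file must have columns lg, marker, position", call. = FALSE)
  }
  for (lg in unique(df$lg)) {
    idx <- which(df$lg == lg)
    pos <- df$position[idx]
    if (any(is.na(pos)) || any(pos < 0) || is.unsorted(pos)) {
      off <- idx[which(is.na(pos) | pos < 0 | c(FALSE, diff(pos) < 0))[1]]
      stop("non-monotone or invalid position in ", lg, " at line ",
           off + 1L, " of ", path, call. = FALSE)
    }
  }
  df
}

#' Write a JoinMap-style .loc file
#'
#' A minimal dialect of the JoinMap CP-population locus file: a header
#' with `name`, `popt = CP`, `nloc` and `nind`, then one record per marker
#' with segregation type `<lmxll>` (single-dose marker heterozygous in the
#' informative parent) and per-progeny codes `lm` (present), `ll`
#' (absent), `--` (missing). Write-only.
#'
#' @param mm A [marker_matrix()].
#' @param path Output path.
#' @param name Population name for the header.
#' @return Invisibly, `path`.
#' @export
write_loc <- function(mm, path, name = "population") {
  stopifnot(inherits(mm, "marker_matrix"))
  calls <- mm$calls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("name =", name),
               "popt = CP",
               paste("nloc =", nrow(calls)),
               paste("nind =", ncol(calls))), con)
  code <- matrix("--", nrow(calls), ncol(calls))
  code[!is.na(calls) & calls == 1L] <- "lm"
  code[!is.na(calls) & calls == 0L] <- "ll"
  for (i in seq_len(nrow(calls))) {
    writeLines(paste0(rownames(calls)[i], " <lmxll>"), con)
    genos <- code[i, ]
    for (start in seq(1, length(genos), by = 20)) {
      writeLines(paste(" ",
                       paste(genos[start:min(start + 19, length(genos))],
                             collapse = " ")), con)
    }
  }
  invisible(path)
}
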