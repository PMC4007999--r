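#' Invert a marker matrix (swap linkage phase)
#'
#' Swaps present and absent calls, preserving missing values, and suffixes
#' marker ids to mark the inverted phase. Two-point linkage between an
#' original marker and an inverted one is repulsion-phase linkage between
#' the originals; double inversion restores the matrix.
#'
#' @param mm A [marker_matrix()].
#' @param suffix Id suffix marking inverted markers.
#' @return A `marker_matrix` of the same shape with swapped calls.
#' @export
invert_matrix <- function(mm, suffix = "_r") {
  stopifnot(inherits(mm, "marker_matrix"))
  calls <- 1L - mm$calls
  rownames(calls) <- paste0(rownames(mm$calls), suffix)
  meta <- mm$meta
  meta$marker <- paste0(meta$marker, suffix)
  marker_matrix(calls, meta)
}

#' Detect repulsion-phase linkage between linkage groups
#'
#' Runs a two-point scan between every mapped marker and the phase-inverted
#' copy of every marker on a different linkage group. Marker pairs with a
#' repulsion LOD of at least `lod_min` are aggregated per LG pair; a link
#' is accepted when it has at least `min_pairs` supporting marker pairs and
#' the involved markers span at least a fraction `min_span` of each LG's
#' length, since artefactual repulsion tends to involve isolated marker
#' pairs rather than large parts of a linkage group. Accepted repulsion
#' between LGs is the mapping signature of preferential pairing between
#' the underlying homologues.
#'
#' @param mm The [marker_matrix()] used to build the map.
#' @param map A `genetic_map` from [two_stage_build()].
#' @param lod_min Minimum repulsion LOD for a supporting marker pair
#'   (inclusive).
#' @param min_pairs Minimum supporting marker pairs per LG pair.
#' @param min_span Minimum fraction of each LG's length spanned by the
#'   involved markers (LGs of zero length count as fully spanned).
#' @param min_informative Minimum shared progeny per marker pair.
#' @return Data frame of class `repulsion_links`: `lg1`, `lg2`,
#'   `best_lod`, `n_support`, `span1`, `span2`, `accepted`; the supporting
#'   marker pairs are attached as attribute `"pairs"`.
#' @export
detect_repulsion <- function(mm, map, lod_min = 5, min_pairs = 3,
                             min_span = 0.3, min_informative = 30) {
  stopifnot(inherits(mm, "marker_matrix"))
  mapdf <- if (inherits(map, "genetic_map")) map$map else map
  X <- mm$calls[mapdf$marker, , drop = FALSE]
  tp <- two_point_matrix(X, 1L - X, min_informative = min_informative)

  lg_of <- mapdf$lg
  pos_of <- stats::setNames(mapdf$position, mapdf$marker)
  lg_len <- vapply(split(mapdf$position, mapdf$lg), max, numeric(1))

  hit <- which(!is.na(tp$lod) & tp$lod >= lod_min, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]           # unordered pairs
  hit <- hit[lg_of[hit[, 1]] != lg_of[hit[, 2]], , drop = FALSE]

  empty <- data.frame(lg1 = character(0), lg2 = character(0),
                      best_lod = numeric(0), n_support = integer(0),
                      span1 = numeric(0), span2 = numeric(0),
                      accepted = logical(0))
  if (nrow(hit) == 0) {
    attr(empty, "pairs") <- data.frame(
      marker1 = character(0), marker2 = character(0), lg1 = character(0),
      lg2 = character(0), rf = numeric(0), lod = numeric(0))
    class(empty) <- c("repulsion_links", "data.frame")
    return(empty)
  }

  m1 <- mapdf$marker[hit[, 1]]
  m2 <- mapdf$marker[hit[, 2]]
  l1 <- lg_of[hit[, 1]]
  l2 <- lg_of[hit[, 2]]
  swap <- l1 > l2
  tmp <- m1[swap]; m1[swap] <- m2[swap]; m2[swap] <- tmp
  tmp <- l1[swap]; l1[swap] <- l2[swap]; l2[swap] <- tmp
  pairs <- data.frame(
    marker1 = m1, marker2 = m2, lg1 = l1, lg2 = l2,
    rf = tp$rf[hit], lod = tp$lod[hit], stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$lg1, pairs$lg2, -pairs$lod), ]

  links <- do.call(rbind, lapply(
    split(pairs, paste(pairs$lg1, pairs$lg2, sep = "\r")),
    function(d) {
      span_frac <- function(markers, lg) {
        len <- lg_len[[lg]]
        if (len <= 0) return(1)
        (max(pos_of[markers]) - min(pos_of[markers])) / len
      }
      s1 <- span_frac(d$marker1, d$lg1[1])
      s2 <- span_frac(d$marker2, d$lg2[1])
      data.frame(lg1 = d$lg1[1], lg2 = d$lg2[1],
                 best_lod = max(d$lod), n_support = nrow(d),
                 span1 = s1, span2 = s2,
                 accepted = nrow(d) >= min_pairs && s1 >= min_span &&
                   s2 >= min_span,
                 stringsAsFactors = FALSE)
    }))
  rownames(links) <- NULL
  attr(links, "pairs") <- pairs
  class(links) <- c("repulsion_links", "data.frame")
  links
}

#' Interval difference ratio between two homologous linkage groups
#'
#' Given the lengths of the k shared marker intervals on the reference
#' (most densely mapped) LG and on a compared LG of the same homology
#' group, the difference ratio is the sum of absolute interval length
#' differences normalised by the summed shared-interval length of both
#' LGs: sum_k |ref_k - cmp_k| / (sum_k ref_k + sum_k cmp_k). It is 0 when
#' all shared intervals have identical lengths and at most 1.
#'
#' @param ref_intervals,cmp_intervals Non-negative interval lengths (cM) of
#'   equal positive length.
#' @return List of class `difference_ratio`: `k`, `sum_abs_diff`,
#'   `sum_total`, `ratio`, and the two interval vectors.
#' @export
#' @examples
#' difference_ratio(12.1, 4.8)$ratio   # 7.3 / 16.9 = 0.43
difference_ratio <- function(ref_intervals, cmp_intervals) {
  if (length(ref_intervals) != length(cmp_intervals) ||
      length(ref_intervals) < 1) {
    stop("interval vectors must have equal positive length", call. = FALSE)
  }
  if (any(ref_intervals < 0) || any(cmp_intervals < 0)) {
    stop("interval lengths must be non-negative", call. = FALSE)
  }
  sum_abs <- sum(abs(ref_intervals - cmp_intervals))
  sum_total <- sum(ref_intervals) + sum(cmp_intervals)
  structure(
    list(k = length(ref_intervals), sum_abs_diff = sum_abs,
         sum_total = sum_total,
         ratio = if (sum_total > 0) sum_abs / sum_total else 0,
         ref_intervals = ref_intervals, cmp_intervals = cmp_intervals),
    class = "difference_ratio"
  )
}

#' @export
print.difference_ratio <- function(x, ...) {
  cat(sprintf(
    "difference ratio: k = %d, sum|diff| = %.1f cM, total = %.1f cM, ratio = %.1f\n",
    x$k, x$sum_abs_diff, x$sum_total, x$ratio))
  invisible(x)
}

#' Difference ratio between two mapped linkage groups
#'
#' Shared markers are alleles of the same locus family appearing on both
#' LGs (homologous LGs never share the same single-dose marker); intervals
#' are taken between consecutive shared markers in the reference order.
#' Intervals whose order is inverted on the compared LG are skipped with a
#' message; families with several alleles on one LG use the allele at the
#' smallest position.
#'
#' @param map A `genetic_map` or map data frame.
#' @param meta Marker metadata (`marker`, `family`).
#' @param ref_lg,cmp_lg LG names; `ref_lg` should be the denser LG.
#' @return A [difference_ratio()] object with `ref_lg`/`cmp_lg` fields, or
#'   NULL (with a message) when fewer than two shared families exist.
#' @export
lg_difference_ratio <- function(map, meta, ref_lg, cmp_lg) {
  mapdf <- if (inherits(map, "genetic_map")) map$map else map
  fam_of <- stats::setNames(meta$family, meta$marker)
  get_lg <- function(lg) {
    d <- mapdf[mapdf$lg == lg, , drop = FALSE]
    d$family <- fam_of[d$marker]
    d <- d[!is.na(d$family), , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    d[!duplicated(d$family), , drop = FALSE]   # first allele per family
  }
  a <- get_lg(ref_lg)
  b <- get_lg(cmp_lg)
  shared <- intersect(a$family, b$family)
  if (length(shared) < 2) {
    message("no shared marker interval between ", ref_lg, " and ", cmp_lg)
    return(NULL)
  }
  a <- a[a$family %in% shared, ]
  a <- a[order(a$position), ]
  pos_b <- stats::setNames(b$position, b$family)[a$family]

  # LG orientation is arbitrary: flip the compared LG when its shared
  # markers run predominantly opposite to the reference order
  flip <- if (length(shared) == 2) {
    pos_b[2] < pos_b[1]
  } else {
    stats::cor(a$position, pos_b, method = "spearman") < 0
  }
  if (isTRUE(flip)) pos_b <- -pos_b

  ref_int <- unname(diff(a$position))
  cmp_int <- unname(diff(pos_b))
  conflict <- cmp_int < 0
  if (any(conflict)) {
    message(sum(conflict), " shared interval(s) with conflicting order on ",
            cmp_lg, " skipped")
    ref_int <- ref_int[!conflict]
    cmp_int <- cmp_int[!conflict]
  }
  if (!length(ref_int)) {
    message("no usable shared interval between ", ref_lg, " and ", cmp_lg)
    return(NULL)
  }
  out <- difference_ratio(ref_int, cmp_int)
  out$ref_lg <- ref_lg
  out$cmp_lg <- cmp_lg
  out
}

#' Difference ratios of every LG against its homology group reference
#'
#' For each homology group the most marker-dense LG is the reference
#' (ties: longer, then lexicographically first) and every other member LG
#' with shared intervals is compared to it.
#'
#' @param map A `genetic_map` or map data frame.
#' @param meta Marker metadata (`marker`, `family`).
#' @param assignment LG-to-HG assignment from [assemble_hgs()].
#' @return Data frame: `hg`, `ref_lg`, `cmp_lg`, `k`, `ref_cm`, `cmp_cm`,
#'   `sum_abs_diff_cm`, `sum_total_cm`, `ratio`.
#' @export
hg_difference_ratios <- function(map, meta, assignment) {
  mapdf <- if (inherits(map, "genetic_map")) map$map else map
  res <- list()
  for (hg in setdiff(sort(unique(assignment$hg)), "unassigned")) {
    members <- assignment$lg[assignment$hg == hg]
    stats_lg <- do.call(rbind, lapply(members, function(lg) {
      d <- mapdf[mapdf$lg == lg, ]
      data.frame(lg = lg, n = nrow(d), len = max(d$position),
                 stringsAsFactors = FALSE)
    }))
    ref <- stats_lg$lg[order(-stats_lg$n, -stats_lg$len, stats_lg$lg)][1]
    for (cmp in setdiff(members, ref)) {
      dr <- lg_difference_ratio(mapdf, meta, ref, cmp)
      if (is.null(dr)) next
      res[[length(res) + 1L]] <- data.frame(
        hg = hg, ref_lg = ref, cmp_lg = cmp, k = dr$k,
        ref_cm = sum(dr$ref_intervals), cmp_cm = sum(dr$cmp_intervals),
        sum_abs_diff_cm = dr$sum_abs_diff, sum_total_cm = dr$sum_total,
        ratio = dr$ratio, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    return(data.frame(hg = character(0), ref_lg = character(0),
                      cmp_lg = character(0), k = integer(0),
                      ref_cm = numeric(0), cmp_cm = numeric(0),
                      sum_abs_diff_cm = numeric(0),
                      sum_total_cm = numeric(0), ratio = numeric(0)))
  }
  do.call(rbind, res)
}

#' Summarise chromosome pairing evidence per homology group
#'
#' Combines accepted repulsion links and difference ratios: per homology
#' group the number and percentage of member LGs involved in accepted
#' repulsion (both LGs of a link must belong to the group) and the mean
#' difference ratio; across groups, the least-squares R-squared between
#' the two (computed when at least three groups have both statistics).
#'
#' @param repulsion A [detect_repulsion()] result.
#' @param dratios A [hg_difference_ratios()] result.
#' @param assignment LG-to-HG assignment from [assemble_hgs()].
#' @return List with `per_hg` (data frame `hg`, `n_lg`,
#'   `n_lg_in_repulsion`, `pct_in_repulsion`, `mean_diff_ratio`) and
#'   `r_squared`.
#' @export
pairing_summary <- function(repulsion, dratios, assignment) {
  hg_of <- stats::setNames(assignment$hg, assignment$lg)
  acc <- repulsion[repulsion$accepted, , drop = FALSE]
  hgs <- setdiff(sort(unique(assignment$hg)), "unassigned")
  per_hg <- do.call(rbind, lapply(hgs, function(hg) {
    members <- assignment$lg[assignment$hg == hg]
    within <- acc[acc$lg1 %in% members & acc$lg2 %in% members, ,
                  drop = FALSE]
    in_rep <- unique(c(within$lg1, within$lg2))
    mr <- dratios$ratio[dratios$hg == hg]
    data.frame(
      hg = hg, n_lg = length(members),
      n_lg_in_repulsion = length(in_rep),
      pct_in_repulsion = 100 * length(in_rep) / length(members),
      mean_diff_ratio = if (length(mr)) mean(mr) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  ok <- !is.na(per_hg$mean_diff_ratio)
  r2 <- if (sum(ok) >= 3) {
    x <- per_hg$mean_diff_ratio[ok]
    y <- per_hg$pct_in_repulsion[ok]
    # least-squares R^2 of the simple regression y ~ x
    sum((x - mean(x)) * (y - mean(y)))^2 /
      (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  } else {
    message("fewer than 3 homology groups with both statistics; ",
            "R-squared omitted")
    NA_real_
  }
  list(per_hg = per_hg, r_squared = r2)
}
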