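#' Multi-allelic anchor families from a genetic map
#'
#' Locus families (SSR/SNP/RFLP source loci whose distinct alleles were
#' scored as separate dominant markers) become homology anchors when at
#' least two of their alleles are mapped on distinct linkage groups.
#' Families with a single mapped allele are flagged uninformative.
#'
#' @param map A `genetic_map` (from [two_stage_build()]) or a data frame
#'   with columns `lg` and `marker`.
#' @param meta Marker metadata data frame with columns `marker` and
#'   `family` (NA for markers outside any family).
#' @return Data frame with one row per family carrying mapped alleles:
#'   `family`, `n_alleles_mapped`, `n_lgs`, `informative`, and a list
#'   column `lgs` of the distinct linkage groups hit.
#' @export
anchor_families <- function(map, meta) {
  mapdf <- if (inherits(map, "genetic_map")) map$map else map
  m <- merge(mapdf[, c("lg", "marker")],
             meta[!is.na(meta$family), c("marker", "family")],
             by = "marker")
  if (nrow(m) == 0) {
    return(data.frame(family = character(0), n_alleles_mapped = integer(0),
                      n_lgs = integer(0), informative = logical(0),
                      lgs = I(list())))
  }
  fams <- split(m$lg, m$family)
  res <- data.frame(
    family = names(fams),
    n_alleles_mapped = lengths(fams),
    n_lgs = vapply(fams, function(x) length(unique(x)), integer(1)),
    stringsAsFactors = FALSE
  )
  res$informative <- res$n_lgs >= 2
  res$lgs <- I(lapply(fams, function(x) sort(unique(x))))
  rownames(res) <- NULL
  res
}

#' Assemble linkage groups into homology groups
#'
#' Builds a graph over linkage groups with an edge wherever two LGs share
#' at least `min_shared` distinct anchor families; homology groups are the
#' connected components with two or more LGs, singleton components are
#' reported unassigned. Requiring two distinct families (not two alleles of
#' one family) guards against multi-locus families bridging unrelated
#' groups. Components held together by a single articulation LG are
#' flagged with a message, since a chain rule is weaker than pairwise
#' support.
#'
#' @param lgs Character vector of all linkage group names.
#' @param anchors An [anchor_families()] data frame.
#' @param min_shared Minimum number of distinct anchor families two LGs
#'   must share to be joined.
#' @return List with `assignment` (data frame `lg`, `hg`; `hg` is
#'   "unassigned" for singleton components), `hgs` (named list of member
#'   LG vectors, largest first) and `unassigned`.
#' @export
assemble_hgs <- function(lgs, anchors, min_shared = 2) {
  anchors <- anchors[anchors$informative, , drop = FALSE]
  unknown <- setdiff(unlist(anchors$lgs), lgs)
  if (length(unknown)) {
    stop("anchor families reference unknown linkage group(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  # family x LG incidence; shared-family counts per LG pair
  inc <- matrix(0L, nrow(anchors), length(lgs),
                dimnames = list(anchors$family, lgs))
  for (i in seq_len(nrow(anchors))) {
    inc[i, anchors$lgs[[i]]] <- 1L
  }
  shared <- if (nrow(inc)) t(inc) %*% inc else
    matrix(0L, length(lgs), length(lgs), dimnames = list(lgs, lgs))
  adj <- shared >= min_shared
  diag(adj) <- FALSE

  g <- igraph::graph_from_adjacency_matrix(adj * 1L, mode = "undirected")
  comp <- igraph::components(g)
  members <- unname(split(lgs, comp$membership))
  hg_members <- members[lengths(members) >= 2]
  unassigned <- sort(unlist(members[lengths(members) == 1]))
  if (is.null(unassigned)) unassigned <- character(0)

  ord <- order(-lengths(hg_members),
               vapply(hg_members, min, character(1)))
  hg_members <- hg_members[ord]
  names(hg_members) <- sprintf("HG%d", seq_along(hg_members))

  for (hg in names(hg_members)) {
    sub <- igraph::induced_subgraph(g, hg_members[[hg]])
    arts <- igraph::articulation_points(sub)
    if (length(arts)) {
      message(hg, " is held together by articulation LG(s): ",
              paste(igraph::V(sub)$name[arts], collapse = ", "))
    }
  }

  assignment <- data.frame(lg = lgs, hg = "unassigned",
                           stringsAsFactors = FALSE)
  for (hg in names(hg_members)) {
    assignment$hg[assignment$lg %in% hg_members[[hg]]] <- hg
  }
  list(assignment = assignment, hgs = hg_members, unassigned = unassigned)
}

#' Per-homology-group map totals
#'
#' Marker counts, summed map length and marker density (cM per marker) per
#' homology group, plus an overall row. Either
#' supply an LG-to-HG `assignment` with the `map` it refers to, or a ready
#' table of per-HG `n_markers` and `length_cm` (e.g. transcribed from a
#' published map summary) to recompute densities.
#'
#' @param x Either the `assignment` data frame from [assemble_hgs()]
#'   (columns `lg`, `hg`) or a data frame with columns `hg`, `n_markers`,
#'   `length_cm`.
#' @param map A `genetic_map`, required in the first form.
#' @return Data frame `hg`, (`n_lg`,) `n_markers`, `length_cm`,
#'   `density_cm`, with a final "Total" row.
#' @export
#' @examples
#' hg_summary(data.frame(hg = "HG6", n_markers = 232, length_cm = 678.3))
hg_summary <- function(x, map = NULL) {
  if (is.null(map)) {
    if (!all(c("hg", "n_markers", "length_cm") %in% names(x))) {
      stop("without `map`, `x` needs columns hg, n_markers, length_cm",
           call. = FALSE)
    }
    tab <- x[, intersect(c("hg", "n_lg", "n_markers", "length_cm"),
                         names(x)), drop = FALSE]
  } else {
    mapdf <- if (inherits(map, "genetic_map")) map$map else map
    if (nrow(x) == 0 || nrow(mapdf) == 0) {
      stop("empty homology group assignment or map", call. = FALSE)
    }
    per_lg <- do.call(rbind, lapply(split(mapdf, mapdf$lg), function(d) {
      data.frame(lg = d$lg[1], n_markers = nrow(d),
                 length_cm = max(d$position), stringsAsFactors = FALSE)
    }))
    per_lg <- merge(per_lg, x, by = "lg")
    agg <- split(per_lg, per_lg$hg)
    tab <- do.call(rbind, lapply(agg, function(d) {
      data.frame(hg = d$hg[1], n_lg = nrow(d),
                 n_markers = sum(d$n_markers),
                 length_cm = sum(d$length_cm), stringsAsFactors = FALSE)
    }))
    tab <- tab[order(tab$hg), , drop = FALSE]
  }
  if (any(tab$n_markers <= 0)) {
    stop("homology group with no markers", call. = FALSE)
  }
  total <- data.frame(hg = "Total", n_markers = sum(tab$n_markers),
                      length_cm = sum(tab$length_cm),
                      stringsAsFactors = FALSE)
  if ("n_lg" %in% names(tab)) total$n_lg <- sum(tab$n_lg)
  tab <- rbind(tab, total[, names(tab)])
  # full precision here; report writers round to one decimal for display
  tab$density_cm <- tab$length_cm / tab$n_markers
  rownames(tab) <- NULL
  tab
}

#' Fraction of anchor families spanning more than one homology group
#'
#' Multi-locus SSR/SNP sources are common in polyploids; this reports how
#' many informative anchor families have mapped alleles in two or more
#' homology groups (unassigned LGs are ignored).
#'
#' @param anchors An [anchor_families()] data frame.
#' @param assignment LG-to-HG assignment from [assemble_hgs()].
#' @return List with `n_families`, `n_multi_hg` and `fraction`.
#' @export
multilocus_rate <- function(anchors, assignment) {
  anchors <- anchors[anchors$informative, , drop = FALSE]
  hg_of <- stats::setNames(assignment$hg, assignment$lg)
  n_hgs <- vapply(anchors$lgs, function(l) {
    h <- hg_of[l]
    length(unique(h[!is.na(h) & h != "unassigned"]))
  }, integer(1))
  n_multi <- sum(n_hgs >= 2)
  list(n_families = nrow(anchors), n_multi_hg = n_multi,
       fraction = if (nrow(anchors)) n_multi / nrow(anchors) else NA_real_)
}

#' Fraction of markers lying in dense clusters
#'
#' Within each linkage group, markers (optionally restricted to one marker
#' system) are greedily partitioned into maximal runs whose span does not
#' exceed `window` cM; runs with at least `min_markers` markers count as
#' clusters. Reports the fraction of (filtered) mapped markers inside
#' clusters.
#'
#' @param map A `genetic_map` or a data frame with `lg`, `marker`,
#'   `position`.
#' @param window Maximum span of a cluster, cM.
#' @param min_markers Minimum markers per cluster.
#' @param system Optional marker system to restrict to (needs `meta`).
#' @param meta Marker metadata (columns `marker`, `system`) when filtering.
#' @return List with `fraction`, `n_clustered`, `n_total` and a `clusters`
#'   data frame (lg, start, end, n).
#' @export
cluster_fraction <- function(map, window = 10, min_markers = 5,
                             system = NULL, meta = NULL) {
  mapdf <- if (inherits(map, "genetic_map")) map$map else map
  if (!is.null(system)) {
    if (is.null(meta)) stop("`meta` needed to filter by system",
                            call. = FALSE)
    keep <- meta$marker[!is.na(meta$system) & meta$system %in% system]
    mapdf <- mapdf[mapdf$marker %in% keep, , drop = FALSE]
  }
  n_total <- nrow(mapdf)
  clusters <- list()
  n_clustered <- 0L
  for (d in split(mapdf, mapdf$lg)) {
    pos <- sort(d$position)
    i <- 1L
    while (i <= length(pos)) {
      j <- i
      while (j < length(pos) && pos[j + 1] - pos[i] <= window) j <- j + 1L
      run_n <- j - i + 1L
      if (run_n >= min_markers) {
        n_clustered <- n_clustered + run_n
        clusters[[length(clusters) + 1L]] <-
          data.frame(lg = d$lg[1], start = pos[i], end = pos[j], n = run_n,
                     stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(lg = character(0), start = numeric(0), end = numeric(0),
               n = integer(0))
  list(fraction = if (n_total) n_clustered / n_total else NA_real_,
       n_clustered = n_clustered, n_total = n_total, clusters = clusters)
}
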