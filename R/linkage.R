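#' Two-point linkage estimate for coupling-phase single-dose markers
#'
#' In a pseudo-testcross, single-dose markers in coupling on the same
#' homologue co-segregate, so the recombination fraction is estimated
#' directly from the discordance rate: with R discordant calls among n
#' progeny informative for both markers, rf = min(R/n, 0.5) and
#' LOD = R log10(rf) + (n - R) log10(1 - rf) + n log10(2), with the rf = 0
#' limit handled exactly (LOD = n log10 2).
#'
#' @param calls_a,calls_b Integer vectors of 0/1/NA calls of equal length.
#' @param min_informative Minimum shared non-missing progeny; below this the
#'   estimate is flagged uninformative (NA rf and LOD).
#' @return List with `rf`, `lod`, `n_informative` and `informative`.
#' @export
#' @examples
#' a <- rep(c(1L, 0L), 50)
#' two_point(a, a)$lod  # 100 * log10(2) = 30.10
two_point <- function(calls_a, calls_b, min_informative = 30) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors must have equal length", call. = FALSE)
  }
  obs <- !is.na(calls_a) & !is.na(calls_b)
  n <- sum(obs)
  if (n < min_informative) {
    return(list(rf = NA_real_, lod = NA_real_, n_informative = n,
                informative = FALSE))
  }
  R <- sum(calls_a[obs] != calls_b[obs])
  rf <- min(R / n, 0.5)
  lod <- if (R == 0) {
    n * log10(2)
  } else if (rf >= 0.5) {
    0
  } else {
    R * log10(rf) + (n - R) * log10(1 - rf) + n * log10(2)
  }
  list(rf = rf, lod = lod, n_informative = n, informative = TRUE)
}

#' Pairwise two-point estimates for a whole marker matrix
#'
#' Vectorised computation of [two_point()] over all marker pairs, using
#' pairwise-complete observations. With `Y` supplied the estimates are
#' between the rows of `X` and the rows of `Y` (used for repulsion scans
#' against an inverted matrix); otherwise between all row pairs of `X`.
#'
#' @param X,Y Integer call matrices (markers x progeny, 0/1/NA) with marker
#'   rownames; `Y` defaults to `X`.
#' @param min_informative Pairs with fewer shared non-missing progeny get
#'   NA rf/LOD.
#' @return List of matrices `rf`, `lod` and `n` (informative counts), with
#'   marker dimnames.
#' @export
two_point_matrix <- function(X, Y = NULL, min_informative = 30) {
  symmetric <- is.null(Y)
  if (symmetric) Y <- X
  X1 <- (!is.na(X) & X == 1L) + 0
  X0 <- (!is.na(X) & X == 0L) + 0
  Y1 <- (!is.na(Y) & Y == 1L) + 0
  Y0 <- (!is.na(Y) & Y == 0L) + 0

  N <- (X1 + X0) %*% t(Y1 + Y0)
  S <- X1 %*% t(Y1) + X0 %*% t(Y0)   # concordant
  R <- N - S

  rf <- ifelse(N > 0, pmin(R / N, 0.5), NA_real_)
  lod <- matrix(0, nrow(rf), ncol(rf))
  zero <- !is.na(rf) & R == 0
  mid <- !is.na(rf) & R > 0 & rf < 0.5
  lod[zero] <- N[zero] * log10(2)
  lod[mid] <- R[mid] * log10(rf[mid]) +
    (N[mid] - R[mid]) * log10(1 - rf[mid]) + N[mid] * log10(2)

  low <- N < min_informative
  rf[low] <- NA_real_
  lod[low] <- NA_real_
  dimnames(rf) <- dimnames(lod) <- dimnames(N) <-
    list(rownames(X), rownames(Y))
  list(rf = rf, lod = lod, n = N)
}

#' Haldane map distance
#'
#' Converts a recombination fraction to centiMorgans under the Haldane
#' (no-interference) map function, d = -50 ln(1 - 2 rf).
#'
#' @param rf Recombination fraction(s) in [0, 0.5). NA passes through.
#' @return Distance(s) in cM.
#' @export
#' @examples
#' haldane_cm(0.25)  # 34.66 cM
haldane_cm <- function(rf) {
  if (any(!is.na(rf) & (rf < 0 | rf >= 0.5))) {
    stop("recombination fraction must lie in [0, 0.5); the Haldane ",
         "distance is undefined at rf >= 0.5", call. = FALSE)
  }
  -50 * log(1 - 2 * rf)
}

#' Inverse Haldane map function
#'
#' @param d Distance(s) in cM.
#' @return Expected recombination fraction(s), (1 - exp(-2d/100)) / 2.
#' @export
haldane_rf <- function(d) {
  if (any(!is.na(d) & d < 0)) stop("distance must be >= 0", call. = FALSE)
  (1 - exp(-2 * d / 100)) / 2
}

#' Form marker groups by two-point linkage
#'
#' Single-linkage transitive closure over marker pairs with LOD of at least
#' `lod_min` and recombination fraction of at most `rf_max` (both
#' inclusive). Uninformative pairs (NA estimates) never link.
#'
#' @param tp A [two_point_matrix()] result (symmetric).
#' @param lod_min Minimum LOD score for an edge.
#' @param rf_max Maximum recombination fraction for an edge.
#' @return List with `groups` (list of character vectors, each a linkage
#'   group of >= 2 markers, ordered by decreasing size) and `unlinked`
#'   (markers in no group).
#' @export
group_markers <- function(tp, lod_min = 10, rf_max = 0.35) {
  adj <- !is.na(tp$lod) & tp$lod >= lod_min &
    !is.na(tp$rf) & tp$rf <= rf_max
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj * 1L, mode = "undirected")
  comp <- igraph::components(g)
  ids <- rownames(tp$lod)
  groups <- unname(split(ids, comp$membership))
  unlinked <- sort(unlist(groups[lengths(groups) == 1]))
  if (is.null(unlinked)) unlinked <- character(0)
  groups <- groups[lengths(groups) >= 2]
  first <- vapply(groups, min, character(1))
  groups <- groups[order(-lengths(groups), first)]
  list(groups = groups, unlinked = unlinked)
}

RF_CEILING <- 0.49999   # stand-in for missing/unlinked rf in ordering

sarf <- function(ord, D) sum(D[cbind(ord[-length(ord)], ord[-1])])

#' Order the markers of one linkage group
#'
#' Seriation by sum of adjacent recombination fractions (SARF): a greedy
#' path construction (start from the closest pair, repeatedly append the
#' marker nearest to either end) refined by 2-opt segment reversals until
#' no reversal lowers the SARF. Ties are broken lexicographically by marker
#' name, and the final orientation is canonicalised so the lexicographically
#' smaller terminal marker comes first. Positions are cumulative Haldane
#' distances over adjacent recombination fractions, starting at 0.
#'
#' @param rf Square recombination-fraction matrix with marker dimnames
#'   (from [two_point_matrix()]). NA entries are treated as unlinked
#'   (rf near 0.5) for ordering, but the matrix restricted to non-NA
#'   entries must be connected.
#' @return An object of class `linkage_group`: list with `markers`
#'   (ordered ids), `positions` (cM, starting at 0), `length` (cM) and
#'   `name` (NA until assigned).
#' @export
order_group <- function(rf) {
  ids <- rownames(rf)
  m <- length(ids)
  if (m < 2) stop("a linkage group needs at least 2 markers", call. = FALSE)

  finite <- !is.na(rf)
  diag(finite) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(finite * 1L, mode = "undirected")
  if (igraph::components(g)$no > 1) {
    stop("disconnected recombination matrix: markers were grouped without ",
         "pairwise estimates linking them", call. = FALSE)
  }

  D <- rf
  D[is.na(D)] <- RF_CEILING
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)

  if (m == 2) {
    ord <- sort(ids)
  } else {
    # greedy seeding: the closest pair, ties by name
    cand <- which(upper.tri(D), arr.ind = TRUE)
    vals <- D[cand]
    best <- cand[order(vals, ids[cand[, 1]], ids[cand[, 2]]), , drop = FALSE][1, ]
    path <- sort(ids[best])
    left <- setdiff(ids, path)
    while (length(left)) {
      d_head <- D[left, path[1]]
      d_tail <- D[left, path[length(path)]]
      dmin <- pmin(d_head, d_tail)
      pick <- left[order(dmin, left)][1]
      if (D[pick, path[1]] <= D[pick, path[length(path)]]) {
        path <- c(pick, path)
      } else {
        path <- c(path, pick)
      }
      left <- setdiff(left, pick)
    }
    # 2-opt refinement on SARF
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      cur <- sarf(path, D)
      for (i in seq_len(m - 1)) {
        for (j in seq(i + 1, m)) {
          trial <- path
          trial[i:j] <- rev(trial[i:j])
          if (sarf(trial, D) < cur - 1e-12) {
            path <- trial
            cur <- sarf(path, D)
            improved <- TRUE
          }
        }
      }
    }
    ord <- path
  }

  if (ord[length(ord)] < ord[1]) ord <- rev(ord)
  adj <- D[cbind(ord[-m], ord[-1])]
  adj <- pmin(adj, RF_CEILING)
  positions <- c(0, cumsum(haldane_cm(adj)))
  structure(
    list(name = NA_character_, markers = ord, positions = positions,
         length = positions[m]),
    class = "linkage_group"
  )
}

#' @export
print.linkage_group <- function(x, ...) {
  cat("linkage group", if (!is.na(x$name)) x$name else "(unnamed)", ":",
      length(x$markers), "markers,", sprintf("%.1f cM", x$length), "\n")
  invisible(x)
}

new_genetic_map <- function(lgs, unplaced, params) {
  map <- do.call(rbind, lapply(lgs, function(lg) {
    data.frame(lg = lg$name, marker = lg$markers, position = lg$positions,
               stringsAsFactors = FALSE)
  }))
  if (is.null(map)) {
    map <- data.frame(lg = character(0), marker = character(0),
                      position = numeric(0))
  }
  rownames(map) <- NULL
  structure(list(map = map, lgs = lgs, unplaced = unplaced,
                 params = params),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  lens <- vapply(x$lgs, `[[`, numeric(1), "length")
  cat("genetic map:", length(x$lgs), "linkage groups,", nrow(x$map),
      "markers,", sprintf("%.1f cM total", sum(lens)), ";",
      length(x$unplaced), "unplaced\n")
  invisible(x)
}

#' Build a genetic map in two stages (framework + insertion)
#'
#' Stage one builds a framework map from markers scored on at least
#' `framework_min_scored` progeny: two-point estimates, linkage grouping at
#' (`lod_min`, `rf_max`) and SARF ordering per group. Stage two inserts the
#' remaining markers (e.g. those scored only on a reduced progeny panel)
#' one at a time, each at the linkage group and slot that minimises the
#' SARF increase, without reordering the framework. Markers with no
#' framework linkage at `lod_min`/`rf_max` remain unplaced.
#'
#' @param mm A [marker_matrix()] of (filtered, single-dose) markers.
#' @param lod_min,rf_max Linkage thresholds, both inclusive.
#' @param framework_min_scored Minimum non-missing calls for a marker to
#'   enter the framework stage.
#' @param min_informative Minimum shared progeny for a pairwise estimate.
#' @return A `genetic_map` object: `map` (data frame lg/marker/position),
#'   `lgs` (list of `linkage_group`s), `unplaced` (marker ids), `params`.
#' @export
two_stage_build <- function(mm, lod_min = 10, rf_max = 0.35,
                            framework_min_scored = 188,
                            min_informative = 30) {
  stopifnot(inherits(mm, "marker_matrix"))
  calls <- mm$calls
  scored <- rowSums(!is.na(calls))
  fw_ids <- rownames(calls)[scored >= framework_min_scored]
  ins_ids <- sort(setdiff(rownames(calls), fw_ids))
  if (length(fw_ids) < 2) {
    stop("fewer than 2 markers scored on >= ", framework_min_scored,
         " progeny; no framework can be built", call. = FALSE)
  }
  message("two_stage_build: ", length(fw_ids), " framework markers, ",
          length(ins_ids), " to insert")

  tp <- two_point_matrix(calls[fw_ids, , drop = FALSE],
                         min_informative = min_informative)
  grp <- group_markers(tp, lod_min = lod_min, rf_max = rf_max)
  lgs <- lapply(grp$groups, function(g) {
    order_group(tp$rf[g, g, drop = FALSE])
  })
  for (i in seq_along(lgs)) {
    lgs[[i]]$name <- sprintf("LG%02d", i)
  }
  unplaced <- grp$unlinked

  # per-LG bookkeeping for insertion: marker order and adjacent rfs
  orders <- lapply(lgs, `[[`, "markers")
  adj_rf <- lapply(lgs, function(lg) {
    m <- length(lg$markers)
    haldane_inv <- function(d) (1 - exp(-2 * d / 100)) / 2
    haldane_inv(diff(lg$positions))
  })

  for (x in ins_ids) {
    tpx <- two_point_matrix(calls[x, , drop = FALSE],
                            calls[fw_ids, , drop = FALSE],
                            min_informative = min_informative)
    linked <- !is.na(tpx$lod[1, ]) & tpx$lod[1, ] >= lod_min &
      tpx$rf[1, ] <= rf_max
    if (!any(linked)) {
      unplaced <- c(unplaced, x)
      next
    }
    linked_ids <- fw_ids[linked]
    cand_lgs <- which(vapply(orders, function(o) {
      any(o %in% linked_ids)
    }, logical(1)))

    best <- NULL
    for (li in cand_lgs) {
      o <- orders[[li]]
      tpo <- two_point_matrix(calls[x, , drop = FALSE],
                              calls[o, , drop = FALSE],
                              min_informative = min_informative)
      r <- pmin(ifelse(is.na(tpo$rf[1, ]), RF_CEILING, tpo$rf[1, ]),
                RF_CEILING)
      k <- length(o)
      inc <- c(r[1],                                     # before first
               if (k > 1) r[-k] + r[-1] - adj_rf[[li]],  # interior slots
               r[k])                                     # after last
      slot <- which.min(inc)
      if (is.null(best) || inc[slot] < best$inc - 1e-12) {
        best <- list(lg = li, slot = slot, inc = inc[slot], r = r)
      }
    }
    o <- orders[[best$lg]]
    k <- length(o)
    s <- best$slot   # 1 = prepend, k + 1 = append, else between s-1 and s
    if (s == 1) {
      orders[[best$lg]] <- c(x, o)
      adj_rf[[best$lg]] <- c(best$r[1], adj_rf[[best$lg]])
    } else if (s == k + 1) {
      orders[[best$lg]] <- c(o, x)
      adj_rf[[best$lg]] <- c(adj_rf[[best$lg]], best$r[k])
    } else {
      orders[[best$lg]] <- append(o, x, after = s - 1)
      old <- adj_rf[[best$lg]]
      adj_rf[[best$lg]] <- append(old[-(s - 1)],
                                  c(best$r[s - 1], best$r[s]),
                                  after = s - 2)
    }
  }

  for (i in seq_along(lgs)) {
    o <- orders[[i]]
    pos <- c(0, cumsum(haldane_cm(pmin(adj_rf[[i]], RF_CEILING))))
    lgs[[i]]$markers <- o
    lgs[[i]]$positions <- pos
    lgs[[i]]$length <- pos[length(pos)]
  }
  new_genetic_map(lgs, sort(unique(unplaced)),
                  params = list(lod_min = lod_min, rf_max = rf_max,
                                framework_min_scored = framework_min_scored,
                                min_informative = min_informative))
}
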