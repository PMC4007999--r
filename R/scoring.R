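#' Expected presence probability of a dominant marker by dosage
#'
#' Under random chromosomal segregation in an autopolyploid of even ploidy
#' m, a gamete receives m/2 of the m homologues uniformly at random, so a
#' marker present on `dose` homologues of the informative parent is absent
#' from the gamete with probability C(m - dose, m/2) / C(m, m/2). For an
#' octoploid this gives expected present:absent ratios of 1:1 (single
#' dose), 55:15 (double dose) and 65:5 (triple dose).
#'
#' @param dose Number of homologues carrying the marker (1, 2 or 3).
#' @param ploidy Even ploidy of the informative parent.
#' @return Probability that a progeny individual shows the marker.
#' @export
#' @examples
#' dosage_presence_prob(2, 8)  # 55/70
dosage_presence_prob <- function(dose, ploidy) {
  if (ploidy %% 2 != 0 || ploidy < 4) {
    stop("`ploidy` must be an even number >= 4", call. = FALSE)
  }
  if (any(dose < 1) || any(dose > ploidy)) {
    stop("`dose` must be between 1 and the ploidy", call. = FALSE)
  }
  1 - choose(ploidy - dose, ploidy / 2) / choose(ploidy, ploidy / 2)
}

chisq_ratio <- function(n_present, n_absent, p_present) {
  n <- n_present + n_absent
  e <- n * c(p_present, 1 - p_present)
  (n_present - e[1])^2 / e[1] + (n_absent - e[2])^2 / e[2]
}

#' Classify marker dosage from segregation counts
#'
#' Tests the observed present:absent split against the expected single-,
#' double- and triple-dose ratios at the given ploidy (see
#' [dosage_presence_prob()]) with 1-df chi-square statistics. A marker is
#' `SD` when the 1:1 test is non-significant at `alpha`; `SD_skewed` when
#' 1:1 is rejected but its chi-square is still strictly smaller than the
#' chi-square against the double-dose ratio (moderate segregation
#' distortion, not a likely double dose); `DD`/`TD` when the respective
#' statistic is the minimum and non-significant; otherwise `unclassified`.
#'
#' A chi-square against the classical 3:1 bi-parental ratio is reported for
#' reference (`chi2_3to1`) but only competes when `biparental = TRUE`,
#' because at realistic progeny sizes the double-dose and 3:1 ratios are
#' statistically indistinguishable; bi-parental markers are excluded from
#' single-dose mapping in any case.
#'
#' @param n_present,n_absent Non-missing progeny counts. Their sum must be
#'   at least 30.
#' @param ploidy Even ploidy of the informative parent (default 8).
#' @param alpha Chi-square significance level (1 df).
#' @param marker Optional marker id carried into the result.
#' @param biparental Set TRUE for markers known to segregate from both
#'   parents; allows the `biparental_3to1` class.
#' @return One-row data frame: marker, counts, `chi2_1to1`, `chi2_dd`,
#'   `chi2_td`, `chi2_3to1`, `p_1to1`, `skew_log2`, `class`.
#' @export
#' @examples
#' classify_dosage(113, 114, ploidy = 8)$class     # "SD"
#' classify_dosage(178, 49, ploidy = 8)$class      # "DD"
#' classify_dosage(130, 97, ploidy = 8)$class      # "SD_skewed"
classify_dosage <- function(n_present, n_absent, ploidy = 8, alpha = 0.05,
                            marker = NA_character_, biparental = FALSE) {
  if (ploidy %% 2 != 0 || ploidy < 4) {
    stop("`ploidy` must be an even number >= 4", call. = FALSE)
  }
  if (n_present == 0 && n_absent == 0) {
    stop("no informative progeny: both counts are zero", call. = FALSE)
  }
  n <- n_present + n_absent
  if (n < 30) {
    stop("fewer than 30 informative progeny (", n,
         "); dosage classification is unreliable", call. = FALSE)
  }

  p_dd <- dosage_presence_prob(2, ploidy)
  p_td <- dosage_presence_prob(3, ploidy)
  chi2_1to1 <- chisq_ratio(n_present, n_absent, 0.5)
  chi2_dd <- chisq_ratio(n_present, n_absent, p_dd)
  chi2_td <- chisq_ratio(n_present, n_absent, p_td)
  chi2_3to1 <- chisq_ratio(n_present, n_absent, 0.75)
  crit <- stats::qchisq(1 - alpha, df = 1)

  cand <- c(DD = chi2_dd, TD = chi2_td)
  if (biparental) cand <- c(cand, biparental_3to1 = chi2_3to1)

  class <- if (chi2_1to1 <= crit) {
    "SD"
  } else if (chi2_1to1 < chi2_dd) {
    "SD_skewed"
  } else if (min(cand) <= crit) {
    names(cand)[which.min(cand)]
  } else {
    "unclassified"
  }

  data.frame(
    marker = marker,
    n_present = n_present, n_absent = n_absent,
    chi2_1to1 = chi2_1to1, chi2_dd = chi2_dd, chi2_td = chi2_td,
    chi2_3to1 = chi2_3to1,
    p_1to1 = stats::pchisq(chi2_1to1, df = 1, lower.tail = FALSE),
    skew_log2 = log2(n_present / n_absent),
    class = class,
    stringsAsFactors = FALSE
  )
}

#' Segregation skew statistic
#'
#' The log2 ratio of carrier to non-carrier progeny, with a chi-square test
#' of the 1:1 single-dose expectation. Zero counts give an infinite skew
#' flagged significant rather than an error.
#'
#' @param n_present,n_absent Non-missing progeny counts.
#' @param alpha Significance level of the 1-df chi-square test.
#' @return List with `skew_log2`, `chi2` and `significant`.
#' @export
#' @examples
#' skew_statistic(130, 97)  # skewed: chi2 = 4.80 > 3.84
skew_statistic <- function(n_present, n_absent, alpha = 0.05) {
  if (n_present == 0 || n_absent == 0) {
    return(list(skew_log2 = if (n_present == 0) -Inf else Inf,
                chi2 = Inf, significant = TRUE))
  }
  chi2 <- chisq_ratio(n_present, n_absent, 0.5)
  list(skew_log2 = log2(n_present / n_absent),
       chi2 = chi2,
       significant = chi2 > stats::qchisq(1 - alpha, df = 1))
}

#' Score every marker of a matrix for dosage and skew
#'
#' Applies [classify_dosage()] and [skew_statistic()] over all markers,
#' using complete cases only (missing calls are excluded from the counts).
#' Markers with fewer than `min_informative` non-missing calls are left
#' `unclassified` with NA statistics.
#'
#' @param mm A [marker_matrix()].
#' @param ploidy Even ploidy of the informative parent.
#' @param alpha Chi-square significance level.
#' @param min_informative Minimum non-missing calls required to classify.
#' @return Data frame with one row per marker: counts, chi-square columns,
#'   `p_1to1`, `skew_log2`, `skew_significant` and `class`.
#' @export
score_markers <- function(mm, ploidy = 8, alpha = 0.05,
                          min_informative = 30) {
  stopifnot(inherits(mm, "marker_matrix"))
  calls <- mm$calls
  np <- rowSums(calls == 1L, na.rm = TRUE)
  na_ <- rowSums(calls == 0L, na.rm = TRUE)
  nm <- rowSums(is.na(calls))
  n <- np + na_

  p_dd <- dosage_presence_prob(2, ploidy)
  p_td <- dosage_presence_prob(3, ploidy)
  crit <- stats::qchisq(1 - alpha, df = 1)

  chi <- function(p) {
    e1 <- n * p
    e0 <- n * (1 - p)
    (np - e1)^2 / e1 + (na_ - e0)^2 / e0
  }
  chi2_1to1 <- chi(0.5)
  chi2_dd <- chi(p_dd)
  chi2_td <- chi(p_td)
  chi2_3to1 <- chi(0.75)

  class <- rep("unclassified", length(n))
  ok <- n >= min_informative
  class[ok & chi2_1to1 <= crit] <- "SD"
  skewed <- ok & chi2_1to1 > crit & chi2_1to1 < chi2_dd
  class[skewed] <- "SD_skewed"
  rest <- ok & class == "unclassified"
  dd_best <- rest & chi2_dd <= chi2_td & chi2_dd <= crit
  td_best <- rest & chi2_td < chi2_dd & chi2_td <= crit
  class[dd_best] <- "DD"
  class[td_best] <- "TD"

  blank <- function(x) ifelse(ok, x, NA_real_)
  res <- data.frame(
    marker = rownames(calls),
    n_present = np, n_absent = na_, n_missing = nm,
    chi2_1to1 = blank(chi2_1to1), chi2_dd = blank(chi2_dd),
    chi2_td = blank(chi2_td), chi2_3to1 = blank(chi2_3to1),
    p_1to1 = blank(stats::pchisq(chi2_1to1, df = 1, lower.tail = FALSE)),
    skew_log2 = blank(log2(np / na_)),
    skew_significant = ifelse(ok, chi2_1to1 > crit, NA),
    class = class,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Find duplicate markers
#'
#' Two markers are considered duplicates when their calls agree on every
#' progeny where both are non-missing and they share at least `min_overlap`
#' such progeny (the overlap floor guards against spurious merges between
#' markers scored on disjoint reduced panels). Duplicate clusters are the
#' connected components of this relation; on fully observed data it is a
#' true equivalence relation.
#'
#' @param mm A [marker_matrix()].
#' @param min_overlap Minimum shared non-missing progeny.
#' @return List of duplicate clusters (character vectors of marker ids,
#'   each of size >= 2) with a `representative` attribute naming, per
#'   cluster, the marker with the highest call rate (ties broken by name).
#' @export
find_duplicates <- function(mm, min_overlap = 50) {
  stopifnot(inherits(mm, "marker_matrix"))
  X <- mm$calls
  if (nrow(X) < 2) {
    out <- list()
    attr(out, "representative") <- character(0)
    return(out)
  }
  A1 <- (!is.na(X) & X == 1L) + 0
  A0 <- (!is.na(X) & X == 0L) + 0
  mismatch <- A1 %*% t(A0) + A0 %*% t(A1)
  overlap <- (A1 + A0) %*% t(A1 + A0)
  adj <- mismatch == 0 & overlap >= min_overlap
  diag(adj) <- FALSE

  g <- igraph::graph_from_adjacency_matrix(adj * 1L, mode = "undirected")
  comp <- igraph::components(g)
  ids <- rownames(X)
  clusters <- split(ids, comp$membership)
  clusters <- clusters[lengths(clusters) >= 2]
  clusters <- unname(clusters[order(vapply(clusters, min, character(1)))])

  call_rate <- stats::setNames(mm$meta$call_rate, mm$meta$marker)
  reps <- vapply(clusters, function(cl) {
    cl[order(-call_rate[cl], cl)][1]
  }, character(1))
  attr(clusters, "representative") <- reps
  clusters
}

#' Collapse duplicate markers to one representative each
#'
#' @inheritParams find_duplicates
#' @return A [marker_matrix()] with non-representative duplicates removed.
#' @export
collapse_duplicates <- function(mm, min_overlap = 50) {
  clusters <- find_duplicates(mm, min_overlap)
  if (!length(clusters)) return(mm)
  reps <- attr(clusters, "representative")
  drop <- setdiff(unlist(clusters), reps)
  message("collapsing ", length(unlist(clusters)), " duplicate markers in ",
          length(clusters), " clusters; dropping ", length(drop))
  keep <- setdiff(rownames(mm$calls), drop)
  subset_markers(mm, keep)
}

#' Filter markers on quality score and call rate
#'
#' Retains markers with quality strictly above `q_min` and call rate of at
#' least `call_rate_min`. Markers with missing quality metadata raise an
#' error naming the first offenders.
#'
#' @param mm A [marker_matrix()].
#' @param q_min Quality threshold (exclusive), on the 0-100 scale.
#' @param call_rate_min Call-rate threshold (inclusive), in [0, 1].
#' @return The filtered [marker_matrix()]; per-criterion removal counts are
#'   reported via `message()`.
#' @export
quality_filter <- function(mm, q_min = 80, call_rate_min = 0.8) {
  stopifnot(inherits(mm, "marker_matrix"))
  if (nrow(mm$calls) == 0) return(mm)
  bad_meta <- mm$meta$marker[is.na(mm$meta$quality)]
  if (length(bad_meta)) {
    stop("missing quality score for marker(s): ",
         paste(utils::head(bad_meta, 5), collapse = ", "), call. = FALSE)
  }
  fail_q <- mm$meta$quality <= q_min
  fail_cr <- mm$meta$call_rate < call_rate_min
  message("quality_filter: removing ", sum(fail_q), " markers with Q <= ",
          q_min, " and ", sum(fail_cr & !fail_q),
          " more with call rate < ", call_rate_min)
  keep <- mm$meta$marker[!(fail_q | fail_cr)]
  if (!length(keep)) {
    return(marker_matrix(mm$calls[0, , drop = FALSE],
                         mm$meta[0, , drop = FALSE]))
  }
  subset_markers(mm, keep)
}
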