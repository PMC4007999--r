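#' Simulate the informative parent of a polyploid pseudo-testcross
#'
#' Constructs a parental genome: `n_homology_groups` homology groups, each a
#' set of homologues of identical genetic length, carrying dominant markers
#' of known dosage (single dose on one homologue, double on two, triple on
#' three) plus multi-allelic anchor families whose single-dose alleles sit
#' at a homologous position on several homologues of the same group (and
#' occasionally on a second group, mimicking multi-locus SSRs).
#'
#' The second parent of the cross is assumed to contribute no segregating
#' alleles for these markers (pure pseudo-testcross), so the parent object
#' fully determines progeny genotypes given gametes.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_parent`: a list with the resolved
#'   `homologues_per_hg`, a `markers` data frame (marker, hg, pos, dosage,
#'   family, system, enzyme, quality) and a parallel `carriers` list of
#'   homologue index vectors.
#' @export
simulate_parent <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config object", call. = FALSE)
  }
  set.seed(config$seed)
  n_hg <- config$n_homology_groups
  hph <- config$homologues_per_hg
  if (is.null(hph)) hph <- sample(13:23, n_hg, replace = TRUE)
  L <- config$chromosome_length

  rows <- list()
  carriers <- list()
  k <- config$markers_per_homologue

  for (hg in seq_len(n_hg)) {
    H <- hph[hg]
    for (hom in seq_len(H)) {
      if (k == 0) next
      pos <- if (!is.null(config$marker_positions)) {
        rep_len(config$marker_positions, k)
      } else {
        runif(k, 0, L)
      }
      # triple dose needs >= 3 homologues; renormalise the mix if not
      mix <- config$dosage_mix
      max_dose <- min(3L, H)
      if (max_dose < 3) {
        mix <- mix[seq_len(max_dose)]
        mix <- mix / sum(mix)
      }
      dose <- sample(seq_len(max_dose), k, replace = TRUE, prob = mix)
      system <- sample(c("DArT", "AFLP"), k, replace = TRUE,
                       prob = c(0.6, 0.4))
      enzyme <- ifelse(system == "DArT",
                       sample(c("PTB", "PTH", "PTP"), k, replace = TRUE,
                              prob = c(0.47, 0.41, 0.12)),
                       "none")
      for (j in seq_len(k)) {
        extra <- if (dose[j] > 1) {
          sample(setdiff(seq_len(H), hom), dose[j] - 1L)
        } else integer(0)
        rows[[length(rows) + 1L]] <- data.frame(
          hg = hg, pos = pos[j], dosage = dose[j],
          family = NA_character_, system = system[j], enzyme = enzyme[j],
          stringsAsFactors = FALSE
        )
        carriers[[length(carriers) + 1L]] <- c(hom, extra)
      }
    }

    # multi-allelic anchor families
    for (f in seq_len(config$anchor_families_per_hg)) {
      fam <- sprintf("F%02d_%02d", hg, f)
      fpos <- runif(1, 0, L)
      lo <- min(config$anchor_allele_range[1], H)
      hi <- min(config$anchor_allele_range[2], H)
      n_all <- if (lo >= hi) lo else sample(lo:hi, 1)
      homs <- sample(seq_len(H), n_all)
      for (hom in homs) {
        rows[[length(rows) + 1L]] <- data.frame(
          hg = hg, pos = fpos, dosage = 1L, family = fam,
          system = "SSR", enzyme = "none", stringsAsFactors = FALSE
        )
        carriers[[length(carriers) + 1L]] <- hom
      }
      if (n_hg > 1 && runif(1) < config$anchor_cross_hg_rate) {
        hg2 <- sample(setdiff(seq_len(n_hg), hg), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          hg = hg2, pos = runif(1, 0, L), dosage = 1L, family = fam,
          system = "SSR", enzyme = "none", stringsAsFactors = FALSE
        )
        carriers[[length(carriers) + 1L]] <- sample(seq_len(hph[hg2]), 1)
      }
    }
  }

  markers <- do.call(rbind, rows)
  markers$quality <- round(runif(nrow(markers), 85, 100), 1)
  markers$marker <- sprintf("M%05d", seq_len(nrow(markers)))
  markers <- markers[, c("marker", "hg", "pos", "dosage", "family",
                         "system", "enzyme", "quality")]
  rownames(markers) <- NULL

  # long format (marker row x carrier homologue), used by gamete_calls()
  reps <- lengths(carriers)
  long <- data.frame(
    row = rep.int(seq_len(nrow(markers)), reps),
    hg = rep.int(markers$hg, reps),
    hom = unlist(carriers),
    pos = rep.int(markers$pos, reps)
  )
  long <- long[order(long$hg, long$hom), ]

  structure(
    list(config = config, homologues_per_hg = hph,
         markers = markers, carriers = carriers, long = long),
    class = "sim_parent"
  )
}

#' @export
print.sim_parent <- function(x, ...) {
  cat("Simulated polyploid parent:", x$config$n_homology_groups,
      "homology groups,", sum(x$homologues_per_hg), "homologues,",
      nrow(x$markers), "markers\n")
  invisible(x)
}

#' Simulate one meiosis of the polyploid parent
#'
#' Within each homology group, homologues are partitioned into bivalents:
#' uniformly at random when no preferential pairing applies, or within the
#' configured `partner_sets` with probability `pairing_preference`. With an
#' odd homologue count under random pairing one homologue is left unpaired
#' (dropped) at random, mimicking aneuploid meiosis. Each bivalent transmits
#' one recombinant chromatid: crossover switch points follow a Poisson
#' process at 1 per 100 cM with uniform placement and no interference, so
#' recombination fractions obey the Haldane map function.
#'
#' @param parent A [simulate_parent()] result.
#' @param seed Optional integer seed for this single meiosis; by default the
#'   current RNG stream is used (callers such as [generate_population()]
#'   seed the stream once).
#' @return An object of class `sim_gamete`: per homology group, the bivalent
#'   `pairs` (2 x n matrix of homologue indices), the transmitted `start`
#'   homologue per bivalent, sorted crossover `breaks` per bivalent, and any
#'   `dropped` homologue.
#' @export
simulate_meiosis <- function(parent, seed = NULL) {
  if (!inherits(parent, "sim_parent")) {
    stop("`parent` must be a sim_parent object", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  config <- parent$config
  L <- config$chromosome_length
  lambda <- L / 100

  out <- vector("list", config$n_homology_groups)
  for (hg in seq_len(config$n_homology_groups)) {
    H <- parent$homologues_per_hg[hg]
    sets <- if (!is.null(config$partner_sets)) config$partner_sets[[hg]]
    use_sets <- !is.null(sets) &&
      runif(1) < config$pairing_preference
    if (use_sets) {
      pairs <- do.call(cbind, lapply(sets, function(s) {
        matrix(sample(s, length(s)), nrow = 2)
      }))
      dropped <- integer(0)
    } else {
      homs <- seq_len(H)
      dropped <- integer(0)
      if (H %% 2 == 1) {
        dropped <- sample(homs, 1)
        homs <- setdiff(homs, dropped)
      }
      pairs <- matrix(sample(homs, length(homs)), nrow = 2)
    }
    nb <- ncol(pairs)
    start_row <- sample(1:2, nb, replace = TRUE)
    start <- pairs[cbind(start_row, seq_len(nb))]
    breaks <- lapply(seq_len(nb), function(b) {
      sort(runif(rpois(1, lambda), 0, L))
    })
    out[[hg]] <- list(pairs = pairs, start = start, breaks = breaks,
                      dropped = dropped)
  }
  structure(out, class = "sim_gamete")
}

#' Evaluate marker presence in a gamete
#'
#' A dominant marker is present in the gamete when at least one transmitted
#' chromatid carries a homologue segment bearing it at the marker position.
#'
#' @param parent A [simulate_parent()] result.
#' @param gamete A [simulate_meiosis()] result from the same parent.
#' @return Logical vector, one entry per row of `parent$markers`.
#' @export
gamete_calls <- function(parent, gamete) {
  long <- parent$long
  present <- logical(nrow(parent$markers))
  for (hg in seq_len(parent$config$n_homology_groups)) {
    g <- gamete[[hg]]
    H <- parent$homologues_per_hg[hg]
    lf <- long[long$hg == hg, ]
    if (nrow(lf) == 0) next

    bv_of <- integer(H)
    other <- integer(H)
    nb <- ncol(g$pairs)
    bv_of[g$pairs[1, ]] <- seq_len(nb)
    bv_of[g$pairs[2, ]] <- seq_len(nb)
    other[g$pairs[1, ]] <- g$pairs[2, ]
    other[g$pairs[2, ]] <- g$pairs[1, ]

    bv <- bv_of[lf$hom]            # 0 for a dropped homologue
    ok <- bv > 0
    cnt <- integer(nrow(lf))
    for (b in unique(bv[ok])) {
      idx <- which(bv == b)
      cnt[idx] <- findInterval(lf$pos[idx], g$breaks[[b]])
    }
    src <- integer(nrow(lf))
    sb <- g$start[pmax(bv, 1L)]    # start homologue of the row's bivalent
    src[ok] <- ifelse(cnt[ok] %% 2 == 0, sb[ok], other[sb[ok]])
    hit <- ok & src == lf$hom
    present[lf$row[hit]] <- TRUE
  }
  present
}

#' Generate a simulated pseudo-testcross marker population
#'
#' Runs [simulate_parent()] once and [simulate_meiosis()] per progeny, then
#' imposes the observation model: a fraction of markers is scored only on a
#' reduced progeny panel (all other calls missing) and remaining calls are
#' masked at `missing_rate`. Random streams are per stage, derived from
#' `config$seed` (parent: seed, meiosis: seed + 1, missingness: seed + 2),
#' so each stage is independently reproducible.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_population`: a list with
#'   \describe{
#'     \item{matrix}{a [marker_matrix()] of presence/absence/missing calls}
#'     \item{truth}{per-marker truth: dosage class, homology group, owner
#'       homologue, position and anchor family}
#'     \item{parent}{the simulated parent}
#'   }
#' @export
generate_population <- function(config) {
  parent <- simulate_parent(config)
  nm <- nrow(parent$markers)
  n <- config$n_progeny

  set.seed(config$seed + 1L)
  calls <- matrix(NA_integer_, nm, n,
                  dimnames = list(parent$markers$marker,
                                  sprintf("P%03d", seq_len(n))))
  for (i in seq_len(n)) {
    calls[, i] <- as.integer(gamete_calls(parent, simulate_meiosis(parent)))
  }

  set.seed(config$seed + 2L)
  if (config$subset_scored_fraction > 0 && n > config$subset_panel_size) {
    nsub <- round(config$subset_scored_fraction * nm)
    if (nsub > 0) {
      sub_markers <- sample(nm, nsub)
      panel <- sample(n, config$subset_panel_size)
      calls[sub_markers, setdiff(seq_len(n), panel)] <- NA_integer_
    }
  }
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(calls)) < config$missing_rate, nm, n)
    calls[mask & !is.na(calls)] <- NA_integer_
  }

  meta <- parent$markers[, c("marker", "system", "enzyme", "family",
                             "quality")]
  mm <- marker_matrix(calls, meta)

  truth <- data.frame(
    marker = parent$markers$marker,
    dosage = c("SD", "DD", "TD")[parent$markers$dosage],
    hg = parent$markers$hg,
    homologue = vapply(parent$carriers, `[`, integer(1), 1L),
    position = parent$markers$pos,
    family = parent$markers$family,
    stringsAsFactors = FALSE
  )
  attr(truth, "partner_sets") <- config$partner_sets

  structure(list(matrix = mm, truth = truth, parent = parent),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Simulated mapping population:", nrow(x$matrix$calls), "markers x",
      ncol(x$matrix$calls), "progeny\n")
  invisible(x)
}
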