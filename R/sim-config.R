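#' Configuration for the autopolyploid cross simulator
#'
#' Builds and validates the parameter set for [generate_population()], the
#' forward simulator of a pseudo-testcross between a highly polyploid,
#' possibly aneuploid informative parent and a non-contributing second
#' parent. Defaults emulate a modern sugarcane mapping cross: 8 homology
#' groups with 13-23 homologues each, 227 progeny, a marker panel dominated
#' by single-dose presence/absence markers, and a subset of markers scored
#' on only 94 progeny.
#'
#' @param n_homology_groups Number of homology groups (basic chromosomes).
#' @param homologues_per_hg Integer vector of homologue counts per homology
#'   group (recycled to `n_homology_groups`). `NULL` draws each count
#'   uniformly from 13-23 when the parent is simulated.
#' @param markers_per_homologue Number of dominant markers seeded on each
#'   homologue (in addition to anchor-family alleles).
#' @param chromosome_length Genetic length of every homologue, in
#'   centiMorgans.
#' @param n_progeny Number of F1 progeny.
#' @param dosage_mix Named proportions of single-, double- and triple-dose
#'   markers, `c(SD = , DD = , TD = )`; must sum to 1.
#' @param pairing_preference Probability, per meiosis and homology group,
#'   that bivalents form within `partner_sets` rather than at random.
#'   0 is fully polysomic (random chromosomal pairing), 1 with partner sets
#'   of size two is strict disomy.
#' @param partner_sets List (one element per homology group) of lists of
#'   integer vectors partitioning homologue indices into preferential
#'   pairing subsets. Every subset must have even size. `NULL` disables
#'   preferential pairing regardless of `pairing_preference`.
#' @param missing_rate Per-call probability of a missing genotype.
#' @param subset_scored_fraction Fraction of markers scored only on a
#'   reduced progeny panel (all other progeny set to missing).
#' @param subset_panel_size Size of the reduced panel.
#' @param anchor_families_per_hg Number of multi-allelic anchor (locus)
#'   families seeded per homology group. Each family places single-dose
#'   alleles at a homologous position on several homologues.
#' @param anchor_allele_range Integer range (length 2) for the number of
#'   alleles per anchor family; capped at the homologue count.
#' @param anchor_cross_hg_rate Probability that an anchor family places one
#'   additional allele in a different homology group (multi-locus family).
#' @param marker_positions Optional numeric vector of marker positions (cM)
#'   used for every homologue instead of uniform placement; recycled or
#'   truncated to `markers_per_homologue`. Mostly useful for controlled
#'   validation designs.
#' @param seed Integer seed; each downstream stage (parent construction,
#'   meiosis, missingness) derives its own stream from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_parent()], [generate_population()]
#' @export
#' @examples
#' cfg <- sim_config(n_homology_groups = 2, homologues_per_hg = 4,
#'                   markers_per_homologue = 5, n_progeny = 50, seed = 1)
sim_config <- function(n_homology_groups = 8L,
                       homologues_per_hg = NULL,
                       markers_per_homologue = 15L,
                       chromosome_length = 100,
                       n_progeny = 227L,
                       dosage_mix = c(SD = 0.79, DD = 0.155, TD = 0.055),
                       pairing_preference = 0,
                       partner_sets = NULL,
                       missing_rate = 0.02,
                       subset_scored_fraction = 0.14,
                       subset_panel_size = 94L,
                       anchor_families_per_hg = 8L,
                       anchor_allele_range = c(2L, 6L),
                       anchor_cross_hg_rate = 0.2,
                       marker_positions = NULL,
                       seed = 1L) {
  check_count <- function(x, field, min = 1) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min ||
        x != round(x)) {
      stop("invalid `", field, "`: must be a single integer >= ", min,
           call. = FALSE)
    }
    as.integer(x)
  }
  check_prob <- function(x, field) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      stop("invalid `", field, "`: must be a probability in [0, 1]",
           call. = FALSE)
    }
    as.numeric(x)
  }

  n_homology_groups <- check_count(n_homology_groups, "n_homology_groups")
  markers_per_homologue <- check_count(markers_per_homologue,
                                       "markers_per_homologue", min = 0)
  n_progeny <- check_count(n_progeny, "n_progeny")
  subset_panel_size <- check_count(subset_panel_size, "subset_panel_size")
  anchor_families_per_hg <- check_count(anchor_families_per_hg,
                                        "anchor_families_per_hg", min = 0)
  seed <- check_count(seed, "seed", min = 0)

  if (!is.null(homologues_per_hg)) {
    if (!is.numeric(homologues_per_hg) || anyNA(homologues_per_hg) ||
        any(homologues_per_hg < 2) ||
        any(homologues_per_hg != round(homologues_per_hg))) {
      stop("invalid `homologues_per_hg`: entries must be integers >= 2",
           call. = FALSE)
    }
    homologues_per_hg <- rep_len(as.integer(homologues_per_hg),
                                 n_homology_groups)
  }

  if (length(chromosome_length) != 1 || !is.numeric(chromosome_length) ||
      is.na(chromosome_length) || chromosome_length < 0) {
    stop("invalid `chromosome_length`: must be a single value >= 0",
         call. = FALSE)
  }

  if (length(dosage_mix) != 3 || !is.numeric(dosage_mix) ||
      anyNA(dosage_mix) || any(dosage_mix < 0) || any(dosage_mix > 1) ||
      abs(sum(dosage_mix) - 1) > 1e-8) {
    stop("invalid `dosage_mix`: three proportions in [0, 1] summing to 1",
         call. = FALSE)
  }
  names(dosage_mix) <- c("SD", "DD", "TD")

  pairing_preference <- check_prob(pairing_preference, "pairing_preference")
  missing_rate <- check_prob(missing_rate, "missing_rate")
  subset_scored_fraction <- check_prob(subset_scored_fraction,
                                       "subset_scored_fraction")
  anchor_cross_hg_rate <- check_prob(anchor_cross_hg_rate,
                                     "anchor_cross_hg_rate")

  if (!is.null(partner_sets)) {
    if (!is.list(partner_sets) ||
        length(partner_sets) != n_homology_groups) {
      stop("invalid `partner_sets`: must be a list with one element per ",
           "homology group", call. = FALSE)
    }
    if (is.null(homologues_per_hg)) {
      stop("invalid `partner_sets`: requires explicit `homologues_per_hg`",
           call. = FALSE)
    }
    for (h in seq_along(partner_sets)) {
      sets <- partner_sets[[h]]
      if (!is.list(sets)) stop("invalid `partner_sets`: element ", h,
                               " is not a list of integer vectors",
                               call. = FALSE)
      idx <- sort(unlist(sets))
      if (!identical(as.integer(idx), seq_len(homologues_per_hg[h]))) {
        stop("invalid `partner_sets`: sets for homology group ", h,
             " must partition 1..", homologues_per_hg[h], call. = FALSE)
      }
      if (any(lengths(sets) %% 2 != 0)) {
        stop("invalid `partner_sets`: sets for homology group ", h,
             " must have even sizes (bivalent pairing needs partners)",
             call. = FALSE)
      }
    }
  }

  if (length(anchor_allele_range) != 2 ||
      !is.numeric(anchor_allele_range) ||
      any(anchor_allele_range < 2) ||
      anchor_allele_range[1] > anchor_allele_range[2]) {
    stop("invalid `anchor_allele_range`: two integers >= 2, low <= high",
         call. = FALSE)
  }

  if (!is.null(marker_positions)) {
    if (!is.numeric(marker_positions) || anyNA(marker_positions) ||
        any(marker_positions < 0) ||
        any(marker_positions > chromosome_length)) {
      stop("invalid `marker_positions`: values must lie in [0, ",
           "chromosome_length]", call. = FALSE)
    }
  }

  structure(
    list(
      n_homology_groups = n_homology_groups,
      homologues_per_hg = homologues_per_hg,
      markers_per_homologue = markers_per_homologue,
      chromosome_length = as.numeric(chromosome_length),
      n_progeny = n_progeny,
      dosage_mix = dosage_mix,
      pairing_preference = pairing_preference,
      partner_sets = partner_sets,
      missing_rate = missing_rate,
      subset_scored_fraction = subset_scored_fraction,
      subset_panel_size = subset_panel_size,
      anchor_families_per_hg = anchor_families_per_hg,
      anchor_allele_range = as.integer(anchor_allele_range),
      anchor_cross_hg_rate = anchor_cross_hg_rate,
      marker_positions = marker_positions,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Autopolyploid cross simulation config\n")
  cat("  homology groups:", x$n_homology_groups, "\n")
  cat("  homologues/HG:  ",
      if (is.null(x$homologues_per_hg)) "drawn 13-23"
      else paste(x$homologues_per_hg, collapse = " "), "\n")
  cat("  progeny:        ", x$n_progeny, "\n")
  cat("  dosage mix:     ",
      paste(names(x$dosage_mix), x$dosage_mix, sep = "=", collapse = " "),
      "\n")
  cat("  pairing pref.:  ", x$pairing_preference, "\n")
  cat("  seed:           ", x$seed, "\n")
  invisible(x)
}
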