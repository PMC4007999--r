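#' Pipeline configuration
#'
#' Collects and validates every threshold of the mapping pipeline. All
#' values that drive stage behaviour are configurable here; nothing is
#' hard-coded downstream.
#'
#' @param genotypes Path to the genotype CSV ([read_genotypes()] dialect).
#' @param metadata Optional path to the metadata TSV sidecar.
#' @param out_dir Output directory for the report bundle.
#' @param ploidy Even ploidy of the informative parent.
#' @param alpha Chi-square significance level for dosage classification.
#' @param q_min,call_rate_min Quality-filter thresholds.
#' @param dup_min_overlap Minimum shared progeny to merge duplicates.
#' @param lod_min,rf_max Linkage grouping thresholds (inclusive).
#' @param framework_min_scored Minimum scored progeny for framework
#'   markers.
#' @param min_informative Minimum shared progeny per pairwise estimate.
#' @param repulsion_lod_min Repulsion LOD threshold.
#' @param repulsion_min_pairs,repulsion_min_span Repulsion acceptance rule.
#' @param min_shared_anchors Anchor families required to join two LGs.
#' @param cluster_window,cluster_min_markers Marker-cluster definition.
#' @param seed Integer seed (mandatory; recorded in the run manifest).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, metadata = NULL,
                            out_dir = "sdmap_out",
                            ploidy = 8, alpha = 0.05,
                            q_min = 80, call_rate_min = 0.8,
                            dup_min_overlap = 50,
                            lod_min = 10, rf_max = 0.35,
                            framework_min_scored = 188,
                            min_informative = 30,
                            repulsion_lod_min = 5,
                            repulsion_min_pairs = 3,
                            repulsion_min_span = 0.3,
                            min_shared_anchors = 2,
                            cluster_window = 10, cluster_min_markers = 5,
                            seed = 1L) {
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  chk(ploidy %% 2 == 0 && ploidy >= 4, "`ploidy` must be even and >= 4")
  chk(alpha > 0 && alpha < 1, "`alpha` must be in (0, 1)")
  chk(rf_max > 0 && rf_max <= 0.5,
      "`rf_max` must be in (0, 0.5]")
  chk(lod_min >= 0, "`lod_min` must be >= 0")
  chk(repulsion_lod_min >= 0, "`repulsion_lod_min` must be >= 0")
  chk(repulsion_min_span >= 0 && repulsion_min_span <= 1,
      "`repulsion_min_span` must be in [0, 1]")
  chk(call_rate_min >= 0 && call_rate_min <= 1,
      "`call_rate_min` must be in [0, 1]")
  chk(length(seed) == 1 && is.numeric(seed) && seed == round(seed),
      "`seed` is mandatory and must be a single integer")
  structure(as.list(environment())[setdiff(names(formals()), "")],
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML key-value file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return Validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full single-dose mapping pipeline
#'
#' Executes, in order: quality filtering, dosage scoring (keeping SD and
#' SD_skewed markers for mapping), duplicate collapsing, the two-stage map
#' build, homology-group assembly from anchor families, repulsion
#' detection, difference ratios and the pairing summary. Every artifact is
#' written as TSV into `config$out_dir` together with a YAML run manifest
#' (config echo, package version, seed, stage counts). Stage failures
#' abort with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param mm Optionally, an in-memory [marker_matrix()] instead of
#'   `config$genotypes`.
#' @return Invisibly, a list with every intermediate result (`scores`,
#'   `map`, `assignment`, `hg_table`, `repulsion`, `dratios`, `pairing`).
#' @export
run_pipeline <- function(config, mm = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_n <- function(name, n_in, n_out) {
    message(sprintf("[%s] %d in -> %d out", name, n_in, n_out))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (is.null(mm)) {
    if (is.null(config$genotypes)) {
      stop("either `mm` or config$genotypes is required", call. = FALSE)
    }
    mm <- stage("read_genotypes",
                read_genotypes(config$genotypes, config$metadata))
  }
  n0 <- nrow(mm$calls)

  mm_q <- stage("quality_filter",
                quality_filter(mm, config$q_min, config$call_rate_min))
  log_n("quality_filter", n0, nrow(mm_q$calls))

  scores <- stage("score_markers",
                  score_markers(mm_q, ploidy = config$ploidy,
                                alpha = config$alpha,
                                min_informative = config$min_informative))
  sd_ids <- scores$marker[scores$class %in% c("SD", "SD_skewed")]
  mm_sd <- subset_markers(mm_q, sd_ids)
  log_n("dosage_filter", nrow(mm_q$calls), nrow(mm_sd$calls))

  mm_uni <- stage("collapse_duplicates",
                  collapse_duplicates(mm_sd, config$dup_min_overlap))
  log_n("collapse_duplicates", nrow(mm_sd$calls), nrow(mm_uni$calls))

  map <- stage("two_stage_build", two_stage_build(
    mm_uni, lod_min = config$lod_min, rf_max = config$rf_max,
    framework_min_scored = config$framework_min_scored,
    min_informative = config$min_informative))
  log_n("two_stage_build", nrow(mm_uni$calls), nrow(map$map))

  anchors <- stage("anchor_families", anchor_families(map, mm_uni$meta))
  asm <- stage("assemble_hgs", assemble_hgs(
    unique(map$map$lg), anchors, min_shared = config$min_shared_anchors))
  hg_table <- stage("hg_summary", hg_summary(asm$assignment, map))

  repulsion <- stage("detect_repulsion", detect_repulsion(
    mm_uni, map, lod_min = config$repulsion_lod_min,
    min_pairs = config$repulsion_min_pairs,
    min_span = config$repulsion_min_span,
    min_informative = config$min_informative))
  dratios <- stage("difference_ratio",
                   hg_difference_ratios(map, mm_uni$meta, asm$assignment))
  pairing <- stage("pairing_summary",
                   pairing_summary(repulsion, dratios, asm$assignment))

  clusters <- stage("cluster_fraction", cluster_fraction(
    map, window = config$cluster_window,
    min_markers = config$cluster_min_markers))

  wt <- function(x, name) {
    utils::write.table(x, file.path(config$out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "NA")
  }
  wt(scores, "dosage_report.tsv")
  write_map(map, file.path(config$out_dir, "map.tsv"), meta = mm_uni$meta)
  wt(asm$assignment, "hg_assignment.tsv")
  wt(hg_table, "hg_summary.tsv")
  wt(as.data.frame(repulsion), "repulsion_links.tsv")
  wt(dratios, "difference_ratios.tsv")
  wt(pairing$per_hg, "pairing_summary.tsv")
  write_loc(mm_uni, file.path(config$out_dir, "markers.loc"))

  manifest <- list(
    package = "sdmap",
    version = as.character(utils::packageVersion("sdmap")),
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))],
    counts = list(input = n0, quality_pass = nrow(mm_q$calls),
                  single_dose = nrow(mm_sd$calls),
                  unique = nrow(mm_uni$calls), mapped = nrow(map$map),
                  linkage_groups = length(map$lgs),
                  homology_groups = length(asm$hgs))
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(matrix = mm_uni, scores = scores, map = map,
                 anchors = anchors, assignment = asm$assignment,
                 hgs = asm$hgs, hg_table = hg_table,
                 repulsion = repulsion, dratios = dratios,
                 pairing = pairing, clusters = clusters))
}
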