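test_that("matrix inversion swaps phase and is an involution", {
  calls <- matrix(c(1L, 0L, NA, 0L, 1L, 1L), 2, 3,
                  dimnames = list(c("a", "b"), sprintf("P%d", 1:3)))
  mm <- marker_matrix(calls)
  inv <- invert_matrix(mm)
  expect_equal(unname(inv$calls[1, ]), c(0L, NA, 0L))
  expect_equal(rownames(inv$calls), c("a_r", "b_r"))
  back <- invert_matrix(inv, suffix = "")
  expect_equal(unname(back$calls), unname(mm$calls))
})

test_that("repulsion LOD equals coupling LOD after complementing one marker", {
  set.seed(61)
  for (r in 1:20) {
    a <- rbinom(120, 1, 0.5)
    b <- rbinom(120, 1, 0.5)
    a[sample(120, 10)] <- NA
    rep_est <- two_point(a, 1L - b)
    coup_est <- two_point(a, b)
    # complementing flips discordance: rf_rep = 1 - discord(a, b) capped
    expect_equal(rep_est$lod, two_point(1L - a, b)$lod)
    expect_equal(rep_est$n_informative, coup_est$n_informative)
  }

  # a marker and its exact complement are in perfect repulsion
  x <- rep(c(1L, 0L), 50)
  est <- two_point(x, 1L - (1L - x))  # inverted complement = coupling
  expect_equal(est$lod, 100 * log10(2), tolerance = 1e-10)
  perfect <- two_point(x, 1L - x)
  expect_equal(perfect$rf, 0.5)  # fully discordant before inversion (capped)
  expect_equal(two_point(x, 1L - (1L - x))$rf, 0)
})

test_that("strict disomic partners are detected in repulsion, polysomic octoploids are not", {
  # strict disomy: partner sets of size 2, preference 1
  cfg_dis <- quick_config(homologues_per_hg = 8L,
                          markers_per_homologue = 10L,
                          marker_positions = seq(5, 95, by = 10),
                          pairing_preference = 1,
                          partner_sets = list(list(1:2, 3:4, 5:6, 7:8)),
                          n_progeny = 227L, seed = 71L)
  pop <- generate_population(cfg_dis)
  map <- suppressMessages(two_stage_build(pop$matrix))
  expect_length(map$lgs, 8)
  rep_links <- detect_repulsion(pop$matrix, map, lod_min = 5)
  acc <- rep_links[rep_links$accepted, ]
  expect_gt(nrow(acc), 0)

  # every accepted link joins true pairing partners
  hom_of_lg <- vapply(split(map$map$marker, map$map$lg), function(mk) {
    pop$truth$homologue[match(mk[1], pop$truth$marker)]
  }, integer(1))
  partner_key <- c(2L, 1L, 4L, 3L, 6L, 5L, 8L, 7L)
  for (i in seq_len(nrow(acc))) {
    h1 <- hom_of_lg[[acc$lg1[i]]]
    h2 <- hom_of_lg[[acc$lg2[i]]]
    expect_equal(h2, partner_key[h1])
  }
  # all four partner pairs are recovered
  found <- unique(apply(cbind(hom_of_lg[acc$lg1], hom_of_lg[acc$lg2]), 1,
                        function(z) paste(sort(z), collapse = "-")))
  expect_setequal(found, c("1-2", "3-4", "5-6", "7-8"))

  # fully polysomic octoploid control: no accepted repulsion
  cfg_pol <- quick_config(homologues_per_hg = 8L,
                          markers_per_homologue = 10L,
                          marker_positions = seq(5, 95, by = 10),
                          pairing_preference = 0,
                          n_progeny = 227L, seed = 72L)
  pop2 <- generate_population(cfg_pol)
  map2 <- suppressMessages(two_stage_build(pop2$matrix))
  rep2 <- detect_repulsion(pop2$matrix, map2, lod_min = 5)
  expect_equal(sum(rep2$accepted), 0)
})

test_that("repulsion detection power increases with pairing preference", {
  n_acc <- vapply(c(0, 0.5, 1), function(pref) {
    total <- 0
    for (r in 1:15) {
      cfg <- quick_config(homologues_per_hg = 8L,
                          markers_per_homologue = 8L,
                          marker_positions = seq(10, 80, by = 10),
                          pairing_preference = pref,
                          partner_sets = list(list(1:2, 3:4, 5:6, 7:8)),
                          n_progeny = 227L, seed = 400L + r)
      pop <- generate_population(cfg)
      map <- suppressMessages(two_stage_build(pop$matrix))
      links <- detect_repulsion(pop$matrix, map, lod_min = 5)
      total <- total + sum(links$accepted)
    }
    total
  }, numeric(1))
  expect_lte(n_acc[1], n_acc[2])
  expect_lte(n_acc[2], n_acc[3])
  expect_lt(n_acc[1], n_acc[3])
})

test_that("difference ratio reproduces worked single-interval examples", {
  # one shared interval: 12.1 cM on the reference, 4.8 cM on the compared
  dr1 <- difference_ratio(12.1, 4.8)
  expect_equal(dr1$sum_abs_diff, 7.3)
  expect_equal(dr1$sum_total, 16.9)
  expect_equal(dr1$ratio, 7.3 / 16.9)
  expect_equal(round(dr1$ratio, 1), 0.4)

  dr2 <- difference_ratio(17.1, 24.6)
  expect_equal(dr2$sum_abs_diff, 7.5)
  expect_equal(dr2$sum_total, 41.7)
  expect_equal(round(dr2$ratio, 1), 0.2)

  # identical interval structure gives ratio 0
  expect_equal(difference_ratio(c(5, 10, 3), c(5, 10, 3))$ratio, 0)
  expect_error(difference_ratio(c(1, 2), 3), "equal")
  expect_error(difference_ratio(-1, 1), "non-negative")
})

test_that("map-level difference ratio uses shared families in reference order", {
  map <- data.frame(
    lg = c(rep("LGA", 4), rep("LGB", 3)),
    marker = c("a1", "a2", "a3", "a4", "b1", "b2", "b3"),
    position = c(0, 10, 25, 30, 0, 4, 10))
  meta <- data.frame(marker = c("a1", "a2", "a3", "a4", "b1", "b2", "b3"),
                     family = c("F1", "F2", "F3", NA, "F1", "F2", "F3"))
  dr <- lg_difference_ratio(map, meta, "LGA", "LGB")
  expect_equal(dr$k, 2)
  expect_equal(dr$ref_intervals, c(10, 15))
  expect_equal(dr$cmp_intervals, c(4, 6))
  expect_equal(dr$ratio, (6 + 9) / (25 + 10))

  # order conflict on the compared LG: interval skipped with a message
  meta2 <- meta
  map2 <- map
  map2$position[map2$marker == "b2"] <- 12   # b2 now after b3
  expect_message(dr2 <- lg_difference_ratio(map2, meta2, "LGA", "LGB"),
                 "conflicting order")
  expect_equal(dr2$k, 1)

  # fewer than two shared families: NULL with a message
  meta3 <- data.frame(marker = map$marker,
                      family = c("F1", NA, NA, NA, "F1", NA, NA))
  expect_message(dr3 <- lg_difference_ratio(map, meta3, "LGA", "LGB"),
                 "no shared")
  expect_null(dr3)
})

test_that("identical simulated homologues give difference ratio 0", {
  map <- data.frame(
    lg = c(rep("LG1", 3), rep("LG2", 3)),
    marker = c("p1", "p2", "p3", "q1", "q2", "q3"),
    position = c(0, 8, 20, 0, 8, 20))
  meta <- data.frame(marker = map$marker,
                     family = rep(c("F1", "F2", "F3"), 2))
  dr <- lg_difference_ratio(map, meta, "LG1", "LG2")
  expect_equal(dr$ratio, 0)
})

test_that("pairing summary computes per-HG rates and least-squares R^2", {
  assignment <- data.frame(
    lg = sprintf("LG%d", 1:8),
    hg = rep(c("HG1", "HG2", "HG3", "HG4"), each = 2))
  links <- data.frame(lg1 = c("LG1", "LG3"), lg2 = c("LG2", "LG4"),
                      best_lod = c(10, 8), n_support = c(5, 4),
                      span1 = 1, span2 = 1, accepted = c(TRUE, FALSE))
  dr <- data.frame(hg = c("HG1", "HG2", "HG3", "HG4"),
                   ratio = c(0.8, 0.3, 0.1, 0.5))
  ps <- pairing_summary(links, dr, assignment)
  expect_equal(ps$per_hg$pct_in_repulsion,
               c(100, 0, 0, 0))
  expect_equal(ps$per_hg$mean_diff_ratio, c(0.8, 0.3, 0.1, 0.5))
  expect_equal(ps$r_squared,
               r_squared_oracle(c(0.8, 0.3, 0.1, 0.5), c(100, 0, 0, 0)))
  expect_equal(ps$r_squared,
               summary(stats::lm(c(100, 0, 0, 0) ~
                                   c(0.8, 0.3, 0.1, 0.5)))$r.squared)

  # perfectly collinear summaries give R^2 = 1
  links2 <- links[0, ]
  dr2 <- data.frame(hg = c("HG1", "HG2", "HG3"), ratio = c(0.1, 0.2, 0.3))
  assignment2 <- assignment[1:6, ]
  ps2 <- pairing_summary(links2, dr2, assignment2)
  expect_equal(ps2$per_hg$pct_in_repulsion, c(0, 0, 0))
  # zero-variance response: R^2 via lm is NaN; construct collinear case
  links3 <- data.frame(lg1 = c("LG3", "LG5"), lg2 = c("LG4", "LG6"),
                       best_lod = 10, n_support = 5, span1 = 1, span2 = 1,
                       accepted = TRUE)
  dr3 <- data.frame(hg = c("HG1", "HG2", "HG3"), ratio = c(0.1, 0.5, 0.5))
  ps3 <- pairing_summary(links3, dr3, assignment2)
  expect_equal(ps3$per_hg$pct_in_repulsion, c(0, 100, 100))
  expect_equal(ps3$r_squared, 1)

  # fewer than 3 HGs with both statistics: R^2 omitted
  dr4 <- dr3[1:2, ]
  expect_message(ps4 <- pairing_summary(links3, dr4, assignment2),
                 "fewer than 3")
  expect_true(is.na(ps4$r_squared))

  # known regression noise matches the closed form
  set.seed(77)
  x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  y <- 20 + 60 * x + rnorm(5, 0, 5)
  fit_r2 <- summary(stats::lm(y ~ x))$r.squared
  expect_equal(fit_r2, r_squared_oracle(x, y))
})

test_that("disomic partner LGs show larger difference ratios between partner sets than within", {
  # two partner sets of two homologues each; strict disomy makes homologues
  # within one bivalent share recombination structure only via the anchors
  cfg <- quick_config(homologues_per_hg = 4L, markers_per_homologue = 6L,
                      pairing_preference = 1,
                      partner_sets = list(list(1:2, 3:4)),
                      anchor_families_per_hg = 6L,
                      anchor_allele_range = c(4L, 4L),
                      n_progeny = 227L, seed = 81L)
  pop <- generate_population(cfg)
  map <- suppressMessages(two_stage_build(pop$matrix))
  expect_length(map$lgs, 4)
  hom_of_lg <- vapply(split(map$map$marker, map$map$lg), function(mk) {
    pop$truth$homologue[match(mk[1], pop$truth$marker)]
  }, integer(1))
  lg_of_hom <- stats::setNames(names(hom_of_lg), hom_of_lg)
  ratios <- matrix(NA_real_, 4, 4)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      dr <- suppressMessages(
        lg_difference_ratio(map, pop$matrix$meta,
                            lg_of_hom[[as.character(i)]],
                            lg_of_hom[[as.character(j)]]))
      if (!is.null(dr)) ratios[i, j] <- dr$ratio
    }
  }
  within <- c(ratios[1, 2], ratios[3, 4])
  between <- c(ratios[1, 3], ratios[1, 4], ratios[2, 3], ratios[2, 4])
  expect_true(mean(within, na.rm = TRUE) <= mean(between, na.rm = TRUE))
})
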