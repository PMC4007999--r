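# Shared fixtures and independent oracles used across the suite.

# A small, fast simulation config; override fields as needed.
quick_config <- function(...) {
  args <- utils::modifyList(
    list(n_homology_groups = 1L, homologues_per_hg = 4L,
         markers_per_homologue = 6L, chromosome_length = 100,
         n_progeny = 100L, dosage_mix = c(SD = 1, DD = 0, TD = 0),
         pairing_preference = 0, missing_rate = 0,
         subset_scored_fraction = 0, anchor_families_per_hg = 0L,
         anchor_cross_hg_rate = 0, seed = 1L),
    list(...))
  do.call(sim_config, args)
}

# Exhaustive SARF minimisation: the ordering oracle for small groups.
exhaustive_order <- function(rf) {
  ids <- rownames(rf)
  D <- rf
  D[is.na(D)] <- 0.49999
  diag(D) <- 0
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_s <- Inf
  for (p in perms(ids)) {
    s <- sum(D[cbind(p[-length(p)], p[-1])])
    if (s < best_s - 1e-12) {
      best <- p
      best_s <- s
    }
  }
  list(order = best, sarf = best_s)
}

# Closed-form simple-regression R^2 (oracle for pairing_summary).
r_squared_oracle <- function(x, y) {
  ssr <- sum((y - mean(y)) * (x - mean(x)))^2 / sum((x - mean(x))^2)
  ssr / sum((y - mean(y))^2)
}

# Chi-square statistic against an arbitrary present:absent ratio, by hand.
chisq_oracle <- function(np, na, p) {
  n <- np + na
  (np - n * p)^2 / (n * p) + (na - n * (1 - p))^2 / (n * (1 - p))
}
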