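# Shared fixtures, built in code. Heavier simulated cohorts are memoised in
# this environment so several test files can reuse them.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small universe + cohort with a strong planted signal, for workflow tests.
small_signal_cohort <- function() {
  memo("small_signal", {
    u <- simulate_gene_universe(300, n_chromosomes = 2, seed = 42)
    occ <- occupancy_model(u, depletion_depth = 0.6)
    planted <- u$transcripts$transcript_id[seq(10, 100, by = 10)]
    sp <- cohort_spec(14, 14, planted_promoters = planted, effect_lfc = 1.5,
                      fragments_per_sample = 40000, seed = 11)
    co <- simulate_cohort(u, occ, sp)
    w <- build_ptss_windows(u$transcripts, chrom_sizes = u$chrom_sizes)
    cov <- build_coverage_matrix(co$fragments, w, co$metadata)
    list(universe = u, occupancy = occ, spec = sp, cohort = co,
         windows = w, cov = cov, planted = planted)
  })
}

# Coverage tibble built directly from a value matrix (no simulation).
toy_cov <- function(values, labels, sample_ids = NULL, bmi = NULL) {
  n <- nrow(values)
  ids <- sample_ids %||% sprintf("S%03d", seq_len(n))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = ids, label = labels,
                   bmi = bmi %||% rep(22, n)),
    tibble::as_tibble(values, .name_repair = "minimal"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force oracles ---------------------------------------------------

# AUC as the Mann-Whitney U over all case/control pairs, ties counting 1/2.
brute_force_auc <- function(probs, y) {
  p1 <- probs[y]
  p0 <- probs[!y]
  s <- 0
  for (a in p1) for (b in p0) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(p1) * length(p0))
}

# Exhaustive optimal-cutoff search over all candidates and both directions.
brute_force_cutoff <- function(values, y) {
  u <- sort(unique(values))
  cand <- if (length(u) == 1) c(u - 1, u + 1) else
    c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  best_score <- -Inf
  best_cut <- NA
  for (cc in cand) {
    pred <- values > cc
    ba <- (mean(pred[y]) + mean(!pred[!y])) / 2
    sc <- max(ba, 1 - ba)
    if (sc > best_score + 1e-12) {
      best_score <- sc
      best_cut <- cc
    }
  }
  list(cutoff = best_cut, score = best_score)
}

# Exact two-sided rank-sum p by enumerating every labeling of the pooled
# (tie-free) values.
enumerate_ranksum_p <- function(case_values, control_values) {
  m <- length(case_values)
  pooled <- c(case_values, control_values)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(length(pooled), m)
  us <- apply(idx, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  centre <- m * length(control_values) / 2
  mean(abs(us - centre) >= abs(obs - centre) - 1e-9)
}

# ---- Acceptance-scale fixtures (memoised; shared across acceptance checks) --

# Signal cohort at study scale: 2000 promoters, 40 cases + 40 controls,
# 50 planted promoters at log2FC 1.5, ~0.5x genome coverage.
acc_signal <- function() {
  memo("acc_signal", {
    u <- simulate_gene_universe(2000, n_chromosomes = 4, seed = 11)
    occ <- occupancy_model(u, depletion_depth = 0.6)
    planted <- u$transcripts$transcript_id[seq(1, 2000, by = 40)]
    sp <- cohort_spec(40, 40, planted_promoters = planted, effect_lfc = 1.5,
                      fragments_per_sample = round(0.003 * sum(u$chrom_sizes)),
                      seed = 11)
    co <- simulate_cohort(u, occ, sp)
    w <- build_ptss_windows(u$transcripts, chrom_sizes = u$chrom_sizes)
    cov <- build_coverage_matrix(co$fragments, w, co$metadata)
    list(universe = u, occupancy = occ, spec = sp, windows = w,
         cov = cov, planted = planted)
  })
}

acc_differential <- function() {
  memo("acc_differential", {
    fx <- acc_signal()
    select_differential(fx$cov, windows = fx$windows)
  })
}

# Independent validation cohort from the same generative parameters.
acc_validation_cov <- function() {
  memo("acc_validation", {
    fx <- acc_signal()
    sp2 <- fx$spec
    sp2$seed <- 77L
    co2 <- simulate_cohort(fx$universe, fx$occupancy, sp2)
    co2$metadata$sample_id <- paste0("V", co2$metadata$sample_id)
    names(co2$fragments) <- co2$metadata$sample_id
    co2$metadata$cohort <- "internal_validation"
    build_coverage_matrix(co2$fragments, fx$windows, co2$metadata)
  })
}

# Mechanism cohort: 1000 genes, 20 healthy samples, ~1x coverage for
# stable per-base metagene profiles.
mech_cohort <- function() {
  memo("mech_cohort", {
    u <- simulate_gene_universe(1000, n_chromosomes = 2, seed = 5)
    occ <- occupancy_model(u, depletion_depth = 0.6)
    sp <- cohort_spec(10, 10, effect_lfc = 0,
                      fragments_per_sample = round(0.006 * sum(u$chrom_sizes)),
                      seed = 5)
    co <- simulate_cohort(u, occ, sp)
    w <- build_ptss_windows(u$transcripts, chrom_sizes = u$chrom_sizes)
    list(universe = u, occupancy = occ, cohort = co, windows = w)
  })
}
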