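test_that("gene universe is deterministic and its rank sets are well formed", {
  u1 <- simulate_gene_universe(100, n_chromosomes = 2, seed = 7)
  u2 <- simulate_gene_universe(100, n_chromosomes = 2, seed = 7)
  expect_identical(u1$transcripts, u2$transcripts)
  expect_identical(u1$expression, u2$expression)
  expect_identical(u1$gene_sets, u2$gene_sets)

  u <- simulate_gene_universe(1000, n_chromosomes = 2, seed = 1)
  expect_equal(nrow(u$transcripts), 1000)
  expect_length(u$gene_sets$top500, 500)
  expect_length(u$gene_sets$bottom500, 500)
  expect_length(intersect(u$gene_sets$top500, u$gene_sets$bottom500), 0)
  expect_true(all(unlist(u$gene_sets) %in% u$transcripts$transcript_id))
  expect_true(all(u$expression$placenta >= 0 & u$expression$blood >= 0))
  expect_setequal(unique(u$transcripts$strand), c("+", "-"))
  # top500 really are the 500 largest placental expression values
  thr <- sort(u$expression$placenta, decreasing = TRUE)[500]
  top_expr <- u$expression$placenta[match(u$gene_sets$top500,
                                          u$expression$transcript_id)]
  expect_true(all(top_expr >= thr))

  expect_error(simulate_gene_universe(5), ">= 10")
  expect_error(simulate_gene_universe(-3), ">= 10")
})

test_that("TSSs on the same chromosome are at least 10 kb apart", {
  u <- simulate_gene_universe(100, n_chromosomes = 2, seed = 7)
  for (ch in unique(u$transcripts$chrom)) {
    tss <- sort(u$transcripts$tss[u$transcripts$chrom == ch])
    d <- outer(tss, tss, function(a, b) abs(a - b))
    expect_true(all(d[upper.tri(d)] >= 10000))
  }
})

test_that("fragments are conserved: exact count, declared chromosomes, valid intervals", {
  u <- simulate_gene_universe(50, seed = 2)
  occ <- occupancy_model(u, depletion_depth = 0.4)
  sp <- cohort_spec(1, 1, fragments_per_sample = 5000, seed = 5)
  fr <- simulate_sample_fragments(u, occ, sp, sample_seed = 9)
  expect_equal(nrow(fr), 5000)
  expect_equal(total_mapped(fr), 5000)
  expect_true(all(fr$chrom %in% names(u$chrom_sizes)))
  expect_true(all(fr$start < fr$end))
  expect_true(all(fr$start >= 0))
  expect_true(all(fr$end <= u$chrom_sizes[fr$chrom]))
  # deterministic per sample seed
  fr2 <- simulate_sample_fragments(u, occ, sp, sample_seed = 9)
  expect_identical(fr, fr2)
})

test_that("no depletion gives flat promoter coverage; full depletion obeys the thinning model", {
  u <- simulate_gene_universe(30, n_chromosomes = 1, seed = 4)
  w <- build_ptss_windows(u$transcripts, chrom_sizes = u$chrom_sizes)
  sp <- cohort_spec(1, 1, placental_fraction = 1,
                    fragments_per_sample = 60000, seed = 3)

  depth_ratio <- function(occ, tid, n_samples = 12, centre_idx = 900:1100) {
    win <- w[w$transcript_id == tid, ]
    centre <- flank <- 0
    for (i in seq_len(n_samples)) {
      fr <- simulate_sample_fragments(u, occ, sp, sample_seed = 100 + i)
      d <- per_base_depth(fr, win)
      centre <- centre + mean(d[centre_idx])
      # 10-kb flanks on both sides of the window
      fw <- win
      fw$window_start <- win$window_start - 10000
      fw$window_end <- win$window_end + 10000
      df <- per_base_depth(fr, fw)
      flank <- flank + mean(df[c(1:9000, 13001:22000)])
    }
    centre / flank
  }

  top_id <- u$gene_sets$top500[1]  # placental activity percentile ~ 1
  occ0 <- occupancy_model(u, depletion_depth = 0)
  # no dip anywhere: the whole window matches the flanks
  expect_lt(abs(depth_ratio(occ0, top_id, centre_idx = 1:2000) - 1), 0.04)

  occ6 <- occupancy_model(u, depletion_depth = 0.6)
  expect_lt(abs(depth_ratio(occ6, top_id, n_samples = 25) - 0.4), 0.06)
})

test_that("dip strength scales with the placental mixture fraction", {
  u <- simulate_gene_universe(30, n_chromosomes = 1, seed = 4)
  w <- build_ptss_windows(u$transcripts, chrom_sizes = u$chrom_sizes)
  occ <- occupancy_model(u, depletion_depth = 0.6)
  # a placenta-only gene: active in placenta, silent in blood
  ps <- u$gene_sets$placenta_specific
  act <- occ$activity[match(ps, occ$activity$transcript_id), ]
  tid <- act$transcript_id[which.max(act$placenta)]
  expect_equal(act$blood[which.max(act$placenta)], 0)
  a_p <- act$placenta[which.max(act$placenta)]

  sp <- cohort_spec(1, 1, placental_fraction = 0.10,
                    fragments_per_sample = 100000, seed = 3)
  win <- w[w$transcript_id == tid, ]
  centre <- base <- 0
  for (i in seq_len(30)) {
    fr <- simulate_sample_fragments(u, occ, sp, sample_seed = 300 + i)
    d <- per_base_depth(fr, win)
    centre <- centre + mean(d[750:1250])
    fw <- win
    fw$window_start <- win$window_start - 10000
    fw$window_end <- win$window_end + 10000
    df <- per_base_depth(fr, fw)
    base <- base + mean(df[c(1:9000, 13001:22000)])
  }
  observed_dip <- 1 - centre / base
  expect_lt(abs(observed_dip - 0.10 * 0.6 * a_p), 0.02)
})

test_that("cohort simulation validates planted promoters and honours the null", {
  u <- simulate_gene_universe(50, seed = 2)
  occ <- occupancy_model(u)
  expect_error(
    simulate_cohort(u, occ, cohort_spec(2, 2, planted_promoters = "nope",
                                        effect_lfc = 1,
                                        fragments_per_sample = 100)),
    "absent")
  # effect_lfc = 0: the planted set is empty in the truth record
  co <- simulate_cohort(u, occ, cohort_spec(
    2, 2, planted_promoters = u$transcripts$transcript_id[1],
    effect_lfc = 0, fragments_per_sample = 1000, seed = 8))
  expect_length(co$truth$planted_promoters, 0)
  expect_equal(co$metadata$label, c("case", "case", "control", "control"))
})

test_that("planted promoters realize approximately the target log2 fold change", {
  fx <- small_signal_cohort()
  d <- select_differential(fx$cov, windows = fx$windows)
  planted_lfc <- d$log2_fold_change[match(fx$planted, d$window)]
  expect_lt(abs(mean(planted_lfc) - 1.5), 0.3)
})

test_that("fixtures round-trip to disk deterministically", {
  u <- simulate_gene_universe(20, seed = 6)
  occ <- occupancy_model(u)
  sp <- cohort_spec(2, 2, fragments_per_sample = 500, seed = 13)
  co <- simulate_cohort(u, occ, sp)

  dir1 <- withr::local_tempdir()
  man1 <- write_fixtures(co, u, dir1)
  beds <- grep("\\.bed$", man1$file, value = TRUE)
  expect_length(beds, 4)
  for (b in beds) {
    expect_equal(length(readLines(file.path(dir1, b))), 500)
  }
  # truth record round-trips
  tr <- read_truth(file.path(dir1, "truth.json"))
  expect_equal(tr$effect_lfc, co$truth$effect_lfc)
  expect_equal(tr$planted_promoters, co$truth$planted_promoters)
  expect_equal(tr$fragments_per_sample, co$truth$fragments_per_sample)

  # regenerating with the same seed writes byte-identical files
  co2 <- simulate_cohort(u, occ, sp)
  dir2 <- withr::local_tempdir()
  man2 <- write_fixtures(co2, u, dir2)
  expect_identical(man1$md5, man2$md5)

  # empty cohort: annotation + metadata only
  man0 <- write_fixtures(NULL, u, withr::local_tempdir())
  expect_setequal(man0$file, c("annotation.refflat", "metadata.tsv"))
})
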