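one_window <- tibble::tibble(
  transcript_id = "W1", gene_symbol = "W1", chrom = "chr1", strand = "+",
  tss = 10000L, window_start = 9000L, window_end = 11000L,
  effective_length = 2000L)

frag <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(chrom = "chr1", start = m[, 1], end = m[, 2])
}

test_that("fragment counting uses >=1 bp overlap with half-open arithmetic", {
  expect_equal(unname(count_fragments_in_windows(frag(9500, 9700), one_window)), 1L)
  expect_equal(unname(count_fragments_in_windows(frag(8999, 9001), one_window)), 1L)
  # abutting half-open intervals do not overlap
  expect_equal(unname(count_fragments_in_windows(frag(8000, 9000), one_window)), 0L)
  expect_equal(unname(count_fragments_in_windows(frag(11000, 11200), one_window)), 0L)
  # a fragment overlapping two windows counts once in each
  w2 <- dplyr::bind_rows(one_window,
                         dplyr::mutate(one_window, transcript_id = "W2",
                                       window_start = 10500L,
                                       window_end = 12500L))
  n <- count_fragments_in_windows(frag(10900, 11100), w2)
  expect_equal(unname(n), c(1L, 1L))
})

test_that("fragments on unannotated chromosomes only warn and count toward the library", {
  fr <- tibble::tibble(chrom = c("chr1", "chrUn"), start = c(9500L, 10L),
                       end = c(9700L, 200L))
  expect_warning(n <- count_fragments_in_windows(fr, one_window),
                 "total_mapped")
  expect_equal(unname(n), 1L)
})

test_that("per-base depth matches a brute-force overlap oracle", {
  d <- per_base_depth(frag(9500, 9600), one_window)
  expect_length(d, 2000)
  expect_equal(sum(d), 100)
  expect_equal(sum(d == 1), 100)
  expect_equal(which(d == 1), 501:600)
  # additivity of identical fragments
  d2 <- per_base_depth(frag(9500, 9600, 9500, 9600), one_window)
  expect_equal(d2, 2L * d)

  withr::with_seed(5, {
    for (rep in 1:5) {
      n <- sample(100, 1)
      st <- sample(8000:11500, n, replace = TRUE)
      en <- st + sample(50:400, n, replace = TRUE)
      fr <- tibble::tibble(chrom = "chr1", start = st, end = en)
      d <- per_base_depth(fr, one_window)
      # brute force: loop over bases
      oracle <- vapply(9000:10999, function(b) sum(st <= b & en > b), 0L)
      expect_equal(d, oracle)
      expect_equal(sum(d), sum(pmax(0, pmin(en, 11000) - pmax(st, 9000))))
    }
  })
})

test_that("RPKM follows count * 1e9 / (length * library size)", {
  expect_equal(rpkm_normalize(10, 2000, 1e6), 5.0)
  expect_equal(rpkm_normalize(0, 2000, 123), 0.0)
  expect_equal(rpkm_normalize(2000, 2000, 2e7), 50.0)
  expect_error(rpkm_normalize(1, 2000, 0), "total_mapped")
  expect_error(rpkm_normalize(1, 0, 100), "window_length")
  # invariance under joint scaling; monotone in count
  expect_equal(rpkm_normalize(10, 2000, 1e6), rpkm_normalize(20, 2000, 2e6))
  expect_lt(rpkm_normalize(10, 2000, 1e6), rpkm_normalize(11, 2000, 1e6))
})

test_that("the coverage table is RPKM cell-by-cell and demands complete metadata", {
  meta <- tibble::tibble(sample_id = c("a", "b"),
                         label = c("case", "control"))
  samples <- list(a = frag(9100, 9300, 9500, 9700, 100, 200),
                  b = frag(500, 700))
  attr(samples$a, "total_mapped") <- 3L
  attr(samples$b, "total_mapped") <- 1L
  cov <- build_coverage_matrix(samples, one_window, meta)
  expect_equal(cov$W1, c(2 * 1e9 / (2000 * 3), 0))
  expect_equal(cov$sample_id, c("a", "b"))
  expect_error(build_coverage_matrix(samples, one_window,
                                     meta[1, , drop = FALSE]),
               "metadata missing")

  # doubling fragments and library size leaves RPKM unchanged
  samples2 <- lapply(samples, function(fr) {
    out <- dplyr::bind_rows(fr, fr)
    attr(out, "total_mapped") <- 2L * attr(fr, "total_mapped")
    out
  })
  cov2 <- build_coverage_matrix(samples2, one_window, meta)
  expect_equal(cov2$W1, cov$W1)

  # brute-force recount on a random fixture
  withr::with_seed(9, {
    st <- sample(7000:12000, 200, replace = TRUE)
    fr <- tibble::tibble(chrom = "chr1", start = st, end = st + 150L)
    oracle <- sum(st < 11000 & st + 150 > 9000)
    cov3 <- build_coverage_matrix(
      list(x = fr), one_window, tibble::tibble(sample_id = "x", label = "case"))
    expect_equal(cov3$W1, oracle * 1e9 / (2000 * 200))
  })
})

test_that("metagene profiles are flat under uniform coverage and mirror minus-strand genes", {
  withr::with_seed(31, {
    st <- sample(0:30000, 300000, replace = TRUE)
    fr <- tibble::tibble(chrom = "chr1", start = st, end = st + 160L)
  })
  prof <- metagene_profile(fr, one_window, bin_size = 100)
  expect_equal(nrow(prof), 20)
  expect_true(all(abs(prof$mean_relative_depth - 1) < 0.1))
  expect_true(all(diff(prof$position) > 0))

  # an asymmetric pile-up downstream of a minus-strand TSS lands at the
  # same signed offsets as its mirrored plus-strand construction
  wp <- one_window
  wm <- dplyr::mutate(one_window, strand = "-")
  offs <- 300:450  # downstream of the + TSS at 10000
  frp <- tibble::tibble(chrom = "chr1", start = 10000L + offs,
                        end = 10000L + offs + 10L)
  # mirrored fragments upstream of the same coordinate for the - gene:
  # base b downstream of a minus-strand TSS sits at tss - 1 - offset
  frm <- tibble::tibble(chrom = "chr1", start = 10000L - offs - 10L,
                        end = 10000L - offs)
  base <- tibble::tibble(chrom = "chr1", start = seq(8000L, 12000L, 5L),
                         end = seq(8000L, 12000L, 5L) + 160L)
  pp <- metagene_profile(dplyr::bind_rows(frp, base), wp)
  pm <- metagene_profile(dplyr::bind_rows(frm, base), wm)
  # the mirrored construction yields the identical oriented profile:
  # the pile-up sits at the same downstream offsets for both strands
  expect_equal(pm$mean_relative_depth, pp$mean_relative_depth,
               tolerance = 1e-8)

  expect_error(metagene_profile(fr, one_window, gene_set = "absent"),
               "empty gene set")
})

test_that("central/flank ratio summarizes a profile's dip", {
  prof <- tibble::tibble(position = -1000:999,
                         mean_relative_depth = c(rep(1, 900), rep(0.4, 200),
                                                 rep(1, 900)),
                         gene_set = "x", n_genes = 1L)
  class(prof) <- c("metagene_profile", class(prof))
  expect_lt(abs(central_flank_ratio(prof) - 0.4), 0.01)
})
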