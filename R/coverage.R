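#' @importFrom GenomicRanges GRanges countOverlaps
#' @importFrom IRanges IRanges coverage Views
NULL

# GRanges from a 0-based half-open fragment/window tibble; fragments on
# chromosomes absent from `seqlevels` are dropped with a warning (they still
# count toward total_mapped).
.to_gr <- function(tbl, start_col = "start", end_col = "end",
                   seqlevels = NULL) {
  chrom <- tbl$chrom
  if (!is.null(seqlevels)) {
    unknown <- !chrom %in% seqlevels
    if (any(unknown)) {
      warn(sprintf("%d fragment(s) on chromosome(s) absent from the annotation (%s) count toward total_mapped only",
                   sum(unknown),
                   paste(utils::head(unique(chrom[unknown]), 3), collapse = ", ")))
      tbl <- tbl[!unknown, , drop = FALSE]
      chrom <- tbl$chrom
    }
  }
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = tbl[[start_col]] + 1L,
                                          end = tbl[[end_col]]))
}

#' Count fragments overlapping each pTSS window
#'
#' A fragment is counted once in every window it overlaps by at least 1 bp
#' (0-based half-open arithmetic; abutting intervals do not overlap).
#'
#' @param fragments fragment tibble (chrom, start, end).
#' @param windows tibble from [build_ptss_windows()].
#' @return integer vector of counts, named by transcript_id.
#' @export
count_fragments_in_windows <- function(fragments, windows) {
  win_gr <- .to_gr(windows, "window_start", "window_end")
  frag_gr <- .to_gr(fragments, seqlevels = unique(windows$chrom))
  n <- GenomicRanges::countOverlaps(win_gr, frag_gr, minoverlap = 1L)
  names(n) <- windows$transcript_id
  n
}

#' Per-base read depth across one pTSS window
#'
#' `depth[i]` is the number of fragments covering base `window_start + i - 1`;
#' the sum over the window equals the total overlap length of all fragments.
#'
#' @param fragments fragment tibble.
#' @param window a single-row window tibble.
#' @return integer vector of length `effective_length`.
#' @export
per_base_depth <- function(fragments, window) {
  if (nrow(window) != 1) abort("`window` must be a single-row tibble")
  fr <- fragments[fragments$chrom == window$chrom, , drop = FALSE]
  len <- window$window_end - window$window_start
  if (nrow(fr) == 0) return(integer(len))
  cov <- IRanges::coverage(IRanges::IRanges(start = fr$start + 1L,
                                            end = fr$end),
                           width = max(window$window_end, max(fr$end)))
  as.integer(S4Vectors::window(cov, start = window$window_start + 1L,
                               end = window$window_end))
}

#' RPKM normalization
#'
#' Reads per kilobase per million mapped reads:
#' `count * 1e9 / (window_length * total_mapped)`.
#'
#' @param count fragment count(s) in the window.
#' @param window_length window length in bp (> 0).
#' @param total_mapped genome-wide mapped, deduplicated fragment count (> 0).
#' @return numeric RPKM value(s).
#' @export
rpkm_normalize <- function(count, window_length, total_mapped) {
  if (any(window_length <= 0)) abort("`window_length` must be > 0")
  if (any(total_mapped <= 0)) abort("`total_mapped` must be > 0")
  if (any(count < 0)) abort("`count` must be >= 0")
  count * 1e9 / (window_length * total_mapped)
}

#' Build the samples x promoters RPKM coverage table
#'
#' Counts fragments per pTSS window for every sample, normalizes to RPKM
#' using each sample's genome-wide `total_mapped`, and returns a wide tibble:
#' the metadata columns (sample_id, cohort, label, bmi, gestational_age as
#' available) followed by one column per window (named by transcript_id).
#'
#' @param samples named list of fragment tibbles (names = sample ids; if
#'   unnamed, the `sample_id` attribute is used).
#' @param windows tibble from [build_ptss_windows()].
#' @param metadata tibble with a `sample_id` column covering every sample.
#' @param total_mapped optional named vector of library sizes; defaults to
#'   each fragment set's `total_mapped` attribute (or its row count).
#' @return the coverage tibble.
#' @export
build_coverage_matrix <- function(samples, windows, metadata,
                                  total_mapped = NULL) {
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- vapply(samples, function(fr)
      attr(fr, "sample_id", exact = TRUE) %||% NA_character_, "")
  }
  if (any(is.na(names(samples)))) abort("samples must be named by sample id")
  missing_meta <- setdiff(names(samples), metadata$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("metadata missing sample(s): ",
                 paste(missing_meta, collapse = ", ")))
  }
  counts <- vapply(samples, count_fragments_in_windows, windows = windows,
                   FUN.VALUE = integer(nrow(windows)))
  counts <- matrix(counts, nrow = nrow(windows),
                   dimnames = list(windows$transcript_id, names(samples)))
  tm <- if (is.null(total_mapped)) {
    vapply(samples, cfpromoter::total_mapped, 1L)
  } else {
    as.integer(total_mapped[names(samples)])
  }
  rpkm <- t(counts) * 1e9 /
    outer(as.numeric(tm), as.numeric(windows$effective_length))
  meta <- metadata[match(names(samples), metadata$sample_id), , drop = FALSE]
  out <- dplyr::bind_cols(
    as_tibble(meta[, intersect(.meta_cols, names(meta)), drop = FALSE]),
    as_tibble(rpkm, .name_repair = "minimal"))
  out
}

#' TSS metagene depth profile for a gene set
#'
#' Per-base depth is averaged across the gene set's full-width pTSS windows
#' and all samples (minus-strand windows are reversed first, so positive
#' offsets are downstream of the TSS), then divided by the mean depth over
#' the outermost 10% of positions on each side of the window — the
#' relative-depth baseline. Active promoters therefore show a central dip
#' below 1.
#'
#' @param samples named list (or single tibble) of fragment sets.
#' @param windows window tibble, typically already restricted to a gene set
#'   via `gene_set`.
#' @param gene_set optional character vector of transcript ids to restrict
#'   to (must be nonempty after intersection).
#' @param bin_size optional bp bin width; must divide the window width.
#' @param gene_set_name label stored in the output.
#' @return tibble (position, mean_relative_depth, gene_set, n_genes) of
#'   class `metagene_profile`; `position` is the bp offset (bin centre)
#'   relative to the TSS.
#' @export
metagene_profile <- function(samples, windows, gene_set = NULL,
                             bin_size = NULL, gene_set_name = NULL) {
  if (is.data.frame(samples)) samples <- list(sample = samples)
  if (!is.null(gene_set)) {
    gene_set_name <- gene_set_name %||% deparse(substitute(gene_set))
    windows <- windows[windows$transcript_id %in% gene_set, , drop = FALSE]
  }
  if (nrow(windows) == 0) abort("empty gene set: no windows to profile")
  width <- max(windows$effective_length)
  full <- windows$effective_length == width
  windows <- windows[full, , drop = FALSE]

  acc <- numeric(width)
  for (fr in samples) {
    for (ch in unique(windows$chrom)) {
      w <- windows[windows$chrom == ch, , drop = FALSE]
      f <- fr[fr$chrom == ch, , drop = FALSE]
      if (nrow(f) == 0) next
      cov <- IRanges::coverage(IRanges::IRanges(start = f$start + 1L,
                                                end = f$end),
                               width = max(w$window_end, max(f$end)))
      v <- IRanges::Views(cov, start = w$window_start + 1L,
                          end = w$window_end)
      m <- as.matrix(v)
      rev_rows <- w$strand == "-"
      if (any(rev_rows)) {
        m[rev_rows, ] <- m[rev_rows, rev(seq_len(width)), drop = FALSE]
      }
      acc <- acc + colSums(m)
    }
  }
  mean_depth <- acc / (nrow(windows) * length(samples))

  edge <- max(1L, floor(0.10 * width))
  baseline <- mean(mean_depth[c(seq_len(edge), width - edge + seq_len(edge))])
  if (baseline <= 0) abort("flank baseline depth is zero; cannot normalize")
  rel <- mean_depth / baseline

  offsets <- seq_len(width) - 1L - width %/% 2L
  if (!is.null(bin_size)) {
    bin_size <- as.integer(bin_size)
    if (width %% bin_size != 0) abort("`bin_size` must divide the window width")
    grp <- rep(seq_len(width %/% bin_size), each = bin_size)
    rel <- as.numeric(tapply(rel, grp, mean))
    offsets <- as.numeric(tapply(offsets, grp, mean))
  }
  out <- tibble(position = offsets, mean_relative_depth = rel,
                gene_set = gene_set_name %||% "all",
                n_genes = nrow(windows))
  class(out) <- c("metagene_profile", class(out))
  out
}

#' Central/flank depth ratio of a metagene profile
#'
#' Mean relative depth over the central `central_frac` of positions; since
#' the profile is already normalized to the outer-flank baseline, this is
#' the central-to-flank coverage ratio (1 for inactive promoters, < 1 for
#' nucleosome-depleted ones).
#'
#' @param profile a [metagene_profile()] result.
#' @param central_frac fraction of positions treated as central.
#' @return a single numeric ratio.
#' @export
central_flank_ratio <- function(profile, central_frac = 0.10) {
  n <- nrow(profile)
  half <- max(1L, floor(central_frac * n / 2))
  centre <- which.min(abs(profile$position))
  idx <- max(1L, centre - half):min(n, centre + half)
  mean(profile$mean_relative_depth[idx])
}

#' Write a coverage table or metagene profile as TSV
#' @param x a coverage tibble or metagene profile.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_coverage_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
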