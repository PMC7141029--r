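#' Read transcript annotation (refFlat or BED12)
#'
#' refFlat-style TSV: columns geneName, name (transcript id), chrom, strand,
#' txStart, txEnd (further columns ignored); txStart is treated as 0-based
#' and txEnd as half-open, the UCSC convention. BED12 is parsed with
#' rtracklayer; the BED name field supplies both transcript id and gene
#' symbol.
#'
#' @param path file path.
#' @param format `"refflat"` or `"bed12"`.
#' @return tibble with columns transcript_id, gene_symbol, chrom, strand,
#'   tx_start, tx_end (0-based half-open).
#' @export
read_annotation <- function(path, format = c("refflat", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  tr <- switch(format,
               refflat = .read_refflat(path),
               bed12 = .read_bed12(path))
  dup <- tr$transcript_id[duplicated(tr$transcript_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate transcript ids in annotation: ",
                 paste(unique(utils::head(dup, 5)), collapse = ", ")))
  }
  bad <- which(tr$tx_start >= tr$tx_end)
  if (length(bad) > 0) {
    abort(sprintf("annotation line %d: txStart >= txEnd", bad[1]))
  }
  tr
}

.read_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(transcript_id = character(), gene_symbol = character(),
                  chrom = character(), strand = character(),
                  tx_start = integer(), tx_end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    abort(sprintf("refFlat parse error at line %d: expected >= 6 tab-separated fields, found %d",
                  which(nf < 6)[1], nf[which(nf < 6)[1]]))
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  strand <- get(4)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("refFlat parse error at line %d: unknown strand symbol '%s'",
                  bad[1], strand[bad[1]]))
  }
  ts <- suppressWarnings(as.integer(get(5)))
  te <- suppressWarnings(as.integer(get(6)))
  bad <- which(is.na(ts) | is.na(te))
  if (length(bad) > 0) {
    abort(sprintf("refFlat parse error at line %d: non-numeric txStart/txEnd",
                  bad[1]))
  }
  tibble(transcript_id = get(2), gene_symbol = get(1), chrom = get(3),
         strand = strand, tx_start = ts, tx_end = te)
}

.read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(BiocGenerics::strand(gr))
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("BED12 parse error at record %d: unknown strand symbol '%s'",
                  bad[1], strand[bad[1]]))
  }
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    sprintf("record%d", seq_along(gr))
  tibble(transcript_id = nm, gene_symbol = nm,
         chrom = as.character(GenomeInfoDb::seqnames(gr)),
         strand = strand,
         tx_start = BiocGenerics::start(gr) - 1L,
         tx_end = BiocGenerics::end(gr))
}

#' Build strand-aware pTSS promoter windows
#'
#' The primary TSS region (pTSS) of a transcript is the window from -`flank`
#' to +`flank` bp around its transcription start site: `tx_start` on the
#' plus strand, `tx_end` (the half-open end) on the minus strand. Windows
#' are clipped to `[0, chromosome length)`; one window is produced per
#' transcript, and windows of different transcripts may overlap.
#'
#' @param transcripts tibble from [read_annotation()] (or the `transcripts`
#'   element of a `gene_universe`).
#' @param flank half-width in bp (default 1000, i.e. -1 kb..+1 kb).
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   right-edge clipping.
#' @return tibble with columns transcript_id, gene_symbol, chrom, strand,
#'   tss, window_start, window_end, effective_length (0-based half-open).
#' @export
build_ptss_windows <- function(transcripts, flank = 1000, chrom_sizes = NULL) {
  .check_scalar_number(flank, "flank", 1)
  tss <- ifelse(transcripts$strand == "+", transcripts$tx_start,
                transcripts$tx_end)
  ws <- pmax(0L, as.integer(tss - flank))
  we <- as.integer(tss + flank)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[transcripts$chrom]
    if (any(is.na(lim))) {
      abort("chrom_sizes missing a chromosome present in the annotation")
    }
    we <- pmin(we, as.integer(lim))
    ws <- pmin(ws, we)
  }
  tibble(transcript_id = transcripts$transcript_id,
         gene_symbol = transcripts$gene_symbol,
         chrom = transcripts$chrom, strand = transcripts$strand,
         tss = as.integer(tss), window_start = ws, window_end = we,
         effective_length = we - ws)
}

#' Write pTSS windows as BED6
#'
#' name = transcript id, score = 0, strand preserved.
#' @param windows tibble from [build_ptss_windows()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  out <- tibble(chrom = windows$chrom, start = windows$window_start,
                end = windows$window_end, name = windows$transcript_id,
                score = 0L, strand = windows$strand)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read aligned cfDNA fragments from a BED3+ file
#'
#' Only the first three columns (chrom, 0-based start, half-open end) are
#' used. The `total_mapped` attribute is set to the number of records;
#' override it when the file is a subset of the library.
#'
#' @param path BED file path.
#' @param total_mapped optional genome-wide mapped-fragment count.
#' @return fragment tibble (chrom, start, end) with `total_mapped` and
#'   `sample_id` attributes.
#' @export
read_fragments_bed <- function(path, total_mapped = NULL) {
  fr <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(fr) < 3) abort(paste0("BED file has fewer than 3 columns: ", path))
  out <- tibble(chrom = as.character(fr[[1]]), start = as.integer(fr[[2]]),
                end = as.integer(fr[[3]]))
  if (any(out$start >= out$end)) abort("BED fragment with start >= end")
  attr(out, "total_mapped") <- as.integer(total_mapped %||% nrow(out))
  attr(out, "sample_id") <- sub("\\.bed$", "", basename(path))
  out
}

#' Read aligned fragments from a coordinate-sorted SAM file
#'
#' Each mapped record contributes one fragment `[pos - 1, pos - 1 + qwidth)`.
#' The SAM must carry \verb{@SQ} header lines; it is converted to BAM in a
#' temporary directory via Rsamtools.
#'
#' @inheritParams read_fragments_bed
#' @return fragment tibble as in [read_fragments_bed()].
#' @export
read_fragments_sam <- function(path, total_mapped = NULL) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "qwidth"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  keep <- !is.na(res$pos)
  out <- tibble(chrom = as.character(res$rname)[keep],
                start = res$pos[keep] - 1L,
                end = res$pos[keep] - 1L + res$qwidth[keep])
  attr(out, "total_mapped") <- as.integer(total_mapped %||% nrow(out))
  attr(out, "sample_id") <- sub("\\.sam$", "", basename(path))
  out
}
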