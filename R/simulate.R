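#' Simulate a gene universe: annotation, expression, and gene sets
#'
#' Generates a miniature genome of transcripts with widely spaced TSSs (>=
#' 10 kb apart, so +-1 kb promoter windows never overlap), together with
#' long-tailed expression levels for two tissues (placenta and whole blood)
#' and the gene sets used throughout the promoter-profiling analysis.
#'
#' Expression is log-normal with a shared gene-level component, so placental
#' and blood expression are positively correlated, as in real tissue panels.
#' A fraction of genes is made tissue-specific (expressed in exactly one
#' tissue) and another fraction unexpressed in both; `top500`/`bottom500`
#' are the highest/lowest placental expression ranks.
#'
#' @param n_genes number of transcripts (>= 10); one transcript per gene.
#' @param n_chromosomes number of chromosomes the genes are spread over.
#' @param seed integer seed; the universe is deterministic given the seed.
#' @param prop_placenta_specific,prop_blood_specific,prop_unexpressed
#'   fractions of genes expressed only in placenta, only in blood, or in
#'   neither tissue.
#' @return an object of class `gene_universe`: a list with `transcripts`
#'   (tibble: transcript_id, gene_symbol, chrom, strand, tss, tx_start,
#'   tx_end), `expression` (tibble: transcript_id, placenta, blood),
#'   `gene_sets` (named list of transcript-id vectors: top500, bottom500,
#'   placenta_specific, blood_specific, unexpressed), and `chrom_sizes`
#'   (named integer vector).
#' @export
simulate_gene_universe <- function(n_genes, n_chromosomes = 2, seed = 1,
                                   prop_placenta_specific = 0.08,
                                   prop_blood_specific = 0.08,
                                   prop_unexpressed = 0.10) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 10) {
    abort("`n_genes` must be a single number >= 10")
  }
  n_genes <- as.integer(n_genes)
  n_chromosomes <- max(1L, as.integer(n_chromosomes))

  withr::with_seed(as.integer(seed), {
    chrom <- sort(rep_len(paste0("chr", seq_len(n_chromosomes)), n_genes))
    # TSS spacing: 10 kb minimum plus uniform jitter keeps windows disjoint.
    gaps <- 10000L + as.integer(floor(stats::runif(n_genes, 0, 5000)))
    tss <- unlist(lapply(split(gaps, chrom), function(g) 20000L + cumsum(g)),
                  use.names = FALSE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    tx_len <- as.integer(floor(stats::runif(n_genes, 2000, 9000)))
    tx_start <- ifelse(strand == "+", tss, tss - tx_len)
    tx_end <- ifelse(strand == "+", tss + tx_len, tss)

    transcripts <- tibble(
      transcript_id = sprintf("T%05d", seq_len(n_genes)),
      gene_symbol = sprintf("G%05d", seq_len(n_genes)),
      chrom = chrom, strand = strand,
      tss = as.integer(tss),
      tx_start = as.integer(tx_start), tx_end = as.integer(tx_end)
    )

    # Expression classes: shared (correlated across tissues), tissue-specific,
    # unexpressed.
    n_ps <- round(prop_placenta_specific * n_genes)
    n_bs <- round(prop_blood_specific * n_genes)
    n_un <- round(prop_unexpressed * n_genes)
    cls <- sample(c(rep("placenta_specific", n_ps), rep("blood_specific", n_bs),
                    rep("unexpressed", n_un),
                    rep("shared", n_genes - n_ps - n_bs - n_un)))
    base <- stats::rnorm(n_genes)
    pl <- exp(1.2 * (0.8 * base + 0.6 * stats::rnorm(n_genes)))
    bl <- exp(1.2 * (0.8 * base + 0.6 * stats::rnorm(n_genes)))
    hi <- function(n) exp(1.2 * (1 + abs(stats::rnorm(n))))
    pl[cls == "blood_specific"] <- 0
    pl[cls == "unexpressed"] <- 0
    pl[cls == "placenta_specific"] <- hi(sum(cls == "placenta_specific"))
    bl[cls == "placenta_specific"] <- 0
    bl[cls == "unexpressed"] <- 0
    bl[cls == "blood_specific"] <- hi(sum(cls == "blood_specific"))

    expression <- tibble(transcript_id = transcripts$transcript_id,
                         placenta = pl, blood = bl)

    m <- min(500L, n_genes %/% 2L)
    ord <- order(pl, seq_len(n_genes), decreasing = TRUE)  # deterministic ties
    gene_sets <- list(
      top500 = transcripts$transcript_id[ord[seq_len(m)]],
      bottom500 = transcripts$transcript_id[rev(ord)[seq_len(m)]],
      placenta_specific = transcripts$transcript_id[cls == "placenta_specific"],
      blood_specific = transcripts$transcript_id[cls == "blood_specific"],
      unexpressed = transcripts$transcript_id[cls == "unexpressed"]
    )

    sizes <- vapply(split(transcripts$tx_end, transcripts$chrom), max, 0)
    chrom_sizes <- as.integer(sizes + 20000)
    names(chrom_sizes) <- names(sizes)

    structure(list(transcripts = transcripts, expression = expression,
                   gene_sets = gene_sets, chrom_sizes = chrom_sizes),
              class = "gene_universe")
  })
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("<gene_universe> %d transcripts on %d chromosome(s)\n",
              nrow(x$transcripts), length(x$chrom_sizes)))
  invisible(x)
}

#' Nucleosome-occupancy model for cfDNA fragment simulation
#'
#' cfDNA fragment starts are sampled from a baseline intensity that dips at
#' the promoters of transcriptionally active genes: active promoters are
#' nucleosome-depleted in the tissue of origin, so the naked DNA is digested
#' and contributes fewer fragments. The dip on fragment-start intensity is
#' an inverted Gaussian centred at the TSS with scale `depletion_width / 2`
#' (so the dip has essentially decayed `depletion_width` away from the TSS),
#' and maximal relative depth `activity * depletion_depth`.
#'
#' Per-tissue activity maps expression to dip strength as the within-tissue
#' expression percentile (0 for unexpressed genes, approaching 1 for the
#' most expressed).
#'
#' @param universe a [simulate_gene_universe()] result (supplies expression
#'   for the activity mapping).
#' @param depletion_depth fraction in \[0, 1\] by which fragment-start
#'   intensity dips at a fully active promoter.
#' @param depletion_width bp scale of the dip (full width; Gaussian sigma is
#'   half of it).
#' @param baseline_depth expected fragment starts per bp (used only when a
#'   cohort spec does not fix `fragments_per_sample`).
#' @return an object of class `occupancy_model` with the activity table.
#' @export
occupancy_model <- function(universe, depletion_depth = 0.6,
                            depletion_width = 1000, baseline_depth = 0.003) {
  .check_scalar_number(depletion_depth, "depletion_depth", 0, 1)
  .check_scalar_number(depletion_width, "depletion_width", 1)
  .check_scalar_number(baseline_depth, "baseline_depth", 0)
  pct <- function(e) {
    a <- rep(0, length(e))
    pos <- e > 0
    a[pos] <- rank(e[pos], ties.method = "average") / sum(pos)
    a
  }
  activity <- tibble(
    transcript_id = universe$expression$transcript_id,
    placenta = pct(universe$expression$placenta),
    blood = pct(universe$expression$blood)
  )
  structure(list(depletion_depth = depletion_depth,
                 depletion_width = depletion_width,
                 baseline_depth = baseline_depth,
                 activity = activity),
            class = "occupancy_model")
}

#' Cohort specification for cfDNA simulation
#'
#' @param n_cases,n_controls sample counts.
#' @param placental_fraction proportion of fragments drawn from the placenta
#'   occupancy track; the remainder follows the maternal-blood track.
#'   Defaults to 0.10, the typical placental contribution to plasma cfDNA
#'   in pregnancy.
#' @param planted_promoters transcript ids given a case-specific coverage
#'   shift (ignored when `effect_lfc == 0`).
#' @param effect_lfc target log2 change of mean pTSS window coverage in
#'   cases at the planted promoters.
#' @param fragments_per_sample fragments simulated per sample; `NULL` means
#'   derive from the occupancy model's `baseline_depth` times genome length.
#' @param fragment_length_mean,fragment_length_sd fragment length Normal
#'   parameters in bp (truncated to \[50, 400\]); 167 bp is the canonical
#'   mononucleosome cfDNA mode.
#' @param bmi_shift mean case-minus-control BMI difference (kg/m^2) for the
#'   simulated BMI covariate.
#' @param flank half-width (bp) of the promoter window the planted effect
#'   acts on.
#' @param seed master seed; per-sample seeds are derived by fixed offsets.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, placental_fraction = 0.10,
                        planted_promoters = character(), effect_lfc = 0,
                        fragments_per_sample = NULL,
                        fragment_length_mean = 167, fragment_length_sd = 20,
                        bmi_shift = 1.5, flank = 1000, seed = 1) {
  .check_scalar_number(n_cases, "n_cases", 0)
  .check_scalar_number(n_controls, "n_controls", 0)
  .check_scalar_number(placental_fraction, "placental_fraction", 0, 1)
  .check_scalar_number(effect_lfc, "effect_lfc")
  if (!is.null(fragments_per_sample)) {
    .check_scalar_number(fragments_per_sample, "fragments_per_sample", 1)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 placental_fraction = placental_fraction,
                 planted_promoters = as.character(planted_promoters),
                 effect_lfc = effect_lfc,
                 fragments_per_sample = fragments_per_sample,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 bmi_shift = bmi_shift, flank = flank,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Genome layout helpers: concatenate chromosomes into one coordinate axis.
.genome_layout <- function(universe) {
  sizes <- universe$chrom_sizes
  offsets <- c(0, cumsum(as.numeric(sizes)))[seq_along(sizes)]
  names(offsets) <- names(sizes)
  list(sizes = sizes, offsets = offsets, total = sum(as.numeric(sizes)))
}

#' Simulate one sample's cfDNA fragments
#'
#' Fragment start positions are drawn by thinning a uniform genome-wide
#' intensity with the two-tissue occupancy mixture
#' `placental_fraction * placenta + (1 - placental_fraction) * blood`:
#' the acceptance probability dips at active promoters by
#' `mixture_activity * depletion_depth * exp(-d^2 / (2 sigma^2))` where `d`
#' is the distance to the nearest TSS. In case samples, fragment-start
#' intensity inside planted promoter windows is additionally multiplied by
#' `2^effect_lfc`, so the expected window-count ratio between cases and
#' controls approximates the target log2 fold change. Fragment lengths are
#' Normal(`fragment_length_mean`, `fragment_length_sd`) truncated to
#' \[50, 400\] bp.
#'
#' @param universe a `gene_universe`.
#' @param occupancy an [occupancy_model()].
#' @param spec a [cohort_spec()].
#' @param is_case logical; does the sample get the planted shift?
#' @param sample_seed integer seed for this sample.
#' @return a tibble (chrom, start, end), 0-based half-open, sorted by
#'   position, with attributes `total_mapped` (= number of fragments) and
#'   `sample_id` (NA here; set by [simulate_cohort()]).
#' @export
simulate_sample_fragments <- function(universe, occupancy, spec,
                                      is_case = FALSE, sample_seed = 1) {
  stopifnot(inherits(universe, "gene_universe"),
            inherits(occupancy, "occupancy_model"),
            inherits(spec, "cohort_spec"))
  .check_scalar_number(occupancy$depletion_depth, "depletion_depth", 0, 1)
  layout <- .genome_layout(universe)
  n_frag <- spec$fragments_per_sample %||%
    max(1L, round(occupancy$baseline_depth * layout$total))

  tr <- universe$transcripts
  act <- occupancy$activity
  mix_act <- spec$placental_fraction * act$placenta +
    (1 - spec$placental_fraction) * act$blood
  gtss <- layout$offsets[tr$chrom] + tr$tss
  ord <- order(gtss)
  gtss <- gtss[ord]
  mix_act <- mix_act[ord]
  planted <- tr$transcript_id[ord] %in% spec$planted_promoters &
    spec$effect_lfc != 0 & is_case
  boost <- ifelse(planted, 2^spec$effect_lfc, 1)

  d <- occupancy$depletion_depth
  sigma <- occupancy$depletion_width / 2
  fmax <- max(1, boost)

  withr::with_seed(as.integer(sample_seed), {
    starts <- numeric(0)
    while (length(starts) < n_frag) {
      need <- n_frag - length(starts)
      n_draw <- ceiling(need * fmax / 0.85) + 64L
      x <- stats::runif(n_draw, 0, layout$total)
      # nearest TSS on the concatenated axis
      i <- findInterval(x, gtss)
      lo <- pmax(i, 1L)
      hi <- pmin(i + 1L, length(gtss))
      nearer_hi <- abs(x - gtss[hi]) < abs(x - gtss[lo])
      g <- ifelse(nearer_hi, hi, lo)
      dist <- abs(x - gtss[g])
      supp <- ifelse(dist < 4 * sigma,
                     d * mix_act[g] * exp(-dist^2 / (2 * sigma^2)), 0)
      fac <- (1 - supp) * ifelse(dist < spec$flank, boost[g], 1)
      keep <- stats::runif(n_draw) < fac / fmax
      starts <- c(starts, x[keep])
    }
    starts <- starts[seq_len(n_frag)]
    len <- pmin(400, pmax(50, round(stats::rnorm(
      n_frag, spec$fragment_length_mean, spec$fragment_length_sd))))

    ci <- findInterval(starts, c(layout$offsets, layout$total),
                       rightmost.closed = TRUE)
    chrom <- names(layout$sizes)[ci]
    local <- floor(starts - layout$offsets[ci])
    end <- pmin(local + len, as.numeric(layout$sizes[ci]))

    out <- tibble(chrom = chrom, start = as.integer(local),
                  end = as.integer(end))
    out <- out[order(out$chrom, out$start, out$end), ]
    attr(out, "total_mapped") <- n_frag
    attr(out, "sample_id") <- NA_character_
    out
  })
}

#' Total mapped fragment count of a fragment set
#'
#' Falls back to the number of stored fragments when the `total_mapped`
#' attribute is absent (e.g. after dplyr manipulation).
#' @param fragments a fragment tibble.
#' @return integer count.
#' @export
total_mapped <- function(fragments) {
  tm <- attr(fragments, "total_mapped", exact = TRUE)
  as.integer(tm %||% nrow(fragments))
}

#' Simulate a case/control cfDNA cohort
#'
#' Generates `n_cases + n_controls` fragment sets under the occupancy model;
#' case samples carry the planted coverage shift at `planted_promoters`.
#' Sample seeds are `spec$seed + 1000 + i`, so the cohort is reproducible
#' sample by sample. Metadata includes a simulated BMI (Normal(22.5, 2.5),
#' cases shifted by `bmi_shift`) and gestational age (weeks).
#'
#' @param universe,occupancy,spec see [simulate_sample_fragments()].
#' @return an object of class `cfdna_cohort`: list with `fragments` (named
#'   list of fragment tibbles), `metadata` (tibble: sample_id, cohort,
#'   label, bmi, gestational_age), and `truth` (list of planted promoters
#'   and generative parameters).
#' @export
simulate_cohort <- function(universe, occupancy, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  planted <- if (spec$effect_lfc == 0) character() else spec$planted_promoters
  missing_ids <- setdiff(planted, universe$transcripts$transcript_id)
  if (length(missing_ids) > 0) {
    abort(paste0("planted promoters absent from universe: ",
                 paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  n <- spec$n_cases + spec$n_controls
  is_case <- c(rep(TRUE, spec$n_cases), rep(FALSE, spec$n_controls))
  ids <- sprintf("S%03d", seq_len(n))

  fragments <- vector("list", n)
  names(fragments) <- ids
  for (i in seq_len(n)) {
    fr <- simulate_sample_fragments(universe, occupancy, spec,
                                    is_case = is_case[i],
                                    sample_seed = spec$seed + 1000L + i)
    attr(fr, "sample_id") <- ids[i]
    fragments[[i]] <- fr
  }

  metadata <- withr::with_seed(spec$seed + 500L, tibble(
    sample_id = ids,
    cohort = "training",
    label = ifelse(is_case, "case", "control"),
    bmi = round(stats::rnorm(n, 22.5, 2.5) + spec$bmi_shift * is_case, 2),
    gestational_age = round(stats::rnorm(n, 17, 1.5), 1)
  ))

  truth <- list(planted_promoters = planted,
                effect_lfc = spec$effect_lfc,
                placental_fraction = spec$placental_fraction,
                depletion_depth = occupancy$depletion_depth,
                depletion_width = occupancy$depletion_width,
                fragments_per_sample = total_mapped(fragments[[1]]),
                n_cases = spec$n_cases, n_controls = spec$n_controls,
                seed = spec$seed)

  structure(list(fragments = fragments, metadata = metadata, truth = truth),
            class = "cfdna_cohort")
}

#' @export
print.cfdna_cohort <- function(x, ...) {
  cat(sprintf("<cfdna_cohort> %d samples (%d case / %d control), %d planted promoters\n",
              nrow(x$metadata), sum(x$metadata$label == "case"),
              sum(x$metadata$label == "control"),
              length(x$truth$planted_promoters)))
  invisible(x)
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' One BED3+ file per sample (`<sample_id>.bed`), a refFlat-style annotation
#' TSV (`annotation.refflat`), the sample metadata (`metadata.tsv`), and the
#' simulation truth (`truth.json`). Rewriting the same cohort produces
#' byte-identical files.
#'
#' @param cohort a [simulate_cohort()] result (or NULL for annotation +
#'   metadata only).
#' @param universe the `gene_universe` the cohort was simulated from.
#' @param dir output directory (created if needed).
#' @return a manifest tibble (file, md5) of everything written, invisibly
#'   also written to `manifest.tsv`.
#' @export
write_fixtures <- function(cohort, universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  tr <- universe$transcripts
  refflat <- tibble(geneName = tr$gene_symbol, name = tr$transcript_id,
                    chrom = tr$chrom, strand = tr$strand,
                    txStart = tr$tx_start, txEnd = tr$tx_end,
                    cdsStart = tr$tx_start, cdsEnd = tr$tx_end,
                    exonCount = 1L,
                    exonStarts = paste0(tr$tx_start, ","),
                    exonEnds = paste0(tr$tx_end, ","))
  ann_path <- file.path(dir, "annotation.refflat")
  readr::write_tsv(refflat, ann_path, col_names = FALSE)
  files <- ann_path

  if (!is.null(cohort)) {
    for (sid in names(cohort$fragments)) {
      p <- file.path(dir, paste0(sid, ".bed"))
      fr <- cohort$fragments[[sid]]
      readr::write_tsv(fr[, c("chrom", "start", "end")], p, col_names = FALSE)
      files <- c(files, p)
    }
    meta_path <- file.path(dir, "metadata.tsv")
    readr::write_tsv(cohort$metadata, meta_path)
    truth_path <- file.path(dir, "truth.json")
    jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, meta_path, truth_path)
  } else {
    meta_path <- file.path(dir, "metadata.tsv")
    readr::write_tsv(tibble(sample_id = character(), cohort = character(),
                            label = character(), bmi = double(),
                            gestational_age = double()), meta_path)
    files <- c(files, meta_path)
  }

  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}

#' Read a simulation truth record written by [write_fixtures()]
#' @param path path to `truth.json`.
#' @return the truth list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_promoters <- as.character(x$planted_promoters)
  x
}
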