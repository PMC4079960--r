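#' Junction filter criteria
#'
#' The confident-junction filter keeps a junction only if its overhang is
#' strictly greater than `min_overhang` (default 20 bp) and it has at least
#' `min_reads` supporting reads (default 2).
#'
#' @param min_overhang exclusive overhang threshold in bp
#' @param min_reads inclusive read-support threshold
#' @export
filter_criteria <- function(min_overhang = 20L, min_reads = 2L) {
  stopifnot(min_overhang >= 0, min_reads >= 0)
  structure(list(min_overhang = as.integer(min_overhang),
                 min_reads = as.integer(min_reads)),
            class = "filter_criteria")
}

#' Apply the confident-junction filter
#'
#' Kept iff `max_overhang > min_overhang` AND `read_count >= min_reads`.
#' Idempotent; strengthening the criteria never adds junctions.
#'
#' @param junctions junction data.frame (see [extract_junctions()])
#' @param criteria a [filter_criteria()]
#' @return the kept subset
#' @export
filter_junctions <- function(junctions, criteria = filter_criteria()) {
  stopifnot_cols(junctions, c("max_overhang", "read_count"), "junction table")
  keep <- junctions$max_overhang > criteria$min_overhang &
    junctions$read_count >= criteria$min_reads
  out <- junctions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decoy junction specification
#'
#' Decoy junctions are built by splicing together annotated exons from
#' different chromosomes; any read support they attract is a false positive
#' by construction. Each decoy sequence is `2 * flank_len` bp: a
#' `flank_len` suffix of one exon followed by a `flank_len` prefix of an exon
#' from another chromosome. With reads of `read_len` bp fully contained in
#' the decoy sequence, a junction-spanning read is guaranteed an overhang of
#' at least `read_len - flank_len` bp (11 bp at the defaults).
#'
#' @param n_junctions number of decoys (default 80000)
#' @param flank_len flank length in bp (default 90)
#' @param read_len read length the calibration assumes (default 101)
#' @param seed RNG seed for exon sampling
#' @export
decoy_spec <- function(n_junctions = 80000L, flank_len = 90L,
                       read_len = 101L, seed = 1L) {
  stopifnot(n_junctions >= 1, flank_len >= 1, read_len > 2)
  structure(list(n_junctions = as.integer(n_junctions),
                 flank_len = as.integer(flank_len),
                 junction_seq_len = 2L * as.integer(flank_len),
                 read_len = as.integer(read_len),
                 min_guaranteed_overhang =
                   max(0L, as.integer(read_len) - as.integer(flank_len)),
                 seed = as.integer(seed)),
            class = "decoy_spec")
}

#' Build decoy junction sequences
#'
#' Samples pairs of annotated exons (each at least `flank_len` bp wide) from
#' different chromosomes and splices a suffix of the first to a prefix of the
#' second, in transcript orientation. Deterministic under the spec's seed.
#'
#' @param annotation a `genome_annotation`
#' @param genome named [Biostrings::DNAStringSet]
#' @param spec a [decoy_spec()]
#' @return [Biostrings::DNAStringSet] of `n_junctions` sequences, each
#'   `2 * flank_len` bp, with an element metadata data.frame (`left_chrom`,
#'   `right_chrom`, exon coordinates) retrievable via `S4Vectors::mcols()`
#' @export
build_decoy_junctions <- function(annotation, genome, spec = decoy_spec()) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(spec, "decoy_spec"))
  ex <- annotation$exons
  ex <- ex[!duplicated(ex[c("chrom", "start", "end")]), , drop = FALSE]
  ex <- ex[ex$end - ex$start + 1L >= spec$flank_len, , drop = FALSE]
  if (length(unique(ex$chrom)) < 2L) {
    stop("decoy construction needs exons of at least ", spec$flank_len,
         " bp on at least 2 chromosomes")
  }
  n <- spec$n_junctions
  pick <- with_seed(spec$seed, {
    left <- sample(nrow(ex), n, replace = TRUE)
    right <- integer(n)
    for (i in seq_len(n)) {
      cand <- which(ex$chrom != ex$chrom[left[i]])
      right[i] <- cand[sample.int(length(cand), 1L)]
    }
    list(left = left, right = right)
  })
  fl <- spec$flank_len
  exon_seq <- function(i) {
    get_seq(genome, ex$chrom[i], ex$start[i], ex$end[i], ex$strand[i])
  }
  seqs <- character(n)
  left_cache <- new.env(parent = emptyenv())
  cached <- function(i) {
    k <- as.character(i)
    if (is.null(left_cache[[k]])) left_cache[[k]] <- exon_seq(i)
    left_cache[[k]]
  }
  for (i in seq_len(n)) {
    a <- cached(pick$left[i])
    b <- cached(pick$right[i])
    seqs[i] <- paste0(substr(a, nchar(a) - fl + 1L, nchar(a)),
                      substr(b, 1L, fl))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("decoy%06d", seq_len(n))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    left_chrom = ex$chrom[pick$left], right_chrom = ex$chrom[pick$right],
    left_start = ex$start[pick$left], left_end = ex$end[pick$left],
    right_start = ex$start[pick$right], right_end = ex$end[pick$right]
  )
  out
}

#' Anchor geometry of reads fully contained in a decoy sequence
#'
#' Enumerates every placement of a read of `read_len` bp inside the
#' `2 * flank_len` bp decoy sequence that spans the junction midpoint and
#' reports both anchors. The smallest possible overhang across placements
#' is `read_len - flank_len` (11 bp at the paper-scale defaults of 101 bp
#' reads on 90 nt flanks).
#'
#' @param spec a [decoy_spec()]
#' @return data.frame with `start`, `left_anchor`, `right_anchor`,
#'   `overhang` (the smaller anchor) per placement
#' @export
decoy_read_overhangs <- function(spec = decoy_spec()) {
  fl <- spec$flank_len
  L <- spec$read_len
  if (L > 2L * fl) stop("read longer than the decoy sequence")
  starts <- seq_len(2L * fl - L + 1L)
  starts <- starts[starts <= fl & starts + L - 1L > fl]
  left <- fl - starts + 1L
  data.frame(start = starts, left_anchor = left, right_anchor = L - left,
             overhang = pmin(left, L - left))
}

#' Calibrate the junction filter on decoy versus annotated junctions
#'
#' Reads aligned to decoy junctions are false positives by construction;
#' comparing their overhang/coverage distributions with those of annotated
#' junctions shows how many decoys a given filter removes and how many
#' annotated junctions it retains.
#'
#' @param decoy_support junction table of decoy-supported junctions
#'   (`read_count`, `max_overhang`)
#' @param annotated_support junction table of annotated junctions
#' @param criteria [filter_criteria()] at which the fractions are reported
#' @return a `calibration_report`: overhang and coverage histograms per
#'   class plus `fraction_decoys_removed` and `fraction_annotated_retained`
#' @export
calibrate_filter <- function(decoy_support, annotated_support,
                             criteria = filter_criteria()) {
  if (!nrow(decoy_support)) stop("decoy junction class is empty")
  if (!nrow(annotated_support)) stop("annotated junction class is empty")
  hist_of <- function(x) table(factor(x, levels = seq_len(max(x))))
  kept_d <- nrow(filter_junctions(decoy_support, criteria))
  kept_a <- nrow(filter_junctions(annotated_support, criteria))
  structure(list(
    criteria = criteria,
    decoy_overhang_distribution = hist_of(decoy_support$max_overhang),
    decoy_coverage_distribution = hist_of(decoy_support$read_count),
    annotated_overhang_distribution = hist_of(annotated_support$max_overhang),
    annotated_coverage_distribution = hist_of(annotated_support$read_count),
    n_decoys = nrow(decoy_support),
    n_annotated = nrow(annotated_support),
    fraction_decoys_removed = 1 - kept_d / nrow(decoy_support),
    fraction_annotated_retained = kept_a / nrow(annotated_support)
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "junction filter calibration (overhang > %d bp, reads >= %d):\n",
    x$criteria$min_overhang, x$criteria$min_reads))
  cat(sprintf("  decoys removed:      %5.1f%% of %d\n",
              100 * x$fraction_decoys_removed, x$n_decoys))
  cat(sprintf("  annotated retained:  %5.1f%% of %d\n",
              100 * x$fraction_annotated_retained, x$n_annotated))
  invisible(x)
}

#' Read a TopHat-style junctions.bed (BED12) file
#'
#' TopHat encodes a junction as two blocks (the maximal anchors); the intron
#' is the gap between them and the score column carries the read count.
#'
#' @param path BED12 file
#' @return junction data.frame (`chrom`, `start`, `end`, `key`,
#'   `read_count`, `max_overhang`, `strand`)
#' @export
read_junctions_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (!length(lines)) return(empty_junctions())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 12L)) {
    stop("BED12 junction record with fewer than 12 fields at line ",
         which(lengths(f) < 12L)[1])
  }
  chrom <- vapply(f, `[`, "", 1L)
  chrom_start <- as.integer(vapply(f, `[`, "", 2L)) # 0-based
  score <- as.integer(vapply(f, `[`, "", 5L))
  strand <- vapply(f, `[`, "", 6L)
  sizes <- lapply(strsplit(vapply(f, `[`, "", 11L), ","), as.integer)
  starts <- lapply(strsplit(vapply(f, `[`, "", 12L), ","), as.integer)
  if (any(lengths(sizes) != 2L)) stop("junction BED12 must have exactly 2 blocks")
  b1 <- vapply(sizes, `[`, 0L, 1L)
  b2 <- vapply(sizes, `[`, 0L, 2L)
  s2 <- vapply(starts, `[`, 0L, 2L)
  intron_start <- chrom_start + b1 + 1L # 1-based first intron base
  intron_end <- chrom_start + s2       # last intron base
  data.frame(
    chrom = chrom, start = intron_start, end = intron_end,
    key = junction_key(chrom, intron_start, intron_end),
    read_count = score, max_overhang = pmin(b1, b2), strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Write a junction table as a TopHat-style BED12 file
#'
#' @param junctions junction data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_junctions_bed <- function(junctions, path) {
  j <- junctions
  anchor <- pmax(j$max_overhang, 1L)
  chrom_start <- j$start - anchor - 1L # 0-based block start
  chrom_end <- j$end + anchor
  strand <- if (is.null(j$strand)) rep(".", nrow(j)) else j$strand
  strand[!strand %in% c("+", "-")] <- "."
  lines <- sprintf(
    "%s\t%d\t%d\tJUNC%05d\t%d\t%s\t%d\t%d\t255,0,0\t2\t%d,%d\t0,%d",
    j$chrom, chrom_start, chrom_end, seq_len(nrow(j)), j$read_count, strand,
    chrom_start, chrom_end, anchor, anchor, anchor + (j$end - j$start + 1L)
  )
  writeLines(lines, path)
  invisible(path)
}
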