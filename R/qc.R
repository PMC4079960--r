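#' Library quality metrics
#'
#' Computes (i) the fraction of reads falling in exonic, intronic and
#' intergenic space, (ii) a coverage profile over relative transcript
#' position (5' to 3', fixed number of bins) to reveal 3'/5' bias, and
#' (iii) a gene-detection saturation curve over a grid of subsampled depths.
#'
#' A read is exonic when its aligned interval overlaps any exon, intronic
#' when it overlaps a gene but no exon, intergenic otherwise. A gene counts
#' as detected when at least one read overlaps one of its exons.
#'
#' @param aln alignment table or SAM path
#' @param annotation a `genome_annotation`
#' @param n_bins bins of the relative-position profile
#' @param depth_grid number of evenly spaced depths for the saturation curve
#' @param repeats random repeats averaged per depth
#' @param min_mapq MAPQ floor for counted reads
#' @param seed RNG seed for the saturation subsampling
#' @return a `qc_report` list: `feature_fractions`, `coverage_profile`,
#'   `saturation` (data.frame depth/genes_detected), `n_reads`
#' @export
library_qc <- function(aln, annotation, n_bins = 40L, depth_grid = 10L,
                       repeats = 3L, min_mapq = 10L, seed = 1L) {
  if (is.character(aln)) aln <- read_sam(aln)
  stopifnot(inherits(annotation, "genome_annotation"))
  keep <- bitwAnd(aln$flag, 4L) == 0L & aln$mapq >= min_mapq
  a <- aln[keep, , drop = FALSE]
  if (!nrow(a)) stop("no usable reads for QC")
  a$end <- a$pos + cigar_ref_width(a$cigar) - 1L

  ex <- annotation$exons
  g <- annotation$genes
  exonic <- logical(nrow(a))
  genic <- logical(nrow(a))
  if (nrow(ex)) {
    h <- overlap_hits(a$chrom, a$pos, a$end, ex$chrom, ex$start, ex$end)
    exonic[unique(h$query)] <- TRUE
  }
  if (nrow(g)) {
    h <- overlap_hits(a$chrom, a$pos, a$end, g$chrom, g$start, g$end)
    genic[unique(h$query)] <- TRUE
  }
  frac <- c(
    exonic = mean(exonic),
    intronic = mean(genic & !exonic),
    intergenic = mean(!genic)
  )

  # relative-position profile over transcript spans (midpoint of each read,
  # 5' -> 3' in transcript orientation)
  tx_span <- do.call(rbind, lapply(split(ex, ex$tx_id), function(e) {
    data.frame(tx_id = e$tx_id[1], chrom = e$chrom[1], strand = e$strand[1],
               start = min(e$start), end = max(e$end),
               stringsAsFactors = FALSE)
  }))
  profile <- rep(0, n_bins)
  if (!is.null(tx_span) && nrow(tx_span)) {
    h <- overlap_hits(a$chrom, a$pos, a$end,
                      tx_span$chrom, tx_span$start, tx_span$end)
    if (length(h$query)) {
      mid <- (a$pos[h$query] + a$end[h$query]) / 2
      rel <- (mid - tx_span$start[h$subject]) /
        (tx_span$end[h$subject] - tx_span$start[h$subject] + 1)
      minus <- tx_span$strand[h$subject] == "-"
      rel[minus] <- 1 - rel[minus]
      rel <- pmin(pmax(rel, 0), 1 - 1e-9)
      profile <- tabulate(floor(rel * n_bins) + 1L, nbins = n_bins)
      profile <- profile / sum(profile)
    }
  }

  # saturation: detected genes vs depth, averaged over random repeats
  gene_of_exon <- ex$gene_id
  depths <- unique(round(seq_len(depth_grid) / depth_grid * nrow(a)))
  sat <- with_seed(seed, {
    vapply(depths, function(d) {
      mean(vapply(seq_len(repeats), function(r) {
        i <- sample(nrow(a), d)
        h <- overlap_hits(a$chrom[i], a$pos[i], a$end[i],
                          ex$chrom, ex$start, ex$end)
        length(unique(gene_of_exon[h$subject]))
      }, 0))
    }, 0)
  })

  structure(list(
    feature_fractions = frac,
    coverage_profile = profile,
    saturation = data.frame(depth = depths, genes_detected = sat),
    n_reads = nrow(a)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  f <- x$feature_fractions
  cat(sprintf("library QC over %d reads:\n", x$n_reads))
  cat(sprintf("  exonic %.1f%%, intronic %.1f%%, intergenic %.1f%%\n",
              100 * f["exonic"], 100 * f["intronic"], 100 * f["intergenic"]))
  cat(sprintf("  saturation: %d gene(s) detected at full depth\n",
              as.integer(utils::tail(x$saturation$genes_detected, 1))))
  invisible(x)
}

#' @export
plot.qc_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$coverage_profile) / length(x$coverage_profile),
                 x$coverage_profile, type = "l",
                 xlab = "relative transcript position (5'->3')",
                 ylab = "read fraction", main = "coverage profile")
  graphics::plot(x$saturation$depth, x$saturation$genes_detected, type = "b",
                 xlab = "reads sampled", ylab = "genes detected",
                 main = "saturation")
  invisible(x)
}
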