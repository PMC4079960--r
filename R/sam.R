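## Spliced-alignment handling. Alignments are held as a plain data.frame
## ("alignment table") with columns qname, flag, chrom, pos, mapq, cigar.
## Junction extraction is CIGAR N-gap parsing: for every gap the read's
## anchors are the matched/mismatched (M/=/X) aligned bases on either side,
## and a read's overhang at that junction is the smaller anchor.

#' Read a SAM file into an alignment table
#'
#' Only the columns the pipeline uses are kept (qname, flag, chrom, pos,
#' mapq, cigar). Unmapped records are dropped.
#'
#' @param path SAM file path
#' @return data.frame alignment table
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_alignments())
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) {
    stop("malformed SAM record at line ", which(nf < 11L)[1],
         " (fewer than 11 fields)")
  }
  aln <- data.frame(
    qname = vapply(f, `[`, "", 1L),
    flag = as.integer(vapply(f, `[`, "", 2L)),
    chrom = vapply(f, `[`, "", 3L),
    pos = as.integer(vapply(f, `[`, "", 4L)),
    mapq = as.integer(vapply(f, `[`, "", 5L)),
    cigar = vapply(f, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
  aln[bitwAnd(aln$flag, 4L) == 0L & aln$chrom != "*", , drop = FALSE]
}

#' @noRd
empty_alignments <- function() {
  data.frame(qname = character(0), flag = integer(0), chrom = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             stringsAsFactors = FALSE)
}

#' Write an alignment table as SAM
#'
#' Sequences and qualities are emitted as `*`; the records carry everything
#' junction extraction needs (position, CIGAR, MAPQ, flags).
#'
#' @param aln alignment table
#' @param path output path
#' @param chrom_lengths named integer vector for the `@SQ` header lines
#' @return `path`, invisibly
#' @export
write_sam <- function(aln, path, chrom_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  if (nrow(aln)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                       aln$qname, aln$flag, aln$chrom, aln$pos, aln$mapq,
                       aln$cigar), con)
  }
  invisible(path)
}

#' @noRd
parse_cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
  regmatches(cigar, m)
}

#' Reference width consumed by a CIGAR string
#' @noRd
cigar_ref_width <- function(cigar) {
  vapply(parse_cigar_ops(cigar), function(ops) {
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, 0L)
}

#' Per-gap junction records of one alignment table
#'
#' @return data.frame with one row per (read, N gap): chrom, start, end of
#'   the intron and the left/right anchor sizes (M/=/X bases on each side of
#'   the gap).
#' @noRd
gap_records <- function(aln) {
  has_n <- grepl("N", aln$cigar, fixed = TRUE)
  idx <- which(has_n)
  if (!length(idx)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), left_anchor = integer(0),
                      right_anchor = integer(0), row = integer(0),
                      stringsAsFactors = FALSE))
  }
  ops_all <- parse_cigar_ops(aln$cigar[idx])
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    ops <- ops_all[[i]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    ref_pos <- aln$pos[idx[i]]
    n_at <- which(op == "N")
    # aligned (M/=/X) bases accumulated between consecutive gaps
    seg_aligned <- integer(length(n_at) + 1L)
    seg <- 1L
    gap_start <- integer(length(n_at))
    gap_end <- integer(length(n_at))
    g <- 0L
    for (j in seq_along(op)) {
      if (op[j] == "N") {
        g <- g + 1L
        gap_start[g] <- ref_pos
        gap_end[g] <- ref_pos + len[j] - 1L
        ref_pos <- ref_pos + len[j]
        seg <- seg + 1L
      } else {
        if (op[j] %in% c("M", "=", "X")) {
          seg_aligned[seg] <- seg_aligned[seg] + len[j]
        }
        if (op[j] %in% c("M", "=", "X", "D")) ref_pos <- ref_pos + len[j]
      }
    }
    # anchors: total aligned bases on each side of the gap
    left <- cumsum(seg_aligned)[seq_along(n_at)]
    right <- rev(cumsum(rev(seg_aligned)))[seq_along(n_at) + 1L]
    out[[i]] <- data.frame(
      chrom = aln$chrom[idx[i]], start = gap_start, end = gap_end,
      left_anchor = left, right_anchor = right, row = idx[i],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Extract splice junctions from spliced alignments
#'
#' Every CIGAR N gap of a uniquely mapped read supports the junction whose
#' intron is the gapped interval. A junction's `read_count` is the number of
#' supporting reads and its `max_overhang` the maximum over reads of the
#' smaller anchor. With an annotation the junctions are labeled
#' known/novel, assigned to containing genes (primary assignment = longest
#' containing gene) and given a strand (annotated intron strand, else the
#' strand of the primary gene, else `"."`).
#'
#' @param aln alignment table (see [read_sam()]) or path to a SAM file
#' @param annotation optional `genome_annotation`
#' @param min_mapq reads with MAPQ below this floor are not counted
#'   ("uniquely mapped" proxy; default 10)
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, `key`,
#'   `read_count`, `max_overhang`, `annotated`, `gene_id`
#' @export
extract_junctions <- function(aln, annotation = NULL, min_mapq = 10L) {
  if (is.character(aln)) aln <- read_sam(aln)
  keep <- bitwAnd(aln$flag, 4L) == 0L &
    bitwAnd(aln$flag, 256L) == 0L &
    bitwAnd(aln$flag, 2048L) == 0L &
    aln$mapq >= min_mapq
  gaps <- gap_records(aln[keep, , drop = FALSE])
  if (!nrow(gaps)) return(empty_junctions())
  gaps$key <- junction_key(gaps$chrom, gaps$start, gaps$end)
  gaps$overhang <- pmin(gaps$left_anchor, gaps$right_anchor)
  sp <- split(seq_len(nrow(gaps)), gaps$key)
  j <- do.call(rbind, lapply(sp, function(i) {
    data.frame(
      chrom = gaps$chrom[i][1], start = gaps$start[i][1],
      end = gaps$end[i][1], key = gaps$key[i][1],
      read_count = length(i), max_overhang = max(gaps$overhang[i]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(j) <- NULL
  j <- j[order(j$chrom, j$start, j$end), , drop = FALSE]
  annotate_junction_table(j, annotation)
}

#' @noRd
empty_junctions <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             key = character(0), read_count = integer(0),
             max_overhang = integer(0), strand = character(0),
             annotated = logical(0), gene_id = character(0),
             stringsAsFactors = FALSE)
}

#' Label a junction table against an annotation
#'
#' Adds `annotated`, `strand` and primary `gene_id` columns; exported because
#' junction tables can also come from BED12 files.
#'
#' @param j junction data.frame with `chrom`, `start`, `end`
#' @param annotation optional `genome_annotation`
#' @export
annotate_junction_table <- function(j, annotation = NULL) {
  if (is.null(annotation)) {
    j$strand <- "."
    j$annotated <- NA
    j$gene_id <- NA_character_
    return(j)
  }
  if (is.null(j$key)) j$key <- junction_key(j$chrom, j$start, j$end)
  known <- enumerate_introns(annotation)
  j$annotated <- j$key %in% known$key
  g <- annotation$genes
  j$gene_id <- NA_character_
  j$strand <- "."
  if (nrow(g) && nrow(j)) {
    hits <- overlap_hits(j$chrom, j$start, j$end, g$chrom, g$start, g$end,
                         type = "within")
    if (length(hits$query)) {
      width <- g$end[hits$subject] - g$start[hits$subject]
      o <- order(hits$query, -width) # primary = longest containing gene
      first <- !duplicated(hits$query[o])
      j$gene_id[hits$query[o][first]] <- g$gene_id[hits$subject[o][first]]
      j$strand[!is.na(j$gene_id)] <- g$strand[match(j$gene_id[!is.na(j$gene_id)], g$gene_id)]
    }
  }
  ann_strand <- known$strand[match(j$key, known$key)]
  j$strand[!is.na(ann_strand)] <- ann_strand[!is.na(ann_strand)]
  j
}

#' Subsample an alignment table to a fixed number of records
#'
#' Sampling is uniform without replacement and deterministic under `seed`.
#' When the library is paired (any record has the paired flag), only
#' properly-paired records are eligible and mates are kept or dropped
#' together, so `n` must be even.
#'
#' @param aln alignment table
#' @param n number of records to keep
#' @param seed RNG seed
#' @param min_mapq eligibility floor on MAPQ
#' @return alignment table with exactly `n` rows
#' @export
subsample_alignments <- function(aln, n, seed = 1L, min_mapq = 10L) {
  paired <- any(bitwAnd(aln$flag, 1L) == 1L)
  elig <- bitwAnd(aln$flag, 4L) == 0L & aln$mapq >= min_mapq
  if (paired) elig <- elig & bitwAnd(aln$flag, 2L) == 2L
  pool <- aln[elig, , drop = FALSE]
  if (paired) {
    units <- split(seq_len(nrow(pool)), pool$qname)
    units <- units[lengths(units) == 2L]
    avail <- 2L * length(units)
    if (n > avail) {
      stop(sprintf("requested %d records but only %d eligible", n, avail))
    }
    if (n %% 2L != 0L) {
      stop("n must be even when sampling read pairs")
    }
    take <- with_seed(seed, sample(length(units), n %/% 2L))
    out <- pool[sort(unlist(units[take], use.names = FALSE)), , drop = FALSE]
  } else {
    if (n > nrow(pool)) {
      stop(sprintf("requested %d records but only %d eligible", n, nrow(pool)))
    }
    take <- with_seed(seed, sample(nrow(pool), n))
    out <- pool[sort(take), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Per-intron coverage by intron-reads
#'
#' An intron-read is a read whose aligned bases fall entirely within the
#' intron (no gap). Boundary-spanning reads are reported separately and do
#' not count toward the retention thresholds.
#'
#' @param aln alignment table or SAM path
#' @param annotation `genome_annotation`
#' @param min_mapq MAPQ floor
#' @return data.frame with one row per distinct intron: `key`, `chrom`,
#'   `start`, `end`, `strand`, `gene_ids`, `intron_read_count`,
#'   `covered_fraction`, `boundary_read_count`, `left_exon_reads`,
#'   `right_exon_reads`
#' @export
intron_coverage <- function(aln, annotation, min_mapq = 10L) {
  if (is.character(aln)) aln <- read_sam(aln)
  stopifnot(inherits(annotation, "genome_annotation"))
  intr <- enumerate_introns(annotation)
  keep <- bitwAnd(aln$flag, 4L) == 0L & aln$mapq >= min_mapq &
    !grepl("N", aln$cigar, fixed = TRUE)
  a <- aln[keep, , drop = FALSE]
  a$end <- a$pos + cigar_ref_width(a$cigar) - 1L

  n_intr <- nrow(intr)
  res <- data.frame(
    key = intr$key, chrom = intr$chrom, start = intr$start, end = intr$end,
    strand = intr$strand, gene_ids = intr$gene_ids,
    intron_read_count = 0L, covered_fraction = 0,
    boundary_read_count = 0L, left_exon_reads = 0L, right_exon_reads = 0L,
    stringsAsFactors = FALSE
  )
  if (!n_intr) return(res)

  if (nrow(a)) {
    within <- overlap_hits(a$chrom, a$pos, a$end,
                           intr$chrom, intr$start, intr$end, type = "within")
    tab <- table(factor(within$subject, levels = seq_len(n_intr)))
    res$intron_read_count <- as.integer(tab)
    sp <- split(within$query, within$subject)
    for (s in names(sp)) {
      i <- as.integer(s)
      cov <- IRanges::reduce(IRanges::IRanges(a$pos[sp[[s]]], a$end[sp[[s]]]))
      res$covered_fraction[i] <-
        sum(IRanges::width(IRanges::restrict(cov, intr$start[i], intr$end[i]))) /
        (intr$end[i] - intr$start[i] + 1L)
    }
    anyhit <- overlap_hits(a$chrom, a$pos, a$end,
                           intr$chrom, intr$start, intr$end, type = "any")
    span <- setdiff(
      paste(anyhit$query, anyhit$subject),
      paste(within$query, within$subject)
    )
    if (length(span)) {
      sj <- as.integer(sub("^[0-9]+ ", "", span))
      tab <- table(factor(sj, levels = seq_len(n_intr)))
      res$boundary_read_count <- as.integer(tab)
    }
    # flanking exon read counts (reads overlapping the adjacent exons of the
    # transcripts carrying this intron)
    ex <- annotation$exons
    flank_counts <- function(fstart, fend, i) {
      hit <- overlap_hits(a$chrom, a$pos, a$end,
                          intr$chrom[i], fstart, fend, type = "any")
      length(unique(hit$query))
    }
    for (i in seq_len(n_intr)) {
      tx1 <- strsplit(intr$tx_ids[i], ",")[[1]][1]
      e <- ex[ex$tx_id == tx1, ]
      left <- e[e$end == intr$start[i] - 1L, ]
      right <- e[e$start == intr$end[i] + 1L, ]
      if (nrow(left)) res$left_exon_reads[i] <- flank_counts(left$start[1], left$end[1], i)
      if (nrow(right)) res$right_exon_reads[i] <- flank_counts(right$start[1], right$end[1], i)
    }
  }
  res
}
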