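#' Load a genome annotation from GFF3 or GTF
#'
#' Parses gene/transcript/exon (and optional CDS) features into an indexed
#' annotation object: genes, transcripts, exons, derived introns and the set
#' of annotated junctions used downstream to label junctions as known or
#' novel. Coordinates are 1-based inclusive throughout; a junction key is the
#' intron interval (see [junction_key()]).
#'
#' @param x path to a GFF3/GTF file, or a character vector of GFF lines
#' @param format `"auto"` (detect from extension / column-9 syntax),
#'   `"gff3"` or `"gtf"`
#' @param genome optional named [Biostrings::DNAStringSet]; when given,
#'   chromosome lengths are taken from it and every exon is validated against
#'   them
#' @return a `genome_annotation` object: a list with elements
#'   `chrom_lengths`, `genes`, `transcripts`, `exons`, `cds`, `introns`
#' @examples
#' gff <- c(
#'   "##gff-version 3",
#'   "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\tsrc\texon\t1\t200\t.\t+\t.\tParent=t1",
#'   "chr1\tsrc\texon\t301\t600\t.\t+\t.\tParent=t1",
#'   "chr1\tsrc\texon\t701\t1000\t.\t+\t.\tParent=t1"
#' )
#' ann <- read_annotation(gff)
#' nrow(ann$introns) # 2
#' @export
read_annotation <- function(x, format = c("auto", "gff3", "gtf"), genome = NULL) {
  format <- match.arg(format)
  if (length(x) > 1L || grepl("[\n\t]", x[1]) || startsWith(x[1], "#")) {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".gff")
    writeLines(lines, path)
    on.exit(unlink(path))
  } else {
    path <- x
    if (!file.exists(path)) stop("annotation file not found: ", path)
    lines <- readLines(path)
  }

  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1]]
    stop(sprintf("malformed annotation line %d: expected 9 tab-separated fields, found %d",
                 bad, nf[nf != 9L][1]))
  }

  if (format == "auto") {
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) {
      "gtf"
    } else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
      "gff3"
    } else if (any(grepl("transcript_id \"", lines[body], fixed = TRUE))) {
      "gtf"
    } else {
      "gff3"
    }
  }

  if (!any(body)) {
    return(empty_annotation())
  }

  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  type <- tolower(as.character(df$type))

  if (format == "gff3") {
    id <- as.character(df$ID)
    parent <- df$Parent # CharacterList
    first_parent <- vapply(parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else {
    id <- df$transcript_id %||% rep(NA_character_, nrow(df))
    first_parent <- NULL
  }

  is_gene <- type == "gene"
  is_tx <- type %in% c("mrna", "transcript")
  is_exon <- type == "exon"
  is_cds <- type == "cds"

  if (format == "gff3") {
    genes <- data.frame(
      gene_id = id[is_gene], chrom = df$seqnames[is_gene],
      strand = df$strand[is_gene],
      start = df$start[is_gene], end = df$end[is_gene],
      stringsAsFactors = FALSE
    )
    tx <- data.frame(
      tx_id = id[is_tx], gene_id = first_parent[is_tx],
      chrom = df$seqnames[is_tx], strand = df$strand[is_tx],
      stringsAsFactors = FALSE
    )
    exon_parent <- parent[is_exon]
    reps <- lengths(exon_parent)
    exons <- data.frame(
      tx_id = unlist(exon_parent),
      chrom = rep(df$seqnames[is_exon], reps),
      strand = rep(df$strand[is_exon], reps),
      start = rep(df$start[is_exon], reps),
      end = rep(df$end[is_exon], reps),
      stringsAsFactors = FALSE
    )
    cds_parent <- parent[is_cds]
    reps <- lengths(cds_parent)
    cds <- data.frame(
      tx_id = unlist(cds_parent),
      chrom = rep(df$seqnames[is_cds], reps),
      strand = rep(df$strand[is_cds], reps),
      start = rep(df$start[is_cds], reps),
      end = rep(df$end[is_cds], reps),
      stringsAsFactors = FALSE
    )
  } else {
    gene_of <- as.character(df$gene_id)
    genes <- if (any(is_gene)) {
      data.frame(
        gene_id = gene_of[is_gene], chrom = df$seqnames[is_gene],
        strand = df$strand[is_gene],
        start = df$start[is_gene], end = df$end[is_gene],
        stringsAsFactors = FALSE
      )
    } else NULL
    tx_rows <- if (any(is_tx)) which(is_tx) else NULL
    tx <- if (!is.null(tx_rows)) {
      data.frame(
        tx_id = id[tx_rows], gene_id = gene_of[tx_rows],
        chrom = df$seqnames[tx_rows], strand = df$strand[tx_rows],
        stringsAsFactors = FALSE
      )
    } else NULL
    exons <- data.frame(
      tx_id = id[is_exon], chrom = df$seqnames[is_exon],
      strand = df$strand[is_exon],
      start = df$start[is_exon], end = df$end[is_exon],
      stringsAsFactors = FALSE
    )
    exons$gene_hint <- gene_of[is_exon]
    cds <- data.frame(
      tx_id = id[is_cds], chrom = df$seqnames[is_cds],
      strand = df$strand[is_cds],
      start = df$start[is_cds], end = df$end[is_cds],
      stringsAsFactors = FALSE
    )
    if (is.null(tx)) {
      u <- !duplicated(exons$tx_id)
      tx <- data.frame(
        tx_id = exons$tx_id[u], gene_id = exons$gene_hint[u],
        chrom = exons$chrom[u], strand = exons$strand[u],
        stringsAsFactors = FALSE
      )
    }
    if (is.null(genes)) {
      sp <- split(seq_len(nrow(exons)), tx$gene_id[match(exons$tx_id, tx$tx_id)])
      genes <- do.call(rbind, lapply(names(sp), function(g) {
        i <- sp[[g]]
        data.frame(gene_id = g, chrom = exons$chrom[i][1],
                   strand = exons$strand[i][1],
                   start = min(exons$start[i]), end = max(exons$end[i]),
                   stringsAsFactors = FALSE)
      }))
    }
    exons$gene_hint <- NULL
  }

  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene id in annotation: ",
         genes$gene_id[duplicated(genes$gene_id)][1])
  }

  exons$gene_id <- tx$gene_id[match(exons$tx_id, tx$tx_id)]
  if (nrow(cds)) cds$gene_id <- tx$gene_id[match(cds$tx_id, tx$tx_id)]

  # order exons within transcript by coordinate and check non-overlap
  exons <- exons[order(exons$tx_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  for (t in unique(exons$tx_id)) {
    e <- exons[exons$tx_id == t, ]
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)])) {
      stop("overlapping exons within transcript ", t)
    }
  }
  exons$exon_rank <- stats::ave(exons$start, exons$tx_id, FUN = seq_along)

  # CDS containment in exons
  if (nrow(cds)) {
    hits <- overlap_hits(cds$chrom, cds$start, cds$end,
                         exons$chrom, exons$start, exons$end, type = "within")
    ok <- logical(nrow(cds))
    same_tx <- cds$tx_id[hits$query] == exons$tx_id[hits$subject]
    ok[unique(hits$query[same_tx])] <- TRUE
    if (!all(ok)) {
      stop("CDS interval not contained in exons of its transcript: ",
           cds$tx_id[!ok][1])
    }
  }

  chrom_lengths <- annotation_chrom_lengths(lines, genome, exons)
  too_far <- exons$end > chrom_lengths[exons$chrom]
  if (any(too_far, na.rm = TRUE)) {
    i <- which(too_far)[1]
    stop(sprintf("exon %s:%d-%d extends past chromosome length %d",
                 exons$chrom[i], exons$start[i], exons$end[i],
                 chrom_lengths[exons$chrom[i]]))
  }

  introns <- derive_introns(exons)

  structure(
    list(chrom_lengths = chrom_lengths, genes = genes, transcripts = tx,
         exons = exons, cds = cds, introns = introns),
    class = "genome_annotation"
  )
}

#' @noRd
empty_annotation <- function() {
  empty <- function(...) {
    cols <- c(...)
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df
  }
  structure(
    list(
      chrom_lengths = stats::setNames(integer(0), character(0)),
      genes = data.frame(gene_id = character(0), chrom = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE),
      transcripts = data.frame(tx_id = character(0), gene_id = character(0),
                               chrom = character(0), strand = character(0),
                               stringsAsFactors = FALSE),
      exons = data.frame(tx_id = character(0), chrom = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0), gene_id = character(0),
                         exon_rank = integer(0), stringsAsFactors = FALSE),
      cds = data.frame(),
      introns = data.frame(tx_id = character(0), gene_id = character(0),
                           chrom = character(0), strand = character(0),
                           start = integer(0), end = integer(0),
                           key = character(0), stringsAsFactors = FALSE)
    ),
    class = "genome_annotation"
  )
}

#' @noRd
annotation_chrom_lengths <- function(lines, genome, exons) {
  if (!is.null(genome)) {
    return(stats::setNames(Biostrings::width(genome), names(genome)))
  }
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (length(sr)) {
    parts <- strsplit(trimws(sr), "[ \t]+")
    return(stats::setNames(
      vapply(parts, function(p) as.integer(p[4]), 0L),
      vapply(parts, function(p) p[2], "")
    ))
  }
  # fall back to the rightmost exon per chromosome
  tapply(exons$end, exons$chrom, max)
}

#' @noRd
derive_introns <- function(exons) {
  out <- vector("list", length(unique(exons$tx_id)))
  k <- 0L
  for (t in unique(exons$tx_id)) {
    e <- exons[exons$tx_id == t, ]
    if (nrow(e) < 2L) next
    k <- k + 1L
    out[[k]] <- data.frame(
      tx_id = t, gene_id = e$gene_id[1], chrom = e$chrom[1],
      strand = e$strand[1],
      start = e$end[-nrow(e)] + 1L, end = e$start[-1] - 1L,
      stringsAsFactors = FALSE
    )
  }
  if (k == 0L) {
    return(data.frame(tx_id = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      key = character(0), stringsAsFactors = FALSE))
  }
  introns <- do.call(rbind, out[seq_len(k)])
  if (any(introns$start > introns$end)) {
    stop("zero-length intron implies adjacent exons within one transcript")
  }
  introns$key <- junction_key(introns$chrom, introns$start, introns$end)
  introns
}

#' Enumerate the distinct introns of an annotation
#'
#' @param annotation a `genome_annotation`
#' @return data.frame with one row per distinct intron: `chrom`, `start`,
#'   `end`, `strand`, `key`, and comma-separated `tx_ids` / `gene_ids` of the
#'   transcripts sharing it
#' @export
enumerate_introns <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  intr <- annotation$introns
  if (!nrow(intr)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      key = character(0), tx_ids = character(0),
                      gene_ids = character(0), stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(intr)), intr$key)
  res <- do.call(rbind, lapply(sp, function(i) {
    data.frame(
      chrom = intr$chrom[i][1], start = intr$start[i][1],
      end = intr$end[i][1], strand = intr$strand[i][1],
      key = intr$key[i][1],
      tx_ids = paste(sort(unique(intr$tx_id[i])), collapse = ","),
      gene_ids = paste(sort(unique(intr$gene_id[i])), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' The set of annotated junction keys
#'
#' Junctions found in this set are labeled "known" downstream; all others are
#' novel.
#'
#' @param annotation a `genome_annotation`
#' @return sorted character vector of junction keys
#' @export
annotated_junctions <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  sort(unique(annotation$introns$key))
}

#' Write an annotation back to GFF3
#'
#' @param annotation a `genome_annotation`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  cl <- annotation$chrom_lengths
  for (ch in names(cl)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ch, cl[[ch]]), con)
  }
  g <- annotation$genes
  tx <- annotation$transcripts
  ex <- annotation$exons
  cds <- annotation$cds
  for (i in seq_len(nrow(g))) {
    writeLines(sprintf("%s\tsplicescope\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom[i], g$start[i], g$end[i], g$strand[i],
                       g$gene_id[i]), con)
    for (t in tx$tx_id[tx$gene_id == g$gene_id[i]]) {
      e <- ex[ex$tx_id == t, ]
      writeLines(sprintf("%s\tsplicescope\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         e$chrom[1], min(e$start), max(e$end), e$strand[1],
                         t, g$gene_id[i]), con)
      writeLines(sprintf("%s\tsplicescope\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         e$chrom, e$start, e$end, e$strand, t), con)
      if (nrow(cds)) {
        cc <- cds[cds$tx_id == t, ]
        if (nrow(cc)) {
          writeLines(sprintf("%s\tsplicescope\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                             cc$chrom, cc$start, cc$end, cc$strand, t), con)
        }
      }
    }
  }
  invisible(path)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:",
      length(x$chrom_lengths), "chromosome(s),",
      nrow(x$genes), "gene(s),",
      nrow(x$transcripts), "transcript(s),",
      nrow(x$exons), "exon row(s),",
      length(unique(x$introns$key)), "distinct intron(s)\n")
  invisible(x)
}
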