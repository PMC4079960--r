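## In-silico splicing of event isoforms and premature-termination-codon
## (PTC) prediction. The variant transcript is spliced from the genome, the
## annotated CDS start is mapped into it, and translation proceeds with the
## standard nuclear code; a stop codon upstream of the annotated stop is a
## PTC. No NMD distance rule is applied.

#' @noRd
tx_coord <- function(pos, exons, strand) {
  # transcript coordinate (1-based, 5'->3') of a genomic base inside an exon
  exons <- exons[order(exons$start), , drop = FALSE]
  w <- exons$end - exons$start + 1L
  hit <- which(pos >= exons$start & pos <= exons$end)
  if (!length(hit)) return(NA_integer_)
  plus_coord <- sum(w[seq_len(hit - 1L)]) + (pos - exons$start[hit]) + 1L
  if (strand == "-") sum(w) - plus_coord + 1L else plus_coord
}

#' @noRd
spliced_seq <- function(genome, exons, strand) {
  exons <- exons[order(exons$start), , drop = FALSE]
  s <- paste(vapply(seq_len(nrow(exons)), function(i) {
    get_seq(genome, exons$chrom[i], exons$start[i], exons$end[i], "+")
  }, ""), collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Predict premature termination codons for event isoforms
#'
#' For intron-retention events the variant transcript keeps the intron (the
#' flanking exons fuse across it); for cassette-exon events the affected
#' exon is inserted into (or, if already present, removed from) the host
#' transcript. The variant is translated from the annotated CDS start;
#' `ptc_introduced` is `TRUE` when the first in-frame stop codon falls
#' upstream of the annotated stop. Events outside the CDS leave the reading
#' frame untouched (`ptc_introduced = FALSE`, region `5'UTR`/`3'UTR`). When
#' the host transcript has no CDS annotation the verdict is indeterminate
#' (`NA`).
#'
#' @param events events data.frame (types `IR` and `CE` are assessed; other
#'   types are returned indeterminate)
#' @param annotation a `genome_annotation` with CDS rows where available
#' @param genome named [Biostrings::DNAStringSet]
#' @return data.frame with `event_id`, `type`, `tx_id`, `region`
#'   (`5'UTR`/`CDS`/`3'UTR`/`NA`), `ptc_introduced`, `predicted_peptide_len`
#' @export
predict_ptc <- function(events, annotation, genome) {
  stopifnot(inherits(annotation, "genome_annotation"))
  out <- data.frame(
    event_id = events$event_id, type = events$type,
    tx_id = NA_character_, region = NA_character_,
    ptc_introduced = NA, predicted_peptide_len = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(events))) {
    if (!events$type[i] %in% c("IR", "CE")) next
    v <- ptc_one(events[i, ], annotation, genome)
    out$tx_id[i] <- v$tx_id
    out$region[i] <- v$region
    out$ptc_introduced[i] <- v$ptc
    out$predicted_peptide_len[i] <- v$pep
  }
  out
}

#' @noRd
ptc_one <- function(ev, annotation, genome) {
  none <- list(tx_id = NA_character_, region = NA_character_, ptc = NA,
               pep = NA_integer_)
  ex <- annotation$exons
  cds <- annotation$cds
  # host transcript: contains the event interval within its span; prefer one
  # with CDS annotation
  tx_cand <- unique(ex$tx_id[ex$gene_id %in% ev$gene_id])
  if (!length(tx_cand)) return(none)
  has_cds <- if (nrow(cds)) tx_cand %in% cds$tx_id else rep(FALSE, length(tx_cand))
  tx_cand <- tx_cand[order(!has_cds)]
  for (t in tx_cand) {
    e <- ex[ex$tx_id == t, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    strand <- e$strand[1]
    if (ev$type == "IR") {
      li <- which(e$end == ev$start - 1L)
      ri <- which(e$start == ev$end + 1L)
      if (!length(li) || !length(ri)) next
      var <- e
      var$end[li] <- var$end[ri]
      var <- var[-ri, , drop = FALSE]
    } else { # CE
      present <- any(e$start == ev$start & e$end == ev$end)
      if (present) {
        var <- e[!(e$start == ev$start & e$end == ev$end), , drop = FALSE]
        if (nrow(var) == nrow(e)) next
      } else {
        if (ev$start <= min(e$start) || ev$end >= max(e$end)) next
        var <- rbind(e, data.frame(tx_id = t, chrom = e$chrom[1],
                                   strand = strand, start = ev$start,
                                   end = ev$end, gene_id = e$gene_id[1],
                                   exon_rank = NA_real_,
                                   stringsAsFactors = FALSE)[names(e)])
        var <- var[order(var$start), , drop = FALSE]
      }
    }
    cc <- if (nrow(cds)) cds[cds$tx_id == t, , drop = FALSE] else cds[0, ]
    if (!nrow(cc)) {
      # region indeterminate without a CDS; report what is computable
      return(list(tx_id = t, region = NA_character_, ptc = NA,
                  pep = NA_integer_))
    }
    cds_start_g <- if (strand == "+") min(cc$start) else max(cc$end)
    cds_end_g <- if (strand == "+") max(cc$end) else min(cc$start)
    cds_start_tx <- tx_coord(cds_start_g, e, strand)
    cds_end_tx <- tx_coord(cds_end_g, e, strand)
    # transcript-upstream exonic base adjacent to the event, to place the
    # event in transcript coordinates
    anchor_g <- if (ev$type == "IR") {
      if (strand == "+") ev$start - 1L else ev$end + 1L
    } else if (strand == "+") {
      cand <- e$end[e$end < ev$start]
      if (!length(cand)) next else max(cand)
    } else {
      cand <- e$start[e$start > ev$end]
      if (!length(cand)) next else min(cand)
    }
    a_tx <- tx_coord(anchor_g, e, strand)
    if (is.na(a_tx)) next
    ins_point <- a_tx + 0.5
    region <- if (ins_point < cds_start_tx) {
      "5'UTR"
    } else if (ins_point > cds_end_tx) {
      "3'UTR"
    } else {
      "CDS"
    }
    ann_pep <- (cds_end_tx - cds_start_tx + 1L) %/% 3L - 1L
    if (region != "CDS") {
      return(list(tx_id = t, region = region, ptc = FALSE, pep = ann_pep))
    }
    mrna <- spliced_seq(genome, var, strand)
    start_var <- tx_coord(cds_start_g, var, strand)
    stop_var <- tx_coord(cds_end_g, var, strand)
    if (is.na(start_var)) next
    coding <- substr(mrna, start_var, nchar(mrna))
    coding <- substr(coding, 1L, 3L * (nchar(coding) %/% 3L))
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(coding), no.init.codon = TRUE
    ))
    stop_at <- regexpr("*", aa, fixed = TRUE)[1]
    ann_stop_codon <- if (!is.na(stop_var)) {
      (stop_var - start_var + 1L) %/% 3L
    } else {
      NA_integer_
    }
    ptc <- !is.na(ann_stop_codon) && stop_at > 0L && stop_at < ann_stop_codon
    pep <- if (stop_at > 0L) stop_at - 1L else nchar(aa)
    return(list(tx_id = t, region = region, ptc = ptc, pep = pep))
  }
  none
}
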