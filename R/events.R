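## Junction-based classification of alternative-splicing events.
##
## Operational definitions (strand-aware; "anchor" boundaries are exon/intron
## borders, a junction is its intron interval):
##  - CE  : exon E with junctions into and out of E plus one junction bridging
##          E's flanks (the exclusion junction).
##  - CCE : >= 2 chained exons bridged together by a single exclusion junction.
##  - MXE : two exons sharing outer anchors, each with inclusion junctions,
##          whose co-inclusion junction is absent from the junction set.
##  - A5SS/A3SS : >= 2 junctions sharing one anchor and differing at the
##          donor (5') or acceptor (3') side of the intron.
##  - AFE/ALE  : the shared-anchor pattern where the varying sites coincide
##          exactly with boundaries of distinct transcript-first (AFE) or
##          transcript-last (ALE) exons.

EVENT_TYPES <- c("CE", "A5SS", "A3SS", "MXE", "CCE", "AFE", "ALE", "IR")

#' @noRd
empty_events <- function() {
  data.frame(event_id = character(0), type = character(0),
             gene_id = character(0), chrom = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             inclusion_junctions = character(0),
             exclusion_junctions = character(0),
             anchor = integer(0), dominant_site = integer(0),
             alt_sites = character(0), novel = logical(0),
             stringsAsFactors = FALSE)
}

#' Classify alternative-splicing events from confident junctions
#'
#' Takes the filtered (confident) junction set plus the annotation's exon
#' structures and emits typed events: cassette exons (CE), coordinate
#' cassette exons (CCE), mutually exclusive exons (MXE), alternative 5'/3'
#' splice sites (A5SS/A3SS) and alternative first/last exons (AFE/ALE).
#' Intron retention is called separately from intronic coverage
#' ([call_intron_retention()]). The result is deterministic and invariant
#' under junction input order.
#'
#' @param junctions junction data.frame (`chrom`, `start`, `end`,
#'   `read_count`; `key`/`annotated`/`gene_id` added if missing)
#' @param annotation a `genome_annotation`
#' @return events data.frame; one row per event with its affected interval,
#'   inclusion/exclusion junction keys and, for alternative-site events, the
#'   dominant and alternative sites
#' @export
classify_events <- function(junctions, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!nrow(junctions)) return(empty_events())
  j <- junctions
  unknown <- !j$chrom %in% names(annotation$chrom_lengths)
  if (any(unknown)) {
    warning(sum(unknown), " junction(s) on unknown chromosome(s) skipped")
    j <- j[!unknown, , drop = FALSE]
  }
  if (is.null(j$key)) j$key <- junction_key(j$chrom, j$start, j$end)
  if (is.null(j$gene_id) || is.null(j$annotated)) {
    j <- annotate_junction_table(j[setdiff(names(j), c("gene_id", "annotated", "strand"))],
                                 annotation)
  }
  j <- j[order(j$chrom, j$start, j$end), , drop = FALSE]

  ex <- annotation$exons
  term <- terminal_exon_sets(annotation)
  ajset <- annotated_junctions(annotation)

  out <- list()
  for (g in unique(j$gene_id[!is.na(j$gene_id)])) {
    Jg <- j[!is.na(j$gene_id) & j$gene_id == g, , drop = FALSE]
    exg <- ex[ex$gene_id == g, , drop = FALSE]
    exg <- exg[!duplicated(exg[c("start", "end")]), , drop = FALSE]
    exg <- exg[order(exg$start), , drop = FALSE]
    strand <- annotation$genes$strand[annotation$genes$gene_id == g]
    res <- classify_gene(Jg, exg, g, strand, term, ajset)
    if (nrow(res)) out[[length(out) + 1L]] <- res
  }
  if (!length(out)) return(empty_events())
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$chrom, ev$start, ev$end, ev$type), , drop = FALSE]
  ev$event_id <- sprintf("EV%04d", seq_len(nrow(ev)))
  ev$novel <- NA
  rownames(ev) <- NULL
  ev[, names(empty_events())]
}

#' First/last exon sets per gene, in transcript orientation
#' @noRd
terminal_exon_sets <- function(annotation) {
  ex <- annotation$exons
  firsts <- character(0); lasts <- character(0)
  for (t in unique(ex$tx_id)) {
    e <- ex[ex$tx_id == t, ]
    e <- e[order(e$start), ]
    if (e$strand[1] == "-") {
      f <- nrow(e); l <- 1L
    } else {
      f <- 1L; l <- nrow(e)
    }
    firsts <- c(firsts, paste(e$chrom[f], e$start[f], e$end[f]))
    lasts <- c(lasts, paste(e$chrom[l], e$start[l], e$end[l]))
  }
  list(first = unique(firsts), last = unique(lasts))
}

#' @noRd
classify_gene <- function(Jg, exg, gene, strand, term, ajset) {
  has_j <- function(s, e) any(Jg$start == s & Jg$end == e)
  key_of <- function(s, e) junction_key(Jg$chrom[1], s, e)
  rows <- list()
  used_excl <- character(0)   # exclusion junction keys (CE/CCE)
  used_mxe <- character(0)    # MXE inclusion junction keys

  ## ---- CE / CCE: chains of exons bridged by one exclusion junction ----
  for (xi in seq_len(nrow(Jg))) {
    s0 <- Jg$start[xi]; e0 <- Jg$end[xi]
    inside <- exg[exg$start > s0 & exg$end < e0, , drop = FALSE]
    if (!nrow(inside)) next
    chains <- list()
    walk <- function(i, path) {
      path <- c(path, i)
      if (has_j(inside$end[i] + 1L, e0)) chains[[length(chains) + 1L]] <<- path
      nxt <- which(inside$start > inside$end[i])
      for (k in nxt) {
        if (has_j(inside$end[i] + 1L, inside$start[k] - 1L)) walk(k, path)
      }
    }
    entries <- which(vapply(seq_len(nrow(inside)),
                            function(i) has_j(s0, inside$start[i] - 1L), TRUE))
    for (i in entries) walk(i, integer(0))
    for (path in chains) {
      exons <- inside[path, , drop = FALSE]
      incl <- c(
        key_of(s0, exons$start[1] - 1L),
        if (nrow(exons) > 1L) {
          key_of(exons$end[-nrow(exons)] + 1L, exons$start[-1] - 1L)
        },
        key_of(exons$end[nrow(exons)] + 1L, e0)
      )
      used_excl <- c(used_excl, Jg$key[xi])
      rows[[length(rows) + 1L]] <- event_row(
        type = if (nrow(exons) == 1L) "CE" else "CCE",
        gene = gene, chrom = Jg$chrom[1], strand = strand,
        start = min(exons$start), end = max(exons$end),
        inclusion = incl, exclusion = Jg$key[xi]
      )
    }
  }

  ## ---- MXE: shared outer anchors, absent co-inclusion junction ----
  if (nrow(exg) >= 2L) {
    for (i in seq_len(nrow(exg) - 1L)) {
      for (k in (i + 1L):nrow(exg)) {
        E1 <- exg[i, ]; E2 <- exg[k, ]
        if (E1$end >= E2$start) next
        in1 <- Jg$start[Jg$end == E1$start - 1L]
        in2 <- Jg$start[Jg$end == E2$start - 1L]
        out1 <- Jg$end[Jg$start == E1$end + 1L]
        out2 <- Jg$end[Jg$start == E2$end + 1L]
        s <- intersect(in1, in2); e <- intersect(out1, out2)
        s <- s[s < E1$start]; e <- e[e > E2$end]
        if (!length(s) || !length(e)) next
        if (has_j(E1$end + 1L, E2$start - 1L)) next
        s <- max(s); e <- min(e)
        incl <- c(key_of(s, E1$start - 1L), key_of(E1$end + 1L, e),
                  key_of(s, E2$start - 1L), key_of(E2$end + 1L, e))
        used_mxe <- c(used_mxe, incl)
        rows[[length(rows) + 1L]] <- event_row(
          type = "MXE", gene = gene, chrom = Jg$chrom[1], strand = strand,
          start = E1$start, end = E2$end,
          inclusion = incl, exclusion = ""
        )
      }
    }
  }

  ## ---- shared-anchor groups: A5SS/A3SS/AFE/ALE ----
  pool <- Jg[!(Jg$key %in% used_excl) & !(Jg$key %in% used_mxe), , drop = FALSE]
  for (side in c("start", "end")) {
    groups <- split(seq_len(nrow(pool)), pool[[side]])
    for (grp in groups) {
      if (length(grp) < 2L) next
      gj <- pool[grp, , drop = FALSE]
      sites <- if (side == "start") gj$end else gj$start
      r <- alt_site_event(gj, sites, side, strand, exg, term, ajset, gene)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }

  if (!length(rows)) return(empty_events()[0, setdiff(names(empty_events()), c("event_id", "novel"))])
  ev <- do.call(rbind, rows)
  ev[!duplicated(ev[c("type", "chrom", "start", "end")]), , drop = FALSE]
}

#' @noRd
event_row <- function(type, gene, chrom, strand, start, end, inclusion,
                      exclusion, anchor = NA_integer_,
                      dominant = NA_integer_, alt = "") {
  data.frame(type = type, gene_id = gene, chrom = chrom, strand = strand,
             start = as.integer(start), end = as.integer(end),
             inclusion_junctions = paste(inclusion, collapse = ";"),
             exclusion_junctions = paste(exclusion, collapse = ";"),
             anchor = as.integer(anchor), dominant_site = as.integer(dominant),
             alt_sites = alt, stringsAsFactors = FALSE)
}

#' Classify one shared-anchor junction group
#' @noRd
alt_site_event <- function(gj, sites, side, strand, exg, term, ajset, gene) {
  # which splice-site side varies: group by start varies the genomic right
  # boundary of the intron, group by end varies the left.
  vary_right <- side == "start"
  if (vary_right) {
    bound <- sites + 1L # exon starts abutting the varying acceptor/donor
    match_ex <- lapply(bound, function(b) which(exg$start == b))
  } else {
    bound <- sites - 1L
    match_ex <- lapply(bound, function(b) which(exg$end == b))
  }
  term_kind <- if (vary_right) {
    if (strand == "+") "last" else "first"
  } else {
    if (strand == "+") "first" else "last"
  }
  matched_terminal <- vapply(match_ex, function(ix) {
    length(ix) > 0L &&
      any(paste(exg$chrom[ix], exg$start[ix], exg$end[ix]) %in% term[[term_kind]])
  }, TRUE)
  exon_ids <- vapply(match_ex, function(ix) if (length(ix)) ix[1] else NA_integer_, 0L)
  uniq <- unique(exon_ids[!is.na(exon_ids)])
  disjoint <- length(uniq) >= 2L && {
    m <- exg[uniq, , drop = FALSE]
    m <- m[order(m$start), , drop = FALSE]
    all(m$start[-1] > m$end[-nrow(m)])
  }
  # distinct, non-overlapping terminal exons = a genuine alternative
  # first/last exon; overlapping ones are an alternative site within one exon
  if (all(matched_terminal) && disjoint) {
    type <- if (term_kind == "first") "AFE" else "ALE"
  } else {
    ss5 <- (vary_right && strand == "-") || (!vary_right && strand == "+")
    type <- if (ss5) "A5SS" else "A3SS"
  }
  ann <- gj$key %in% ajset
  dominant <- if (sum(ann) == 1L) {
    sites[ann]
  } else {
    cand <- which(gj$read_count == max(gj$read_count))
    if (length(cand) > 1L && any(ann[cand])) cand <- cand[ann[cand]]
    sites[cand[which.min(sites[cand])]]
  }
  event_row(
    type = type, gene = gene, chrom = gj$chrom[1], strand = strand,
    start = min(sites), end = max(sites),
    inclusion = sort(gj$key), exclusion = "",
    anchor = gj[[side]][1], dominant = dominant,
    alt = paste(sort(setdiff(sites, dominant)), collapse = ";")
  )
}

#' Intron-retention calling criteria
#'
#' A retained intron needs at least `min_intron_reads` intron-reads
#' (inclusive, default 5) and strictly more than `min_breadth` of its bases
#' covered by intron-reads (default 0.8).
#'
#' @param min_intron_reads inclusive read threshold
#' @param min_breadth exclusive covered-fraction threshold, in `[0, 1]`
#' @export
ir_criteria <- function(min_intron_reads = 5L, min_breadth = 0.8) {
  stopifnot(min_breadth >= 0, min_breadth <= 1)
  structure(list(min_intron_reads = as.integer(min_intron_reads),
                 min_breadth = min_breadth),
            class = "ir_criteria")
}

#' Call intron retention from intronic coverage
#'
#' @param coverage per-intron coverage data.frame from [intron_coverage()]
#'   (or any table with `key`, `intron_read_count`, `covered_fraction`)
#' @param criteria an [ir_criteria()]
#' @param annotation optional `genome_annotation`; when given, coverage rows
#'   whose intron is not annotated are skipped with a warning
#' @return the subset of introns called retained
#' @export
call_intron_retention <- function(coverage, criteria = ir_criteria(),
                                  annotation = NULL) {
  stopifnot_cols(coverage, c("key", "intron_read_count", "covered_fraction"),
                 "intron coverage table")
  cov <- coverage
  if (!is.null(annotation)) {
    known <- annotated_junctions(annotation)
    bad <- !cov$key %in% known
    if (any(bad)) {
      warning(sum(bad), " coverage row(s) for unannotated introns skipped")
      cov <- cov[!bad, , drop = FALSE]
    }
  }
  keep <- cov$intron_read_count >= criteria$min_intron_reads &
    cov$covered_fraction > criteria$min_breadth
  out <- cov[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert intron-retention calls to event rows
#'
#' @param ir_calls output of [call_intron_retention()]
#' @return events data.frame rows of type `"IR"`
#' @export
ir_as_events <- function(ir_calls) {
  if (!nrow(ir_calls)) return(empty_events())
  data.frame(
    event_id = sprintf("IR%04d", seq_len(nrow(ir_calls))),
    type = "IR",
    gene_id = vapply(strsplit(ir_calls$gene_ids %||% rep("", nrow(ir_calls)), ","),
                     function(x) if (length(x)) x[1] else NA_character_, ""),
    chrom = ir_calls$chrom, strand = ir_calls$strand,
    start = ir_calls$start, end = ir_calls$end,
    inclusion_junctions = "", exclusion_junctions = ir_calls$key,
    anchor = NA_integer_, dominant_site = NA_integer_, alt_sites = "",
    novel = NA, stringsAsFactors = FALSE
  )
}

#' Label events as annotated or novel
#'
#' A junction-defined event is novel when any of its defining junctions is
#' absent from the annotated junction set. An IR event is novel when no
#' annotated exon spans the retained intron together with both flanks.
#'
#' @param events events data.frame
#' @param annotation a `genome_annotation`
#' @return `events` with the `novel` column filled
#' @export
annotate_novelty <- function(events, annotation) {
  if (!nrow(events)) return(events)
  ajset <- annotated_junctions(annotation)
  ex <- annotation$exons
  novel <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (events$type[i] == "IR") {
      spanning <- ex$chrom == events$chrom[i] &
        ex$start <= events$start[i] - 1L & ex$end >= events$end[i] + 1L
      novel[i] <- !any(spanning)
    } else {
      keys <- unlist(strsplit(c(events$inclusion_junctions[i],
                                events$exclusion_junctions[i]), ";"))
      keys <- keys[nzchar(keys)]
      novel[i] <- !all(keys %in% ajset)
    }
  }
  events$novel <- novel
  events
}
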