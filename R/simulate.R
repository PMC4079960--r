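## Synthetic splicing experiment: a toy genome with multi-exon GT-AG genes,
## planted AS events of every classified type, condition-dependent inclusion
## shifts (the DAS truth), simulated counts and spliced alignments including
## decoy-like artifact junctions (short anchors, single read). Everything is
## deterministic under the spec seed.

#' Specification of a synthetic splicing experiment
#'
#' Defaults describe a small but fully featured experiment: 4 chromosomes,
#' 40 genes of 6-8 exons with 101 bp reads, a planted event mix covering all
#' eight event classes, a 30% differential fraction with inclusion shift
#' 0.3, and a 10% spurious-junction artifact rate mimicking non-specific
#' alignment (anchors of at most 20 bp, single-read support).
#'
#' @param n_chromosomes,n_genes genome size
#' @param exons_per_gene,exon_len,intron_len structural ranges (bp)
#' @param read_len read length (bp)
#' @param junction_depth reads per supported junction in simulated alignments
#' @param exon_depth reads per exon
#' @param ir_depth intron-read budget of a fully retained intron
#' @param event_depth per-condition read depth of the count model
#' @param event_mix named counts of planted events per type
#' @param das_fraction fraction of planted events given a condition shift
#' @param delta_psi inclusion shift of differential events
#' @param psi_base,ir_psi baseline inclusion levels (junction events / IR)
#' @param offset_choices,offset_weights distribution of planted
#'   alternative-site offsets (transcript orientation, bp); concentrated at
#'   +/- 4 by default
#' @param artifact_rate spurious junctions per true junction
#' @param conditions condition labels; the first is the control
#' @param intergenic_gap bp between genes
#' @param seed master RNG seed
#' @export
synthetic_spec <- function(n_chromosomes = 4L, n_genes = 40L,
                           exons_per_gene = c(6L, 8L),
                           exon_len = c(120L, 260L),
                           intron_len = c(90L, 160L),
                           read_len = 101L,
                           junction_depth = 12L, exon_depth = 8L,
                           ir_depth = 20L, event_depth = 300L,
                           event_mix = c(CE = 6L, A5SS = 8L, A3SS = 8L,
                                         MXE = 2L, CCE = 2L, AFE = 2L,
                                         ALE = 2L, IR = 8L),
                           das_fraction = 0.3, delta_psi = 0.3,
                           psi_base = 0.4, ir_psi = 0.6,
                           offset_choices = c(4L, -4L, 8L, -8L, 12L, -12L),
                           offset_weights = c(0.35, 0.35, 0.1, 0.1, 0.05, 0.05),
                           artifact_rate = 0.1,
                           conditions = c("control", "treatment"),
                           intergenic_gap = 400L, seed = 1L) {
  stopifnot(n_chromosomes >= 2L, n_genes >= 1L, read_len > 2L,
            delta_psi >= 0, delta_psi <= 1, das_fraction >= 0,
            das_fraction <= 1, length(conditions) >= 2L)
  if (exon_len[1] < read_len + max(abs(offset_choices)) + 5L) {
    stop("exon_len[1] must exceed read_len + max offset so anchors stay exonic")
  }
  if (intron_len[1] <= 2L * max(abs(offset_choices))) {
    stop("intron_len[1] too small for the requested offsets")
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    exon_len = as.integer(exon_len), intron_len = as.integer(intron_len),
    read_len = as.integer(read_len),
    junction_depth = as.integer(junction_depth),
    exon_depth = as.integer(exon_depth), ir_depth = as.integer(ir_depth),
    event_depth = as.integer(event_depth), event_mix = event_mix,
    das_fraction = das_fraction, delta_psi = delta_psi,
    psi_base = psi_base, ir_psi = ir_psi,
    offset_choices = as.integer(offset_choices),
    offset_weights = offset_weights, artifact_rate = artifact_rate,
    conditions = conditions, intergenic_gap = as.integer(intergenic_gap),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @noRd
rc_string <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

#' write `seq` (given in transcript orientation) into a chromosome string
#' @noRd
write_tx_seq <- function(chrom_seq, start, end, strand, s) {
  if (strand == "-") s <- rc_string(s)
  stopifnot(nchar(s) == end - start + 1L)
  substr(chrom_seq, start, end) <- s
  chrom_seq
}

#' genomic interval of transcript-oriented offsets a..b within [s, e]
#' @noRd
tx_offset_interval <- function(s, e, strand, a, b) {
  if (strand == "+") c(s + a - 1L, s + b - 1L) else c(e - b + 1L, e - a + 1L)
}

#' Generate the synthetic genome, annotation and planted event structure
#'
#' Every intron (annotated and planted-alternative) begins GT and ends AG in
#' transcript orientation. Alternative first/last exons are emitted as a
#' second annotated transcript of their host gene; all other planted events
#' are novel relative to the annotation. Deterministic under the spec seed.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   (`genome_annotation`), `truth` (list of `events`, `junctions`,
#'   `offsets` data.frames)
#' @export
generate_genome_and_annotation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, build_synthetic(spec))
}

#' @noRd
build_synthetic <- function(spec) {
  ng <- spec$n_genes
  mix <- spec$event_mix
  strands <- rep(c("+", "-"), length.out = ng)
  n_ex <- sample(spec$exons_per_gene[1]:spec$exons_per_gene[2], ng,
                 replace = TRUE)

  # host assignment: one planted event per gene
  need <- rep(names(mix), times = mix)
  host <- rep(NA_character_, ng)
  for (ty in need) {
    ok <- which(is.na(host))
    if (ty %in% c("AFE", "ALE")) ok <- ok[strands[ok] == "+"]
    if (ty %in% c("MXE", "CCE")) ok <- ok[n_ex[ok] >= 6L]
    if (!length(ok)) {
      stop("event mix exceeds genome capacity: no free host gene for ", ty)
    }
    host[ok[1]] <- ty
  }

  genes <- vector("list", ng)
  chrom_names <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  cursor <- stats::setNames(rep(500L, spec$n_chromosomes), chrom_names)

  for (i in seq_len(ng)) {
    n <- n_ex[i]
    strand <- strands[i]
    ty <- host[i]
    exlen <- sample(spec$exon_len[1]:spec$exon_len[2], n, replace = TRUE)
    ilen <- sample(spec$intron_len[1]:spec$intron_len[2], n - 1L,
                   replace = TRUE)

    g <- list(idx = i, id = sprintf("g%03d", i), strand = strand, type = ty,
              n = n)
    if (!is.na(ty) && ty == "IR") {
      # a quarter of IR hosts retain their 5'UTR intron, the rest a CDS one
      ir_rank <- sum(host[seq_len(i)] == "IR", na.rm = TRUE)
      utr <- ir_rank <= max(1L, floor(mix[["IR"]] / 4))
      tx_intron <- if (utr) 1L else 2L
      gi <- if (strand == "+") tx_intron else n - tx_intron
      ilen[gi] <- spec$read_len + 60L + sample(0:40, 1L)
      g$ir_gi <- gi
      g$ir_region <- if (utr) "5'UTR" else "CDS"
    }
    if (!is.na(ty) && ty == "AFE") {
      g$f2_len <- sample(spec$exon_len[1]:spec$exon_len[2], 1L)
      g$gap1 <- sample(60:90, 1L); g$gap2 <- sample(60:90, 1L)
      ilen[1] <- g$gap1 + g$f2_len + g$gap2
    }
    if (!is.na(ty) && ty == "ALE") {
      g$l2_len <- sample(spec$exon_len[1]:spec$exon_len[2], 1L)
      g$gap1 <- sample(60:90, 1L); g$gap2 <- sample(60:90, 1L)
      ilen[n - 1L] <- g$gap1 + g$l2_len + g$gap2
    }
    # keep the CDS (genomic exons 2..n-1) in frame
    w_cds <- sum(exlen[2:(n - 1L)])
    exlen[2] <- exlen[2] + (3L - w_cds %% 3L) %% 3L

    ch <- chrom_names[(i - 1L) %% spec$n_chromosomes + 1L]
    e_start <- integer(n); e_end <- integer(n)
    pos <- cursor[[ch]]
    for (j in seq_len(n)) {
      e_start[j] <- pos
      e_end[j] <- pos + exlen[j] - 1L
      pos <- e_end[j] + (if (j < n) ilen[j] else 0L) + 1L
    }
    cursor[[ch]] <- e_end[n] + spec$intergenic_gap + 1L
    g$chrom <- ch; g$e_start <- e_start; g$e_end <- e_end
    genes[[i]] <- g
  }
  chrom_len <- cursor + 500L

  # random chromosome sequences, then planted signal written over them
  seqs <- lapply(chrom_len, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  })

  exon_rows <- list(); tx_rows <- list(); gene_rows <- list()
  cds_rows <- list(); junc_rows <- list(); event_rows <- list()
  offset_rows <- list()
  add_junc <- function(g, s, e, annotated, role) {
    junc_rows[[length(junc_rows) + 1L]] <<- data.frame(
      chrom = g$chrom, start = s, end = e, strand = g$strand,
      gene_id = g$id, annotated = annotated, role = role,
      key = junction_key(g$chrom, s, e), stringsAsFactors = FALSE
    )
  }
  add_event <- function(g, type, start, end, novel, side = NA_character_,
                        offset = NA_integer_, region = NA_character_,
                        ptc_expected = NA) {
    event_rows[[length(event_rows) + 1L]] <<- data.frame(
      type = type, gene_id = g$id, chrom = g$chrom, strand = g$strand,
      start = start, end = end, novel = novel, side = side, offset = offset,
      region = region, ptc_expected = ptc_expected, stringsAsFactors = FALSE
    )
  }
  plant_intron <- function(ch, s, e, strand) {
    d <- tx_offset_interval(s, e, strand, 1L, 2L)
    a <- tx_offset_interval(s, e, strand, e - s, e - s + 1L)
    seqs[[ch]] <<- write_tx_seq(seqs[[ch]], d[1], d[2], strand, "GT")
    seqs[[ch]] <<- write_tx_seq(seqs[[ch]], a[1], a[2], strand, "AG")
  }

  for (g in genes) {
    n <- g$n; ch <- g$chrom; strand <- g$strand
    es <- g$e_start; ee <- g$e_end
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = g$id, chrom = ch, strand = strand,
      start = es[1], end = ee[n], stringsAsFactors = FALSE
    )
    t1 <- paste0(g$id, ".1")
    tx_rows[[length(tx_rows) + 1L]] <- data.frame(
      tx_id = t1, gene_id = g$id, chrom = ch, strand = strand,
      stringsAsFactors = FALSE
    )
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      tx_id = t1, chrom = ch, strand = strand, start = es, end = ee,
      stringsAsFactors = FALSE
    )
    # canonical introns: GT..AG and read support (except the MXE
    # co-inclusion intron, which stays annotated but unsupported)
    mxe_c <- if (!is.na(g$type) && g$type == "MXE") 3L else NA_integer_
    for (j in seq_len(n - 1L)) {
      s <- ee[j] + 1L; e <- es[j + 1L] - 1L
      plant_intron(ch, s, e, strand)
      if (is.na(mxe_c) || j != mxe_c) add_junc(g, s, e, TRUE, "canonical")
    }
    # CDS: ATG + stop-free codons + TAA over genomic exons 2..n-1
    cds_ex <- 2:(n - 1L)
    w <- sum(ee[cds_ex] - es[cds_ex] + 1L)
    codons <- setdiff(mkAllStrings_codons(), c("TAA", "TAG", "TGA"))
    body <- paste(sample(codons, w / 3L - 2L, replace = TRUE), collapse = "")
    cds_seq <- paste0("ATG", body, "TAA")
    ord <- if (strand == "+") cds_ex else rev(cds_ex)
    at <- 1L
    for (j in ord) {
      wj <- ee[j] - es[j] + 1L
      seqs[[ch]] <- write_tx_seq(seqs[[ch]], es[j], ee[j], strand,
                                 substr(cds_seq, at, at + wj - 1L))
      at <- at + wj
    }
    cds_rows[[length(cds_rows) + 1L]] <- data.frame(
      tx_id = t1, chrom = ch, strand = strand,
      start = es[cds_ex], end = ee[cds_ex], stringsAsFactors = FALSE
    )

    if (is.na(g$type)) next
    if (g$type == "CE") {
      c0 <- ceiling(n / 2)
      add_junc(g, ee[c0 - 1L] + 1L, es[c0 + 1L] - 1L, FALSE, "exclusion")
      add_event(g, "CE", es[c0], ee[c0], novel = TRUE)
    } else if (g$type == "CCE") {
      c0 <- 3L
      add_junc(g, ee[c0 - 1L] + 1L, es[c0 + 2L] - 1L, FALSE, "exclusion")
      add_event(g, "CCE", es[c0], ee[c0 + 1L], novel = TRUE)
    } else if (g$type == "MXE") {
      c0 <- 3L # exons c0, c0+1 mutually exclusive; flanks c0-1, c0+2
      add_junc(g, ee[c0] + 1L, es[c0 + 2L] - 1L, FALSE, "mxe_cross")
      add_junc(g, ee[c0 - 1L] + 1L, es[c0 + 1L] - 1L, FALSE, "mxe_cross")
      add_event(g, "MXE", es[c0], ee[c0 + 1L], novel = TRUE)
    } else if (g$type %in% c("A5SS", "A3SS")) {
      k <- 2L # host intron (genomic index)
      s <- ee[k] + 1L; e <- es[k + 1L] - 1L
      o <- sample(spec$offset_choices, 1L, prob = spec$offset_weights)
      if (g$type == "A5SS") {
        if (strand == "+") {
          alt <- c(s + o, e); dom_site <- s; alt_site <- s + o
        } else {
          alt <- c(s, e - o); dom_site <- e; alt_site <- e - o
        }
        d <- tx_offset_interval(alt[1], alt[2], strand, 1L, 2L)
        seqs[[ch]] <- write_tx_seq(seqs[[ch]], d[1], d[2], strand, "GT")
        side <- "5'SS"
      } else {
        if (strand == "+") {
          alt <- c(s, e + o); dom_site <- e; alt_site <- e + o
        } else {
          alt <- c(s - o, e); dom_site <- s; alt_site <- s - o
        }
        w_alt <- alt[2] - alt[1] + 1L
        a <- tx_offset_interval(alt[1], alt[2], strand, w_alt - 1L, w_alt)
        seqs[[ch]] <- write_tx_seq(seqs[[ch]], a[1], a[2], strand, "AG")
        side <- "3'SS"
      }
      add_junc(g, alt[1], alt[2], FALSE, "alt_site")
      add_event(g, g$type, min(dom_site, alt_site), max(dom_site, alt_site),
                novel = TRUE, side = side, offset = o)
      offset_rows[[length(offset_rows) + 1L]] <- data.frame(
        gene_id = g$id, side = side, offset = o, stringsAsFactors = FALSE
      )
    } else if (g$type == "IR") {
      gi <- g$ir_gi
      s <- ee[gi] + 1L; e <- es[gi + 1L] - 1L
      if (g$ir_region == "CDS") {
        # in-frame stop inside the retained intron: the CDS bases upstream
        # of this intron are the width of transcript exon 2
        w2 <- if (strand == "+") ee[2] - es[2] + 1L else ee[n - 1L] - es[n - 1L] + 1L
        p <- ((3L - w2 %% 3L) %% 3L) + 1L
        iv <- tx_offset_interval(s, e, strand, p + 3L, p + 5L)
        seqs[[ch]] <- write_tx_seq(seqs[[ch]], iv[1], iv[2], strand, "TAA")
      }
      add_event(g, "IR", s, e, novel = TRUE, region = g$ir_region,
                ptc_expected = (g$ir_region == "CDS"))
    } else if (g$type == "AFE") {
      f2s <- ee[1] + g$gap1 + 1L; f2e <- f2s + g$f2_len - 1L
      t2 <- paste0(g$id, ".2")
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        tx_id = t2, gene_id = g$id, chrom = ch, strand = strand,
        stringsAsFactors = FALSE
      )
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        tx_id = t2, chrom = ch, strand = strand,
        start = c(f2s, es[-1]), end = c(f2e, ee[-1]),
        stringsAsFactors = FALSE
      )
      plant_intron(ch, f2e + 1L, es[2] - 1L, strand)
      add_junc(g, f2e + 1L, es[2] - 1L, TRUE, "afe_alt")
      add_event(g, "AFE", min(ee[1] + 1L, f2e + 1L), max(ee[1] + 1L, f2e + 1L),
                novel = FALSE)
    } else if (g$type == "ALE") {
      l2s <- ee[n - 1L] + g$gap1 + 1L; l2e <- l2s + g$l2_len - 1L
      t2 <- paste0(g$id, ".2")
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        tx_id = t2, gene_id = g$id, chrom = ch, strand = strand,
        stringsAsFactors = FALSE
      )
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        tx_id = t2, chrom = ch, strand = strand,
        start = c(es[-n], l2s), end = c(ee[-n], l2e),
        stringsAsFactors = FALSE
      )
      plant_intron(ch, ee[n - 1L] + 1L, l2s - 1L, strand)
      add_junc(g, ee[n - 1L] + 1L, l2s - 1L, TRUE, "ale_alt")
      add_event(g, "ALE", min(es[n] - 1L, l2s - 1L), max(es[n] - 1L, l2s - 1L),
                novel = FALSE)
    }
  }

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chrom_names

  exons <- do.call(rbind, exon_rows)
  tx <- do.call(rbind, tx_rows)
  gene_df <- do.call(rbind, gene_rows)
  cds <- do.call(rbind, cds_rows)
  exons <- exons[order(exons$tx_id, exons$start), , drop = FALSE]
  exons$gene_id <- tx$gene_id[match(exons$tx_id, tx$tx_id)]
  exons$exon_rank <- stats::ave(exons$start, exons$tx_id, FUN = seq_along)
  cds$gene_id <- tx$gene_id[match(cds$tx_id, tx$tx_id)]
  annotation <- structure(
    list(chrom_lengths = chrom_len, genes = gene_df, transcripts = tx,
         exons = exons, cds = cds, introns = derive_introns(exons)),
    class = "genome_annotation"
  )

  events <- do.call(rbind, event_rows)
  events$event_id <- sprintf("T%04d", seq_len(nrow(events)))
  junctions <- do.call(rbind, junc_rows)
  junctions <- junctions[!duplicated(junctions$key), , drop = FALSE]
  rownames(junctions) <- NULL
  offsets <- if (length(offset_rows)) do.call(rbind, offset_rows) else {
    data.frame(gene_id = character(0), side = character(0),
               offset = integer(0), stringsAsFactors = FALSE)
  }
  list(genome = genome, annotation = annotation,
       truth = list(events = events, junctions = junctions,
                    offsets = offsets))
}

#' @noRd
mkAllStrings_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
}

#' Assign inclusion levels and the differential truth to planted events
#'
#' Every planted event gets a per-condition inclusion level: the baseline
#' (`psi_base`, or `ir_psi` for intron retention) in the control, and for a
#' `das_fraction` of events a `delta_psi` shift (alternating sign) in every
#' treatment condition.
#'
#' @param sim output of [generate_genome_and_annotation()]
#' @param spec the [synthetic_spec()]
#' @return `sim` with `truth$events` gaining `das` and one `psi_<condition>`
#'   column per condition
#' @export
plant_events <- function(sim, spec) {
  ev <- sim$truth$events
  n <- nrow(ev)
  base <- ifelse(ev$type == "IR", spec$ir_psi, spec$psi_base)
  n_das <- round(spec$das_fraction * n)
  das_idx <- with_seed(spec$seed + 1L, sample(n, n_das))
  ev$das <- seq_len(n) %in% das_idx
  sign <- rep_len(c(1, -1), n)
  for (cond in spec$conditions) {
    psi <- base
    if (cond != spec$conditions[1]) {
      shift <- ifelse(ev$das, sign * spec$delta_psi, 0)
      psi <- pmin(0.95, pmax(0.05, base + shift))
    }
    ev[[paste0("psi_", cond)]] <- psi
  }
  sim$truth$events <- ev
  sim
}

#' Simulate per-event count tables
#'
#' For every planted event and condition, the event reads (junction reads,
#' or intron reads for IR) are binomial draws at the event's inclusion level
#' against the per-condition event depth; the corresponding exon reads are
#' the remainder of that depth. Deterministic under the spec seed.
#'
#' @param sim output of [plant_events()]
#' @param spec the [synthetic_spec()]
#' @param conditions condition labels to simulate (default all)
#' @return data.frame with `event_id`, `type`, `gene_id`, `condition`,
#'   `event_reads`, `exon_reads`, `covered_fraction`
#' @export
simulate_counts <- function(sim, spec, conditions = spec$conditions) {
  ev <- sim$truth$events
  if (is.null(ev$das)) stop("run plant_events() first")
  with_seed(spec$seed + 2L, {
    rows <- lapply(conditions, function(cond) {
      psi <- ev[[paste0("psi_", cond)]]
      er <- stats::rbinom(nrow(ev), spec$event_depth, psi)
      data.frame(
        event_id = ev$event_id, type = ev$type, gene_id = ev$gene_id,
        condition = cond, event_reads = er,
        exon_reads = spec$event_depth - er,
        covered_fraction = ifelse(ev$type == "IR" & er > 0L, 0.95, 0),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate independent event count pairs under a two-condition model
#'
#' A lightweight counts-only simulator for calibration studies: `n` events,
#' each with `event_reads ~ Binomial(depth, psi)` per condition and exon
#' reads the remainder of the depth.
#'
#' @param n number of events
#' @param depth per-condition event depth
#' @param psi_control,psi_treatment inclusion levels (equal = null)
#' @param seed RNG seed
#' @return data.frame with one row per event: `event_reads_control`,
#'   `exon_reads_control`, `event_reads_treatment`, `exon_reads_treatment`
#' @export
simulate_event_counts <- function(n, depth, psi_control, psi_treatment,
                                  seed = 1L) {
  with_seed(seed, {
    a <- stats::rbinom(n, depth, psi_control)
    c2 <- stats::rbinom(n, depth, psi_treatment)
    data.frame(event_reads_control = a, exon_reads_control = depth - a,
               event_reads_treatment = c2, exon_reads_treatment = depth - c2)
  })
}

#' Simulate spliced alignments for one condition
#'
#' True junction reads span their junction with the left anchor uniform on
#' `1..read_len-1`; exon reads lie fully inside exons; intron-reads cover
#' retained introns in proportion to their inclusion level; spurious
#' artifact junctions are emitted at the artifact rate with anchors of at
#' most 20 bp and a single read each (so the confident-junction filter
#' removes them by construction).
#'
#' @param sim output of [plant_events()]
#' @param spec the [synthetic_spec()]
#' @param condition condition label (default the control)
#' @return list with `alignments` (alignment table) and `spurious`
#'   (data.frame of planted artifact junctions)
#' @export
simulate_alignments <- function(sim, spec, condition = spec$conditions[1]) {
  ev <- sim$truth$events
  jn <- sim$truth$junctions
  L <- spec$read_len
  with_seed(spec$seed + 3L + match(condition, spec$conditions), {
    rows <- list()
    emit <- function(chrom, pos, cigar) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, pos = as.integer(pos), cigar = cigar,
        stringsAsFactors = FALSE
      )
    }
    for (i in seq_len(nrow(jn))) {
      ilen <- jn$end[i] - jn$start[i] + 1L
      a <- sample(seq_len(L - 1L), spec$junction_depth, replace = TRUE)
      emit(jn$chrom[i], jn$start[i] - a,
           sprintf("%dM%dN%dM", a, ilen, L - a))
    }
    ex <- sim$annotation$exons
    ex <- ex[!duplicated(ex[c("chrom", "start", "end")]), , drop = FALSE]
    for (i in seq_len(nrow(ex))) {
      w <- ex$end[i] - ex$start[i] + 1L
      len <- min(L, w)
      st <- sample(ex$start[i]:(ex$end[i] - len + 1L), spec$exon_depth,
                   replace = TRUE)
      emit(ex$chrom[i], st, sprintf("%dM", len))
    }
    ir <- ev[ev$type == "IR", , drop = FALSE]
    if (nrow(ir)) {
      psi <- ir[[paste0("psi_", condition)]]
      if (is.null(psi)) stop("condition not planted: ", condition)
      for (i in seq_len(nrow(ir))) {
        k <- round(psi[i] * spec$ir_depth)
        if (k < 1L) next
        w <- ir$end[i] - ir$start[i] + 1L
        st <- ir$start[i] + floor((w - L) * (seq_len(k) - 0.5) / k)
        emit(ir$chrom[i], st, sprintf("%dM", L))
      }
    }
    n_sp <- round(spec$artifact_rate * nrow(jn))
    sp_rows <- list()
    gdf <- sim$annotation$genes
    tries <- 0L
    while (length(sp_rows) < n_sp && tries < 50L * n_sp) {
      tries <- tries + 1L
      gi <- sample(nrow(gdf), 1L)
      s <- gdf$start[gi] + sample(150:400, 1L)
      e <- s + sample(60:150, 1L)
      if (e + L > gdf$end[gi]) next
      key <- junction_key(gdf$chrom[gi], s, e)
      if (key %in% jn$key || key %in% vapply(sp_rows, `[[`, "", "key")) next
      aa <- sample(1:20, 1L)
      emit(gdf$chrom[gi], s - aa, sprintf("%dM%dN%dM", aa, e - s + 1L, L - aa))
      sp_rows[[length(sp_rows) + 1L]] <- data.frame(
        chrom = gdf$chrom[gi], start = s, end = e, key = key,
        anchor = aa, stringsAsFactors = FALSE
      )
    }
    aln <- do.call(rbind, rows)
    aln <- data.frame(qname = sprintf("read%07d", seq_len(nrow(aln))),
                      flag = 0L, chrom = aln$chrom, pos = aln$pos,
                      mapq = 50L, cigar = aln$cigar,
                      stringsAsFactors = FALSE)
    spurious <- if (length(sp_rows)) do.call(rbind, sp_rows) else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 key = character(0), anchor = integer(0),
                 stringsAsFactors = FALSE)
    }
    list(alignments = aln, spurious = spurious)
  })
}

#' Simulate decoy-junction read support
#'
#' Emulates the alignment of reads to decoy junction sequences: short
#' overhangs (uniform on `overhang_range`) and mostly single-read coverage.
#'
#' @param n number of decoy junctions with read support
#' @param seed RNG seed
#' @param overhang_range range of maximum overhangs (bp)
#' @param p_single fraction of decoys with a single supporting read
#' @return junction table (`read_count`, `max_overhang`)
#' @export
simulate_decoy_support <- function(n, seed = 1L, overhang_range = c(1L, 15L),
                                   p_single = 0.6) {
  with_seed(seed, {
    data.frame(
      key = sprintf("decoy%06d", seq_len(n)),
      read_count = ifelse(stats::runif(n) < p_single, 1L,
                          1L + stats::rpois(n, 2L) + 1L),
      max_overhang = sample(overhang_range[1]:overhang_range[2], n,
                            replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate annotated-junction read support
#'
#' Annotated junctions carry large overhangs (enriched near 90 bp) and
#' higher read coverage, mirroring what real libraries show for known
#' introns.
#'
#' @param n number of junctions
#' @param seed RNG seed
#' @return junction table (`read_count`, `max_overhang`)
#' @export
simulate_annotated_support <- function(n, seed = 1L) {
  with_seed(seed, {
    data.frame(
      key = sprintf("known%06d", seq_len(n)),
      read_count = 1L + stats::rpois(n, 4L),
      max_overhang = pmax(1L, pmin(100L, round(stats::rnorm(n, 85, 15)))),
      stringsAsFactors = FALSE
    )
  })
}

#' Run the full synthetic generation (structure + inclusion levels)
#'
#' @param spec a [synthetic_spec()]
#' @return list with `genome`, `annotation`, `truth`
#' @export
simulate_splicing_experiment <- function(spec = synthetic_spec()) {
  plant_events(generate_genome_and_annotation(spec), spec)
}
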