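#' Donor/acceptor dinucleotides of junctions
#'
#' The donor dinucleotide is the first two intron bases and the acceptor the
#' last two, read in transcript orientation (reported in the DNA alphabet,
#' so the canonical pair is GT/AG). Junctions without a resolved strand are
#' skipped with a warning.
#'
#' @param junctions junction data.frame with `chrom`, `start`, `end`,
#'   `strand`
#' @param genome named [Biostrings::DNAStringSet]
#' @return list with `per_junction` (key, donor, acceptor) and `freq`
#'   (table of donor/acceptor pairs)
#' @export
splice_site_dinucleotides <- function(junctions, genome) {
  stopifnot_cols(junctions, c("chrom", "start", "end", "strand"),
                 "junction table")
  j <- junctions
  unresolved <- !j$strand %in% c("+", "-")
  if (any(unresolved)) {
    warning(sum(unresolved), " junction(s) without strand skipped")
    j <- j[!unresolved, , drop = FALSE]
  }
  n <- nrow(j)
  donor <- character(n); acceptor <- character(n)
  for (i in seq_len(n)) {
    if (j$strand[i] == "+") {
      donor[i] <- get_seq(genome, j$chrom[i], j$start[i], j$start[i] + 1L, "+")
      acceptor[i] <- get_seq(genome, j$chrom[i], j$end[i] - 1L, j$end[i], "+")
    } else {
      donor[i] <- get_seq(genome, j$chrom[i], j$end[i] - 1L, j$end[i], "-")
      acceptor[i] <- get_seq(genome, j$chrom[i], j$start[i], j$start[i] + 1L, "-")
    }
  }
  per <- data.frame(key = junction_key(j$chrom, j$start, j$end),
                    donor = donor, acceptor = acceptor,
                    stringsAsFactors = FALSE)
  list(per_junction = per,
       freq = table(pair = paste(donor, acceptor, sep = "/")))
}

#' Offsets of alternative splice sites from the dominant site
#'
#' For each A5SS/A3SS event the offset of every alternative site from the
#' dominant one, signed in transcript orientation: positive means downstream
#' of the dominant site (for a 5' splice site, into the intron).
#'
#' @param events events data.frame (only `A5SS`/`A3SS` rows are used); needs
#'   the `dominant_site`/`alt_sites` columns filled by [classify_events()]
#' @param window half-width (bp) of the reported histogram
#' @return list with `offsets` (event_id, side, offset) and `histogram`
#'   (named vector over `-window:window`, position 0 removed)
#' @export
alt_ss_offsets <- function(events, window = 30L) {
  ev <- events[events$type %in% c("A5SS", "A3SS"), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    if (is.na(ev$dominant_site[i]) || !nzchar(ev$alt_sites[i])) next
    alt <- as.integer(strsplit(ev$alt_sites[i], ";")[[1]])
    off_gen <- alt - ev$dominant_site[i]
    off <- if (ev$strand[i] == "-") -off_gen else off_gen
    off <- off[off != 0L]
    if (!length(off)) next
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = ev$event_id[i],
      side = if (ev$type[i] == "A5SS") "5'SS" else "3'SS",
      offset = off, stringsAsFactors = FALSE
    )
  }
  offsets <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(event_id = character(0), side = character(0),
               offset = integer(0), stringsAsFactors = FALSE)
  }
  lev <- setdiff(-window:window, 0L)
  inside <- offsets$offset[abs(offsets$offset) <= window]
  hist <- table(factor(inside, levels = lev))
  list(offsets = offsets, histogram = hist)
}

#' Position frequency matrix around splice sites
#'
#' Extracts, strand-oriented, the bases at `window[1]..window[2]` relative
#' to each site (offset 0 = the site itself) and tallies them per position.
#' Column sums equal the number of contributing (non-skipped) sites.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`
#' @param genome named [Biostrings::DNAStringSet]
#' @param window integer length-2 vector of relative offsets
#' @return matrix with rows A/C/G/T and one column per offset; attribute
#'   `n_skipped` counts out-of-bounds sites
#' @export
site_pfm <- function(sites, genome, window = c(-3L, 6L)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  width <- window[2] - window[1] + 1L
  seqs <- character(0)
  skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]; p <- sites$pos[i]; s <- sites$strand[i]
    if (s == "+") {
      a <- p + window[1]; b <- p + window[2]
    } else {
      a <- p - window[2]; b <- p - window[1]
    }
    len <- Biostrings::width(genome[ch])
    if (a < 1L || b > len) {
      skipped <- skipped + 1L
      next
    }
    seqs <- c(seqs, get_seq(genome, ch, a, b, s))
  }
  pfm <- matrix(0L, nrow = 4L, ncol = width,
                dimnames = list(c("A", "C", "G", "T"),
                                as.character(window[1]:window[2])))
  if (length(seqs)) {
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
    for (b in c("A", "C", "G", "T")) {
      if (b %in% rownames(cm)) pfm[b, ] <- cm[b, ]
    }
  }
  attr(pfm, "n_skipped") <- skipped
  pfm
}

#' Co-occurrence of exon skipping and alternative splice sites
#'
#' Observed: the fraction of skipped (cassette) exons that also carry an
#' alternative 5'/3' splice site at one of their own boundaries (the
#' alternative-site event's dominant site abuts the exon). Expected: the
#' same fraction among `n_perm` random draws of annotated exons matched in
#' number. A Fisher exact test compares skipped versus sampled exons.
#'
#' @param events events data.frame from [classify_events()]
#' @param annotation a `genome_annotation`
#' @param n_perm number of random draws
#' @param seed RNG seed
#' @return a `cooccurrence_result` list with `observed_fraction`,
#'   `expected_fraction`, `p_value`, `n_skipped_exons`, `n_with_alt_ss`,
#'   `table`, or with `testable = FALSE` when there are no CE events
#' @export
skipping_altss_cooccurrence <- function(events, annotation, n_perm = 200L,
                                        seed = 1L) {
  ce <- events[events$type == "CE", , drop = FALSE]
  res <- list(observed_fraction = NA_real_, expected_fraction = NA_real_,
              p_value = NA_real_, n_skipped_exons = 0L, n_with_alt_ss = 0L,
              table = NULL, testable = FALSE)
  class(res) <- "cooccurrence_result"
  if (!nrow(ce)) return(res)
  alt <- events[events$type %in% c("A5SS", "A3SS"), , drop = FALSE]
  # an exon "has an alt SS" when some alternative-site event's dominant site
  # is immediately adjacent to one of the exon's boundaries
  has_alt <- function(chrom, start, end) {
    any(alt$chrom == chrom &
          (alt$dominant_site == end + 1L | alt$dominant_site == start - 1L),
        na.rm = TRUE)
  }
  hit <- vapply(seq_len(nrow(ce)),
                function(i) has_alt(ce$chrom[i], ce$start[i], ce$end[i]),
                TRUE)
  n_sk <- nrow(ce)
  obs_with <- sum(hit)

  ex <- annotation$exons
  ex <- ex[!duplicated(ex[c("chrom", "start", "end")]), , drop = FALSE]
  exp_with <- with_seed(seed, {
    draws <- vapply(seq_len(n_perm), function(r) {
      i <- sample(nrow(ex), n_sk, replace = nrow(ex) < n_sk)
      sum(vapply(i, function(k) has_alt(ex$chrom[k], ex$start[k], ex$end[k]),
                 TRUE))
    }, 0)
    sum(draws)
  })
  n_sampled <- n_perm * n_sk
  tab <- rbind(skipped = c(obs_with, n_sk - obs_with),
               sampled = c(exp_with, n_sampled - exp_with))
  ft <- fisher_exact_2x2(tab)
  res$observed_fraction <- obs_with / n_sk
  res$expected_fraction <- exp_with / n_sampled
  res$p_value <- ft$p_value
  res$n_skipped_exons <- n_sk
  res$n_with_alt_ss <- obs_with
  res$table <- tab
  res$testable <- TRUE
  res
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  if (!x$testable) {
    cat("exon-skipping x alt-SS co-occurrence: untestable (no CE events)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "exon-skipping x alt-SS co-occurrence: %d/%d skipped exons (%.1f%%) vs %.2f%% expected, p = %.3g\n",
    x$n_with_alt_ss, x$n_skipped_exons, 100 * x$observed_fraction,
    100 * x$expected_fraction, x$p_value))
  invisible(x)
}
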