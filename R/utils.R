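#' @keywords internal
"_PACKAGE"

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Junction key
#'
#' A junction is identified by its intron interval: chromosome, first intron
#' base and last intron base (1-based, inclusive). Strand is carried as an
#' attribute elsewhere so that known/novel matching is strand-agnostic.
#'
#' @param chrom chromosome id
#' @param start first base of the intron
#' @param end last base of the intron
#' @return character vector of keys `"chrom:start-end"`
#' @export
junction_key <- function(chrom, start, end) {
  stopifnot(all(start <= end))
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' @noRd
parse_junction_key <- function(key) {
  m <- regmatches(key, regexec("^(.*):([0-9]+)-([0-9]+)$", key))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed junction key: ", key[bad][1])
  data.frame(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' @noRd
stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
}

## Per-chromosome interval overlap helpers built on IRanges.

#' @noRd
overlap_hits <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end,
                         type = c("any", "within")) {
  type <- match.arg(type)
  qh <- integer(0); sh <- integer(0)
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch)
    si <- which(s_chrom == ch)
    if (!length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(q_start[qi], q_end[qi]),
      IRanges::IRanges(s_start[si], s_end[si]),
      type = type
    )
    qh <- c(qh, qi[S4Vectors::queryHits(hits)])
    sh <- c(sh, si[S4Vectors::subjectHits(hits)])
  }
  list(query = qh, subject = sh)
}

#' Fetch genomic sequence, strand-aware
#'
#' @param genome a named [Biostrings::DNAStringSet] (one entry per chromosome)
#' @param chrom,start,end 1-based inclusive interval
#' @param strand `"+"` or `"-"`; minus returns the reverse complement
#' @return a character scalar
#' @export
get_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- Biostrings::width(genome[chrom])
  if (start < 1L || end > len) {
    stop(sprintf("interval %s:%d-%d outside chromosome bounds (1-%d)",
                 chrom, start, end, len))
  }
  s <- Biostrings::subseq(genome[[chrom]], start, end)
  if (identical(strand, "-")) s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
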