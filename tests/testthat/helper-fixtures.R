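# Independent hypergeometric enumeration oracle for the two-sided Fisher
# test: log-probabilities from lchoose, p = sum of probabilities of tables
# (with the observed margins) at most as probable as the observed one.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(1)
  x <- max(0, c1 - r2):min(c1, r1)
  lp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  lp_obs <- lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  min(1, sum(exp(lp[lp <= lp_obs + 1e-7])))
}

# One-gene GFF3 fixture: exons as a list of c(start, end) pairs, optional
# CDS intervals.
gff_one_gene <- function(exons, cds = NULL, strand = "+", chrom = "chr1",
                         chrom_len = 10000L, gene_id = "g1", tx_id = "t1") {
  span <- range(unlist(exons))
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", chrom, chrom_len),
    sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            chrom, span[1], span[2], strand, gene_id),
    sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            chrom, span[1], span[2], strand, tx_id, gene_id)
  )
  for (e in exons) {
    lines <- c(lines, sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                              chrom, e[1], e[2], strand, tx_id))
  }
  for (e in cds) {
    lines <- c(lines, sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                              chrom, e[1], e[2], strand, tx_id))
  }
  lines
}

# SAM record builder (seq/qual omitted).
sam_line <- function(qname, chrom, pos, cigar, mapq = 50L, flag = 0L) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*", qname, flag, chrom, pos,
          mapq, cigar)
}

sam_file <- function(records, chrom_lengths = c(chr1 = 10000L)) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                       as.integer(chrom_lengths)),
               records), path)
  path
}

# Junction table row builder for filter/classifier tests.
jrow <- function(chrom, start, end, reads = 10L, overhang = 50L) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             key = junction_key(chrom, start, end),
             read_count = as.integer(reads),
             max_overhang = as.integer(overhang), stringsAsFactors = FALSE)
}

# Seeded evaluation for randomized test cases.
with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# A small cached synthetic experiment shared by slower tests.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(seed = 42L)
      cache <<- list(spec = spec, sim = simulate_splicing_experiment(spec))
    }
    cache
  }
})
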