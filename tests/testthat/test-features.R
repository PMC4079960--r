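test_that("donor/acceptor dinucleotides are extracted strand-aware", {
  # chr1: intron 21-60 carries GT..AG on the plus strand;
  # chr2: same motif encoded for a minus-strand gene (CT..AC genomically);
  # chr3: a GC..AG non-canonical donor
  s1 <- strrep("A", 100); substr(s1, 21, 22) <- "GT"; substr(s1, 59, 60) <- "AG"
  s2 <- strrep("A", 100); substr(s2, 21, 22) <- "CT"; substr(s2, 59, 60) <- "AC"
  s3 <- strrep("A", 100); substr(s3, 21, 22) <- "GC"; substr(s3, 59, 60) <- "AG"
  genome <- Biostrings::DNAStringSet(c(chr1 = s1, chr2 = s2, chr3 = s3))
  j <- data.frame(chrom = c("chr1", "chr2", "chr3"),
                  start = 21L, end = 60L, strand = c("+", "-", "+"),
                  stringsAsFactors = FALSE)
  dn <- splice_site_dinucleotides(j, genome)
  expect_equal(dn$per_junction$donor, c("GT", "GT", "GC"))
  expect_equal(dn$per_junction$acceptor, c("AG", "AG", "AG"))
  j$strand[2] <- "."
  expect_warning(dn2 <- splice_site_dinucleotides(j, genome), "strand")
  expect_equal(nrow(dn2$per_junction), 2L)
})

test_that("alternative-site offsets are signed in transcript orientation", {
  ev <- data.frame(
    event_id = c("E1", "E2", "E3"),
    type = c("A5SS", "A5SS", "A3SS"),
    gene_id = "g", chrom = "chr1",
    strand = c("+", "-", "+"),
    start = 0L, end = 0L,
    inclusion_junctions = "", exclusion_junctions = "",
    anchor = NA_integer_,
    dominant_site = c(100L, 200L, 300L),
    alt_sites = c("104", "196", "296;310"),
    novel = FALSE, stringsAsFactors = FALSE
  )
  off <- alt_ss_offsets(ev)
  # +4 downstream on both strands despite opposite genomic direction
  expect_equal(off$offsets$offset[off$offsets$event_id == "E1"], 4L)
  expect_equal(off$offsets$offset[off$offsets$event_id == "E2"], 4L)
  expect_setequal(off$offsets$offset[off$offsets$event_id == "E3"],
                  c(-4L, 10L))
  h <- off$histogram
  expect_equal(unname(h[names(h) == "4"]), 2L)
  expect_equal(sum(h), 4L)
})

test_that("position frequency matrices tally hand-checked fixtures", {
  # 5 sites over a known sequence; window -1..+2
  s <- "ACGTACGTACGTACGTACGT"
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  sites <- data.frame(chrom = "chr1", pos = c(2L, 6L, 10L, 14L, 3L),
                      strand = c("+", "+", "+", "+", "-"))
  pfm <- site_pfm(sites, genome, window = c(-1L, 2L))
  # plus sites at 2,6,10,14 all read ACGT; the minus site at 3 reads
  # revcomp(2..5 shifted): positions 1..4 = ACGT -> window on minus covers
  # 1..4 reversed-complemented = ACGT
  expect_equal(colSums(pfm), c(`-1` = 5, `0` = 5, `1` = 5, `2` = 5))
  expect_equal(unname(pfm["A", "-1"]), 5L)
  expect_equal(unname(pfm["C", "0"]), 5L)
  expect_equal(unname(pfm["G", "1"]), 5L)
  expect_equal(unname(pfm["T", "2"]), 5L)
  # out-of-bounds sites are skipped and counted
  sites2 <- rbind(sites, data.frame(chrom = "chr1", pos = 20L, strand = "+"))
  pfm2 <- site_pfm(sites2, genome, window = c(-1L, 2L))
  expect_equal(attr(pfm2, "n_skipped"), 1L)
  expect_equal(colSums(pfm2), colSums(pfm))
})

test_that("planted coupling of skipping and alternative sites is detected", {
  cc <- shared_sim()
  ann <- cc$sim$annotation
  ex <- ann$exons[!duplicated(ann$exons[c("chrom", "start", "end")]), ]
  ex <- ex[seq_len(25), ]
  # every "skipped" exon is given an alternative donor at its own boundary
  ce <- data.frame(event_id = sprintf("CE%d", 1:20), type = "CE",
                   gene_id = ex$gene_id[1:20], chrom = ex$chrom[1:20],
                   strand = "+", start = ex$start[1:20], end = ex$end[1:20],
                   inclusion_junctions = "", exclusion_junctions = "",
                   anchor = NA_integer_, dominant_site = NA_integer_,
                   alt_sites = "", novel = TRUE, stringsAsFactors = FALSE)
  alt <- ce
  alt$event_id <- sprintf("A%d", 1:20)
  alt$type <- "A5SS"
  alt$dominant_site <- ce$end + 1L
  alt$alt_sites <- as.character(ce$end + 5L)
  co <- skipping_altss_cooccurrence(rbind(ce, alt), ann, n_perm = 200,
                                    seed = 9)
  expect_true(co$testable)
  expect_equal(co$observed_fraction, 1.0)
  expect_lt(co$p_value, 0.001)
  # and the trivial ratio: 10 skipped exons, 2 with an alternative site
  alt2 <- alt[1:2, ]
  co2 <- skipping_altss_cooccurrence(rbind(ce[1:10, ], alt2), ann,
                                     n_perm = 50, seed = 9)
  expect_equal(co2$observed_fraction, 0.2)
  # no CE events -> explicitly untestable
  expect_false(skipping_altss_cooccurrence(alt, ann)$testable)
})
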