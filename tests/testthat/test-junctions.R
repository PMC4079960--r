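test_that("junction extraction computes anchors and read counts from CIGAR gaps", {
  # one read with anchors 95/6 around a gap -> overhang 6
  # two reads on a second key with anchor minima 6 and 50 -> overhang 50
  recs <- c(
    sam_line("r1", "chr1", 100, "95M200N6M"),
    sam_line("r2", "chr1", 1000, "6M100N95M"),
    sam_line("r3", "chr1", 956, "50M100N51M"),
    sam_line("r4", "chr1", 3000, "101M") # ungapped: contributes nothing
  )
  j <- extract_junctions(read_sam(sam_file(recs)))
  expect_equal(nrow(j), 2L)
  j1 <- j[j$start == 195, ]
  expect_equal(j1$read_count, 1L)
  expect_equal(j1$max_overhang, 6L)
  j2 <- j[j$start == 1006, ]
  expect_equal(j2$read_count, 2L)
  expect_equal(j2$max_overhang, 50L)
})

test_that("extraction honours MAPQ, secondary flags and multi-gap reads", {
  recs <- c(
    sam_line("r1", "chr1", 100, "30M50N30M60N41M"),
    sam_line("lowq", "chr1", 100, "30M50N71M", mapq = 0L),
    sam_line("sec", "chr1", 100, "30M50N71M", flag = 256L)
  )
  j <- extract_junctions(read_sam(sam_file(recs)))
  expect_equal(nrow(j), 2L)
  # first gap: 30 left, 30+41 right; second gap: 60 left, 41 right
  expect_equal(j$max_overhang[j$start == 130], 30L)
  expect_equal(j$max_overhang[j$start == 210], 41L)
  expect_equal(sum(j$read_count), 2L)
})

test_that("extraction agrees with GenomicAlignments junction calling", {
  skip_if_not_installed("GenomicAlignments")
  skip_if_not_installed("Rsamtools")
  cc <- shared_sim()
  a <- simulate_alignments(cc$sim, cc$spec, "control")
  sam <- tempfile(fileext = ".sam")
  write_sam(a$alignments, sam, cc$sim$annotation$chrom_lengths)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  ga <- GenomicAlignments::readGAlignments(bam)
  jr <- unlist(GenomicAlignments::junctions(ga))
  ref <- table(sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(jr)),
                       BiocGenerics::start(jr), BiocGenerics::end(jr)))
  mine <- extract_junctions(a$alignments)
  expect_setequal(mine$key, names(ref))
  expect_equal(mine$read_count[match(names(ref), mine$key)],
               as.integer(ref))
})

test_that("junction tables are labeled known/novel and assigned to genes", {
  ann <- read_annotation(gff_one_gene(
    exons = list(c(11, 40), c(101, 160), c(221, 280))
  ))
  j <- rbind(jrow("chr1", 41, 100), jrow("chr1", 50, 100))
  j <- annotate_junction_table(j, ann)
  expect_equal(j$annotated, c(TRUE, FALSE))
  expect_equal(j$gene_id, c("g1", "g1"))
  expect_equal(j$strand, c("+", "+"))
})

test_that("subsampling is exact, deterministic and validates its input", {
  recs <- vapply(1:1000, function(i) {
    sam_line(sprintf("r%04d", i), "chr1", i, "101M")
  }, "")
  aln <- read_sam(sam_file(recs))
  s1 <- subsample_alignments(aln, 100, seed = 7)
  s2 <- subsample_alignments(aln, 100, seed = 7)
  expect_equal(nrow(s1), 100L)
  expect_identical(s1, s2)
  expect_false(identical(s1$qname,
                         subsample_alignments(aln, 100, seed = 8)$qname))
  expect_equal(nrow(subsample_alignments(aln, 1000, seed = 1)), 1000L)
  expect_error(subsample_alignments(aln, 1001, seed = 1), "1000 eligible")
})

test_that("paired subsampling keeps mates together", {
  recs <- unlist(lapply(1:50, function(i) {
    c(sam_line(sprintf("p%02d", i), "chr1", i * 10, "50M", flag = 99L),
      sam_line(sprintf("p%02d", i), "chr1", i * 10 + 100, "50M", flag = 147L))
  }))
  aln <- read_sam(sam_file(recs))
  s <- subsample_alignments(aln, 20, seed = 3)
  expect_equal(nrow(s), 20L)
  expect_true(all(table(s$qname) == 2L))
  expect_error(subsample_alignments(aln, 21, seed = 3), "even")
})

test_that("BED12 junction files round-trip through the TopHat encoding", {
  j <- rbind(jrow("chr1", 41, 100, reads = 7, overhang = 33),
             jrow("chr2", 500, 800, reads = 2, overhang = 21))
  j$strand <- c("+", "-")
  path <- tempfile(fileext = ".bed")
  write_junctions_bed(j, path)
  j2 <- read_junctions_bed(path)
  expect_equal(j2$key, j$key)
  expect_equal(j2$read_count, j$read_count)
  expect_equal(j2$max_overhang, j$max_overhang)
  expect_equal(j2$strand, j$strand)
})
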