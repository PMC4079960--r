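toy_ann <- function() {
  read_annotation(gff_one_gene(
    exons = list(c(11, 110), c(211, 310), c(411, 510))
  ))
}

test_that("a bridged internal exon is classified as one cassette exon", {
  ann <- toy_ann()
  j <- rbind(jrow("chr1", 111, 210),  # e1-e2
             jrow("chr1", 311, 410),  # e2-e3
             jrow("chr1", 111, 410))  # e1-e3 exclusion
  ev <- classify_events(j, ann)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "CE")
  expect_equal(c(ev$start, ev$end), c(211L, 310L))
  expect_equal(ev$exclusion_junctions, "chr1:111-410")
  expect_setequal(strsplit(ev$inclusion_junctions, ";")[[1]],
                  c("chr1:111-210", "chr1:311-410"))
})

test_that("junctions sharing an anchor with shifted sites give alternative-site events", {
  ann <- toy_ann()
  # shared acceptor (intron end 210), donors 4 bp apart -> A5SS on +
  j <- rbind(jrow("chr1", 111, 210), jrow("chr1", 115, 210))
  ev <- classify_events(j, ann)
  expect_equal(ev$type, "A5SS")
  expect_equal(ev$dominant_site, 111L) # the annotated donor dominates
  expect_equal(ev$alt_sites, "115")
  # shared donor, acceptors differing -> A3SS on +
  j2 <- rbind(jrow("chr1", 311, 410), jrow("chr1", 311, 406))
  ev2 <- classify_events(j2, ann)
  expect_equal(ev2$type, "A3SS")
  expect_equal(ev2$dominant_site, 410L)
})

test_that("strand flips the alternative-site assignment", {
  ann <- read_annotation(gff_one_gene(
    exons = list(c(11, 110), c(211, 310), c(411, 510)), strand = "-"
  ))
  # varying genomic-left boundary on minus strand = acceptor side
  j <- rbind(jrow("chr1", 111, 210), jrow("chr1", 115, 210))
  expect_equal(classify_events(j, ann)$type, "A3SS")
  j2 <- rbind(jrow("chr1", 311, 410), jrow("chr1", 311, 406))
  expect_equal(classify_events(j2, ann)$type, "A5SS")
})

test_that("the empty junction set yields no events and order does not matter", {
  ann <- toy_ann()
  expect_equal(nrow(classify_events(empty <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    read_count = integer(0), max_overhang = integer(0)
  ), ann)), 0L)
  j <- rbind(jrow("chr1", 111, 210), jrow("chr1", 311, 410),
             jrow("chr1", 111, 410), jrow("chr1", 115, 210))
  e1 <- classify_events(j, ann)
  e2 <- classify_events(j[c(3, 1, 4, 2), ], ann)
  expect_equal(e1[order(e1$type), -1], e2[order(e2$type), -1],
               ignore_attr = TRUE)
})

test_that("intron retention calls respect both thresholds exactly", {
  cov <- data.frame(
    key = c("chr1:1-100", "chr1:201-300", "chr1:401-500", "chr1:601-700"),
    intron_read_count = c(6L, 4L, 0L, 5L),
    covered_fraction = c(0.85, 1.0, 0, 0.8)
  )
  called <- call_intron_retention(cov, ir_criteria(5, 0.8))
  # 6 reads/85% called; 4 reads/100% fails the read floor; 0 reads fails;
  # 5 reads at exactly 80% fails the strict breadth inequality
  expect_equal(called$key, "chr1:1-100")
})

test_that("IR calling is monotone in coverage", {
  base <- data.frame(key = "chr1:1-100", intron_read_count = 5L,
                     covered_fraction = 0.81)
  expect_equal(nrow(call_intron_retention(base)), 1L)
  richer <- transform(base, intron_read_count = intron_read_count + 10L,
                      covered_fraction = 0.95)
  expect_equal(nrow(call_intron_retention(richer)), 1L)
})

test_that("events are novel exactly when a defining junction is unannotated", {
  ann <- toy_ann()
  j <- rbind(jrow("chr1", 111, 210), jrow("chr1", 311, 410),
             jrow("chr1", 111, 410))
  ev <- annotate_novelty(classify_events(j, ann), ann)
  expect_true(ev$novel) # the exclusion junction is not annotated
  # an alternative-site event whose members are all annotated is not novel
  lines <- c(
    gff_one_gene(exons = list(c(11, 110), c(211, 310))),
    "chr1\ttest\tmRNA\t11\t310\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\ttest\texon\t11\t106\t.\t+\t.\tParent=t2",
    "chr1\ttest\texon\t211\t310\t.\t+\t.\tParent=t2"
  )
  ann2 <- read_annotation(lines)
  j2 <- rbind(jrow("chr1", 111, 210), jrow("chr1", 107, 210))
  ev2 <- annotate_novelty(classify_events(j2, ann2), ann2)
  expect_equal(ev2$type, "A5SS")
  expect_false(ev2$novel)
})

test_that("classification from annotated junctions alone reproduces annotation-derivable events", {
  cc <- shared_sim()
  ann <- cc$sim$annotation
  intr <- enumerate_introns(ann)
  j <- data.frame(chrom = intr$chrom, start = intr$start, end = intr$end,
                  read_count = 10L, max_overhang = 50L,
                  stringsAsFactors = FALSE)
  ev <- classify_events(j, ann)
  # the only events derivable from the annotation itself are the AFE/ALE
  # isoform pairs; every one must be recovered and nothing else
  truth <- cc$sim$truth$events
  expected <- truth[truth$type %in% c("AFE", "ALE"), ]
  expect_equal(sort(paste(ev$type, ev$chrom, ev$start, ev$end)),
               sort(paste(expected$type, expected$chrom, expected$start,
                          expected$end)))
})
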