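test_that("GFF3 loading yields exons, derived introns and CDS containment", {
  ann <- read_annotation(gff_one_gene(
    exons = list(c(11, 40), c(101, 160), c(221, 280)),
    cds = list(c(101, 160), c(221, 250))
  ))
  expect_equal(nrow(ann$exons), 3L)
  expect_equal(nrow(ann$introns), 2L)
  expect_equal(ann$introns$start, c(41L, 161L))
  expect_equal(ann$introns$end, c(100L, 220L))
  expect_equal(nrow(ann$cds), 2L)
  # CDS outside exons must fail validation
  expect_error(
    read_annotation(gff_one_gene(
      exons = list(c(11, 40), c(101, 160)),
      cds = list(c(90, 120))
    )),
    "CDS"
  )
})

test_that("empty and malformed annotations are handled explicitly", {
  ann <- read_annotation("##gff-version 3")
  expect_equal(nrow(ann$genes), 0L)
  expect_equal(nrow(ann$introns), 0L)
  bad <- c("##gff-version 3", "chr1\ttest\tgene\t1\t100")
  expect_error(read_annotation(bad), "line 2")
  out_of_bounds <- gff_one_gene(exons = list(c(11, 40), c(101, 20000)))
  expect_error(read_annotation(out_of_bounds), "chromosome length")
})

test_that("intron enumeration de-duplicates shared introns across transcripts", {
  lines <- c(
    "##gff-version 3",
    "##sequence-region chr1 1 5000",
    "chr1\ttest\tgene\t1\t1000\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t1\t1000\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chr1\ttest\texon\t201\t300\t.\t+\t.\tParent=t1",
    "chr1\ttest\texon\t401\t500\t.\t+\t.\tParent=t1",
    "chr1\ttest\tmRNA\t1\t1000\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\ttest\texon\t1\t100\t.\t+\t.\tParent=t2",
    "chr1\ttest\texon\t201\t320\t.\t+\t.\tParent=t2"
  )
  ann <- read_annotation(lines)
  intr <- enumerate_introns(ann)
  # t1 has 2 introns, t2 has 1; the first intron (101-200) is shared, so
  # only 2 distinct introns remain
  expect_equal(nrow(intr), 2L)
  shared <- intr[intr$start == 101, ]
  expect_equal(shared$tx_ids, "t1,t2")
  expect_setequal(annotated_junctions(ann), intr$key)
})

test_that("single-exon transcripts contribute no introns", {
  ann <- read_annotation(gff_one_gene(exons = list(c(11, 400))))
  expect_equal(nrow(ann$introns), 0L)
  expect_length(annotated_junctions(ann), 0L)
})

test_that("introns and exons tile each transcript span exactly", {
  cc <- shared_sim()
  ann <- cc$sim$annotation
  for (t in unique(ann$exons$tx_id)) {
    e <- ann$exons[ann$exons$tx_id == t, ]
    i <- ann$introns[ann$introns$tx_id == t, ]
    pieces <- rbind(e[c("start", "end")], i[c("start", "end")])
    pieces <- pieces[order(pieces$start), ]
    expect_equal(pieces$start[-1], pieces$end[-nrow(pieces)] + 1L)
    expect_equal(pieces$start[1], min(e$start))
    expect_equal(pieces$end[nrow(pieces)], max(e$end))
  }
})

test_that("GFF3 round trip preserves all intervals and the junction set", {
  cc <- shared_sim()
  ann <- cc$sim$annotation
  path <- tempfile(fileext = ".gff3")
  write_annotation(ann, path)
  ann2 <- read_annotation(path)
  key <- function(a) {
    e <- a$exons[order(a$exons$tx_id, a$exons$start), ]
    paste(e$tx_id, e$chrom, e$start, e$end, e$strand)
  }
  expect_equal(key(ann2), key(ann))
  expect_equal(annotated_junctions(ann2), annotated_junctions(ann))
  expect_equal(sort(ann2$cds$start), sort(ann$cds$start))
})

test_that("junction set is invariant under transcript order in the file", {
  lines <- gff_one_gene(exons = list(c(11, 40), c(101, 160), c(221, 280)))
  body <- lines[5:7]
  shuffled <- c(lines[1:4], body[c(3, 1, 2)], lines[-(1:7)])
  expect_equal(annotated_junctions(read_annotation(shuffled)),
               annotated_junctions(read_annotation(lines)))
})

test_that("GTF input is parsed equivalently", {
  gtf <- c(
    paste0("chr1\ttest\texon\t11\t40\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";'),
    paste0("chr1\ttest\texon\t101\t160\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1";')
  )
  path <- tempfile(fileext = ".gtf")
  writeLines(gtf, path)
  ann <- read_annotation(path)
  expect_equal(nrow(ann$exons), 2L)
  expect_equal(ann$introns$key, "chr1:41-100")
  expect_equal(ann$genes$gene_id, "g1")
})
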