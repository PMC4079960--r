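# A hand-built locus on an all-C chromosome (no stop codons anywhere unless
# planted): exons 11-40 (5'UTR), 101-160, 221-280; CDS = 101-160 + 221-250.
# Intron 161-220 is 60 bp (frame-preserving) and sits inside the CDS.
ptc_fixture <- function(strand = "+", plant = NULL) {
  seq <- strrep("C", 400)
  for (p in plant) {
    substr(seq, p[1], p[1] + 2L) <- if (strand == "+") "TAA" else "TTA"
  }
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  ann <- read_annotation(gff_one_gene(
    exons = list(c(11, 40), c(101, 160), c(221, 280)),
    cds = list(c(101, 160), c(221, 250)),
    strand = strand, chrom_len = 400L
  ), genome = genome)
  list(ann = ann, genome = genome)
}

ir_event <- function(start, end) {
  data.frame(event_id = "E1", type = "IR", gene_id = "g1", chrom = "chr1",
             strand = "+", start = start, end = end,
             inclusion_junctions = "", exclusion_junctions = "",
             stringsAsFactors = FALSE)
}

test_that("a retained CDS intron with an in-frame stop introduces a PTC", {
  # CDS bases before the intron: 60 (exon 101-160), so codons restart at
  # 161; TAA planted at 164-166 is in frame
  fx <- ptc_fixture(plant = list(c(164, 166)))
  v <- predict_ptc(ir_event(161, 220), fx$ann, fx$genome)
  expect_equal(v$region, "CDS")
  expect_true(v$ptc_introduced)
  # 60 CDS bases + 3 intron bases before the stop = 21 codons
  expect_equal(v$predicted_peptide_len, 21L)
})

test_that("a frame-preserving stop-free retained intron introduces no PTC", {
  fx <- ptc_fixture()
  v <- predict_ptc(ir_event(161, 220), fx$ann, fx$genome)
  expect_equal(v$region, "CDS")
  expect_false(v$ptc_introduced)
})

test_that("UTR intron retention leaves the CDS untouched", {
  fx <- ptc_fixture()
  v <- predict_ptc(ir_event(41, 100), fx$ann, fx$genome)
  expect_equal(v$region, "5'UTR")
  expect_false(v$ptc_introduced)
  # the same genomic intron on the minus strand is downstream of the CDS
  fxm <- ptc_fixture(strand = "-")
  evm <- ir_event(41, 100); evm$strand <- "-"
  vm <- predict_ptc(evm, fxm$ann, fxm$genome)
  expect_equal(vm$region, "3'UTR")
  expect_false(vm$ptc_introduced)
})

test_that("missing CDS annotation gives an indeterminate verdict", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("C", 400)))
  ann <- read_annotation(gff_one_gene(
    exons = list(c(11, 40), c(101, 160), c(221, 280)), chrom_len = 400L
  ), genome = genome)
  v <- predict_ptc(ir_event(161, 220), ann, genome)
  expect_true(is.na(v$ptc_introduced))
})

test_that("an inserted cassette exon carrying an in-frame stop is a PTC event", {
  fx <- ptc_fixture(plant = list(c(184, 186)))
  ce <- ir_event(181, 201) # 21 bp novel exon inside the CDS intron
  ce$type <- "CE"
  v <- predict_ptc(ce, fx$ann, fx$genome)
  expect_equal(v$region, "CDS")
  expect_true(v$ptc_introduced)
})

test_that("the synthetic CDS intron retentions carry their planted PTC truth", {
  cc <- shared_sim()
  tr <- cc$sim$truth$events
  ir <- tr[tr$type == "IR", ]
  ev <- data.frame(event_id = ir$event_id, type = "IR", gene_id = ir$gene_id,
                   chrom = ir$chrom, strand = ir$strand, start = ir$start,
                   end = ir$end, stringsAsFactors = FALSE)
  v <- predict_ptc(ev, cc$sim$annotation, cc$sim$genome)
  expect_equal(v$region, ir$region)
  expect_equal(v$ptc_introduced[ir$region == "CDS"],
               rep(TRUE, sum(ir$region == "CDS")))
  expect_equal(v$ptc_introduced[ir$region == "5'UTR"],
               rep(FALSE, sum(ir$region == "5'UTR")))
})
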