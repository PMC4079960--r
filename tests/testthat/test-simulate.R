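test_that("the generator is deterministic and produces the requested structure", {
  spec <- synthetic_spec(seed = 7L)
  s1 <- generate_genome_and_annotation(spec)
  s2 <- generate_genome_and_annotation(spec)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$events, s2$truth$events)
  expect_equal(nrow(s1$annotation$genes), spec$n_genes)
  tt <- table(s1$truth$events$type)
  expect_equal(as.integer(tt[names(spec$event_mix)]),
               unname(spec$event_mix))
  # different seed, different genome
  s3 <- generate_genome_and_annotation(synthetic_spec(seed = 8L))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("every annotated intron carries GT..AG in transcript orientation", {
  cc <- shared_sim()
  intr <- enumerate_introns(cc$sim$annotation)
  dn <- splice_site_dinucleotides(intr, cc$sim$genome)
  expect_true(all(dn$per_junction$donor == "GT"))
  expect_true(all(dn$per_junction$acceptor == "AG"))
})

test_that("an infeasible event mix errors with the missing type named", {
  expect_error(
    generate_genome_and_annotation(synthetic_spec(
      n_genes = 4L, event_mix = c(CE = 3L, AFE = 3L)
    )),
    "AFE"
  )
})

test_that("inclusion levels carry the differential truth", {
  spec <- synthetic_spec(seed = 3L, das_fraction = 0.25)
  sim <- simulate_splicing_experiment(spec)
  ev <- sim$truth$events
  expect_equal(sum(ev$das), round(0.25 * nrow(ev)))
  shifted <- abs(ev$psi_treatment - ev$psi_control) > 1e-9
  expect_equal(shifted, ev$das)
  expect_true(all(abs(ev$psi_treatment - ev$psi_control)[ev$das] > 0.2))
})

test_that("simulated counts follow the planted inclusion levels", {
  spec <- synthetic_spec(seed = 5L)
  sim <- simulate_splicing_experiment(spec)
  counts <- simulate_counts(sim, spec)
  expect_equal(sort(unique(counts$condition)), sort(spec$conditions))
  expect_true(all(counts$event_reads + counts$exon_reads ==
                    spec$event_depth))
  # per-event reads track psi
  ev <- sim$truth$events
  for (cond in spec$conditions) {
    sub <- counts[counts$condition == cond, ]
    psi <- ev[[paste0("psi_", cond)]][match(sub$event_id, ev$event_id)]
    expect_lt(max(abs(sub$event_reads / spec$event_depth - psi)), 0.15)
  }
})

test_that("null count pairs give a calibrated Fisher rejection rate", {
  d <- simulate_event_counts(2000, 300, 0.3, 0.3, seed = 11)
  p <- vapply(seq_len(nrow(d)), function(i) {
    fisher_exact_2x2(rbind(
      c(d$event_reads_control[i], d$exon_reads_control[i]),
      c(d$event_reads_treatment[i], d$exon_reads_treatment[i])
    ))$p_value
  }, 0)
  rate <- mean(p < 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(rate, 0.05 - se3)
  expect_lt(rate, 0.05 + se3)
})

test_that("a 0.3 inclusion shift at depth 200 is detected with high power", {
  d <- simulate_event_counts(500, 200, 0.3, 0.6, seed = 13)
  res <- vapply(seq_len(nrow(d)), function(i) {
    fisher_exact_2x2(rbind(
      c(d$event_reads_control[i], d$exon_reads_control[i]),
      c(d$event_reads_treatment[i], d$exon_reads_treatment[i])
    ))$p_value < 0.05
  }, TRUE)
  expect_gt(mean(res), 0.8)
})

test_that("simulated alignments reproduce the truth junction set exactly", {
  cc <- shared_sim()
  a <- simulate_alignments(cc$sim, cc$spec, "control")
  j <- extract_junctions(a$alignments, cc$sim$annotation)
  truth_keys <- cc$sim$truth$junctions$key
  spur_keys <- a$spurious$key
  expect_setequal(j$key, c(truth_keys, spur_keys))
  # spurious junctions are single-read with anchors <= 20 by construction
  sp <- j[j$key %in% spur_keys, ]
  expect_true(all(sp$read_count == 1L))
  expect_true(all(sp$max_overhang <= 20L))
  # spanning reads of 101 bp have anchor minima of at most 50
  expect_true(all(j$max_overhang <= 50L))
})
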