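test_that("the uniqueness rule assigns p = 0 only with enough support", {
  thr <- das_thresholds()
  r5 <- test_event("A5SS",
                   list(event_reads = 0L, exon_reads = 100L),
                   list(event_reads = 5L, exon_reads = 100L), thr)
  expect_true(r5$unique_rule_applied)
  expect_equal(r5$p_value, 0)
  expect_true(r5$significant)
  expect_equal(r5$direction, "over_in_treatment")
  r4 <- test_event("A5SS",
                   list(event_reads = 0L, exon_reads = 100L),
                   list(event_reads = 4L, exon_reads = 100L), thr)
  expect_false(r4$unique_rule_applied)
  expect_false(r4$significant)
  # IR uniqueness needs both coverage and breadth in the present condition
  ir_ok <- test_event("IR",
                      list(event_reads = 6L, exon_reads = 50L,
                           covered_fraction = 0.9),
                      list(event_reads = 0L, exon_reads = 50L), thr)
  expect_true(ir_ok$unique_rule_applied)
  expect_equal(ir_ok$direction, "over_in_control")
  ir_shallow <- test_event("IR",
                           list(event_reads = 6L, exon_reads = 50L,
                                covered_fraction = 0.5),
                           list(event_reads = 0L, exon_reads = 50L), thr)
  expect_false(ir_shallow$unique_rule_applied)
})

test_that("type-specific thresholds and untestable events are honoured", {
  thr <- das_thresholds()
  # IR table below the junction threshold but above the IR one
  tab <- test_event("IR", list(event_reads = 6L, exon_reads = 100L),
                    list(event_reads = 40L, exon_reads = 100L), thr)
  p <- fisher_oracle(6, 100, 40, 100)
  expect_equal(tab$p_value, p, tolerance = 1e-12)
  expect_equal(tab$significant, p < 0.001)
  same_junction <- test_event("A3SS", list(event_reads = 6L, exon_reads = 100L),
                              list(event_reads = 40L, exon_reads = 100L), thr)
  expect_equal(same_junction$significant, p < 0.05)
  none <- test_event("A3SS", list(event_reads = 0L, exon_reads = 100L),
                     list(event_reads = 0L, exon_reads = 90L), thr)
  expect_false(none$testable)
})

test_that("swapping condition labels preserves p and flips direction", {
  set.seed(5)
  for (i in 1:50) {
    a <- list(event_reads = rpois(1, 30), exon_reads = rpois(1, 100))
    b <- list(event_reads = rpois(1, 60), exon_reads = rpois(1, 100))
    r1 <- test_event("CE", a, b)
    r2 <- test_event("CE", b, a)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    if (r1$significant && r1$direction != "none") {
      flip <- c(over_in_treatment = "over_in_control",
                over_in_control = "over_in_treatment")
      expect_equal(r2$direction, unname(flip[r1$direction]))
    }
  }
})

test_that("the global per-type comparison behaves on degenerate inputs", {
  tc <- data.frame(
    condition = rep(c("control", "salt"), each = 2),
    type = rep(c("A5SS", "IR"), 2),
    n_events = c(10L, 20L, 10L, 20L),
    junction_reads = c(100L, 900L, 100L, 900L)
  )
  g <- global_as_comparison(tc)
  expect_equal(g$tests$p_value, rep(1, 2), tolerance = 1e-9)
  expect_equal(unname(g$read_totals), c(1000, 1000))
  # a planted difference is detected by the per-type Fisher test
  tc2 <- tc
  tc2$junction_reads <- c(10L, 990L, 30L, 970L)
  g2 <- global_as_comparison(tc2)
  expect_equal(g2$tests$p_value[g2$tests$type == "A5SS"],
               fisher_oracle(10, 990, 30, 970), tolerance = 1e-12)
  expect_error(global_as_comparison(tc[tc$condition == "control", ]),
               "treatment")
  expect_error(global_as_comparison(tc, depths = c(control = 10, salt = 20)),
               "unequal")
})

test_that("DAS summaries count genes, directions and overlaps", {
  res <- data.frame(
    event_id = sprintf("E%d", 1:5),
    type = "A5SS",
    gene_id = c("A", "B", "B", "C", "B"),
    treatment = c("t1", "t1", "t2", "t2", "t3"),
    p_value = 0.01, odds_ratio = 2,
    direction = c("over_in_treatment", "over_in_treatment",
                  "over_in_control", "over_in_treatment",
                  "over_in_treatment"),
    significant = TRUE, unique_rule_applied = FALSE, testable = TRUE,
    stringsAsFactors = FALSE
  )
  s <- das_summary(res)
  expect_equal(s$n_das_genes, 3L)
  expect_equal(s$genes_in_multiple, "B")
  expect_equal(s$fraction_in_multiple, 1 / 3)
  expect_equal(s$all_overlap, "B")
  expect_equal(s$per_treatment$n_over_in_treatment[
    s$per_treatment$treatment == "t2"], 1L)
  expect_equal(das_summary(res[0, ])$n_das_genes, 0L)
  s2 <- das_summary(res, de_genes = c("B", "Z"))
  expect_equal(s2$de_overlap, 1L)
})

test_that("test_events drives per-event tests over a count table", {
  counts <- data.frame(
    event_id = rep(c("E1", "E2"), each = 2),
    type = rep(c("A5SS", "IR"), each = 2),
    gene_id = rep(c("g1", "g2"), each = 2),
    condition = rep(c("control", "salt"), 2),
    event_reads = c(30L, 90L, 0L, 6L),
    exon_reads = c(270L, 210L, 300L, 294L),
    covered_fraction = c(0, 0, 0, 0.95),
    stringsAsFactors = FALSE
  )
  res <- test_events(counts, control = "control")
  expect_equal(nrow(res), 2L)
  e1 <- res[res$event_id == "E1", ]
  expect_equal(e1$p_value, fisher_oracle(30, 270, 90, 210), tolerance = 1e-12)
  e2 <- res[res$event_id == "E2", ]
  expect_true(e2$unique_rule_applied)
  expect_equal(e2$p_value, 0)
})
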