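#' Differential-splicing thresholds
#'
#' Junction-based events (alternative 5'/3' splice sites, exon skipping) are
#' significant below `p_junction_events` (default 0.05); intron retention
#' below `p_intron_retention` (default 0.001). Events present in only one
#' condition are significant, with p assigned 0, when supported by at least
#' `unique_min_junction_reads` junction reads (default 5) or, for intron
#' retention, at least `unique_min_ir_coverage` intron reads with breadth
#' above `unique_min_ir_breadth` (defaults 5 and 0.8).
#'
#' @param p_junction_events,p_intron_retention significance thresholds
#' @param unique_min_junction_reads,unique_min_ir_coverage,unique_min_ir_breadth
#'   uniqueness-rule supports
#' @export
das_thresholds <- function(p_junction_events = 0.05,
                           p_intron_retention = 0.001,
                           unique_min_junction_reads = 5L,
                           unique_min_ir_coverage = 5L,
                           unique_min_ir_breadth = 0.8) {
  stopifnot(p_junction_events > 0, p_intron_retention > 0)
  structure(list(p_junction_events = p_junction_events,
                 p_intron_retention = p_intron_retention,
                 unique_min_junction_reads = as.integer(unique_min_junction_reads),
                 unique_min_ir_coverage = as.integer(unique_min_ir_coverage),
                 unique_min_ir_breadth = unique_min_ir_breadth),
            class = "das_thresholds")
}

#' Test one event for differential splicing between two conditions
#'
#' Builds the 2x2 table of event reads (junction reads, or intron reads for
#' IR) versus the corresponding exon reads in control and treatment and
#' applies the two-sided Fisher exact test. An event absent from one
#' condition is handled by the uniqueness rule: with enough support in the
#' other condition it is called significant with p assigned 0.
#'
#' @param type event type (`"IR"` uses the intron-retention threshold and
#'   uniqueness rule; anything else the junction-event ones)
#' @param counts_control,counts_treatment lists (or one-row data.frames)
#'   with `event_reads` and `exon_reads`; for IR uniqueness also
#'   `covered_fraction` of the present condition
#' @param thresholds a [das_thresholds()]
#' @return a `contingency_result` list: `table`, `p_value`, `odds_ratio`,
#'   `direction` (`over_in_treatment` / `over_in_control` / `none`),
#'   `significant`, `unique_rule_applied`, `testable`
#' @export
test_event <- function(type, counts_control, counts_treatment,
                       thresholds = das_thresholds()) {
  ec <- counts_control$event_reads; xc <- counts_control$exon_reads
  et <- counts_treatment$event_reads; xt <- counts_treatment$exon_reads
  is_ir <- identical(type, "IR")
  p_cut <- if (is_ir) thresholds$p_intron_retention else thresholds$p_junction_events
  res <- list(table = rbind(control = c(ec, xc), treatment = c(et, xt)),
              p_value = NA_real_, odds_ratio = NA_real_,
              direction = "none", significant = FALSE,
              unique_rule_applied = FALSE, testable = TRUE)
  class(res) <- "contingency_result"
  if (ec == 0L && et == 0L) {
    res$testable <- FALSE
    return(res)
  }
  if (ec == 0L || et == 0L) {
    present <- if (ec == 0L) counts_treatment else counts_control
    supported <- if (is_ir) {
      present$event_reads >= thresholds$unique_min_ir_coverage &&
        (present$covered_fraction %||% NA_real_) > thresholds$unique_min_ir_breadth
    } else {
      present$event_reads >= thresholds$unique_min_junction_reads
    }
    if (isTRUE(supported)) {
      res$p_value <- 0
      res$unique_rule_applied <- TRUE
      res$significant <- TRUE
      res$direction <- if (ec == 0L) "over_in_treatment" else "over_in_control"
      res$odds_ratio <- if (ec == 0L) 0 else Inf
      return(res)
    }
  }
  ft <- fisher_exact_2x2(res$table)
  res$p_value <- ft$p_value
  res$odds_ratio <- ft$odds_ratio
  res$significant <- ft$p_value < p_cut
  if (res$significant) {
    rate_c <- ec / (ec + xc)
    rate_t <- et / (et + xt)
    res$direction <- if (rate_t > rate_c) "over_in_treatment" else "over_in_control"
  }
  res
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 Fisher test (event vs exon reads):\n")
  print(x$table)
  cat(sprintf("  p = %.4g, OR = %.3g, direction = %s%s%s\n",
              x$p_value, x$odds_ratio, x$direction,
              if (x$unique_rule_applied) ", unique-event rule" else "",
              if (!x$testable) ", untestable" else ""))
  invisible(x)
}

#' Test a table of event counts across treatments
#'
#' Vectorised driver over [test_event()]: each treatment is compared to the
#' control independently.
#'
#' @param counts data.frame with columns `event_id`, `type`, `gene_id`,
#'   `condition`, `event_reads`, `exon_reads` (and `covered_fraction` for IR)
#' @param control label of the control condition
#' @param thresholds a [das_thresholds()]
#' @return data.frame, one row per event x treatment, with p-value, odds
#'   ratio, direction, significance and uniqueness flags
#' @export
test_events <- function(counts, control = "control",
                        thresholds = das_thresholds()) {
  stopifnot_cols(counts, c("event_id", "type", "condition", "event_reads",
                           "exon_reads"), "count table")
  if (!control %in% counts$condition) {
    stop("control condition '", control, "' absent from count table")
  }
  treatments <- setdiff(unique(counts$condition), control)
  rows <- list()
  for (tr in treatments) {
    ctrl <- counts[counts$condition == control, , drop = FALSE]
    trt <- counts[counts$condition == tr, , drop = FALSE]
    common <- intersect(ctrl$event_id, trt$event_id)
    for (id in common) {
      c1 <- ctrl[ctrl$event_id == id, ][1, ]
      c2 <- trt[trt$event_id == id, ][1, ]
      r <- test_event(c1$type, c1, c2, thresholds)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = id, type = c1$type,
        gene_id = c1$gene_id %||% NA_character_, treatment = tr,
        event_reads_control = c1$event_reads, exon_reads_control = c1$exon_reads,
        event_reads_treatment = c2$event_reads, exon_reads_treatment = c2$exon_reads,
        p_value = r$p_value, odds_ratio = r$odds_ratio,
        direction = r$direction, significant = r$significant,
        unique_rule_applied = r$unique_rule_applied, testable = r$testable,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Global per-type comparison of alternative splicing
#'
#' Compares, between the control and each treatment, the number of junction
#' reads assigned to each event type against the remainder of the condition's
#' junction reads, with a Fisher exact test per type. Conditions must have
#' been subsampled to equal depth.
#'
#' @param type_counts data.frame with `condition`, `type`, `n_events`,
#'   `junction_reads`
#' @param control control condition label
#' @param depths optional named vector of library depths per condition used
#'   to enforce the equal-depth precondition
#' @param allow_unequal_depth set `TRUE` to override the equal-depth check
#' @return list with the per-condition event-count table and a data.frame of
#'   per-type Fisher tests against control
#' @export
global_as_comparison <- function(type_counts, control = "control",
                                 depths = NULL,
                                 allow_unequal_depth = FALSE) {
  stopifnot_cols(type_counts, c("condition", "type", "n_events",
                                "junction_reads"), "type count table")
  conds <- unique(type_counts$condition)
  if (!control %in% conds) stop("control condition absent")
  if (length(conds) < 2L) stop("need at least one treatment condition")
  if (!is.null(depths) && length(unique(depths[conds])) > 1L &&
      !allow_unequal_depth) {
    stop("conditions have unequal depths; subsample first ",
         "(or set allow_unequal_depth = TRUE)")
  }
  totals <- vapply(split(type_counts$junction_reads, type_counts$condition),
                   sum, 0)
  event_table <- stats::xtabs(n_events ~ type + condition, data = type_counts)
  rows <- list()
  for (tr in setdiff(conds, control)) {
    for (ty in unique(type_counts$type)) {
      rc <- type_counts$junction_reads[type_counts$condition == control &
                                         type_counts$type == ty]
      rt <- type_counts$junction_reads[type_counts$condition == tr &
                                         type_counts$type == ty]
      rc <- if (length(rc)) rc[1] else 0L
      rt <- if (length(rt)) rt[1] else 0L
      ft <- fisher_exact_2x2(rbind(c(rc, totals[[control]] - rc),
                                   c(rt, totals[[tr]] - rt)))
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, type = ty, reads_control = rc, reads_treatment = rt,
        p_value = ft$p_value, odds_ratio = ft$odds_ratio,
        stringsAsFactors = FALSE
      )
    }
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  list(event_table = event_table, read_totals = totals, tests = tests)
}

#' Summarise differential-splicing results into DAS genes and overlaps
#'
#' @param results data.frame from [test_events()] (needs `gene_id`,
#'   `treatment`, `significant`, `direction`)
#' @param de_genes optional external list of differentially expressed genes
#'   for an overlap count
#' @return list: `per_treatment` counts split by direction, `genes_by_treatment`,
#'   `das_genes`, `n_das_genes`, `genes_in_multiple`, `fraction_in_multiple`,
#'   pairwise/all-treatment overlap counts, and `de_overlap` when `de_genes`
#'   is given
#' @export
das_summary <- function(results, de_genes = NULL) {
  if (!nrow(results)) {
    return(list(per_treatment = data.frame(), genes_by_treatment = list(),
                das_genes = character(0), n_das_genes = 0L,
                genes_in_multiple = character(0), fraction_in_multiple = 0,
                pairwise_overlap = NULL, all_overlap = character(0),
                de_overlap = if (is.null(de_genes)) NULL else 0L))
  }
  sig <- results[results$significant, , drop = FALSE]
  treatments <- unique(results$treatment)
  per_treatment <- do.call(rbind, lapply(treatments, function(tr) {
    s <- sig[sig$treatment == tr, ]
    data.frame(treatment = tr,
               n_events = nrow(s),
               n_over_in_treatment = sum(s$direction == "over_in_treatment"),
               n_over_in_control = sum(s$direction == "over_in_control"),
               n_genes = length(unique(s$gene_id)),
               stringsAsFactors = FALSE)
  }))
  genes_by_treatment <- lapply(stats::setNames(treatments, treatments),
                               function(tr) unique(sig$gene_id[sig$treatment == tr]))
  das_genes <- sort(unique(unlist(genes_by_treatment)))
  counts <- table(unlist(lapply(genes_by_treatment, unique)))
  genes_in_multiple <- sort(names(counts)[counts >= 2L])
  pairwise <- NULL
  if (length(treatments) >= 2L) {
    prs <- utils::combn(treatments, 2L)
    pairwise <- data.frame(
      a = prs[1, ], b = prs[2, ],
      overlap = apply(prs, 2L, function(p) {
        length(intersect(genes_by_treatment[[p[1]]], genes_by_treatment[[p[2]]]))
      }),
      stringsAsFactors = FALSE
    )
  }
  all_overlap <- if (length(treatments)) {
    Reduce(intersect, genes_by_treatment)
  } else character(0)
  list(
    per_treatment = per_treatment,
    genes_by_treatment = genes_by_treatment,
    das_genes = das_genes,
    n_das_genes = length(das_genes),
    genes_in_multiple = genes_in_multiple,
    fraction_in_multiple = if (length(das_genes)) {
      length(genes_in_multiple) / length(das_genes)
    } else 0,
    pairwise_overlap = pairwise,
    all_overlap = sort(all_overlap),
    de_overlap = if (is.null(de_genes)) NULL else {
      length(intersect(das_genes, de_genes))
    }
  )
}
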