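# Positive-selection tests: the intron-calibrated 3u threshold for 5'
# regulatory regions, and per-branch dN/dS plus the amino-acid-rate fallback
# for coding regions.

#' Intron lengths qualifying for background-rate estimation
#'
#' Introns are the neutral proxy; only introns whose ungapped reference
#' length exceeds `min_bp` (default 800 bp, chosen to be comparable to the
#' 1 kb 5' regions) qualify.
#'
#' @param loci List of locus objects, each with elements `coding`
#'   ([ortholog_set()]) and `annotation` ([region_annotation()]).
#' @param min_bp Minimum ungapped reference intron length.
#' @return Data frame `locus_id`, `intron_index`, `length_bp`, `start`,
#'   `end` (qualifying introns only).
#' @export
intron_table <- function(loci, min_bp = 800) {
  rows <- list()
  for (lc in loci) {
    ann <- lc$annotation
    m <- ann$intron_spans
    for (k in seq_len(nrow(m))) {
      len <- ungapped_length(lc$coding, ann$reference_role,
                             m[k, , drop = FALSE])
      if (len > min_bp) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = ann$locus_id, intron_index = k, length_bp = len,
          start = m[k, "start"], end = m[k, "end"],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(locus_id = character(0), intron_index = integer(0),
                      length_bp = integer(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

phase_category <- function(phase) {
  switch(phase,
         phase1 = "early_phase1",
         phase2_indica = "lineage_indica",
         phase2_japonica = "lineage_japonica",
         ggm_stop(paste0("unknown phase: ", phase), "ggm_config_error"))
}

#' Estimate the neutral background mutation rate from long introns
#'
#' Pools mutation counts (substitutions and indels alike) over qualifying
#' introns and divides by pooled kilobases: `u = total_mutations / total_kb`,
#' in mutations per kb per period.
#'
#' @param events Classified events (coding regions; intronic events are
#'   selected by position within the qualifying introns).
#' @param introns Qualifying-intron table from [intron_table()].
#' @param phase `"phase1"`, `"phase2_indica"` or `"phase2_japonica"`.
#' @return Object of class `background_rate`: `phase`, `u`,
#'   `total_mutations`, `total_kb`, `introns_used`.
#' @export
estimate_background_rate <- function(events, introns, phase = "phase1") {
  if (nrow(introns) == 0L) {
    ggm_stop(paste0("no qualifying introns; supply a background rate u ",
                    "explicitly in the run configuration"),
             "ggm_estimation_error")
  }
  cat <- phase_category(phase)
  ev <- events[!is.na(events$category) & events$category == cat &
                 events$region_kind == "coding_genomic", , drop = FALSE]
  n_mut <- 0L
  for (k in seq_len(nrow(introns))) {
    sel <- ev$locus_id == introns$locus_id[k] &
      ev$start >= introns$start[k] & ev$start <= introns$end[k]
    n_mut <- n_mut + sum(sel)
  }
  total_kb <- sum(introns$length_bp) / 1000
  structure(
    list(phase = phase, u = n_mut / total_kb, total_mutations = n_mut,
         total_kb = total_kb, introns_used = introns),
    class = "background_rate"
  )
}

#' @export
print.background_rate <- function(x, ...) {
  cat(sprintf("<background_rate> %s: u = %.4g /kb/period (%d mutations over %.2f kb, %d introns)\n",
              x$phase, x$u, x$total_mutations, x$total_kb, nrow(x$introns_used)))
  invisible(x)
}

#' Background rates for all phases
#'
#' Phase-II uses the higher of the indica and japonica estimates
#' (`phase2_max`).
#'
#' @inheritParams estimate_background_rate
#' @return List with `phase1`, `phase2_indica`, `phase2_japonica`
#'   (`background_rate` objects) and `phase2_max` (numeric).
#' @export
background_rates <- function(events, introns) {
  b1 <- estimate_background_rate(events, introns, "phase1")
  bi <- estimate_background_rate(events, introns, "phase2_indica")
  bj <- estimate_background_rate(events, introns, "phase2_japonica")
  list(phase1 = b1, phase2_indica = bi, phase2_japonica = bj,
       phase2_max = max(bi$u, bj$u))
}

selection_call <- function(locus_id, region, phase, test, statistic,
                           threshold, positive) {
  data.frame(locus_id = locus_id, region = region, phase = phase,
             test = test, statistic = statistic, threshold = threshold,
             positive = positive, stringsAsFactors = FALSE)
}

#' 5' regulatory-region positive-selection threshold test
#'
#' The observed mutation rate (count per kb over the period, substitutions
#' and indels counting equally) is compared to three times the intron
#' background rate; strictly exceeding `3u` signals positive selection. At
#' `u = 0.56`/kb and a 1 kb region this reduces to a cutoff of two
#' mutations.
#'
#' @param mutation_count Integer mutation count over the region and period.
#' @param region_kb Ungapped region length in kb (> 0).
#' @param u Background rate in mutations per kb per period.
#' @param locus_id,phase Identifiers stamped on the call.
#' @return One-row `SelectionCall` data frame.
#' @export
test_5prime <- function(mutation_count, region_kb, u,
                        locus_id = NA_character_, phase = "phase1") {
  if (region_kb <= 0) ggm_stop("region_kb must be > 0", "ggm_config_error")
  if (u < 0) ggm_stop("u must be >= 0", "ggm_config_error")
  statistic <- mutation_count / region_kb
  selection_call(locus_id, "five_prime", phase, "rate_threshold_5prime",
                 statistic, 3 * u, statistic > 3 * u)
}

#' Coding-region positive-selection test
#'
#' When synonymous changes are observed and no indels intervene, the branch
#' dN/dS (NG86) must strictly exceed 1. When `dS = 0` or indels are present,
#' the fallback counts amino-acid changes (substitution- and indel-derived)
#' per kb against a cutoff of 2; stop-gain and frameshift events satisfy the
#' fallback automatically since they alter the protein wholesale.
#'
#' @param branch_events Classified, coding-annotated events of one branch.
#' @param ancestral_coding Ungapped ancestral coding sequence for the branch.
#' @param coding_kb Ungapped reference coding length in kb.
#' @param locus_id,phase Identifiers stamped on the call.
#' @param aa_cutoff Amino-acid changes per kb cutoff (default 2).
#' @return One-row `SelectionCall` data frame.
#' @export
test_coding <- function(branch_events, ancestral_coding, coding_kb,
                        locus_id = NA_character_, phase = "phase1",
                        aa_cutoff = 2) {
  if (coding_kb <= 0) ggm_stop("coding_kb must be > 0", "ggm_config_error")
  exonic <- branch_events[!is.na(branch_events$coding_effect) &
                            branch_events$coding_effect != "none", , drop = FALSE]
  has_indel <- any(exonic$kind == "indel")
  nd <- compute_dnds(exonic, ancestral_coding)
  if (nd$dS > 0 && !has_indel) {
    ratio <- nd$dN / nd$dS
    return(selection_call(locus_id, "coding", phase, "dnds",
                          ratio, 1, ratio > 1))
  }
  aa_total <- sum(exonic$aa_change_count)
  disruptive <- any(exonic$coding_effect %in% c("stop_gain", "frameshift"))
  statistic <- aa_total / coding_kb
  selection_call(locus_id, "coding", phase, "aa_rate", statistic, aa_cutoff,
                 disruptive || statistic >= aa_cutoff)
}

#' Run both selection tests over every locus and phase
#'
#' @param loci List of locus objects (elements `five_prime`, `coding`,
#'   `annotation`).
#' @param events Classified events for the whole dataset.
#' @param u Optional background-rate override (single rate used for all
#'   phases); when `NULL`, rates are estimated from qualifying introns
#'   (Phase II uses the max of the two lineage estimates).
#' @return List with `calls` (all `SelectionCall` rows), `rates` (the
#'   background rates used) and `introns` (the qualifying-intron table).
#' @export
selection_scan <- function(loci, events, u = NULL) {
  introns <- intron_table(loci)
  if (is.null(u)) {
    rates <- background_rates(events, introns)
    u_phase <- c(phase1 = rates$phase1$u,
                 phase2_indica = rates$phase2_max,
                 phase2_japonica = rates$phase2_max)
  } else {
    rates <- NULL
    u_phase <- c(phase1 = u, phase2_indica = u, phase2_japonica = u)
  }
  phases <- c("phase1", "phase2_indica", "phase2_japonica")
  calls <- list()
  for (lc in loci) {
    lid <- lc$annotation$locus_id
    ev <- events[events$locus_id == lid, , drop = FALSE]
    fp_kb <- ungapped_length(lc$five_prime, lc$annotation$reference_role) / 1000
    cd_kb <- ungapped_length(lc$coding, lc$annotation$reference_role,
                             lc$annotation$exon_spans) / 1000
    cons_cd <- consensus_indica(lc$coding)
    ev_cd <- ev[ev$region_kind == "coding_genomic", , drop = FALSE]
    for (ph in phases) {
      cat <- phase_category(ph)
      n5 <- sum(ev$region_kind == "five_prime" & ev$category == cat)
      calls[[length(calls) + 1L]] <-
        test_5prime(n5, fp_kb, u_phase[[ph]], lid, ph)
      br <- ev_cd[ev_cd$category == cat, , drop = FALSE]
      anc <- branch_coding_seq(lc$coding, lc$annotation, ev_cd,
                               phase = if (ph == "phase1") "phase1" else "phase2",
                               cons = cons_cd)
      if (cd_kb > 0 && nchar(anc) >= 3L) {
        calls[[length(calls) + 1L]] <-
          test_coding(br, anc, cd_kb, lid, ph)
      }
    }
  }
  list(calls = do.call(rbind, calls), rates = rates, introns = introns)
}

#' Summarize selection calls per locus and phase
#'
#' @param calls `SelectionCall` data frame.
#' @return List with `table` (one row per locus x phase with `pos_5prime`,
#'   `pos_coding`, `pos_any`) and `counts` (per phase: loci positive in 5',
#'   coding, both, and the union).
#' @export
summarize_selection <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    return(list(
      table = data.frame(locus_id = character(0), phase = character(0),
                         pos_5prime = logical(0), pos_coding = logical(0),
                         pos_any = logical(0), stringsAsFactors = FALSE),
      counts = data.frame(phase = character(0), n_5prime = integer(0),
                          n_coding = integer(0), n_both = integer(0),
                          n_union = integer(0), stringsAsFactors = FALSE)))
  }
  key <- interaction(calls$locus_id, calls$phase, drop = TRUE)
  tab <- data.frame(
    locus_id = tapply(calls$locus_id, key, `[`, 1L),
    phase = tapply(calls$phase, key, `[`, 1L),
    pos_5prime = as.logical(tapply(
      calls$positive & calls$region == "five_prime", key, any)),
    pos_coding = as.logical(tapply(
      calls$positive & calls$region == "coding", key, any)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$pos_any <- tab$pos_5prime | tab$pos_coding
  tab <- tab[order(tab$phase, tab$locus_id), , drop = FALSE]
  counts <- do.call(rbind, lapply(split(tab, tab$phase), function(d) {
    data.frame(phase = d$phase[1L],
               n_5prime = sum(d$pos_5prime), n_coding = sum(d$pos_coding),
               n_both = sum(d$pos_5prime & d$pos_coding),
               n_union = sum(d$pos_any), stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(table = tab, counts = counts)
}
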