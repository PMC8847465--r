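# Eight-type classification of crop loci by parental affinity, detection of
# single-crossover recombinant alleles, and concordance checks against an
# additional genome.
#
# Type vocabulary: 1 ancient/conserved, 2 On-like, 3 Or-like, 4 mixed
# bi-specific, 5 Or-japonica/On-indica associated, 6 the reverse
# association, 7 split 5'-vs-coding parental origin, 8 new allele (layered
# annotation on the base type).

#' Default thresholds for gene typing
#'
#' @param theta Minimum fraction of diagnostic sites a lineage must match a
#'   parent for a clean affinity call (operationalizes "identical or
#'   similar").
#' @param min_sites Minimum diagnostic sites for any affinity call.
#' @param ancient_max Maximum crop mutations per region for the ancient type.
#' @param type8_5prime,type8_coding New-allele cutoffs: a lineage's new
#'   mutations must exceed these (5 in 5', 2 in coding) to annotate Type 8.
#' @return Named list of thresholds.
#' @export
typing_config <- function(theta = 0.9, min_sites = 3, ancient_max = 1,
                          type8_5prime = 5, type8_coding = 2) {
  list(theta = theta, min_sites = min_sites, ancient_max = ancient_max,
       type8_5prime = type8_5prime, type8_coding = type8_coding)
}

#' Parental-diagnostic sites with per-lineage parent-match labels
#'
#' @param events Classified events.
#' @return Data frame ordered by locus, region and position: `locus_id`,
#'   `region_kind`, `start`, `label_i`, `label_j` with labels `"Or"`,
#'   `"On"` or `"neither"` (a novel crop state at a diagnostic site carries
#'   no parental signal).
#' @export
diagnostic_sites <- function(events) {
  d <- events[!is.na(events$category) &
                events$category == "parental_diagnostic", , drop = FALSE]
  lab <- function(state, or, on) {
    ifelse(is.na(state), "neither",
           ifelse(state == or, "Or", ifelse(state == on, "On", "neither")))
  }
  out <- data.frame(
    locus_id = d$locus_id, region_kind = d$region_kind,
    subregion = d$subregion, start = d$start,
    label_i = lab(d$state_indica, d$state_or, d$state_on),
    label_j = lab(d$state_japonica, d$state_or, d$state_on),
    stringsAsFactors = FALSE
  )
  out[order(out$locus_id, out$region_kind, out$start), , drop = FALSE]
}

#' Region affinity from diagnostic-site match fractions
#'
#' Decision ladder: (a) no diagnostic sites and at most `ancient_max` crop
#' mutations: ancient; (b) fewer than `min_sites` sites: insufficient;
#' (c) both lineages match On at a fraction of at least `theta`: On-like;
#' (d) both match Or: Or-like; (e) japonica matches Or and indica matches
#' On: the Or-j/On-i association; (f) the reverse; (g) otherwise mixed.
#' Match fractions use all diagnostic sites as denominator, so
#' fraction(Or) + fraction(On) <= 1 per lineage.
#'
#' @param diag Diagnostic sites of one locus region ([diagnostic_sites()]
#'   rows).
#' @param os_mutation_count Total crop (early + lineage) mutations in the
#'   region.
#' @param cfg [typing_config()].
#' @return List with `affinity`, `n_sites` and match fractions `mi_or`,
#'   `mi_on`, `mj_or`, `mj_on`.
#' @export
classify_region <- function(diag, os_mutation_count, cfg = typing_config()) {
  n <- nrow(diag)
  frac <- function(lab, parent) if (n == 0L) 0 else mean(lab == parent)
  mi_or <- frac(diag$label_i, "Or"); mi_on <- frac(diag$label_i, "On")
  mj_or <- frac(diag$label_j, "Or"); mj_on <- frac(diag$label_j, "On")
  th <- cfg$theta
  affinity <-
    if (n == 0L && os_mutation_count <= cfg$ancient_max) "ancient"
    else if (n < cfg$min_sites) "insufficient"
    else if (mi_on >= th && mj_on >= th) "on_like"
    else if (mi_or >= th && mj_or >= th) "or_like"
    else if (mj_or >= th && mi_on >= th) "or_j_on_i"
    else if (mj_on >= th && mi_or >= th) "or_i_on_j"
    else "mixed"
  list(affinity = affinity, n_sites = n,
       mi_or = mi_or, mi_on = mi_on, mj_or = mj_or, mj_on = mj_on)
}

#' Minimal-switch scan for single-crossover recombinant alleles
#'
#' Writes a lineage's allele as a mosaic of Or- and On-source blocks over the
#' ordered diagnostic sites; the minimal number of parent switches equals the
#' number of label changes in a linear scan over the informative (non-neither)
#' sites. A single switch is the signature of one crossover; "neither" sites
#' are tallied as private mutations, and a clean recombinant requires none.
#'
#' @param labels Character vector of per-site labels (`"Or"`, `"On"`,
#'   `"neither"`), ordered by position.
#' @param positions Alignment positions of the sites (same length).
#' @return List with `switch_count` (NA when fewer than 2 informative
#'   sites), `breakpoint` (interval `c(lo, hi)` between the flanking sites
#'   when `switch_count == 1`, else NULL), `private_mutation_count` and
#'   `clean` (single switch with no private mutations).
#' @export
detect_recombinant <- function(labels, positions = seq_along(labels)) {
  stopifnot(length(labels) == length(positions))
  info <- labels != "neither"
  private <- sum(!info)
  lab <- labels[info]
  pos <- positions[info]
  if (length(lab) < 2L) {
    return(list(switch_count = NA_integer_, breakpoint = NULL,
                private_mutation_count = private, clean = FALSE))
  }
  r <- rle(lab)
  switches <- length(r$lengths) - 1L
  breakpoint <- NULL
  if (switches == 1L) {
    k <- r$lengths[1L]
    breakpoint <- c(pos[k], pos[k + 1L])
  }
  list(switch_count = switches, breakpoint = breakpoint,
       private_mutation_count = private,
       clean = switches == 1L && private == 0L)
}

# Base type integer from two region affinities.
BASE_TYPE <- c(ancient = 1L, on_like = 2L, or_like = 3L, mixed = 4L,
               or_j_on_i = 5L, or_i_on_j = 6L)
PARENTAL_CLEAN <- c("on_like", "or_like", "or_j_on_i", "or_i_on_j")

#' Combine region affinities and new-allele evidence into a locus type
#'
#' Agreeing affinities give the base type (1-6); two clean but different
#' parental origins between the 5' and coding regions give Type 7; an
#' uninformative (ancient or insufficient) region defers to the other; a
#' clean origin paired with a mixed region is mixed at locus level (Type 4).
#' A lineage-region whose new-mutation count exceeds the Type-8 cutoffs
#' (5 in 5', 2 in coding) adds the Type-8 new-allele annotation on top of
#' the base type.
#'
#' @param region_calls Named list with elements `five_prime` and `coding`,
#'   each a [classify_region()] result.
#' @param new_mutation_counts Named numeric vector of lineage-specific
#'   mutation counts: `i_5prime`, `j_5prime`, `i_coding`, `j_coding`.
#' @param cfg [typing_config()].
#' @return List with `final_type` (1-7, NA when untyped), `type8`,
#'   `new_alleles` (character vector like `"japonica:five_prime"`) and
#'   `reason` for untyped loci.
#' @export
classify_locus <- function(region_calls, new_mutation_counts,
                           cfg = typing_config()) {
  a5 <- region_calls$five_prime$affinity
  ac <- region_calls$coding$affinity
  informative <- function(a) !a %in% c("insufficient")
  final_type <- NA_integer_
  reason <- NA_character_
  if (!informative(a5) && !informative(ac)) {
    reason <- "insufficient diagnostic signal in both regions"
  } else {
    if (!informative(a5)) final_type <- BASE_TYPE[[ac]]
    else if (!informative(ac)) final_type <- BASE_TYPE[[a5]]
    else if (a5 == ac) final_type <- BASE_TYPE[[a5]]
    else if (a5 %in% PARENTAL_CLEAN && ac %in% PARENTAL_CLEAN) final_type <- 7L
    else if (a5 == "ancient") final_type <- BASE_TYPE[[ac]]
    else if (ac == "ancient") final_type <- BASE_TYPE[[a5]]
    else final_type <- 4L  # clean origin + mixed region: mixed at locus level
  }
  cutoffs <- c(i_5prime = cfg$type8_5prime, j_5prime = cfg$type8_5prime,
               i_coding = cfg$type8_coding, j_coding = cfg$type8_coding)
  nm <- names(cutoffs)
  counts <- new_mutation_counts[nm]
  counts[is.na(counts)] <- 0
  hit <- counts > cutoffs
  new_alleles <- character(0)
  if (any(hit)) {
    lineage <- ifelse(startsWith(nm[hit], "i_"), "indica", "japonica")
    region <- ifelse(endsWith(nm[hit], "5prime"), "five_prime", "coding")
    new_alleles <- paste(lineage, region, sep = ":")
  }
  list(final_type = final_type, type8 = any(hit),
       new_alleles = new_alleles, reason = reason)
}

#' Type every locus in a dataset
#'
#' Coding-region affinity uses exonic diagnostic sites only (introns inform
#' the background rate, not the coding genealogy); crop mutation counts
#' follow the same convention.
#'
#' @param events Classified events for the whole dataset.
#' @param cfg [typing_config()].
#' @return List with `table` (one row per locus: affinities, final type,
#'   type-8 and recombinant annotations) and `detail` (per-region match
#'   fractions and recombinant scans per lineage).
#' @export
gene_type_calls <- function(events, cfg = typing_config()) {
  diag <- diagnostic_sites(events)
  loci <- sort(unique(events$locus_id))
  rows <- list()
  detail <- list()
  for (lid in loci) {
    ev <- events[events$locus_id == lid, , drop = FALSE]
    dg <- diag[diag$locus_id == lid, , drop = FALSE]
    per_region <- list()
    rec_notes <- character(0)
    rec_clean <- FALSE
    for (rk in c("five_prime", "coding_genomic")) {
      keep_sub <- if (rk == "coding_genomic") "exon" else "five_prime"
      dgr <- dg[dg$region_kind == rk & !is.na(dg$subregion) &
                  dg$subregion == keep_sub, , drop = FALSE]
      evr <- ev[ev$region_kind == rk, , drop = FALSE]
      if (rk == "coding_genomic") {
        evr <- evr[!is.na(evr$subregion) & evr$subregion == "exon", , drop = FALSE]
      }
      os_count <- sum(evr$category %in%
                        c("early_phase1", "lineage_indica", "lineage_japonica"))
      cr <- classify_region(dgr, os_count, cfg)
      key <- if (rk == "five_prime") "five_prime" else "coding"
      per_region[[key]] <- cr
      for (lin in c("i", "j")) {
        labs <- dgr[[paste0("label_", lin)]]
        if (length(labs) >= 2L) {
          rec <- detect_recombinant(labs, dgr$start)
          detail[[length(detail) + 1L]] <- data.frame(
            locus_id = lid, region = key,
            lineage = if (lin == "i") "indica" else "japonica",
            n_sites = cr$n_sites, switch_count = rec$switch_count,
            breakpoint_lo = if (is.null(rec$breakpoint)) NA_integer_ else rec$breakpoint[1L],
            breakpoint_hi = if (is.null(rec$breakpoint)) NA_integer_ else rec$breakpoint[2L],
            private_mutations = rec$private_mutation_count,
            clean = rec$clean,
            mi_or = cr$mi_or, mi_on = cr$mi_on,
            mj_or = cr$mj_or, mj_on = cr$mj_on,
            stringsAsFactors = FALSE)
          if (!is.na(rec$switch_count) && rec$switch_count == 1L) {
            rec_notes <- c(rec_notes, sprintf(
              "%s:%s:%d-%d", if (lin == "i") "indica" else "japonica",
              key, rec$breakpoint[1L], rec$breakpoint[2L]))
            if (rec$clean) rec_clean <- TRUE
          }
        }
      }
    }
    new_counts <- c(
      i_5prime = sum(ev$region_kind == "five_prime" &
                       ev$category == "lineage_indica"),
      j_5prime = sum(ev$region_kind == "five_prime" &
                       ev$category == "lineage_japonica"),
      i_coding = sum(ev$region_kind == "coding_genomic" &
                       !is.na(ev$subregion) & ev$subregion == "exon" &
                       ev$category == "lineage_indica"),
      j_coding = sum(ev$region_kind == "coding_genomic" &
                       !is.na(ev$subregion) & ev$subregion == "exon" &
                       ev$category == "lineage_japonica"))
    cl <- classify_locus(per_region, new_counts, cfg)
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = lid,
      affinity_5prime = per_region$five_prime$affinity,
      affinity_coding = per_region$coding$affinity,
      n_sites_5prime = per_region$five_prime$n_sites,
      n_sites_coding = per_region$coding$n_sites,
      final_type = cl$final_type,
      type8 = cl$type8,
      new_alleles = paste(cl$new_alleles, collapse = ","),
      recombinant = paste(rec_notes, collapse = ","),
      recombinant_clean = rec_clean,
      untyped_reason = cl$reason,
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows),
       detail = if (length(detail) > 0L) do.call(rbind, detail) else NULL)
}

#' Census of gene types
#'
#' Type-8 (new-allele) loci are binned under "new" regardless of their base
#' type, which is retained in the detail table. Summary bins: ancient
#' (type 1), uni-specific (types 2-3), bi-specific (types 4-7), new
#' (type 8).
#'
#' @param calls `table` element of [gene_type_calls()].
#' @return List with `by_type` (counts per displayed type 1-8), `bins`
#'   (counts and fractions per summary bin) and `n_typed`.
#' @export
type_census <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    return(list(by_type = integer(0), bins = data.frame(), n_typed = 0L))
  }
  typed <- calls[!is.na(calls$final_type), , drop = FALSE]
  display_type <- ifelse(typed$type8, 8L, typed$final_type)
  by_type <- table(factor(display_type, levels = 1:8))
  n <- nrow(typed)
  bin_of <- c("ancient", "uni_specific", "uni_specific", "bi_specific",
              "bi_specific", "bi_specific", "bi_specific", "new")
  bins_raw <- tapply(as.integer(by_type), bin_of, sum)
  bins <- data.frame(
    bin = c("ancient", "uni_specific", "bi_specific", "new"),
    count = as.integer(bins_raw[c("ancient", "uni_specific", "bi_specific", "new")]),
    stringsAsFactors = FALSE)
  bins$fraction <- if (n > 0L) bins$count / n else NA_real_
  list(by_type = as.integer(by_type), bins = bins, n_typed = n)
}

#' Concordance of an extra genome with the classified mutations
#'
#' For each event, checks whether the extra genome (role `"extra"` in the
#' supplied sets) carries the derived state: expected for early mutations
#' and for mutations of the lineage the extra genome belongs to.
#'
#' @param loci List of locus objects whose `five_prime`/`coding` sets
#'   include an `"extra"` genome.
#' @param events Classified events.
#' @param extra_lineage Which crop lineage the extra genome represents
#'   (`"japonica"` or `"indica"`).
#' @return List with `by_category` (events checked / derived-state matches /
#'   fraction per category), `disagreements` (event rows where the expected
#'   derived state is absent) and `introgression_like` loci (extra genome
#'   carrying the other lineage's derived states but not its own).
#' @export
genome_concordance <- function(loci, events, extra_lineage = "japonica") {
  own_cat <- if (extra_lineage == "japonica") "lineage_japonica" else "lineage_indica"
  other_cat <- if (extra_lineage == "japonica") "lineage_indica" else "lineage_japonica"
  checked <- list()
  for (lc in loci) {
    for (key in c("five_prime", "coding")) {
      set <- lc[[key]]
      if (is.null(set)) next
      extra_row <- names(set$roles)[set$roles == "extra"]
      if (length(extra_row) == 0L) next
      ex <- set$mat[extra_row[1L], ]
      lid <- set$locus_id
      ev <- events[events$locus_id == lid &
                     events$region_kind == set$region_kind &
                     events$category %in%
                       c("early_phase1", own_cat, other_cat), , drop = FALSE]
      for (r in seq_len(nrow(ev))) {
        e <- ev[r, ]
        span <- seq.int(e$start, e$end)
        carries <- if (e$kind == "indel") {
          if (identical(e$derived_state, "-")) all(ex[span] == "-")
          else all(ex[span] != "-")
        } else {
          identical(unname(ex[e$start]), e$derived_state)
        }
        checked[[length(checked) + 1L]] <- cbind(
          e, carries_derived = carries, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(checked) == 0L) {
    return(list(by_category = data.frame(), disagreements = empty_events(),
                introgression_like = character(0)))
  }
  ck <- do.call(rbind, checked)
  by_category <- do.call(rbind, lapply(split(ck, ck$category), function(d) {
    data.frame(category = d$category[1L], n_checked = nrow(d),
               n_carrying = sum(d$carries_derived),
               fraction = mean(d$carries_derived), stringsAsFactors = FALSE)
  }))
  rownames(by_category) <- NULL
  expected <- ck$category %in% c("early_phase1", own_cat)
  disagreements <- ck[expected & !ck$carries_derived, , drop = FALSE]
  intro <- vapply(split(ck, ck$locus_id), function(d) {
    own <- d[d$category == own_cat, , drop = FALSE]
    oth <- d[d$category == other_cat, , drop = FALSE]
    nrow(own) >= 1L && nrow(oth) >= 1L &&
      all(!own$carries_derived) && all(oth$carries_derived)
  }, logical(1))
  list(by_category = by_category, disagreements = disagreements,
       introgression_like = names(intro)[intro])
}
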