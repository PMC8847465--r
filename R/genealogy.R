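# Gene-genealogy mutation (GGM) core: detect variant columns on the fixed
# four-taxon topology ((indica, japonica), Or, On), collapse indel runs into
# single events, and place every event on the branch where it arose.

#' Detect variant alignment columns on the four-role genealogy
#'
#' A column is a variant when at least two of the four role states (Or, On,
#' indica consensus, japonica) differ. Columns where any genome carries `N`
#' are excluded as missing; columns where the indica consensus is ambiguous
#' are excluded from fixed-mutation calling and reported separately as
#' transient.
#'
#' @param set An [ortholog_set()].
#' @param cons Output of [consensus_indica()] (computed if omitted).
#' @return List with `variants` (data frame: `column`, `or`, `on`, `ind`,
#'   `jap`), `masked` (ambiguous columns) and `missing` (N-containing
#'   columns).
#' @export
call_variant_columns <- function(set, cons = consensus_indica(set)) {
  core <- set$mat[set$roles[rownames(set$mat)] != "extra", , drop = FALSE]
  missing <- which(colSums(core == "N") > 0L)
  rs <- role_state_matrix(set, cons)
  masked <- setdiff(which(cons$ambiguous), missing)
  usable <- setdiff(seq_len(set$alignment_length), c(missing, masked))
  if (length(usable) == 0L) {
    variants <- data.frame(column = integer(0), or = character(0),
                           on = character(0), ind = character(0),
                           jap = character(0), stringsAsFactors = FALSE)
  } else {
    sub <- rs[, usable, drop = FALSE]
    is_var <- colSums(sub != sub[rep(1L, 4L), , drop = FALSE]) > 0L
    cols <- usable[is_var]
    variants <- data.frame(column = cols,
                           or = rs["Or", cols], on = rs["On", cols],
                           ind = rs["I", cols], jap = rs["J", cols],
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  list(variants = variants, masked = masked, missing = missing)
}

# Canonical role-state pattern: states renamed by order of first appearance,
# so (A,A,T,T) and (C,C,G,G) share pattern "1122". Used both for indel-run
# merging (on gap presence) and for the shared-multiplicity annotation of
# adjacent substitution columns.
state_pattern <- function(or, on, ind, jap) {
  vapply(seq_along(or), function(i) {
    s <- c(or[i], on[i], ind[i], jap[i])
    paste(match(s, s), collapse = "")  # first-occurrence canonical labels
  }, character(1))
}

#' Collapse variant columns into mutation events
#'
#' Maximal runs of adjacent gap columns sharing an identical role-presence
#' pattern merge into one indel event (a single mutational origin regardless
#' of length). Adjacent substitution columns with an identical
#' category-relevant pattern remain separate events but share a multiplicity
#' annotation for reporting. Substitution states observed at indel columns
#' among the gap-free roles are emitted as additional substitution events and
#' resolved by [classify_events()].
#'
#' @param variants Variant-column data frame from [call_variant_columns()]
#'   (sorted by column).
#' @param locus_id,region_kind Identifiers stamped on the events.
#' @return Event data frame with `kind` and states set, `category` unset.
#' @export
collapse_indels <- function(variants, locus_id = "locus",
                            region_kind = "five_prime") {
  if (nrow(variants) == 0L) return(empty_events())
  roles4 <- c("or", "on", "ind", "jap")
  gap <- as.matrix(variants[roles4]) == "-"
  gap_pat <- apply(gap, 1L, function(z) paste(as.integer(z), collapse = ""))
  is_indel <- rowSums(gap) > 0L

  out <- list()
  add <- function(df) out[[length(out) + 1L]] <<- df

  # --- indel events: merge adjacent same-pattern gap runs -------------------
  if (any(is_indel)) {
    idx <- which(is_indel)
    cols <- variants$column[idx]
    run_break <- c(TRUE, diff(cols) != 1L | gap_pat[idx[-1L]] != gap_pat[idx[-length(idx)]])
    run_id <- cumsum(run_break)
    for (r in unique(run_id)) {
      members <- idx[run_id == r]
      pres <- ifelse(gap[members[1L], ], "-", "+")
      add(data.frame(
        locus_id = locus_id, region_kind = region_kind,
        subregion = NA_character_,
        start = variants$column[members[1L]],
        end = variants$column[members[length(members)]],
        kind = "indel", multiplicity = 1L, category = NA_character_,
        state_or = pres[["or"]], state_on = pres[["on"]],
        state_indica = pres[["ind"]], state_japonica = pres[["jap"]],
        derived_state = NA_character_, coding_effect = "none",
        aa_change_count = 0L, stringsAsFactors = FALSE))
      # secondary substitution signal among the gap-free roles
      for (m in members) {
        present <- !gap[m, ]
        states <- unlist(variants[m, roles4])[present]
        if (length(unique(states)) > 1L) {
          s <- unlist(variants[m, roles4])
          s[gap[m, ]] <- NA_character_
          add(data.frame(
            locus_id = locus_id, region_kind = region_kind,
            subregion = NA_character_,
            start = variants$column[m], end = variants$column[m],
            kind = "substitution", multiplicity = 1L,
            category = NA_character_,
            state_or = s[["or"]], state_on = s[["on"]],
            state_indica = s[["ind"]], state_japonica = s[["jap"]],
            derived_state = NA_character_, coding_effect = "none",
            aa_change_count = 0L, stringsAsFactors = FALSE))
        }
      }
    }
  }

  # --- substitution events: one per column, shared multiplicity -------------
  if (any(!is_indel)) {
    idx <- which(!is_indel)
    cols <- variants$column[idx]
    pat <- state_pattern(variants$or[idx], variants$on[idx],
                         variants$ind[idx], variants$jap[idx])
    run_break <- c(TRUE, diff(cols) != 1L | pat[-1L] != pat[-length(pat)])
    run_id <- cumsum(run_break)
    mult <- ave(run_id, run_id, FUN = length)
    add(data.frame(
      locus_id = locus_id, region_kind = region_kind,
      subregion = NA_character_,
      start = cols, end = cols,
      kind = "substitution", multiplicity = as.integer(mult),
      category = NA_character_,
      state_or = variants$or[idx], state_on = variants$on[idx],
      state_indica = variants$ind[idx], state_japonica = variants$jap[idx],
      derived_state = NA_character_, coding_effect = "none",
      aa_change_count = 0L, stringsAsFactors = FALSE))
  }

  ev <- do.call(rbind, out)
  ev[order(ev$start, ev$end, ev$kind), , drop = FALSE]
}

# Decision table for one event given its four role states. States may be
# bases, or "-"/"+" presence symbols for indels; NA marks a role that is
# unobservable at the column (gapped under an overlapping indel).
classify_one <- function(o, n, i, j) {
  wild <- c(o, n)
  if (is.na(o) || is.na(n)) {
    # absence in both wild parents cannot be established
    return(list(category = "transient_ambiguous", derived = NA_character_))
  }
  if (is.na(i) || is.na(j)) {
    crop <- if (is.na(i)) j else i
    if (!crop %in% wild) {
      cat <- if (is.na(i)) "lineage_japonica" else "lineage_indica"
      return(list(category = cat, derived = crop))
    }
    return(list(category = "transient_ambiguous", derived = NA_character_))
  }
  if (i == j && !(i %in% wild)) {
    return(list(category = "early_phase1", derived = i))
  }
  if (i != j && !(i %in% wild) && !(j %in% wild)) {
    return(list(category = "recurrent_suspect", derived = NA_character_))
  }
  if (!(i %in% c(wild, j))) {
    return(list(category = "lineage_indica", derived = i))
  }
  if (!(j %in% c(wild, i))) {
    return(list(category = "lineage_japonica", derived = j))
  }
  if (o != n && i %in% wild && j %in% wild) {
    return(list(category = "parental_diagnostic", derived = NA_character_))
  }
  list(category = "transient_ambiguous", derived = NA_character_)
}

#' Assign each event to its branch on the gene genealogy
#'
#' Decision table: a state shared by indica and japonica but absent from both
#' wild parents is an early (Phase-I) mutation; a state private to one crop
#' lineage is a Phase-II lineage mutation; a column where the wild parents
#' differ and every crop state is drawn from the parental states is a
#' parental diagnostic site (used for topology and parental-origin typing,
#' not counted as a crop mutation); two different novel crop states at one
#' column violate the no-recurrence assumption and are emitted as two events
#' flagged `recurrent_suspect`; anything else is transient/ambiguous.
#'
#' @param events Event data frame from [collapse_indels()].
#' @return Events with `category` and `derived_state` filled; recurrent
#'   columns are expanded into two rows (one per lineage).
#' @export
classify_events <- function(events) {
  if (nrow(events) == 0L) return(events)
  o <- events$state_or; n <- events$state_on
  i <- events$state_indica; j <- events$state_japonica
  complete <- !(is.na(o) | is.na(n) | is.na(i) | is.na(j))
  category <- rep("transient_ambiguous", nrow(events))
  derived <- rep(NA_character_, nrow(events))
  iw <- i == o | i == n   # indica state present in a wild parent
  jw <- j == o | j == n
  early <- complete & i == j & !iw
  rec <- complete & i != j & !iw & !jw
  lini <- complete & !rec & !iw & i != j
  linj <- complete & !rec & !jw & j != i & iw
  pard <- complete & o != n & iw & jw
  category[pard] <- "parental_diagnostic"
  category[early] <- "early_phase1"; derived[early] <- i[early]
  category[lini] <- "lineage_indica"; derived[lini] <- i[lini]
  category[linj] <- "lineage_japonica"; derived[linj] <- j[linj]
  category[rec] <- "recurrent_suspect"
  for (r in which(!complete)) {
    cl <- classify_one(o[r], n[r], i[r], j[r])
    category[r] <- cl$category
    derived[r] <- cl$derived
  }
  events$category <- category
  events$derived_state <- derived
  if (any(rec)) {
    # emit both lineage events for a recurrent column
    idx <- sort(c(seq_len(nrow(events)), which(rec)))
    events <- events[idx, , drop = FALSE]
    pos <- which(rec) + seq_along(which(rec)) - 1L
    events$derived_state[pos] <- events$state_indica[pos]
    events$derived_state[pos + 1L] <- events$state_japonica[pos + 1L]
  }
  rownames(events) <- NULL
  events
}

# Transient records for masked (ambiguous indica consensus) columns.
masked_events <- function(set, masked_cols) {
  if (length(masked_cols) == 0L) return(empty_events())
  rs <- set$mat
  data.frame(
    locus_id = set$locus_id, region_kind = set$region_kind,
    subregion = NA_character_,
    start = masked_cols, end = masked_cols,
    kind = "substitution", multiplicity = 1L,
    category = "transient_ambiguous",
    state_or = rs[role_rows(set, "Or"), masked_cols],
    state_on = rs[role_rows(set, "On"), masked_cols],
    state_indica = NA_character_,
    state_japonica = rs[role_rows(set, "japonica"), masked_cols],
    derived_state = NA_character_, coding_effect = "none",
    aa_change_count = 0L, stringsAsFactors = FALSE)
}

#' Call and classify all mutation events for one locus region
#'
#' Convenience wrapper: indica consensus, variant-column detection, indel
#' collapse, branch classification, subregion labelling and (for coding
#' regions) coding-effect annotation.
#'
#' @param set An [ortholog_set()].
#' @param ann Optional [region_annotation()]; required for subregion labels
#'   and coding effects.
#' @return Classified event data frame (including transient records for
#'   masked columns).
#' @export
call_mutations <- function(set, ann = NULL) {
  cons <- consensus_indica(set)
  vc <- call_variant_columns(set, cons)
  ev <- collapse_indels(vc$variants, set$locus_id, set$region_kind)
  ev <- classify_events(ev)
  ev <- rbind(ev, masked_events(set, vc$masked))
  if (nrow(ev) == 0L) return(empty_events())
  if (!is.null(ann)) {
    sub <- subregion_of_columns(set, ann)
    ev$subregion <- sub[ev$start]
    if (set$region_kind == "coding_genomic") {
      ev <- annotate_coding_effect(ev, ann, set, cons)
    }
  } else {
    ev$subregion <- if (set$region_kind == "five_prime") "five_prime" else NA_character_
  }
  attr(ev, "missing_columns") <- length(vc$missing)
  ev[order(ev$start, ev$end, ev$kind), , drop = FALSE]
}

#' Per-locus, per-region phase counts
#'
#' Counts classified events (each indel run = one mutation) by temporal
#' category. Transient and recurrent events are tallied separately and, by
#' default, excluded from the phase counts, matching the no-recurrence
#' assumption.
#'
#' @param events Classified event data frame.
#' @param include_recurrent Count `recurrent_suspect` events into the lineage
#'   columns (default `FALSE`).
#' @return Data frame with one row per locus x region: `n_early`,
#'   `n_indica`, `n_japonica`, `n_parental`, `n_transient`, `n_recurrent`.
#' @export
count_by_phase <- function(events, include_recurrent = FALSE) {
  if (nrow(events) == 0L) {
    return(data.frame(locus_id = character(0), region_kind = character(0),
                      n_early = integer(0), n_indica = integer(0),
                      n_japonica = integer(0), n_parental = integer(0),
                      n_transient = integer(0), n_recurrent = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(events$locus_id, events$region_kind, drop = TRUE)
  tally <- function(cat) {
    as.integer(tapply(events$category == cat, key, sum))
  }
  out <- data.frame(
    locus_id = tapply(events$locus_id, key, `[`, 1L),
    region_kind = tapply(events$region_kind, key, `[`, 1L),
    n_early = tally("early_phase1"),
    n_indica = tally("lineage_indica"),
    n_japonica = tally("lineage_japonica"),
    n_parental = tally("parental_diagnostic"),
    n_transient = tally("transient_ambiguous"),
    n_recurrent = tally("recurrent_suspect"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (include_recurrent) {
    rec <- events[events$category == "recurrent_suspect", , drop = FALSE]
    if (nrow(rec) > 0L) {
      rkey <- paste(rec$locus_id, rec$region_kind)
      okey <- paste(out$locus_id, out$region_kind)
      is_ind <- !is.na(rec$derived_state) & rec$derived_state == rec$state_indica
      add_i <- tapply(is_ind, rkey, sum)
      add_j <- tapply(!is_ind, rkey, sum)
      m <- match(names(add_i), okey)
      out$n_indica[m] <- out$n_indica[m] + as.integer(add_i)
      out$n_japonica[m] <- out$n_japonica[m] + as.integer(add_j)
    }
  }
  out[order(out$locus_id, out$region_kind), , drop = FALSE]
}
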