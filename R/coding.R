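# Coding-effect annotation and per-branch Nei-Gojobori (NG86) counting.
#
# Mutations are polarized along the genealogy: the pre-mutation codon is
# reconstructed from the wild-parent state(s) for Phase-I events and from the
# Phase-I (shared crop) state for Phase-II events; each event is a single
# nucleotide change classified directly against that codon (no multiple-hit
# pathways are needed under the infinite-sites assumption).

.ggm_env <- new.env(parent = emptyenv())

# Synonymous site count per sense codon (NG86 fractional sites; changes that
# create a stop codon count as nonsynonymous).
ng86_table <- function() {
  if (!is.null(.ggm_env$ng86)) return(.ggm_env$ng86)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  bases <- c("A", "C", "G", "T")
  syn <- vapply(codons, function(cd) {
    s <- strsplit(cd, "")[[1L]]
    tot <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, s[p])) {
        alt <- s
        alt[p] <- b
        altc <- paste(alt, collapse = "")
        if (gc[[altc]] != "*" && gc[[altc]] == gc[[cd]]) tot <- tot + 1 / 3
      }
    }
    tot
  }, numeric(1))
  .ggm_env$ng86 <- syn
  syn
}

#' NG86 synonymous and nonsynonymous site counts of a coding sequence
#'
#' Fractional sites per codon; codons containing characters outside
#' `A,C,G,T` and stop codons contribute nothing.
#'
#' @param coding Ungapped coding sequence (character scalar, length a
#'   multiple of 3).
#' @return List with `S` (synonymous sites) and `N` (nonsynonymous sites).
#' @export
ng86_site_counts <- function(coding) {
  if (nchar(coding) %% 3L != 0L) {
    ggm_stop("coding length is not a multiple of 3", "ggm_frame_error")
  }
  tab <- ng86_table()
  cods <- substring(coding, seq(1L, nchar(coding), 3L), seq(3L, nchar(coding), 3L))
  s <- tab[cods]
  s[is.na(s)] <- NA  # stop codons / ambiguous codons
  used <- !is.na(s)
  S <- sum(s[used])
  N <- 3 * sum(used) - S
  list(S = S, N = N)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(aa)
}

# Branch-ancestral sequences over alignment columns.
# A0: the pre-domestication crop ancestor (wild state; parental-diagnostic
#     columns resolved to the parent the crop inherited, defaulting to Or
#     when unresolvable).
# A1: A0 with Phase-I derived states applied (context for Phase-II events).
branch_ancestral <- function(set, cons, events) {
  rs <- role_state_matrix(set, cons)
  o <- unname(rs["Or", ]); n <- unname(rs["On", ])
  i <- unname(rs["I", ]); j <- unname(rs["J", ])
  A0 <- o
  res <- o != n & !is.na(i) & !is.na(j) & i == j & (i == o | i == n)
  A0[res] <- i[res]
  A1 <- A0
  early <- events[!is.na(events$category) &
                    events$category == "early_phase1", , drop = FALSE]
  for (r in seq_len(nrow(early))) {
    e <- early[r, ]
    cols <- seq.int(e$start, e$end)
    if (e$kind == "substitution") {
      A1[cols] <- e$derived_state
    } else if (identical(e$derived_state, "-")) {
      A1[cols] <- "-"
    } else {
      A1[cols] <- j[cols]  # shared insertion: take the crop bases
    }
  }
  list(A0 = A0, A1 = A1)
}

# Alignment columns that are coding positions: exonic columns where the
# reference genome is ungapped, in 5'->3' order.
coding_columns <- function(set, ann) {
  ref <- set$mat[resolve_role_name(set, ann$reference_role), ]
  exon_cols <- cols_in_spans(ann$exon_spans)
  exon_cols[ref[exon_cols] != "-"]
}

# Carrier genome row (character vector of states) for an event category.
carrier_states <- function(set, cons, category, ev) {
  rs <- role_state_matrix(set, cons)
  switch(category,
    lineage_indica = {
      s <- unname(rs["I", ])
      s[is.na(s)] <- set$mat[role_rows(set, "indica")[1L], ][is.na(s)]
      s
    },
    lineage_japonica = unname(rs["J", ]),
    early_phase1 = unname(rs["J", ]),
    parental_diagnostic = {
      if (identical(ev$state_or, "-")) unname(rs["Or", ]) else unname(rs["On", ])
    },
    unname(rs["J", ])
  )
}

#' Annotate coding effects of classified events
#'
#' Substitutions are translated against the pre-mutation codon in the
#' event's branch context (standard genetic code) and labelled synonymous,
#' nonsynonymous or stop-gain. Indels with an exonic length divisible by 3
#' are in-frame (`aa_change_count` = exonic length / 3); frame-disrupting
#' indels are frameshifts with `aa_change_count` the number of codons from
#' the event to the first novel stop in the carrier's reading frame.
#' Intronic events keep effect `none`. Parental-diagnostic substitutions are
#' annotated with the (unpolarized) Or-vs-On codon difference.
#'
#' @param events Classified event data frame for one coding region.
#' @param ann The locus [region_annotation()].
#' @param set The `coding_genomic` [ortholog_set()].
#' @param cons Output of [consensus_indica()] (computed if omitted).
#' @return Events with `coding_effect` and `aa_change_count` filled.
#' @export
annotate_coding_effect <- function(events, ann, set, cons = consensus_indica(set)) {
  if (nrow(events) == 0L) return(events)
  if (set$region_kind != "coding_genomic") {
    ggm_stop("coding effects require a coding_genomic region", "ggm_annotation_error")
  }
  anc <- branch_ancestral(set, cons, events)
  cc <- coding_columns(set, ann)
  f <- ann$frame_offset
  gc_tab <- Biostrings::GENETIC_CODE

  effect_of_sub <- function(e) {
    p <- match(e$start, cc)
    if (is.na(p) || p <= f) return(list(effect = "none", aa = 0L))
    bg <- if (e$category %in% c("early_phase1", "parental_diagnostic")) anc$A0 else anc$A1
    ci <- (p - f - 1L) %/% 3L
    pos3 <- f + ci * 3L + 1:3
    if (any(pos3 > length(cc))) return(list(effect = "none", aa = 0L))
    cols3 <- cc[pos3]
    pre <- bg[cols3]
    gapped <- pre == "-"
    pre[gapped] <- anc$A0[cols3][gapped]
    within <- p - (f + ci * 3L)
    if (e$category == "parental_diagnostic") {
      post <- pre
      pre[within] <- e$state_or
      post[within] <- e$state_on
    } else {
      post <- pre
      post[within] <- e$derived_state
    }
    if (any(!pre %in% c("A", "C", "G", "T")) ||
        any(!post %in% c("A", "C", "G", "T"))) {
      return(list(effect = "none", aa = 0L))
    }
    aa_pre <- gc_tab[[paste(pre, collapse = "")]]
    aa_post <- gc_tab[[paste(post, collapse = "")]]
    if (aa_pre == aa_post) return(list(effect = "synonymous", aa = 0L))
    if (aa_post == "*" && aa_pre != "*") return(list(effect = "stop_gain", aa = 1L))
    list(effect = "nonsynonymous", aa = 1L)
  }

  effect_of_indel <- function(e) {
    cols <- seq.int(e$start, e$end)
    ex_len <- sum(cols %in% cc)
    if (ex_len == 0L) return(list(effect = "none", aa = 0L))
    if (ex_len %% 3L == 0L) {
      return(list(effect = "inframe_indel", aa = ex_len %/% 3L))
    }
    # frameshift: translate the carrier in its own (shifted) frame from the
    # codon containing the event and count codons up to the first stop
    carrier <- carrier_states(set, cons, e$category, e)
    car_cc <- carrier[cc]
    keep <- car_cc != "-" & car_cc != "N"
    car_seq <- car_cc[keep]
    if (length(car_seq) <= f) return(list(effect = "frameshift", aa = 0L))
    car_seq <- car_seq[(f + 1L):length(car_seq)]
    n_before <- sum(keep & cc < e$start)
    start_codon <- max(0L, (n_before - f)) %/% 3L  # 0-based codon index
    n_cod <- length(car_seq) %/% 3L
    aa <- 0L
    if (n_cod > start_codon) {
      for (k in seq.int(start_codon, n_cod - 1L)) {
        cd <- paste(car_seq[(k * 3L + 1L):(k * 3L + 3L)], collapse = "")
        aa <- aa + 1L
        a <- gc_tab[cd]
        if (!is.na(a) && a == "*") break
      }
    }
    list(effect = "frameshift", aa = aa)
  }

  for (r in seq_len(nrow(events))) {
    e <- events[r, , drop = FALSE]
    if (!is.na(e$subregion) && e$subregion == "intron" && e$kind == "substitution") next
    res <- if (e$kind == "substitution") effect_of_sub(e) else effect_of_indel(e)
    events$coding_effect[r] <- res$effect
    events$aa_change_count[r] <- res$aa
  }
  events
}

#' Per-branch NG86 dN and dS
#'
#' Site counts S and N are computed over the branch-ancestral coding
#' sequence; substitution events already classified as synonymous,
#' nonsynonymous or stop-gain supply the change counts. No multiple-hit
#' correction is applied (divergence over domestication time scales is far
#' below saturation).
#'
#' @param branch_events Classified, coding-annotated substitution events of
#'   one branch (phase).
#' @param ancestral_coding Ungapped ancestral coding sequence for the branch.
#' @return List with `dN`, `dS`, `n_N`, `n_S`, `N`, `S`.
#' @export
compute_dnds <- function(branch_events, ancestral_coding) {
  sc <- ng86_site_counts(ancestral_coding)
  subs <- branch_events[branch_events$kind == "substitution", , drop = FALSE]
  n_S <- sum(subs$coding_effect == "synonymous")
  n_N <- sum(subs$coding_effect %in% c("nonsynonymous", "stop_gain"))
  dS <- if (sc$S > 0) n_S / sc$S else 0
  dN <- if (sc$N > 0) n_N / sc$N else 0
  list(dN = dN, dS = dS, n_N = n_N, n_S = n_S, N = sc$N, S = sc$S)
}

# Ungapped ancestral coding sequence for a phase ("phase1" context = A0,
# phase-II context = A1), trimmed to full codons.
branch_coding_seq <- function(set, ann, events, phase = c("phase1", "phase2"),
                              cons = consensus_indica(set)) {
  phase <- match.arg(phase)
  anc <- branch_ancestral(set, cons, events)
  bg <- if (phase == "phase1") anc$A0 else anc$A1
  cc <- coding_columns(set, ann)
  s <- bg[cc]
  s <- s[s != "-"]
  if (ann$frame_offset > 0L && length(s) > ann$frame_offset) {
    s <- s[-seq_len(ann$frame_offset)]
  }
  n <- length(s) - length(s) %% 3L
  paste(s[seq_len(n)], collapse = "")
}
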