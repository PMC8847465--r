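# Shared fixtures and independent oracles for the test suite.

# Quick ortholog_set from per-role strings; `ind` may be a character vector
# for multiple indica genomes.
make_set <- function(or, on, ind, jap, extra = NULL,
                     region = "five_prime", locus = "L1") {
  ind <- as.character(ind)
  seqs <- c(Or1 = or, On1 = on,
            stats::setNames(ind, paste0("I", seq_along(ind))), J1 = jap)
  roles <- c(Or1 = "Or", On1 = "On",
             stats::setNames(rep("indica", length(ind)),
                             paste0("I", seq_along(ind))),
             J1 = "japonica")
  if (!is.null(extra)) {
    seqs <- c(seqs, X1 = extra)
    roles <- c(roles, X1 = "extra")
  }
  ortholog_set(seqs, roles, locus_id = locus, region_kind = region)
}

# A coding-region set with a single exon covering the whole alignment.
make_coding_set <- function(or, on, ind, jap, locus = "L1", extra = NULL) {
  make_set(or, on, ind, jap, extra = extra, region = "coding_genomic",
           locus = locus)
}

one_exon_ann <- function(len, locus = "L1", frame_offset = 0) {
  region_annotation(locus_id = locus, chromosome = "chr1",
                    exon_spans = rbind(c(1L, as.integer(len))),
                    frame_offset = frame_offset, reference_role = "Or")
}

# Independent NG86 oracle: per-codon brute-force enumeration of all nine
# single-nucleotide neighbours, synonymous fractions read off the standard
# genetic code. Stop-creating changes count as nonsynonymous; stop codons
# and codons with ambiguous characters are skipped.
oracle_ng86_sites <- function(coding) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  n <- nchar(coding)
  stopifnot(n %% 3 == 0)
  S <- 0; N <- 0
  for (start in seq(1, n, 3)) {
    cod <- substr(coding, start, start + 2)
    s <- strsplit(cod, "")[[1]]
    if (any(!s %in% bases)) next
    if (gc[[cod]] == "*") next
    for (p in 1:3) {
      for (b in setdiff(bases, s[p])) {
        alt <- s; alt[p] <- b
        altc <- paste(alt, collapse = "")
        if (gc[[altc]] != "*" && gc[[altc]] == gc[[cod]]) S <- S + 1 / 3
        else N <- N + 1 / 3
      }
    }
  }
  list(S = S, N = N)
}

# Exhaustive minimal-switch oracle: minimum number of parent switches over
# all Or/On source assignments consistent with the informative labels.
oracle_min_switches <- function(labels) {
  info <- which(labels != "neither")
  if (length(info) < 2) return(NA_integer_)
  n <- length(labels)
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    src <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, "Or", "On")
    if (all(src[info] == labels[info])) {
      best <- min(best, sum(src[-1] != src[-n]))
    }
  }
  as.integer(best)
}

# One moderately sized synthetic dataset shared across test files
# (generated once per session).
.fixture_env <- new.env(parent = emptyenv())
shared_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- generate_dataset(sim_config(seed = 424242, n_loci = 40))
    .fixture_env$events <- classify_dataset(.fixture_env$ds)
  }
  list(ds = .fixture_env$ds, events = .fixture_env$events)
}

# Compact generator settings for replicate-heavy experiments: only the 5'
# region feeds the quantity under test, so gene models are minimal.
duration_sim_config <- function(seed, r, n_loci = 30, total_rate = 20) {
  sim_config(seed = seed, n_loci = n_loci, five_prime_len = 1000,
             n_exons_range = c(1, 1), exon_len_range = c(150, 150),
             intron_len_range = c(100, 100),
             parental_divergence = 0,
             rate_early = total_rate * r,
             rate_indica = total_rate * (1 - r),
             rate_japonica = total_rate * (1 - r),
             neutral_rate = 0, selected_fraction = 0,
             new_allele_fraction = 0,
             inheritance_weights = c(ancient = 0, on = 0, or = 0, mixed = 1,
                                     type5 = 0, type6 = 0, recombinant = 0))
}

# Pooled 5' branch counts over qualifying loci for one replicate.
duration_replicate <- function(seed, r) {
  ds <- generate_dataset(duration_sim_config(seed, r))
  ev <- do.call(rbind, lapply(ds$loci, function(lc) {
    call_mutations(lc$five_prime, lc$annotation)
  }))
  pc <- count_by_phase(ev)
  pc <- pc[pc$region_kind == "five_prime" &
             pc$n_early >= 1 & pc$n_indica >= 1 & pc$n_japonica >= 1, ]
  c(m_e = sum(pc$n_early), m_i = sum(pc$n_indica), m_j = sum(pc$n_japonica))
}
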