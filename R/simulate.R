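# Synthetic hybrid-origin ortholog datasets with fully known planted
# mutation histories. The generator emulates the structure inferred for
# Asian rice: two diverged wild parents (Or, On), a crop formed as a
# per-locus mosaic of parental haplotypes (uni-parental, well-mixed,
# reciprocal-association and single-crossover inheritance modes), shared
# Phase-I mutations planted before the indica/japonica split and
# lineage-specific Phase-II mutations after it, plus neutral intron
# evolution that calibrates the background rate. Infinite sites are
# enforced by sampling columns without replacement.

#' Simulation configuration
#'
#' Defaults emulate the rice study design: 101 loci across 12 chromosomes,
#' 1 kb 5' regions, multi-exon gene models with introns long enough to
#' qualify for background-rate estimation, parental divergence of 5
#' diagnostic substitutions per kb, and a neutral rate of 0.56 mutations
#' per kb per period on every branch, inflated by `selection_multiplier` at
#' a `selected_fraction` of loci.
#'
#' @param seed Integer RNG seed; a fixed seed makes output byte-identical.
#' @param n_loci Number of loci.
#' @param five_prime_len 5' region length (bp).
#' @param n_exons_range,exon_len_range,intron_len_range Gene-model draws.
#' @param parental_divergence Or-vs-On substitutions per kb.
#' @param rate_early,rate_indica,rate_japonica Mutations per kb per region
#'   on the early, indica and japonica branches (5' regions and exons).
#' @param neutral_rate Intron mutation rate per kb per branch.
#' @param indel_fraction Probability a planted mutation is an indel.
#' @param indel_mean_len Mean of the geometric indel-length distribution.
#' @param inframe_prob Probability an exonic indel is drawn in frame.
#' @param inheritance_weights Named weights over the per-region inheritance
#'   modes `ancient`, `on`, `or`, `mixed`, `type5`, `type6`, `recombinant`.
#' @param selected_fraction Fraction of (non-ancient) locus regions with
#'   inflated mutation rates.
#' @param selection_multiplier Rate multiplier at selected regions.
#' @param new_allele_fraction Fraction of loci where one lineage receives a
#'   new-allele burst exceeding the Type-8 cutoffs.
#' @param n_indica Number of indica genomes emitted (1-3).
#' @param indica_mismatch_prob Per-site disagreement probability of the
#'   second/third indica copies (exercises the consensus logic).
#' @param recurrence_prob Per-locus probability of injecting one recurrent
#'   column (two different novel states at one site) to exercise the
#'   recurrent-suspect path.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_loci = 101L, five_prime_len = 1000L,
                       n_exons_range = c(2L, 5L),
                       exon_len_range = c(150L, 450L),
                       intron_len_range = c(100L, 1500L),
                       parental_divergence = 5,
                       rate_early = 0.56, rate_indica = 0.56,
                       rate_japonica = 0.56, neutral_rate = 0.56,
                       indel_fraction = 0.15, indel_mean_len = 3,
                       inframe_prob = 0.7,
                       inheritance_weights = c(ancient = 0.06, on = 0.12,
                                               or = 0.18, mixed = 0.40,
                                               type5 = 0.18, type6 = 0.02,
                                               recombinant = 0.04),
                       selected_fraction = 0.2, selection_multiplier = 4,
                       new_allele_fraction = 0.1,
                       n_indica = 2L, indica_mismatch_prob = 0,
                       recurrence_prob = 0) {
  w <- inheritance_weights
  need <- c("ancient", "on", "or", "mixed", "type5", "type6", "recombinant")
  if (!setequal(names(w), need) || any(w < 0) || sum(w) <= 0) {
    ggm_stop("inheritance_weights must cover the seven modes with non-negative weights",
             "ggm_config_error")
  }
  if (any(c(rate_early, rate_indica, rate_japonica, neutral_rate,
            parental_divergence) < 0)) {
    ggm_stop("rates must be non-negative", "ggm_config_error")
  }
  if (!n_indica %in% 1:3) {
    ggm_stop("n_indica must be 1, 2 or 3", "ggm_config_error")
  }
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              five_prime_len = as.integer(five_prime_len),
              n_exons_range = n_exons_range, exon_len_range = exon_len_range,
              intron_len_range = intron_len_range,
              parental_divergence = parental_divergence,
              rate_early = rate_early, rate_indica = rate_indica,
              rate_japonica = rate_japonica, neutral_rate = neutral_rate,
              indel_fraction = indel_fraction,
              indel_mean_len = indel_mean_len, inframe_prob = inframe_prob,
              inheritance_weights = w[need] / sum(w),
              selected_fraction = selected_fraction,
              selection_multiplier = selection_multiplier,
              new_allele_fraction = new_allele_fraction,
              n_indica = as.integer(n_indica),
              indica_mismatch_prob = indica_mismatch_prob,
              recurrence_prob = recurrence_prob)
  class(cfg) <- "sim_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

# sample() treats a length-1 vector as 1:x; draw from an integer range safely
sample_int_range <- function(lo, hi, n = 1L) {
  if (lo >= hi) return(rep(as.integer(lo), n))
  sample(seq.int(lo, hi), n, replace = TRUE)
}

# Per-site parental source vectors for the crop lineages over the ordered
# diagnostic columns of one region. bp_sites restricts where a crossover
# may fall (exonic sites for the gene region) so a planted recombinant is
# observable on both sides.
assign_sources <- function(mode, diag_cols, bp_sites = diag_cols,
                           region_span = NULL) {
  n <- length(diag_cols)
  res <- list(I = character(n), J = character(n), breakpoint = NA_integer_)
  if (n == 0L) return(res)
  if (mode == "on") {
    res$I[] <- res$J[] <- "On"
  } else if (mode == "or") {
    res$I[] <- res$J[] <- "Or"
  } else if (mode == "type5") {
    res$J[] <- "Or"; res$I[] <- "On"
  } else if (mode == "type6") {
    res$J[] <- "On"; res$I[] <- "Or"
  } else if (mode == "recombinant") {
    first <- sample(c("Or", "On"), 1L)
    second <- setdiff(c("Or", "On"), first)
    nb <- length(bp_sites)
    if (nb >= 4L) {
      k <- if (nb == 4L) 2L else sample(2:(nb - 2L), 1L)
      bp <- (bp_sites[k] + bp_sites[k + 1L]) %/% 2L
    } else {
      bp <- sample(seq.int(region_span[1L], region_span[2L]), 1L)
    }
    src <- ifelse(diag_cols <= bp, first, second)
    res$I <- res$J <- src
    res$breakpoint <- bp
  } else {
    # "mixed" (and the intron sites of an ancient gene region): a balanced
    # per-site mosaic; redrawn until the minority parent holds >= 20% of
    # sites so the planted label is identifiable
    for (try in 1:50) {
      src <- sample(c("Or", "On"), n, replace = TRUE)
      share <- mean(src == "Or")
      if (n < 5L || (share >= 0.2 && share <= 0.8)) break
    }
    res$I <- res$J <- src
  }
  res
}

# One locus: sequences for all roles, two region ortholog sets, the
# annotation and the planted truth. Assumes the RNG state is managed by the
# caller.
#' Generate one synthetic locus
#'
#' @param cfg A [sim_config()].
#' @param locus_index Index (drives locus id and chromosome assignment).
#' @return List with `locus_id`, `chromosome`, `five_prime` and `coding`
#'   ortholog sets, `annotation`, `truth` (planted mutations in
#'   region-local coordinates) and `meta` (modes, breakpoints, multipliers,
#'   new-allele burst).
#' @export
generate_locus <- function(cfg, locus_index = 1L) {
  fp <- cfg$five_prime_len
  n_ex <- sample_int_range(cfg$n_exons_range[1L], cfg$n_exons_range[2L])
  ex_lens <- sample_int_range(cfg$exon_len_range[1L], cfg$exon_len_range[2L],
                              n_ex)
  rem <- sum(ex_lens) %% 3L
  if (rem > 0L) ex_lens[n_ex] <- ex_lens[n_ex] - rem
  in_lens <- if (n_ex > 1L) {
    sample_int_range(cfg$intron_len_range[1L], cfg$intron_len_range[2L],
                     n_ex - 1L)
  } else integer(0)

  # global layout: [5' region][exon1 intron1 ... exonN]
  subreg <- c(rep("five_prime", fp))
  ex_spans <- matrix(integer(0), ncol = 2)
  in_spans <- matrix(integer(0), ncol = 2)
  pos <- fp
  for (k in seq_len(n_ex)) {
    ex_spans <- rbind(ex_spans, c(pos + 1L, pos + ex_lens[k]))
    subreg <- c(subreg, rep("exon", ex_lens[k]))
    pos <- pos + ex_lens[k]
    if (k < n_ex) {
      in_spans <- rbind(in_spans, c(pos + 1L, pos + in_lens[k]))
      subreg <- c(subreg, rep("intron", in_lens[k]))
      pos <- pos + in_lens[k]
    }
  }
  L <- pos
  ancestral <- sample(BASES, L, replace = TRUE)
  free <- rep(TRUE, L)

  w <- cfg$inheritance_weights
  mode5 <- sample(names(w), 1L, prob = w)
  modeC <- sample(names(w), 1L, prob = w)

  # --- parental divergence (substitutions; the diagnostic sites) ----------
  or_seq <- on_seq <- ancestral
  plant_divergence <- function(pool) {
    n <- stats::rpois(1L, cfg$parental_divergence * length(pool) / 1000)
    n <- min(n, length(pool))
    if (n == 0L) return(integer(0))
    cols <- sort(pool[sample.int(length(pool), n)])
    free[cols] <<- FALSE
    for (cl in cols) {
      mutated <- sample(c("Or", "On"), 1L)
      b <- sample(setdiff(BASES, ancestral[cl]), 1L)
      if (mutated == "Or") or_seq[cl] <<- b else on_seq[cl] <<- b
    }
    cols
  }
  diag5 <- if (mode5 != "ancient") plant_divergence(which(subreg == "five_prime")) else integer(0)
  diagEx <- if (modeC != "ancient") plant_divergence(which(subreg == "exon")) else integer(0)
  diagIn <- plant_divergence(which(subreg == "intron"))

  # --- crop proto-haplotypes: inherit a parent at each diagnostic site ----
  i_seq <- j_seq <- ancestral
  apply_sources <- function(cols, src) {
    for (k in seq_along(cols)) {
      i_seq[cols[k]] <<- if (src$I[k] == "Or") or_seq[cols[k]] else on_seq[cols[k]]
      j_seq[cols[k]] <<- if (src$J[k] == "Or") or_seq[cols[k]] else on_seq[cols[k]]
    }
  }
  src5 <- assign_sources(mode5, diag5, bp_sites = diag5,
                         region_span = c(1L, fp))
  gene_diag <- sort(c(diagEx, diagIn))
  srcG <- assign_sources(if (modeC == "ancient") "mixed" else modeC,
                         gene_diag, bp_sites = diagEx,
                         region_span = c(fp + 1L, L))
  apply_sources(diag5, src5)
  apply_sources(gene_diag, srcG)

  # --- rate multipliers (positive selection) ------------------------------
  mult5 <- if (mode5 != "ancient" && stats::runif(1L) < cfg$selected_fraction)
    cfg$selection_multiplier else 1
  multC <- if (modeC != "ancient" && stats::runif(1L) < cfg$selected_fraction)
    cfg$selection_multiplier else 1

  # --- plant crop mutations (infinite sites, 1-column indel buffer) -------
  t_col <- integer(0); t_end <- integer(0)
  t_kind <- character(0); t_branch <- character(0)
  t_sub <- character(0); t_der <- character(0)
  add_truth <- function(col, end, kind, branch, sub, der) {
    t_col[length(t_col) + 1L] <<- col
    t_end[length(t_end) + 1L] <<- end
    t_kind[length(t_kind) + 1L] <<- kind
    t_branch[length(t_branch) + 1L] <<- branch
    t_sub[length(t_sub) + 1L] <<- sub
    t_der[length(t_der) + 1L] <<- der
  }
  draw_indel_len <- function(sub) {
    len <- stats::rgeom(1L, 1 / cfg$indel_mean_len) + 1L
    if (sub == "exon") {
      if (stats::runif(1L) < cfg$inframe_prob) {
        len <- 3L * max(1L, round(len / 3))
      } else if (len %% 3L == 0L) {
        len <- len + 1L
      }
    }
    len
  }
  find_span <- function(sub, len) {
    ok <- free & subreg == sub
    cand <- which(ok)
    if (length(cand) == 0L) return(NA_integer_)
    for (try in seq_len(40L)) {
      s <- cand[sample.int(length(cand), 1L)]
      e <- s + len - 1L
      lo <- max(1L, s - 1L); hi <- min(L, e + 1L)
      if (e <= L && all(ok[s:e]) && all(free[lo:hi])) return(s)
    }
    NA_integer_
  }
  plant_one <- function(sub, branch) {
    is_indel <- stats::runif(1L) < cfg$indel_fraction
    if (is_indel) {
      len <- draw_indel_len(sub)
      s <- find_span(sub, len)
      if (!is.na(s)) {
        e <- s + len - 1L
        span <- s:e
        if (branch %in% c("phase1", "indica")) i_seq[span] <<- "-"
        if (branch %in% c("phase1", "japonica")) j_seq[span] <<- "-"
        free[max(1L, s - 1L):min(L, e + 1L)] <<- FALSE
        add_truth(s, e, "indel", branch, sub, "-")
        return(invisible(TRUE))
      }
      # fall through to a substitution when no span fits
    }
    cand <- which(free & subreg == sub)
    if (length(cand) == 0L) {
      ggm_stop("sequence saturated: lower the mutation rates or lengthen regions",
               "ggm_config_error")
    }
    cl <- cand[sample.int(length(cand), 1L)]
    b <- sample(setdiff(BASES, ancestral[cl]), 1L)
    if (branch %in% c("phase1", "indica")) i_seq[cl] <<- b
    if (branch %in% c("phase1", "japonica")) j_seq[cl] <<- b
    free[cl] <<- FALSE
    add_truth(cl, cl, "substitution", branch, sub, b)
    invisible(TRUE)
  }
  plant_n <- function(n, sub, branch) {
    for (k in seq_len(n)) plant_one(sub, branch)
  }

  fp_kb <- fp / 1000
  ex_kb <- sum(ex_lens) / 1000
  in_kb <- sum(in_lens) / 1000
  if (mode5 != "ancient") {
    plant_n(stats::rpois(1L, cfg$rate_early * fp_kb * mult5), "five_prime", "phase1")
    plant_n(stats::rpois(1L, cfg$rate_indica * fp_kb * mult5), "five_prime", "indica")
    plant_n(stats::rpois(1L, cfg$rate_japonica * fp_kb * mult5), "five_prime", "japonica")
  }
  if (modeC != "ancient") {
    plant_n(stats::rpois(1L, cfg$rate_early * ex_kb * multC), "exon", "phase1")
    plant_n(stats::rpois(1L, cfg$rate_indica * ex_kb * multC), "exon", "indica")
    plant_n(stats::rpois(1L, cfg$rate_japonica * ex_kb * multC), "exon", "japonica")
  }
  if (in_kb > 0) {
    plant_n(stats::rpois(1L, cfg$neutral_rate * in_kb), "intron", "phase1")
    plant_n(stats::rpois(1L, cfg$neutral_rate * in_kb), "intron", "indica")
    plant_n(stats::rpois(1L, cfg$neutral_rate * in_kb), "intron", "japonica")
  }

  new_allele <- NA_character_
  if (stats::runif(1L) < cfg$new_allele_fraction) {
    lin <- sample(c("indica", "japonica"), 1L)
    sub <- sample(c("five_prime", "exon"), 1L)
    mode_ok <- if (sub == "five_prime") mode5 != "ancient" else modeC != "ancient"
    if (mode_ok) {
      burst <- if (sub == "five_prime") 6L + stats::rpois(1L, 1L) else 3L + stats::rpois(1L, 1L)
      plant_n(burst, sub, lin)
      new_allele <- paste(lin, sub, sep = ":")
    }
  }

  if (stats::runif(1L) < cfg$recurrence_prob) {
    cand <- which(free & subreg == "five_prime")
    if (length(cand) > 0L) {
      cl <- cand[sample.int(length(cand), 1L)]
      two <- sample(setdiff(BASES, ancestral[cl]), 2L)
      i_seq[cl] <- two[1L]; j_seq[cl] <- two[2L]
      free[cl] <- FALSE
      add_truth(cl, cl, "substitution", "recurrent", "five_prime",
                paste(two, collapse = "/"))
    }
  }

  # divergence truth rows
  for (cl in c(diag5, diagEx, diagIn)) {
    add_truth(cl, cl, "substitution", "parental", subreg[cl], NA_character_)
  }

  # --- assemble genomes and region sets -----------------------------------
  locus_id <- sprintf("locus%03d", locus_index)
  chromosome <- paste0("chr", (locus_index - 1L) %% 12L + 1L)
  ind_seqs <- list(i_seq)
  if (cfg$n_indica >= 2L) {
    for (k in 2:cfg$n_indica) {
      s <- i_seq
      if (cfg$indica_mismatch_prob > 0) {
        flip <- stats::runif(L) < cfg$indica_mismatch_prob & s != "-"
        if (any(flip)) {
          s[flip] <- vapply(s[flip], function(b) sample(setdiff(BASES, b), 1L), "")
        }
      }
      ind_seqs[[k]] <- s
    }
  }
  genome_names <- c("rufipogon_W", "nivara_N",
                    paste0("indica_", seq_len(cfg$n_indica)), "japonica_1")
  roles <- c("Or", "On", rep("indica", cfg$n_indica), "japonica")
  names(roles) <- genome_names
  all_seqs <- c(list(or_seq, on_seq), ind_seqs, list(j_seq))
  region_strings <- function(cols) {
    s <- vapply(all_seqs, function(v) paste(v[cols], collapse = ""), "")
    names(s) <- genome_names
    s
  }
  set5 <- ortholog_set(region_strings(seq_len(fp)), roles, locus_id, "five_prime")
  setC <- ortholog_set(region_strings(seq.int(fp + 1L, L)), roles, locus_id,
                       "coding_genomic")
  ann <- region_annotation(
    locus_id = locus_id, chromosome = chromosome,
    five_prime_span = c(1L, fp),
    exon_spans = ex_spans - fp, intron_spans = in_spans - fp,
    frame_offset = 0L, reference_role = "Or")

  tr <- data.frame(col = t_col, end_col = t_end, kind = t_kind,
                   branch = t_branch, subregion = t_sub, derived = t_der,
                   stringsAsFactors = FALSE)
  in_fp <- tr$col <= fp
  tr <- data.frame(
    locus_id = rep(locus_id, nrow(tr)),
    region_kind = ifelse(in_fp, "five_prime", "coding_genomic"),
    subregion = tr$subregion,
    start = ifelse(in_fp, tr$col, tr$col - fp),
    end = ifelse(in_fp, tr$end_col, tr$end_col - fp),
    kind = tr$kind, branch = tr$branch, derived = tr$derived,
    stringsAsFactors = FALSE)
  tr <- tr[order(tr$region_kind, tr$start), , drop = FALSE]
  rownames(tr) <- NULL

  list(locus_id = locus_id, chromosome = chromosome,
       five_prime = set5, coding = setC, annotation = ann, truth = tr,
       meta = list(mode_5prime = mode5, mode_coding = modeC,
                   breakpoint_5prime = src5$breakpoint,
                   breakpoint_coding = srcG$breakpoint,
                   mult_5prime = mult5, mult_coding = multC,
                   new_allele = new_allele,
                   n_diag_5prime = length(diag5),
                   n_diag_exon = length(diagEx)))
}

#' Generate a full synthetic dataset
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory; when given, per-locus FASTA and
#'   GFF3 files, truth TSVs and a JSON manifest are written.
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return A `ggm_dataset`: list with `loci`, `truth`, `locus_truth`,
#'   `aggregate` (planted branch totals) and `manifest`.
#' @export
generate_dataset <- function(cfg = sim_config(), out_dir = NULL,
                             overwrite = FALSE) {
  set.seed(cfg$seed)
  loci <- lapply(seq_len(cfg$n_loci), function(k) generate_locus(cfg, k))
  names(loci) <- vapply(loci, `[[`, "", "locus_id")
  truth <- do.call(rbind, lapply(loci, `[[`, "truth"))
  rownames(truth) <- NULL
  locus_truth <- do.call(rbind, lapply(loci, function(lc) {
    data.frame(locus_id = lc$locus_id, chromosome = lc$chromosome,
               mode_5prime = lc$meta$mode_5prime,
               mode_coding = lc$meta$mode_coding,
               breakpoint_5prime = lc$meta$breakpoint_5prime,
               breakpoint_coding = lc$meta$breakpoint_coding,
               mult_5prime = lc$meta$mult_5prime,
               mult_coding = lc$meta$mult_coding,
               new_allele = lc$meta$new_allele,
               n_diag_5prime = lc$meta$n_diag_5prime,
               n_diag_exon = lc$meta$n_diag_exon,
               stringsAsFactors = FALSE)
  }))
  rownames(locus_truth) <- NULL
  aggregate <- list(
    m_e = sum(truth$branch == "phase1"),
    m_i = sum(truth$branch == "indica"),
    m_j = sum(truth$branch == "japonica"),
    n_parental = sum(truth$branch == "parental"))
  roles <- loci[[1L]]$five_prime$roles
  manifest <- list(seed = cfg$seed, n_loci = cfg$n_loci,
                   config_hash = rlang::hash(unclass(cfg)),
                   role_map = as.list(roles),
                   loci = names(loci))
  ds <- structure(list(loci = loci, truth = truth, locus_truth = locus_truth,
                       aggregate = aggregate, manifest = manifest,
                       config = cfg),
                  class = "ggm_dataset")
  if (!is.null(out_dir)) write_dataset(ds, out_dir, overwrite = overwrite)
  ds
}

#' @export
print.ggm_dataset <- function(x, ...) {
  cat(sprintf("<ggm_dataset> %d loci, %d planted mutations (m_e=%d, m_i=%d, m_j=%d)\n",
              length(x$loci), nrow(x$truth), x$aggregate$m_e,
              x$aggregate$m_i, x$aggregate$m_j))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the same FASTA/GFF3 dialects that [load_ortholog_set()] and
#' [load_annotation()] consume, plus truth tables (TSV) and a JSON manifest.
#'
#' @param ds A `ggm_dataset`.
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(ds, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !overwrite) {
    ggm_stop(paste0("output directory not empty: ", out_dir), "ggm_io_error")
  }
  dir.create(file.path(out_dir, "loci"), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (lc in ds$loci) {
    base <- file.path(out_dir, "loci", lc$locus_id)
    write_ortholog_set(lc$five_prime, paste0(base, "_five_prime.fasta"))
    write_ortholog_set(lc$coding, paste0(base, "_coding.fasta"))
    write_annotation_gff(lc$annotation, paste0(base, ".gff3"))
    files <- c(files, paste0(lc$locus_id, c("_five_prime.fasta",
                                            "_coding.fasta", ".gff3")))
  }
  utils::write.table(ds$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(ds$locus_truth, file.path(out_dir, "locus_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  manifest <- ds$manifest
  manifest$files <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `ggm_dataset` (without truth-aggregate recomputation beyond the
#'   stored tables).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  role_map <- unlist(manifest$role_map)
  loci <- list()
  for (lid in manifest$loci) {
    base <- file.path(dir, "loci", lid)
    set5 <- load_ortholog_set(paste0(base, "_five_prime.fasta"), role_map,
                              "five_prime", locus_id = lid)
    setC <- load_ortholog_set(paste0(base, "_coding.fasta"), role_map,
                              "coding_genomic", locus_id = lid)
    ann <- load_annotation(paste0(base, ".gff3"), lid)
    loci[[lid]] <- list(locus_id = lid, chromosome = ann$chromosome,
                        five_prime = set5, coding = setC, annotation = ann,
                        truth = NULL, meta = NULL)
  }
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  locus_truth <- utils::read.table(file.path(dir, "locus_truth.tsv"),
                                   sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE)
  structure(list(loci = loci, truth = truth, locus_truth = locus_truth,
                 aggregate = list(
                   m_e = sum(truth$branch == "phase1"),
                   m_i = sum(truth$branch == "indica"),
                   m_j = sum(truth$branch == "japonica"),
                   n_parental = sum(truth$branch == "parental")),
                 manifest = manifest, config = NULL),
            class = "ggm_dataset")
}
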