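# Population-genetic duration model: Kimura fixation probability under
# selfing, expected fixed-mutation counts, and the relative duration of the
# early domestication phase measured from branch mutation totals.

#' Kimura diffusion fixation probability
#'
#' `P = (1 - exp(-4*s*q*Ne)) / (1 - exp(-4*s*Ne))`. The `s = 0` singularity
#' is removable and handled analytically: when `|4*s*Ne| < tol` the neutral
#' limit `q` is returned. Strongly deleterious inputs are evaluated on the
#' log scale to avoid overflow.
#'
#' @param s Selection coefficient.
#' @param q Initial mutant frequency (0 < q < 1).
#' @param Ne Effective population size (> 0).
#' @param tol Switch-over to the neutral limit (default 1e-8 on `|4*s*Ne|`).
#' @return Fixation probability.
#' @export
fixation_probability <- function(s, q, Ne, tol = 1e-8) {
  if (Ne <= 0) ggm_stop("Ne must be > 0", "ggm_config_error")
  if (q <= 0 || q >= 1) ggm_stop("q must be in (0, 1)", "ggm_config_error")
  a <- 4 * s * Ne
  if (abs(a) < tol) return(q)
  if (a < -700) {
    # numerator and denominator both explode; ratio -> exp(-|a|*(1-q))
    return(exp(-abs(a) * (1 - q)))
  }
  expm1(-a * q) / expm1(-a)
}

#' Fixation probability of a new mutant in a selfing population
#'
#' With census size N, initial frequency `q = 1/(2N)` and selfing effective
#' size `Ne = N/2`, the Kimura probability reduces to approximately
#' `1 - exp(-s)` for a positively selected mutant.
#'
#' @param s Selection coefficient (> 0 for the approximation to be
#'   meaningful; `s = 0` returns 0).
#' @return `1 - exp(-s)`.
#' @export
selfing_fixation_approx <- function(s) {
  -expm1(-s)
}

#' Expected number of fixed mutations on a lineage
#'
#' `m = 2 * v * Ne * P * T`: mutational input `2*v*Ne` per generation times
#' fixation probability times generations.
#'
#' @param v Per-generation mutation rate.
#' @param Ne Effective population size.
#' @param P Fixation probability.
#' @param T_gen Generations spent in the lineage.
#' @return Expected fixed-mutation count.
#' @export
expected_fixed_mutations <- function(v, Ne, P, T_gen) {
  stopifnot(v >= 0, Ne >= 0, P >= 0, T_gen >= 0)
  2 * v * Ne * P * T_gen
}

#' Relative duration of the early phase
#'
#' `T_e / T_w = m_e / (m_e + m_lineage)`: under constant mutation and
#' selection conditions the fixation-rate terms cancel, so the fraction of
#' branch time spent in the shared early phase equals the fraction of
#' mutations that accumulated there.
#'
#' @param m_e Early (shared) mutation total.
#' @param m_lineage Lineage-specific (indica or japonica) mutation total.
#' @return Fraction in `[0, 1]`.
#' @export
relative_duration <- function(m_e, m_lineage) {
  if (m_e < 0 || m_lineage < 0) {
    ggm_stop("mutation totals must be non-negative", "ggm_config_error")
  }
  if (m_e + m_lineage == 0) {
    ggm_stop("relative duration undefined: both mutation totals are zero",
             "ggm_estimation_error")
  }
  m_e / (m_e + m_lineage)
}

#' Select loci informative for duration estimation
#'
#' Keeps loci with at least one mutation in each of the early, indica and
#' japonica branches (mutations throughout domestication), then excludes
#' outlier loci whose indica or japonica count exceeds `Q3 + iqr_mult * IQR`
#' of the included per-lineage distributions (formalizing the exclusion of
#' single loci with disproportional influence on a lineage total). A manual
#' exclusion list is applied first so a published locus set can be
#' reproduced exactly.
#'
#' @param phase_counts Data frame from [count_by_phase()] (one region).
#' @param iqr_mult IQR multiplier (default 3).
#' @param manual_exclude Locus ids to exclude unconditionally.
#' @return List with `included` and `excluded` data frames (the latter with
#'   a `reason` column).
#' @export
select_duration_loci <- function(phase_counts, iqr_mult = 3,
                                 manual_exclude = character(0)) {
  pc <- phase_counts
  excl <- list()
  manual <- pc$locus_id %in% manual_exclude
  if (any(manual)) {
    excl[[length(excl) + 1L]] <-
      cbind(pc[manual, , drop = FALSE], reason = "manual")
    pc <- pc[!manual, , drop = FALSE]
  }
  has_all <- pc$n_early >= 1L & pc$n_indica >= 1L & pc$n_japonica >= 1L
  if (any(!has_all)) {
    excl[[length(excl) + 1L]] <-
      cbind(pc[!has_all, , drop = FALSE], reason = "missing branch mutations")
    pc <- pc[has_all, , drop = FALSE]
  }
  if (nrow(pc) > 0L) {
    fence <- function(x) {
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
      q[2L] + iqr_mult * (q[2L] - q[1L])
    }
    out <- pc$n_indica > fence(pc$n_indica) | pc$n_japonica > fence(pc$n_japonica)
    if (any(out)) {
      excl[[length(excl) + 1L]] <-
        cbind(pc[out, , drop = FALSE], reason = "lineage-count outlier")
      pc <- pc[!out, , drop = FALSE]
    }
  }
  excluded <- if (length(excl) > 0L) do.call(rbind, excl) else
    cbind(phase_counts[0, , drop = FALSE], reason = character(0))
  rownames(pc) <- rownames(excluded) <- NULL
  list(included = pc, excluded = excluded)
}

#' Duration estimate from per-locus phase counts
#'
#' Pools branch mutation totals over the retained loci and reports the
#' relative early-phase duration measured through each continuing lineage
#' (`m_e/(m_e+m_i)` and `m_e/(m_e+m_j)`), as fractions and percentages.
#'
#' @param phase_counts [count_by_phase()] rows for one region basis.
#' @param region_basis `"five_prime"` or `"coding"`.
#' @param iqr_mult,manual_exclude Passed to [select_duration_loci()].
#' @return Object of class `duration_estimate`.
#' @export
duration_estimate <- function(phase_counts, region_basis = "five_prime",
                              iqr_mult = 3, manual_exclude = character(0)) {
  sel <- select_duration_loci(phase_counts, iqr_mult, manual_exclude)
  inc <- sel$included
  if (nrow(inc) == 0L) {
    return(structure(
      list(status = "insufficient loci", region_basis = region_basis,
           loci_included = character(0),
           loci_excluded_outliers = sel$excluded$locus_id,
           m_e = 0L, m_i = 0L, m_j = 0L,
           fraction_by_indica = NA_real_, fraction_by_japonica = NA_real_),
      class = "duration_estimate"))
  }
  m_e <- sum(inc$n_early); m_i <- sum(inc$n_indica); m_j <- sum(inc$n_japonica)
  structure(
    list(status = "ok", region_basis = region_basis,
         loci_included = inc$locus_id,
         loci_excluded_outliers = sel$excluded$locus_id,
         m_e = m_e, m_i = m_i, m_j = m_j,
         fraction_by_indica = relative_duration(m_e, m_i),
         fraction_by_japonica = relative_duration(m_e, m_j)),
    class = "duration_estimate")
}

#' @export
print.duration_estimate <- function(x, ...) {
  cat(sprintf("<duration_estimate> basis %s (%s): %d loci\n",
              x$region_basis, x$status, length(x$loci_included)))
  if (identical(x$status, "ok")) {
    cat(sprintf("  m_e=%d m_i=%d m_j=%d\n", x$m_e, x$m_i, x$m_j))
    cat(sprintf("  early-phase share: %.1f%% (via indica), %.1f%% (via japonica)\n",
                100 * x$fraction_by_indica, 100 * x$fraction_by_japonica))
  }
  invisible(x)
}

#' Monomorphic-site assurance from n agreeing genomes
#'
#' Under the equal-frequency binomial model, the probability that agreement
#' among `n` independent genomes at a site correctly indicates a fixed
#' (monomorphic) site is `1 - (1/2)^n`: 75% for two genomes, 93.75%
#' (printed 94%) for four.
#'
#' @param n Number of independent agreeing genomes (>= 1).
#' @return Assurance probability.
#' @export
monomorphic_assurance <- function(n) {
  if (any(n < 1)) ggm_stop("n must be >= 1", "ggm_config_error")
  1 - 0.5^n
}
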