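# gene_typing: diagnostic sites, affinity ladder, recombinant scan, locus
# types, census, and extra-genome concordance.

mk_diag <- function(li, lj, region = "five_prime") {
  data.frame(locus_id = rep("L1", length(li)),
             region_kind = rep(region, length(li)),
             subregion = rep(if (region == "five_prime") "five_prime" else "exon",
                             length(li)),
             start = seq_along(li) * 10L, label_i = li, label_j = lj,
             stringsAsFactors = FALSE)
}

test_that("the affinity ladder orders its rules as specified", {
  cfg <- typing_config()
  # no diagnostic signal and almost no crop change: ancient
  expect_equal(classify_region(mk_diag(character(0), character(0)), 0, cfg)$affinity,
               "ancient")
  expect_equal(classify_region(mk_diag(character(0), character(0)), 3, cfg)$affinity,
               "insufficient")
  expect_equal(classify_region(mk_diag("On", "On"), 0, cfg)$affinity,
               "insufficient")  # below min_sites
  both <- function(lab, n) classify_region(
    mk_diag(rep(lab, n), rep(lab, n)), 2, cfg)
  expect_equal(both("On", 10)$affinity, "on_like")
  expect_equal(both("Or", 10)$affinity, "or_like")
  # reciprocal parental associations
  expect_equal(classify_region(mk_diag(rep("On", 10), rep("Or", 10)), 2,
                               cfg)$affinity, "or_j_on_i")
  expect_equal(classify_region(mk_diag(rep("Or", 10), rep("On", 10)), 2,
                               cfg)$affinity, "or_i_on_j")
  # alternating japonica labels: mixed
  mixed <- classify_region(
    mk_diag(rep("On", 10), rep(c("Or", "On"), 5)), 2, cfg)
  expect_equal(mixed$affinity, "mixed")
  # match fractions never sum above one per lineage
  d <- mk_diag(c("Or", "On", "neither", "Or"), c("On", "On", "On", "neither"))
  cr <- classify_region(d, 0, cfg)
  expect_lte(cr$mi_or + cr$mi_on, 1)
  expect_lte(cr$mj_or + cr$mj_on, 1)
})

test_that("minimal-switch scan finds single crossovers and matches brute force", {
  # canonical single crossover
  r <- detect_recombinant(c(rep("Or", 4), rep("On", 3)), 1:7 * 100L)
  expect_equal(r$switch_count, 1L)
  expect_equal(r$breakpoint, c(400L, 500L))
  expect_true(r$clean)
  # uniform labels: no switch
  expect_equal(detect_recombinant(rep("Or", 5))$switch_count, 0L)
  # alternating labels need three switches, the exhaustive minimum
  lab <- c("Or", "On", "Or", "On")
  expect_equal(detect_recombinant(lab)$switch_count, 3L)
  expect_equal(detect_recombinant(lab)$switch_count, oracle_min_switches(lab))
  # fewer than two informative sites: insufficient signal
  expect_true(is.na(detect_recombinant(c("Or", "neither"))$switch_count))
  # neither sites are skipped and tallied as private mutations
  r2 <- detect_recombinant(c("Or", "neither", "Or", "On"), c(1, 2, 3, 4))
  expect_equal(r2$switch_count, 1L)
  expect_equal(r2$private_mutation_count, 1L)
  expect_false(r2$clean)

  # property: linear scan equals exhaustive minimisation, sites <= 12
  set.seed(314)
  for (k in 1:60) {
    n <- sample(2:12, 1)
    lab <- sample(c("Or", "On", "neither"), n, replace = TRUE,
                  prob = c(0.4, 0.4, 0.2))
    got <- detect_recombinant(lab)$switch_count
    expect_identical(got, oracle_min_switches(lab))
  }
})

test_that("locus types combine region affinities, split origins and new alleles", {
  cfg <- typing_config()
  rc <- function(a5, ac) list(
    five_prime = list(affinity = a5, n_sites = 10, mi_or = 0, mi_on = 0,
                      mj_or = 0, mj_on = 0),
    coding = list(affinity = ac, n_sites = 10, mi_or = 0, mi_on = 0,
                  mj_or = 0, mj_on = 0))
  no_new <- c(i_5prime = 0, j_5prime = 0, i_coding = 0, j_coding = 0)
  # split parental origin between regions: Type 7
  expect_equal(classify_locus(rc("or_like", "on_like"), no_new, cfg)$final_type, 7L)
  expect_equal(classify_locus(rc("mixed", "mixed"), no_new, cfg)$final_type, 4L)
  expect_equal(classify_locus(rc("ancient", "or_like"), no_new, cfg)$final_type, 3L)
  expect_equal(classify_locus(rc("or_j_on_i", "or_j_on_i"), no_new, cfg)$final_type, 5L)
  expect_true(is.na(classify_locus(rc("insufficient", "insufficient"),
                                   no_new, cfg)$final_type))
  # six japonica 5' mutations exceed the >5 cutoff: Type-8 annotation
  t8 <- classify_locus(rc("or_like", "or_like"),
                       c(i_5prime = 0, j_5prime = 6, i_coding = 0,
                         j_coding = 0), cfg)
  expect_true(t8$type8)
  expect_equal(t8$new_alleles, "japonica:five_prime")
  # five 5' mutations do not (cutoff is strict)
  expect_false(classify_locus(rc("or_like", "or_like"),
                              c(i_5prime = 5, j_5prime = 0, i_coding = 0,
                                j_coding = 0), cfg)$type8)
  # three coding mutations exceed the >2 coding cutoff
  expect_true(classify_locus(rc("or_like", "or_like"),
                             c(i_5prime = 0, j_5prime = 0, i_coding = 3,
                               j_coding = 0), cfg)$type8)
})

test_that("swapping the parents maps types 2<->3 and 5<->6 and fixes 1, 4", {
  cfg <- typing_config()
  swap_lab <- function(x) c(Or = "On", On = "Or", neither = "neither")[x]
  cases <- list(
    list(mk_diag(rep("On", 8), rep("On", 8)), 2),      # on_like
    list(mk_diag(rep("On", 8), rep("Or", 8)), 2),      # or_j_on_i
    list(mk_diag(rep(c("Or", "On"), 4), rep(c("Or", "On"), 4)), 2),  # mixed
    list(mk_diag(character(0), character(0)), 0))      # ancient
  map <- c(on_like = "or_like", or_like = "on_like",
           or_j_on_i = "or_i_on_j", or_i_on_j = "or_j_on_i",
           mixed = "mixed", ancient = "ancient")
  for (cs in cases) {
    d <- cs[[1]]
    a <- classify_region(d, cs[[2]], cfg)$affinity
    d2 <- d
    d2$label_i <- unname(swap_lab(d$label_i))
    d2$label_j <- unname(swap_lab(d$label_j))
    b <- classify_region(d2, cs[[2]], cfg)$affinity
    expect_equal(b, unname(map[a]))
  }
})

test_that("planted inheritance modes are recovered on identifiable loci", {
  sh <- shared_dataset()
  types <- gene_type_calls(sh$events)
  tt <- merge(types$table, sh$ds$locus_truth, by = "locus_id")
  expected_affinity <- c(ancient = "ancient", on = "on_like", or = "or_like",
                         mixed = "mixed", type5 = "or_j_on_i",
                         type6 = "or_i_on_j")
  # 5' region affinities at loci with >= 5 diagnostic sites
  strong <- tt[tt$n_diag_5prime >= 5 & tt$mode_5prime %in%
                 names(expected_affinity), ]
  expect_gt(nrow(strong), 10)
  expect_true(all(strong$affinity_5prime ==
                    expected_affinity[strong$mode_5prime]))
  # ancient 5' regions classify ancient
  anc <- tt[tt$mode_5prime == "ancient", ]
  if (nrow(anc) > 0) expect_true(all(anc$affinity_5prime == "ancient"))
  # planted recombinants with enough flanking sites are flagged with a
  # breakpoint interval containing the planted crossover
  rec <- tt[tt$mode_5prime == "recombinant" & tt$n_diag_5prime >= 5, ]
  if (nrow(rec) > 0) {
    det <- types$detail
    for (k in seq_len(nrow(rec))) {
      dd <- det[det$locus_id == rec$locus_id[k] & det$region == "five_prime", ]
      expect_true(all(dd$switch_count == 1L))
      expect_true(all(dd$breakpoint_lo <= rec$breakpoint_5prime[k] &
                        rec$breakpoint_5prime[k] <= dd$breakpoint_hi))
    }
  }
})

test_that("the census bins ancient, uni-specific, bi-specific and new loci", {
  empty <- type_census(NULL)
  expect_equal(empty$n_typed, 0L)
  calls <- data.frame(
    locus_id = sprintf("L%02d", 1:10),
    final_type = c(1L, 2L, 3L, 2L, 3L, 4L, 5L, 6L, 7L, 4L),
    type8 = c(rep(FALSE, 9), TRUE),
    stringsAsFactors = FALSE)
  cz <- type_census(calls)
  expect_equal(cz$n_typed, 10L)
  b <- cz$bins
  expect_equal(b$fraction[b$bin == "ancient"], 0.1)
  expect_equal(b$fraction[b$bin == "uni_specific"], 0.4)
  expect_equal(b$fraction[b$bin == "bi_specific"], 0.4)
  expect_equal(b$fraction[b$bin == "new"], 0.1)
  expect_equal(sum(b$fraction), 1)
})

test_that("an extra genome is scored for carrying the derived states", {
  # one locus, five early mutations; extra genome carries all of them
  or <- strrep("A", 60); on <- or
  crop <- paste0(strrep("A", 10), "TTTTT", strrep("A", 45))
  s_all <- make_set(or, on, crop, crop, extra = crop, locus = "LC")
  ann <- region_annotation("LC", five_prime_span = c(1, 60))
  loci <- list(list(locus_id = "LC", five_prime = s_all, coding = NULL,
                    annotation = ann))
  ev <- call_mutations(s_all, ann)
  conc <- genome_concordance(loci, ev, extra_lineage = "japonica")
  expect_equal(conc$by_category$fraction[
    conc$by_category$category == "early_phase1"], 1.0)

  # the extra genome equals the On parent: no derived states at all
  s_wild <- make_set(or, on, crop, crop, extra = on, locus = "LC")
  conc2 <- genome_concordance(
    list(list(locus_id = "LC", five_prime = s_wild, coding = NULL,
              annotation = ann)),
    call_mutations(s_wild, ann), extra_lineage = "japonica")
  expect_equal(conc2$by_category$fraction[
    conc2$by_category$category == "early_phase1"], 0.0)
  expect_equal(nrow(conc2$disagreements), 5L)

  # a Kitaake-like genome missing exactly one of 20 early mutations
  or20 <- strrep("A", 100); on20 <- or20
  crop20 <- paste0(paste(rep("TAAAA", 20), collapse = ""))
  miss1 <- paste0("A", substr(crop20, 2, 100))
  s20 <- make_set(or20, on20, crop20, crop20, extra = miss1, locus = "LK")
  ann20 <- region_annotation("LK", five_prime_span = c(1, 100))
  conc3 <- genome_concordance(
    list(list(locus_id = "LK", five_prime = s20, coding = NULL,
              annotation = ann20)),
    call_mutations(s20, ann20), extra_lineage = "japonica")
  expect_equal(conc3$by_category$n_checked, 20L)
  expect_equal(conc3$by_category$fraction, 19 / 20)
})
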