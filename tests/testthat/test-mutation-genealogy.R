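# mutation_genealogy: variant columns, indel collapse, the temporal
# decision table, and phase counting.

fp_ann <- function(len) region_annotation("L1", five_prime_span = c(1, len))

test_that("variant columns are detected, masked and missing columns set aside", {
  # no variation anywhere
  s0 <- make_set("ACGT", "ACGT", "ACGT", "ACGT")
  vc0 <- call_variant_columns(s0)
  expect_equal(nrow(vc0$variants), 0L)

  # one shared crop change
  s1 <- make_set("AAAA", "AAAA", "ATAA", "ATAA")
  vc1 <- call_variant_columns(s1)
  expect_equal(vc1$variants$column, 2L)
  expect_equal(vc1$variants$ind, "T")

  # an ambiguous indica column is excluded and reported as transient
  s2 <- make_set("AAAA", "AAAA", c("ATAA", "ACAA"), "AAAA")
  vc2 <- call_variant_columns(s2)
  expect_equal(nrow(vc2$variants), 0L)
  expect_equal(vc2$masked, 2L)
  ev2 <- call_mutations(s2, fp_ann(4))
  expect_equal(ev2$category, "transient_ambiguous")

  # N in any genome excludes the column entirely
  s3 <- make_set("ANAA", "AAAA", "ATAA", "ATAA")
  vc3 <- call_variant_columns(s3)
  expect_equal(vc3$missing, 2L)
  expect_equal(nrow(vc3$variants), 0L)
})

test_that("adjacent same-pattern gap columns collapse into one indel event", {
  # three columns gapped in japonica only: one event of span 3
  s <- make_set(strrep("A", 10), strrep("A", 10), strrep("A", 10),
                "AAA---AAAA")
  ev <- call_mutations(s, fp_ann(10))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "indel")
  expect_equal(c(ev$start, ev$end), c(4L, 6L))
  expect_equal(ev$category, "lineage_japonica")

  # discordant patterns never merge
  s2 <- make_set(strrep("A", 10), strrep("A", 10), "AAA-AAAAAA",
                 "AAAA-AAAAA")
  ev2 <- call_mutations(s2, fp_ann(10))
  expect_equal(nrow(ev2), 2L)
  expect_setequal(ev2$category, c("lineage_indica", "lineage_japonica"))

  # a 7-column run shared by both crop lineages is one early event
  gap7 <- paste0("A", strrep("-", 7), "AA")
  s3 <- make_set(strrep("A", 10), strrep("A", 10), gap7, gap7)
  ev3 <- call_mutations(s3, fp_ann(10))
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$category, "early_phase1")
  expect_equal(ev3$end - ev3$start + 1L, 7L)
})

test_that("the decision table assigns temporal categories", {
  classify1 <- function(or, on, i, j) {
    s <- make_set(paste0(or, "A"), paste0(on, "A"), paste0(i, "A"),
                  paste0(j, "A"))
    call_mutations(s, fp_ann(2))
  }
  # shared novel state absent from both parents: early
  e <- classify1("A", "A", "T", "T")
  expect_equal(e$category, "early_phase1")
  expect_equal(e$derived_state, "T")
  # private novel state: lineage mutation
  expect_equal(classify1("A", "A", "A", "G")$category, "lineage_japonica")
  expect_equal(classify1("A", "A", "G", "A")$category, "lineage_indica")
  # parental polymorphism with crop states drawn from the parents
  p <- classify1("A", "G", "G", "A")
  expect_equal(p$category, "parental_diagnostic")
  d <- diagnostic_sites(p)
  expect_equal(d$label_i, "On")
  expect_equal(d$label_j, "Or")
  # novel shared state despite parental polymorphism: still early
  expect_equal(classify1("A", "G", "T", "T")$category, "early_phase1")
  # two different novel states: both lineage events, flagged recurrent
  r <- classify1("A", "A", "T", "G")
  expect_equal(nrow(r), 2L)
  expect_true(all(r$category == "recurrent_suspect"))
  expect_setequal(r$derived_state, c("T", "G"))
})

test_that("substitution signal under an overlapping gap uses gap-free roles", {
  # japonica gapped; indica carries a novel state at the same column:
  # the indel and the indica substitution are both reported
  s <- make_set("AAAAA", "AAAAA", "AATAA", "AA-AA")
  ev <- call_mutations(s, fp_ann(5))
  expect_setequal(ev$kind, c("indel", "substitution"))
  sub <- ev[ev$kind == "substitution", ]
  expect_equal(sub$category, "lineage_indica")
  # a gap in a wild parent makes absence unverifiable: transient
  s2 <- make_set("AA-AA", "AAAAA", "AATAA", "AATAA")
  ev2 <- call_mutations(s2, fp_ann(5))
  sub2 <- ev2[ev2$kind == "substitution", ]
  expect_equal(sub2$category, "transient_ambiguous")
})

test_that("adjacent same-pattern substitutions stay separate with shared multiplicity", {
  s <- make_set("AAAAA", "AAAAA", "ATTAA", "ATTAA")
  ev <- call_mutations(s, fp_ann(5))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$multiplicity, c(2L, 2L))
  expect_true(all(ev$category == "early_phase1"))
})

test_that("phase counts aggregate per locus and region with totals conserved", {
  expect_equal(nrow(count_by_phase(empty_events())), 0L)

  sh <- shared_dataset()
  pc <- count_by_phase(sh$events)
  # one row per locus-region with at least one event
  expect_lte(nrow(pc), 2L * length(sh$ds$loci))
  expect_true(all(pc$locus_id %in% names(sh$ds$loci)))
  # totals over the count matrix match the planted branch totals exactly
  expect_equal(sum(pc$n_early), sh$ds$aggregate$m_e)
  expect_equal(sum(pc$n_indica), sh$ds$aggregate$m_i)
  expect_equal(sum(pc$n_japonica), sh$ds$aggregate$m_j)
  expect_equal(sum(pc$n_parental), sh$ds$aggregate$n_parental)

  # a constructed locus with planted (3, 2, 0) counts
  or <- strrep("A", 40); on <- or
  i <- paste0(strrep("A", 10), "TTT", strrep("A", 10), "GG", strrep("A", 15))
  j <- paste0(strrep("A", 10), "TTT", strrep("A", 27))
  pc1 <- count_by_phase(call_mutations(make_set(or, on, i, j), fp_ann(40)))
  expect_equal(pc1$n_early, 3L)
  expect_equal(pc1$n_indica, 2L)
  expect_equal(pc1$n_japonica, 0L)
})

test_that("swapping the wild-parent labels preserves early calls and mirrors labels", {
  set.seed(99)
  ds <- generate_dataset(sim_config(seed = 77, n_loci = 6))
  for (lc in ds$loci[1:3]) {
    s <- lc$five_prime
    swapped <- s
    orr <- which(s$roles == "Or"); onr <- which(s$roles == "On")
    swapped$roles[c(orr, onr)] <- c("On", "Or")
    ev <- call_mutations(s, lc$annotation)
    ev2 <- call_mutations(swapped, lc$annotation)
    expect_equal(ev[ev$category == "early_phase1", "start"],
                 ev2[ev2$category == "early_phase1", "start"])
    d1 <- diagnostic_sites(ev); d2 <- diagnostic_sites(ev2)
    expect_equal(d1$start, d2$start)
    flip <- c(Or = "On", On = "Or", neither = "neither")
    expect_equal(unname(flip[d1$label_i]), d2$label_i)
    expect_equal(unname(flip[d1$label_j]), d2$label_j)
  }
})

test_that("every variant column contributes to exactly one event", {
  sh <- shared_dataset()
  for (lc in sh$ds$loci[1:5]) {
    for (set in list(lc$five_prime, lc$coding)) {
      vc <- call_variant_columns(set)
      ev <- call_mutations(set, lc$annotation)
      # recurrent columns are expanded to two rows; count them once
      ev_cols <- unique(unlist(Map(seq.int, ev$start, ev$end)))
      expect_setequal(ev_cols, c(vc$variants$column, vc$masked))
    }
  }
})
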