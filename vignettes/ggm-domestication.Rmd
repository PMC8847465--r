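---
title: "Stratifying domestication mutations on gene genealogies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying domestication mutations on gene genealogies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Asian rice (*Oryza sativa*) and its two wild relatives, *O. rufipogon* (Or)
and *O. nivara* (On), define a fixed four-taxon gene genealogy at every
locus: the two crop subspecies, indica (I) and japonica (J), form a clade
nested between the two wild parents. On that topology every alignment
column where the taxa disagree falls into one of a small number of
temporal classes, and `ggmrice` assigns each mutation event to the branch
on which it arose:

* **Parental diagnostic sites** — columns where Or and On differ and every
  crop state is drawn from the two parental states. These are the oldest
  polymorphisms; they set the topology and carry the parental-origin
  signal used for gene typing, but they are never counted as crop
  mutations.
* **Early (Phase-I) mutations** — a state shared by indica and japonica
  and absent from both wild parents. These arose after the crop lineage
  separated from its wild ancestry but before the indica/japonica split.
* **Lineage (Phase-II) mutations** — a state private to one crop lineage,
  absent from the other three taxa.
* **Transient/ambiguous** — columns that cannot be polarized (an ambiguous
  indica consensus, or a wild parent hidden under a gap).
* **Recurrent suspects** — two different novel crop states at one column.
  Under the infinite-sites assumption appropriate for the shallow time
  depth of domestication these should not occur; they are reported but
  excluded from phase counts by default.

Two genealogies are built per gene — one from the ~1 kb 5' regulatory
region, one from the genomic coding region — because regulatory and
protein changes are selected differently and often independently.

Indel runs are collapsed before classification: a maximal run of adjacent
gap columns with an identical taxon-presence pattern is one event,
regardless of length, because it has a single mutational origin. Adjacent
substitution columns with the same character pattern remain separate
events (each is an independent nucleotide change) but share a multiplicity
annotation for compact reporting.

## Positive selection

Two detectors operate per locus, region and phase.

**5' regions.** Introns longer than 800 bp within the sampled genes serve
as a neutral yardstick; their pooled mutation count per kilobase per
period is the background rate *u*. A 5' region is called positively
selected when its own rate strictly exceeds 3*u*. At the rice-like rate
*u* = 0.56/kb this reduces, over a full 1 kb region, to a cutoff of two
mutations. Both substitutions and indels count. Because the threshold sits
at count 2, a Poisson(0.56) neutral locus still exceeds it with
probability `1 - ppois(1, 0.56)` ≈ 0.109 — the detector is a screening
rule, deliberately simple, not a calibrated hypothesis test; the test
suite asserts agreement with this exact tail rather than an arbitrary
smaller bound. Phase II uses the higher of the two lineage rate estimates,
which is conservative in the same direction.

**Coding regions.** Each phase's substitutions are polarized against the
branch-ancestral codon (the wild state for Phase-I events, the
post-Phase-I crop state for Phase-II events) and classified synonymous,
nonsynonymous or stop-gain with the standard genetic code. Site counts
follow Nei–Gojobori (1986) fractional counting over the branch-ancestral
sequence; no multiple-hit correction is applied because divergence over
domestication time scales is orders of magnitude below saturation. When
synonymous changes exist and no indels intervene, positive selection
requires dN/dS > 1. When dS = 0 or indels are present, a fallback counts
amino-acid changes (substitution- and indel-derived) per kb against a
cutoff of 2 — equivalent to treating every site as nonsynonymous, hence
stricter than dN/dS. Stop gains and frameshifts rewrite the protein
downstream of the event and satisfy the fallback automatically.

## Gene types

Parental-diagnostic sites give each crop lineage a per-site label (Or, On,
or neither for a novel state). Region affinity follows a decision ladder:
no diagnostic sites and ≤ `ancient_max` crop mutations is *ancient*; fewer
than `min_sites` sites is *insufficient*; both lineages matching one
parent at ≥ θ of sites is *On-like* or *Or-like*; japonica→Or with
indica→On (or the reverse) are the two reciprocal association types;
anything else is *mixed*. Locus types 1–6 follow from agreeing region
affinities, discordant clean parental origins between the 5' and coding
regions give type 7, and a lineage-region accumulating more than 5 (5')
or 2 (coding) new mutations is annotated type 8 (a new allele) on top of
its base type. θ = 0.9 and `min_sites` = 3 operationalize "identical or
similar"; both are exposed in `typing_config()` because the underlying
notion is qualitative. When region affinities disagree and one of them is
*ancient* the other region decides (an unchanged region carries no origin
signal); a clean origin paired with a *mixed* region is mixed at locus
level.

Recombinant alleles are detected by a minimal-switch scan: writing a
lineage's allele as a mosaic of Or and On blocks over the ordered
diagnostic sites, the minimum number of parent switches equals the number
of label changes in a linear scan (novel-state sites are skipped and
tallied as private mutations). One switch is the signature of a single
crossover; a clean recombinant additionally requires zero private
mutations. The linear scan is provably minimal — the test suite checks it
against exhaustive minimization over all source assignments up to 12
sites.

## Duration of the early phase

Under Kimura's diffusion approximation a mutant with selection coefficient
*s*, initial frequency *q* and effective size Ne fixes with probability
(1 − e^(−4sqNe)) / (1 − e^(−4sNe)); the removable singularity at *s* = 0
is evaluated analytically (the neutral limit *q*) whenever |4sNe| < 1e−8,
and strongly deleterious inputs are computed on the log scale to avoid
overflow. In a selfing crop Ne = N/2 and q = 1/(2N), so the probability
collapses to ≈ 1 − e^(−s): fixation is driven by selection intensity, not
population size. The expected number of fixations on a branch is
2·v·Ne·P·T, so with mutation and selection conditions held constant the
rate terms cancel between branches and the relative duration of the early
phase is simply m_e / (m_e + m_lineage), computable once per continuing
lineage. Loci enter this estimator only if they accumulated at least one
mutation on each of the three crop branches; a locus whose lineage count
exceeds Q3 + 3·IQR of the included distribution is excluded as an outlier
(this formalizes the exclusion of single loci with disproportional
influence on one lineage's total), and a manual exclusion list allows a
published locus set to be reproduced exactly.

The monomorphic-assurance helper implements the equal-frequency binomial
agreement model, 1 − (1/2)^n for n independent agreeing genomes (75% for
two, 93.75% ≈ 94% for four). This closed form is a reconstruction from
the stated values; substitution-model-aware versions would be strictly
higher.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults describe a rice-like study: 101 loci across 12
chromosomes, 1 kb 5' regions, 2–5 exons of 150–450 bp with introns of
0.1–1.5 kb (so a realistic fraction qualify for the >800 bp background
panel), parental divergence of 5 diagnostic substitutions per kb, a
neutral rate of 0.56 mutations per kb per period on every branch, 15% of
mutations drawn as indels (geometric lengths, mean 3; exonic indels
in-frame with probability 0.7), a 20% share of loci with rates inflated
fourfold by selection, 10% of loci receiving a new-allele burst, and
per-region inheritance modes weighted 6/12/18/40/18/2/4% across
ancient/On/Or/mixed/reciprocal-association (both directions)/recombinant —
matching the relative prevalence of the types reported for rice.

Design choices that matter for interpretation:

* **Infinite sites are enforced**, so classification on generated data is
  exact by construction and the category-recovery test demands 100%, not a
  statistical bound. An optional recurrence-injection flag exercises the
  recurrent-suspect path.
* **Indels are deletions only** (gap runs in carrier lineages), keeping
  alignment coordinates equal to ancestral coordinates. Insertion columns
  are still *classified* correctly when present in real alignments; they
  are simply not generated.
* **A one-column buffer surrounds every planted indel.** Two independent
  same-pattern indels planted adjacent would be collapsed into one event
  by the (correct) merge convention, making the planted history
  unrecoverable by construction rather than by error; the buffer is an
  identifiability condition, not a modelling claim.
* **The well-mixed mode redraws until the minority parent holds ≥ 20% of
  diagnostic sites**, and a planted crossover is placed so at least two
  diagnostic sites flank each side when four or more exist — again so that
  the planted label is identifiable from the data.
* **No coalescent realism**: genealogy depth is homogeneous across loci,
  there is no migration, no demography, and the second/third indica
  genomes are copies of the first (with optional per-site disagreement
  noise to exercise the consensus logic). Passing tests on this generator
  demonstrate the correctness of the classification and estimation
  machinery, not robustness to alignment error, incomplete lineage sorting
  or population structure in real resequencing data.

Problem sizes used by the test suite are the package's own choices: the
shared synthetic fixture uses 40 loci, the category-recovery check 101,
the neutral-calibration check 180, and the duration-recovery experiment
200 replicates of 30 single-exon loci whose total 5' mutation rate of
20/kb keeps the ≥1-mutation qualification filter's truncation bias below a
tenth of a standard error.

## Numerical and convention choices

* Coordinates are 1-based inclusive throughout — internal spans, event
  tables and reports alike — matching the R/Bioconductor convention
  (IRanges, GFF3) and removing a conversion layer.
* Columns containing `N` in any genome are excluded from calling
  (conservative: a missing base can neither establish nor refute absence
  in the wild parents).
* A substitution signal observed among the gap-free taxa inside an indel
  region is emitted as a separate event; if a wild parent is gapped there
  the column is transient/ambiguous, because absence in both parents
  cannot be established.
* NG86 site counting treats stop-creating changes as nonsynonymous and
  skips stop codons in the ancestral sequence; the frameshift
  amino-acid count scans the carrier's shifted frame from the event codon
  to the first stop.
* The Phase-I ancestral state at a column where the parents disagree and
  the crop carries a novel state defaults to the Or state; this affects
  only the codon context of the rare Phase-I events that share a codon
  with a diagnostic site.
* Duration fractions are reported to three decimals and percentages to
  one decimal.

## Limitations

The package takes alignments as given and performs no realignment;
misaligned regions must be excluded upstream. The temporal order of
mutations within a branch is unresolved by design. The intron-calibrated
threshold is conservative wherever introns themselves experience
selection, and no multiple-testing correction is applied across loci —
per-locus calls are screening results. The monomorphic-assurance formula
is the simplest model consistent with the stated values. The eight-type
classification depends on configurable thresholds wherever the underlying
biological notion ("identical or similar", "nearly unchanged") is
qualitative; defaults are stated above and echoed into every run summary.
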