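# ggmrice

Gene-genealogy-based mutation (GGM) analysis of rice domestication.

Asian rice (*Oryza sativa*, subspecies indica and japonica) descends from
two wild parents, *O. rufipogon* (Or) and *O. nivara* (On). At any locus,
the four taxa form a fixed genealogy on which every variant alignment
column can be placed in time: polymorphisms between the wild parents are
the oldest (they set the topology and carry parental-origin signal), states
shared by both crop subspecies but absent from both parents arose in the
early phase of domestication (Phase I, before the indica/japonica split),
and states private to one subspecies arose afterwards (Phase II).
`ggmrice` implements this stratification and the analyses built on it, for
anyone studying how selection shaped a crop with a hybrid origin:

* **Mutation calling and temporal classification** on per-locus ortholog
  alignments (FASTA) with exon/intron/5' annotations (GFF3 or BED); indel
  runs collapse to single events, and ambiguous or recurrent columns are
  set aside rather than forced into a category.
* **Positive-selection tests**: a 5' regulatory region is called selected
  when its mutation rate strictly exceeds 3*u*, where *u* is the neutral
  background rate estimated from introns longer than 800 bp (at the
  rice-like *u* = 0.56/kb per period this reduces to two mutations per
  kb). Coding regions use per-branch Nei–Gojobori counting with
  d<sub>N</sub>/d<sub>S</sub> > 1, falling back to a cutoff of two
  amino-acid changes per kb when d<sub>S</sub> = 0 or indels are involved.
* **Eight gene types** from parental-diagnostic sites: ancient (1),
  On-like (2), Or-like (3), mixed (4), the two reciprocal
  parent–subspecies associations (5, 6), split 5'-versus-coding origin
  (7), and new alleles (8, layered on the base type). A minimal-switch
  scan flags single-crossover recombinant alleles.
* **Relative duration of Phase I**: with selfing (Ne = N/2) the Kimura
  fixation probability reduces to ≈ 1 − e<sup>−s</sup>, rate terms cancel
  between branches, and the early-phase share of domestication time is
  m<sub>e</sub>/(m<sub>e</sub> + m<sub>lineage</sub>) from branch mutation
  totals.
* **A synthetic-data generator** that emulates the hybrid-origin structure
  (parental divergence, inheritance mosaics, planted Phase-I/II mutations,
  indels, selection multipliers, new-allele bursts) with fully known
  truth, so every stage is testable end to end without external data.

## Worked example

Simulate a rice-like dataset (101 loci, defaults documented in
`?sim_config`) and run the full pipeline:

```r
library(ggmrice)

ds <- generate_dataset(sim_config(seed = 7))
ds
#> <ggm_dataset> 101 loci, 2796 planted mutations (m_e=259, m_i=333, m_j=272)

res <- run_pipeline(ds, out_dir = "reports")

res$duration$five_prime
#> <duration_estimate> basis five_prime (ok): 15 loci
#>   m_e=24 m_i=23 m_j=24
#>   early-phase share: 51.1% (via indica), 50.0% (via japonica)

res$selection_summary$counts
#>             phase n_5prime n_coding n_both n_union
#> 1          phase1        3       10      0      13
#> 2   phase2_indica        9       17      2      24
#> 3 phase2_japonica        6       18      1      23

res$census$bins
#>            bin count   fraction
#> 1      ancient     3 0.03030303
#> 2 uni_specific    16 0.16161616
#> 3  bi_specific    54 0.54545455
#> 4          new    26 0.26262626

res$selection$rates$phase1
#> <background_rate> phase1: u = 0.6987 /kb/period (100 mutations over 143.13 kb, 122 introns)
```

Reading the output: the generator planted equal Phase-I and Phase-II
mutation rates, and the duration estimator recovers an early-phase share
of ~50% through both lineages from the loci that accumulated mutations on
every branch. The background rate pools 122 qualifying introns
(estimate 0.70/kb against a configured 0.56/kb, within Poisson sampling
error of the 143 kb panel); 5' regions exceeding three times that rate and
coding regions passing the codon tests are counted per phase in the
selection summary. The census bins the per-locus types into
ancient / uni-specific / bi-specific / new.

`run_pipeline()` writes `events.tsv`, `phase_counts.tsv`,
`background_rates.tsv`, `selection_calls.tsv`, `selection_summary.tsv`,
`gene_types.tsv`, `type_census.json`, `duration.json`, `manhattan.tsv`
(per-chromosome mutation positions, the tabular equivalent of a Manhattan
plot) and `run_summary.json` (configuration echo, hash, seed and
per-stage counts). Reruns on the same inputs are byte-identical.

Real alignments enter through `load_ortholog_set()` (aligned multi-FASTA
plus a name→role map) and `load_annotation()` (GFF3 or BED); a YAML run
configuration (`read_run_config()`) carries the role map and thresholds.

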