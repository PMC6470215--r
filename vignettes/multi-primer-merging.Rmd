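---
title: "Merging multi-primer 16S amplicon profiles: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging multi-primer 16S amplicon profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerfusion)
```

## The problem

No single pair of 16S rRNA primers amplifies all of a complex microbial
community. The gene's nine hypervariable regions (V1–V9) sit between
conserved stretches, and every region-specific primer set carries its own
amplification bias: two primer sets applied to the same DNA extract reveal
substantially different taxon inventories, especially among provisionally
named (candidate) and unassigned taxa. `primerfusion` implements the
downstream arithmetic of a multi-primer design: each primer set is sequenced
separately, each dataset is collapsed to taxon tables at a chosen rank
(phylum, class, ... genus) by closed-reference OTU picking against a
Greengenes-style database, and the per-primer tables are then merged into
one combined profile whose coverage gain over any single primer set can be
quantified.

The pipeline starts from taxon tables; read-level processing
(demultiplexing, quality trimming, chimera removal, OTU picking) is out of
scope and is assumed done by standard tools.

## The merging rule

For one sample at one rank, let $r_{t,p}$ be the read count of taxon $t$ in
the table of primer set $p$, with $r_{t,p}$ undefined when $p$ did not
detect $t$. The combined profile is the union of detected taxa, and each
taxon's **representative throughput** is

$$R_t = \max_{p \,:\, t \in p} r_{t,p}.$$

A taxon unique to one primer set keeps its single count (unique reads are
added directly); a taxon shared by several sets takes the maximum count
among them. Both rules are one per-taxon maximum, so the combined
sequencing throughput is $\sum_t R_t$. Ties in the maximum are kept as the
full set of contributing primer sets in the provenance field rather than
resolved arbitrarily — the representative value is unaffected, and the tie
set is what summaries report.

The merging key is the rank-collapsed taxonomy label, not sequence
identity: amplicons from different regions cannot share sequence-level
OTUs, so cross-primer comparison is only meaningful at taxonomy ranks.
Detection means a positive read count by default; `min_reads` in
`merge_profiles()` imposes a stricter floor when desired, but the default
applies no abundance filter because the statistics are meant to capture
rare taxa.

## Affiliation status

Each taxon label is classified at the working rank into exactly one of:

* **affiliated** — a validly named taxon;
* **candidate** — a provisional division (TM7, OD1, WS3, SAR406, ...);
* **unassigned** — the bucket of reads with no database match, or a lineage
  with no name at the rank.

"Unaffiliated" means candidate or unassigned. Candidate recognition has no
grammar in Greengenes, so `candidate_rules()` combines an explicit,
overridable name list (seeded with the common candidate divisions; see
`greengenes_candidate_divisions()`) with a pattern fallback that flags
names made entirely of uppercase letters and digits (at least two
characters). The list is auditable and deliberately not claimed complete;
disable the pattern or extend the list per study.

Two conventions matter for counting:

* the Unassigned bucket is **one taxon** at any rank — all unassigned
  lineages collapse into it, once per primer set and once in any union or
  intersection;
* read counts are the canonical unit. Fractional tables are accepted by
  `read_taxa_table()` and usable for classification and comparison, but
  throughput operations refuse them, because the combined-throughput
  arithmetic is defined on reads.

## Coverage statistics

`tally_by_status()`, `unique_taxa()`, `shared_fraction()`,
`venn_partition()`, `unaffiliated_fraction()`, `missed_fraction()`,
`increase_vs_best_single()`, `abundance_by_status()` and
`cross_group_shared()` compute the per-primer and combined counts, the
taxa unique to one primer set, intersection-over-union overlap, the
unaffiliated share $100\,U/(U+A)$, the single-primer shortfall
$100\,(C-S)/S$, and per-status relative-abundance totals and means. All
overlap accounting is on taxon label sets, independent of abundance.
Percentages are rounded to one decimal, **half away from zero**; all
internal arithmetic is exact before that final rounding (half-to-even
would, for instance, turn 44/124 into 35.4% instead of 35.5%).

```{r coverage-example}
profiles <- list(
  V4 = taxon_profile("s1", "V4", "phylum", counts = c(
    "k__Bacteria;p__Proteobacteria" = 5200,
    "k__Bacteria;p__Chloroflexi"    = 800,
    "k__Bacteria;p__TM7"            = 40,
    "Unassigned"                    = 700)),
  V5V8 = taxon_profile("s1", "V5V8", "phylum", counts = c(
    "k__Bacteria;p__Proteobacteria" = 9100,
    "k__Bacteria;p__Acidobacteria"  = 300,
    "k__Bacteria;p__OD1"            = 25,
    "Unassigned"                    = 1100))
)
tally_by_status(profiles)
combined_throughput(merge_profiles(profiles))
```

## In-silico primer coverage

`match_primer()` slides a degenerate oligo along a reference and accepts a
window when total mismatches stay within `max_mismatch` **and** the
3'-terminal `anchor_3prime` bases match exactly — the elongation-stringency
convention of TestPrime-style evaluations, since polymerase extension
requires a matched 3' end. The default policy is 0 mismatches with a 3-base
anchor; both are configurable, and the defaults are deliberately
conservative because published coverage evaluations rarely state their
mismatch setting. IUPAC codes in the primer match their base sets; an `N`
in the reference matches nothing (strict mode, counted as a mismatch).
`find_amplicons()` matches the reverse primer as its reverse complement
(3' anchor at the left of the window) and pairs sites left to right,
each forward site taking the nearest unconsumed reverse site whose inner
product length lies within the configured bounds. Coordinates are 0-based
half-open throughout; the primer-exclusive (inner) interval is canonical
and the primer-inclusive one is also reported. `rank_coverage()` aggregates
amplification over a reference panel by taxon.

Primer oligos ship as user-supplied YAML (`read_primer_config()`); no
default sequences are hard-coded, because region-specific primer choices
are study decisions.

## Mock-community validation

`pearson_concordance()` correlates expected and observed fractions over the
union of labels (absent taxa count as zero) and errors when either vector
has zero variance, where $r$ is undefined — note this makes a perfectly
even expected composition unusable for correlation, which is why the even
eight-genus `zymo_mock_composition()` is a composition stand-in, not a
concordance fixture. `recovery_report()` ranks primer sets by descending
$r$, with total-variation distance $\tfrac12\sum_i |p_i - q_i|$ as a
bounded tiebreaker (an extension; correlation alone is scale-free but
insensitive to calibrated over/under-representation). The comparison rank
defaults to genus, the level at which defined mock communities are usually
scored; any rank is accepted.

## Profile comparison

`preprocess_matrix()` applies row-wise centring or unit-variance scaling
(rows are taxa). Constant rows cannot be unit-scaled and are dropped with a
warning rather than propagating division by zero. `svd_impute()` fills
missing cells by iterating rank-$k$ truncated-SVD reconstruction from a
row-mean initialisation until the imputed cells change by less than `tol`
(max-norm); defaults $k = 2$ (the plotted components), `tol = 1e-6`,
`max_iter = 100`. Observed cells are never altered. `pca_profiles()` treats
columns (profiles) as observations, and `hcluster_profiles()` clusters rows
or columns with correlation distance $d = 1 - r \in [0, 2]$ under average
linkage (UPGMA), with Newick export via `dendrogram_newick()`. For
heatmap-style displays, rows are centred and unit-scaled before clustering.

## The synthetic generator

Real multi-primer datasets require a sequencing run; the generator in
`generator_spec()` / `simulate_pool()` / `simulate_profiles()` produces
datasets with the structure the statistics operate on, with planted ground
truth. Defaults describe one sponge-like dataset:

* 27 affiliated and 29 candidate phylum-level taxa, plus an Unassigned
  bucket holding 10.8% of each primer set's reads — the inventory scale a
  host-associated community shows at phylum rank;
* per-primer detection probabilities of 0.75–0.90 for affiliated taxa and
  0.20–0.65 for candidate taxa, encoding that conserved, well-represented
  taxa are seen by most regions while candidate taxa are strongly
  region-dependent;
* per-primer read budgets of 57k–299k, the range of one MiSeq amplicon
  dataset per primer set;
* log-normal abundance weights (`meanlog = 0`, `sdlog = 2`), giving the
  few-dominant/many-rare structure of real communities.

What the generator does **not** emulate: sequencing error, chimeras,
compositional correlation between taxa, or taxonomy misassignment between
related ranks. Passing tests therefore demonstrate the correctness of the
accounting and merging arithmetic on realistic table shapes — not
robustness to upstream processing artefacts.

`fixture_from_marginals()` builds label sets that satisfy published
overlap marginals (per-set sizes, all-set intersection, union) exactly and
deterministically: the common core is allocated first, remaining labels get
membership multiplicities capped at $k - 1$ (so the intersection stays
exact), and are placed greedily into the sets with most remaining capacity.
Infeasible marginals raise an error naming the violated inequality. Only
the given constraints are honoured; pairwise overlaps beyond them are a
by-product of the deterministic construction, not data.

## Numerical and design notes

* Percentage rounding: one decimal, half away from zero (see above);
  per-taxon abundance means are reported unrounded and displayed at two
  decimals.
* Relative-abundance vectors must sum to 1 within 1e-6 on input; profiles
  derived from counts renormalise exactly.
* `svd_impute()` convergence is measured on the imputed cells only; for a
  rank-$k$ matrix with isolated masked cells the fixed point is the exact
  completion, which the tests verify for rank-1 constructions.
* Degenerate-primer matching is validated against an independent
  expand-and-scan oracle (every concrete expansion, exact string scan) for
  degeneracies up to 256, and against Biostrings exact matching for
  non-degenerate probes.
* Problem sizes in the test suite (≤ 5 primer sets × ≤ 50 taxa for merge
  oracles, ≤ 400 nt references for matching oracles, 50–60 Monte-Carlo
  replicates for noise monotonicity) were chosen so every oracle is
  enumerable and exact while the full suite stays fast on one CPU.

## Limitations

* Greengenes 7-rank lineages only; SILVA/RDP dialects are not parsed.
* Merging at a taxonomy rank cannot resolve two different organisms mapped
  to the same label, and conversely splits one organism inconsistently
  named across regions — a database property the arithmetic cannot repair.
* The representative-throughput rule is a coverage-oriented upper bound on
  what a single library would have produced; it is not a normalisation
  method, and no rarefaction or compositional correction is applied.
* In-silico coverage reflects primer-template matching only; it ignores
  thermodynamics, multi-template competition and amplification efficiency.
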