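---
title: "Methods: quantifying genome scrambling from pairwise alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying genome scrambling from pairwise alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(scramblr)
```

scramblr quantifies how thoroughly two related genomes have been
rearranged ("scrambled") relative to one another, starting from a
one-to-one pairwise whole-genome alignment. This vignette documents the
statistical definitions, the modelling assumptions behind them, and the
rationale for the default parameters. The worked examples are tiny and
run in well under a second.

## Input model

All computation starts from an `alignment_set`: a tibble of aligned
blocks with target coordinates (`t_chrom`, `t_start`, `t_end`), query
coordinates (`q_chrom`, `q_start`, `q_end`) and a relative `strand`,
plus a `genome_layout` for each genome giving chromosome lengths and,
optionally, chromosome arms with classes (`short`, `long`, `PAR`,
`XSR`, `YSR`). Coordinates are 0-based and half-open internally; GFF3
input is converted at the boundary.

The alignment is required to be **one-to-one**: no two blocks may
overlap on either genome. This matches the situation after filtering a
raw aligner's output down to reciprocal best, split-free blocks, and it
is what makes every downstream statistic well defined (each base has at
most one homologous partner). Violations are validation errors that
name the offending blocks rather than silently dropped.

## Strict collinearity and the four-class partition

Two blocks are **linked** when all of the following hold:

1. they are adjacent in target order on the same target chromosome;
2. they lie on the same query chromosome with the same strand;
3. they are adjacent in query order, and the query order matches the
   strand (ascending for `+`, descending for `-`).

This is the strictest reasonable definition: *any* intervening aligned
block on either genome, a strand flip, or a chromosome change breaks
the chain, no matter how small the interruption. Maximal sets of linked
blocks with at least two members are **collinear chains**. The
definition is deliberately gap-agnostic: an unaligned gap of any size
between two linked blocks does not break a chain, because unaligned
sequence carries no evidence of rearrangement, only of unalignability.

Given the chains, the target genome is partitioned into exactly four
segment classes:

* **collinear_alignment** — aligned bases inside a chain member;
* **isolated_alignment** — aligned bases of a block in no chain;
* **bridge** — unaligned gaps *between consecutive members of the same
  chain*;
* **breakpoint** — every other unaligned region, including the regions
  between non-linked neighbouring blocks and the chromosome ends.

Two non-linked blocks that abut produce a **zero-width breakpoint**:
the rearrangement junction is real even though no unaligned sequence
marks it. Zero-width breakpoints are counted by default (they are
junctions, and junction counts are what the accumulation rate needs)
but carry no bases in coverage summaries. Chromosome ends are always
breakpoints, never bridges: there is no second chain member to bridge
to. The partition tiles each chromosome exactly — this is asserted
property-style in the test suite across thousands of random alignment
sets.

```{r}
aln <- alignment_set(
  tibble::tibble(
    t_chrom = "t1", t_start = c(0, 20, 25), t_end = c(10, 25, 30),
    q_chrom = "q1", q_start = c(0, 15, 50), q_end = c(10, 20, 55),
    strand = c("+", "+", "-")
  ),
  layout_from_lengths(c(t1 = 40)), layout_from_lengths(c(q1 = 60))
)
tidy(classify_segments(aln))
```

## The scrambling index

For a unit of the genome (a chromosome, an arm, or the whole genome),
let $L_{same}$ and $L_{opposite}$ be the total aligned target bases on
the same and opposite relative strand. The **strand-randomisation
(scrambling) index** is

$$ I = \frac{|L_{same} - L_{opposite}|}{L_{same} + L_{opposite}}. $$

A perfectly conserved (or merely inverted-in-one-piece) unit scores 1;
a unit whose local orientations have been fully randomised by many
inversions drifts to 0, because random orientation equalises the two
totals in expectation. The genome-level summary is the mean of unit
indices weighted by the **full** unit length (aligned plus unaligned),
so that a large, poorly aligned chromosome is not up-weighted relative
to its actual share of the genome. Units with no aligned bases are
excluded (`NA`), not counted as zero — an empty unit carries no
orientation evidence. When arms are annotated, blocks straddling an arm
boundary contribute length to each arm proportionally to the overlap.

## Breakpoint accumulation rate

`breakpoint_rate()` divides the breakpoint-region count by the aligned
megabases (collinear plus isolated bases — the sequence in which a
breakpoint could have been observed) and by the divergence time in
million years:

$$ r = \frac{\#\,breakpoints}{\mathrm{aligned\ Mbp} \times
\mathrm{divergence\ My}}. $$

The count is width-independent (zero-width junctions count), so the
rate measures rearrangement events, not unalignable sequence. A zero
divergence time or an alignment with no aligned bases is a domain
error, not an `Inf`.

## Operons and cross-genome conservation

`call_operons()` groups same-strand consecutive genes with intergenic
distance at most `max_gap` (default 500 bases; a 501-base gap breaks
the run, overlapping genes count as gap 0) into operons of at least two
genes. Two operons from different genomes are **exactly** equivalent
when their orthogroup multisets are equal, and **inexactly** equivalent
when they have equal size at least 3 and differ by at most one
substitution: an operon ABC accepts ABC, XBC, AXC and ABX. Size-2
operons admit no substitution (one of two genes replaced is half the
operon), but identical size-2 operons still match. Genes without an
orthogroup receive unique sentinels so that two unassigned genes never
spuriously match each other.

### The operonic-status association test and its degrees of freedom

`operonic_status_test()` cross-tabulates single-copy ortholog pairs by
operonic status in each genome (both / only A / only B / neither) and
compares observed counts to expectations formed from the observed
marginal operonic fractions. The quoted statistic is reported with
**df = 3** (four cells, one total constraint), following the
convention of treating the table as a 4-category goodness-of-fit test.
Algebraically, however, this statistic is identical to the Pearson 2×2
independence statistic, and because the two marginal proportions are
estimated from the data its null distribution is chi-squared with
**df = 1**. The df = 3 p-value is therefore conservative. The result
object reports both: `statistic_gof`/`df_gof`/`p_gof` (quoted, df = 3)
and the identical statistic with `df_indep = 1` and `p_indep`, which is
the calibrated p-value (it equals `chisq.test(m, correct = FALSE)` on
the 2×2 table) and is what the package's own calibration tests assert
~5% type-I error against. Use `p_indep` for inference; `p_gof` exists
to reproduce the quoted convention.

## Profiles

`boundary_enrichment()` slides a window (default 1000 bases, step 10)
across offsets around segment-class boundaries and reports the fraction
of boundaries whose window position is covered by a feature track
(repeats, genes, ...). Offsets that fall off the chromosome for a given
boundary are excluded from that offset's denominator rather than
counted as uncovered. `binned_profile()` bins element positions into
percent-of-chromosome-length bins (`bin = min(floor(B\,pos/len),
B-1)`), averaging within genomes first and then across genomes, so a
gene-dense genome does not dominate a pooled mean.
`arm_class_compare()` runs pairwise two-sided Wilcoxon rank-sum tests
of a per-gene quantity (e.g. dN/dS) between arm classes, and
`gene_breakpoint_rate_by_arm()` tests equality of gene-breakpoint
overlap rates across arm classes with a chi-squared test on the
class-by-overlap table.

## The simulator

The simulator is coordinate-only: it evolves an annotated ancestral
genome (genes, exons, operons, repeats, per-gene dN/dS, arm layout) by
a logged sequence of inversions, translocations, deletions and
duplications, and emits the *true* one-to-one alignment between two
descendants as the intersection of their ancestral coordinates. No
nucleotide sequence is simulated, because every statistic in the
package is coordinate-based.

Key modelling choices:

* **Events never split genes.** Cut points are snapped to intergenic
  space. This keeps ortholog bookkeeping exact, at the cost of not
  modelling gene-disrupting breakage.
* **Event counts, not rates, by default** (`n_events`), so tests can
  reason about exact outcomes; a rate mode draws
  Poisson(`event_rate` × branch length) events per branch for
  accumulation-rate experiments.
* **Scoped events.** By default 94% of translocations stay within
  their chromosome, and 99% of intra-chromosomal events stay within
  one arm (the arm fraction is conditional on being
  intra-chromosomal — as absolute fractions the two scopes would be
  contradictory). Inversions are always intra-chromosomal. The default
  mix is 70% inversions, 25% translocations, 2.5% deletions, 2.5%
  duplications.
* **Unalignable breakpoint sequence** is modelled, optionally, as
  flank loss: up to 500 bases deleted on each side of an event
  junction (default 0). This reproduces width-positive breakpoint
  regions without simulating substitution divergence.
* **Duplications create paralogs** that share the original gene's OG
  but receive a distinct HOG, mirroring how orthology inference groups
  recent paralogs; only the original copy participates in the emitted
  one-to-one alignment.

Determinism is strict: all outputs are reproducible from
(configuration, seed), per-branch seeds are derived deterministically
from the base seed, and replaying a recorded event log reproduces the
descendant exactly.

```{r}
pair <- simulate_genome_pair(sim_config(seed = 1L, n_genes = 60L,
                                        n_events = 10L))
report <- compare_genomes(
  pair$alignment,
  sim_annotation(pair$genomes$A), sim_annotation(pair$genomes$B),
  orthologs = sim_ortholog_map(pair$genomes),
  divergence_time = 5
)
report
```

## Limitations

* The collinearity definition is intentionally strict; it will report
  more, smaller chains than gap-tolerant chainers. That is the point —
  every interruption is evidence of rearrangement — but it means chain
  statistics are not comparable across tools.
* The breakpoint rate assumes breakpoints accumulate linearly with
  time and are observable only in aligned sequence; saturation at high
  divergence biases the rate downward.
* The simulator's event-length distribution is a configurable
  placeholder (uniform fraction of the region); no empirical
  distribution is imposed.
* Repeat-mediated rearrangement mechanisms, nucleotide-level
  divergence and chromatin contact data are out of scope.
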