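---
title: "Classifying splicing orthology from exon-intron structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying splicing orthology from exon-intron structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceortho)
```

## The problem

Orthology is conventionally assigned between genes, but a gene expresses
multiple splicing isoforms, and isoforms of orthologous genes need not
correspond to one another. Two transcripts — one per species — that use
the same exon-intron organization of their shared coding region are
*iso-orthologs*: they represent the same ancestral splicing variant and
are the pairs most likely to encode functionally equivalent products.
`spliceortho` decides, for each transcript of each orthologous gene
pair, whether the partner gene annotates an iso-ortholog, and at what
level of stringency.

The comparison deliberately ignores sequence: it works on the **coding
structure** of a transcript, i.e. the ordered lengths (in bp) of the
coding portions of its exons plus the **phase** of every intron that
interrupts the CDS — the cumulative coding length upstream of the
intron modulo 3. Untranslated exons and the untranslated parts of
external exons are excluded, because UTR annotation is far more
variable in length and number than CDS annotation.

## The pipeline

1. **Projection** (`project_cds`). Each gene model (genePred/refFlat
   dialect, 0-based half-open coordinates) is projected onto its coding
   structure; exons without CDS overlap are dropped and external exons
   are trimmed to their coding portion. Lengths are reported 5'→3' in
   transcript orientation. A CDS boundary falling inside an intron is
   rejected as a malformed annotation (it would corrupt the phase
   arithmetic); a CDS whose exonic length is not a multiple of 3 is
   accepted with a warning, since curated collections contain such
   records.
2. **Filtering** (`passes_filters`). A transcript is analyzed only if
   it has at least four exons (counting untranslated ones) and at least
   two internal fully coding exons. The two conditions use different
   exon universes on purpose: the first is a property of the transcript
   annotation, the second of the coding structure. "Internal fully
   coding" is read as: internal to the coding structure *and* with the
   whole transcript exon inside the CDS. The wording could also be read
   as "internal to the transcript"; the stricter reading was chosen
   because it is the one under which the redundancy signature below is
   well defined for every analyzed transcript.
3. **Redundancy collapsing** (`dedup_transcripts`). Restricting to
   coding structure makes transcripts differing only in UTRs
   indistinguishable. Transcripts of one gene sharing internal coding
   exons of the same size and reading frame are represented by one
   transcript: the one with the greatest total coding length (the most
   informative structure), ties broken by smallest accession so the
   choice is deterministic.
4. **Alignment** (`align_structures`). Every query structure is
   globally aligned against every candidate structure of the partner
   gene with a dynamic program whose moves are one-to-one exon columns
   (DIAG), unpaired exons (GAP), and merges of up to `k_max` adjacent
   exons against a single exon (MERGE) — the signature of an intron
   gained in one lineage or lost in the other.
5. **Classification** (`best_match`, `classify_colinear`). Only the
   highest-scoring alignment is considered. If it is colinear (all
   DIAG), the pair is classified by three criteria of decreasing
   stringency; if it is not — i.e. the structures are best explained by
   intron gain/loss or exon skipping — the query has no iso-ortholog
   (`NONE`), which is exactly why gain/loss-aware alignment is run:
   a forced colinear comparison of such pairs could assign a spurious
   category.

With Δᵢ the absolute difference of the i-th coding exon lengths and
phase equality required elementwise:

| Category | Conditions |
|----------|------------|
| ISO1 | same exon count, all phases equal, every Δᵢ = 0 |
| ISO2 | same exon count, all phases equal, every Δᵢ ∈ {0,3,6,9,12,15}, some Δᵢ > 0 |
| ISO3 | same exon count, all phases equal, any other Δ |
| NONE | different exon count, any phase mismatch, or non-colinear best alignment |

ISO2 is read so that the categories nest (ISO1 pairs satisfy ISO2's
band with all Δ = 0): requiring *every* exon to differ would make the
criteria non-nested and contradict their decreasing stringency. Note
that phase equality already forces Δᵢ ≡ 0 (mod 3) for every exon except
the last — a property the test-suite asserts on thousands of random
pairs — so ISO2's band genuinely constrains only the magnitudes and the
last exon.

Queries are always curated transcripts. Computationally predicted
transcripts (tagged `PREDICTED` at load time) can be added to the
candidate set only; a score tie between a curated and a predicted
candidate resolves to the curated one, so a prediction changes a
query's assignment only when it strictly outscores every curated
candidate. Adding predictions can therefore only improve or preserve a
query's category, never weaken it.

Gene-pair level, a pair is counted under the strongest category
achieved by any of its transcript pairs; per-direction gene counts are
also reported, since the two query sets differ.

## The scoring scheme

The classification depends on the alignment only through (i) which
candidate wins and (ii) whether the winning alignment is colinear, so a
transparent parametric scheme is used rather than an empirical one. Per
column:

* DIAG: `s_max − w·min(|la − lb|, d_cap) + b_phase·[phases equal]`
* MERGE of k exons: the DIAG formula on the summed merged lengths,
  minus `m_merge·(k − 1)`; the phase bonus is evaluated at the column's
  leading intron boundary
* GAP: `−g_gap`

Columns involving either structure's first exon carry no phase bonus:
there is no preceding intron within the CDS. Defaults are `s_max = 10`
score units, `w = 0.1` per bp, `d_cap = 100` bp, `b_phase = 2`,
`g_gap = 8`, `m_merge = 5`, `k_max = 3`. They were chosen so that (a)
a colinear pairing always beats gaps and merges when exon counts agree
and structures are broadly similar (worst DIAG column scores 0, while
replacing two DIAG columns by a gap pair costs 16 plus the lost
rewards), (b) a length-exact merge (intron gain/loss) beats the
corresponding gap pair (−5 vs −16 plus a lost column), and (c) exact
matches with phase agreement dominate everything. Any scheme must keep
two contract properties the tests enforce: self-alignment is optimal
and colinear, and the score is symmetric under argument swap. All
parameters are user-settable (`scoring_scheme()`, or a `key=value`
file via `read_scoring_config`); the traceback breaks score ties in
the fixed order DIAG, MERGE (side A first, fewer exons first), GAP on
side A, GAP on side B, so results are deterministic.

`enumerate_alignments` is an exhaustive-enumeration oracle over all
global alignments of small structures (≤ 6 exons); it exists purely so
the dynamic program can be checked against an implementation that
shares none of its logic.

## The synthetic cohort generator

No public corpus ships with the package, so validation uses
`generate_cohort`: orthologous gene pairs whose species-B partner is
derived from the species-A base by a *labelled* perturbation, making
the truth known by construction. The seven families are exactly the
preimages of the classifier's outcomes: identical structure (ISO1);
1–3 exon shifts by multiples of 3 within ±15 bp (ISO2 — multiples of 3
preserve every phase automatically); phase-preserving shifts outside
that band (ISO3); an internal exon deleted (exon skipping), an exon
split in two (intron gain), an internal shift with Δ mod 3 ≠ 0 (phase
break), or a structurally unrelated partner (species-specific isoform)
— all NONE. Phase-break shifts avoid multiples of 3 by construction,
because a multiple-of-3 internal shift can never break a phase.

Default study conditions: coding exon counts uniform on 4–12 (so every
base transcript passes the analysis filters), coding exon lengths
uniform on 30–300 bp, introns 80–2000 bp, both strands equally likely,
a 0.3 probability of an untranslated exon on each side, 1–4 isoforms
per species-A gene (the extras are UTR-only variants that the
redundancy step must collapse), a uniform mixture over the seven
labels, and a 0.25 probability that a matching partner is emitted as
PREDICTED. In that case species B also receives a curated decoy (the
partner with one internal exon skipped), so the pair is unmatched in a
curated-only run and recovered when predictions are included — the
generator's model of how predicted isoforms rescue queries whose true
counterpart is missing from the curated annotation. The decoy cannot
win by accident: skipping an exon costs at least a gap or merge column
(≥ 15 score units below the colinear ideal under the defaults), while
the true partner is within 6 units of it. Species-B genomic layout
(chromosome, offsets, intron sizes, UTRs) is drawn independently of
species A, so nothing downstream can covertly rely on coordinates.

What the generator does **not** emulate: realistic sequence content,
empirical exon-length and intron-length distributions, annotation
noise (truncated or mis-mapped transcripts), many-to-many orthology,
and genuinely mixed events (e.g. a skip *and* a shift in one pair).
A perfect recovery rate on synthetic cohorts therefore demonstrates
the internal consistency of projection, alignment and classification —
not the accuracy of any particular biological annotation.

## Worked example

```{r example}
cohort <- suppressWarnings(
  generate_cohort(generator_config(n_genes = 50, seed = 42)))
result <- suppressWarnings(
  classify_cohort(cohort$index_a, cohort$index_b, cohort$pairs,
                  include_predicted = TRUE))
result$summary

## agreement with the generator's truth
m <- merge(cohort$truth, result$matches_ab, by = "query_accession")
table(truth = m$expected_type, called = m$match_type)
```

A single alignment can be inspected directly:

```{r alignment}
a <- coding_structure("qry", "g", "CURATED", c(100L, 60L, 90L),
                      phases = c(1L, 1L), n_internal_fully_coding = 1L,
                      total_exon_count = 3L)
b <- coding_structure("cnd", "g", "CURATED", c(160L, 90L),
                      phases = 1L, n_internal_fully_coding = 0L,
                      total_exon_count = 2L)
al <- align_structures(a, b)
al
cat(render_alignment(al, a, b))
```

The merge column pairs the query's first two exons (100 + 60 bp)
against the candidate's single 160 bp exon: the candidate lost the
intervening intron. The alignment is not colinear, so this pair would
be classified `NONE` regardless of the equal summed lengths.

## Numerical and design notes

* All coordinates are 0-based half-open (UCSC genePred); 1-based
  dialects are out of scope.
* Scores are plain doubles; score equality (for ties) is exact
  floating-point equality, which is safe here because all defaults are
  decimal fractions combined by sums of at most a few hundred terms
  drawn from the same grid.
* Degenerate inputs: empty structures cannot be constructed
  (projection requires CDS overlap with at least one exon); single-exon
  structures align as one DIAG column and can only classify against
  equal-count candidates; an empty candidate list yields a `NONE`
  record with no counterpart.
* Problem sizes used in validation: the label-recovery cohort has 500
  gene pairs under the uniform label mixture; the aligner is checked
  against the enumeration oracle on 200 random pairs of up to 5 exons
  with lengths from {30, 60, 90, 100, 151}; the criteria algebra is
  asserted on 10,000 random colinear pairs.
* Known limitations: 1:1 orthology only (a gene appearing in two pairs
  is an input error); no local or semi-global alignment; the scoring
  scheme is a package-defined parametric model, not a reimplementation
  of any published empirical exon-length scoring; transcripts mapping
  to multiple loci are assumed to have been resolved upstream (one
  mapping per accession).
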