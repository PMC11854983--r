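---
title: "Composition and codon usage bias in mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition and codon usage bias in mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocub)
```

## The analysis

Animal mitochondrial genomes are compact, circular molecules of roughly
15–18 kb carrying a near-invariant inventory: 13 protein-coding genes
(PCGs), 22 tRNAs, 2 rRNAs and one A+T-rich control region (`OH`), split
between the two strands (labelled J/N, major/minor, in annotation tables).
Because replication and transcription treat the strands asymmetrically,
the base composition of these genomes is strongly skewed, and because the
tRNA pool and mutation pressure are both biased, synonymous codons are
used very unevenly. mitocub implements the standard descriptive toolkit
for this situation over annotated mitogenomes:

* **Composition and strand skew.** For any sequence,
  $\mathrm{AT\,skew} = (A - T)/(A + T)$ and
  $\mathrm{GC\,skew} = (G - C)/(G + C)$, computed from raw counts of
  unambiguous bases; IUPAC ambiguity codes are excluded from every
  denominator, and an undefined skew (zero denominator) is reported as
  missing rather than 0. Per-gene rows use the gene's *sense* strand, so
  genes on opposite strands show mirrored skews — the classic pattern in
  which NADH-dehydrogenase genes on one strand have positive GC skew
  while the cytochrome genes on the other are negative.

* **Codon counting and RSCU.** Relative synonymous codon usage of codon
  $i$ in a family of degeneracy $d$ is
  $\mathrm{RSCU}_i = d\,x_i / \sum_{j} x_j$: the observed count divided by
  the family mean, 1 under no bias, summing to $d$ within each observed
  family. Stop codons never enter counts (usage is defined over sense
  codons); start codons are counted unless `include_start = FALSE`; a
  family never observed is reported as missing, not as 0. Degeneracy-1
  families (Met, Trp under the standard code — none under the
  invertebrate mitochondrial code) have no synonymous alternative and
  are excluded from RSCU and from GC3s.

* **Effective number of codons.** The field-standard ENC-plot needs both
  an observed ENC and the mutation-only expectation
  $\mathrm{ENC}_{\exp} = 2 + \mathrm{GC3s} +
  29/[\mathrm{GC3s}^2 + (1-\mathrm{GC3s})^2]$. For the observed value we
  use Wright's estimator: per amino-acid family the codon homozygosity
  $\hat F = (n\sum_i p_i^2 - 1)/(n-1)$, families grouped into degeneracy
  classes, $N_c = \sum_{d} n_d / \bar F_d$. The textbook constants
  (2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆) hard-code the standard code's class
  structure; mitochondrial codes have different families (the
  invertebrate code has an 8-fold serine and a 6-fold leucine family and
  no singletons), so mitocub derives the classes from the genetic code
  itself. One-codon families contribute $\bar F = 1$; a class with no
  usable $\hat F$ borrows the mean of the nearest available classes by
  degeneracy distance, which reduces to Wright's original interpolation
  for the missing 3-fold class. $N_c$ is clipped at the code's
  sense-codon count, which small-sample noise can otherwise exceed.

* **Neutrality plot.** Per gene, GC12 (the mean of first- and
  second-position G+C) is regressed on GC3 by ordinary least squares,
  with Pearson's $r$ and its two-sided $t$-test ($n-2$ df) — the
  smallest-assumption classical test, since no specific test is standard
  in this literature. A slope near 1 indicates the three positions drift
  together (mutation-driven composition); a slope near 0 indicates
  constrained positions 1–2 (selection). Plain GC3 feeds this plot;
  GC3s — third-position G+C restricted to codons of families with
  degeneracy ≥ 2 — feeds the expected-ENC curve. Under the invertebrate
  mitochondrial code the two coincide, but they differ whenever
  one-codon families exist.

## Coordinates, strands and incomplete stops

All coordinates are 1-based and inclusive (GenBank convention), and the
intergenic spacing between consecutive features is
`start(next) − end(this) − 1`, so negative values are overlaps and 0 is
abutting; on a circular genome a final junction joins the last feature
back to the first across the origin. The parser trusts the GenBank
location for orientation (`+`/`-` on the deposited strand) and keeps any
J/N major/minor label as metadata only, because which strand depositors
call "major" varies.

Many mitochondrial PCGs end in an incomplete stop codon — a terminal `T`
or `TA` completed to `TAA` by polyadenylation, annotated as spans whose
length is not a multiple of 3. mitocub *trims* the remainder (recording
it as the incomplete stop) rather than padding it to `TAA`: completion is
an inference about the transcript, not an observation of the genome, so
no invented nucleotides ever enter codon statistics. The trimmed
remainder plus the whole-codon body always reconstructs the annotated
span. The same rule silently handles annotations that claim a complete
stop over a non-multiple-of-3 span, which real records do contain.
Codons containing non-ACGT symbols are excluded from all counts.

## The synthetic mitogenome generator

Real annotated mitogenomes cannot be bundled or downloaded at test time,
so `generate_mitogenome()` produces fully annotated stand-ins with the
statistical structure the analysis assumes. The default
`synthetic_spec()` emulates a beetle mitogenome:

* **Geometry** — the 37-gene-plus-control-region order, strand
  assignment, feature lengths and overlap/gap structure of the reference
  annotation shipped as `crataceus_annotation()` (GenBank OP963801.1),
  with spacings recomputed from its coordinates. Realizing the default
  spec reproduces those coordinates exactly, including 1–8 bp overlaps
  and the three PCGs whose spans force incomplete stops.
* **Composition** — whole-genome A+T targeted at 0.7182, the published
  content of the reference record. Non-coding features and gaps are
  filled i.i.d. from a base distribution with that A+T fraction (A:T and
  G:C ratios matching the published whole-genome composition); PCG
  amino-acid frequencies follow the same AT-rich background (a fixed
  tilt solved deterministically by `uniroot` so that expected
  position-1/2 A+T equals the target), which also mimics the
  Phe/Ile/Leu-rich amino-acid usage of real mitochondrial proteins.
* **Codon bias** — within each synonymous family, codon probabilities
  are one Dirichlet draw with concentration `bias_concentration`
  (`Inf` = exactly uniform, small values = strong bias), then tilted at
  the third position toward `gc3_target` (default `1 − at_content`, so
  coding and non-coding regions share the A+T level). After sampling,
  synonymous third-position swaps pin the realized GC3 count to
  `round(target · n)`: a gene of 1000 codons recovers its GC3 target to
  about ±0.001 instead of the ±0.03 binomial noise of pure i.i.d.
  draws, so parameter-recovery checks are sharp at realistic gene
  lengths. Decreasing the concentration strictly decreases mean observed
  ENC, giving a controlled dial for bias strength.
* **Determinism** — every stochastic draw flows from a single stream
  seeded by `spec$seed`; equal specs give byte-identical GenBank output,
  and the generator restores the caller's RNG state.

Overlapping features share sequence, written once; in PCG–PCG overlaps
the downstream gene's bases take precedence (as in real atp8/atp6
overlaps), so the upstream partner's final codons are genuinely
corrupted — extraction then reports its stop as incomplete or absent,
which is realistic and exercised deliberately. Features are otherwise
written non-coding-first so tRNA neighbours never clobber coding
sequence.

What the generator does *not* emulate: tRNA/rRNA secondary structure
(their sequence is composition-matched noise), transcription-driven
strand-asymmetry gradients, phylogenetic correlation between "species",
or sequencing/assembly error. Tests passing on synthetic data therefore
validate the *computations* — parsing, extraction, counting, the
estimators — not any biological claim about real genomes.

## Numerical choices and degenerate inputs

* `enc_expected()` rejects GC3s outside [0, 1]; its maximum on a dense
  grid is ≈ 60.50 at GC3s ≈ 0.51 (the linear term shifts it off 0.5).
* `family_homozygosity()` is missing (not 0) for family totals ≤ 1;
  Wright's $N_c$ is an error only when *no* class has a usable mean —
  e.g. a table whose observed families are all single-count. Totals
  below ~30 codons warn.
* Wright's estimator is not exactly scale-free: $\hat F$ carries an
  $O(1/n)$ term, so doubling all counts moves $N_c$ by about one unit at
  a thousand codons and converges from there; the suite asserts the
  convergence, not exact invariance.
* The GC3 tilt and the A+T tilt are both solved by `uniroot` to 1e-9 on
  the realized probability vectors; an unreachable target raises an
  `infeasible-target` error rather than silently clamping.
* `neutrality_fit()` requires ≥ 3 genes and non-constant GC3 and errors
  otherwise; missing GC values are dropped before fitting.
* Report TSVs round percentages to 2 d.p. and skews to 3 d.p. (matching
  the conventions of published composition tables), GC fractions to
  4 d.p. and ENC/RSCU to 3 d.p.; raw values are kept in memory and
  rounding is applied only at write time, with fixed formatting so
  re-running an analysis is byte-identical.

## Scale of the validation runs

The suite sizes its simulations to be decisive but quick: ENC
oracle-equivalence on ~500 random codon tables under the standard and
invertebrate mitochondrial codes; RSCU family-sum checks on 1000 random
tables; GC3 recovery over 20 seeded 1000-codon genes; whole-genome A+T
recovery over 20 seeded default genomes; neutrality-slope recovery with
500 replicates per slope in {0, 0.5, 1} at 13 genes and σ = 0.02; a
17-species synthetic comparative panel. The uniform-usage RSCU check
uses one 100,000-codon gene with a uniform amino-acid distribution so
that even the 8-fold serine family's sampling noise sits far inside the
0.15 assertion band — at a few thousand codons that band would be a
coin-flip, which is a property of sampling noise, not of the
implementation.

## Limitations

* The ENC-plot and neutrality plot are descriptive; mitocub fits no
  mutation–selection model and computes no CAI/tAI-style selection
  indices, correspondence analysis or PR2 plots.
* De novo annotation, assembly and tRNA structure prediction are out of
  scope: inputs must already be annotated (GenBank flat file, or FASTA
  plus a feature table).
* Published ENC values in the literature come from assorted
  implementations with differing repair rules; exact numeric parity with
  any particular figure is not claimed, only with the estimator as
  defined above (verified against an independent brute-force
  implementation).
* The GenBank writer emits a minimal record (fixed date, `/gene` and
  `/note` qualifiers) designed for lossless round-tripping of this
  package's objects, not a full-featured submission formatter.
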