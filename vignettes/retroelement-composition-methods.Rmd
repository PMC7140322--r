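---
title: "Composition, codon usage and mutation spectra of retroelement families: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition, codon usage and mutation spectra of retroelement families: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrocomp)
```

## The problem

Autonomous non-LTR retrotransposons (L1, L2, CR1, RTE and related clades)
often carry a base composition very different from their host's genes — the
mammalian L1 is the classic case, AT-rich with a strong A bias on the
positive strand.  Composition shapes how well an element is transcribed
(AT-rich ORFs accumulate premature polyadenylation signals) and how well it
is translated (biased codon usage is deoptimized relative to the host's
tRNA pool), so it sits at the centre of the element-host trade-off between
transposition efficiency and harm to the host.  `retrocomp` provides the
statistics needed to characterise this trade-off for consensus families of
element coding sequences, the host reference tables to score them against,
and a singleton-based procedure to estimate the de novo mutation spectrum
that composition evolves under.  A synthetic-data generator with known
ground truth makes every stage testable end to end.

All analyses run on the element's positive strand (the strand encoding the
ORFs); strand asymmetries such as A-richness are only meaningful in that
frame.

## Composition statistics

For a frame-validated ORF the package reports base fractions over non-N
positions (%AT, %GC, %A), GC at the three codon positions (GC3 being the
mostly-synonymous, mutation-facing position), amino-acid counts, and two
motif/word statistics:

* **Dinucleotide odds ratios.**  Overlapping dinucleotides are counted in
  a sliding window (no wrap-around; windows containing N are skipped) and
  compared with the zero-order expectation, the product of the
  mononucleotide fractions.  A chi-square on the 16 observed vs expected
  window counts uses 15 degrees of freedom and no continuity correction.
  CpG, TpA and GpT depletion is the expected vertebrate signature.
* **PolyA signals.**  Occurrences of the canonical AATAAA and
  non-canonical ATTAAA hexamers on the positive strand, counted with
  overlap.  Counting overlaps is a deliberate convention: it is
  deterministic and checkable against a position-by-position oracle;
  with two A-rich hexamers, overlapping hits are rare enough that the
  choice moves counts by at most a few per ORF.  Reverse-strand motifs
  are not scanned — premature termination of the element's own transcript
  is a positive-strand phenomenon.

Trailing stop codons are trimmed during frame validation, so codon-level
statistics run on the sense-codon payload; whether to include the stop in
whole-ORF base fractions is a judgement call, and trimming it keeps the
mono- and codon-level reports consistent with each other.  Codons
containing N are excluded from codon statistics, and N positions break
dinucleotide windows; the excluded counts are reported.

## Codon-usage statistics

All indices use the standard genetic code partitioned into synonymous
families: 2 single-codon families (Met, Trp), 9 two-fold, 1 three-fold
(Ile), 5 four-fold and 3 six-fold (Leu, Ser, Arg).

**RSCU** is a codon's count divided by its family's mean count; the family
sum equals the family size.

**Nc (effective number of codons)** uses Wright's class-averaged estimator

$$N_c = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} + \frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$

with family homozygosity $F = \sum_c p_c^2$ by default
(frequency-based), under which the definitional identities hold exactly:
20 when one codon is used per family, 61 under uniform usage.  Wright's
finite-sample correction $F = (n\sum p^2 - 1)/(n-1)$ is available behind
`sample_correction = TRUE` for short sequences.  When a degeneracy class
is entirely unobserved its $\bar F$ is borrowed from the mean
homozygosity of all observed multi-codon families; the result is clipped
to $[20, 61]$.

**CAI** is the geometric mean over the query's codon occurrences of
relative adaptiveness $w_c = f_{\mathrm{ref}}(c) / \max_{c' \in
\mathrm{syn}(c)} f_{\mathrm{ref}}(c')$, with Met, Trp and stops excluded.
**RCDI** is the arithmetic mean over occurrences of
$f_{\mathrm{query}}(c)/f_{\mathrm{ref}}(c)$ (conditional frequencies), so
identical usage gives exactly 1 and deoptimized usage values above 1.
The ratio is oriented query/reference precisely so that deoptimization
raises the index.  Reference codons with zero counts inside a family the
query uses receive a pseudo-count of 0.5 (switchable), avoiding infinite
or zero ratios on sparse references.

**eCAI and eRCDI** are randomization expectations.  eCAI draws
`n_random` sequences of the query's codon length with codon probabilities
proportional to the product of the query's mononucleotide frequencies
(stops excluded, renormalized); eRCDI keeps the query's amino-acid
sequence and redraws each codon among its synonyms with those same
composition-driven weights.  Both default to `n_random = 500` and report
the replicate mean (a 95th-percentile summary is available for eCAI);
means are stable to ~1% at 500 replicates for kilobase queries, and both
are bit-reproducible given a seed.  The replicates are drawn as
multinomial codon counts, which is exact because both indices depend on
the codon multiset only, not on codon order.

Host reference tables pool codon counts genome-wide over the supplied
gene set (per-gene averaging is a coherent alternative but pooling is the
convention of codon-adaptation references and is scale-invariant in the
conditional frequencies); per-gene base composition is attached for
element-vs-host comparisons.

## Singleton mutation spectrum

For each family, genomic copies aligned to their consensus are scanned
column by column; substitutions are recorded in ungapped consensus
coordinates and columns with a gap or N on either side are skipped
(indels are outside scope).  The consensus is treated as the ancestral
state, which is safe only for young families — hence the default filters:
at least 8 copies and mean copy divergence below 5%.

Substitutions observed in two or more copies (identical position, from,
to) were likely inherited from a common progenitor and are removed; only
**singletons** enter the spectrum.  Two different substitutions at one
position remain singletons.  C>N substitutions are CpG-context when the
consensus has G immediately 3'; G>N when C is immediately 5'; a missing
neighbour at a sequence edge counts as non-CpG.  Counts are normalized by
mutational opportunity — each X>Y count divided by the number of X in the
consensus — and rescaled to percentages summing to 100; raw counts are
retained alongside for the unnormalized alternative.  The GC→AT excess is
the ratio of the pooled normalized rates (C>T, C>A, G>A, G>T) over
(T>C, A>G, A>C, T>G).

## The synthetic generator

The generator exists to give every stage a ground truth, and its defaults
are the study conditions the pipeline is validated under:

* **Element consensi**: codons drawn as three i.i.d. bases from a target
  composition, stop codons rejected and redrawn.  Realized composition is
  within ~2 points of target from 1,000 codons up (stop rejection pulls
  slightly against extreme AT-richness).  Clade presets used in the
  analysis scripts span the empirically observed range, 65% AT with an A
  bias (L1-like) to 44% AT (L2-like).
* **Host gene sets**: ATG-initiated, stop-terminated genes with amino
  acids drawn uniformly (configurable) and codons per family from a
  supplied conditional profile; used to build reference tables whose
  conditional frequencies converge on the profile.
* **Copy families**: a star tree with an optional shared ancestral
  branch.  A fraction *s* of the target divergence is applied once to the
  consensus and inherited by all copies; each copy then accrues the
  remaining divergence independently, as per-site Bernoulli events with
  no back-mutation (adequate below 5% divergence, the same regime the
  pipeline restricts itself to).  Per-site rates are uniform except for a
  CpG multiplier on C/G in CpG context, evaluated on the current
  ancestral sequence at injection time; rates are rescaled so expected
  divergence matches the target.  Substitution targets follow a
  row-stochastic 4×4 weight matrix (default: transitions twice each
  transversion).  Validation runs use 2% divergence, CpG ×10 (within the
  10–50× range reported for vertebrate genomes) and *s* = 0.2.  Copies
  may acquire stop codons; the consensus cannot.

What the generator does **not** emulate: retrotransposition bursts and
non-star genealogies, gene conversion, APOBEC-style strand-coupled
editing, alignment error, indels, and sequencing artefacts.  Passing
recovery tests therefore demonstrates the pipeline's correctness under
its stated model, not robustness to misalignment or non-clocklike
copy histories.

## Validation design

Three layers of tests back the implementation:

1. **Identities and closed forms** — Nc at its 20/61 extremes, CAI = 1
   for most-frequent-synonym queries, RCDI = 1 for query ≡ reference,
   two-codon toy closed forms (CAI 0.25, RCDI 2).
2. **Oracle equivalence** — polyA counts, dinucleotide counts,
   codon-position GC and variant calls compared exactly against naive
   position-by-position reference implementations on 1,000 random
   sequences.
3. **Parameter recovery** — 20 simulated families × 10 copies × 1,000
   codons; the pooled non-CpG singleton spectrum must match the
   configured matrix rows within binomial confidence intervals held
   jointly at 95% (Bonferroni-adjusted per-cell level across the 12
   cells, so the whole check has the stated coverage rather than each
   cell separately); the CpG-context singleton count must match its
   analytic expectation, which accounts for the thinning the singleton
   filter itself applies (a true mutation is discarded when a second
   copy happens to carry the same substitution — at CpG sites, with a
   ×10 rate, that retention factor $(1-pM)^{n-1}$ is materially below
   1); and the GC→AT excess must sit within 10% of its analytic value
   under the configuration.

Problem sizes in the default suite (sequence lengths of a few hundred
codons, 5–20 families, 100–500 randomization replicates) were chosen so
the whole suite exercises every stage at statistically meaningful depth
while remaining quick to run; all simulation tests are seeded.

## Statistical comparisons

The comparison module wires the standard tests the analysis needs —
one-way ANOVA, pooled-variance t-test, a Kolmogorov–Smirnov normality
screen against a normal fitted to the sample (parameters estimated from
the data, so p-values are conservative in the Lilliefors sense), OLS
regression, and a paired z for observed-versus-expected RCDI (the
construction is paired per family because observed and expected values
share a sequence).  No multiple-testing correction is applied; the
comparison table reports raw p-values.

## Known limitations

* The consensus-as-ancestor assumption biases spectra when families are
  old or when copies gene-convert; the divergence filter mitigates but
  does not remove this.
* Opportunity normalization divides by consensus base counts; if the
  "normalized percentage" of a published figure is raw percentages
  instead, the raw counts columns reproduce that alternative.
* eCAI summaries differ among published servers (mean vs upper
  percentile); both are exposed, the mean is the default.
* The dinucleotide chi-square treats windows as independent; overlapping
  windows are positively dependent, so its p-values are anticonservative
  at small lengths — at ORF scale (kilobases) the test is effectively a
  descriptive index, which is how it should be read.
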