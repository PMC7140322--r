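# retrocomp

Base composition, codon usage and de novo mutation spectra for families of
non-LTR retrotransposons (LINEs and relatives) and the host genes they
coexist with.

## The problem

Autonomous non-LTR retrotransposons often evolve a base composition very
different from their host's exome — the mammalian L1 is AT-rich with a
strong A bias on its positive strand.  Composition controls how well an
element is transcribed (AT-rich ORFs accumulate premature polyadenylation
signals) and translated (biased codon usage is deoptimized against the
host's), so quantifying it, scoring it against the host, and asking
whether mutation pressure alone explains it are the core analyses of
element–host co-evolution studies.  `retrocomp` implements that toolkit
for consensus coding sequences (typically ORF2, the reverse-transcriptase
ORF shared across clades):

* **Composition** — base fractions (%AT, %GC, %A), GC at the three codon
  positions, amino-acid composition, overlapping dinucleotide
  observed/expected ratios with the 15-df chi-square, and counts of the
  AATAAA/ATTAAA polyA hexamers.
* **Codon usage** — RSCU; Wright's effective number of codons
  `Nc = 2 + 9/F̄2 + 1/F̄3 + 5/F̄4 + 3/F̄6` (20 = one codon per amino acid,
  61 = uniform synonymous use); the Codon Adaptation Index
  `CAI = exp(mean log w)`, `w = f_ref(c)/max f_ref(syn)`, against a pooled
  host reference table, with its randomization expectation eCAI under the
  query's own base composition; and the Relative Codon Deoptimization
  Index `RCDI = mean f_query(c)/f_ref(c)` (1 = host-identical usage) with
  its expectation eRCDI.
* **Mutation spectrum** — substitutions of genomic copies called against
  the family consensus, restricted to *singletons* (seen in exactly one
  copy, hence de novo rather than inherited), split by CpG context,
  normalized by mutational opportunity, and summarized as the GC→AT
  excess ratio.
* **Synthetic data** — generators for host gene sets with a chosen
  codon-usage profile, element consensi with a target composition, and
  copy families diverged under a 4×4 substitution model with CpG
  hypermutability and a shared ancestral branch, so every stage has a
  known ground truth.

## Worked example

```r
library(retrocomp)

# an AT-rich, A-biased "L1-like" ORF2 and a GC-leaning host gene set
cons <- simulate_element_consensus(c(A = .40, C = .17, G = .17, T = .26),
                                   length_codons = 1000, seed = 1)
host <- simulate_host_cds(
  vapply(sense_codons(),
         function(cod) 2^sum(strsplit(cod, "")[[1]] %in% c("G", "C")),
         numeric(1)),
  n_genes = 100, mean_length = 300, seed = 2)
ref <- build_reference_table(host)

base_composition(cons)$pct_AT      # 64.9  (% A+T on the positive strand)
count_polya_signals(cons)          # 8     premature polyA hexamers
effective_number_of_codons(cons)   # 48.1  (biased, below the uniform 61)
cai(codon_usage_table(cons), ref)  # 0.57
rcdi(codon_usage_table(cons), ref) # 1.90  (> 1: deoptimized vs host)
expected_rcdi(cons, ref, n_random = 500, seed = 3)  # 1.64 expected from
                                   # composition alone

# copy family: 2% divergence, CpG sites x10, 20% shared mutations
fam <- simulate_family(cons, n_copies = 10, expected_divergence = 0.02,
                       cpg_multiplier = 10, shared_fraction = 0.2, seed = 4)
ms <- mutation_spectrum(fam)       # singletons only
ms$gc_to_at_excess                 # 1.48  (mutation pressure toward AT)
subset(ms$spectrum, type %in% c("C>T", "G>A"))[, c("type", "count_cpg",
                                                   "count_noncpg",
                                                   "normalized_pct")]
#   type count_cpg count_noncpg normalized_pct
#   C>T        29           19           14.5
#   G>A        25           21           15.8
```

The transition counts concentrate in CpG context although CpG sites are a
small minority of the sequence — the hypermutability the generator
injected and the spectrum recovers.

## Analysis workflow

`analysis/` holds the numbered drivers that chain the package into the
full study on a synthetic dataset (written under `results/`):

```sh
Rscript analysis/01_simulate.R          # consensi, host CDS, copy families
Rscript analysis/02_composition.R       # per-family + group composition, ORF1 vs ORF2
Rscript analysis/03_codon_usage.R       # Nc, CAI/eCAI, RCDI/eRCDI, RSCU tables
Rscript analysis/04_mutation_spectrum.R # singleton spectra, GC->AT excess
Rscript analysis/05_stats.R             # ANOVA/t/KS/regression comparison table
```

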