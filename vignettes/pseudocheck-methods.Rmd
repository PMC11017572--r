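---
title: "Quantifying spurious pseudogenes in bacterial assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spurious pseudogenes in bacterial assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bacterial genomes are dense with protein-coding sequence, and annotation
pipelines routinely flag a subset of coding loci as pseudogenes: genes
interrupted by a frameshift (an indel whose length is not a multiple of
three) or by an internal stop codon (a nonsense substitution upstream of
the gene's real terminator). Both signatures are exactly what a
base-calling or assembly error produces. When two assemblies of
near-identical genomes disagree about whether a locus is a gene or a
pseudogene, at least one of them is wrong — and the disagreement rate
turns out to depend strongly on how the assembly was made: read
coverage, base quality, sequencing platform, and assembler.

`pseudocheck` implements the building blocks to quantify this artifact
and to use it for assembly quality control:

1. **Pairwise congruence.** Coding sequences of two assemblies are
   clustered at a nucleotide similarity threshold (default ≥ 90%);
   clusters of more than two members suggest paralogs and are excluded.
   For each cause (frameshift, internal stop), a matched pair is
   *congruent* when both members are pseudogenes and *incongruent* when
   exactly one is. The incongruent fraction,
   `incongruent / (congruent + incongruent)`, measures annotation
   disagreement between near-identical genomes.

2. **A binomial error model.** Treating each coding feature as a
   Bernoulli trial, the count `k` of spurious pseudogenes among `n`
   features follows `Binomial(n, p)` with

   `logit(p) = beta0 + beta_cov * log10(coverage) + beta_q * quality`.

   The model is fit by maximum likelihood (IRLS). Two derived
   quantities summarize a fit: the expected spurious-pseudogene density
   (per Mbp) at 50-fold coverage, and the coverage needed to push the
   density down to one per Mbp.

3. **A nearest-neighbor anomaly filter.** For an assembly whose nearest
   neighbor by average nucleotide identity (ANI) is at least 99.9%
   identical, the assembly is rejected when its internal-stop count
   exceeds the exact 99th-percentile binomial quantile
   `min{t : CDF(t; n_cds, neighbor_rate) >= 0.99}` implied by its own
   CDS count and the neighbor's internal-stop rate. Rejection requires
   a strictly greater count, so the test is conservative by
   construction.

## Design choices

Several aspects of the procedure are genuinely open and were fixed as
follows.

**Pseudogene dialects.** Annotation pipelines express pseudogene status
inconsistently across builds; a feature is treated as a pseudogene when
it carries `pseudo=true`, or `gene_biotype=pseudogene`, or is of GFF3
type `pseudogene` (the union). Causes are recovered by case-insensitive
substring matching in the `Note`/`pseudogene` qualifiers ("frameshift",
"internal stop", "incomplete"/"partial"). A pseudogene with an
unrecognized cause string is retained with an empty cause set, is
reported, and is excluded from cause-specific tallies. Truncation
("partial") pseudogenes are parsed and counted but never fed into the
frameshift/internal-stop statistics: partial features commonly reflect
incomplete assemblies rather than base-level error, so they carry no
signal for this analysis.

**Alignment scoring.** All sequence comparisons use one fixed scheme:
match +1, mismatch −1, affine gaps costing 2 + L for a gap of length L,
with deterministic tie-breaking. Identity is matches / aligned columns
with gap columns in the denominator; this makes identity 1.0 exactly
only for identical sequences. The exact similarity definition inside
CDS clustering tools is tool-specific; matches-over-columns is this
package's fixed convention.

**The ORF classifier.** Large annotation pipelines call pseudogenes via
homology search; their exact decision rules are not public. The
classifier here is an explicit, reproducible stand-in: the observed
sequence is globally aligned to its reference ORF, the reading frame is
tracked through the alignment, and

* *frameshift* is called when some aligned segment is out of frame
  (the cumulative net indel length over any prefix of the indel runs is
  not a multiple of 3), ignoring indels within the final 5% of the
  reference length, where alignment end gaps are unreliable;
* *internal stop* is called when the in-frame translation (frame
  inherited from the reference through the alignment) contains a stop
  strictly before the reference's terminal stop; a stop in the last
  complete codon before the terminator is not "internal" since it
  terminates where the gene terminates;
* out-of-frame regions are never translated, so one frameshift does not
  cascade into spurious internal-stop calls;
* sequences with more than 10% ambiguous bases are unclassifiable.

The genetic code is bacterial (table 11); start codons ATG/GTG/TTG.
The classifier's verdicts are validated against the synthetic
generator's ground truth, not against any external annotation pipeline
— that is the honest scope of what it can claim.

**ANI dialect.** The query genome is cut into non-overlapping 1-kb
fragments; each fragment is placed on its best subject locus by exact
21-mer seed voting and accepted when it aligns at ≥ 70% identity over ≥
70% of its length; ANI is the mean identity of accepted fragments,
averaged over both directions. When seeds agree on a single diagonal
the fragment identity is computed by direct base comparison (exact for
substitution-only divergence); otherwise the fragment is realigned with
the package's global-local aligner. `ani(A, A)` is exactly 100; when no
fragment passes, ANI is undefined (`NA`), never 0.

**Clustering.** Single-linkage clustering under the relation
`identity >= 0.90`. Candidate pairs come from an exact shared-21-mer
prefilter (sequences are first collapsed to unique strings, and k-mers
are compared as exact 2-bit-packed numeric codes); at ≥ 90% identity
over the 150-bp minimum CDS length, the expected number of shared
21-mers is ≈ 14, so the prefilter changes cost, not results — a
property the test suite checks against exhaustive all-pairs comparison.
Tie-breaking is lexicographic on feature ids everywhere, making cluster
output invariant to input order.

**Model fitting.** The IRLS loop iterates to |Δ log-likelihood| <
1e-8 (≤ 100 iterations). A constant-quality design drops the quality
term with a flag rather than failing. Complete separation is detected
from diverging coefficients or degenerate fitted probabilities and
handled with a visible 1e-6 ridge — never silently. When every count is
zero the likelihood has no interior maximum; the fit carries a
`boundary` flag and refuses to predict. The inverse problem (coverage
for a target density) is solved by bisection on log10(coverage) over
[0.1, 1e6] to 1e-6 relative tolerance; the tests cross-check bisection
against the closed-form logit inversion. The choice of logit link with
log10(coverage) and untransformed quality is this package's own: log
coverage makes the error-vs-coverage decay monotone and scale-free, and
the link is recorded in the fit object.

**The filter quantile** uses the exact discrete binomial CDF, not a
normal approximation; the threshold is therefore an integer and the
realized false-positive rate is at most 1% (usually below, due to
discreteness). The neighbor's rate is its internal-stop count over its
own CDS count; a shared-gene denominator would require clustering every
pair up front and is not what the count data supports.

## The synthetic-data generator

The generator stands in for the full read-simulation → assembly →
annotation chain, which is out of scope. It emulates:

* a single-contig bacterial genome (circular convention; features do
  not wrap the origin) of ATG-initiated ORFs with GC-controlled codon
  composition, exponential intergenic spacers, and both strands;
* a chosen fraction of *true* pseudogenes (`round(n_genes * fraction)`
  exactly), broken by an internal stop substitution or a 1–2-bp indel;
* corrupted "reassemblies" in two modes. In **feature-level** mode each
  intact gene independently becomes a spurious pseudogene with
  probability `plogis(beta0 + beta_cov*log10(cov) + beta_q*Q)` — by
  construction exactly the model family the analysis fits, which makes
  parameter recovery a sharp end-to-end test. In **base-level** mode
  substitutions and indels are scattered at per-bp rates scaled by the
  same logit-linear factor, exercising the classifier on realistic
  mutation patterns (including in-frame indels and silent
  substitutions).

Default generator coefficients are (beta0, beta_cov, beta_q) =
(2, −3, −0.1): at Q35 this yields roughly one spurious pseudogene per
Mbp at ~60-fold coverage, decaying to essentially none above 200-fold —
the regime where careful short-read assemblies stop producing spurious
calls. The default condition grid mirrors the standard subsampling
series (5, 10, 25, 50, 100, 250, 500-fold; Q 20/30/35; 3 replicates).

**Randomness.** A master seed derives per-replicate streams by hashing,
so replicates are independent but reproducible. Within a replicate, the
per-feature flip draw depends only on the replicate stream — not on the
condition — so runs across a coverage grid share common random numbers:
the realized spurious count is non-increasing in coverage *by
construction*, not merely in expectation. Cause choice and mutation
placement come from separate per-feature streams, so the flipped subset
at high coverage is always a subset of the one at low coverage.

Features destroyed by contig fragmentation are recorded as truncation
events and excluded from frameshift/internal-stop tallies, consistent
with treating partial features as assembly artifacts.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: repeat-induced misassembly, coverage
fluctuation along the genome, platform-specific error motifs
(homopolymer indels), assembler-specific behavior, and contamination.
Real reads show more variance than any of this; conclusions from the
synthetic pipeline are about the correctness of the statistics, not
about the error rates of any particular instrument.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to
exercise every code path at full fidelity while staying desk-scale:
1,000-gene (~1 Mbp) genomes for the end-to-end controls and the
monotone-decay check (20 replicates × 7 coverages); a 7-coverage ×
2-quality × 2-replicate grid for end-to-end parameter recovery (two
qualities, so both model coefficients are identified from data rather
than extrapolated); 1-Mbp genomes for ANI calibration; 10,000 draws per
setting for filter calibration; and 100-kb genomes with 3 replicates
for the ANI-vs-substitution-rate ordering. The same machinery scales to
full bacterial genomes unchanged.

## A worked run

```{r example}
library(pseudocheck)

# ground truth genome with 2% true pseudogenes
g <- make_genome(genome_spec(n_genes = 1000, true_pseudo_fraction = 0.02,
                             seed = 1))

# a low-coverage "reassembly", annotated by reference-based classification
st <- corrupt(g, coverage = 10, quality = 35, seed = 2)
re <- annotate_with_classifier(st$corrupted, g)
spurious_counts(re, g)

# full grid -> binomial fit -> the two predictions
sim <- simulate_experiment(genome_spec(n_genes = 1000, seed = 1),
                           coverages = c(5, 10, 25, 50, 100, 250, 500),
                           qualities = c(20, 35), replicates = 2, seed = 3)
run_coverage_experiment(sim$observations, quality = 35)$predictions
```

## Known limitations

* The ORF classifier is validated only against the synthetic
  generator's ground truth; no claim is made that it reproduces any
  specific annotation pipeline's verdicts on real genomes.
* Truncation/partial pseudogenes are deliberately out of scope for the
  statistics (they confound incompleteness with error).
* The ANI implementation is a fragment-based calculator with fixed
  cutoffs, adequate for near-identical genomes; it is not a replacement
  for dedicated whole-genome ANI tools at larger evolutionary
  distances.
* Base-level corruption labels substitutions in the original reading
  frame and indels by net length; compound events within one feature
  (e.g., an in-frame deletion whose junction creates a stop) have
  genuinely ambiguous ground truth and are excluded from
  classifier-vs-truth comparisons.
* The binomial model pools all features as exchangeable trials; gene
  length, local GC, and repeat context are not covariates.
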