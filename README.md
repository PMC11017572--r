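# pseudocheck

Many pseudogenes annotated in bacterial genome assemblies — coding loci
apparently broken by a frameshift or an internal stop codon — are not
biology but technical artifacts: indels and nonsense base calls
introduced by low-coverage or low-quality sequencing and by the
assembler. `pseudocheck` is an R package for scientists who work with
bacterial assemblies and want to (i) measure how often near-identical
genomes disagree about pseudogene calls, (ii) model how the spurious
calls depend on read coverage and base quality, and (iii) flag
anomalous assemblies by their pseudogene excess.

## What it computes

**Congruence between near-identical genomes.** Coding sequences of two
assemblies are clustered at ≥ 90% nucleotide identity (single linkage;
clusters with more than two members suggest paralogs and are excluded).
For a cause *c* ∈ {frameshift, internal stop} the incongruent fraction
is

&nbsp;&nbsp;&nbsp;&nbsp;f_c = n(pseudogene/gene pairs) / [n(pseudogene/pseudogene) + n(pseudogene/gene)]

**A binomial error model.** With *k* spurious pseudogenes among *n*
coding features of an assembly built at fold-coverage *C* and mean base
quality *Q*:

&nbsp;&nbsp;&nbsp;&nbsp;k ~ Binomial(n, p),&nbsp;&nbsp; logit(p) = β₀ + β_cov · log₁₀(C) + β_q · Q

fit by maximum likelihood (IRLS). From the fit: the expected
spurious-pseudogene density (per Mbp) at 50× coverage, and the coverage
required to reach one spurious pseudogene per Mbp.

**A nearest-neighbor binomial filter.** An assembly whose nearest
neighbor by ANI is ≥ 99.9% identical is rejected when its internal-stop
count exceeds the exact binomial 99th percentile implied by its CDS
count and the neighbor's internal-stop rate.

A synthetic-genome generator (`make_genome()`, `corrupt()`,
`simulate_experiment()`) produces ground-truth genomes with true
pseudogenes and coverage/quality-dependent corruption, so the entire
pipeline — classification, clustering, counting, fitting, inversion —
is exercised end to end against known truth.

## Worked example

```r
library(pseudocheck)

# a 1,000-gene ground-truth genome, 2% true pseudogenes
g <- make_genome(genome_spec(n_genes = 1000, true_pseudo_fraction = 0.02,
                             seed = 1))
g
#> <assembly_annotation> synthetic_1: 1 contig(s), 1,027,972 bp, 1000 CDS (20 pseudogene)

# corrupt it as if reassembled from 10-fold Q35 reads, then re-annotate
# each coding sequence against its reference ORF
st <- corrupt(g, coverage = 10, quality = 35, seed = 2)
re <- annotate_with_classifier(st$corrupted, g)

spurious_counts(re, g)
#> <spurious_counts> synthetic_1_reassembly vs reference synthetic_1 (1000 CDS)
#>   frameshift    count 5, rate 0.005, density 4.86 /Mbp
#>   internal_stop count 5, rate 0.005, density 4.86 /Mbp

pseudogene_density(re)
#> <pseudogene_density> 1000 CDS on 1,027,972 bp: frameshift 14 (13.619 /Mbp), internal stop 16 (15.565 /Mbp), partial 0
```

At 10-fold coverage, 10 of the 1,000 genes came back as pseudogenes
that the reference says are intact — spurious calls at ~5 per Mbp per
cause — on top of the 20 genuine pseudogenes (the densities in the last
line count both). Rerunning at `coverage = 500` yields zero spurious
calls: coverage is the dial.

Fitting the model over a coverage × quality grid and deriving its two
predictions:

```r
sim <- simulate_experiment(genome_spec(n_genes = 1000, seed = 1),
                           coverages = c(5, 10, 25, 50, 100, 250, 500),
                           qualities = c(20, 35), replicates = 2, seed = 3)
run_coverage_experiment(sim$observations, quality = 35)$predictions
```

which reports, per cause, `density_at_report` (expected spurious
pseudogenes per Mbp at 50×) and `coverage_for_target` (fold coverage
needed to reach 1 per Mbp).

File-based workflows use `read_assembly()` / `write_assembly()`
(FASTA + GFF3 with `pseudo`/`Note` qualifiers) and the thin CLI at
`inst/cli/pseudocheck.R` (verbs: `annotate-stats`, `classify`, `ani`,
`compare`, `fit`, `predict`, `filter`, `simulate`).

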