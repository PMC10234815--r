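---
title: "Quantifying personal information in the host reads of gut metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying personal information in the host reads of gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metareid)
```

## The problem

Stool samples contain shed host cells, so shotgun metagenome sequencing of
the gut microbiome always captures a small fraction of human reads —
typically well under 1% of the library, corresponding to human-genome
coverages from around 1e-5x to a few 1e-1x. That is far too sparse for
genotype calling, but not too sparse to carry personal information. This
package implements three inferences from such reads, plus the simulation
machinery to study their operating characteristics:

1. **Re-identification**: is this metagenome sample from one of the
   individuals in a genotype database?
2. **Ancestry**: which population's allele frequencies best explain the
   reads?
3. **Genetic sex**: does the sex-chromosome read depth look XX or XY?

## The likelihood score

Consider a biallelic SNP site $i$ covered by $n_i$ read bases, $k_i$ of
them matching the reference allele, and a candidate individual $j$ whose
genotype carries $g_{i,j} \in \{0, 1, 2\}$ copies of the alternative
allele. Each read base derives from one of the two chromosomes uniformly
and is misread as the other allele with probability $\varepsilon$
(default $10^{-6}$, a deliberately conservative constant rather than a
per-base quality, so a single discordant base is strongly penalized).
Then

$$L_{i,j}(g,n,k) = \frac{1}{2^n}\,
  \big[(2-g)\varepsilon + g(1-\varepsilon)\big]^{\,n-k}\,
  \big[g\varepsilon + (2-g)(1-\varepsilon)\big]^{\,k},$$

and the likelihood score of individual $j$ over the $N$ (approximately
independent) sites is $LS_j = \sum_i \log L_{i,j}$. Heterozygous sites
contribute $\log(1/2^{n_i})$ regardless of the data — all of the
discrimination comes from homozygous sites, where a base matching the
genotype costs almost nothing and a mismatching base costs
$\log\varepsilon \approx -13.8$.

To decide whether $LS_j$ is surprisingly high, it is standardized
against the null hypothesis that the genotypes are those of a random
member of the reference population. Under Hardy–Weinberg equilibrium the
genotype at site $i$ is 0/1/2 with probabilities
$(1-p_i)^2,\,2p_i(1-p_i),\,p_i^2$, where $p_i$ is the population
alternative-allele frequency, which yields closed-form moments

$$E = \sum_i \sum_g P(g, p_i) \log L_i(g),\qquad
  V = \sum_i \sum_g P(g, p_i)\,[\log L_i(g) - E_i]^2,$$

a z-score $z_j = (LS_j - E)/\sqrt{V}$, and a one-sided normal P value
(the score of the true donor is *higher* than the null). An empirical P
value is also available by simulating genotype vectors from the
frequencies; it uses the rank formula
$(1 + \#\{LS_{sim} > LS_j\})/(n_{draws}+1)$ with strict inequality, so
ties count toward the null.

Two conventions here were genuinely open and are our choices:

* **Per-candidate null moments.** When a candidate has missing
  genotypes, $E$ and $V$ are recomputed over exactly the sites that
  entered that candidate's score, keeping z-scores comparable across
  candidates with different missingness.
* **Degenerate nulls return NA.** With $V = 0$ (e.g. all frequencies 0)
  no P value is reported, rather than 0 or 1, so a degenerate panel can
  never produce a spurious match.

Site independence is what makes the summed moments valid, so scoring is
preceded by LD pruning of the covered sites ([pruneSites()]): a sliding
window (default 100 sites, step 30) within which any pair with dosage
$r^2 > 0.1$ loses its later member, repeated to a fixed point. The
defaults mirror the standard `--indep-pairwise 100 30 0.1` pruning flag.
We always drop the later site of an offending pair; PLINK's internal
preference differs across versions, and downstream results depend only
on approximate independence of what remains. Pruning is per query sample
(on its covered sites), and the LD reference is the same panel that
supplies the allele frequencies.

The two decision rules mirror common practice: the candidate with the
top score, and candidates whose normal P falls below the
Bonferroni-corrected threshold $\alpha / (\text{queries} \times
\text{candidates})$ — e.g. $0.05/117{,}649 \approx 4.25\times10^{-7}$
for a 343-by-343 experiment, or $1.5\times10^{-12}$ against a
hypothetical database of $10^8$ genotypes.

## Ancestry

For ancestry, the candidate genotypes are unknown, so the score of
population $A$ is the *expected* likelihood score when genotypes are
drawn from $A$'s frequencies: $E(LS_A) = \sum_i \sum_g P(g, p_{i,A})
\log L_i(g)$, and the prediction is the argmax over populations. All
populations are evaluated on the identical site set (a site missing a
frequency in any scored population is dropped for all) so the scores are
comparable. No variance standardization is used — the argmax of the
expectation is the published form of the method. Near-ties (relative
difference below $10^{-9}$) are flagged and broken lexicographically.

## Genetic sex

Each chromosome's read count is normalized twice: by the total read
count (library size) and by the chromosome length (target size), giving
a normalized depth; X and Y use only the non-pseudo-autosomal regions
(the packaged GRCh37 mask uses the standard PAR1/PAR2 coordinates, and a
user mask substitutes for GRCh38/T2T analyses). The Y/X depth ratio is
near 0 in females (residual Y depth comes from mismapping) and near 1 in
males; a single-feature logistic regression on the ratio gives the
decision boundary. The packaged reference model uses the published
boundary of 0.43 with a nominal slope — only the boundary matters for
classification. Because training cohorts are usually perfectly
separable, the maximum-likelihood fit diverges; [fitSexModel()] then
switches to a lightly L2-penalized fit so the boundary lands strictly
between the class extremes. A ratio exactly at the boundary, or an
undefined ratio (zero X depth), is a no-call.

## What the simulator emulates — and what it does not

[simulatePanel()] draws ancestral frequencies from a MAF spectrum
(default uniform on [0.01, 0.5]; a 1/p-weighted option approximates the
neutral site-frequency spectrum) and per-population frequencies from the
Balding–Nichols model, $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, with
divergence $F$ (0.1 in the two-population experiments here, a typical
between-continental-population value). Genotypes are Hardy–Weinberg
draws; families come from Mendelian transmission
([simulateOffspring()]).

Read data are simulated at site level: depth per site is
Poisson($\lambda$) and each base is flipped with the simulation error
rate. At coverages far below 1x this is statistically equivalent to
downsampling whole reads from a genome — each read covers at most one
panel SNP — and it avoids carrying a reference genome, so $\lambda$
plays the role of fold-coverage. Contamination by a second person's DNA
mixes at base level ([mixContamination()]), equivalent to read-level
mixing at these depths. Consequently the power experiments
([powerSweep()]) generate candidate genotypes only at the covered sites;
uncovered sites contribute nothing to the score or its moments, so this
is exact, and it lets a 1.5-million-site panel run in seconds per
replicate.

Features of real data deliberately *not* emulated: LD between panel
sites (clumping tests use explicitly constructed correlated dosage
columns instead), batch- and extraction-dependent coverage biases,
mapping artefacts, and sequence-level errors (no FASTQ). Passing the
simulation experiments therefore demonstrates the statistical machinery
under the model's own assumptions, not robustness to
reference/alignment artefacts.

Depth profiles for sex inference allocate reads multinomially with
weight copy-number × length per chromosome; female Y receives 1% of a
one-copy weight by default, reflecting the small but nonzero Y depth
observed in real female samples (mismapping), whose magnitude is not
published — 1% is our choice and puts the female ratio near 0.005, two
orders below the 0.43 boundary.

## Numerical and interface choices

* All likelihood products are accumulated in log space;
  $\varepsilon^{n}$ underflows double precision already for $n \ge 52$.
* Coordinates: VCF, pileup and site-count tables are 1-based; BED masks
  are 0-based half-open. Leading `chr` prefixes are stripped on load.
* Genotype records aligning to a panel site with exactly swapped alleles
  are complemented ($g \to 2-g$); any other allele mismatch is dropped
  rather than guessed (unambiguity over recall). The treatment of allele
  mismatches between a metagenome pileup and a panel is not standardized
  anywhere; this is our convention.
* Pileup bases matching neither panel allele are excluded from $n_i$
  (the model is biallelic); whether to count third-allele bases is
  likewise a convention, and exclusion is the conservative one.
* Base quality below Q20 excludes a base (the usual `-Q 20` pileup
  filter); mapping quality must be filtered upstream when the pileup is
  generated, since pileup text has no per-base MAPQ.
* Every stochastic function takes a `seed` and is bit-reproducible under
  it on a given platform; internal replicate seeds are derived from the
  master seed and stay below $2^{31}$.

## Problem sizes used in the shipped experiments

The test-suite and acceptance experiments run at desk scale, chosen so
each completes in minutes on one core while leaving the conclusions
qualitatively stable: a 1.5-million-site panel for the coverage sweep
(mean per-site depths $10^{-5}$–$10^{-3}$, 25 replicates per tier, 100
candidates), 2,000 null scores at ~350 bases for calibration, 200
Mendelian trios at ~500 bases for the relatedness ordering, 200 queries
at ~1,200 bases for two-population ancestry, and 100 simulated samples
per sex at ~20,000 reads. Headline cohort figures reported for real
data (sensitivities and accuracies over hundreds of individuals at
tens of millions of reads) require the original cohorts and are not
reproduced here; the shipped experiments verify the analytic values,
the oracle equivalences, calibration, and the shape of the power
surface.

## Known limitations

* The normal P value leans on the central limit theorem across sites;
  with very few covered sites (tens) the empirical P value is the safer
  choice.
* Related individuals inflate the null rate: a parent or child shares
  half the genome and scores between unrelated individuals and the
  donor, which is exactly what the trio experiment quantifies — the
  method detects *genomes*, not persons, and monozygotic twins are
  indistinguishable by construction.
* Heavy non-host human contamination (e.g. 50:50 mixtures) biases the
  score toward whichever contributor dominates; the mitochondrial
  non-major-allele fraction ([nonmajorAlleleFraction()]) flags such
  samples but does not decompose them.
* The sex model is binary by design and will misreport karyotype
  anomalies (XXY, X0) as one of the two classes.
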