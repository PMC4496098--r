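---
title: "Autozygosity mapping with autozyg: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity mapping with autozyg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The problem

Intense directional selection with artificial insemination concentrates the
gene pool of dairy cattle in a handful of elite sires. The resulting
inbreeding raises autozygosity — stretches of the genome where both
chromosomes descend from a single ancestral copy — and with it the risk
that recessive deleterious alleles are expressed in fitness traits such as
fertility (daughter pregnancy rate, DPR) and udder health (somatic cell
score, SCS). `autozyg` provides a complete, tested tool chain for studying
this process from SNP-array data: detecting runs of homozygosity (ROH),
comparing genomic with pedigree inbreeding, locating the genomic regions
whose autozygosity moves with inbreeding, birth year or trait transmitting
abilities, and decomposing ROH into haplotype-level homozygosity to ask
whether an association is better explained by an additive or a recessive
gene action.

Because array cohorts of this kind are rarely public, the package also
contains a first-class synthetic-data generator — a pedigree simulator and
a gene-dropping engine with exact identity-by-descent tracking — so every
stage of the analysis can be validated end to end against a known truth.

## Models and procedures

### Quality control

Standard array screens are applied in a fixed order: individuals with
≥ 20 % missing genotypes are removed first; then SNPs with call rate
≤ 0.8, minor allele frequency ≤ 0.01 (computed on non-missing calls), and
SNPs whose Hardy–Weinberg test reaches −log10 p ≥ 3. The HWE test is the
exact conditional test on the heterozygote count given the allele counts —
the default of the standard whole-genome toolkits and robust at low MAF —
with a 1-df chi-square variant behind a flag. The order matters only at
the margins, but it is fixed and logged so that QC reports reconcile
exactly (`in − removed = out` on both axes). The filter thresholds are
deliberately strict inequalities (MAF > 0.01 keeps, MAF = 0.01 removes),
matching the usual convention. QC is idempotent: re-running it on its own
output removes nothing.

One caveat is inherited from practice rather than fixed: HWE filtering is
computed on all retained individuals, although they are related. Relatives
deflate the effective sample and distort HWE p-values slightly; founders-
only filtering would need pedigree information inside QC and is not
attempted.

### Pedigree inbreeding

Wright's coefficient F of an animal is the kinship of its parents.
Kinship is computed by the tabular method: animals are ordered parents
first, each new row is the average of the parental rows, and the diagonal
is ½(1 + F). The recursive per-pair formulation is mathematically the
same; the tabular form was chosen because it vectorises cleanly in R and
avoids deep recursion on long pedigrees. Any animal with an unknown (or
unrecorded) parent has F = 0 — the classic "founders are unrelated and
non-inbred" convention. This convention is also a known bias: if founders
are cryptically related, pedigree F underestimates true autozygosity. The
package reproduces the bias rather than correcting it, because comparing
FPED with genomic FROH is exactly how that bias is studied.

### Runs of homozygosity and FROH

The calling rule is deliberately literal: a run is a maximal stretch of
consecutive homozygous genotype calls on one chromosome, and a segment is
reported when it contains at least `min_snps` SNPs (default 50, roughly
2–3 Mb at 50K-array density) or, in the alternative length mode, spans at
least `min_bp` (3 or 5 Mb are conventional). Heterozygous calls always
break a run; missing calls break a run too unless a per-run allowance is
granted (`max_missing_in_run`, default 0 — strict is conservative, and the
allowance is exposed for sensitivity analysis). No heterozygote allowance
exists at all: unlike some human protocols the rule is pure consecutive
homozygosity. Runs never join across chromosomes, and physical gap size
does not break a run — the logic is SNP-count based, which in sparse
regions can let a run bridge a large physical gap; reported segment spans
make this visible.

From the segments, the binary state matrix `H` (individuals × SNPs, 1 =
SNP inside an ROH of that individual) is the central object: its row
means are FROH, the genomic inbreeding coefficient (fraction of genotyped
SNPs inside ROH), and its column means are the locus autozygosity F_L. A
length-based FROH (covered bp over map span) is provided for comparisons
across by-length rules. The expected length of a segment inherited from a
common ancestor g generations back is 100/(2g) cM — with the cattle rule
of thumb of 1 cM ≈ 1 Mb, a 10-generation-old ancestor contributes ~5 Mb
segments, which is why a ~2 Mb (50-SNP) threshold targets inbreeding in
the last ~10–25 generations.

### Stratification covariates

Principal components are computed on the mean-centred `H` (and, for
comparison, on genotype dosages with per-column mean imputation).
Columns are not variance-scaled by default: ROH states are binary, and
scaling would inflate rarely autozygous loci; a scaled variant sits
behind a flag. Each component's sign is fixed by making its largest
loading positive, so score files are bit-reproducible. Five components
are the default covariate set in adjusted models. Low-dimensional
structure in `H` largely reflects the inbreeding gradient itself, so the
first component typically correlates strongly with F — which is precisely
why PC-adjusted association results must be interpreted with care, and
why both raw and adjusted profiles are always produced.

### Locus-level association and permutation thresholds

Every association model in the package is the same ordinary least squares
fit: response (FPED, birth year, or a trait PTA) on one locus state
(binary ROH state, or haplotype dosage) plus optional PC covariates, with
a two-sided t test on the locus slope at n − p − 2 degrees of freedom.
The engine residualises the response and all locus columns on the
covariates once (Frisch–Waugh), so a genome scan is two cross-products;
`lm()` is used in the test suite as an independent oracle, never in the
scan itself. Degenerate loci (constant within the complete cases, or
collinear with covariates) yield NA rather than errors, and −log10 p is
capped at 300 to keep perfect fits finite. Trait PTAs are treated as
pre-adjusted responses: any mixed-model polygenic adjustment belongs to
PTA estimation upstream and is out of scope here — a deliberate and
visible limitation.

Genome-wide thresholds come from the maximum-statistic permutation
scheme: the response alone is shuffled across individuals (covariates
stay attached to their individuals, preserving covariate–locus structure
under the null), the scan is rerun, and the largest defined −log10 p of
each permutation is kept. The suggestive and significant thresholds are
the 95th and 99th percentiles of that distribution over (by default)
1,000 permutations under a fixed seed. Undefined loci never enter the
maximum. The permutation engine requires a missing-free locus matrix —
true of `H` by construction; per-permutation complete-case juggling would
defeat vectorisation for no primary use case.

Regions are called from a profile by grouping threshold-exceeding SNPs
per chromosome, merging groups separated by at most 1 Mb (the merge gap
is configurable; no standard exists) and dropping regions spanning less
than 1 Mb; each region reports its peak SNP (ties to the smallest
position), peak slope, peak F_L and the companion ROH–FPED statistic at
the peak, both raw and PC-adjusted companions being available. Effect
profiles of different responses are compared by the Pearson correlation
of per-SNP slopes over the SNPs defined in both.

### Haplotype windows

Phased haplotypes (phasing itself is upstream and out of scope; input is
a two-rows-per-individual 0/1 table) are cut into windows of exactly 50
SNPs. The step is a genuine free choice the package exposes twice: step =
window (non-overlapping) for genome-wide catalogue summaries, where each
SNP contributes once, and step = 1 for fine mapping. Window alleles are
exact 0/1 strings — no mismatch tolerance, which is correct for synthetic
data and a documented limitation for real phased data with switch errors.
Alleles are ranked by descending frequency (ties broken by first genomic
occurrence); expected homozygosity of an allele is its squared frequency,
observed homozygosity the fraction of individuals whose two window
haplotypes both equal it, and the total observed haplotype homozygosity
(HH) of a window is the fraction of individuals with two identical window
haplotypes. Note a reporting subtlety: squaring a mean frequency is not
the mean of squared frequencies, so a table of mean-frequency and
mean-expected-HH columns will not satisfy the square relation exactly row
by row; the package emits per-window values so either summary can be
formed.

The window-level association models mirror the SNP-level machinery: the
additive model regresses the trait on the number of copies (0/1/2) of the
window's most frequent allele, the recessive model on the homozygote
indicator. ROH is the sum of homozygosity over all alleles, so the
additive effect of a specific haplotype is inestimable from ROH alone —
decomposing into the most frequent allele is exactly what makes the
additive/recessive comparison possible.

## The synthetic cohort

The generator is not a mock: it defines the study conditions under which
the package's claims are tested.

**Pedigree.** Generation 0 holds 60 unrelated founders. Each of 10
subsequent generations draws a team of 4 sires from the males of the two
preceding generations, adds 12 fresh unrelated dams (the wider,
unrecorded cow population — also the reason many animals have F = 0, as
in real pedigrees with missing ancestors), and produces 60 calves.
With probability 0.15 a mating deliberately turns toward kin: the dam is
drawn with probability proportional to her kinship with the chosen sire.
These defaults were fixed once, by a short tuning pass of the mating
parameters (the inbreeding they generate is an emergent property that
cannot be written down in closed form), so that non-founder F spans
roughly 0–0.3 with mean ≈ 0.04 and a long right tail — the shape of a
sire-limited AI population. An optional truncation-selection mode picks
sires by an infinitesimal-model breeding value instead of at random.

**Genome and gene drop.** 10 chromosomes × 100 Mb × 1,500 evenly spaced
SNPs (15 SNPs/Mb ≈ 68 kb spacing, a 50K bovine array after QC, at
desk scale; a 29-chromosome configuration is a parameter change).
Founder haplotypes draw alleles independently per SNP from a uniform MAF
spectrum on [0.05, 0.5], which creates chance homozygosity even without
inbreeding. Transmission recombines parental haplotypes with
Poisson-Haldane crossovers at 1 cM/Mb — no interference, so the
expectations used in tests are exact. Founder haplotypes carry unique
labels that travel with the alleles; true autozygosity at a SNP is label
identity, giving every downstream claim a ground truth. Traits add
additive effects × dosage, recessive effects × true-autozygosity
indicator (DPR-like negative at BTA3-like 40 Mb, effect −0.4; SCS-like
positive), and Gaussian noise (sd 0.25, so a planted recessive effect is
detectable but not trivial at n = 600).

**What the simulation does not emulate** — and hence what green tests do
not establish about real data: founder linkage disequilibrium and
realistic allele-frequency spectra (founders are in linkage equilibrium,
so chance ROH are rarer than on a real array), genotyping error,
non-random missingness, phasing switch errors, crossover interference,
selection on the measured traits, and the mixed-model machinery behind
real PTAs. Conclusions about method behaviour under those features need
real data or a richer simulator.

## Numerical choices

* Genotypes are coded 0/1/2 with `NA` for missing; the PED reader fixes
  the reference allele per SNP as the first observed allele, so codes are
  defined up to a per-SNP relabelling 0 ↔ 2 (round-trip tests assert
  exactly that equivalence).
* The exact HWE test computes the heterozygote-count distribution by a
  normalised log-space enumeration; p-values accumulate probabilities
  ≤ the observed one with a 1e−10 relative guard against ties lost to
  floating point.
* OLS: loci with residualised sum of squares below `sqrt(eps) · n` are
  declared degenerate; residual sums of squares are floored at 0;
  p-values are computed on the log scale (`pt(..., log.p = TRUE)`) so
  extreme statistics do not underflow before the −log10 p cap at 300.
* PCA uses the eigendecomposition of the smaller Gram matrix side;
  components with vanishing singular value are zeroed and flagged.
* Permutation thresholds use R's default (type 7) quantile on the max
  distribution; fewer than 100 permutations triggers an instability
  warning. All randomness flows through explicit integer seeds; derived
  seeds stay within 32-bit range.
* Region peaks break −log10 p ties by smallest genomic position.

## Problem sizes used in the packaged checks

The test suite and the acceptance script run at desk scale, chosen so the
full chain exercises every code path on one CPU in minutes: the default
cohort (780 animals, 15,000 SNPs) for the FPED–FROH correlation, planted-
locus recovery and PC checks; a 340-animal, 2,000-SNP cohort with 200
permutations and 200 fresh null responses for threshold calibration; 400
independent full-sib families for the Mendelian 25 % autozygosity check;
and oracle comparisons (brute-force run scanning, path-counting F, `lm`,
string counting) at hundreds of random instances each. The acceptance
script averages the FPED–FROH correlation over three seeds derived from
its `--seed` argument.

## Known limitations

* Pedigree F assumes founders unrelated; the package measures, rather
  than removes, the resulting downward bias relative to FROH.
* SNP-count ROH calling is density-dependent: in regions of sparse
  coverage a 50-SNP run may span far more than the nominal ~2–3 Mb.
* PTAs are consumed as-is; no mixed-model or GRM adjustment is performed
  inside the association scans.
* Haplotype windows assume error-free phased input.
* The permutation engine requires complete locus matrices.

## A minimal session

```{r example, eval = FALSE}
library(autozyg)

sim <- simulate_cohort(sim_config(), seed = 1)
fped <- compute_fped(sim$pedigree)
seg  <- detect_roh(sim$genotypes, roh_definition(min_snps = 50))
H    <- roh_state_matrix(seg, sim$genotypes)
cor(fped[rownames(H)], froh(H))          # FPED vs FROH

pc   <- structure_pca(H, k = 5, source = "roh-states")
scan <- genome_scan(fped[rownames(H)], H, map = sim$map,
                    response_name = "FPED")
thr  <- permutation_thresholds(fped[rownames(H)], H, n_perm = 1000, seed = 1)
call_regions(scan, thr, f_l = locus_autozygosity(H))
```

Or, end to end with files on disk:

```{r pipeline, eval = FALSE}
run_pipeline(default_pipeline_config(), out_dir = "run1", seed = 1)
```
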