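---
title: "Models and design choices in asexdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in asexdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asexdiv)
```

## The scientific question

Obligately asexual lineages have stopped recombining genome-wide. Three
consequences are predicted. First, GC-biased gene conversion (gBGC) — the
repair bias that favours G/C over A/T alleles during meiotic recombination —
should arrest, so base composition drifts back towards the mutational
equilibrium. Second, the amount of polymorphism segregating in populations
should change (in practice, drop, through background selection and loss of
genotype diversity). Third, purifying selection should become less
effective, because linked selection interferes among loci, so mildly
deleterious nonsynonymous variants both segregate longer (higher pN/pS) and
fix faster (higher dN/dS).

`asexdiv` implements a complete comparative pipeline for testing these
predictions in paired sexual/asexual sister species — per-gene codon
alignments across a fixed species tree plus pooled-population SNP data per
species — together with a simulator that generates all of those inputs with
known ground truth. The packaged default tree has ten tips in five
sexual/asexual pairs, patterned on the *Timema* stick-insect system in
which all five asexual lineages arose independently and differ in age.

## Equilibrium GC3: a nonstationary two-state model

Third codon positions are recoded as strong (S = G/C) versus weak
(W = A/T) and modelled as a two-state Markov chain along the rooted tree.
On a branch with equilibrium strong frequency $\theta_b$ and scaled length
$v = \rho\,t_b$ the transition probabilities are the binary analogue of
Felsenstein's F81 chain,

$$P(W \to S) = \theta_b (1 - e^{-v}), \qquad
  P(S \to S) = \theta_b + (1 - \theta_b)e^{-v},$$

so $\theta_b$ is exactly the GC3 the branch's substitution process would
reach if run indefinitely. The likelihood is computed by pruning over
site patterns pooled across genes; because all genes share the tree and
parameters, pooling patterns is identical to summing per-gene
log-likelihoods (the alternative — concatenation — is the same computation
here). Two models are fitted by bounded maximum likelihood
($\theta \in [10^{-4}, 1-10^{-4}]$ on a logit scale, relative tolerance
$10^{-8}$, three optimisation starts):

* **stationary**: one shared $\theta$ for the root and every branch, plus a
  global rate multiplier $\rho$;
* **per-branch**: one $\theta_b$ per branch plus a free root frequency and
  the shared $\rho$.

The likelihood-ratio statistic is referred to a $\chi^2$ with degrees of
freedom equal to the difference in free parameter counts — the number of
branches (18 for the ten-taxon tree). Calibration on stationary
simulations (400 columns on a four-taxon tree, 500 replicates) puts the
empirical type-I error at the nominal 5% within Monte-Carlo error; this is
part of the test suite. Arrested gBGC predicts
$\hat\theta_{\mathrm{asex}} < \hat\theta_{\mathrm{sex}}$ within every pair.

This is a deliberate simplification of the four-state nonhomogeneous
(NHML-style) machinery used in the primary literature: a two-state chain
captures the one quantity of interest — branch-specific equilibrium GC —
with far less machinery, at the cost of ignoring transition/transversion
structure within the strong and weak classes.

## Mapping substitutions: parsimony, and the W→S / S→W spectrum

Ancestral sequences are reconstructed column-wise by Fitch parsimony with a
deterministic resolution rule (prefer the parent's state; otherwise the
first state in the fixed order A < C < G < T), so reconstructions are
reproducible. Columns containing a gap or ambiguity code in any tip are
excluded from mapping. On simulations at the packaged divergences, over
90% of true single-hit substitutions are assigned to the correct branch
(tested); parsimony does undercount multiple hits as divergence grows,
which is why the packaged tree keeps terminal branches short. This
replaces empirical-Bayes substitution mapping under a codon model; the
trade is transparency and zero dependencies for a small loss of accuracy
deep in the tree.

Synonymous substitutions on terminal branches are classified as
weak-to-strong (A/T → G/C), strong-to-weak (G/C → A/T) or GC-conservative
(A ↔ T, G ↔ C). Codon pairs differing at several positions are resolved by
enumerating every ordering of the changed positions through sense codons:
if every such ordering keeps all steps synonymous the step categories are
counted with weight 1/(number of orderings), otherwise the codon is
excluded and logged — a conservative rule that never manufactures
synonymous counts from ambiguous paths.

## dN/dS by counting

Per-branch $\omega$ is computed by Nei–Gojobori (1986) counting on each
(parent, child) pair from the reconstruction: synonymous and nonsynonymous
*sites* are fractional counts over the sequence (stop-creating mutations
count as nonsynonymous, so N + S = 3 × codons), averaged over the two
sequences; observed differences in multi-position codons are averaged over
all stop-free mutational paths; the per-site proportions are Jukes–Cantor
corrected ($d = -\tfrac34\log(1 - \tfrac43 p)$, with $p \ge \tfrac34$
flagged as saturated and excluded). This is the counting analogue of a
"free" branch model (one $\omega$ per gene × branch); the three-ratio
summary pools counts within asexual-terminal, sexual-terminal and internal
branch classes. Counting underestimates absolute $\omega$ when transitions
are common (it ignores the transition/transversion bias that maximum
likelihood models), but sexual/asexual *contrasts* are preserved — on
simulations with a 1.2-fold contrast the pooled three-ratio recovers it
within sampling error, which is verified in the test suite. Gene-level
filtering mirrors standard practice: genes with no substitutions, no
synonymous substitutions, or pooled $\omega \ge 1$ are removed (with
per-reason counts), because only genes under purifying selection are
interpretable for this contrast. Gene-level $\omega$ for the filter comes
from pooled counts, not a mean of branch ratios, which would be unstable
when branch dS is tiny; both count-pooled and equal-gene-weight summaries
are reported by the three-ratio function.

## Polymorphism from pooled reads

Pileup sites are filtered with the conventional pooled-sequencing
thresholds — coverage ≥ 20, minor-allele read fraction ≥ 10%, mean phred
≥ 20 — keeping only biallelic sites (tri-allelic sites are dropped and
logged, matching the behaviour of standard pooled SNP callers). Minor
allele frequency is computed from read counts, not genotypes; the pooled
sample the design emulates (three diploid females, six haplotypes) would
put true frequencies on a grid of sixths, but we model frequency
continuously on [0.1, 0.5] — with ≥ 20-fold coverage the read-level
binomial noise dominates the grid anyway. Kept variants are classified
through the genetic code (synonymous iff the amino acid is unchanged;
stop-creating variants are nonsynonymous and flagged) and annotated with
the fold degeneracy of their position. Per gene,
$pN = n_{\mathrm{nonsyn}}/N_{\mathrm{sites}}$ and
$pS = n_{\mathrm{syn}}/S_{\mathrm{sites}}$ with the same Nei–Gojobori site
normalisation as the divergence side (a raw-count mode is provided for
comparison); the ratio is undefined when $pS = 0$ rather than imputed.
The per-species summary reports the fraction of transcripts with at least
one SNP and, among transcripts with SNPs, the median per-transcript
proportion of variable sites with a seeded percentile-bootstrap interval
(5,000 replicates by default). The denominator of the variable-site
proportion is the ungapped ORF length — transcript length including UTRs
would be an alternative; the ORF is what the alignments define.

## Codon usage: Enc and CDC

The effective number of codons uses Wright's estimator: per amino acid
with $n \ge 2$ observations, $F = (n\sum p_i^2 - 1)/(n-1)$; class means
$\bar F_k$ over the 2-, 3-, 4- and 6-fold amino acids; and
$\mathrm{Enc} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
clamped to [20, 61]. The sixfold amino acids (Leu, Ser, Arg) are kept as
their own class, which is what makes the analytic bounds exact: a gene
using one codon per amino acid scores exactly 20, equal synonymous usage
scores 61 (some codon-usage software instead splits sixfold families into
2+4 sub-families; that convention changes neither bound but gives slightly
different interior values). When no threefold amino acid is observed,
$\bar F_3$ is imputed as $(\bar F_2 + \bar F_4)/2$ per Wright; a gene
missing any other entire class is flagged undefined rather than guessed.

The codon deviation coefficient measures how far observed usage deviates
from what the gene's own composition predicts. Per codon position $i$ the
observed GC share $g_i$ and purine share $a_i$ imply base probabilities
$P(G) = g_i a_i$, $P(C) = g_i(1-a_i)$, $P(A) = (1-g_i)a_i$,
$P(T) = (1-g_i)(1-a_i)$ (floored at $10^{-6}$ for degenerate
compositions); expected codon usage is the product over positions,
renormalised within each amino-acid family so that amino-acid composition
itself cannot contribute; and
$\mathrm{CDC} = 1 - \cos(\text{observed}, \text{expected}) \in [0, 1]$.
A usage vector equal to its own expectation — constructible as the fixed
point of the composition → expectation map — scores 0 to numerical
precision (tested to $10^{-6}$).

## The inference layer

The permutation ANOVA tests a per-gene, per-species response against
`gene`, `pair`, `mode` and `pair:mode` with sequential (type-I) sums of
squares in that order, and obtains factor p-values by unrestricted
permutation of the raw response, recomputing all F statistics each time:
$p = (1 + \#\{F^* \ge F\})/(B + 1)$ with $B = 5000$ by default. Raw-response
permutation is the simplest exchangeability-based scheme and calibrates at
the nominal level on null simulations (600 replicates at $B = 200$ in the
test suite); a Freedman–Lane residual-permutation variant is available for
settings with strong nuisance effects. Implementation-wise the factor
blocks are orthonormalised once and all permutations are scored with one
matrix product, so $B = 5000$ on thousands of rows costs seconds. Paired
sexual/asexual summaries get two-sided paired t tests (df = pairs − 1)
and Wilcoxon signed-rank tests; bootstrap intervals are seeded percentile
intervals; and age correlations are Pearson product-moment tests with a
warning attached whenever they rest on five pairs, since a single old
lineage can drive them.

## The simulator

Coding sequences evolve along the annotated tree by a continuous-time
(Gillespie) codon substitution process. A single-nucleotide codon change
has rate

$$\mu \cdot \kappa^{[\mathrm{ts}]} \cdot \omega^{[\mathrm{nonsyn}]} \cdot
  (1+b)^{[\mathrm{syn\,W\to S}]} \cdot (1+b)^{-[\mathrm{syn\,S\to W}]},$$

with stops unreachable and $\mu = 1/(2+\kappa)$ so that one unit of branch
length is one expected neutral substitution per nucleotide site. The
unbiased baseline is symmetric, so with $b = 0$ a 50% GC composition is
stationary and gBGC is the only compositional force — that is what makes
$b$ interpretable as the simulated gBGC intensity. Root sequences draw the
third-position strong/weak class first and resample only the first two
positions when a stop would form, so realised root GC3 is unbiased for the
target. No indels are simulated: the pipeline analyses curated, gap-poor
alignments, and alignment curation is out of scope.

Polymorphism is laid on tip sequences post hoc rather than via a
coalescent: segregating sites are placed at the mode's configured density,
each drawing its effect first (nonsynonymous with the mode's configured
probability) and then a site offering that effect, a true minor-allele
frequency uniform on [0.1, 0.5], negative-binomial read depth, binomial
allele counts and Gaussian mean base quality; sub-threshold noise sites
(low coverage, low frequency, or low quality) are emitted alongside to
exercise the filters. This is sufficient to validate classification,
filtering and the pN/pS contrast, but it does not model linkage, allele
frequency spectra, or shared ancestry of variants — a documented
limitation.

All randomness flows through substreams keyed by (seed, gene, stage), so
any gene or stage can be regenerated independently and the whole study is
a deterministic function of the seed.

### Default study conditions and why

| Parameter | Default | Rationale |
|---|---|---|
| tree | 10 tips, 5 pairs; tip lengths 0.004–0.025, internal 0.02–0.06 | transcriptome-scale divergences for sister pairs of increasing age; youngest pair most recently derived |
| $\kappa$ | 2 | typical transition/transversion rate ratio |
| $\omega$ sexual / internal | 0.15 | genes under purifying selection |
| $\omega$ asexual | 0.18 | a 1.2-fold relaxation, the size of effect reported for real sexual/asexual contrasts |
| $b$ sexual / internal | 0.3 | moderate gBGC: equilibrium GC3 ≈ 0.63 at fourfold sites, a realistic shift from the 0.5 mutational equilibrium |
| $b$ asexual | 0 | arrested gBGC |
| gene-level $b$ multiplier | lognormal, sd 0.5 | genes experience different recombination rates; shared by the gene's UTR, which is what creates the positive GC$_{UTR}$–GC3 correlation across genes |
| root GC3 | 0.5 | the mutational equilibrium of the symmetric baseline |
| $\theta$ (segregating sites/kb) | 2.0 sexual / 0.25 asexual | an 8-fold difference in transcripts containing SNPs |
| fraction nonsynonymous | 0.3 sexual / 0.5 asexual | roughly doubles pN/pS in asexuals |
| coverage | NB(mean 50, size 10) | pooled RNA-seq depth with realistic overdispersion |
| mean phred | N(35, 3) | modern base qualities; noise sites are pushed below the filters |

### What the tests show — and what they do not

The recovery suite runs the full pipeline on 500 genes × 100 codons and
checks that the equilibrium-GC3 ordering, the polymorphism ordering and
the pN/pS ordering are recovered in all five pairs, and that the pooled
three-ratio $\omega$ contrast lands near the simulated 1.2. At this scale
the terminal branches carry only on the order of a thousand nonsynonymous
substitutions per mode class, so the $\omega$-ratio estimate has a
Monte-Carlo standard error of roughly 6%; individual simulation draws can
land outside a ±0.1 band around the truth even though the estimator
tracks each draw's own realised count ratio closely. Passing these tests
shows the machinery is correct and the effects detectable under the
generator's assumptions; it does not validate the pipeline against
alignment error, assembly artifacts, orthology mistakes, expression-level
biases or demographic history, none of which the simulator emulates.

### Numerical and degenerate-input choices

* Jukes–Cantor distances abort with a classed saturation error at
  $p \ge 3/4$; saturated genes are skipped (and counted) in pair ranking,
  and saturated branches are flagged and excluded from $\omega$.
* Gapped or ambiguous columns are pairwise-deleted for distances and GC3
  (the convention for gapped codons is otherwise undefined), excluded from
  parsimony mapping, and skipped in codon counting.
* Equilibrium-GC fits that fail to converge from any start are returned
  flagged (`converged`), never silently.
* Ties: ranking ties break by pair id; Fitch ambiguities break by the
  fixed base order; bootstrap and permutation streams are always seeded.
* All coordinates are 0-based half-open internally; serialised outputs
  (VCF input, reports) use the 1-based conventions of their formats.

### Problem sizes used by the packaged checks

Unit tests run on toy alignments and simulations of 10–60 genes; the
recovery experiment uses 500 genes × 100 codons (about four minutes on one
CPU); calibration uses 600 null ANOVA replicates at $B = 200$ and 500 null
LRT replicates at 400 columns. These sizes were chosen so the whole suite
exercises every claim at desk scale while leaving the statistical
conclusions unambiguous.
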