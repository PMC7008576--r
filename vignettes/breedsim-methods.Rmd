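---
title: "Models and methods in breedsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in breedsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedsim)
```

`breedsim` simulates breeding programs forward in time from a panel of
phased founder genotypes. This vignette documents the models it implements,
the choices made where several reasonable implementations exist, and what
the package's own verification does and does not establish.

## The block representation of genomes

Every allele in a simulation originates in the founder haplotype matrix: a
SNP × haplotype 0/1 matrix with `ploidy` columns per founder. An
individual's genome is a list of homologs per chromosome, each homolog an
ordered sequence of half-open blocks `(start, end]` labelled with the
founder haplotype they descend from. Meiosis only ever cuts and reassembles
blocks, so no new alleles appear (mutation is out of scope) and memory does
not grow with SNP density. Genotypes are decoded on demand: per homolog, a
binary search finds the covering block and the founder matrix supplies the
allele; dosages are sums over homologs.

Two conventions matter for correctness and are therefore fixed:

* Blocks are half-open on the left. A SNP at position `x` belongs to the
  block with the smallest `end >= x`. Crossover positions drawn between two
  SNPs can be fractional; the same rule applies unchanged.
* Adjacent blocks with the same founder haplotype are fused after each
  meiosis. Normalization cannot change decoded genotypes (the test suite
  asserts this indirectly by comparing decodes against an independent
  full-allele propagation oracle).

## Meiosis

Per chromosome and meiosis:

1. Homologs are paired at random into ploidy/2 bivalents (a uniform random
   partition, drawn independently per chromosome and meiosis). Preferential
   pairing and double reduction in polyploids are not modelled.
2. Each bivalent receives a crossover count drawn from Poisson(L), where L
   is the chromosome's genetic length in Morgans under the parent's
   sex-specific map. There is no obligate chiasma and no interference;
   zero crossovers is a legitimate outcome.
3. Crossover positions are uniform in *genetic* coordinates and mapped back
   to base pairs through the inverse map, so local recombination rates
   follow the map by construction.
4. One strand per bivalent, starting from a uniformly chosen member of the
   pair and switching at every crossover, enters the gamete. This yields
   exactly ploidy/2 homologs per gamete; making both strands available
   would be an equally defensible reading of standard meiosis descriptions,
   but the one-strand rule is simpler and has the same marginal
   distribution per transmitted homolog.

Sex chromosomes are capped at two copies regardless of autosomal ploidy.
A male transmits his X or his Y intact with probability 1/2 (the Y is
non-recombining by definition and the male X has no pairing partner — no
pseudo-autosomal region is modelled); a female recombines her two X copies
as an ordinary bivalent. Offspring sex is determined by the transmitted
paternal chromosome, so the 1:1 ratio is a consequence, not an input.
Mitochondria are transmitted maternally and intact. A genetic map can be
all-zero for one sex, which is the supported way to model achiasmate males
(as in *Drosophila*); no special flag exists.

Dihaploids duplicate a single maternal-type gamete and are therefore
homozygous at every SNP; they are restricted to diploids.

## Recombination maps

Maps are cumulative-cM anchor lists per chromosome and sex, linearly
interpolated between anchors; beyond the last anchor the final segment's
rate is extrapolated to the chromosome end. Without a map, the default is
1 cM per Mb everywhere. Physical→genetic conversion and its inverse are
exact functional inverses on segment interiors; plateaus (zero local
recombination) invert to their leftmost base pair, which is immaterial
because crossovers are drawn in genetic coordinates and land in a plateau
with probability zero. Chromosome lengths default to the last SNP position
when no map provides more.

## Founder input

VCF input auto-detects ploidy from the GT field (it must be uniform),
treats within-call allele order as phase (the intended inputs are phased or
inbred sequence panels), drops multi-allelic sites, and imputes missing
allele calls by drawing allele 1 with the site's observed frequency — the
simulator needs complete haplotypes, and this choice preserves frequencies
in expectation; seed the RNG for reproducibility. The plink-like dialect is
deliberately narrow: classic 6-column PED plus 4-column MAP, diploid only,
first-observed allele coded 0; polyploid data must come as VCF.

Small founder panels can be expanded with "dummy" base individuals, either
by gene-dropping down a short random pedigree (depth 2 — random founder
grandparents, then parents, then the dummy; the depth is a package choice,
as any shallow pedigree serves the purpose) or by drawing Poisson
breakpoints per homolog and assigning random founder haplotypes to each
block. Both modes only recombine existing founder material.

## Genetic architecture and phenotypes

The genotypic value of individual *i* is, for diploids,
$g_i = \sum_j \gamma_{ij} a_j + \sum_j \delta_{ij} d_j$ with
$\gamma \in \{-1,0,1\}$ and $\delta = 1$ for heterozygotes only; for
autopolyploids $\eta_{ij} = \text{dosage} - \text{ploidy}/2$ replaces
$\gamma$ and $\varphi_{ij} = 1$ for every dosage ≥ 1 replaces $\delta$, so
all carriers share the dominance value of the complete '1' homozygote (one
dominance coefficient instead of the ploidy−2 that would be formally
possible).

QTN sets come three ways: random positions among segregating SNPs with
gamma-sampled additive effects; positions from a file with gamma-sampled
effects; or positions plus per-trait additive/dominance effects read
verbatim (the only multi-trait option — zero cross-trait effects give
non-pleiotropic traits, though linkage can still induce genetic
correlation; nothing adjusts correlations automatically). Random modes are
single-trait and additive by construction. QTN stay in the sequence SNP
set; exclude them from a chip to keep causal loci out of evaluation.

Two interpretation choices in the effect sampler are worth stating. The
gamma parameters (shape 0.2, scale 5) are read as shape/*scale* — mean
magnitude `0.2 × 5 = 1` — not shape/rate; and sampled magnitudes get a
random sign with probability 1/2 each, because a one-sided effect
distribution would build directional bias into the founders.

Phenotypes are $y = \mu + g + e$, $e \sim N(0, \mathrm{Var}(e))$, drawn
independently per individual and trait (environmental correlations are
zero). $\mathrm{Var}(e)$ is calibrated once per trait from the *base*
population: $\mathrm{Var}(e) = \mathrm{Var}(g)(1-H^2)/H^2$, with
$\mathrm{Var}(g)$ the population variance (divisor *n*, a determinism
choice) of base genotypic values, dominance included — $H^2$ is broad
sense. Individuals created later are phenotyped at birth under the same
calibration, so heritability in later generations drifts with the genetic
variance, as it should under selection.

The per-QTN variance tables use the allele substitution effect
$\alpha = a + d(1-2p)$ and, for diploids, the one-locus equilibrium
variances $V_A = 2p(1-p)\alpha^2$, $V_D = (2p(1-p)d)^2$. Here $p$ is the
frequency of the '1' allele, which is what the substitution-effect algebra
requires (using the folded minor-allele frequency would flip the dominance
term's sign above 0.5); the folded MAF is reported alongside for plotting.
For polyploids no standard closed form exists at arbitrary ploidy, so the
package reports empirical variances from the genotype frequencies of the
evaluated individuals instead.

## Genetic evaluation

Four methods share one mixed-model core. Mass selection uses the phenotype
itself. Pedigree BLUP uses the numerator relationship matrix A from the
tabular recursion with founders unrelated and non-inbred. GBLUP uses
VanRaden's first G on the chip dosages, generalized to autopolyploids by
centring dosages at $k p_j$ and dividing by $k \sum_j p_j(1-p_j)$ with
$k$ = ploidy (at $k = 2$ this is exactly the standard diploid formula).
Frequencies are computed from the evaluated individuals themselves, not
the founders — a declared choice; with everyone genotyped the two differ
only through drift. G's diagonal is multiplied by 1.05 against
singularity. Single-step GBLUP uses the basic
$H^{-1} = A^{-1} + \mathrm{block}(G^{-1} - A_{22}^{-1})$ without τ/ω
weighting or additional blending beyond the 1.05 safeguard; it reduces
exactly to GBLUP when everyone is genotyped and to pedigree BLUP when no
one is.

The mixed model is a single-trait animal model whose only fixed effect is
an overall mean (the simulator generates no systematic environment), with
shrinkage $\lambda = (1-h^2)/h^2$ from a *user-supplied* heritability —
variance components are never estimated. EBVs are returned for every
individual in the relationship matrix, phenotyped or not. An export/import
pair writes chip dosages and phenotypes as TSV and reads back id/value EBV
files, so external evaluation software can stand in for the built-in
methods.

## The selection cycle

Each cycle evaluates (by default on all individuals simulated so far),
truncates within sex (top `n_females` and `n_males` by EBV, ties broken by
ascending id — reproducibility over realism), mates, and phenotypes the
offspring immediately; the alternative of phenotyping just before the next
evaluation would only relabel the time axis. Discrete generations restrict
candidates to the newest cohort; continuous generations admit every
individual not already used as a parent (no age-structure culling beyond
that). Mating is hierarchical by default — each selected sire receives
⌈n_females/n_males⌉ dams, remainder to the top sires — with random
(uniform sire per dam) and assortative (rank-matching on EBV) variants.
Offspring sex follows the transmitted sex chromosome, or a 1:1 draw
without one. The per-generation summary reports cohort means/variances of
y and g and the realized accuracy cor(EBV, g) among candidates — a
diagnostic the simulator can compute because it knows g.

## The synthetic founder generator

`make_fixture()` writes a VCF (plus map, pedigree, QTN and chip files
exercising every reader) with per-SNP allele-1 frequencies drawn from
Uniform(0.05, 0.95) and founder haplotypes sampled independently per site —
unrelated founders in linkage equilibrium. That is deliberately idealized:
real panels have LD, relatedness, rare alleles and missing data. An
optional mode builds each founder haplotype as a mosaic of a small shared
haplotype pool, giving block LD for genomic-prediction experiments (GBLUP
only beats pedigree BLUP when markers tag QTN). Optional X, Y and MT
chromosomes are written with sex-consistent calls, padded to uniform ploidy
with placeholder alleles that never enter any simulated genome (male
founders carry their X in haplotype column one and their Y in column two).
Consequently, passing tests demonstrate correctness of the machinery under
known conditions, not realism of any particular organism's genome; for
realistic studies the intended input is real sequence data.

## Numerical and degenerate-input behaviour

* All randomness flows through R's global RNG: `set.seed()` once makes an
  entire run — pedigree, genotypes, phenotypes — bit-reproducible.
* Monomorphic chip sets make G's denominator zero and are an error;
  monomorphic SNPs in GWAS are reported with effect 0 and p = 1 rather
  than dropped, keeping output rows aligned with the SNP list.
* Y-linked SNPs decode to `NA` in females (missing by structure); such
  structural `NA`s contribute zero deviation in G and zero genotypic value.
* A pedigree individual with exactly one known parent is an error rather
  than silently creating a founder, because that almost always indicates a
  data problem; cycles are detected and rejected.
* `calibrate_var_e()` rejects $H^2 = 0$ and a zero founder genetic variance
  (nothing to calibrate against) except in the trivial $H^2 = 1$ case.
* Singular mixed-model or relationship matrices surface as errors naming
  the offending matrix rather than silently pseudo-inverting.

## Verification scales

The test suite's heavier checks run at the following sizes, chosen to make
sampling error small relative to the tolerances asserted: gamma
method-of-moments recovery on 10⁶ draws (2%); realized heritability on
10,000 base individuals (±0.02 around targets 0.2/0.5/0.8); recombination
rate from 10,000 meioses on a 100-Mb chromosome (5%); block-vs-naive decode
equality on 20-individual, 5-generation pedigrees at ploidy 2 and 4
(exact); EBVs against an independent generalized-least-squares solver on
≤10-individual toys (10⁻⁸); five cycles of mass selection with 500
offspring per generation (strict increase of mean g); GWAS p-values against
the closed-form regression t-test (10⁻¹⁰) and uniformity of null p-values
(KS at α = 0.01).

## Known limitations

No mutation, gene conversion, epistasis, imprinting, crossover
interference, multivalents, preferential pairing or double reduction; no
pseudo-autosomal region; sex chromosomes capped at two copies; single-trait
evaluation only (multi-trait phenotypes simulate fine, but each evaluation
is univariate); no optimal-contribution mating (the mating table from
`return_new_ped()` can be edited by hand); heritabilities are inputs, not
estimates. The simulator targets short horizons — generations to tens of
generations — where the absence of new mutations is defensible; long-term
questions about the maintenance of variability need a different tool.
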