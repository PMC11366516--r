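---
title: "Models and methods behind wssgblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wssgblup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wssgblup` evaluates lowly heritable, repeated-record litter traits by
pedigree BLUP and single-step genomic BLUP, and localizes trait loci with a
weighted single-step GWAS. This vignette explains the models, the numerical
choices, and what the synthetic data generator does and does not emulate.

## The repeatability animal model

Every record (one farrowing of one sow) is modelled as

$$y = Xb + Za + W\,pe + e$$

with fixed effects $b$ (year-season and parity as categorical levels, first
level dropped for identifiability, aliased columns removed by pivoted QR),
additive genetic effects $a \sim N(0, K\sigma^2_a)$ where $K$ is a
relationship matrix over all pedigree animals, one permanent-environment
level per sow with records $pe \sim N(0, I\sigma^2_{pe})$, and i.i.d.
residuals. Heritability is $h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_{pe} +
\sigma^2_e)$: the permanent-environment variance stays in the denominator,
which is why litter traits with repeatabilities near 0.2 still have $h^2$
near 0.1.

$K$ is either the pedigree numerator matrix $A$ (PBLUP) or the single-step
matrix $H$ (ssGBLUP) whose inverse is

$$H^{-1} = A^{-1} + \begin{bmatrix}0 & 0\\ 0 & G^{-1} - A_{22}^{-1}\end{bmatrix}$$

on the genotyped block. $A$ is built by the tabular recursion, $A^{-1}$ by
Henderson's rules with inbreeding (Mendelian sampling variance
$d_i = 0.5 - 0.25(F_s + F_d)$ for two known parents, $0.75 - 0.25F_p$ for
one, 1 for founders). Commercial evaluations differ in whether they account
for inbreeding in these rules; accounting for it is the safer general
default here, and `a_inverse(use_inbreeding = FALSE)` disables it. Unknown
parents are the sentinel `"0"`; unknown-parent groups are not implemented.
Inbreeding is read off the tabular diagonal, which is simple and exact but
quadratic in pedigree size — fine at the package's desk scale (a few
thousand animals).

## Genomic relationships

With centered gene content $Z$ (calls minus $2p_i$, residual missing calls
mean-imputed to $2p_i$) and per-SNP weights $D$,

$$G = \frac{Z D Z'}{\sum_i 2p_i(1-p_i)}.$$

$2p(1-p)$ is symmetric in allele labelling, so the scaling constant is
unchanged whether $p$ is the minor or the counted allele frequency; the
package centers by the counted allele. Because $p$ is computed from the
genotyped animals themselves, the columns of $Z$ sum to zero and $G$ is
singular with the ones vector in its null space. For use inside $H^{-1}$,
$G$ is blended, $G^* = 0.95\,G + 0.05\,A_{22}$, the common single-step
default. No additional tuning of $G$ to the $A_{22}$ means is applied by
default — on simulated data the two matrices agree closely without it — and
both the blending proportion and the tuning are exposed as options.

## AI-REML

Variance components are estimated by average-information REML with an
EM-REML safety net. Each round computes, from one factorization of the
mixed-model equations: the EM updates, the REML scores (via the standard
trace identities against the inverse coefficient matrix), and the AI matrix
(quadratic forms of the projected component-wise fitted vectors, each
needing only one extra solve against the reused factorization). The AI
(Newton) step is accepted only if it stays inside the parameter space and
does not decrease the restricted likelihood, halving it up to three times
before falling back to EM — so the recorded likelihood trajectory is
monotone by construction, which the tests check on every fit. Convergence
is declared when the largest relative component change drops below 1e-8,
with a 200-round cap. Components are floored at 1e-10 times the phenotypic
variance. Standard errors come from the inverse AI matrix at convergence
and the $h^2$ standard error by the delta method; if the AI matrix is
singular or near-singular (reciprocal condition below 1e-10) the fit is
flagged `flat_likelihood` rather than reporting meaningless standard
errors — this is exactly what happens in the non-identifiable case of an
identity kinship with one record per animal.

The permanent-environment block of the coefficient matrix is diagonal, so
it is absorbed analytically and the dense Cholesky runs on the Schur
complement over fixed effects plus animals; the traces the updates need are
recovered from that factorization. This keeps a fit with 1,500 recorded
sows and a 1,800-animal pedigree at a few seconds per round on one core.

## The weighted single-step GWAS loop

Starting from $D = I$: build $G_{(t)} = Z D_{(t)} Z' \lambda$, solve the
MME under $H^{-1}$ for GEBVs, back-solve SNP effects from the genotyped
animals' GEBVs,

$$\hat u = \lambda D_{(t)} Z' G_{(t)}^{-1} \hat a_g,$$

update the weights $d_i = \hat u_i^2\, 2p_i(1-p_i)$, rescale them so
$\mathrm{tr}(D)$ equals the marker count (keeping total genetic variance
constant, with proportions preserved and a floor of 1e-8 preventing a
degenerate all-zero diagonal), rebuild $G$, and repeat — three cycles by
default. The scan uses the final cycle's effects; published workflows vary
between the second and third cycle, so this is configurable.

Two numerical points. First, the back-solve uses the *unblended* weighted
$G$, because that is the matrix algebraically linked to $Z$: then
$Z\hat u = G G^{-1}\hat a$ reconstructs the GEBVs exactly, which is the
loop's self-check. Second, since the centered $G$ annihilates the ones
vector, SNP effects can only represent deviations from the genotyped-group
mean — the group level is not attributable to any marker — so the package
back-solves the mean-centered GEBVs through a pseudo-inverse (a rank-one
shifted Cholesky with iterative refinement, falling back to an
eigendecomposition if the weighted $G$ has lost further rank). The
reconstruction identity $Z\hat u = \hat a_g - \overline{\hat a_g}$ then
holds to machine precision at every iteration, and an error above 1e-6
raises a warning.

## Window scan, significance, annotation

Windows are anchored at every SNP and contain the consecutive SNPs within
0.52 Mb on the same chromosome — the published region tables report ~0.5 Mb
spans at arbitrary offsets, which matches sliding windows rather than a
fixed non-overlapping grid. The statistic is the percentage of additive
genetic variance explained,
$\mathrm{Var}(\sum_j Z_j \hat u_j)/\sigma^2_a \times 100$, computed across
genotyped individuals with population-variance denominator $n$ (an $n-1$
option exists). Windows at or above 1.56% — a 50-fold enrichment over the
0.031% an average window would explain — are significant; overlapping
significant windows merge into regions reported with their span, maximum
percentage and SNP count, with positions rounded to 0.01 Mb only in the
human-readable table. Annotation is a local half-open interval overlap
against a user-supplied BED/GFF3 (a gene starting exactly at a region's end
is excluded); regions with no overlapping gene print `-`. No p-values are
attached: the scan statistic has no sampling distribution in this
framework, which is a known limitation of the approach.

## LD decay

$r^2$ is the squared Pearson correlation of gene content over jointly
non-missing samples — the reproducible genotype-based estimator, equal to
the haplotype $r^2$ under random mating, and invariant to allele-label
flips. All intra-chromosomal pairs within 1 Mb are binned by distance
(10 kb bins); the decay distance is where the binned mean first crosses
0.2, linearly interpolated between adjacent occupied bin midpoints. Empty
bins report zero pairs and an undefined mean, never zero.

## The synthetic data generator

Commercial litter-trait data sets are proprietary, so the generator stands
in for one structurally: a closed herd bred in discrete
generations under a nested mating design; founder marker alleles drawn
independently at frequencies in 0.05–0.5; gametes recombining under a
Haldane map at 1 cM/Mb, so linkage disequilibrium arises from
co-transmission down the pedigree rather than from ancestral history. The
default genome (18 chromosomes of 6 Mb carrying 1,800 markers) is a
deliberately scaled-down stand-in: it preserves the *SNPs-per-window*
geometry of a dense commercial chip (about 8–10 markers per 0.52 Mb window,
matching the 10–31 SNPs per significant window seen in practice) instead of
absolute genome length, because the scan statistic aggregates over markers
within a window.

Phenotypes follow the repeatability model exactly. The additive values are
marker-borne: a few named QTL with assigned variance fractions (drawn from
common variants, MAF 0.15–0.5, so a planted "25% QTL" is a mappable
signal), plus a background of 200 small-effect loci carrying the remaining
additive variance, plus an optional pedigree-only polygenic residual
(default zero — in real data the polygenic background is itself tagged by
the chip, and an untagged background would misrepresent what genomic
relationships can capture). Each component, and then the total, is rescaled
so the realized additive variance among recorded sows equals
$\sigma^2_a$ exactly; variance defaults 0.9 / 0.68 / 5.49 give
$h^2 \approx 0.13$, matching a total-number-born-type trait. Records go to
the females of one generation (three parities each by default), with
year-season levels assigned at random per record; litter counts can be
rounded to non-negative integers, but the default keeps the trait
continuous, as it is modelled.

What passing tests on these simulations do *not* show: performance under
ancestral LD structure, selection, genotyping error, or the marker
densities of a real 50K+ chip; absolute accuracies and window percentages
of any particular farm's evaluation are not reproducible from synthetic
data and are not targets —
the simulations check structural properties (consistency of single-step
with pedigree BLUP, recovery of generating parameters, ordering of method
accuracies, localization of planted QTL).

## Problem sizes used in the checks

The shipped checks run REML recovery with 1,500 recorded sows times three
parities over ten seeds, the accuracy-ordering comparison on a
three-generation herd (400 recorded sows, 800 genotyped candidates, one
30% QTL) over ten seeds, and the localization scan (450 sows, one 25% QTL)
over ten seeds — sizes chosen so each property has reasonable statistical
power while a full run of the suite stays comfortably on a single core.
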