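---
title: "Methods: population genetics and in silico prioritization of intronic SNPs"
author: "ovisMstn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics and in silico prioritization of intronic SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovisMstn)
```

## Scope and data model

`ovisMstn` implements the analysis chain used to characterize a panel of
biallelic intronic SNPs in a single population — here the nine variants of
intron 1 of the ovine myostatin (*MSTN*) gene segregating in a 54-animal
Ukrainian Carpathian Mountain (UCM) sheep cohort — and the in silico
tools used to prioritize those variants: per-locus diversity statistics
with Hardy–Weinberg (HWE) tests, EM haplotype phasing, gamete-level
linkage disequilibrium (LD), allele-aware position-weight-matrix (PWM)
scanning, and molecular-dynamics trajectory metrics for comparing allelic
pre-miRNA variants.

Genotypes live in a `GenotypeMatrix` (individuals × loci, codes 0/1/2,
−1 for missing), with locus metadata (rsID, HGVS-like intronic label
`c.373+N`, 1-based intron offset, ref/alt alleles) kept sorted by intron
offset so that haplotype strings and ambiguity motifs are well defined.
Missing calls are excluded locus-wise from allele counts; the reference
cohort has none, but reuse on other panels requires the convention.

## Diversity statistics

For genotype counts $(n_0, n_1, n_2)$ at one locus:
$p = (2n_0 + n_1)/2n$, $H_o = n_1/n$, $H_e = 1 - \sum_i p_i^2$ (the plain
estimator, no $n/(n-1)$ correction), $F_{IS} = (H_e - H_o)/H_e$, and
$PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$.  The HWE test
compares observed genotype counts with $n(p^2, 2pq, q^2)$ via
$\chi^2 = \sum (O-E)^2/E$ over all three genotype classes on 1 degree of
freedom, with no continuity correction; all three classes enter even when
an expected count is far below 5 (a warning flags the rough
approximation), because that is how the reference statistics were
computed.  Monomorphic loci return $H_e = 0$, undefined $F_{IS}$ and
$\chi^2 = 0$ — flagged, never raised.

`pic()` has two rounding modes.  Published marker tables are typically
computed from allele frequencies printed to three decimals;
`printed_compat` reproduces that convention (round frequencies to 3
decimals first), while `exact` (the default) uses full precision.  For
the cohort's most polymorphic locus the two differ in the fourth decimal
(0.0994 vs 0.1001).  Both behaviours are kept because neither is
"wrong": one matches reporting practice, the other the formula.

## EM haplotype phasing and its parsimony refinement

Phases are inferred from unphased diploid genotypes under the multinomial
HWE likelihood.  Each individual with $h$ heterozygous loci is compatible
with $\max(1, 2^{h-1})$ unordered haplotype pairs (individuals are capped
at 20 heterozygous loci; missing calls are enumerated over all three
genotypes and flagged).  The E-step weights each compatible pair
$\{h_i, h_j\}$ by $2^{[i \ne j]} f_i f_j$; the M-step divides expected
gamete counts by $2n$.  Initialization is uniform over the union of
compatible haplotypes, convergence is a maximum absolute frequency change
below $10^{-8}$ (cap 10,000 iterations), and the log-likelihood is
non-decreasing by construction (asserted per iteration in the tests).

Plain EM returns the maximum-likelihood frequency estimate, and that
estimate is *not* always the parsimonious solution a Bayesian phasing
algorithm reports.  On the UCM cohort the one individual heterozygous at
both `c.373+259G>T` and `c.373+283T>C` can be phased as Hap2/Hap3 (both
supported elsewhere in the sample) or as Hap1 plus a haplotype carrying
both minor alleles.  Because Hap1 is very common, the unpenalized
likelihood actually prefers splitting the individual (posterior 0.83 for
the Hap1 pairing), leaving a seventh haplotype at frequency 0.0077.  The
default `refine = "bic"` therefore performs a backward elimination over
sparsely supported haplotypes (expected gamete count < 4): each candidate
is removed, the restricted model re-converged, and the removal kept when
it lowers $\mathrm{BIC} = -2\log L + (K-1)\log 2n$.  On this cohort the
seventh haplotype costs 0.77 log-likelihood units but saves
$\tfrac12\log 108 = 2.34$, so it is eliminated, while removing any of
the three singleton haplotypes Hap4–Hap6 costs ~2.8 units and is
rejected.  The refined solution is exactly the published six-haplotype
table.  `refine = "none"` exposes the plain ML fixed point, which is what
the grid-likelihood oracle test verifies.  After refinement, haplotypes
below $1/(4n)$ are pruned, and gamete counts are rounded by largest
remainder (ties toward the more frequent haplotype) so they sum to $2n$.

Individuals whose best pair has posterior below 0.9 are flagged
`ambiguous` rather than dropped.

## Linkage disequilibrium

LD is computed from the *inferred gamete pool* ($2n = 108$ gametes), not
from genotype composite LD: `gameteCounts()` marginalizes the haplotype
table onto a locus pair, and `ldCoefficients()` applies
$D = p_{AB} - p_A p_B$, the piecewise $D_{max}$
($\min(p_A(1-p_B), (1-p_A)p_B)$ if $D > 0$, else
$\min(p_A p_B, (1-p_A)(1-p_B))$), $D' = D/D_{max}$ (defined 0 when
$D = 0$), and $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$.  A and B denote the
alternative alleles; $r^2$ and $|D'|$ are orientation-invariant, so the
choice only fixes the sign of $D$.  The two-sided Fisher exact test sums
hypergeometric probabilities of tables no more probable than the observed
one (relative tie tolerance $10^{-7}$); `stats::fisher.test` implements
exactly this rule and is cross-checked against full enumeration in the
tests.  In this cohort every haplotype pair is either nested or disjoint,
so $|D'| = 1$ at all 36 pairs — a small-sample artifact that limits the
interpretive value of $D'$, and no correction is applied.

## Ambiguity motifs

`encodeMotifs()` renders each individual's unphased multilocus genotype
as one string (ref letter, alt letter, or the IUPAC two-allele code at
heterozygous positions; `N` when missing), giving a phase-free view of
genotype combinations; `tallyMotifs()` orders the distinct motifs by
descending count, then lexicographically.

## PWM motif scanning

Motifs are read from MEME minimal letter-probability format.  Scores are
log2 odds of pseudocounted probabilities (default pseudocount 0.001,
since public motif matrices contain exact zeros) over a 0-order
background — uniform by default, with a sequence-derived background
available by flag, because scanning tools differ in their default and the
choice should be explicit.  P-values are exact upper-tail probabilities
of the score under the background, obtained by dynamic programming over
integer-discretized scores: the bin width is $10^{-3}/w$ for width $w$,
bounding the accumulated rounding error by $5 \times 10^{-4}$ score
units, and observed window scores are discretized identically so the DP
agrees with exhaustive word enumeration to $10^{-9}$.  Both strands are
scanned (minus-strand hits reported on forward coordinates), q-values are
Benjamini–Hochberg across all windows of one (motif, sequence) scan, and
the default reporting threshold is $p < 0.001$.

`scanAlleles()` substitutes each allele of a variant into the sequence,
scans a ±(max width − 1) window, keeps hits whose footprint covers the
variant, and classifies each motif as `gained`, `lost`, `unchanged` or
`absent-in-both`.  Reproducing any specific published table of affected
binding sites requires the exact genomic sequence and motif-database
versions used there; those are external inputs, so the engine is
validated on constructed cases instead.

## Trajectory metrics

Trajectories are frames × atoms × 3 arrays in nanometres with per-atom
roles (backbone, ribose C1′, donor/hydrogen/acceptor, base-pairing edge)
and masses/van der Waals radii.  Superposition is the Kabsch algorithm
(proper rotations only; collinear selections are an error).  RMSD is
computed over sugar-phosphate backbone atoms after per-frame fitting;
RMSF over C1′ atoms after fitting to frame 1, then once more to the mean
structure.  $R_g$ is mass-weighted.  SASA uses Shrake–Rupley with a
deterministic golden-spiral point set (default 960 points, probe 0.14 nm);
absolute values depend on the radius table, so it is validated against
sphere closed forms (an isolated atom is exact by construction, and
agreement at 1% is the stated contract).  Hydrogen bonds count
donor–hydrogen–acceptor triples with donor–acceptor distance ≤ 0.35 nm
and hydrogen–donor–acceptor angle ≤ 30° — the convention of common MD
analysis tools; the angle convention is configurable since "angle ≤ 30°"
alone is ambiguous.  The `base_pairing` filter restricts both donor and
acceptor to atoms flagged as base-pairing-edge atoms; which atoms those
are is an input convention, not something the package asserts.  PCA
decomposes the fitted C1′ coordinates (frames × 3k) and the free energy
landscape is $G = -\ln(N_{bin}/N_{max})$ in kT over the first two
components, with unsampled bins left unset and the modal bin at exactly 0.

No periodic-boundary handling is performed: trajectories are assumed
whole-molecule and PBC-corrected upstream, and binary MD formats are out
of scope (plain frame/atom tables are read and written).

## Synthetic data and what the tests do and do not show

`reconstructUcmFixture()` rebuilds the 54 × 9 cohort deterministically
from published aggregates; the uniqueness argument is in its
documentation.  `simulateCohort()` draws haplotype pairs i.i.d. from a
frequency vector with an optional inbreeding mixture (probability $f$ of
copying the first draw), and `simulateTrajectory()` superimposes harmonic
modes (integer cycles across the frame window, so sinusoid closed forms
are exact) and isotropic Gaussian noise on a helical base structure.

The simulators emulate idealized conditions — HWE with known haplotype
frequencies, rigid harmonic motion — and deliberately omit genotyping
error, population structure, linkage to unobserved loci, anharmonic
dynamics and solvent effects.  Passing tests therefore demonstrate
correctness of the estimators and metrics, not robustness to real-data
pathologies.  Problem sizes were chosen for tight statistical bounds at
desk scale: parameter recovery uses $n = 2000$ individuals (3 binomial
SE), HWE recovery $n = 10^4$, trajectory checks ≤ 64 frames and ≤ 10
atoms, and the PWM enumeration oracle widths ≤ 6.

The cohort-level acceptance values (haplotype frequencies 87.96 / 5.56 /
3.70 / 3 × 0.93 %, the reference motif at 79.63 %, the full $r^2$
matrix) are recomputed from the reconstructed fixture by
`scripts/acceptance.R` and the test suite.  Published trajectory-derived
numbers (e.g. mean $R_g$ or PCA variance fractions of specific pre-miRNA
simulations) are not reproducible without the original trajectories,
which are not deposited; those modules are covered by closed-form and
oracle-based checks instead.
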