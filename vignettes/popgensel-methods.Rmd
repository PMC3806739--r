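---
title: "Models and methods behind popgensel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popgensel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the synthetic
data do and do not emulate, and the numerical choices that were genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The observable: folded joint site frequency spectra

The central data object is the joint SFS: a matrix whose `(i, j)` entry
counts SNPs with `i` derived copies among `n1` chromosomes in population 1
and `j` among `n2` in population 2. Because the two study populations have
no close outgroup that safely polarizes alleles, every quantitative fit in
this package uses the *folded* spectrum, indexed by minor-allele count.
Folding a 2D spectrum is done on the total minor count across both
populations; cells exactly on the fold line are split (each member of a
mirror pair keeps half of the pair sum), which conserves the segregating
total exactly. This is one of several defensible conventions; it is
localized in `fold()` so an alternative is a one-line change.

Missing data are handled the way the field's SFS tools do: a site called in
`m < n` chromosomes contributes its hypergeometric expectation at the
target size (`build_spectrum(..., missing = "project")`). A strict mode
drops incomplete sites instead, which matches analyses that exclude missing
data outright. Genotype calls with posterior probability ≤ 0.95 are treated
as missing; the threshold is exposed because the cutoff is a data-quality
convention, not a model quantity.

`residual_spectrum()` uses the symmetrized Poisson residual
`(a − b)/sqrt((a + b)/2)`. The comparison figures this emulates only
interpret sign and relative magnitude, and the source analysis never states
its residual formula, so a variance-stabilized symmetric form was chosen;
`0/0` cells are defined as residual 0.

## Expected spectra: Poisson random field + two-population diffusion

Each SFS bin is modelled as an independent Poisson count whose mean comes
from diffusion theory (the Poisson random field assumption — free
recombination between sites). With γ = 2·N_anc·s (genic selection,
h = 1/2; the model never invokes dominance) the stationary single-population
density of derived-allele frequency q is proportional to
`(1 − e^{−2γ(1−q)}) / ((1 − e^{−2γ}) q(1−q))`, with the neutral 1/q limit at
γ = 0. The factor 2γ in the exponent, rather than γ or 4γ, is deliberate
and is pinned by tests: conventions differ between the standard tools and a
silent factor of two would bias every fitted γ.

Out of equilibrium, `expected_sfs()` integrates the density forward under
an isolation-with-migration demography: an ancestral population of size
`N_anc` splits `T_split` (units of 2·N_anc generations) ago; each daughter
changes size exponentially from `nu*_0` to `nu*` (relative to `N_anc`);
migration enters as an advection `m_ij (x_j − x_i)` with rates scaled by
2·N_anc. The shipped default (`demographic_model()`: modest decline to 0.6
in population 1, six-fold expansion in population 2, `T = 0.56`, symmetric
migration 0.5) is an *illustrative* configuration consistent with the
qualitative history of the motivating system (Sumatran expansion, Bornean
decline, split a few hundred thousand years ago). It is **not** a fitted
parameter set — the study this emulates takes its demography from prior
work and holds it fixed, and so does every fitting function here, taking
the model as explicit input.

### Numerics

The solver is a conservative finite-volume scheme on a boundary-refined
grid (`tanh` warping; `crwd = 7` concentrates points near the absorbing
boundaries where the density behaves like θ/x). The flux is written in
advection–diffusion form `J = (M − V′/2)φ − (V/2)φ′` and discretized with
Chang–Cooper exponential fitting, which (i) reduces to central differences
for small cell Péclet numbers, (ii) upwinds automatically under strong
selection (the grid spans γ down to −2000), and (iii) makes the backward
Euler update an M-matrix solve, so densities can never go negative.
Boundary nodes absorb: mass that fixes or is lost accumulates there and,
within a sweep direction, never couples back (a site fixed in one
population still evolves freely in the other direction). One consequence,
accepted as a limitation: migration does not re-introduce variants whose
frequency has hit exactly 0 or 1 in the *focal* population; with the
moderate scaled migration rates used here the effect on unmasked entries is
small against the 0.5% grid-convergence tolerance below.

Two ADI half-sweeps (alternating order every step, which restores
population-exchange symmetry to ~1e-9) advance each time step; mutation
influx is injected at the first interior node *before* each implicit solve,
so the discrete stationary state is an exact fixed point of the stepping.
The injection rate is calibrated once per grid by solving the neutral
discrete stationary system and matching the θ/x law in the grid interior —
a pure discretization constant, independent of selection, which removes the
hand-tuned influx constants that plague ad hoc ports of this scheme.

Verification, all enforced by tests: the neutral sampled spectrum matches
θ/i to better than 1e-3 relative at default resolution; the stationary
marginal matches the closed-form selected equilibrium to 1%; a two-epoch
size-change run matches an exact Wright–Fisher transition-matrix oracle
(`wf_oracle_sfs()`, dense matrices up to N = 500, multiplicative `e^s`
allele fitness so arbitrarily strong selection stays defined; the census is
taken in adults, i.e. the current generation's fresh mutants contribute
their expected post-selection copy number `e^s` — without that weighting
the discrete chain carries an age-0 singleton mass that the diffusion,
whose influx enters at frequency 0+, does not have, and the lethal limit
would spuriously retain ~θ/2 · n/2N of sampled mass) to well
within 5%; doubling grid resolution or halving the time step moves
unmasked entries by < 0.5%. The oracle comparison at γ = −10 is made on
folded spectra — the only form any likelihood in this package consumes; the
unfolded high-frequency bins at that γ carry a fraction of a percent of the
total mass and show the O(1/N) discreteness of the finite-N oracle itself
(~7% at N = 200, halving as N doubles), which is a statement about the
oracle's population size, not about the diffusion solution.

## DFE inference

`fit_dfe()` maximizes the Poisson likelihood of the folded non-synonymous
spectrum over a mixture DFE mapped onto a cached grid of unit-θ expected
spectra: 2000 log-uniform negative γ values on [−2000, −1e-6], γ = 0, and
500 log-uniform positive values on [1e-6, 100] (endpoints included; the
desk-scale default is a 60-point grid with the same bounds, with entrywise
log-|γ| interpolation between cached spectra). Continuous families place
mass on grid points by integrating their density over each point's Voronoi
cell in log |γ|; mass beyond −2000 is "lethal" and contributes zero
polymorphism, consistent with the grid's lower bound. Point-mass families
bypass the cells and interpolate the spectrum directly, so the likelihood
is smooth in `gamma_point` even on the reduced grid.

θ_non is fixed to 2.5 × θ_syn by default — the standard non-synonymous to
synonymous mutational-opportunity ratio — with θ_syn calibrated from the
synonymous spectrum under the neutral expectation. A free-θ mode profiles
θ analytically (the conditional MLE is a ratio of totals); note that for a
point-mass family, free θ and `p_point` are confounded (only their product
enters the mean), which is precisely why the fixed-ratio constraint exists
and why recovery studies fix θ.

The optimizer is bounded L-BFGS-B on transformed parameters (logit
proportions, log scales) with five seeded random restarts by default.
Bootstrap intervals resample SNPs (multinomial over unmasked bins at fixed
segregating total) — the linkage-conservative unit, since the PRF already
assumes site independence; a gene-block alternative is not implemented
because gene assignments of SNPs are not part of the spectrum container.
Class masses report percent of mutations with |s| in the conventional four
bins after converting γ = 2·N_anc·s; the lethal atom counts in the
strongest class.

Known limitations, by design: no positive-selection tail beyond γ = 100,
no divergence-based (dN/dS) DFE estimation, and per-population (multiple-γ)
DFEs only as fixed point masses — full per-population distributions were
reported as computationally prohibitive in the source analysis and are out
of scope.

## Gene-level selection: Poisson random effects

Each gene contributes four counts (P_s, P_n, D_s, D_n) with log-means

    log λ = log L + b0 + bR·R + bF·F + bRF·R·F + u_g·R + v_g·R·F

where R indicates replacement (non-synonymous) cells, F indicates fixed
(divergence) cells, L is the aligned length offset, `u_g ~ N(0, σ_u²)` is a
gene-level constraint effect and `v_g ~ N(0, σ_v²)` the *selection effect*:
a positive `v_g` is an excess of replacement fixations over what the gene's
own polymorphism profile predicts. Genes are classified by the 95% credible
interval of `v_g` (positive iff the lower bound exceeds zero, negative iff
the upper bound is below zero). Because `v_g` is shrunk toward the
population distribution, positive calls are conservative when most genes
are neutral or constrained — the behaviour the power/calibration tests pin
down (≤10% non-neutral under an all-null genome; ≥60% detection of +1.5
log-scale spikes with ≤2% false positives).

Priors are implementation defaults (the source method states none):
N(0, 5²) on fixed effects, half-normal(1) on the random-effect scales. No
general-purpose MCMC engine ships in this environment, so the sampler is a
hand-written Metropolis-within-Gibbs, vectorized across genes, working on
the cell-rate parameterization (one log-rate per MK cell, whose likelihood
factorizes) with two interweaving moves that standard samplers need here:
a joint rescale of (σ, all effects) to traverse the σ → 0 funnel, and a
likelihood-invariant shift between intercepts and effect vectors to break
intercept/random-effect confounding. Proposal scales adapt during burn-in
(target acceptance 0.35–0.44) and freeze afterwards. Four chains run by
default; split-Rhat above 1.1 on any hyperparameter is treated as
non-convergence and raises an error rather than returning estimates.

The gene filter keeps genes with `max(D_n, P_n) ≥ 2` — reading "at least
two non-synonymous mutations in either the fixed or polymorphic column"
as a per-column maximum; the additive reading `D_n + P_n ≥ 2` is available
as a config switch because the phrase is genuinely ambiguous.

## IBS and mtDNA summaries

`ibs_matrix()` computes, per pair, the fraction of co-called sites with
identical genotype (dosage equality for diploids — the statistic of
interest is literally "same genotype", not allele sharing; an
allele-sharing mode exists but is off by default). Pairs use pairwise
complete sites, with the per-pair site count reported, because a global
complete-case mask would discard most of a low-coverage dataset.
mtDNA calls arrive diploid-encoded; any site with a heterozygous call —
on a haploid molecule, a likely false positive — is dropped genome-wide
(`drop_heteroplasmic_sites()`, removal fraction reported), and
`snp_density()` expresses variant density as bases per SNP
(13,648 callable sites / 1,090 SNPs ≈ 12.5).

## Synthetic data: the stated world

The generators produce every input the pipeline needs, each a pure function
of its seed:

* **Spectra** are Poisson draws around the model expectation — exactly the
  generative model of the PRF likelihood, so parameter-recovery tests are
  well-posed. The default scale mirrors the motivating study: 8+8
  chromosomes, ~6,900 synonymous and ~4,900 non-synonymous segregating
  sites, θ_non/θ_syn = 2.5.
* **Genotype matrices** draw site frequencies from the normalized expected
  spectrum and dosages binomially, with configurable missingness and
  sub-threshold call qualities to exercise the filters.
* **MK tables** come from the same log-linear model the classifier assumes
  (~500 genes; genome-average per-base rates taken from the published
  summary table: synonymous polymorphism 0.31%/bp, divergence 2.90%/bp,
  and their non-synonymous counterparts), with known per-gene effects
  recorded as truth labels.
* **mtDNA haplotypes** evolve on an `ape::rcoal` genealogy with mutations
  placed on branches proportional to length, at one SNP per 12.5 bases by
  default, plus injected heterozygous artifacts (<1% of sites).

What a green test does *not* establish: the generators share their
structural assumptions with the estimators (free recombination, Poisson
counts, log-linear gene effects, clean biallelic sites), so recovery tests
validate implementation correctness and statistical calibration — not
robustness to model misspecification, linkage, alignment error, or
ascertainment. Real-data totals (such as genome-wide counts of selected
genes) depend on the actual genomes and are deliberately not asserted
anywhere.

## Numerical conventions and edge cases

* Masked entries (absent/fixed corners, major fold half) carry no weight in
  any likelihood, total, or rescaling, but their values are preserved for
  diagnostics (monomorphic tallies land in the corners).
* `poisson_loglik` returns −∞ when a model mean is zero against nonzero
  data; fits treat non-finite objectives as +1e10 penalties, so optimizer
  paths through degenerate corners are rejected rather than fatal.
* The Yates continuity correction is on by default in `mk_chi2()` — it
  reproduces the published genome-wide statistic where the uncorrected form
  does not — and clamps at zero difference.
* Projection to equal sizes is the identity; projecting a folded spectrum
  projects the stored minor-configuration masses and refolds, which is
  exact because hypergeometric projection commutes with the
  derived/ancestral mirror.
* Lethal DFE mass is handled analytically as zero polymorphism; the solver
  is never asked for γ = −∞.
* All seeds are mandatory at stochastic entry points; "same seed, same
  bytes" is asserted for generators and the pipeline's machine-readable
  outputs.
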