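---
title: "Methods: codon-model selection scans in omegascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-model selection scans in omegascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and the
defaults chosen for them, what the synthetic-data generator does and does not
emulate, and the numerical choices that make the fits reproducible.

## The substitution model

All likelihood computations run on a Goldman–Yang style codon model over the
61 sense codons of the standard genetic code (stop codons are excluded from
the state space; the sense codons are ordered lexicographically with
A < C < G < T, and that ordering is shared by the rate matrix, the pruning
engine and the simulator). The instantaneous rate from codon $i$ to codon
$j$ is

$$q_{ij} = s\,\pi_j\,\kappa^{[\text{transition}]}\,\omega^{[\text{nonsynonymous}]}$$

for codon pairs differing at exactly one nucleotide, and zero otherwise.
$\kappa$ is the transition/transversion rate ratio, $\omega$ the
nonsynonymous/synonymous rate ratio — the quantity of scientific interest:
$\omega < 1$ indicates purifying selection, $\omega > 1$ positive selection.
$\pi$ holds the equilibrium codon frequencies; the default is F3x4
(products of position-specific nucleotide frequencies estimated from the
alignment, floored at $10^{-8}$ and renormalised so no sense codon has zero
mass), with `equal`, `F1x4` and `empirical` available. The scale $s$
normalises the mean rate at stationarity to 1, so branch lengths are
expected substitutions per codon site. The model is time-reversible
($\pi_i q_{ij} = \pi_j q_{ji}$), which the tests exploit: the likelihood is
invariant to root placement, and $P(t) = e^{Qt}$ is computed through the
eigendecomposition of the $\pi$-symmetrised generator
$\mathrm{diag}(\sqrt{\pi})\,Q\,\mathrm{diag}(1/\sqrt{\pi})$, whose spectrum
is real; tiny negative entries of $P(t)$ from floating-point rounding are
clamped to zero.

Likelihoods are computed by Felsenstein pruning with per-internal-node
rescaling, after compressing identical alignment columns into weighted site
patterns (which provably leaves the likelihood unchanged). Codons containing
`N` or `-` are treated as wholly missing data — their partial-likelihood
vector is all ones — never as partially informative. This is the simplest
defensible convention for gapped codons; the alternative (ambiguity-aware
partial vectors) changes little at these data scales and is harder to test.

## Branch models and the QEG/CQEG tests

The one-ratio null shares a single $\omega$ across the tree. The two-ratio
alternative gives the marked foreground branches their own shared
$\omega_{fg}$ (one extra parameter, so the LRT statistic
$2\Delta\ell$ is referred to $\chi^2_1$). A raw $p < 0.01$ calls a quickly
evolving gene; no multiple-testing correction is applied at this stage,
mirroring the uncorrected convention for this test. The foreground may be
one focal species (QEG) or the full set of highland lineages (CQEG) — the
shared-$\omega_{fg}$ design is the standard choice for a non-monophyletic
foreground, since the convergence hypothesis is a *common* rate shift. A
`per_branch_omega` mode (one $\omega$ per foreground branch,
df = number of foreground branches) covers the alternative reading.

**Branch lengths.** The default fit estimates, per gene, a single rate
scale multiplying the input tree's branch lengths, together with $\kappa$
and the $\omega$ parameters. Genes share the species tree's relative branch
lengths but differ mainly in overall rate, so the gene-specific multiplier
captures the dominant mode of variation at a fraction of the cost of
per-branch optimisation, and it keeps studies of hundreds of genes
practical on one core; `branch_lengths = "free"` optimises every branch
length for genes where the proportionality assumption is suspect. The
two-ratio alternative reuses the null's scale and $\kappa$ (profiling only
the $\omega$ split), which makes the test, if anything, slightly
conservative.

**Optimisation.** All parameters are optimised on the log scale with
L-BFGS-B inside documented bounds ($\omega \in [10^{-4}, 50]$,
$\kappa \in [0.01, 100]$, scale $\in [10^{-3}, 100]$). Three candidate
starts for $\omega$ (0.2, 1, 3) are evaluated once and the best is refined
by the full optimiser — a cheap guard against the mild multimodality that
arises when foreground data are sparse. Every fit is deterministic: there
is no stochastic restart, so identical inputs give identical outputs
regardless of gene order or parallel scheduling.

## The branch-site model and the PSG test

Model A mixes four site classes over the foreground/background partition:
class 0 ($\omega_0 \le 1$ everywhere), class 1 ($\omega = 1$ everywhere),
and classes 2a/2b where foreground branches switch to $\omega_2 \ge 1$
while the background keeps $\omega_0$ or 1. Class proportions derive from
$(p_0, p_1)$ as $p_{2a} = (1 - p_0 - p_1)\,p_0/(p_0+p_1)$ and
$p_{2b} = (1 - p_0 - p_1)\,p_1/(p_0+p_1)$. The null fixes $\omega_2 = 1$;
the LRT uses $\chi^2_1$, the conventional (slightly conservative) choice
given the boundary constraint.

Two implementation decisions matter here:

- **Shared synonymous rate across classes.** Each class's generator is
  divided by one common constant — the mean raw rate at the gene's
  one-ratio $\hat\omega$ — rather than being renormalised to unit rate per
  class. Renormalising per class would erase the very signal the model
  describes: a site under $\omega_2 = 8$ does not evolve at the same total
  rate as a neutral site, it accumulates nonsynonymous changes faster at
  the same synonymous rate. Branch lengths remain interpretable as expected
  substitutions per codon at the gene's average $\omega$. The simulator
  uses the same convention (normalising the mixture-average rate with the
  true proportions), and the unit choice is absorbed by the per-gene scale
  the fit estimates.
- **Profiled mixture proportions.** Reparameterising
  $s = p_0 + p_1,\ r = p_0/(p_0+p_1)$, the class proportions factor as
  $(sr,\, s(1-r),\, (1-s)r,\, (1-s)(1-r))$. Given the per-class site
  likelihoods, the mixture likelihood is maximised over $(s, r)$ in an
  inner Nelder–Mead on the logistic scale (two starts), while the outer
  optimiser moves only $\omega_0$ (null: 1-D Brent) or
  $(\omega_0, \omega_2)$ (alternative: 2-D L-BFGS-B). This is the same MLE,
  found much faster, because class-1 likelihoods never change and classes
  0/2a/2b depend only on $\omega_0$ and $\omega_2$ (memoised by value).

Site identification uses naive empirical Bayes: posterior class
probabilities proportional to MLE proportion × class site likelihood. Full
Bayes empirical Bayes would integrate over parameter uncertainty with a
prior; NEB is the plug-in version — well-defined, testable, and known to be
anti-conservative when estimates are noisy, which is why the PSG rule
requires *both* a BH-corrected LRT $p < 0.05$ across the gene family *and*
at least one site with selection posterior above 0.95. The correction
family for the branch-site p-values is all converged gene fits (BH by
default; Bonferroni and none are options); unconverged fits are reported
but excluded from the family unless asked.

## Substitution screens

Both screens work on translated alignment columns. A lineage-specific call
requires the focal species to carry residue $f$, the background to agree on
a single consensus $b \ne f$ at (by default) 100% identity among non-gap
residues, and no background taxon to carry $f$; a convergent call requires
both focal species to share $f$ under the same background rule. Columns
with under 50% non-gap background coverage are skipped (configurable), so no
call rests on a handful of taxa. Positions are reported in the ungapped
coordinate of the focal (or a chosen reference) taxon, giving the familiar
`D965E` notation. The strict 100% background identity default matches the
conserved-replacement use case; `min_background_identity` relaxes it, since
whether the original screens demanded full conservation or mere absence of
the focal residue is not documented — both are supported, strict is the
default. Severity is annotated with the published Grantham (1974)
physicochemical distance matrix; this is deliberately *not* a PROVEAN
score (PROVEAN needs a database search, out of scope here) and is labelled
as such everywhere.

## Four-fold degenerate sites

A codon column is accepted as four-fold degenerate when every taxon's codon
is ungapped, unambiguous and 4-fold degenerate at its third position, and —
under the strict default — the first two codon positions are identical
across all taxa, which guarantees the third position is selectively
equivalent in every lineage. The per-taxon (`strict = FALSE`) variant
classifies degeneracy independently per taxon; the strict rule is the
default because a supergene intended for clock work should contain no site
whose neutrality is lineage-dependent. Accepted third positions are
concatenated per species in ascending gene-id order (so the output is
order-invariant) with a boundary map, and written as FASTA or sequential
PHYLIP. Tree inference from the supergene is out of scope.

## Enrichment

Hypergeometric upper-tail tests (`P(X >= k)`, computed in log space) of
each annotation term with at least one study hit, against the universe of
all annotated genes, exactly as flat gene→term tables define it — no
ontology-graph propagation is performed, and the docs say so. Two
significance conventions are exposed because both are in common use:
BH-corrected $q < 0.05$ (ontology-style) and raw $p < 0.05$
(pathway-style); the threshold is configurable.

## The synthetic-data generator

The generator shares the transition-matrix code with the likelihood engine
— by construction, not by testing alone — and emulates: codon alignments
evolved site-independently on a fixed tree under one-ratio, branch, or
branch-site regimes; planted lineage-specific/convergent replacement
columns (focal taxa overwritten with a canonical codon of the target
residue, background with the consensus residue); and annotation tables with
one planted term covering the accelerated genes among decoys. The default
study — the conditions under which the package's properties are
demonstrated — is 50 genes of 300 codons on a fixed 8-taxon tree (total
length ≈ 1.5 substitutions/codon) with two non-sister foreground leaves,
$\kappa = 2$, F3x4 frequencies from a fixed mildly GC-rich base
composition, background $\omega = 0.2$ (typical purifying ortholog), five
genes accelerated at $\omega_{fg} = 5$, and three planted replacement
events. These sizes keep a full scan in minutes on one core while leaving
the planted effects comfortably detectable.

What the simulator does **not** emulate — and therefore what green tests do
not certify about real data: indels and alignment error (alignments are
simulated already aligned), recombination or among-gene tree discordance,
among-site rate variation beyond the branch-site classes, codon usage
heterogeneity along the sequence, sequencing/annotation error, and
ortholog misassignment. Calibration statements (e.g. the two-ratio LRT
rejecting at the nominal level under the null) hold under the simulator's
correctly specified conditions; real alignments violate them to varying
degrees, which is one reason the gene-level cutoffs in the pipeline are
deliberately strict.

## Numerical choices and degenerate inputs

- lnL convergence uses L-BFGS-B `factr = 1e7` (≈ $10^{-9}$ relative);
  nested-model invariants are asserted to $10^{-6}$.
- LRT statistics that come out marginally negative (optimizer noise on
  boundary-true data) are clamped to zero; $p = 1$.
- A two-ratio fit whose optimum falls below the null's likelihood reports
  the null's (the models are nested; this guards optimizer failures).
- Empty alignments after filtering, genes with fewer than 3 taxa, and
  empty study sets are skipped with logged reasons, never silent drops; an
  alignment taxon missing from the tree is a fatal error because it
  indicates a study misconfiguration rather than a bad gene.
- Single-sequence "trees" reduce the likelihood to $\sum \log \pi$ over
  observed codons.
- Ties in enrichment ranking are broken by term id, so outputs are fully
  deterministic.

## Known limitations

NEB rather than BEB posteriors (see above); the scaled-branch-length
default trades a little power for large speed gains on genome-scale gene
sets; $\chi^2_1$ for the branch-site LRT is conservative relative to the
boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; the screens are
definitional (no phylogenetic correction for background substitution), so
on deep trees some lineage-specific calls are expected by chance — they are
screens, not tests. Problem sizes in the shipped tests (4-taxon enumeration
oracles, 300-gene calibration, 100-replicate power arms, 1000-alignment
screen comparisons) were chosen to demonstrate each property at desk scale;
all scale up linearly if stronger evidence is wanted.
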