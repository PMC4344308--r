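---
title: "Sectors versus conservation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sectors versus conservation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scasector)
```

## The scientific question

Statistical coupling analysis (SCA) weights the pairwise covariance structure
of a protein multiple sequence alignment by conservation-derived positional
weights and reads groups of coevolving residues — *sectors* — off the leading
eigenvectors of the resulting matrix. Because conservation enters the
construction twice (through the weights and through the per-column variance),
the leading eigenvector of a single-sector protein tends to recapitulate the
conservation profile. This package implements the machinery needed to make
that statement quantitative: the SCA matrix itself, a relative-entropy
conservation score, a battery of statistical comparisons between the sector
and the equally sized set of most-conserved positions, and an analytic model
of the top eigenmode that explains when and why the two coincide.

## The model pipeline

An alignment is an `N x n` matrix over the 20 amino acids plus gap. Columns
with 40% or more gaps are treated as insert states and removed before any
computation (`filter_gap_columns`, inclusive threshold). Conservation of
column i is the Kullback–Leibler divergence

$$D_i = \sum_a f_i(a)\,\ln\frac{f_i(a)}{q(a)},$$

in nats (any other log base rescales all columns uniformly and changes no
ranking). The sum includes the gap symbol; the background gap frequency is
the alignment's column-averaged gap fraction, with the amino-acid background
rescaled so the 21-vector is a distribution (`average_gap`, the default), or
gaps are dropped column-wise (`ignore_gap`). The shipped amino-acid
background is the database-averaged table conventionally used with SCA; a
uniform background (0.05 per residue) is provided so that numeric examples
are self-contained.

The projection-method SCA matrix collapses each alignment cell to a single
number, $\tilde x_{ki} = \phi_i(a_{ki}) f_i(a_{ki}) / \|\phi_i f_i\|$ for
non-gap cells and 0 at gaps, with log-odds weights
$\phi_i(a) = \ln[f_i(a)(1-q(a))/((1-f_i(a))q(a))]$, and takes the
elementwise absolute value of the population covariance (divisor `N`) of the
projected matrix. The sector is the `round(fraction * n)` columns with the
largest top-eigenvector components; rank-based extraction (rather than a
numeric threshold on the components) makes the sector size deterministic at
the conventional 25%.

### Numerical choices

- **Frequency clamping.** $\phi_i(a)$ diverges as $f \to 0$ or $1$;
  frequencies are clamped to $[\varepsilon, 1-\varepsilon]$ with
  $\varepsilon = 10^{-3}$ (configurable). This is the minimal regularization
  that leaves the weight untouched for any frequency an alignment of fewer
  than 1000 sequences can produce.
- **Gap-inclusive frequencies.** The projection's numerator and denominator
  both use the gap-inclusive column frequencies from `column_frequencies`.
  Gap-excluded renormalization was considered and rejected: it changes
  nothing on gap-free columns and only rescales low-gap columns slightly,
  while keeping a single frequency object throughout removes a class of
  shape mismatches.
- **Eigenvector orientation.** Eigenvectors are returned unit-norm with
  nonnegative component sums, so sector extraction and regression are
  deterministic. Ties in component values break toward the lower column
  index.
- **Degenerate columns.** A column whose weighted frequencies vanish
  identically (e.g. frequencies exactly at background) has no projection
  direction; it is set to zero with a warning rather than an error, since a
  single such column should not abort an analysis of hundreds.
- **Coordinates.** Column indices are 1-based everywhere (the R convention);
  all reports translate columns to 1-based reference-sequence residue
  numbers via `map_columns_to_reference`, matching how mutagenesis tables
  are keyed. Sequences consisting mostly of gaps are *not* filtered: row
  filtering is a curation step that belongs upstream of the analysis.

## The statistical battery

`call_functional_sites` flags positions as functionally significant either by
effect magnitude (`|effect| >= threshold`, e.g. 1 kcal/mol for free-energy
data) or by a count of deleterious substitutions (e.g. at least 8 of 12–13
tested). `contingency` cross-tabulates set membership against those flags
over the scored universe, and `fisher_one_tailed` computes the exact
hypergeometric upper-tail probability of the observed in-set functional
count (enrichment direction).

Two design points deserve comment:

- **Comparing two contingency tables.** The sector table and the
  conserved-set table share their universe, so their out-of-set rows are
  nearly identical and would be double-counted by any test on the full
  tables. `chi2_compare_tables` therefore tests homogeneity of the two
  *in-set* rows only (Pearson chi-squared, 1 df). Yates correction is off by
  default and available as an option; identical rows give statistic 0 and
  p = 1 exactly.
- **Overlapping sets.** The sector and the conserved set typically share
  57–84% of their members. The Mann–Whitney comparison uses the sets as
  given: disjointifying them would change the hypothesis being tested (the
  full prediction of each method, not its disagreement with the other). The
  price is that the two samples are not independent, which makes the test
  conservative in the direction of not rejecting; this caveat is inherited
  by every analysis of this kind and is flagged here rather than "fixed".

`mannwhitney_values` enumerates all assignments exactly when both samples
have at most 8 members (ties handled by mid-ranks within the enumeration)
and otherwise uses the normal approximation with tie correction and no
continuity correction. `sweep_sector_size` repeats the comparison across
sector sizes and reports the overlap fraction alongside each p-value; no
multiple-testing correction is applied across the sweep, since the sweep is
a robustness display, not a family of hypotheses.

## The structural module

For domain-insertion experiments, a residue "touches" an insertion site if
any of its heavy atoms lies within a fixed radius (default 4 Å, inclusive)
of any of the four atoms of the peptide bond broken by the insertion. Which
four atoms form "the peptide bond" is ambiguous in the experimental
literature; the package uses C and O of the preceding residue and N and CA
of the insertion residue — the amide hydrogen is absent from X-ray
structures, and CA is the natural fourth anchor. The choice is configurable
(`center_atoms`). Alternate locations resolve to the highest-occupancy
conformer; multi-model files use the first model. The center-of-mass
analysis uses unit atom masses (a geometric center): at the resolution of a
"does conservation fall with distance from the core" question, mass
weighting changes distances by fractions of an Ångström.

## The idealized top eigenmode

The analytic model replaces the SCA matrix with
$M_{ii} = \Delta_i$, $M_{ij} = x\,d_i d_j$, $d_i = \sqrt{\Delta_i}$: a
conservation-like diagonal plus off-diagonal entries of uniform relative
magnitude $x$, the structure produced by taking absolute values of
covariances whose true means are zero. The eigenvalue equation gives the
exact componentwise relation
$v_i\,(\lambda - \Delta_i(1-x)) = x\,d_i \sum_j d_j v_j$
(`eigen_relation_residual` verifies it to numerical precision), and in the
regime where the top eigenvalue dominates every diagonal level,

$$\lambda_{\mathrm{top}} \approx \frac{x}{1+x} \sum_i \Delta_i,
\qquad v_{i,\mathrm{top}} \propto \sqrt{\Delta_i}.$$

The tests bound the eigenvalue approximation by the band
$2(x + 1/(nx))$, derived from the uniform-level case where the exact answer
$\Delta(1 + (n-1)x)$ is available in closed form, and require Pearson
$r \ge 0.99$ between $v_\mathrm{top}$ and $\sqrt{\Delta}$ whenever
$\lambda_\mathrm{top} \ge 10 \max_i \Delta_i$.

`estimate_offdiag_scale` recovers $x$ as the mean of
$C_{ij}/\sqrt{C_{ii}C_{jj}}$ over pairs. Its scaling with alignment depth
distinguishes two origins of the off-diagonal magnitude: pure sampling noise
decays (the measured exponent is close to $-1/2$, the standard
sample-covariance fluctuation rate for magnitudes — the package reports the
fitted exponent rather than asserting any particular value), while true
uniform correlations, e.g. from shared ancestry, hold `x_hat` approximately
constant. `scaling_experiment` runs this contrast on the synthetic
generators with a default ladder of N = 500 to 4000 at n = 50 and three
replicates per depth — sizes at which one run takes well under a second yet
the two regimes separate cleanly.

## What the synthetic generators emulate — and what they do not

All generators take explicit integer seeds, restore the caller's RNG state,
and are bit-reproducible.

- **Independent columns** (`sample_independent_alignment`): each column has
  a dominant residue carrying mass `p` from a conservation profile, the
  remainder uniform over the other 19 amino acids; no gaps, no correlations.
  The default profile (`heterogeneous_profile`) ramps p from 0.05
  (background level, D near 0) to 0.55. The upper end is deliberate: the
  projected-column variance behaves like $p(1-p)$ and turns over at
  $p = 0.5$, so columns frozen beyond $p \approx 0.6$ — which do occur in
  real alignments — would *not* rank at the top of the eigenvector. The
  generator thus emulates the monotone single-sector regime in which the
  conservation-dominance phenomenon lives; behavior at strongly frozen
  columns is a real-data feature the synthetic tests do not probe.
- **Planted sector** (`sample_sector_alignment`): a hidden ±1 state per
  sequence; in sector cells a latent bit agrees with the state with
  probability `(1+coupling)/2` and tilts the dominant-emission probability
  to $p \pm \delta_0$ with $\delta_0 = \min(p, 1-p)/2$ (half the admissible
  headroom). Because the bit is marginally a fair coin, sector columns have
  *exactly* the same marginal distribution as non-sector columns:
  conservation cannot see the sector even in principle, while the
  dominant-residue indicators correlate within the block with strength
  $\mathrm{coupling}^2 \delta_0^2 / (p(1-p))$. This makes the
  correlation-versus-conservation separation exact by construction rather
  than approximate. At `coupling = 0` the distribution reduces to the
  independent generator. A mechanism that swaps *which* residue is dominant
  would be invisible to the projection method (the two residues carry equal
  weights), and any mechanism strong enough to drive per-cell correlations
  to 1 necessarily distorts the marginals — the tilt design is the
  compromise that keeps both properties testable.
- **Star phylogeny** (`sample_star_phylogeny_alignment`): sequences copy one
  of a few ancestors and redraw each position with the mutation rate.
  Defaults (5 ancestors, rate 0.25, i.e. ~75% identity to the ancestor) put
  the alignment firmly in the ancestry-dominated regime where `x_hat` is
  flat in N. This is a deliberately crude model of phylogenetic bias — no
  tree depth, no rate variation, no substitution matrix — sufficient to
  produce the uniform positive correlations whose spectral consequences the
  eigenmode module studies, and nothing more.
- **Mutational effects** (`sample_mutational_effects`): per-position effects
  are a monotone link of conservation plus Gaussian noise
  (default link: identity; noise s.d. 0.3 in the packaged studies, roughly a
  quarter of the conservation range, so that effects are clearly
  conservation-driven but individual rankings are noisy). This emulates the
  empirical premise that mutational-effect magnitude tracks conservation; it
  does not emulate epistasis, position-specific mutational spectra, or
  measurement floors/ceilings.

Consequently, a green test suite demonstrates the internal logic of the
sector-versus-conservation comparison — not that any particular real protein
family behaves this way. Real alignments add phylogenetic structure,
gap patterns, frozen columns and non-uniform minor-residue distributions
that the generators intentionally omit.

## Study sizes used by the packaged analyses

The packaged studies (test suite and `scripts/acceptance.R`) use: 10
alignments of N = 500, n = 100 for the top-eigenvector/diagonal correlation;
100 replicates of the same size for the sector-versus-conservation
equivalence fraction; one N = 1000, n = 100 alignment with a 20-column
planted sector at coupling 0.8 for the separability analysis; and the
N = 500–4000 ladder for the scaling contrast. These sizes were chosen as the
smallest at which the respective effects are stable across seeds.

## Known limitations

- The exact background frequencies used in the original SCA studies are not
  published; analyses of real alignments therefore depend on the chosen
  background table (shipped default, user-overridable).
- Sector extraction uses the top eigenvector only; multi-sector
  identification (independent component rotations, multi-eigenvector
  thresholds) is out of scope.
- The Mann-Whitney and chi-squared tests assume independent samples;
  mutational effects at different residues of one protein are not
  independent, so reported p-values are descriptive comparisons, not
  calibrated error rates.
- The touching criterion depends on the identity of the four peptide-bond
  atoms and on complete heavy-atom coordinates; missing side chains shrink
  touch sets silently.
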