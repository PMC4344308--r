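# scasector

Statistical coupling analysis (SCA) identifies "sectors" — groups of
coevolving residues — from the spectral structure of a conservation-weighted
covariance matrix of a protein multiple sequence alignment. For proteins in
which SCA finds a single sector, the sector positions are largely the
conserved positions: the top eigenvector of the SCA matrix tracks the square
root of the matrix's diagonal, a quantity computable from single-site
statistics alone. `scasector` implements the projection-method SCA matrix,
relative-entropy conservation, and the statistical battery needed to compare
the two as predictors of functionally important residues — together with an
analytic model of the top eigenmode and seeded synthetic-alignment generators
that make every claim testable without external data.

## The quantities computed

For an alignment with `N` sequences and `n` columns over the 20 amino acids
plus gap:

- **Conservation** (relative entropy, nats):
  `D_i = sum_a f_i(a) ln[f_i(a)/q(a)]`, where `f_i(a)` is the frequency of
  amino acid `a` in column `i` and `q(a)` a background distribution. The
  background gap frequency is taken as the alignment's mean gap fraction
  (`average_gap`), or gaps are ignored column-wise (`ignore_gap`).
- **SCA matrix** (projection method): positional log-odds weights
  `phi_i(a) = ln[f_i(a)(1-q(a)) / ((1-f_i(a)) q(a))]` collapse each cell to
  `x_ki = phi_i(a_ki) f_i(a_ki) / sqrt(sum_b phi_i(b)^2 f_i(b)^2)` (0 at
  gaps), and `C_ij = |cov(x_i, x_j)|` (population covariance, elementwise
  absolute value).
- **Sector**: the `round(0.25 n)` columns with the largest components of the
  top eigenvector of `C`.
- **Comparison battery**: 2x2 contingency tables of set membership versus
  functional significance, one-tailed Fisher exact enrichment p-values,
  chi-squared comparison of two tables, two-sided Mann-Whitney U tests on
  effect distributions (exact for small sets), sector-size sweeps, and OLS
  regression of phenotypes on eigenvector components.
- **Structural touching**: residues with any atom within 4 Å (3/5 Å options)
  of the four peptide-bond atoms at a domain-insertion site, and conservation
  versus distance from the protein's geometric center.
- **Top-eigenmode theory**: for the idealized matrix `M_ii = Delta_i`,
  `M_ij = x sqrt(Delta_i Delta_j)`, the approximations
  `lambda_top ~ x/(1+x) sum_i Delta_i` and `v_top ~ sqrt(Delta_i)`, an
  estimator `x_hat = mean_ij C_ij / sqrt(C_ii C_jj)`, and experiments fitting
  how `x_hat` scales with alignment depth (decaying for sampling noise,
  roughly flat for shared ancestry).

## Worked example

```r
library(scasector)

# a synthetic alignment with heterogeneous conservation and no coupling
aln <- sample_independent_alignment(500, 100, heterogeneous_profile(100), seed = 1)
res <- run_sca(aln, q_aa = aa_background("uniform"))

topvec_diag_correlation(res$C, res$spec, res$D)$r_sqrt_diag
#> [1] 0.9486714
res$sector$size
#> [1] 25

# conservation-linked mutational effects: is the sector any better than
# the equally sized conserved set?
data <- sample_mutational_effects(res$D, noise_sd = 0.3,
                                  functional_threshold = 1, seed = 2)
sweep_sector_size(res$spec, res$D, data, sizes = c(15, 25))
#>   size p_mannwhitney   overlap
#> 1   15     0.2538055 0.2666667
#> 2   25     0.5934736 0.7200000
```

The top eigenvector correlates at r = 0.95 with the square root of the SCA
matrix diagonal even though the columns were generated independently, and the
Mann-Whitney test finds no difference between the effect distributions of the
sector and of the equally sized most-conserved set (p = 0.59 at the 25%
sector size, with 72% of positions shared) — the single-sector regime in
which conservation and SCA make statistically equivalent predictions.

A published worked number: for a PDZ-domain scan with 80 scored positions of
which 20 are functionally significant, a 21-residue sector containing 14 of
them gives

```r
d <- mutational_dataset(1:80, rep(0, 80))
d$functional <- c(rep(TRUE, 20), rep(FALSE, 60))
fisher_one_tailed(contingency(c(1:14, 21:27), d))
#> [1] 1.561503e-06
```

## Command line

A thin wrapper over `run_pipeline()` lives at
`inst/scripts/sca-pipeline.R`:

```sh
Rscript inst/scripts/sca-pipeline.R --alignment aln.fasta --ref-id seq1 \
    --effects effects.tsv --sector-fraction 0.25 --outdir out/
```

It writes the filtered alignment, conservation profile, SCA matrix,
eigenmodes, sector, comparison summary and a run manifest under `--outdir`.

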