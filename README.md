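# segkit

Maximum-likelihood segregation analysis for binary (dominant/recessive)
traits in **half-sib families** — the design of strictly monoparous
livestock, where one sire is mated to many dams and each dam contributes a
single offspring. The motivating case is the alpaca fleece dichotomy
(crimped **Huacaya**, modeled as recessive, vs silky **Suri**); the two
cross series that motivated the methods ship with the package as fixtures.

For a sire with `r` recessive offspring among `s`, the family likelihood is
binomial under *complete selection* (families recorded regardless of
phenotypes) or truncated binomial under *truncate selection* (only families
with at least one recessive proband enter the sample):

    Pr(r | s, p) = C(s,r) p^r (1-p)^(s-r)              (complete)
    Pr(r | s, p, r>=1) = C(s,r) p^r (1-p)^(s-r) / (1 - (1-p)^s)  (truncate)

with `p` composed from the segregation ratio `R` and the carrier frequency
`H` as `R`, `H·R`, or `H²·R` depending on which parents' carrier status is
latent. On top of these kernels the package provides:

- `fit_single_R()` — MLE of `R` with profile-likelihood 95% limits (the
  two roots of `logL = Lmax − 5.0238/2`), optionally conditional on a
  fixed `H`;
- `fit_single_offspring()` — closed-form conditional estimation for the
  single-offspring design, where only `H·R` is identifiable;
- `fit_two_ratio()` / `lrt_two_vs_one()` — the hard-max two-ratio mixture
  `L = Σ max[L_i(R1), L_i(R2)]` with per-sire assignment, and its
  chi-square comparison against the single-ratio model;
- `g_test()`, `permutation_test()` — G-square heterogeneity test and a
  seedable Monte Carlo permutation test that redistributes the recessive
  offspring over the observed sibships;
- `gamete_recessive_prob()`, `fit_recombination()`,
  `expected_suri_suri_ratios()`, `heterozygote_decline()` — the
  two-linked-locus recessive model: cis sires segregate at `1/2 − h`,
  trans sires at `h/2`, tying the two observed ratio classes to a single
  recombination fraction `h`;
- `simulate_crosses()` / `ascertain()` — a generative simulator of
  half-sib datasets with known latent truth, for calibration and power
  studies;
- `run_segkit()` — a command-line front end (thin wrapper script in
  `inst/scripts/segkit`).

## Worked example

```r
library(segkit)

t1a <- load_fixture("table1A")             # 9 Suri sires x Huacaya dams
seg <- ascertain(filter_families(t1a, segregating_only = TRUE))

fit_single_R(seg)
#> single-R (truncate, R_only) fit over 8 families
#>   estimate = 0.2898, 95% profile CI [0.1841, 0.4095]
#>   log-likelihood = -20.7665
```

A test-cross of a single-locus recessive should segregate at `R = 0.5`;
0.29 with an upper limit of 0.41 rejects that outright. The ratio is also
heterogeneous across sires:

```r
g_test(t1a)
#> 	G-square test of segregation-ratio heterogeneity
#> data:  table1A
#> G = 28.088, df = 8, p-value = 0.0004579

fit_two_ratio(seg)
#> two-ratio fit over 8 families
#>   R1 = 0.0772 (4 families), R2 = 0.5117 (4 families)
#>   log-likelihood = -11.7568
```

Four sires segregate near 1/2 and four near zero — exactly the structure
the two-linked-locus model predicts, with the low class produced by trans
(`Ab//aB`) sires whose recessive gametes require a recombination:

```r
fit_recombination(seg)
#> recombination-fraction fit over 8 families (truncate kernel)
#>   h = 0.0785, 95% profile CI [0.0116, 0.1955]
#>   groups: 4 trans, 4 cis; log-likelihood = -12.8124
```

The independent Suri × Suri series tells the same story — its 23
segregating sibships are far too dispersed for one binomial ratio:

```r
t2seg <- filter_families(load_fixture("table2"), segregating_only = TRUE)
permutation_test(t2seg, n_replicates = 10000, seed = 1)
#> Monte Carlo permutation test of segregation-ratio homogeneity
#>   pooled ratio p = 0.1421, observed statistic = -44.3836 (complete kernel)
#>   p-value = 0.0079 (79 of 10000 replicates below observed)
```

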