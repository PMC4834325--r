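# sevniche

Bayesian standard ellipsoid volume (SEV) models for stable-isotope niches
in two or three dimensions.

Trophic ecologists summarize a population's isotopic niche by where it sits
in δ-space (δ¹³C, δ¹⁵N, and increasingly δ³⁴S, all in ‰) and how much of
that space it occupies. With two isotopes the standard ellipse area is the
usual niche-width metric; `sevniche` extends the idea to three isotopes.
Each individual's isotope vector is modelled as

    yᵢ ~ MVN(μ, Σ)

with vague priors (normal on μ, variance 1000 ‰² per axis; inverse-Wishart
on Σ, scale 3·I and 4 degrees of freedom). The 1-Mahalanobis-unit surface
of this distribution is the *standard ellipsoid*, with semi-axes
a = √λ₁ ≥ b = √λ₂ ≥ c = √λ₃ (eigenvalues of Σ) and volume

    SEV = (4/3) π a b c = (4/3) π √det(Σ)   [‰³]

(area π√det(Σ) in ‰² for two isotopes). An exact two-block Gibbs sampler —
both full conditionals are conjugate, so there is no Metropolis step —
yields posterior draws of (μ, Σ), and every niche quantity is computed per
draw: SEV with credible intervals, centroid location (CL) and Euclidean
distances between centroids, the probability one niche is wider than
another, a conservative null/test-split test that two centroids differ,
and percent overlap of two ellipsoids by numeric integration
(voxel-grid or Monte-Carlo). A simulation-study engine tabulates power,
bias, and interval coverage across sample sizes.

## Worked example

Three synthetic "ecotypes" patterned on an inshore/coastal/offshore
dolphin comparison (18/9/8 animals), separated mainly on the sulfur axis:

```r
library(sevniche)

generate_fixture("dolphins.csv", seed = 42)          # synthetic data
dat  <- read_isotope_csv("dolphins.csv")
fits <- niche_fit(dat, isotopes = attr(dat, "isotopes"),
                  control = mcmc_control(seed = 1))
glance(fits)
#>   group        n     d draws sev_median sev_mean sev_conf_low sev_conf_high
#> 1 inshore     18     3  3000      12.5     13.1          7.50         22.4
#> 2 coastal      9     3  3000       3.32     3.64         1.63          7.58
#> 3 offshore     8     3  3000       3.25     3.64         1.58          7.89

niche_compare(fits)   # pairwise table (inshore rows shown)
#>   group_a  group_b p_sev_greater distance_median p_centroids_differ
#> 1 inshore  coastal         0.995            6.07                  1
#> 2 inshore offshore         0.994           10.67                  1
```

Read: the inshore group's niche is wider (posterior median SEV 12.5 ‰³,
95% CI 7.5–22.4) than the coastal and offshore groups' (≈3.3 ‰³), with
posterior probability ≈0.99 of the ordering; its centroid sits 6.1 ‰ from
the coastal centroid, a difference supported with probability 1 by the
conservative split test. `niche_overlap(fits, seed = 1)` reports the
percent of each population's volume shared with every other (here 0 — the
groups are fully separated once δ³⁴S is included; drop the sulfur column
and they appear to overlap, which is the point of going to three axes).
`plot_niche_projections(fits)` draws the posterior-median ellipses for
each axis pair.

A command-line wrapper covers the same workflow
(`fit | compare | overlap | simulate | fixture`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sevniche.R", package = "sevniche"))')" \
    compare --input dolphins.csv --output out/ --seed 1
```

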