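---
title: "The p-gain: model, null distribution and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The p-gain: model, null distribution and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgain)
```

## Why ratios, and what the p-gain measures

In association studies with metabolic traits — a SNP dosage against
metabolite concentrations in a GWAS, or a phenotype against them in an
MWAS — the ratio of two metabolite concentrations often associates far
more strongly than either concentration alone. Under steady-state
assumptions a ratio of the substrate and product of an enzymatic reaction
proxies the reaction rate, and dividing two concentrations cancels shared
variation (dilution, normalisation, a common latent influence) that would
otherwise drown the signal.

The p-gain quantifies the extra information in a ratio:

$$\mathrm{p\text{-}gain}(M_1/M_2 \mid X) =
  \frac{\min\{p(M_1 \mid X),\, p(M_2 \mid X)\}}{p(M_1/M_2 \mid X)}$$

where each $p(\cdot \mid X)$ is the two-sided p-value of the trait
coefficient in an ordinary least-squares regression of the (log)
quantity on the trait $X$. A large p-gain says the ratio's association is
orders of magnitude stronger than the best single-metabolite association.

Ratios are analysed as natural-log differences. Since
$\log(a/b) = -\log(b/a)$, the two orientations of a pair give identical
p-values, so each unordered pair is tested once — halving the
multiple-testing burden of a full scan over $\binom{m}{2}$ pairs.

**Everything is carried in log10.** Observed p-gains reach $10^{66}$ and
beyond; ratios of raw double-precision p-values would overflow or hit
exact zeros. `associate()` computes $\log_{10} p$ from the log-tail of
the t distribution (`pt(..., log.p = TRUE)`), never by exponentiating
and re-logging, and `compute_pgain()` is a subtraction of log10
p-values. The linear-scale accessor `pgain_linear()` saturates at the
largest representable double with an explicit flag.

## The conservative null and its critical values

For significance testing the package uses the *conservative* (universal)
p-gain: the numerator p-value is taken to be uncorrelated with the
ratio's p-value, in which case both are independent Uniform(0,1) under
the null and the p-gain is distributed as a ratio of two independent
uniforms. The convolution formula for density ratios gives the split
density and distribution function

$$f(g) = \begin{cases} 1/2 & 0 < g < 1 \\ 1/(2g^2) & g \ge 1 \end{cases}
\qquad
F(g) = \begin{cases} g/2 & 0 < g < 1 \\ 1 - 1/(2g) & g \ge 1.\end{cases}$$

The median null p-gain is 1; the upper tail beyond $g \ge 1$ is
$1/(2g)$. Inverting $F$ at $1 - \alpha/B$ (Bonferroni correction for $B$
tested ratios) yields the critical value

$$g_{\mathrm{crit}} = \frac{B}{2\alpha}, \qquad \alpha/B \le 0.5,$$

i.e. 10 at $\alpha = 0.05$ for a single test, and *ten times* the number
of tested ratios under Bonferroni correction — not the number of
metabolites, as the older rule of thumb had it. The guard
$\alpha/B \le 0.5$ is the domain of the upper branch; `pgain_critical_value()`
rejects settings outside it.

This null is conservative because correlation can only shrink the
p-gain's spread: the more correlated a metabolite is with the ratio, the
closer their p-values, the closer the p-gain to 1. The extreme case —
two fully correlated metabolites, both uncorrelated with their ratio —
attains the uniform-ratio distribution, so its quantiles bound every
real setting from above.

```{r}
pgain_critical_value(0.05, 1)
pgain_critical_value(0.05, 258)
pgain_quantile(c(0.5, 0.95, 0.99))
```

## Simulating the exact null for a correlated setting

When the actual correlation triple
$(\mathrm{cor}(M_1, M_2), \mathrm{cor}(M_1, \mathrm{ratio}),
\mathrm{cor}(M_2, \mathrm{ratio}))$ is known, the exact p-gain
distribution can be simulated and its (smaller) critical value read off
empirically. Per replicate, `simulate_pgain_null()`:

1. draws `n_samples` triples from a **Gaussian copula** with the
   setting's $3 \times 3$ correlation matrix (uniform margins);
2. applies a rank-based **inverse normal transformation** to each margin
   (Blom offsets, $(r - 3/8)/(n + 1/4)$; ties get average ranks), giving
   normal marginals as linear regression assumes;
3. draws an independent standard-normal predictor $X$ and regresses each
   of the three traits on it;
4. forms the p-gain from the three p-values.

The three traits are *free margins* tied only by the correlation
structure; the arithmetic identity $\mathrm{ratio} = M_1/M_2$ is
deliberately not imposed — correlations, not algebra, link the traits.
The design choices here were genuinely open and are package decisions:

* **Copula family: Gaussian.** It is the standard elliptical copula
  parameterised directly by a correlation matrix, which is exactly the
  input this procedure takes. Non-elliptical families would add tail
  dependence the model does not call for.
* **Blom offsets** for the inverse normal transformation; the offset
  convention is not critical (any of Blom/Tukey/van der Waerden gives
  the same ranks-to-normal monotone map to within a whisker) but is
  fixed and documented for bit-for-bit reproducibility.
* **Defaults `n_samples = 1000`, `n_reps = 1e5`, mandatory seed.** 1000
  samples per replicate is a typical cohort size at which t p-values are
  effectively exact; 1e5 replicates resolve a 0.95 quantile to a few
  percent (bootstrap SE about 0.01 on the log10 scale). These sizes are
  the package's own choices.
* **Degenerate settings.** A singular correlation matrix (e.g.
  $\mathrm{cor}(M_1, M_2) = 1$, the conservative case) is handled by
  clipping negative eigenvalues at zero and rescaling to unit diagonal;
  matrices with eigenvalues below $-10^{-8}$ are rejected, naming the
  offending eigenvalue.
* **Quantiles** are linear interpolation of order statistics (type 7) on
  the log10 scale, stated so results reproduce across implementations.
* The per-batch regressions use the correlation form of the simple-OLS t
  statistic, vectorised over replicates; a test pins it to
  `associate()` on an identical RNG stream.

Two properties anchor the simulation to the closed form: the degenerate
setting $(1, 0, 0)$ reproduces $F$ above (Kolmogorov–Smirnov distance
below 0.01 at $10^5$ replicates), and increasing either
metabolite–ratio correlation strictly lowers the 0.95 quantile, so the
analytic critical value bounds every simulated setting.

```{r, eval = FALSE}
sim <- simulate_pgain_null(correlation_setting(1, 0, 0), seed = 1)
empirical_quantiles(sim, c(0.5, 0.95, 0.99))
```

## Sample-size dependence

`pgain_vs_sample_size()` draws bootstrap subsamples (with replacement)
of a cohort at a ladder of sizes — defaults 100, 500, 1000, 1500, 2000
with 1500 replicates per size — recomputes the pair's p-gain per draw,
and summarises the median and quartiles of the log10 p-gain per size.
For a real effect the median log10 p-gain grows roughly linearly with
$n$; the package asserts only the monotone growth. "First and third
quantile" are read as quartiles, interpolated with the same type-7 rule
as everywhere else. Replicates with a degenerate subsample (for example
a monomorphic genotype draw) are skipped and counted; more than 10 %
skips at a size aborts with an error, since the summaries would no
longer be comparable across sizes.

Within a single null cohort the bootstrap medians concentrate around
that cohort's *own* realised p-gain, which is itself a draw from the
null; the analytic median of 1 emerges only across cohorts. Tests
average over cohorts for exactly this reason.

## The synthetic cohort generator

`generate_cohort()` draws the desk-scale cohorts all tests run on:

* genotype $G \sim \mathrm{Binomial}(2, \mathrm{maf})$, Hardy–Weinberg
  proportions; the trait is the additive dosage;
* $\log M_1 = \beta_1 G + u + e_1$,
  $\log M_2 = \beta_2 G + u + e_2$, with a shared latent
  $u \sim N(0, \sigma_u^2)$ and residuals
  $e_i \sim N(0, \sigma_i^2)$;
* concentrations are emitted exponentiated (log-normal, as metabolite
  concentrations are), so the scan's log handling is exercised.

Defaults: $\mathrm{maf} = 0.3$, $\sigma_u = 1$,
$\sigma_1 = \sigma_2 = 0.5$, $\beta_1 = \beta_2 = 0$ (a null cohort).
The canonical alternative is $\beta_1 = -\beta_2 = 0.25$: opposite-sign
effects on the log scale model a substrate/product pair where the SNP
shifts the reaction balance. The shared component $u$ — the "internal
normalisation" that makes ratios powerful — cancels exactly in
$\log(M_1/M_2)$, so the ratio association dwarfs both single-metabolite
associations and the planted pair carries a large p-gain. At
$\beta = 0$ the implied log-metabolite correlation is
$\sigma_u^2 / \sqrt{(\sigma_u^2 + \sigma_1^2)(\sigma_u^2 + \sigma_2^2)}$
(0.8 at the defaults), matched by a test.

What the generator does **not** emulate: measurement batch effects,
limit-of-detection censoring and missingness patterns of real
platforms, non-normal residuals, linkage structure among SNPs, or
correlated metabolite panels beyond one latent factor. Passing tests
therefore certify the statistic, its null and its thresholds — not
robustness to the full messiness of platform data.

## Numerical and engineering decisions

* Complete-case filtering per test; non-positive or missing
  concentrations are excluded pairwise with a warning, never failing a
  scan. Degenerate pairs are skipped with a recorded reason.
* $B$ is the number of ratio associations *actually performed* (skipped
  pairs do not inflate the threshold).
* Scan output is sorted by decreasing log10 p-gain, ties broken by pair
  name; significance flag is `log10_pgain >= log10(B/(2 alpha))`.
* Single metabolites are log-transformed before regression by default
  (consistent with the log-scale ratio and log-normal concentrations);
  `log_single = FALSE` disables this.
* Covariates are supported (incremental $R^2$ of the trait is reported)
  but default to none.
* Genotype traits are plain numeric dosages in $[0, 2]$; no genotype
  file formats are parsed.
* Test problem sizes: the heavy Monte Carlo checks use $10^5$
  copula replicates where a Kolmogorov–Smirnov distance of 0.01 or a
  quantile tolerance of about 1 must be resolved, $2 \times 10^4$
  replicates per setting for the five-setting conservativeness sweep,
  200 cohort replicates for recovery rates, and 200 bootstrap
  replicates per size for the sample-size ladder. These sizes resolve
  each assertion's tolerance with headroom and are the package's own
  choices.

## Known limitations

* The analytic null assumes the single-metabolite and ratio p-values are
  exactly Uniform(0,1) under the null — i.e. correctly specified linear
  models; heavy-tailed residuals on small cohorts will distort both
  p-values, and the p-gain inherits that.
* The conservative threshold can be very conservative for strongly
  correlated pairs; `simulated_critical_value()` exists precisely to
  recover that power when the correlation setting is known.
* The scan tests one trait per call; iterating over many SNPs is left
  to the caller (and $B$ must then count pairs × traits).
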