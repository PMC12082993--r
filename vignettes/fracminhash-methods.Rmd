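---
title: "FracMinHash sketching: estimators, guarantees, and how they were validated"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FracMinHash sketching: estimators, guarantees, and how they were validated}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracminhash)
```

## The sketch

Comparing sequencing samples through their k-mer content quickly becomes
expensive: a metagenome easily holds $10^7$–$10^9$ distinct k-mers, and
pairwise comparisons across hundreds of samples multiply that cost.
Sketching replaces each k-mer set by a small fingerprint on which set
overlap can still be estimated.

A FracMinHash sketch applies a hash function
$h : \Omega \to [0, H]$ to every element of a set $A$ and keeps the hash
values at or below a fraction $s$ of the range:

$$\mathrm{FRAC}_s(A) = \{\, h(a) : a \in A,\; h(a) \le H s \,\}.$$

Unlike classic fixed-size MinHash, the sketch size is proportional to the
input: under a strongly 2-universal hash family each element is retained
independently with probability $s$, so the sketch cardinality
$X_A = |\mathrm{FRAC}_s(A)|$ is a Binomial$(|A|, s)$ variable with
$E[X_A] = s\,|A|$. Because membership depends only on an element's own
hash value, the sketch of an intersection is the intersection of sketches
(up to 64-bit hash collisions, which are negligible at desk scale), which
is what makes overlap estimation work for sets of very different sizes —
the regime where fixed-size MinHash degrades.

For DNA, the universe is the set of canonical k-mers: every window of
length $k$ whose characters are all `A/C/G/T` after uppercasing (windows
containing ambiguity codes are skipped, not substituted), mapped to the
lexicographic minimum of the window and its reverse complement so that
sketches are strand-invariant. Hashing is MurmurHash3 x64_128 with seed
42, keeping the first 64 bits of the digest — the exact convention of the
sourmash ecosystem, so signatures are exchangeable with tools that share
it. MurmurHash3 carries no universality guarantee; the package follows
common practice in assuming the theory's hash-family model and checks
empirical uniformity of the hash values in its test suite instead.

Two numerical conventions worth stating precisely:

* the acceptance threshold is $T = \lfloor s \cdot 2^{64} \rfloor$ with an
  *inclusive* comparison $h \le T$, computed in 80-bit arithmetic so the
  floor is exact for any double-precision $s$; $s = 0$ keeps nothing and
  $s = 1$ keeps everything. Writers using a strict max-hash convention
  differ only on a measure-zero boundary value, and the signature reader
  accepts their files unchanged.
* R has no unsigned 64-bit integer type, so hash values live in R as
  decimal strings, sorted and compared as integers in C++; JSON signature
  files store them the same way, which survives any JSON parser without
  precision loss.

## Estimating similarity and distance

All measures handled here are ratios of the cardinalities $|A|$, $|B|$,
$|A \cap B|$, $|A \cup B|$, $|A \,\Delta\, B|$: Jaccard, the two
containments, cosine (Otsuka–Ochiai), the first and second Kulczynski
measures, Whittaker distance, Sørensen index and Bray–Curtis
dissimilarity. The *plug-in* estimator evaluates the same formula on the
sketch cardinalities $X_A$, $X_B$, $X_{A \cap B}$. It is exact at $s = 1$
and concentrates as $s\,|A \cap B|$ grows.

For Jaccard and containment the plug-in estimator is biased low by
exactly the probability that the denominator sketch is empty. Conditional
on its size, a sketch is a uniform random subset of the denominator set,
so with the convention $0/0 := 0$,

$$E\!\left[\frac{X_{A\cap B}}{X_A}\right]
  = \frac{|A \cap B|}{|A|}\,\Pr[X_A > 0]
  = C(A,B)\,\bigl(1 - (1-s)^{|A|}\bigr),$$

and dividing by $1 - (1-s)^{|A|}$ (or $1-(1-s)^{|A\cup B|}$ for Jaccard)
gives an unbiased estimator. The second Kulczynski index is the mean of
the two corrected containments and the Whittaker distance its complement,
so both inherit unbiasedness linearly. The correction needs the *true*
denominator cardinality; `build_sketch(..., track_cardinality = TRUE)`
stores it exactly, and when it is absent the package substitutes the
sketch estimate $X/s$ and says so — the correction is then itself
estimated, which is the honest fallback rather than a silent one.

No tractable correction exists for cosine, Kulczynski-1, Sørensen or
Bray–Curtis. For these the package provides probability guarantees
instead. Applying the Chernoff bound

$$\Pr\bigl[\,|X_A - s|A|\,| \ge \epsilon\, s |A|\,\bigr]
   \le 2 e^{-s |A| \epsilon^2 / 3}$$

to $A$, $B$ and $A \cap B$ and pushing the three events through the ratio
gives, after tightening the relative-error algebra
($\epsilon \mapsto \epsilon/(2+\epsilon)$, already folded into the
constants below),

$$\Pr\bigl[\,|\cos\theta' - \cos\theta| \le \epsilon \cos\theta\,\bigr]
   \ge 1 - 6\, e^{-s |A \cap B|\, \epsilon^2 / [3 (2+\epsilon)^2]},$$

with the same expression for Sørensen and Bray–Curtis, and a
$4$-exponential variant over $\min(|A \cap B|, |A \Delta B|)$ for
Kulczynski-1. Bounds are clamped to $[0,1]$; a clamped-to-zero bound is
reported as such rather than hidden, since for nearly disjoint sets the
guarantee is genuinely vacuous (the near-zero estimate still conveys the
dissimilarity — it is only the multiplicative error statement that loses
meaning).

## The recommended scale factor

Solving the cosine guarantee for $s$ at a target confidence $\alpha$
yields the package's central practical output:

$$s \;\ge\; \frac{3\,(2+\epsilon)^2 \,\ln[6/(1-\alpha)]}
                 {\epsilon^2\, \min(|A|, |B|)},$$

capped at 1. `recommend_scale_factor()` takes the minimum *set* size
rather than the intersection size — the sharper
$\min(|A|,|B|,|A \cap B|)$ form is available via `size_intersection`, but
the intersection is rarely known before sketching, and when it is small
the estimate collapses to zero anyway, which is informative on its own.
Plugging the (uncapped) recommendation back into the bound returns
exactly $\alpha$; the test suite asserts this round trip to $10^{-12}$.

```{r}
recommend_scale_factor(1e5, epsilon = 0.05, alpha = 0.95)
scale_factor_table(1e4, epsilons = c(0.05, 0.09, 0.1),
                   alphas = c(0.91, 0.95, 0.99))
```

Tables rendered by `scale_factor_table()` round half-up to four decimals,
matching the published lookup tables this implementation reproduces; the
unrounded grid is kept in the `"raw"` attribute. A widely used default of
$s = 1/1000$ is *not* safe for 5%-accurate cosine estimates on sets of a
few hundred thousand elements — that is precisely what the coverage
simulation below quantifies.

One known conflict in the source material: for sets of about 4.8M
elements at $\epsilon = 0.1$, $\alpha = 0.95$, the formula above gives
$s \approx 1.3\times10^{-3}$, while the accompanying prose quotes
0.0005. The formula as printed is implemented and the discrepancy left
visible rather than matched.

## The simulation harness

`coverage_experiment()` re-creates the validation protocol: a universe of
$N = 10^6$ integers, two independent uniform random subsets per trial
(sizes 100K–500K, so $|A \cap B|$ is hypergeometric with mean
$|A||B|/N$), sketches at either a fixed $s$ or the per-cell
recommendation, and the fraction of 1000 trials in which the plug-in
cosine lands within $\pm 5\%$ of the per-trial true cosine. These
defaults (universe size, grid, repetitions, $\epsilon = 0.05$,
$\alpha = 0.95$, fixed $s = 0.001$) are the published study conditions
and are not tuned. Trials with an empty sampled intersection have true
cosine 0 and count as within-tolerance iff the estimate is exactly 0;
such trials are reported per cell.

Elements can be processed in two modes. In `"hashed"` mode every integer
is encoded as 8 little-endian bytes and pushed through the real
MurmurHash3 path — the full production stack. In `"ideal"` mode each
element receives an i.i.d. uniform acceptance draw, i.e. sketching under
the exact hash-family model the theory assumes. The two modes agree
within Monte-Carlo noise (the suite checks the hashed path against real
sketch objects bit-for-bit); the ideal mode is used for the large
acceptance-scale runs because it isolates estimator behavior from hash
quality and is cheaper on 500K-element sets. Per-cell RNG substreams are
derived from the experiment seed and the cell index, so any cell replays
identically in isolation.

`unbiasedness_experiment()` uses constructed set pairs with an exactly
known overlap, so the true metric value and the analytic plug-in
attenuation factor $1 - (1-s)^{n}$ are available in closed form. With
20K-element sets at $s = 0.005$ the attenuation is numerically
negligible, so the bias is demonstrated separately on 300-element sets
where the factor is $\approx 0.895$ — visibly below 1 but with sketches
still frequently non-empty.

What the synthetic universes do *not* emulate: k-mer composition bias,
sequencing error (which inflates distinct-k-mer counts with singletons),
abundance structure (sketches here are sets, not multisets), and the
correlation pattern of overlapping genomes. Passing coverage tests
therefore validate the estimators and guarantees under the model's own
assumptions — uniform hashing and exchangeable elements — not the
behavior of any particular biological dataset. The file-sketching path is
validated separately on sequence fixtures against frozen reference hash
values.

A reproducibility note: on the fixed-$s$ grid, cells whose expected
retained intersection $s\,|A \cap B|$ is around 10 put the $\pm 5\%$
window at a width of roughly one integer count, so the within-tolerance
fraction is dominated by lattice effects and is acutely sensitive to the
experimental protocol. Our harness yields a stable $\approx 0.13$ for the
100K×100K cell across seeds, somewhat above the published 0.09 — the
published grid itself shows cell-to-cell scatter far beyond binomial
noise at 1000 repetitions (symmetric cells differing by up to 0.15), so
agreement at that resolution is not expected; the 500K×500K cell and the
recommended-scale grid reproduce within noise.

## Degenerate inputs and tie-breaks

* Exact set computation errors on an empty denominator set (the measure
  is undefined); the sketch path instead warns and reports the limiting
  value — 0 for similarities, 1 for Whittaker and Bray–Curtis — keeping
  the complement identities $K_2 + W = 1$ and $S + BC = 1$ exact on both
  paths.
* Kulczynski-1 of identical sets is reported as `Inf` (and serialized as
  the literal `inf` in matrix CSVs) so pairwise matrices stay writable.
* Pairwise-matrix diagonals are filled by definition: 1 for similarities,
  0 for Whittaker/Bray–Curtis, `Inf` for Kulczynski-1.
* Sketch operations on parameter-mismatched sketches (different $k$, $s$
  or hash seed) fail naming the differing field; silent cross-parameter
  comparison is never attempted.

## Problem sizes used in the automated checks

The shipped validation uses the full 1000-repetition protocol for the
three headline coverage cells (universe $10^6$, sets up to 500K), 2000
Monte-Carlo repetitions for unbiasedness, 5000 sketches per point for the
concentration bound, and scaled-down universes (20K–50K elements, 150–200
repetitions) for the property-style tests that only need the invariants,
not the published values. All randomness is seed-derived; identical
seeds replay identical results.
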