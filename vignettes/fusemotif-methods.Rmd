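---
title: "fusemotif: methods and design notes"
author: "fusemotif authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fusemotif: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusemotif)
```

## The problem

Transcription factors (TFs) bind short, degenerate DNA sequence motifs that
are conventionally summarized as position weight matrices (PWMs): a
`width x 4` table of per-position nucleotide probabilities. Scanning a
sequence for motif occurrences means scoring every width-`w` window on both
strands, attaching a p-value to each score under a background (null) model
of the sequence composition, and controlling the false discovery rate over
the many windows tested. Different scanners in wide use differ in the score
transform and the background they calibrate against; `fusemotif` runs five
such scoring *channels* side by side over the same windows and fuses their
p-values with Fisher's combined probability test, the meta-analytic
combination rule

$$\chi^2 = -2 \sum_{i=1}^{5} \ln p_i \;\sim\; \chi^2(10)$$

under the null hypothesis that the five p-values are independent and
uniform. Each reported occurrence carries its five channel scores and
p-values, the fused statistic, the combined p-value, and a q-value.

## The five channels

All channels reduce to an additive position score
$S(x) = \sum_j M_c(j, x_j)$ for a window $x$, with channel-specific score
matrices $M_c$ and null models:

| channel | score matrix entry | null model |
|---|---|---|
| `c1_logodds_uniformbg` | $\log_2\!\big(p(j,b)/0.25\big)$ | uniform |
| `c2_logodds_seqbg` | $\log_2\!\big(p(j,b)/q_0(b)\big)$ | order-0, estimated from input |
| `c3_markov1_weight` | $\ln p(j,b)$ | order-1 Markov, estimated from input |
| `c4_matchsim` | $p(j,b)$ | uniform |
| `c5_floored_logodds` | $\ln\!\big(\max(p(j,b), 10^{-3})/0.25\big)$ | uniform |

Here $p(j,b)$ is the motif probability of base $b$ at position $j$ (after
pseudocount smoothing) and $q_0$ the order-0 input composition. Channel c3
is a *weight* (log-likelihood) score: the order-1 structure lives entirely
in its null distribution, which is what keeps the score additive over
positions and the p-value machinery shared across channels. A log-ratio
against an order-1 null would not be a per-position matrix at all. Channel
c4 is a probability-similarity score; a division by the score range would
be a monotone per-motif rescaling with no effect on p-values or ranking,
so scores are kept on the raw similarity scale.

## Exact p-values by dynamic programming

Every channel's null distribution is computed exactly for a discretized
version of its score. The matrix entries are mapped to integers on a fine
grid of `n_bins * width` levels spanning `[min_score, max_score]`
(default `n_bins = 1000`, so a width-10 motif uses 10,000 levels); the
distribution of the integer window total under the background is then
obtained by convolution (order-0) or by a DP whose state is
(score level, previous base) for the order-1 null. The first base of a
window is drawn from the model's marginal composition.

Scanning uses the *same* integer entries to score each window, so the
per-window channel p-value `survival[total]` is exact for the discrete
statistic — a window's p-value is precisely the probability that a
background window reaches at least its discrete score. Because each entry
is rounded to at most half a fine level, the discrete and the raw
continuous score of a window differ by at most `width/2` fine levels,
i.e. at most half a coarse bin.

The public lookup `score_to_pvalue()` maps an arbitrary raw score
conservatively: the score is floored to its fine level, pushed down by a
slack of `ceiling(width/2) + 1` levels (the maximal entry-rounding error),
and the survival there is returned. The result is an upper bound on the
exact tail probability that exceeds it by at most the null mass inside one
coarse bin. Degenerate matrices with zero score range yield a single point
mass. Scores beyond the attainable maximum have an empty tail and clamp to
`1e-300`, the same floor (`MIN_P`) applied to p-values before the Fisher
log-transform.

Windows containing `N` are skipped rather than penalized: the calibration
argument above assumes the ACGT alphabet, and a worst-case score would
produce spurious non-uniform p-values.

### Strands

The minus strand is scored by applying the reverse-complement score matrix
(rows reversed, A/T and C/G columns swapped) to the forward sequence, with
its own null distribution under the same background, and reporting forward
coordinates. Backgrounds estimated from the input are trained on the
sequences *plus their reverse complements*. This makes the background
complement-symmetric, so the reverse-complement PSSM of a motif is exactly
the PSSM of the reverse-complement motif and every minus-strand hit
coincides — scores, p-values and fused statistic — with a forward hit of
the reverse-complement motif. Without the symmetrization that identity is
unattainable for skewed inputs. P-values are computed per strand per
window with no best-of-strand collapsing, which keeps the per-channel null
calibration exact.

## Fusion, q-values and ranking

Per window and strand the five channel p-values are clamped into
`[1e-300, 1]` and combined: $\chi^2 = -2\sum \ln p_i$, with the combined
p-value from the even-df closed form
$P(X \ge x) = e^{-x/2}\sum_{j=0}^{k-1} (x/2)^j / j!$ evaluated in log
space. q-values use the Storey approach: $\hat\pi_0(\lambda) =
\#\{p > \lambda\}/(m(1-\lambda))$ over $\lambda \in \{0, 0.05, \dots,
0.90\}$, with $\lambda$ chosen to minimize the bootstrap mean squared
error against the plug-in minimum over 100 resamples (seeded), and the
usual min-suffix step $q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$.
q-values are computed per motif over **all** evaluated windows — not per
sequence, and not only over windows passing the report threshold — because
that is the actual family of tests performed. The default report threshold
on the combined p-value is `1e-4`, a desk-scale convention; genome-scale
runs of this kind of scanner use far stricter cutoffs (down to `1e-18`),
which the `p_threshold` argument exposes. Output is sorted by combined
p-value with
deterministic tie-breaking by sequence, start, strand and motif id;
overlapping occurrences are all reported, since downstream evaluation
needs the full candidate set.

## The independence diagnostic

Fisher's rule needs joint independence of the channel p-values, so the
package ships the d-variable Hilbert-Schmidt independence criterion
(dHSIC) as a diagnostic. Gaussian kernels with the median-heuristic
bandwidth are computed per column; the test statistic is the V-statistic
form of dHSIC, and the critical value is the $(1-\alpha)$ quantile of a
permutation null in which columns 2..d are independently permuted
(default 1000 permutations, seeded). Independence is rejected exactly when
the threshold is less than or equal to the statistic. A permutation null
was chosen over a gamma approximation because it is assumption-free and
exactly reproducible under a seed; the permutation loop is implemented in
C++ since the statistic costs $O(d n^2)$ per evaluation.

## What the synthetic generator emulates — and what it does not

`simulate_background()` draws sequences from an order-0/1/2 Markov model;
`plant_motifs()` places non-overlapping sites at uniform positions,
sampling each site's word from the motif's probability rows (reverse
complemented for minus placements); `simulate_reads()` lays
Poisson-distributed treatment counts with a configurable fold enrichment
over truth-overlapping intervals against a flat Poisson control,
mimicking the ChIP/control structure that gold-standard labeling assumes.
One global seed fans out to decoupled component streams through a fixed
affine splitting rule (`split_seed()`).

Defaults were chosen once as a realistic desk-scale study: a width-10
motif with one dominant base at probability ~0.84 per position (~11 bits,
a strong TF motif), 10 sites per 10 kb of background, 200-bp read tiles
with base rate 20 and 10-fold enrichment. Real data differ in ways the
generator does not model: genomic background is not low-order Markov
(repeats, CpG islands), binding sites co-occur and cluster, read
coverage has fragment-length structure and mappability artifacts. Passing
tests therefore certify the *statistical engine* — calibration, fusion
arithmetic, FDR machinery, format fidelity — not biological performance
on real chromatin data.

## A known limitation: the channels are not independent

The five channels are all increasing statistics of the *same* window. On
a uniform background c1, c3 and c5 are exactly monotone transforms of one
another, and c2/c4 are strongly positively correlated with them. Their
p-values are therefore far from jointly independent per window — the
dHSIC diagnostic applied to per-window channel p-values rejects — and
Fisher's combined p-value is anti-conservative under the null: scanning
pure background yields orders of magnitude more sub-threshold combined
p-values than the nominal level suggests (roughly, with near-comonotone
channels a combined threshold of $10^{-6}$ behaves like a single-channel
threshold of $e^{-q_{10}(10^{-6})/10} \approx 5\times 10^{-3}$). For the
same reason the fused ranking cannot systematically beat the best single
channel on synthetic data: there is no complementary information to fuse.
Per-channel p-values remain exactly calibrated, and the combined p-value
remains a well-defined, monotone ranking statistic; treat it as a score,
not as a calibrated tail probability, and rely on q-values computed from
the observed combined-p distribution for error control. This is an
intrinsic property of fusing five scores of one word, not an
implementation artifact; fusing genuinely different scanners on
heterogeneous real data, where the independence diagnostic can pass, is
the setting in which the combination is expected to help.

## Numerical choices and problem sizes

* Motif pseudocount 0.1 (FIMO-like convention, configurable); probability
  records that are already strictly positive are renormalized without
  re-smoothing so serialization round-trips exactly.
* Background probability floor `1e-3` with renormalization that never
  leaves an entry below the floor; ambiguous IUPAC symbols in training
  sequences are skipped, not fractionally distributed.
* Score grid: `n_bins = 1000` coarse bins, `n_bins * width` fine levels;
  lookup slack `ceiling(width/2) + 1` levels; `MIN_P = 1e-300`.
* dHSIC defaults: 1000 permutations, median-heuristic bandwidth.
* Gold-standard labeling: "within a peak" means >= 1 bp overlap; read
  fractions are window counts divided by the library's total mapped
  reads; the instance threshold applies to the combined p-value and is
  exposed as a parameter. The read-count correlation uses a 400-bp window
  centered on the motif midpoint and `-log10(combined p)` as the score.
* Test and acceptance problem sizes, chosen as desk-scale analyses:
  exhaustive enumeration oracles up to width 8 (65,536 words); null
  calibration on $10^5$ i.i.d. windows per channel; dHSIC type-I error
  over 200 replicates of a 100 x 5 uniform matrix; planted-site recovery
  over 20 seeds of 10 sites in 10 kb.
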