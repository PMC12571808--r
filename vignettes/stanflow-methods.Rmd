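---
title: "Modeling interspike intervals with spatial-temporal attention and conditional normalizing flows"
author: "stanflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling interspike intervals with spatial-temporal attention and conditional normalizing flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Each neuron $n$ in a simultaneously recorded population is modeled as a point
process through the conditional density of its interspike intervals,

$$P(\tau_i \mid S_{i-1[\Delta]},\, q,\, t_{i-1}),$$

where $\tau_i = t_i - t_{i-1}$ is the time to the next spike,
$S_{i-1[\Delta]}$ is the $N \times \Delta$ binned spiking history of the
*whole* population in the $\Delta$-long window ending at the previous spike,
$q$ is the stimulus identity (one-hot over the $Q$ training stimuli), and
$t_{i-1}$ is the previous spike's time (rescaled to trial-relative $[0,1]$).
ISIs of one neuron are assumed conditionally independent given this context;
each neuron gets its own model.

Two components implement the conditional density.

**Spatial-temporal attention encoder.** A recurrent encoder (single-layer
LSTM) summarizes the window; a tanh-affine head on its final hidden state,
followed by a softmax over the $\Delta$ bins, gives temporal weights
$\alpha$. A shared affine map embeds each unit's $\Delta$-length history row
into $d$ dimensions; the concatenation of the encoder's last hidden state,
the unit's embedding and $q$ is mapped through a tanh-affine head to one
scalar logit per unit, and **sparsemax** — the Euclidean projection onto the
probability simplex — across units gives spatial weights $\beta$ with exact
zeros. Because both weight vectors are simplex vectors, the mean-normalized
weight matrix is $N\Delta\,\beta\alpha^{\mathsf T}$; multiplying it
elementwise into the window and running a second LSTM yields the context
vector $h'$. Sparsemax rather than softmax is used so that units that do not
co-vary with the modeled neuron receive exactly zero weight, which makes the
averaged weights interpretable as a synchronization measure.

**Conditional flow.** ISIs are mapped to $y = \log(\tau/\tau_{\mathrm{ref}})$
(reference scale $\tau_{\mathrm{ref}} = 50$ ms), which enforces positivity and
puts typical ISIs near the origin. $K$ invertible layers transform $y$; each
layer, conditioned on $x = [h'; q; t_{i-1}]$ through two small feedforward
networks, applies an affine map $v = e^{s(x)} y + t(x)$ followed by a gated
monotone bend $u = v + a(x)\tanh(v + c(x))$ with $|a| \le 0.9$. Since
$\partial u/\partial v \ge 1 - 0.9 > 0$, every layer is strictly monotone, the
scalar Jacobian is exact, and the log-likelihood is the base-Gaussian term
plus a sum of per-layer log-derivatives. The bend matters: a composition of
purely affine scalar maps collapses to a single affine map, i.e. to a
conditional log-normal, which is demonstrably too rigid to match, say, a
gamma ISI law; the tanh bends give the flow genuine shape flexibility while
preserving exactness and invertibility. Sampling inverts each layer with a
Newton iteration on the (globally monotone) bend; the base distribution is a
standard Gaussian, with all conditioning carried by the transform.

The whole stack — both LSTMs, embedding, both attention heads, and all flow
networks — is trained jointly per neuron by minimizing the mean negative
log-likelihood with Adam. The analytic backward pass is implemented in
compiled code (`src/stanflow.cpp`) and is verified against finite differences
in the test suite.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `binMs` | 1 ms | history discretization; resolves the 5 ms synchrony scale |
| `deltaMs` | 20 ms | history window; 5–50 ms are sensible, 20 ms is the default working point |
| `hidden` | 32 | LSTM hidden size (both encoders) |
| `embed` | 8 | per-unit spatial embedding dimension $d$ |
| `layers` | 6 | flow layers $K$ |
| `width` | 64 | hidden width of the flow's conditioner networks |
| `tauRef` | 0.05 s | ISI reference scale of the log transform |
| `aMax` | 0.9 | bend gate bound; the monotonicity margin is $1 - a_{\max}$ |
| `lr`, `epochs`, `batchSize`, `patience` | 1e-3, 200, 128, 20 | Adam settings; validation-NLL early stopping |

Bins are half-open $[l, r)$ with the final bin closed; the history window
*includes* the bin containing $t_{i-1}$, and windows preceding the recording
start are zero-padded. Counts are kept as counts by default; a `binarize`
flag is available. A scale network output is softly bounded to $[-5, 5]$
(via $5\tanh(\hat s/5)$) so that $e^s$ cannot overflow.

**Initialization.** Flow conditioner output layers start at zero, so the
untrained flow is the identity on $y$ and the initial ISI density is
log-normal — a proper density from step one. The spatial head starts
*activity-aligned*: the first embedding coordinate measures a unit's recent
spike presence (near tanh saturation for a single in-window spike, so bursts
are not over-weighted) and carries a positive weight into the spatial logit.
This breaks the permutation symmetry of the sparsemax plateau in the
direction the architecture intends — attention toward recently co-active
units — and is the single most consequential optimization choice in the
package: with a random direction instead, short training runs leave the
spatial weights uninformative. Training is free to move away from it.

## Cross-validation and the synchronization summary

With five trials per stimulus, rotation $r$ trains on trials
$\{r, r{+}1, r{+}2\}$, validates on $r{+}3$ and tests on $r{+}4$ (all mod 5);
the retained checkpoint is the best-validation one and the test trial is
never consulted during selection. For the summary matrix $B$, the spatial
weights $\beta_i$ are averaged over all spikes of the evaluation trials,
per stimulus, per unit model (rows of $B^n$ are therefore simplex vectors),
and $B$ is the mean over the $N$ unit models, optionally pooling several
rotations. When $B$ is compared against the windowed pairwise indices (ESI
and the kernelized binless similarity score the 1 s epoch after stimulus
onset), the summary is restricted to the same epoch so that all three methods
see the same data.

Stimulus clustering reduces the rows of $B$ (or the upper-triangular ESI/KB
feature vectors) to two dimensions and applies 2-means, scoring the best of
the two label assignments against the behavioral annotation. The
dimensionality reduction is PCA: with $Q \le 24$ stimuli a deterministic
linear embedding is preferable to a stochastic neighbor embedding, and
clustering on the raw rows is available as a robustness option
(`reduce = "none"`).

Unit ablation removes columns of $B$ and renormalizes each row back onto the
simplex before re-clustering.

## Baseline synchronization indices

*ESI.* Coincident events are spike pairs within $\pm\delta/2$ of zero lag
($\delta = 5$ ms) counted in the $T = 1000$ ms window after onset; the shift
predictor (mean over the four trial-shifted pairings) is subtracted and the
difference is normalized by the pair's total spike count, as a percentage.
Identical trains with silent shuffles give $\approx 50\%$ by construction; a
brute-force $O(n^2)$ pair count is the test oracle.

*Kernelized binless similarity.* Each train is convolved with the causal
exponential kernel $h(t) = e^{-t/\phi}u(t)$ ($\phi = 5$ ms) on a 0.1 ms grid
and the cosine of the two filtered signals is taken; two single spikes
$\Delta t$ apart give $e^{-|\Delta t|/\phi}$ exactly, which the tests check
against the grid implementation. Trial-shuffle correction subtracts the mean
similarity against the partner's other trials.

*Response index, PSTH, dissimilarity.* The response index is
$((r_{\mathrm{odor}} - r_{\mathrm{control}}) - \bar r)/\mathrm{SD}$ with
rates from the 0–600 ms post-onset window. PSTHs are binned at 20 ms,
smoothed with a Gaussian of 3 bins SD (truncated at 3 SD), and z-scored
against the 200 ms pre-onset baseline; the baseline statistics come from the
*unsmoothed* pre-onset bins, because smoothing correlates neighboring bins
and deflates the SD estimate. The dissimilarity index is the Euclidean
distance between rows of $B$, normalized by the mean over the compared set.

## PN/LN typing

Bursts are detected by the Poisson-Surprise criterion:
$S = rT - \log\sum_{j\ge n}(rT)^j/j!$, computed through the log Poisson
survival function, with seed pairs whose ISI is below $p = 0.2$ times the
mean ISI, greedy one-spike forward extension while $S$ strictly increases,
front pruning on the same rule, a 3-spike minimum, and merging of overlapping
sets. Six features (within-burst maximum instantaneous frequency, mean
spikes per burst, percentage of burst spikes, burst frequency, mean and
maximum Surprise) feed a logistic classifier. Min-max scaling is applied
with *separate* scalers for training and test sets — deliberately, so the
classifier is robust to overall rate-scale differences between preparations —
with conventional train-bounds scaling available by flag. The logistic fit
carries a light ridge penalty ($\lambda = 0.01$): clean bursty-vs-regular
features are completely separable, where unpenalized maximum-likelihood
coefficients are non-identified.

## The simulator and what it does (not) emulate

`simulatePopulation` emulates the structure of small olfactory-ensemble
recordings: $N \approx 7$–19 units, two stimulus classes plus a control,
five trials, 3 s trials with a 400 ms stimulation window, baseline and
evoked firing. Spontaneous activity is type-specific: PN-like units draw an
alternating burst renewal process (100 Hz within bursts, geometric mean 4
spikes per burst, 2 Hz initiation; ISI CV > 1), LN-like units a shape-9
gamma renewal process (CV = 1/3). Synchrony is planted by mother-process
thinning: during a driving stimulus, group members keep each mother spike
with probability 0.9 and 2 ms Gaussian jitter — inside the 5 ms ESI
coincidence window — superposed on their own background.

Evoked drive carries a per-trial multiplicative log-normal gain
(`rateGainSd`, default 0.5 on the log scale, mean 1), shared within a sync
group through its mother process and independent per responsive unit
otherwise. This models the trial-to-trial response variability that real
ensembles show, and it is *essential to identifiability*: with homogeneous
Poisson/renewal drive, every process is memoryless conditional on
$(q, t_{i-1})$ — both of which the flow already receives — so the history
window carries no predictive information and the spatial attention weights
cannot be learned from the likelihood at all. The shared gain turns planted
synchrony into a higher-order *predictive* structure (recent partner
activity reveals the trial's gain, which predicts upcoming ISIs), which is
precisely the kind of structure the attention encoder is built to exploit.

The benchmark conditions (`defaultBenchmarkConfig`): 12 units, of which
units 1–6 form one synchronized PN-like group and 7–12 are independent
LN-like units; four behavioral stimuli drive the whole sync group through a
shared mother process, each of the three non-behavioral stimuli evokes a
distinct *pair* of independent units (emulating single odorants and partial
blends that activate small neuron subsets), and the control evokes nothing;
5 Hz baseline, 25 Hz evoked.

The simulator does **not** emulate: oscillatory population rhythms and
phase-locked spiking, slow drift and adaptation across a session, spike
sorting noise (lost or merged spikes), inhibitory interactions (LN-like
units here are "regular", not functionally inhibitory), or biophysical
conductances. Passing the planted-recovery studies therefore shows that the
pipeline recovers synchrony expressed as shared-gain common input with
millisecond coincidences; it does not certify performance under real
recording artifacts.

## Reduced-scale study conditions

The end-to-end studies run per-neuron training many times, so the evaluation
driver (`benchmarkClusteringStudy`) uses reduced model sizes chosen up front:
hidden 12, embed 4, 3 flow layers of width 24, Adam at 3e-3, batch 256, 50
epochs with patience 8, two trial rotations per simulated replicate, 10
simulated replicates for the main comparison and 5 for the 5 ms window
sweep. The flow-fidelity study trains on 5000 gamma ISIs (shape 2, mean
0.1 s) for 200 epochs and compares 2000 model samples against 2000 held-out
draws. The typing study simulates 20 + 20 units with 5 s of spontaneous
activity and scores a stratified held-out half.

## Numerical and degenerate-case choices

- Sparsemax ties: the sort-threshold algorithm handles ties naturally
  (equal logits share mass); an empty input is an error.
- Flow inversion: Newton on the bend from the starting point $v = u$,
  tolerance $10^{-13}$, at most 100 iterations; the derivative is bounded in
  $[1 - a_{\max},\, 1 + a_{\max}]$ so the iteration is globally stable.
- Quadrature checks of $\int p(\tau)\,d\tau$ integrate in $y = \log\tau$
  between the preimages of $z = \pm 10$, split at the mode, so narrow
  densities cannot be missed.
- Units with fewer than two spikes in a series contribute no training
  examples; a unit with no examples at all is an error naming the unit.
- A stimulus with no spikes in the evaluation trials contributes no row to
  that unit's $B^n$ (warning); the row average skips missing models.
- Zero baseline variance in the PSTH z-score and zero rate variance in the
  response index are errors, not NaNs.
- First spike of a trial: conditioning uses $t_{i-1} = 0$ with an empty
  (zero-padded) window.

## Known limitations

Single-unit ablation under the bundled benchmark has little resolving power:
a six-member synchronized group is highly redundant (removing one column of
$B$ barely changes the behavioral-row contrast), while each non-behavioral
stimulus depends on exactly two independent units, so the sync-vs-independent
ablation contrast is small relative to replicate noise and its sign is not
stable across simulated batches. Ablation analysis becomes informative when
an ensemble contains genuinely critical units, not in this redundant design.

One model per neuron per rotation makes the full pipeline
$O(N \times \text{rotations})$ training runs; the package targets small
ensembles. Attention interpretability is empirical, not guaranteed — the
activity-aligned initialization and the planted-recovery studies are the
package's evidence, and both are exercised in `tests/` and
`scripts/acceptance.R`. The "augmented" two-dimensional coupling variant of
the flow is not implemented; the scalar monotone layers are strictly more
expressive than scalar affine couplings and keep likelihoods exact.
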