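---
title: "Methods: unsupervised latent features and explainable plant classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised latent features and explainable plant classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Convolutional networks classify plant imagery extremely well, but their
decisions are hard to audit: a model may key on background regions that merely
*correlate* with the label (the clever-Hans effect) rather than on the plant
itself. `plantlatent` implements the alternative route: learn image features
**without labels**, keep only the features that demonstrably relate to the
label, classify with a conventional ν-SVM, and — crucially — *visualize every
feature used* as a saliency map whose important pixels are identified by a
formal significance test. Nothing the classifier uses is hidden: if a
label-correlated artifact drives the features, it shows up in the maps.

All images are first converted to the excess-green vegetation index
\[
I_{ExG} = 2 I_G - I_R - I_B,
\]
which brightens green vegetation against soil and stones. ExG values are kept
real-valued internally; only the autoencoder input is mapped affinely to
$[0,1]$ (as $(x + 510)/1020$) because its binary-cross-entropy loss needs
unit-interval targets.

# Stage one: two unsupervised latent models

## Bayesian GP-LVM

The data matrix $Y \in \mathbb{R}^{N \times D}$ (rows = flattened ExG images,
column-centered; the package additionally standardizes the overall scale for
numerical conditioning and folds it back in the projection) is modeled by $D$
Gaussian processes mapping a latent space $X \in \mathbb{R}^{N \times d}$ to
the pixels, with an RBF kernel with automatic relevance determination (ARD),
\[
k(x, x') = \sigma_f^2 \exp\Big(-\tfrac12 \sum_{q=1}^{d} \alpha_q (x_q - x'_q)^2\Big),
\]
Gaussian noise with precision $\beta$, and a standard-normal latent prior.
Inference uses the factorized Gaussian variational posterior
$Q(X) = \prod_n \mathcal{N}(x_n \mid \mu_n, S_n)$ together with a set of
auxiliary (inducing) points, yielding the collapsed sparse variational lower
bound on the marginal likelihood. The bound and its analytic gradients with
respect to every parameter block ($\mu$, $S$, the inducing inputs, $\alpha$,
$\sigma_f^2$, $\beta$) are maximized jointly with L-BFGS-B; the gradients are
verified against finite differences in the unit tests. The latent
**expectations** $\mu_n$ are the features.

Numerical choices that matter:

* **Initialization.** Latent means start at PCA scores rescaled to unit
  variance per dimension, latent variances at 0.5, inducing inputs at a random
  subset of the initial latent points, ARD weights at 1.
* **Two-phase optimization.** The noise precision is initialized at the
  $d$-component PCA residual variance and *frozen* for a first optimization
  phase before all parameters are released. A single joint phase reliably
  collapses to the zero-signal optimum ($\sigma_f^2 \to 0$, everything
  explained as noise) on image data; anchoring $\beta$ at a value consistent
  with what the initial latents can explain removes that attractor.
* **Convergence.** Relative bound-change tolerance $10^{-6}$ (L-BFGS-B
  `factr`), iteration cap 1000 by default; the returned trace is the incumbent
  (best-so-far) bound per evaluation and is monotone by construction.
* **Relevances.** The ARD relevance of latent dimension $q$ is the inverse
  squared lengthscale $\alpha_q$, reported damped by the fitted signal
  fraction $\sigma_f^2/(\sigma_f^2 + \beta^{-1})$. For any fit with
  appreciable signal the factor is $\approx 1$; for a pure-noise fit the
  kernel lengthscales are unidentifiable (the bound is flat in $\alpha$ once
  $\sigma_f^2 \approx 0$) and the damping reports what that fit means — no
  relevant dimensions. The factor is shared by all dimensions, so orderings
  and the median-increase rule below are unaffected.
* **Jitter.** $10^{-6}\sigma_f^2$ on the inducing-kernel diagonal.

Hyperparameters follow a step-wise procedure: the initial $d$ is the number of
principal components explaining 75% of variance; the number of auxiliary
points is the *smallest* grid value whose bound reaches 95% of the grid
maximum; $d$ is then the bound maximizer over its grid. Because log-likelihood
bounds are typically negative, "95% of the maximum" is realized as
$\text{bound} \ge \max - 0.05\,|\max|$, which reduces to the literal rule for
positive bounds. The study-scale grids ({50,75,100,125,150} auxiliary points,
{10,25,50,75,100,150} dimensions) are the documented defaults; the examples
and tests use desk-scale grids (tens of points, $d \le 8$), and the vignette's
problem sizes throughout (e.g. 200 images at 32×32, 150×256 recovery
simulations) were chosen as the smallest sizes at which the statistical
properties under test are comfortably identifiable.

New latent points are projected to image space through the sparse-GP posterior
mean $\mathbb{E}[f(x_*)] = \beta\, k_{*m} A^{-1} \Psi_1^\top Y$ (with
$A = \beta \Psi_2 + K_{mm}$), plus the column means.

## Convolutional autoencoder

The second latent model is a convolutional autoencoder on the $[0,1]$-scaled
ExG images: stride-2 3×3 convolutions with ReLU (default 16–32–64 channels),
a linear bottleneck — the *code*, used as the feature vector — and a mirrored
decoder of stride-2 4×4 transposed convolutions ending in a sigmoid. Training
minimizes binary cross entropy with Adam (learning rate $10^{-3}$, batch size
8) on shuffled minibatches; everything is seeded and single-threaded, so runs
are bit-reproducible. The convolution forward/backward passes are implemented
as shift-and-multiply matrix products and are finite-difference-checked in the
tests. The compact conv stack is the default because a pretrained
ImageNet-scale backbone is neither necessary for these images nor defensible
as a fixed arbitrary choice; deeper stacks can be passed through
`encoder_spec`.

The code size is selected over a grid ({10,20,50,75,100} at study scale) by
the lowest mean squared reconstruction error, with several independently
seeded trainings per grid value. The MSE is computed on a held-out 20% split:
a training-set MSE would always favor the largest code, while the held-out
error is the quantity a practitioner actually wants minimized.

# Stage two: feature selection

**ARD relevance rule (GP-LVM path only).** Sort the relevances; each
feature's *relevance increase* is its gap to the next-smaller relevance; the
threshold is the median increase. Walking from the most relevant feature
downward, features are kept until the first one whose increase falls strictly
below the median. Two conventions make the rule total: the most relevant
feature anchors the walk and is always informative (a small gap between two
*top* features signals two informative features, not the flat tail the rule
is hunting for), and with all increases equal nothing falls strictly below
the median, so everything is kept. The rule is scale-invariant and label-free,
so it may be applied once, outside cross-validation, without leakage.

**Spearman selection (both paths).** Each surviving feature is tested for a
monotone relation with the binary label using Spearman's rank correlation
(Pearson correlation of average-tie ranks; exact two-sided p by full
enumeration of the $n!$ rank permutations for $n \le 9$, the usual
$t$-approximation otherwise). Features with $p \le \alpha = 0.1$ are kept —
the features with a *significant* relation to the label. No multiplicity
correction is applied by default, matching the procedure being implemented; a
Benjamini–Hochberg option exists behind a flag. Autoencoder codes carry no
ARD relevance and enter the Spearman stage directly.

# Saliency maps and their significance

To see what latent dimension $q$ encodes, build $N$ latent vectors equal to
the mean latent expectation except in entry $q$, which takes each sample's
actual expectation; push all $N$ vectors through the model's image-space
projection (GP posterior mean, or the decoder); the **pixel-wise variance**
of the projections is the saliency map. A linear projector makes the
construction transparent: the map is exactly
$\mathrm{Var}(\mu_{\cdot q})\, w_q^2$ pixel-wise, which the tests assert.

Raw maps put the burden of interpretation on the viewer, so important pixels
are identified by a randomization test. Under the null, saliency entries are
drawn from a marked homogeneous spatial Poisson process — sparse, spatially
unstructured mass. The observed map is smoothed with a unit-sum $k \times k$
Gaussian kernel ($k = 5$; $\sigma = 0.3((k-1)/2 - 1) + 0.8 \approx 1.1$, a
conventional kernel-size/σ pairing; zero padding) to give
$s_{\text{alt}}(x,y)$; each of $N$ randomizations permutes all pixel values
uniformly and is smoothed identically to give $s_{\text{null}}(x,y)$; a
randomization supports the null at a pixel when
$s_{\text{alt}} \le s_{\text{null}}$ (ties conservatively favor the null).
The pixel-wise p-value is $(n_{\text{null}} + 1)/(N + 1)$, never exactly
zero and asymptotically the plain fraction. Thresholding at a small $\alpha$
(0.001 in the full-scale configuration, with $N = 10^4$) gives the
significant-pixel mask; masks are nested in $\alpha$. Permuting all pixels
realizes the homogeneous null for any map; relocating only the nonzero marks
is equivalent for sparse maps and available as an option. Maps with negative
entries (external relevance maps) are clipped at zero first, since the null
model assumes nonnegative marks. Note that $\alpha$ must exceed $1/(N+1)$, or
no pixel can be significant.

The test's calibration (pixel-pooled false-positive rate ≈ α on maps drawn
from the null) and power (detection of an injected high-mark block) are both
exercised in the acceptance tests, as is end-to-end localization: on
synthetic imagery, the significant pixels of the selected features'
maps are compared against the union of ground-truth foreground masks dilated
by the smoothing-kernel radius.

# Classification and evaluation

Selected features are classified by a ν-SVM with RBF kernel. The
hyperparameters $(\nu, \gamma)$ are tuned by Bayesian optimization — a GP
surrogate on the unit square with expected-improvement acquisition, ten
random initialization points and ten acquisition points — maximizing inner
cross-validation accuracy, with search ranges $\nu \in [0.01, 0.5]$ and
$\gamma$ log-uniform in $[10^{-4}, 10]$ (a safe feasibility region for the ν
formulation; infeasible points are penalized and never returned). The
protocol is 10 iterations of 5-fold cross-validation on reshuffled,
unstratified splits. Within every training split — before the test fold is
touched — Spearman selection is refit and the SVM is tuned; class
probabilities come from a logistic (Platt-style) calibration of the SVM
decision values, fitted on the training folds. The label-free relevance rule
is applied once up front. A `paper_faithful` flag instead performs the
selection once on the full data before cross-validation (the pipeline-diagram
ordering), at the documented cost of selection leakage; it is off by default.

Metrics:

* **Accuracy** per fold, per iteration, and the grand mean.
* **Mutual information** between true and predicted labels, plug-in estimate
  on the pooled per-iteration confusion matrix, in bits; any accuracy above
  50% on balanced labels gives MI > 0. Hard labels are the default; a
  probability-weighted variant (expected counts under the predictive
  probabilities) sits behind a flag.
* **McNemar's test** on paired predictions of two models: discordant counts
  $b, c$; continuity-corrected statistic $(\,|b-c|-1)_+^2/(b+c)$ always
  reported; exact two-sided binomial p below $b + c = 25$, the $\chi^2(1)$
  tail above; $b + c = 0$ means indistinguishable models and p = 1.

# The synthetic image generator

Every stage is testable without field data through a generator that emulates
square RGB crops from row-crop imagery: brown/gray soil with smooth
low-frequency texture and per-channel noise, gray stone ellipses (both with
ExG ≈ 0), and, on plant images, a connected rosette of rotated ellipse lobes
(`leaf_complexity` controls lobe count — low values emulate simple entire
leaves, high values dissected rosettes) whose pixels have a controlled mean
ExG excess and are recorded exactly in a ground-truth mask. Background images
may carry small green distractor blobs capped at 5% of the image area
(mirroring "other plants" in real background crops) that are *not* counted as
foreground. An optional confound paints a small saturated-green corner marker
with probability $\rho_c$ on plant images and $1 - \rho_c$ on background
images — label-correlated background structure with ExG signal, never added
to the masks — so clever-Hans behavior has a known ground truth. All
randomness flows from one master seed through a counter-based splitter, so
outputs are reproducible regardless of call order.

What the generator does **not** emulate: photorealistic soil or leaf texture,
illumination and perspective variation, occlusion between plants, or the
bounding-box extraction of a detection pipeline. Passing tests on this
imagery demonstrates the machinery (calibration, recovery, localization,
confound exposure) — not field-grade classification performance.

# Known limitations

* The B-GP-LVM optimization is non-convex; different seeds can land on optima
  whose bounds differ in the third significant digit. Grid selections
  therefore fix the seed across grid values.
* The saliency null assumes exchangeable pixels (homogeneous process);
  strongly inhomogeneous but label-irrelevant backgrounds would require an
  inhomogeneous null, which is out of scope.
* The relevance elbow rule assumes a clear drop between informative and
  uninformative dimensions. On small data sets the fitted relevance profile
  can be nearly flat, and the rule may then prune informative dimensions; the
  per-split Spearman stage cannot recover a dimension the relevance rule
  discarded. Inspecting the relevance profile (`print(model)`) before
  trusting the pruning is cheap and recommended.
* The exact Spearman enumeration is limited to $n \le 9$; beyond that the
  $t$-approximation is used, as in common practice.
* Binary labels only, matching the task the pipeline addresses.
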