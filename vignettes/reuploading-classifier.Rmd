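---
title: "A data-reuploading variational classifier for softmax score vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A data-reuploading variational classifier for softmax score vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reuploadr)
```

## The problem and the model

`reuploadr` simulates and trains the quantum half of a hybrid
classification pipeline. Upstream, a convolutional network turns a brain
MRI slice into a softmax **score vector**: four probabilities for the
classes *no tumor* (0), *meningioma* (1), *pituitary tumor* (2) and
*glioma* (3). Downstream — the part this package implements — a small
variational quantum circuit takes that 4-vector and produces the final
class decision. The package deliberately contains no image handling and no
network inference; the interface is the score vector itself, which makes
the whole quantum stage testable on any machine.

The circuit is a **data-reuploading classifier** on four qubits. A
single-qubit state can famously not be split into "input loading" and
"processing" stages the way a deep network can, but re-injecting the input
between every trainable block restores expressivity: the circuit
alternates between encoding and processing, layer after layer. Concretely,
with trainable angles $(\varphi_{lq}, \theta_{lq}, \omega_{lq})$ for layer
$l$ and qubit $q$, each layer applies

$$\mathrm{Rot}(\varphi_{lq} + \pi x_q,\; \theta_{lq} + \pi x_q,\;
  \omega_{lq} + \pi x_q) \quad\text{on qubit } q,$$

followed by the entangling cascade $\mathrm{CNOT}(0,1)$,
$\mathrm{CNOT}(1,2)$, $\mathrm{CNOT}(2,3)$. Here
$\mathrm{Rot}(\varphi,\theta,\omega) = R_z(\omega) R_y(\theta)
R_z(\varphi)$ is the general single-qubit rotation (z-axis, then y-axis,
then z-axis again), and $x_q$ is the $q$-th score component. Each of the
four score components thus has a dedicated qubit, every layer re-uploads
the data, and one layer exposes exactly $3 \times 4 = 12$ trainable
angles; the default six layers expose 72.

Classes are read out by the Born rule. The joint outcome distribution of
qubits 0 and 1 over $\{00, 01, 10, 11\}$ is taken as the class
distribution (qubit 0 contributing the more significant bit), and the
predicted class is its argmax with ties broken toward the lower index. Two
readout qubits are the minimal surjective mapping onto four classes; any
fixed bijection would do, and relabelling outcomes merely permutes the
output probabilities. For two-class problems (e.g. tumor vs. no tumor, or
high- vs. low-grade glioma score pairs) the same circuit is used with the
marginal of qubit 0 alone (`ansatz_config(n_classes = 2)`); a
two-component score vector then drives qubits 0 and 1 and the remaining
qubits receive a zero injection.

### Why these exact conventions

Three conventions are fixed once and tested rather than left configurable:

* **Qubit ordering.** Qubit 0 is the leftmost tensor factor, i.e. the most
  significant bit of the basis index. `apply_1q(zero_state(2),
  gate_hadamard(), 0)` populates $|00\rangle$ and $|10\rangle$.
* **RY is the real rotation.** $R_y$ has off-diagonal entries $\mp\sin
  (\varphi/2)$ with no imaginary unit. A variant with $-i\sin$
  off-diagonals on both sides would coincide with $R_x$ and could not act
  as a second, distinct rotation axis; the Bloch-sphere picture of three
  independent axes forces the real form. `Rot` likewise is *defined* by
  its z–y–z action, and the test suite pins it entrywise to the explicit
  product $R_z(\omega) R_y(\theta) R_z(\varphi)$ rather than to any
  transcribed entry table.
* **Exact simulation.** States are dense complex vectors of length $2^n$
  (capped at $n = 12$); probabilities are exact squared magnitudes. No
  shot sampling and no density matrices: the classifier consumes exact
  Born probabilities, which keeps training deterministic and gradients
  noise-free.

## Loss, gradients and the optimizer

The parts of the model that no convention fixes — the loss and the
gradient method — are standard choices. Training minimizes the mean clipped cross-entropy

$$\mathcal{L} = \frac{1}{B} \sum_{i=1}^{B}
  -\log \max(p_{y_i}(x_i;\Theta),\ 10^{-12}),$$

the default objective for a probabilistic multi-class model. The clip at
$10^{-12}$ keeps the loss finite and non-negative; below the clip the loss
is flat and the gradient is defined as zero there.

Two gradient routes are implemented and pinned against each other:

* **Parameter-shift** (default). Every trainable angle parameterizes one
  rotation whose generator has eigenvalues $\pm\tfrac12$, so each readout
  probability is sinusoidal in that angle and
  $\partial p / \partial\vartheta = \tfrac12\left(p(\vartheta + \pi/2) -
  p(\vartheta - \pi/2)\right)$ *exactly*. The loss derivative follows by
  the chain rule through $-\log p$. This is the exact gradient at the same
  cost as finite differences (two circuit evaluations per angle), which is
  why it is the training default.
* **Central finite differences** with step $h = 10^{-6}$ on the batch
  loss, the plainest possible oracle. The suite requires the two methods
  to agree to $10^{-5}$ on random instances; in practice they agree to
  about $10^{-8}$, consistent with the $O(h^2)$ truncation plus
  $O(\varepsilon/h)$ round-off of central differences.

The optimizer is RMSProp in its textbook form: an exponential moving
average $a \leftarrow \rho a + (1-\rho) g^2$ of the squared gradient and
the update $\Theta \leftarrow \Theta - \eta\, g / (\sqrt{a} +
\varepsilon)$. Reference configuration, exposed as `train_config()`:

| parameter | default | meaning |
|---|---|---|
| `n_qubits` | 4 | one qubit per score component |
| `n_layers` | 6 | reuploading layers |
| `learning_rate` | 0.01 | RMSProp step size (per update) |
| `batch_size` | 26 | samples per gradient step |
| `epochs` | 50 | full passes over the training set |
| `rho` | 0.9 | squared-gradient decay |
| `epsilon` | 1e-8 | denominator stabilizer |
| `seed` | 1 | drives initialization and shuffling |

The count of 50 is read as *epochs* (full passes), the natural reading for
per-epoch loss curves. Angles are initialized uniform on $(-\pi, \pi)$ —
the natural uninformative choice on a periodic domain; `rho` and `epsilon`
are the standard RMSProp defaults. The final incomplete batch of an epoch
is used, not dropped. Every source of randomness (initialization, epoch
shuffles, the synthetic generator, the stratified split) is derived from
an explicit seed without touching the caller's RNG stream, so identical
configurations reproduce bitwise-identical checkpoints.

## The synthetic generator, and what passing tests mean

Real score vectors come from a trained CNN on clinical images; neither is
desk-reproducible, so `generate_scores()` emulates them. Softmax outputs
live on the probability simplex, and the Dirichlet family is the canonical
distribution there: for true class $c$ the generator draws from
$\mathrm{Dir}(\alpha)$ with $\alpha_c = $ `concentration_true` and
$\alpha_{j \ne c} = $ `concentration_other`. One ratio controls
separability: equal concentrations give label-free noise (argmax accuracy
$\approx 1/K$), while the default 50 : 1 gives nearly one-hot vectors — a
reasonable stand-in for a well-trained CNN front-end, whose softmax
outputs are similarly saturated. `bayes_accuracy()` estimates the argmax
rule's accuracy under the generator by Monte Carlo; for this mixture the
argmax rule is the Bayes rule, so it is the ceiling for any downstream
classifier and is what end-to-end expectations are calibrated against
(about 0.9999 at 50 : 1).

What the generator does *not* emulate: the geometry of real CNN
confusions. Real softmax errors are structured (meningioma and glioma
slices get confused in correlated ways; scores are miscalibrated), while
Dirichlet errors are exchangeable across the wrong classes. A passing
end-to-end run therefore shows that the circuit, loss, gradients and
optimizer can jointly recover a separable decision rule on the simplex —
it does not certify any accuracy on clinical data, which depends on the
upstream network and dataset.

The reference experiment (the one `scripts/acceptance.R` reruns) is:
200 samples per class, four classes, concentration 50 : 1, stratified
70 : 30 split, reference training configuration, five seeds. The
expectation is at least 90 % held-out accuracy on at least four of five
seeds with a falling loss curve; observed runs reach 100 % on all five,
with the mean training cross-entropy falling from roughly $\ln 4$ toward
0.02–0.04 over 50 epochs.

## Numerical choices

* **Tolerances.** Gate unitarity and state norms are asserted at
  $10^{-10}$; matrix identities (the z–y–z decomposition, oracle
  equivalence against full Kronecker-product matrices) at $10^{-12}$.
  These sit three-plus orders above double-precision round-off for
  16-amplitude circuits, so they fail on real defects, not on noise.
* **States equal up to phase.** Global phase is unobservable; tests that
  compare prepared states use the overlap criterion
  $|\langle a|b\rangle| = 1$ within $10^{-10}$ where a phase could differ.
* **Compiled inner loop.** The training path (batched forward, loss, both
  gradients) is implemented in C++; the pure-R gate algebra
  (`apply_1q()`, `apply_cnot()`, `build_layer()`) is the readable
  reference, and the suite pins the compiled forward to the R composition
  and to an independent Kronecker-product oracle at $10^{-12}$. A
  full-precision training run (5 seeds × 560 samples × 50 epochs) takes
  about a minute on one CPU.
* **Checkpoints.** JSON with angles at 17 significant digits — the
  round-trip is bit-exact, which the suite asserts. CSV score files
  likewise round-trip exactly.
* **Degenerate inputs.** Empty batches, out-of-range labels, non-finite
  angles, non-unitary gates, duplicate readout indices and malformed CSV
  rows all raise immediate, named errors; a confusion-matrix cell with a
  0/0 metric reports 0 with a warning rather than NaN.
* **Per-class accuracy** is one-vs-rest: $(TP + TN)/\text{total}$ for
  each class against all others — the only standard reading when a
  distinct accuracy is reported per class next to precision and recall.
  Micro-averaged recall equals overall accuracy, which the suite checks.

## Known limitations

* Four and two classes only; a $K$-class readout for other $K$ would need
  a different outcome-to-class mapping.
* No shot-noise model: results are idealized relative to hardware
  execution.
* The linear CNOT cascade is fixed; no ansatz search or alternative
  entangling topologies.
* The compiled fast path assumes the readout qubits are the leading ones;
  other readout sets fall back to the slower R route.
* Synthetic Dirichlet scores are exchangeable across wrong classes — see
  above for why that limits what accuracy claims transfer to real data.
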