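---
title: "Convolution on coevolution: methods and design notes"
author: "coconet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convolution on coevolution: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Homologous structured RNAs conserve their base-pairing pattern more than
their sequence, so columns of a deep RNA multiple sequence alignment (MSA)
that pair in the structure covary. Direct coupling analysis (DCA) turns
that covariation into a ranked list of candidate nucleotide--nucleotide
contacts; but raw DCA score maps are noisy, and true RNA contacts are not
scattered: they come in ordered motifs, most prominently the anti-diagonal
ridges of helical stems. This package layers a single, shallow, linear
convolution over the DCA score map so that the local neighbourhood of each
pair is allowed to vote on it, and learns the convolution weights from
structures.

## The coevolutionary layer

Sequences are encoded over the fixed five-state alphabet (A, C, G, U, gap);
the alignment is first trimmed to the columns where the designated target
sequence has no gap, so all coordinates below are 1-based positions in the
ungapped target of length $L$.

The generative model is a pairwise Potts model,
$$P(\sigma) = \frac{1}{\mathcal{Z}} \exp\Big(\sum_{i<j} J_{ij}(a_i,a_j)
  + \sum_i h_i(a_i)\Big),$$
inferred in the mean-field approximation. Sequence $m$ receives weight
$\omega_m = 1/|\{m' : \mathrm{id}(m,m') \ge t\}|$ (identity fraction over
all columns, gaps compared like any state; threshold $t = 0.8$ by default)
and $M_\mathrm{eff} = \sum_m \omega_m$. Frequencies are reweighted and
regularized with a pseudocount $\lambda$:
$$f_i(a) = \frac{\lambda/q + \sum_m \omega_m \delta_{a,a_i^m}}
  {M_\mathrm{eff}+\lambda}, \qquad
  f_{ij}(a,b) = \frac{\lambda/q^2 + \sum_m \omega_m
  \delta_{a,a_i^m}\delta_{b,a_j^m}}{M_\mathrm{eff}+\lambda},$$
with $q = 5$. Couplings are the negative inverse of the connected
correlation matrix $C_{ij}(a,b) = f_{ij}(a,b) - f_i(a) f_j(b)$. Because
$C$ is gauge-singular over the full alphabet, the inverse is taken in the
reduced basis of $q-1$ states per site with the gap as the excluded
reference state; diagonal site blocks use the single-site statistics
$\mathrm{diag}(f_i) - f_i f_i^\top$.

Each pair is then scored by direct information,
$$\mathcal{DI}_{ij} = \sum_{a,b} p^{\mathrm{dir}}_{ij}(a,b)
  \log \frac{p^{\mathrm{dir}}_{ij}(a,b)}{f_i(a) f_j(b)}, \qquad
  p^{\mathrm{dir}}_{ij}(a,b) \propto \exp\big(J_{ij}(a,b) + \tilde h_i(a)
  + \tilde h_j(b)\big),$$
where the two-site fields $\tilde h$ are fitted so that the marginals of
$p^{\mathrm{dir}}$ reproduce $f_i$ and $f_j$. The sum runs over all five
states including the gap. DI is a Kullback--Leibler divergence, hence
nonnegative, and the map is symmetric by construction.

### Numerical choices in the DCA layer

* **Pseudocount.** $\lambda = 0.5\, M_\mathrm{eff}$ by default, the
  established mean-field DCA relative pseudocount; it is exposed as a
  parameter because no single value suits every alignment depth.
* **Similarity threshold.** 0.8, the mean-field DCA literature standard;
  also exposed.
* **Field fitting.** An alternating marginal-matching fixed point
  (iterative proportional fitting in multiplicative form), tolerance
  `1e-6` on the maximum marginal residual, at most 500 sweeps, with a hard
  error (never a silent result) on non-convergence. The fixed point is
  the stationary condition of a convex dual, which is how the test suite
  cross-checks it with a generic optimizer.
* **No average-product or entropy correction** is applied to DI; the
  convolutional layer that follows is the noise-suppression step.
* A subtlety worth recording: the textbook claim "independent sites give
  $J \approx 0$" holds in the regime where the reduced correlation matrix
  is well conditioned. For gap-free data the four nucleotide frequencies
  sum to one, the reduced basis is compositionally almost closed, and the
  small uniform offset that the $\lambda/q^2$ versus $(\lambda/q)^2$
  pseudocount mismatch leaves in $C$ is amplified into a uniform offset in
  $J$. This offset is constant across states, is largely absorbed by the
  fitted two-site fields, and has no practical effect on DI ranking; the
  unit tests therefore probe the independence property with data that
  populate all five states.

## The convolutional layer

The $L \times L$ DI map is zero-padded by $p = (d-1)/2$ and convolved
(cross-correlation orientation, no kernel flip) with a $d \times d$ filter,
$d \in \{3, 5, 7\}$:
$$\mathrm{out}(i,j) = \sum_{u,v=1}^{d} \mathcal{W}(u,v)\,
  \mathcal{D}\big(i+u-1-p,\; j+v-1-p\big).$$
Zero padding preserves the "no signal" meaning of the border. In **dual
mode** the map is split by the Watson--Crick mask of the target sequence
(`TRUE` where positions $i,j$ hold (A,U) or (C,G) in either order; G·U is
non-WC): the WC part is convolved with one filter, the complement with the
other, and the two results are summed. The output layer sorts pairs with
$j > i + 4$ by decreasing score (ties broken by ascending $(i,j)$) and
keeps the top $n$.

Because the input map is symmetric but a learned filter need not be, the
convolved map is symmetrized as $(\mathrm{out} + \mathrm{out}^\top)/2$ for
prediction. An identity filter (1 at the centre) reproduces the raw DCA
ranking exactly, which anchors the layer's correctness tests.

## Learning the filter

Given training families $R$ with DI maps $\mathcal{D}^R$ and binary
contact labels $\delta(\mathcal{C}^R_{ij})$ (1 iff the minimum heavy-atom
distance is strictly below 10 Å), the cost is the single-batch convex
least-squares objective
$$\mathcal{F} = \sum_R \sum_{j>i+4}
  \big(\mathcal{W} * \mathcal{D}^R_{ij} - \delta(\mathcal{C}^R_{ij})\big)^2,$$
minimized by L-BFGS-B with the analytic gradient (the residual
back-correlated onto each window entry). Design choices:

* **Raw convolution in the objective.** The training residuals use the
  unsymmetrized cross-correlation on the upper triangle. If the
  symmetrized output were used instead, $\mathcal{W}$ and
  $\mathcal{W}^\top$ would be indistinguishable, the quadratic design
  would be rank-deficient by construction, and the minimizer would not be
  unique; with the raw form the design is generically full rank, planted
  filters are recovered exactly, and symmetrizing at prediction time
  changes no ranking decision that training cares about.
* **Zero initialization**; convexity makes the start cosmetic, zero is
  deterministic. Convergence: projected-gradient tolerance `1e-8`, at
  most 1000 iterations. A rank-deficient design (too few in-band pairs
  for $d^2$ or $2d^2$ parameters) triggers a warning rather than an
  error, since the minimum-cost solution is still usable.
* **Labels are strictly 0/1** with no class re-weighting. (For
  calibration tests the training functions also accept plain
  `list(di=, labels=)` entries with continuous labels.)
* Per-family DI maps are computed once and cached in the training pairs;
  the DCA stage has no trainable parameters.

Generalization is measured by strict $k$-fold cross-validation
($k = 5$): families are randomly partitioned into balanced folds (sizes
differ by at most one), each fold is predicted by a model trained on the
others, and the whole procedure is repeated (10 times by default) with
fresh seeded splits; reported metrics are the unweighted mean over all
held-out family evaluations.

## Evaluation

* **PPV($n$)**: true contacts among the $n$ top-ranked candidate pairs,
  divided by $n$; candidates are restricted to $|i-j| > 4$ and, for the
  tertiary stratum, to pairs that are neither nested secondary-structure
  pairs nor within a $5 \times 5$ window (Chebyshev radius 2) of one.
  Pseudoknot pairs are not 2D pairs here, so they neither count as
  secondary nor generate exclusion windows. Window semantics are
  Chebyshev (a square window); per-axis semantics would differ only on
  the window corners.
* **MCC at rank $n$**: the standard Matthews coefficient with the top-$n$
  pairs as predicted positives and all candidate pairs as the universe;
  degenerate margins give 0 with a message. Reported at $n = L$ by
  default.
* **Window patterns**: the mean $7 \times 7$ patch of the padded DI map
  around pairs, binned by minimum heavy-atom distance
  ($r \le 4$, $4 < r \le 10$, $r > 10$ Å), optionally excluding a
  $9 \times 9$ neighbourhood of every 2D pair to isolate tertiary
  signal. On stem-bearing data the near bin shows the anti-diagonal
  ridge that motivates the convolution.

Structures are read from PDB/mmCIF; heavy atoms are element $\ne$ H/D,
alternate locations keep the highest-occupancy conformer, and insertion
codes are preserved. Chain residues map onto the target by exact ungapped
subsequence match or an explicit user-supplied mapping -- deliberately
never by automatic pairwise alignment, because a silent misalignment
corrupts training labels.

## The synthetic data generator

Every stage is testable offline against seeded fixtures drawn from the
model class the inference assumes: a pairwise Potts model with planted
topology.

* **Topology.** Hairpin stems (default two stems of five pairs) carry
  Watson--Crick couplings ($\beta_\mathrm{stem} = 2$ on the (A,U)/(C,G)
  combinations); isolated tertiary pairs carry a weaker non-WC
  covariation pattern ($\beta_\mathrm{3D} = 0.8$), reflecting the
  observation that tertiary-contact coevolution is much weaker than stem
  coevolution. The gap state carries a negative field so gaps stay rare,
  as in curated seed alignments.
* **Sampling.** Single-site heat-bath Gibbs sampling (compiled), burn-in
  $100L$ sweeps, thinning 10 sweeps, fully driven by R's RNG so a seed
  reproduces files byte-for-byte. The target row is drawn from the same
  model with the gap state disallowed, so sampled families are already in
  target coordinates. Sampler correctness is checked against exact
  enumeration on tiny systems.
* **Ground truth is schematic.** Planted pairs sit at 3 Å; the Chebyshev-1
  neighbours of stem pairs at 8 Å (emulating the thick anti-diagonal
  contact bands a 10 Å heavy-atom cutoff produces around real helices);
  chain neighbours at $2|i-j|$ Å; everything else at 20 Å. These
  distances exist to exercise the 10 Å threshold, the distance bins and
  the stratification logic -- they are not a model of RNA geometry, and
  the synthetic PDB writer likewise emits schematic coordinates labelled
  as such.
* **Study sizes.** The end-to-end study uses 10 families, $M = 2000$
  sequences each, lengths drawn from 36--44 -- deep-alignment conditions
  where mean-field DCA is reliable. Passing a vector for `M`
  (e.g. `c(2000, 60)`) spans the $M_\mathrm{eff} = 70$ split used to
  stratify real families by alignment depth. Unit tests use smaller
  fixtures chosen for the property under test.

**What passing synthetic tests does and does not show.** The generator
matches the inference's own model class, plants cleanly separated signals
and pairs them with noise-free labels; real alignments have phylogenetic
correlation, alignment errors, covariation models the Potts form does not
capture, and structures with genuinely ambiguous contacts. The synthetic
improvement of the learned convolution over raw DCA therefore validates
the machinery and the direction of the effect, not any particular
percentage on real families. Reproducing published real-data accuracy
requires the external family alignments and structures; the machinery to
consume them (manifest -> training pairs -> cross-validation) is part of
the package.

## Known limitations

* Mean-field inversion scales as $O(L^3 (q-1)^3)$ memory/time; fine for
  typical structured RNAs (L up to a few hundred), not for very long
  sequences.
* The structure mapper requires the chain to be an exact subsequence of
  the target (or an explicit mapping); it will refuse rather than guess.
* Dot-bracket parsing treats every non-round bracket tier as pseudoknot;
  CT input carries no tier information, so CT pairs are all read as
  nested.
* One convolutional layer, at most two filters, no nonlinearity -- by
  design, to keep the parameter count (9 to 98) learnable from tens of
  structures.
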