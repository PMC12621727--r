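---
title: "Ensemble-conditioned Potts sequence design: models, samplers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-conditioned Potts sequence design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdesign)
```

## The model

`ensdesign` scores length-$L$ amino-acid sequences $S = (s_1, \dots, s_L)$
with a Potts model

$$E(S) = \sum_i h_i(s_i) + \sum_{i<j} J_{ij}(s_i, s_j), \qquad
p(S) = \frac{e^{-E(S)}}{Z}, \qquad Z = \sum_S e^{-E(S)},$$

where the fields $h$ ($L \times A$) score residue identities per site and
each coupling $J_{ij}$ ($A \times A$) scores residue pairs on an undirected
edge. Energies are dimensionless; lower means more favourable. Couplings are
stored as one dense block per edge keyed by the unordered pair, with the
first axis indexing the smaller site — k-NN-derived models are sparse, so
memory scales with the number of edges rather than $L^2 A^2$. Accessors
transpose transparently for reversed queries, so no pair is double-counted.

Given a conformational ensemble of $K$ backbones with identical residue
topology, the ensemble energy of a sequence is the average of the
per-conformer energies,

$$E_{\mathrm{ens}}(S) = \frac{1}{K} \sum_{k=1}^{K} E_k(S).$$

Because $E$ is linear in $(h, J)$, this equals the energy under a single
averaged model: fields are averaged entrywise and the edge set is the
*union* of the per-conformer edge sets with absent couplings treated as
zero. The union convention is what makes the averaging identity exact; an
intersection would silently discard constraints present in only some
conformers. At the distribution level,

$$p_{\mathrm{ens}}(S) \propto \prod_k p_k(S)^{1/K},$$

the renormalized geometric mean of the per-conformer sequence
distributions — a product of experts. Sequences favoured by the averaged
model are those compatible with *all* conformers, not a mixture of
per-conformer designs; the test suite asserts this distinction explicitly.
The same identity at the single-token level (softmax of averaged logits
equals the normalized weighted geometric mean of softmaxes) underlies
`geometric_mean_combine()` and tied autoregressive decoding. Uniform
weights $1/K$ are the default everywhere; non-uniform weights are supported
as an extension but nothing in the package's protocols depends on them.

Potts parameters carry gauge freedom: per-site constant field shifts and
row/column transfers between couplings and fields change $\log Z$ but no
probability. `apply_zero_sum_gauge()` maps any model to the canonical
representative with zero row and column means in every coupling block,
preserving per-sequence energies exactly (the shifted mass moves into the
fields). Comparisons between learned and generating parameters are only
meaningful in a fixed gauge, so every recovery experiment gauges both sides
first.

`enumerate_distribution()` is the package's exact oracle: it computes
$p(S)$ for all $A^L$ sequences in the log domain (log-sum-exp, stable to
$|E| \approx 700$) and refuses instances above a configurable cap,
$10^6$ states by default — large enough for every protocol below, small
enough to stay a desk-scale tool.

## Samplers

`dlmc_sample()` implements Discrete Langevin Monte Carlo as a factorized
locally-informed proposal: in one step, every site $i$ independently draws
a candidate residue $a$ with probability

$$q_i(a) \propto \exp\!\left(-\frac{\Delta_i(a)}{2T}
 - \frac{\mathbf{1}[a \neq s_i]}{2\,\eta}\right),$$

where $\Delta_i(a)$ is the composite single-site energy change evaluated at
the current state and $\eta$ is the step size controlling the proposal's
laziness. With the Metropolis–Hastings correction enabled (the default),
the joint proposal is accepted with the standard reverse-proposal ratio, so
the chain targets $p(S) \propto e^{-E_{\mathrm{comp}}(S)/T}$ *exactly* —
correctness is enforced by enumeration-oracle tests rather than assumed
from the construction. `gibbs_sample()` is the reference chain: a
systematic scan in a seeded random order per sweep, resampling each site
from its full conditional. Both cores are C++ (Rcpp) and draw exclusively
from R's RNG, so identical `(model, config, seed)` give identical output on
any platform.

Step units are sweeps (one DLMC joint proposal $=$ one Gibbs scan of $L$
sites), with conservative defaults `burn_in = 10 L` sweeps and
`thinning = 1`. The sampler-exactness protocols thin DLMC by 3 sweeps: MH
rejections leave consecutive duplicates in the chain, and a short thinning
restores near-independence at negligible cost. The default temperature is a
constant $T = 1$, matching the Boltzmann model as written; linear or
geometric schedules can be passed as an explicit per-sweep vector.

### The low-complexity restraint

The local composition perplexity (LCP) restraint discourages repetitive
stretches during sampling. For every window of `window` consecutive
residues (default 16), let $H$ be the natural-log entropy of the
pseudocount-smoothed composition and $P = e^{H}$ its perplexity (effective
number of residue types, between 1 and $A$). The penalty is a squared
hinge,

$$\mathrm{LCP}(S) = \sum_{\text{windows } w} \max(0,\ P_{\min} - P_w)^2,$$

added to the Potts energy with weight $\lambda$ (default 1). Defaults
`window = 16`, $P_{\min} = 8$, pseudocount 0.1 mean a 16-residue window is
penalized once it drops below roughly eight effective residue types; a
homopolymer window approaches the maximal penalty $(P_{\min}-1)^2$. The
functional form is this package's choice — smooth, local, and incrementally
updatable from single-count changes, which is what lets both samplers treat
the restraint exactly rather than approximately. The defaults are sensible
for 20-letter design and are not calibrated against any external
implementation.

## Structures, ensembles, and features

Backbones are per-residue N/CA/C/O coordinate records (Å). Reading goes
through `bio3d`; multi-MODEL files yield one structure per model; residues
missing a backbone atom are rejected by default, naming the residue (a
`drop` policy exists for sloppy files). Kabsch superposition uses the SVD
construction with the determinant correction so reflections are never
returned; ensemble diversity is the mean superposed CA RMSD of conformers
to the reference — the x-axis on which ensemble effects are reported.

`gaussian_ensemble()` perturbs every backbone atom with i.i.d. zero-mean
Gaussian noise of standard deviation $\sigma$ per axis. Per-atom (rather
than per-residue rigid-body) noise is the simplest reading of a
Gaussian-noise baseline; a rigid-body variant would be a straightforward
extension but is not implemented. The expected squared per-atom displacement
is $3\sigma^2$, which the tests verify as a chi-square sanity check.

Featurization builds a k-NN graph on CA–CA distances (`k_neighbors = 30`
by default, reduced for short toy chains since $k < L$ is required). Edge
features are Gaussian RBF encodings of all 16 backbone atom-pair distances
— 16 centers evenly spaced on $[2, 22]$ Å with width equal to the spacing —
plus a sinusoidal relative-sequence-separation code (clipped at $\pm 32$)
and a same-chain flag; node features are $\sin/\cos$ of $\phi, \psi,
\omega$. All features are functions of distances and dihedrals only, hence
exactly invariant to rigid motions. Neighbour selection quantizes distances
to $10^{-6}$ Å before ordering so that exact ties in ideal geometries break
by residue index, keeping the graph stable under coordinate round-off. The
specific constants ($k$, RBF count and range) are conventional for
MPNN-style featurization and exposed in `featurizer_config()`; no test
depends on their particular values.

## The toy network

`init_network()` builds a message-passing network (3 encoder + 3 decoder
layers, hidden width 128 by default; the `"L"` preset uses 5 + 5 at width
256). The decoder is deliberately *non-causal*: the output is an energy
model over the whole sequence, not an autoregressive factorization, so no
decoding order exists to mask. Each layer computes a one-hidden-layer ReLU
message from (source, target, edge) embeddings, aggregates by neighbour
mean (order-invariant, as the tests check by permuting neighbour lists),
applies a residual update and row-wise layer normalization, and then
updates edge embeddings the same way.

The Potts readout projects node embeddings to the $L \times A$ fields and
edge embeddings to per-edge $A \times A$ blocks. Direction-wise blocks are
transposed into the canonical (smaller-index, larger-index) orientation and
averaged, so predicted couplings satisfy the storage symmetry exactly.

Training minimizes the mean sitewise pseudolikelihood,

$$\mathcal{L} = -\frac{1}{L} \sum_i \log p(s_i \mid s_{-i}),$$

with Adam. Pseudolikelihood is the standard tractable objective for Potts
models — the exact likelihood needs $Z$, which is intractable beyond toy
sizes — and its gradients with respect to $(h, J)$ are available in closed
form. A deliberate design choice: the message-passing weights are drawn
once from seeded Gaussians and *held fixed*; only the readout heads are
trained. This random-features regime makes the fit convex up to the ridge
term, lets embeddings be cached once per structure (training then costs
seconds to minutes on a single CPU), and is sufficient for every behaviour
the package claims: on a single fully-specified graph the readout can
represent any Potts model on that edge set, so pseudolikelihood recovery
experiments probe the estimator rather than the optimizer. Backpropagation
through the message-passing stack is the natural extension but is outside
what the package needs.

Default scales are toy by construction: chains of tens of residues,
hundreds of training items, CPU minutes. The protocols used by the test
suite and the acceptance script are: coupling recovery from 200 sequences
of a known $L = 8$, $A = 4$ model (edge density 0.3, field scale 0.3,
coupling scale 1 — order-unity couplings; 500 Adam epochs at learning rate
0.02, weight decay $10^{-4}$), and the ensemble-robustness comparison on an
80-item, 30-residue rule dataset (150 epochs). With 200 sequences the
pseudolikelihood estimate itself is sample-starved: a direct fit of $(h,J)$
plateaus near Pearson $r \approx 0.58$ against the generating couplings on
this protocol, and the network fit lands a few points below that ceiling.
Across independent 200-sequence draws the recovered correlation spans
roughly $0.46$–$0.61$ — most draws clear $r = 0.5$, some carry genuinely
less information and land just under it. The test suite freezes one
documented draw; the acceptance script re-draws from its `--seed`, so its
reported value moves within that band.

## The synthetic data generator

`make_structure_sequence_dataset()` emulates the single statistical
assumption the method rests on: that sequence preferences are a local,
learnable function of backbone geometry. Each item is a "perturbed"-mode
toy backbone — per-residue torsions drawn from the helical or extended
basin (probability 0.6/0.4) with 12° jitter, built from ideal bond geometry
— whose ground-truth Potts model is defined by a geometric rule: the
residue's burial (number of other CA atoms within 10 Å, binned at 5/8/11
neighbours) sets a favoured class via a field of strength 3, and CA pairs
closer than 8 Å at sequence separation ≥ 3 get a coupling of strength 1.5
favouring complementary classes ($b = A + 1 - a$) over a 4-letter alphabet.
Sequences are Gibbs samples from this model at $T = 1$ with 5% label-noise
flips; conformer observation noise is Gaussian with $\sigma = 0.5$ Å in the
robustness protocol. The constants were chosen once so that toy training is
learnable within CPU minutes and are documented here rather than claimed
biological.

What the fixture does *not* emulate: real amino-acid chemistry, long-range
evolutionary covariation, multi-chain interfaces, or any non-structural
signal of the kind ensemble conditioning is meant to average out. Passing
the robustness test therefore shows the mechanism works — averaging
per-conformer Potts models cancels conformer noise and beats any single
noisy conformer on held-out recovery — not that the toy network rivals
models trained on real structure corpora.

## Numerical choices and degenerate inputs

* Enumeration cap $10^6$ states, configurable; all exact oracles run in the
  log domain.
* Model averaging requires weights on the simplex to $10^{-8}$ and refuses
  empty model lists or mismatched $L$/alphabet.
* Zero-sum gauging preserves energies exactly (not just distributions) by
  absorbing block row/column means and the block mean into the two incident
  fields.
* Sampler edge cases: an all-reject DLMC chain surfaces through the trace's
  acceptance rate, never as an exception; the LCP window must not exceed
  $L$; temperature schedules must cover every sweep.
* Sequences are validated against the model alphabet on every entry point;
  out-of-alphabet FASTA symbols are an error, not a silent wildcard.
* kNN ties: distances quantized at $10^{-6}$ Å, ties broken by residue
  index (documented above).
* PDB output writes 0.001 Å fixed-width coordinates; round-trips are exact
  at that precision.

## The design pipeline

`run_design()` glues the stages: read the input backbone, assemble the
ensemble (explicit conformer files, a multi-MODEL file, or Gaussian noise
with given $\sigma$ and $K$; $K = 16$ and 8 designs per job are the
defaults), predict one Potts model per conformer — exactly $K$ forward
passes, counted by an instrumented counter and recorded in the run manifest
— average, sample with DLMC (+ optional LCP), and write FASTA with
parseable headers (`design_{i}|energy=...|K=...|seed=...`) plus a JSON
manifest (config echo, seed, per-design composite energies, ensemble
diversity). Designs are ranked by composite Potts energy only; selection by
external folding metrics is deliberately downstream of this tool. Identical
jobs with identical seeds reproduce bit-identically, and a $K$-fold
duplicate of one structure reproduces the single-structure job exactly —
the end-to-end form of the averaging idempotence.

## Known limitations

* The network is a mechanism-faithful toy: fixed random message-passing
  features, readout-only training, toy-scale fixtures. It makes no claim of
  competitive recovery on real proteins.
* Ensembles must share residue topology exactly; no alignment or gap
  reconciliation across conformers is attempted.
* The LCP functional form and defaults are package decisions, validated by
  exactness tests, not calibrated to any released sampler.
* Gaussian-noise ensembles are a cheap baseline; physically realistic
  conformer generation (diffusion models, backrub) is explicitly external.
* mmCIF, sidechain packing, and folding-model evaluation are out of scope.
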