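---
title: "Graph-aligned conditional SMILES generation: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-aligned conditional SMILES generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Autoregressive SMILES language models generate chemically plausible molecules
token by token, but a linear string is a lossy view of a molecule: the model
must rediscover ring systems and branching topology from syntax alone.
`moltwin` trains a GPT-style SMILES decoder whose pooled sequence
representation is aligned, during training only, with an explicit
graph-attention encoding of the molecular graph. At inference the graph
encoder is switched off entirely — generation needs no graph, because the
topological signal has already been distilled into the sequence weights.
Generation can be conditioned on target values of four properties (logP,
TPSA, QED, synthetic accessibility) and on a Bemis–Murcko scaffold.

## The two encoders

**Graph encoder.** Each heavy atom is featurised as the concatenation of four
one-hot blocks — atom type over {C, N, O, F, S, Cl, Br, I, P, B, other},
heavy-atom degree 0–5, hydrogen count 0–4, implicit valence 0–5; out-of-range
values map to the last bucket of their block, so exotic atoms degrade
gracefully rather than erroring. Two graph-attention layers follow. For a
node pair (i, j) in a neighbourhood, the attention logit is
`e_ij = LeakyReLU(a^T [W h_i || W h_j])` (negative slope 0.2), normalised by
a softmax over the neighbourhood of i; self-loops are always included, which
also makes isolated atoms well defined. The node update applies a sigmoid to
the attention-weighted sum of transformed neighbours; the first layer runs
four heads of width 8, concatenated (width 32), the second a single head
projecting to the alignment dimension. A ReLU and a global max pool over
nodes give the graph embedding. The sigmoid activation follows the model
family this package implements; canonical graph-attention networks use ELU
instead, and the sigmoid's saturation is one reason the encoder trains more
slowly than the decoder.

**Sequence decoder.** A mini-GPT: learned token and absolute position
embeddings, pre-layer-norm blocks of masked multi-head scaled dot-product
attention (`softmax(QK^T/sqrt(d_k))V`, strictly causal) and a 4× GELU
feed-forward, a final layer norm, and a logits head. Full-scale defaults are
8 layers, 8 heads, width 256, sequence length 100. Conditions are encoded as
a prefix: `[property slots][SEP][scaffold tokens][SEP][BOS molecule EOS]`.
Property targets are not discretised into tokens; each conditioned property
owns one reserved slot position whose embedding is an affine map
`x_norm * w_p + b_p` of the scalar target, normalised by fixed scales
(logP/10, TPSA/150, QED/1, SAS/10) so all slots live on comparable ranges.
Continuous injection avoids inventing a binning scheme and lets the model
interpolate between targets.

## The objective

The loss is the unweighted sum `L = L_BT + L_ground`. `L_ground` is mean
next-token cross-entropy over the molecule span only (condition prefix and
padding are masked out). `L_BT` is a Barlow Twins redundancy-reduction term
on the batch cross-correlation between the graph embedding and the mapped
(mean-pooled over non-PAD positions, then one affine layer) sequence
embedding:

    C_ij = sum_b zA_bi * zB_bj / (||zA_i|| * ||zB_j||)
    L_BT = sum_i (1 - C_ii)^2 + lambda * sum_{i != j} C_ij^2,  lambda = 0.005

The printed cross-correlation is norm-scaled but uncentred. The original
Barlow Twins recipe standardises each dimension across the batch first; both
behaviours are provided through a `standardize` flag (default `TRUE`). The
uncentred literal form is kept for fidelity; the standardised form is the
better-understood objective. Empirically both train at desk scale.

## Numerical choices that matter

* **Gradient clipping.** The alignment term's gradient passes backwards
  through the batch standardisation, which divides by per-dimension batch
  standard deviations. Early in training the sequence embeddings have tiny
  spread, so this division produces gradient spikes that can destroy the
  partially-trained decoder. Global L2 gradient-norm clipping at 1.0 (the
  GPT-family convention, `clip_norm` in `train_config()`) makes joint
  training stable; it is applied to the decoder and graph-encoder gradient
  trees separately.
* **Optimiser.** Decoupled-weight-decay Adam (lr 6e-4 at full scale, 3e-3
  for the small desk models), linear warm-up over the first 5% of steps,
  cosine decay to 10%.
* **Determinism.** One seed drives initialisation, shuffling, dropout and
  sampling; two runs with the same seed and data produce bitwise-identical
  logs and weights. Softmax maxima use `ties.method = "first"`.
* **Degenerate inputs.** A constant embedding dimension makes the
  cross-correlation undefined; this raises an error naming the dimension
  rather than silently propagating NaN. Batches of size 1 are dropped
  (batch standardisation needs n ≥ 2). A diverging loss aborts with a
  diagnostic rather than writing NaN checkpoints.
* **Matrix square root.** The Fréchet distance needs
  `Tr((Sigma_G Sigma_D)^{1/2})`; it is computed through the symmetric form
  `sqrt(S_G) Sigma_D sqrt(S_G)` with eigenvalues clipped at zero within
  tolerance, which is PSD-stable, and cross-checked in the tests against a
  direct eigendecomposition of the product.

## The synthetic fixture generator

`synth_smiles()` assembles molecules from a closed fragment grammar: a ring
core (benzene, pyridine, cyclohexane) with 0–3 substituents drawn from a
small drug-like pool (alkyls, hydroxyl, amino, halogens, aldehyde, carboxyl,
amide, methoxy, hydroxymethyl), or a short heteroatom chain when the
heavy-atom budget (default 16) cannot fit a ring. Every output is valid by
construction and verified against the parser; ring-cored outputs have
non-empty Bemis–Murcko scaffolds. The polar substituents spread TPSA over
roughly 0–110 Å², giving property conditioning a real signal to learn, and
the three cores give scaffold conditioning distinguishable classes.

What the generator does **not** emulate: the property ranges, fragment
diversity, ring-system complexity and long-tail syntax (stereochemistry,
fused polycycles, charged species) of real training corpora. Passing tests
on these fixtures demonstrates that the machinery — encodings, objective,
training loop, conditioning pathway, metrics — is correct and that the
conditioning signal is learnable; it does not certify generation quality on
real chemical libraries, which requires full-scale training.

## Desk-scale study sizes

The test suite and the acceptance script run a deliberately small study so
the full pipeline executes in minutes on one CPU: 500 fixture molecules,
2 decoder layers, width 64, 4 heads, sequence length 32, alignment dimension
32, batch 32, 40 epochs, dropout 0, TPSA as the conditioned property. Under
these conditions the model reaches high sampled validity at mid-range TPSA
targets and its generated-property means track the targets. The graph
ablation study trains both configurations (with and without the graph
encoder) at three seeds each under identical conditions.

A caveat observed at this scale and worth stating: the jointly-trained
configuration converges more slowly than the plain decoder — the alignment
term consumes part of the small model's capacity and training budget — so at
desk scale its conditioning deviations are somewhat wider, not narrower. The
benefit reported for graph alignment belongs to the full-scale regime
(millions of molecules, 7M parameters); the desk-scale study verifies the
mechanics, not the direction of that effect.

## Known limitations

* Tokenisation covers standard organic-subset SMILES plus bracket atoms;
  SELFIES-style robust encodings are out of scope.
* Scaffold extraction uses the standard (non-generic) Bemis–Murcko
  framework, keeping exocyclic multiple bonds.
* The Fréchet metric's default featuriser is a standardised physicochemical
  descriptor block (the nine descriptors of the KL suite); literal
  comparability with neural-activation Fréchet scores requires plugging in
  that external featuriser via `distribution_stats()` on precomputed
  features.
* Whether duplicate molecules should be removed before condition-deviation
  statistics is unspecified in the source method; statistics here run over
  all valid samples.
* The condition SD is reported both about the sample mean (population
  formula) and about the target, since the source tables do not say which
  anchor they use.
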