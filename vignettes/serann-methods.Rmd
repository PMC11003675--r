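---
title: "Self-replicating neural networks: model, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-replicating neural networks: model, methods, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(serann)
```

## The model

A SeRANN (self-replicating artificial neural network) is an individual whose
heritable material is a fixed-length binary genotype $g \in \{0,1\}^k$ and
whose phenotype is a small text specification of a neural-network
architecture. The individual approximates a function

$$ (\hat{y}, g') = F(X, g), \qquad
   F: \mathbb{R}^{m \times n} \times \{0,1\}^k \to [0,1]^L \times \{0,1\}^k $$

taking a grayscale image $X$ and its own genotype, and emitting a class
probability vector $\hat{y}$ (the *fertility task*) and a replicated genotype
$g'$ (the *replication task*). Training minimizes the weighted two-task loss

$$ \ell = \alpha\,\ell_X(y,\hat{y}) + (1-\alpha)\,\ell_g(g,g'), $$

where $\ell_X$ is categorical cross entropy, $\ell_g$ the mean squared error
over the $k$ bits, and the loss weight $\alpha \in [0,1]$ is itself written
in the specification text — so it is inherited through the genotype and
evolves like a modifier allele controlling the mutation rate. Network
weights are *not* inherited: every individual re-learns them from Glorot
initialization by Adam, which makes replication error (and hence mutation)
an emergent property of development rather than a dial.

Populations evolve under a Wright-Fisher model with constant size $N$ and
non-overlapping generations: fertility $F_i$ is classification accuracy on a
shared evaluation set; relative fertility $f_i = F_i/\sum_j F_j$
parameterizes a multinomial draw of newborn counts; each newborn's genotype
is drawn from its parent's pool of replicated genotypes (one per evaluation
image); genotypes are decoded to specification text by the codec, and only
offspring whose text parses and builds survive. Absolute fitness is
$W_i = V_i F_i$ with $V_i$ the offspring survival rate, and relative fitness
is $w_i = V_i F_i / \bar{F}$.

## The phenotype dialect

Self-replicator frameworks often execute generated source code directly in
a host language; this package instead defines a constrained
layer-specification dialect
(`input ; conv 8 ; pool ; dense 6 4 ; merge ; alpha 0 . 1 0 2 6 ; output`)
and maps "execution error" to parse/build failure. That choice removes the
sandboxing hazard of interpreting generated code while keeping the same
degrees of freedom: a fixed scaffold (image input, a merge of the image and
genotype branches, fixed output heads) around a variable hidden-layer chain.
Numbers are tokenized digit by digit and the loss weight is encoded at a
fixed $10^{-4}$ precision (observed adaptive shifts in the loss weight are
of order $2\times10^{-3}$, so the grid must be finer than that). The shipped
vocabulary is 20 tokens; it is configuration, not a constant of the method.

`build_network()` is the survival oracle: it propagates tensor shapes
through the chain (3x3 same-padded convolutions, 2x2 average pooling with
floor semantics, flattening dense layers), enforces the scaffold, computes
the closed-form trainable-parameter count including the fixed post-merge
layer and both heads, and applies the 2,000,000-parameter cap. Individuals
over the cap survive birth but have fertility 0, so they cannot reproduce.

## The generator

The corpus generator is a Markov chain over layer types with a terminal
state. Only the convolutional row is treated as fixed convention
(conv→pool 0.7, conv→conv 0.2, conv→dense 0.1); the remaining rows and the
initial distribution are shipped defaults chosen so that chains are short
(2-6 layers), structurally valid, and absorb quickly. Hyperparameters come
from clipped, rounded normal priors; the fully-connected width uses
$\mathcal{N}(64, 15)$ clipped to $[8,128]$, and the loss-weight prior
$\mathcal{N}(0.10, 0.02)$ clipped to $[0.05, 0.15]$ brackets the regime
where both tasks train. Rounding is half-away-from-zero. Over-budget or
unbuildable draws are rejected and resampled up to 100 times.

## The codec (ribosomal autoencoder)

The genetic code is learned by an autoencoder: the encoder (embedding, three
convolutional stages each followed by width-2 average pooling, and a dense
head with a sigmoid) maps the $d$-token specification to $k$ Bernoulli
parameters $\phi$; the decoder (dense head, one convolutional layer) maps a
genotype to $d$ score vectors over the $r$ vocabulary tokens, normalized by
a softmax into token posteriors. The training loss is the negative
log-likelihood of the input sequence (no KL/prior term; padding positions
included by default). During training the decoder receives a relaxed
Bernoulli sample

$$ z_i = \log \phi_i + \log u_i - \log(1-u_i), \qquad g_i = \sigma(z_i),
   \quad u_i \sim U(0,1), $$

the temperature-1 special case of the concrete distribution, written exactly
as the model defines it (note it uses $\log\phi$, not the logit); at
inference bits are hardened at $\phi_i > 0.5$, with the boundary mapped
to 0.

### Numerical choices that matter

Three additions were needed to make this train reliably at desk scale
(hundreds of corpus examples, one CPU), and they are deliberate parts of the
procedure rather than incidental tuning:

1. **Warm-up phase.** The $\log\phi$ relaxation is one-sided: for
   $\phi \to 1$ the sample approaches plain uniform noise and the gradient
   through $\phi$ vanishes, so a cold-started encoder is easily trapped in a
   saturated, input-independent code. The first phase of training holds the
   uniform draw at its median ($u = 1/2$, so $g = \phi/(1+\phi)$
   deterministically) until an input-dependent code has formed.
2. **Logit regularization.** A small L2 penalty (coefficient $10^{-3}$) on
   the encoder's pre-sigmoid outputs keeps $\phi$ off the hard 0/1 boundary
   during the stochastic phase, where the gradient would otherwise die.
3. **Decoder sharpening.** At inference the decoder sees hardened 0/1 bits,
   a representation it never sees under the relaxation. A final phase
   freezes the encoder and tunes the decoder alone on hardened codes.

The middle (stochastic) phase is the bulk of training and is what makes the
learned code robust: replication noise during training forces decodes to
degrade gracefully under bit flips, which is why most single-bit mutants of
encoded genotypes still decode to buildable specifications (measured by
`single_bit_viability()`, typically 0.6-0.9 at desk scale depending on how
tight $k$ is).

## Desk-scale study conditions

The package's tests and examples run two codec configurations on a
200-specification corpus: a fidelity configuration ($k=48$, $d=64$, 450
epochs) that reaches >90% exact sequence reconstruction, and the
end-to-end configuration ($k=24$, $d=64$, 300 epochs) matching the smoke
experiment ($N=16$, $G=10$, 12x12 glyph images, 224 training and 96
evaluation examples, 15 training epochs per individual). $k=24$ is
information-theoretically tight for this corpus — reconstruction is partial
and offspring survival sits around 0.2-0.6 — which is exactly the regime
where survival selection, mutators, and lethal mutations are visible within
ten generations. The full-scale conventions ($k=100$, $N=1{,}000$, content
capped at 350 tokens, evaluation sets of 3,000, five training epochs,
parameter cap 2,000,000) remain the configuration defaults.

Problem sizes in the test suite (10,000 Monte-Carlo draws for prior means
and transition frequencies, 10,000 replicate generations for the
surviving-offspring law, 2,000 replicates for drift neutrality, 5,000
observations for planted-epistasis recovery) were chosen so each check
resolves its target at 3-4 standard errors.

## The synthetic data

`make_synthetic_images()` draws noisy, jittered 7x5 digit glyphs on a small
grid: balanced classes, values in $[0,1]$, Gaussian pixel noise (sd 0.15),
and ±1-pixel translation jitter. It emulates the *learnability structure*
of a handwritten-digit task — distinct class templates a small network can
separate well above chance within a few epochs — but not its within-class
style variation, correlated strokes, or label noise. Passing tests
therefore demonstrate that the evolutionary machinery behaves correctly on
a learnable task, not that any particular fertility level transfers to real
data; the IDX reader (`read_idx_images()`) is provided for running the same
pipeline on the real dataset.

## The estimators

* **Mutation rate** $\mu_g$: mean Hamming distance between a genotype and
  its replicated offspring, with the per-site spectrum as a by-product.
* **Survival** $V$: fraction of offspring decoding to buildable specs.
* **DFE**: mutant/parent absolute-fitness ratios, classed as lethal (0),
  deleterious (<1), neutral (1), beneficial (>1), sampled per generation
  window; pairs with zero parent fitness are excluded and counted.
* **Robustness**: $\lambda(g) = 1 - \sum_{g'} |W_{g'} - W_g|
  M_{g \to g'} / \sum_{g'} M_{g \to g'}$, undefined (flagged) without
  recorded mutants.
* **Epistasis**: for each ordered site pair, the normal-model fit
  $\hat F = b + a_i g_i + a_j g_j + a_{ij} g_i g_j$ by least squares
  (equal to the maximum-likelihood solution), a likelihood-ratio test of
  $a_{ij} = 0$ against $\chi^2_1$, and Benjamini-Hochberg adjustment across
  performed tests. Ordered enumeration gives $k(k-1)$ tests (9,900 at
  $k=100$) and matches the convention of counting each pair twice; the
  model itself is symmetric. Monomorphic and singular pairs are skipped,
  not imputed. All fits reduce to 4x4 normal-equation solves over
  precomputed cross-tallies, so a full 100-site scan takes well under a
  second.
* **Trajectories**: derived-allele frequencies per site against the
  generation-0 majority state; fixation time defaults to the first
  generation at frequency 1.0, with the 90% reporting threshold always
  exported alongside; richness counts distinct genotypes and distinct
  specification texts.
* **Repeated evaluation**: independent initialize-train-evaluate cycles
  under distinct seed substreams quantify phenotypic variation
  (developmental noise); a permutation test relates variation to fitness.
* **Mutagen comparison**: mutation rates under two image conditions for the
  same trained individuals, compared by a paired t-test — possible only
  because the replication output depends on the paired image input through
  the shared layers.

## Design choices where the design was open

* **Constant N vs. survival deaths** are reconciled by conditional
  resampling: an invalid offspring is replaced by redrawing a parent
  proportional to $f$ and one member of its pool, within a budget of $50N$
  draws (then the run halts as extinct). This preserves
  $E[\tilde{N}_i] = N V_i f_i$ — verified against a 10,000-replicate
  Monte-Carlo — and a constant census size.
* Pool draws are **with replacement** (pools are much larger than typical
  offspring counts).
* The per-generation record stores each parent's *initial* multinomial draw
  and its binomial survival outcome, with replacements logged separately,
  so the expectation law above is testable from logs.
* Training batches **interleave the two tasks** under the single combined
  loss rather than alternating them.
* The genotype pool used as replication targets during training is the
  codec encoding of a generated corpus.
* The LRT null is the asymptotic $\chi^2_1$; the FDR variant is
  Benjamini-Hochberg.
* Degenerate inputs: all-zero fertility halts as a degenerate population;
  an empty offspring set flags the mutation-rate estimate undefined rather
  than returning 0; posterior probabilities are clamped at $10^{-12}$
  before logs.

## Known limitations

* The codec at $k=24$ cannot represent the full corpus; survival rates are
  accordingly low, and long runs at that setting can go extinct under
  unlucky seeds. Use a larger $k$ for faithful-code studies.
* Average pooling (not max) is used in both the codec and the individuals
  for exact, cheap gradients.
* The engine is single-threaded; the full-scale conditions ($N=1{,}000$
  with trained individuals over thousands of generations) are out of reach
  on one CPU and are exercised here only with stub replicators.
* The relaxation is implemented exactly as defined (temperature 1,
  $\log\phi$ parameterization); the usual concrete-distribution
  temperature annealing is intentionally absent.
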