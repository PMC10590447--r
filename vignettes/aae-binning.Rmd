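---
title: "Adversarial autoencoder binning: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial autoencoder binning: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aaebin)
```

This vignette is the package's own account of the method: what the model
assumes, which parameters matter, what the synthetic generator does and
does not emulate, and where the design was genuinely open and a choice had
to be made.

## The binning problem and the two signals

Contigs from one genome share two statistical fingerprints. First,
tetranucleotide composition: 4-mer usage is genome-specific and reasonably
stable along a genome. Second, co-abundance: all contigs of a genome rise
and fall together across samples, because they come from the same
organism. Neither signal alone separates closely related or low-abundance
genomes well; the model's job is to fuse them into a representation in
which genomes form tight clusters.

## Composition features

Raw tetramer frequencies live on a 256-simplex, but carry three exact
linear redundancies: strand symmetry (a tetramer and its reverse
complement are interchangeable when counting on one strand of dsDNA), the
sum-to-one constraint, and the 3-mer overlap constraints (in a long
sequence, the mass of tetramers starting with a 3-mer `w` equals the mass
ending with `w`, up to boundary effects). `tnf_kernel()` removes all three
by projecting onto an orthonormal basis of the constraint null space,
computed by SVD of the stacked constraint matrix. The resulting dimension
is forced by counting: 136 reverse-complement classes, minus the sum
constraint, minus 32 independent overlap constraints, leaves 103. Column
signs are fixed (first non-negligible entry positive) so the kernel is a
deterministic constant.

Counting details: overlapping windows on the given strand; windows with
any non-ACGT symbol are skipped; a contig with no countable window gets
the uniform frequency vector, which projects exactly to zero — "no
composition information" maps to the origin. Projected features are then
z-scaled per dimension across contigs so each dimension contributes
comparably; zero-variance dimensions are centred and left at zero rather
than divided by zero.

Because the kernel columns are themselves reverse-complement symmetric,
counting on one strand and symmetrising counts give identical projections,
so the package counts single-stranded.

## Abundance features

Depths are read from the tab-separated output of the standard depth
summariser (`contigName`, `contigLen`, `totalAvgDepth`, one depth column
per sample, optional `-var` columns which are ignored). Multi-mapping
reads are the upstream mapper's concern; the depth file is the interface.
Each contig's row is normalised to sum to one — the profile becomes the
distribution of a random mapped read over samples, which is what the
cross-entropy reconstruction term expects. All-zero rows fall back to the
uniform profile.

## The adversarial autoencoder

The encoder maps `[TNF, Coab]` through two hidden layers (leaky ReLU,
batch normalisation) to three heads: `mu` and `sigma` (via a clamped
exponential, so `sigma` is positive and bounded in `[1e-6, 50]`)
parameterising the continuous code, and softmax probabilities over `n_y`
categories. Training samples `z = mu + sigma * eps` and a Gumbel-softmax
relaxation of the categorical head at temperature `tau`; the decoder
mirrors the encoder and reconstructs abundances through a softmax head
(cross-entropy loss) and composition through a linear head (mean squared
error). Two discriminators — same trunks, no batch normalisation, one
sigmoid output — are trained to tell codes from prior samples, and the
encoder is trained to fool them. All probabilities inside cross-entropies
are clamped to `[1e-9, 1 - 1e-9]`, so every loss is finite even when a
discriminator saturates.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `sl` | 0.0964 | weight of the adversarial term in the total loss |
| `slr` | 0.5 | share of the categorical space in the adversarial term |
| `tau` | 0.1596 | relaxation temperature, used for encoder samples and the categorical prior |
| `n_z` | 283 | continuous code dimension |
| `n_y` | 700 | number of categories; set to the expected taxonomic diversity |
| `n_hidden` | 547 | hidden width, two layers |
| `w_coab`, `w_tnf` | `0.85/log(S)`, `0.15/103` | reconstruction weights |
| `batch_size`, `epochs`, `learning_rate` | 256, 300, 1e-3 | training schedule, Adam for all three modules |

Design choices that were genuinely open:

* **Two published forms of the regularisation loss.** The encoder-side
  adversarial term can be written as cross-entropy against the "real"
  label, or as the negated discriminator losses. The first is the
  numerically stable non-saturating form and is consistent with the
  per-space terms, so it is the default (`reg_form = "bce"`); the negated
  form is available as `reg_form = "neg_disc"`.
* **Discriminator output.** A softmax over a single output node is
  constant by construction; a sigmoid is the only reading under which the
  discriminator losses are well defined, and is what the package uses.
* **Temperature.** One published value (0.15) appears for the prior and a
  tuned value (0.1596) for the model; the tuned value is used for both,
  configurable.
* **Update order.** Per minibatch: encoder/decoder on
  `(1-sl) L_rec + sl L_reg`, then the z discriminator, then the y
  discriminator. Per-batch alternation is conventional adversarial
  practice; per-epoch alternation trains the discriminators on stale
  codes.
* **Reconstruction weights.** Never published; the package mirrors the
  variational binning convention of weighting the abundance cross-entropy
  by `0.85/log(S)` (keeping the term's scale stable as samples are added)
  and spreading the rest over the 103 composition dimensions.
* **What gets clustered.** The Gaussian mean `mu`, not a posterior
  sample, and argmax categories, not relaxed samples: extraction runs in
  evaluation mode (batch-norm running statistics) and is deterministic.

All randomness — initialisation, shuffling, reparameterisation draws,
prior samples — flows from `config$seed` through R's RNG, so a fixed seed
reproduces training bit for bit on one thread.

## Clustering the latent spaces

The continuous space is clustered by iterative medoid search on cosine
distance `(1 - cos)/2` over centred, length-normalised codes: take the
longest unclustered contig as seed, wander to a local medoid (the
neighbour within 0.05 minimising summed distance to neighbours, at most 25
steps), set the cluster radius at the first density valley of the
medoid's distance histogram, emit everything within the radius, repeat.
Defaults: bin width 0.005 over `[0, 0.3]`, valley = first local minimum
below 60% of the running peak, fallback radius 0.09. Ties everywhere
break lexicographically by contig id, so clustering is deterministic.

One numerical choice deserves a note: at desk scale a 0.005-wide raw
histogram of a few hundred distances is mostly counts of 0–10, and the
first empty bin would masquerade as a valley, shattering genuine clusters.
The package therefore smooths the histogram with a 5-bin moving average
before the valley walk. This is a smoothing of the density estimate, not
a change to any threshold; with it, cluster counts drop from ~100 to
~30 on the reference synthetic community and the adjusted Rand index
against truth rises from ~0.7 to ~0.93.

The categorical space needs no clustering: occupied categories are the
clusters. Both cluster sets are then split by the sample prefix of each
contig id (multi-split binning), because a catalogue-level cluster mixes
the per-sample assemblies of one genome, and a usable MAG must come from
one assembly.

## De-replication

The z and y bin sets (and optionally an external binner's set) cover the
same contigs, so duplication is exact and detectable by contig identity —
no alignment is needed. The merge: score every bin
(`completeness - 5 * contamination`), drop bins that are not near-complete
(strictly above 0.9 completeness and strictly below 0.05 contamination);
for every near-identical pair (at least 75% of the smaller bin's bp
present in the larger), processed in descending overlap, drop the
lower-scoring member; finally, for each contig still owned by several
bins (lexicographic order), re-score each owner without it and keep it
only in the bin whose score would drop most. Ties keep the larger bin,
then the higher-scoring owner, then the lexicographically earlier name —
so the result is independent of the order in which bin sets are supplied.
Bins are deliberately not re-scored between pair removals (removal
deletes whole bins and cannot change other bins' contents); scores are
recomputed during contig reassignment, where contents do change.

Two quality scorers implement the scoring contract. The ground-truth
scorer (synthetic data) computes completeness and contamination exactly
from the contig-to-genome map: dominant genome's bp over the genome's
reference length, and foreign bp over the same denominator. The
report-file adapter wraps an external quality report; since the external
tool cannot be re-run on a modified bin, the adapter scales a sub-bin's
completeness and contamination by the fraction of the original bin's bp
retained — a uniform-information model that is exact at the endpoints and
monotone in between.

## Benchmarking

Per bin `B` and genome `G`: precision is `G`'s bp covered by `B` over all
genome bp covered by `B`; recall is `G`'s bp covered by `B` over `G`'s
total bp. For a clade, recall is the max and precision the sum over its
genomes. A genome counts as recovered when any single bin reaches both
thresholds (default recall 0.9, precision 0.95, inclusive; a strict
`> 0.9 / > 0.9` preset matches the convention used for model selection).
Covered bp comes from the truth table's per-contig annotation; the
synthetic generator emits non-overlapping fragments, so within-genome
double counting cannot arise there.

## The synthetic generator

`simulate_metagenome()` emulates exactly the structure the model exploits,
at desk scale:

* **Genome-specific composition** — each genome has its own order-3
  Markov transition table with flat-Dirichlet rows. Flat Dirichlet makes
  genomes compositionally very distinct; real genomes share much more
  background structure, so this is the generator's easiest axis.
* **Multi-sample catalogue** — each genome is fragmented independently in
  every sample (uniform lengths in a band around
  `genome_bp / contigs_per_genome`, tiling the whole genome), mirroring
  per-sample assemblies concatenated into a catalogue. This is what makes
  multi-split binning meaningful and per-sample bins completable. The
  truth table carries each genome's reference length so that recall and
  completeness are computed against the genome, not against the summed
  multi-sample duplication.
* **Co-abundance** — genome-by-sample abundances are i.i.d. log-normal
  (`meanlog` 1, `sdlog` 1), shared by all of a genome's contigs;
  per-contig, per-sample multiplicative gamma noise (mean 1, variance =
  `depth_dispersion`, default 0.05) perturbs them. Read-level simulation
  is intentionally out of scope: multiplicative noise preserves the
  correlation structure the model uses at negligible cost.

What passing tests on this generator do **not** show: robustness to
strain mixtures, uneven genome presence across samples, chimeric or
misassembled contigs, composition bias varying along a genome, or
read-mapping artefacts. The generator's defaults (10 genomes x 50 kb, 8
samples, ~10 fragments per genome per sample) are the package's reference
experiment; they were chosen as the smallest community that exercises
every pipeline stage, and the reduced model used with them (64 hidden
units, `n_z` 16, `n_y` 32, 200 epochs) trains in well under a minute on
one CPU.

## Degenerate inputs and numerical corners

* Contigs shorter than 4 bp or entirely ambiguous: uniform tetramer row,
  zero projection.
* All-zero depth rows: uniform abundance profile.
* Zero-variance projected dimensions: centred, left at zero.
* Empty clustering input: empty partition; a single point: one singleton.
* Histogram with no valley: fallback radius 0.09.
* A bin losing its last contig during reassignment disappears.
* Probability clamping at `1e-9` in every cross-entropy; `sigma` clamped
  to `[1e-6, 50]`; non-finite losses abort training with the offending
  term named.

## Known limitations

The categorical space is the weaker binner at desk scale: with a roomy
continuous code, reconstruction can bypass `y`, and its argmax labels
align with genomes only coarsely (the de-replicated union remains better
than either space alone, which is the point of the ensemble). When the
continuous code is deliberately bottlenecked, the categorical space takes
over and recovers genomes on its own — the test suite demonstrates both
regimes. Training is single-threaded base R matrix code: ample for
catalogues of a few thousand contigs, but a compiled backend would be the
first change for full-scale data. De-replication quality is bounded by
the scorer: with the report-file adapter, score drops for modified bins
are interpolated, not re-measured.
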