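---
title: "Sparse denoising models for protein backbone generation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse denoising models for protein backbone generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsebb)
```

## The model

sparsebb implements a family of sparse all-atom denoising models for protein
backbones. A structure is represented per residue by its four backbone atoms
(N, CA, C, O), an idealized beta-carbon placed at a fixed tetrahedral offset
in the residue's local frame, and 15 learned pseudoatoms, giving a 20-atom
block per residue (`AugmentedStructure`). A denoising network is trained to
map a noised structure $x_t$ back to the clean structure $x_0$; new backbones
are generated by starting from pure noise and alternating noising at a
decreasing noise level with denoising by the network.

The network is a pre-norm graph transformer whose attention is a sparse
variant of invariant point attention (IPA): each residue attends only to a
precomputed set of $K$ neighbours, reducing the cost of attention from
$O(N^2)$ to $O(NK)$. Neighbours are selected in three stages — the 16
nearest by residue index within the chain, the 16 nearest by CA distance
among the rest, and 32 random residues drawn without replacement with
probability proportional to $1/d_\mathrm{CA}^3$ — plus an optional stage
drawn from pairwise conditioning information (16 random + 16 conditioning
neighbours when self-conditioning is attended). A fresh neighbour set is
drawn in every denoising block because every block moves the coordinates.
Global context that sparse attention cannot see is supplied by the update
module, which mean-pools a projection of the residue features per chain and
per complex and adds both back to each residue.

Equivariance is obtained by construction rather than by constraint: all
inputs to the network are invariant (distance features, directions and
coordinates expressed in per-residue Gram–Schmidt frames), and all outputs
that live in 3D (position updates, pseudoatoms, side-chain atoms, IPA value
points) are emitted as local-frame offsets and rotated out by the current
frames. Frames are recomputed from the current N/CA/C coordinates whenever
coordinates have moved. The test suite verifies end-to-end equivariance of
the full network to 1e-4 and the sparse attention layer against a dense
brute-force IPA oracle to 1e-5.

## Noise schedules

Three noise processes are implemented:

* **VP** (variance-preserving) with a cosine schedule, realized as
  $\sigma_t = \sin(\tfrac{\pi}{2} t)$ so that the signal coefficient is
  $\cos(\tfrac{\pi}{2} t)$:
  $x_t \sim \mathcal{N}(\sqrt{1-\sigma_t^2}\,x,\; \sigma_t^2 \sigma_\mathrm{noise}^2)$
  with $\sigma_\mathrm{noise} = 10$ Å. The closed form of the "cosine
  schedule" is our choice; it satisfies the endpoint semantics
  $\sigma_0 = 0$, $\sigma_1 = 1$.
* **VP-scaled**, identical but with $\sigma_\mathrm{noise}$ set to
  $\sigma(x_\mathrm{CA})$, the pooled per-coordinate standard deviation of
  the CA positions about their centroid (our reading of an otherwise
  undefined symbol), so the fully noised structure has the same spread as
  the input.
* **VE** (variance-expanding): $x_\sigma \sim \mathcal{N}(x, \sigma^2)$ with
  training noise scales drawn from $\ln\sigma \sim \mathcal{N}(1.6, 1.4^2)$
  (in log-Å). The printed parameter order of this law conflicts between two
  places in its source; we follow the equation (log-mean 1.6, log-sd 1.4).
  At inference VE uses a log-linear sigma ladder from 80 Å down to 0.1 Å —
  the training-time law does not define an inference grid, so this is a
  package choice.

VP-family noising presumes data centred at the origin (the mean-shrinkage
pulls toward zero), so the sampler re-centres the running estimate before
each noising step; `applyNoise` itself never re-centres.

**Shaped noise.** For large proteins, the VE process can be initialized from
noise shaped like a multi-domain protein: centres are sampled as a Gaussian
chain with per-coordinate step deviation 10 Å, compacted by ten
gradient-descent steps (learning rate 0.1) on a harmonic restraint centred
on 10 Å over all centre pairs, and 200 consecutive residues are assigned to
each centre with initial noise of standard deviation 80 Å about it. The
chain recursion is printed in its source as a cumulative sum over all
previous centres; read literally that is neither a Gaussian chain nor
consistent with the accompanying text, so the default is the first-order
chain (each centre one step from its predecessor) with the literal
cumulative-sum form available behind the `literal_sum` flag for audit. The
printed "average segment length of 10 Å" is likewise inconsistent with
10 Å-per-coordinate steps (whose mean 3D length is ≈16 Å); we implement the
formula, not the gloss. Whether the harmonic restraint couples all pairs or
only consecutive centres is not stated; all pairs is used. User-supplied
centres (e.g. letter shapes from a CSV of path nodes) take the same route.

## Edited sampling

The sampler partitions $[0, 1]$ into equally spaced time steps, traverses
them from $t = 1$ downward and stops early (defaults: 500 steps, stop after
400). Each iteration applies noise *at the iteration's own grid value* to
the current denoised estimate — the spec of the method deliberately drops
the dependence on the previous noisy iterate — then denoises. Two hooks,
`edit_input` and `edit_output`, transform the structure entering and leaving
the network at every step; because the final iteration ends with
`edit_output`, any constraint the output editor enforces holds exactly in
the returned structure. Implemented editors:

* **Symmetry** (cyclic and screw): subunits are mapped onto the first
  subunit by the inverse group action, averaged (equal weights — the source
  does not specify a weighting), optionally projected to a requested radius
  from the z axis, and replicated by the forward action. The symmetry axis
  is fixed to z; cyclic inputs are re-centred in the xy-plane (making the
  editor a projection), screw inputs are taken in the given axis frame
  because a screw-symmetric structure has no canonical xy-centroid. The
  input hook replicates the first subunit's noise to all subunits so
  corresponding residues attend to identical inputs.
* **Motif replacement**: per rigid group, the motif backbone is Kabsch-fitted
  onto the current coordinates of its target residues and then overwrites
  them; placements sharing a group id move as one rigid body.
* **Multi-state coupling**: one denoising process per state; after every
  step the shared substructures are superposed, averaged (or copied from
  the first state), and written back into each state's frame.

Self-conditioning (feeding the previous prediction back to the model) is
active only while the diffusion time is at or above a threshold (0.8 for
VP, 0.99 for VE). This "on at high noise, off at low noise" direction is a
literal reading of the method's wording; because it is surprising, the
threshold and its direction are configurable.

## Losses and training

Training minimizes a weighted sum of: a per-block trajectory loss (mean
over residues and all 20 atom slots of the squared distance clipped at
10 Å, final block weighted 2×), an all-atom loss on the amino-acid decoder's
atom14 prediction, squared FAPE restricted to the 64 nearest ground-truth
neighbours (16 for the local all-atom FAPE), a rotation loss
$\|R^\top R_\mathrm{gt} - I\|_F^2$ over the trajectory, a simplified
structural violation loss (flat-bottomed bonded terms and a van-der-Waals
clash penalty — exact constant parity with the structure-prediction
literature is out of scope), and cross-entropies for the amino-acid,
secondary-structure and distogram heads with weights 10 / 1 / 0.1. The
violation and local-FAPE terms are zeroed in the high-noise regime
($t > 0.5$ VP, $\sigma > 5$ Å VE). The combined loss contains two 10-weighted
amino-acid terms; we resolve the apparent double-counting by assigning one
to the AADecoder's masked-token cross-entropy and the other (inside the
auxiliary bundle) to the denoiser's own amino-acid head — the only reading
under which both heads described in the methods are trained. The distogram
head is computed sparsely over neighbour pairs with 64 bins on [2, 22] Å
(binning unstated in the source; the standard structure-prediction binning
is adopted), and only at the final layer.

Because no deep-learning framework is available to R, the package carries a
small tape-based reverse-mode autodiff engine over matrices
(`R/autodiff.R`). The network is written once against these ops: with plain
matrix weights the ops fall through to base arithmetic (the inference path),
with parameter tensors they record a tape for the backward sweep. The engine
is validated against central finite differences, both on random composite
graphs and through the entire training loss.

**Toy training.** `toyTrain` runs the full objective at desk scale: Adam
($\beta_1 = 0.9$, $\beta_2 = 0.99$), linear warmup and cosine decay to
1e-7, a mini-batch of structures per optimizer step (all fixtures by
default, mirroring the multi-structure batches of full-scale training),
the two-pass self-conditioning recipe (with probability 0.5 a
gradient-free first pass supplies the previous prediction), and the
high-noise zeroing rule. The toy configuration (local
width 48, pair width 16, 3 denoising blocks, 4 heads) and fixtures of
16–24 residues keep a 500-step run in the minutes range on a single CPU.
Stop-gradients are used where the method implies them: the noised input is
treated as a given sample, the decoder consumes detached coordinates, and
self-conditioning inputs are detached.

Three choices were needed to make gradient-based learning behave at all in
this regime, and are worth recording. First, coordinates inside the network
are expressed in the 10 Å position-scale unit wherever they enter linear
layers or attention point distances: in raw Å, squared point distances
reach the hundreds and the attention softmax saturates into a hard argmax,
killing gradients. Second, the input embedding carries sinusoidal
positional features of the within-chain residue position, giving residues
an identity to memorize against. Third, residual output layers and the
position-offset projection are initialized small-normal rather than
exactly zero: with exact-zero outputs, every gradient path from the
features to the coordinates vanishes at initialization (a two-layer
deadlock between the attention output and the offset projection), so the
untrained model is near-identity (≈1 Å of jitter) rather than exactly the
identity.

Even so, a faithful equivariant denoiser is expensive to train: the
full-scale recipe performs on the order of $10^9$ residue-updates, while a
500-step desk run supplies about $10^4$. The squared FAPE term is dominated
by rigid-frame noise sensitivity (1 Å of per-coordinate noise already
randomizes backbone frames), so sub-Ångström single-pass denoising is not
reached at this budget — the toy trainer demonstrates that the objective
decreases, that its gradients are exact (validated against finite
differences) and that every component participates, not that desk-scale
training reproduces full-scale reconstruction quality.

Batch packing follows the residue-budget rule: structures are appended until
1,024 residues; an entry that would overflow closes the batch with zero
padding and opens the next; per epoch, sequence clusters are sampled without
replacement and a whole complex replaces its selected chain with
probability 0.5 when it fits.

## Synthetic fixtures: what they do and do not show

All tests run on synthetic idealized backbones: helices and strands built
from ideal bond geometry and canonical dihedrals by internal-coordinate
chain construction, Gaussian chains with 3.8 Å CA steps and idealized
N/C/O rebuilt around them, and mixed-topology chains. These fixtures have
exact geometry, single conformations, no missing atoms and no experimental
noise; passing tests therefore demonstrate correctness of the machinery
(equivariance, constraint enforcement, loss algebra, trainability) but say
nothing about designability or diversity of real proteins, which would
require full-scale training and external sequence-design and
structure-prediction tools. The metrics module accordingly accepts
externally computed score tables (scRMSD/pLDDT) and TM matrices, and its
internal fixed-pairing TM-score is a desk-scale substitute for
alignment-based TM tools, valid only for equal-length comparisons.

## Numerical and design choices

* Frames: Gram–Schmidt on (N, CA, C), CA as origin, x-axis along CA→C,
  N in the xy-plane. The source never states its frame convention; the
  rotation loss is convention-dependent up to a fixed per-residue rotation,
  and this is the convention of the IPA literature it builds on.
* Residue indexing is 1-based internally (R's convention); PDB numbering is
  preserved on input and output.
* IPA head shape (8 heads, 32 scalar channels, 4 query / 8 value points)
  follows structure-prediction practice; unstated in the source, fully
  configurable. The per-residue feature width defaults to 256 (stated in
  the methods) although the hyperparameter table prints 128; 128 is one
  config entry away.
* The equivariant position update scales its offsets by a unit factor of
  10 Å; the same unit normalizes coordinates wherever they enter the
  network (see the training section).
* Neighbour ties are broken toward the lower residue position, and the
  random stage clamps distances below 0.1 Å, making runs bit-reproducible
  and degeneracy-safe. A residue is never its own neighbour (IPA's residual
  stream already carries its own features). Sequence-stage neighbours do
  not cross chain boundaries.
* The three-state secondary-structure assigner uses CA-geometry windows
  (distances over offsets 2–4 and the CA pseudo-dihedral), calibrated on
  ideal helices and strands; it is deterministic and has no hydrogen-bond
  parity ambitions.
* Single-linkage clustering uses connected components on the strict
  `tm > 0.6` graph; asymmetric external TM tables are symmetrized by the
  maximum. Whether the clustering threshold is strict or not is not stated
  in the source; strict is chosen per its wording.
* Degenerate inputs: frame construction refuses collinear N/CA/C triples
  naming the residue; superposition requires ≥3 points and resolves
  reflections to proper rotations; softmax rows with no valid neighbour
  yield zero attention output; VP-scaled noise refuses single-residue
  inputs (undefined spread).

## Known limitations

The trainable network is exercised only at toy scale; no claim is made that
the desk-scale configuration reaches the designability of a fully trained
model. Sequence-alignment-based TM scoring, hydrogen-bond secondary
structure, dihedral/tetrahedral point groups and mmCIF I/O are out of
scope. The CLI (`inst/cli/backbone-tool`) generates with random weights
unless a checkpoint is supplied.
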