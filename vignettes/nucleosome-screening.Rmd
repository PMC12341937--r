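---
title: "Confidence-weighted screening of predicted nucleosome binders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted screening of predicted nucleosome binders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucscreen)
```

## The problem

The nucleosome core particle — roughly 147 bp of DNA wrapped around a
histone octamer (two copies each of H2A, H2B, H3 and H4) — is the docking
platform for a large and incompletely catalogued set of chromatin
regulators. Modern complex-structure predictors make it feasible to fold a
candidate protein against a nucleosome template *in silico* and ask whether
the predicted interface looks like a real one. The difficulty is
quantitative triage: a predicted complex always has *some* interface, and
what separates plausible binders from noise is the *confidence* the
predictor assigns to the inter-chain geometry. `nucscreen` implements the
post-prediction stages of such a screen: interface scoring, ranking,
top-hit selection, and a suite of analyses focused on the nucleosome
acidic patch.

## The strength factor

For a predicted binder–nucleosome model, every heavy-atom pair with one
atom on the binder and one on a histone chain at a distance of at most
5 Å defines a contact. Atomic contacts are deduplicated to residue pairs
(confidences are per-residue quantities, so weighting at atom granularity
would multiply-count the same information). Each contacting residue pair
$k$ receives a weight built from two confidence indices:

* $p_{a,k}$ — the transformed predicted aligned error, $31.75 -
  \mathrm{PAE}$. The constant 31.75 is the maximum raw PAE emitted by the
  predictor, so the transform maps "worst possible relative placement" to
  0 and aligns the direction of the index with pLDDT.
* $p_{l,k}$ — the raw per-residue pLDDT.

The PAE matrix is asymmetric, so each pair is read in both directions and
the directional products are averaged:

$$ w_k = \tfrac{1}{2}\left[(31.75 - \mathrm{PAE}_{ij})\,p_{l,i} +
   (31.75 - \mathrm{PAE}_{ji})\,p_{l,j}\right]. $$

The sum $\sum_k w_k$ is the unnormalized strength factor (SF). Dividing
by $B$, the unnormalized SF of a designated reference complex (the
BARD1–nucleosome complex in the screen this package supports), puts all
scores on a common scale; the reference itself scores exactly 1.

Two readings of "the product of the two indices is averaged" are
defensible: average the directional products (above), or average the
transformed PAE and the pLDDT separately and multiply the means. They
differ only in cross terms and obey the same invariants; both are exposed
via `scoring_params(weight_mode = )`, with the directional mean as the
default because it never lets a confident direction be diluted by the
other residue's pLDDT.

Models are excluded before scoring when the predictor's own `has_clash`
flag is set, or when any binder heavy atom sits closer than 1.2 Å to a
histone or DNA heavy atom — an uncontroversial hard-sphere violation;
no published threshold exists for "evident" clashes, so the distance and
the tolerated pair count are both configurable. DNA chains take part in
clash detection but not in SF contacts, which are defined against histone
chains only.

Each candidate protein is predicted several times (five models in the
supported workflow); the protein's score is the *maximum* normalized SF
across its models, excluded models contributing 0. Proteins are ranked by
that score with a stable sort (ties keep input order; the pipeline
pre-sorts protein ids so outputs are reproducible), and the cutoff
between "top hits" and the tail is placed by Kneedle knee detection.

### Kneedle

`kneedle_top()` min–max-normalizes the ranked, non-increasing score list
to the unit square, so the endpoint chord always runs from (0, 1) to
(1, 0), and returns the index with maximal perpendicular distance from
that chord (computed via the difference curve $|1 - x - y|/\sqrt{2}$;
sensitivity 1, no smoothing). A constant list, or one whose maximal chord
distance falls below $10^{-9}$ (a straight line), has no knee and returns
`NA`. On a cliff-shaped list such as `c(1.0, 0.95, 0.9, 0.1, 0.09,
0.08)` the maximal distance lands on the first tail entry (index 4), not
the last high entry — a property worth knowing when interpreting the cut:
"top hits" are the entries up to and including the knee.

## Chain-role assignment

Predicted complexes arrive with arbitrary chain labels. Nucleotide chains
are recognized by residue type; each protein chain is aligned (ends-free
global alignment, BLOSUM62) against full-length reference sequences of
the four core histones, and a chain reaching 80% identity — measured as
matching columns over the length of the shorter sequence, which keeps
short spurious overlaps from scoring high while tailless constructs still
reach 100% — takes that histone role. The one chain matching no histone
is the binder; zero or multiple binder candidates is an error, not a
guess. The shipped references are the isoforms used to assemble the
prediction jobs (H2A type 2-C, H2B type 1-K, H3.2, H4); positions are
counted from the initiator methionine.

## Acidic-patch analyses

The acidic patch — H2A E57, E62, E65, D91, E92, E93 in the reference
numbering — is the dominant docking site for nucleosome binders, usually
engaged by an arginine or lysine anchor inserted into one of two
sub-pockets: AP1 (E62, D91, E93) and AP2 (E62, D91, E65). Patch residues
on an actual H2A chain are located by pairwise alignment to the
reference, never by raw numbering, so truncated or renumbered constructs
are handled transparently.

* **Patch contacts.** The pocket centroid is the unweighted mean of all
  heavy atoms of the AP1 ∪ AP2 residues on one face; binder residues with
  any heavy atom within 5 Å of it are patch-contacting. The nucleosome
  has two H2A faces; both are evaluated and the more occupied one is
  reported (ties go to the first H2A chain). Contiguous runs of binder
  residue numbers form segments; when several segments tie for longest,
  the representative is drawn uniformly under an explicit recorded seed
  (default 985866441) so the choice is reproducible.
* **Consistency.** For each pair among a protein's models, the models are
  superposed over shared histone C$\alpha$ atoms (Kabsch, via SVD;
  pairwise superposition makes the result exactly symmetric and
  permutation-invariant) and the RMSD is taken over C$\alpha$ atoms of
  the intersection of their patch-contacting binder residues. The
  per-protein summary is the *mode* of the 10 pairwise RMSDs, estimated
  by 0.1 Å histogram binning (bin center; ties to the lowest bin). When
  the winning bin's values are all identical — notably the all-zero case
  of five identical models — the exact value is returned rather than the
  bin center, so perfect consistency yields mode 0 and a consistency
  score of exactly 1. The score is $1 - \mathrm{mode}/\max_{\text{cohort}}
  \mathrm{mode}$, clipped to [0, 1]; the cohort maximum is taken over the
  per-protein modes of the current run, so the score is relative to the
  cohort, not absolute. A cohort in which every protein has mode 0 is
  scored 1 throughout.
* **Motif windows.** Every binder Arg/Lys contacting an AP1 or AP2
  residue centers a 21-residue window (±10), gap-padded with `-` at the
  termini so windows stay column-registered for sequence-logo tools.
* **Benchmarking.** A prediction is compared with an experimentally
  solved complex of the same binder through the sets of (binder residue,
  patch residue) pairs, patch residues expressed in reference numbering.
  The call is positive when the Jaccard overlap reaches 0.3 — "agrees
  well" is inherently qualitative, so the threshold is a configurable
  default, and the comparison is symmetric by construction.

## Histone-combination categories

Classifying each binder by *which* of the four histone types it touches
yields $2^4 - 1 = 15$ theoretical categories; an empty contact set is
reported separately as "no histone contact" rather than as a sixteenth
category.

## The synthetic fixture generator

`fixture_spec()` / `write_fixture_files()` build fully synthetic
mini-nucleosomes: eight histone chains embedding exact subsequences of
the reference histones (so classification exercises its real alignment
path, and the H2A windows always end at reference position 93 so the
full patch is present), two short DNA strands, and a binder chain.
Geometry is an ideal C$\alpha$ trace — one heavy atom per residue at
3.8 Å spacing on parallel lanes 24 Å apart — because every quantity the
method consumes is a distance or a confidence value, not chemistry.
Planted contacts are realized exactly: the binder residue is placed at
the planted distance along the lane normal, and a brute-force validator
confirms both that every planted distance reproduces to numerical
precision and that no *unplanned* pair falls below the contact cutoff
plus a 0.5 Å margin (with 3.8 Å spacing, a 4 Å planted contact
necessarily puts chain neighbours at 5.52 Å, so a wider margin would be
geometrically unsatisfiable). Confidence files default to PAE 31.75
everywhere — so non-planted contacts weigh exactly zero — and pLDDT 50,
with planted entries overriding both; generation is a pure function of
seed and spec and is byte-identical across runs.

What the fixtures deliberately do *not* emulate: realistic protein
geometry, the error structure of real predictors (PAE correlated with
distance and domain architecture), side chains, or full-length
nucleosomal DNA. Tests passing on fixtures therefore demonstrate that
the scoring arithmetic, contact detection, and bookkeeping are correct —
not that the screen's biological discrimination transfers to any
particular real protein.

## Numerical choices and degenerate inputs

* Negative transformed PAE (raw PAE above 31.75, possible in other
  predictor dialects) clamps to 0 by default so bad contacts never
  subtract signal; the clamp is a parameter.
* $B$ is always computed by scoring a user-designated reference model
  with identical parameters, never hard-coded: it is a data-dependent
  quantity.
* Empty contact sets score 0; an excluded model scores 0 and carries an
  exclusion flag; a reference model that is excluded or scores $\le 0$
  is an error.
* Pairs of models with no shared patch residues contribute `NA` to the
  RMSD set and are flagged; a protein with all pairs undefined has
  undefined consistency and is reported, not dropped.
* Hydrogens are ignored everywhere; author residue numbering is the
  coordinate convention, and mmCIF `label_seq` is ignored.
* All tie-breaks (best model, ranking, knee, longest segment, mode bin)
  are deterministic or seeded and documented at the function level.

## Problem sizes

The test suite and the acceptance script run entirely on generated
fixtures: mini-nucleosomes of ~370 atoms, screening cohorts of 3–6
proteins with 1–5 models each, 50 fixture replicates for the
contact-detection oracle and 100 random convex curves for the knee
oracle. These sizes exercise every code path (both H2A faces, clash
exclusion, undefined consistency, empty sets) while keeping the whole
suite fast; all operations scale to realistically sized complexes
(~12,000 heavy atoms) through the grid-based neighbour search, whose
result contract is exactly the brute-force all-pairs search.

## Known limitations

* One binder chain per model; assemblies with several non-histone chains
  are rejected rather than guessed at.
* Confidence tokens are one per standard residue or nucleotide; ligands
  and modified residues are unsupported.
* The consistency score is cohort-relative: adding or removing proteins
  changes every score, by design.
* The benchmark call compares pair identity, not geometry; a prediction
  that docks the right residues in a distorted pose still counts as a
  hit at the default setting.
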