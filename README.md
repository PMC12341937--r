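# nucscreen

Confidence-weighted screening of predicted nucleosome-binder complexes.

The nucleosome — ~147 bp of DNA around a histone octamer (2× H2A, H2B,
H3, H4) — is the docking platform for chromatin regulators, most of which
engage the H2A/H2B *acidic patch* through an arginine or lysine anchor.
Structure predictors can now fold a candidate protein against a
nucleosome template, but every predicted complex has *some* interface;
what separates plausible binders from noise is the confidence the
predictor attaches to the inter-chain geometry. `nucscreen` implements
the post-prediction stages of such a screen for structural
bioinformaticians: interface scoring, candidate ranking with knee
detection, and acidic-patch analyses (consistency, anchor motifs,
benchmarking against experimental structures).

## The strength factor

Heavy-atom pairs between the binder and any histone chain at ≤ 5 Å
define contacts, deduplicated to residue pairs. Each contacting pair *k*
is weighted by two confidence indices — *p*<sub>a,k</sub> = 31.75 − PAE
(31.75 is the predictor's maximum raw PAE, so the transform aligns its
direction with pLDDT) and *p*<sub>l,k</sub> = raw pLDDT — with the
directional products averaged over the two orientations of the PAE
matrix:

&nbsp;&nbsp;&nbsp;&nbsp;*w<sub>k</sub>* = ½ [(31.75 − PAE<sub>ij</sub>)
pLDDT<sub>i</sub> + (31.75 − PAE<sub>ji</sub>) pLDDT<sub>j</sub>]

Σ *w<sub>k</sub>* is the unnormalized strength factor (SF); dividing by
*B*, the unnormalized SF of a reference complex (canonically
BARD1–nucleosome), gives the normalized SF, with the reference scoring
exactly 1. Models with predictor clash flags or binder–histone/DNA atoms
closer than 1.2 Å are excluded. A protein's score is the best SF over
its (typically five) models; the ranked list is cut by Kneedle knee
detection.

## Worked example

Inputs are a structure (PDB/mmCIF, pLDDT in the B-factor column) and a
JSON confidence file (`pae` square matrix + `has_clash`). Here both come
from the package's own fixture generator, which plants two binder
contacts with known confidences:

```r
library(nucscreen)

spec <- fixture_spec(seed = 42,
  planted_contacts = data.frame(binder_resno = c(3, 9),
    histone_chain = c("C", "A"), histone_resno = c(62, 50),
    dist = c(4.0, 4.5)),
  planted_pae = data.frame(chain_a = c("K", "K"), resno_a = c(3, 9),
    chain_b = c("C", "A"), resno_b = c(62, 50), value = c(2, 12)),
  planted_plddt = data.frame(chain_id = c("K", "C", "K", "A"),
    resno = c(3, 62, 9, 50), value = c(92, 88, 75, 70)))
fx <- write_fixture_files(spec, tempdir(), "demo")

model <- classify_chains(read_structure(fx$paths$model))
model
#> Predicted complex model 'demo'
#>   11 chains, 370 residues, 370 heavy atoms
#>   chains: A:H3 B:H4 C:H2A D:H2B E:H3 F:H4 G:H2A H:H2B I:DNA J:DNA K:BINDER

conf <- read_confidence(fx$paths$confidence, model)
score_model(model, conf, ref = sf_reference(model, conf))
#> SF result for model 'demo'
#>   contacts: 2  sf_raw: 4109.375  sf: 1
```

The first planted contact (PAE 2 both ways, pLDDT 92/88) weighs
((31.75−2)·92 + (31.75−2)·88)/2 = 2677.5; the second (PAE 12, pLDDT
75/70) weighs 1431.875; their sum 4109.375 is the unnormalized SF, and
scoring the model against its own reference value gives a normalized SF
of exactly 1:

```r
cs <- dedupe_to_residue_pairs(find_atom_contacts(model), "demo")
pair_weights(cs, conf)[, c("binder_resno", "histone_type", "min_dist",
                           "p_a", "p_l", "weight")]
#>   binder_resno histone_type min_dist   p_a  p_l   weight
#> 1            3          H2A      4.0 29.75 90.0 2677.500
#> 2            9           H3      4.5 19.75 72.5 1431.875
```

Batch workflows take TSV manifests: `run_screen()` (score → rank →
knee), `run_consistency()` (mode pairwise patch RMSD across a protein's
models, normalized against the cohort), `run_benchmark()` (Jaccard
overlap of acidic-patch residue pairs against experimental structures).
A thin command-line wrapper lives at `inst/scripts/nucscreen`.

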