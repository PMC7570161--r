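---
title: "Motif-based classification and phylogeny of class B flavoprotein monooxygenases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based classification and phylogeny of class B flavoprotein monooxygenases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmofam)
```

## The biological model

Class B flavoprotein monooxygenases — flavin-containing monooxygenases
(FMOs), Baeyer–Villiger monooxygenases (BVMOs) and N-hydroxylating
monooxygenases (NMOs) — share a conserved sequence architecture: two
Rossmann-fold dinucleotide-binding motifs (`GxGxxG/A`), the first binding
FAD near the N terminus and the second binding NAD(P)H in the central part
of the protein, with the FMO-identifying motif `FxGxxxHxxx[F/Y/W]` sitting
just upstream of the second Rossmann motif. The residues at the two
trailing positions of an extended, 12-position form of the FMO motif are
diagnostic of family membership:

* the six *FMO-like* groups (YUCCA, YUC-like, cyanobacterial, type I, type
  IIa and type IIc FMOs) share `...[Y/F][K/R]` and cannot be told apart
  from the motif alone;
* BVMOs carry an invariant tryptophan at the penultimate position;
* type IIb FMOs carry a histidine at the penultimate position in 70% of
  sequences (Y/F otherwise) and an invariant terminal proline — plus an
  N-terminal extension of roughly 160 residues (an NTF2-like domain)
  absent from every other group;
* NMOs reduce the FMO motif to a single conserved histidine
  (`xxxxxxHxxxx`) and usually replace the third glycine of the FAD motif
  with asparagine;
* class G flavoprotein monooxygenases (the outgroup class) have no FMO
  motif at all.

Secondary signals: type IIb FMOs show asparagine instead of the second
NADPH-motif glycine in 57% of sequences; the last NADPH-motif glycine is
frequently alanine in YUC-like/IIa/IIb/I FMOs and NMOs and is an invariant
alanine in cyanobacterial FMOs and BVMOs; the third FAD-motif glycine is
frequently alanine in type IIc FMOs.

The package turns these observations into an executable pipeline: motif
detection (`annotate()`), family assignment (`call_family()`), per-group
consensus statistics (`build_pfm()`, `diagnostic_fractions()`),
pattern-constrained homolog search with e-value binning
(`run_phi_search()`), distance-based tree reconstruction with
monophyly/sister-clade tests (`neighbor_joining()`, `bootstrap_support()`,
`is_monophyletic()`, `sister_group()`), sample-construction filters, and
abundance/co-occurrence reports.

## Motif detection

Patterns use a small dialect (`compile_pattern()`): uppercase letters are
literals, `x` is a wildcard, `[AB]` an alternative set. An `X` residue in a
sequence (common in translated transcriptomes) matches wildcards but never
a literal. `find_all()` reports every (overlapping) occurrence.

`annotate()` searches the FAD motif `GxGxx[GAN]` in the window `[0, 250)`
— wide enough to sit downstream of the 160-residue type IIb extension —
then the 12-position FMO motif (`FxGxxxHxxx` plus two free positions)
downstream of the FAD hit, then the NADPH motif `Gx[GN]xx[GA]` downstream
of the FMO hit. Among candidate arrangements it (1) maximises the number
of motifs found, (2) prefers the smallest FAD start, and (3) minimises the
total deviation from the expected spacings (FAD start to FMO start 150–220
residues; FMO end to NADPH start 0–40), breaking remaining ties by the
smallest FMO then NADPH start. The spacing priors act only as tie-breakers
for exact matches, never as hard filters: the source of these numbers is a
schematic arrangement, not measured distances. The N-terminal extension
length is defined as the FAD-hit offset and the core coverage as
`(length - fad_start) / length`.

Two noise-tolerance mechanisms matter in practice:

* **Single-mismatch fallback.** A motif with three constrained positions
  is destroyed by any single substitution, so exact matching loses ~1% of
  motifs per constrained position under realistic noise. When no exact
  match exists — or when the exact FAD candidates fail to produce a full
  three-motif arrangement (the NADPH Rossmann motif is itself a perfect
  decoy for the FAD pattern, so a degraded FAD site would otherwise be
  silently replaced by it) — hits with one mismatching constrained
  position are considered. The FMO-core fallback is additionally gated on
  zero spacing deviation *and* both trailing positions carrying residues
  from the known diagnostic repertoire ({H, Y, F, W} × {P, K, R}), so a
  sequence genuinely lacking the motif is not assigned a spurious one.
* **The NMO histidine window.** The relaxed `xxxxxxHxxxx` pattern carries
  almost no information, so the conserved histidine is only sought where
  the FMO motif belongs — near the second Rossmann motif (offsets −46 to
  −9 relative to the NADPH hit, intersected with the ≥6/≥4 flank
  requirement inside the inter-Rossmann region). Searching the whole
  inter-Rossmann region would make the NMO call meaningless: a random
  ~190-residue stretch almost surely contains a histidine.

## Family assignment

`call_family()` applies a total decision order: no Rossmann pair →
unclassified; FMO core absent → NMO if the relaxed histidine is present
(confidence demoted when neither the FAD-third-N nor the NADPH-last-A
variant corroborates it), otherwise a class G candidate; penultimate W →
BVMO; penultimate H → type IIb; terminal P → type IIb (this catches the
~30% of type IIb sequences with Y/F at the penultimate position, and makes
the type IIb call insensitive to the H/(Y/F) split); penultimate Y/F with
terminal K/R → FMO-like, unresolved; anything else → unclassified.

Penultimate H outranks the terminal residue because H at that position is
nearly exclusive to type IIb; in particular a non-canonical terminal
residue (the known charophyte type IIb protein ends its motif in G) never
vetoes a penultimate-H call. The six FMO-like groups are never separated
from motifs alone; `resolve_fmo_like()` accepts a clade label from the
tree stage, which outranks motif evidence. Confidence is `high` when no
secondary evidence (extension ≥ 100 residues for type IIb and only for
type IIb; NADPH-last-A for BVMO) conflicts, `medium` with one conflict,
`low` otherwise. The 100-residue extension threshold is the ~160-residue
domain length minus a noise margin, and is configurable.

## The synthetic corpus: what it emulates, and what it does not

`generate_corpus()` builds, per family, a founder sequence (uniform
background over the 20 amino acids; core 380 residues, in line with a
conserved core occupying roughly two thirds to all of a ~400–550 residue
protein; a 160-residue extension for type IIb only) with the family's
motifs implanted at randomized, recorded offsets, in the strict order
FAD < FMO < NADPH. Records are derived from the founder by per-site
divergence (default 0.25, giving ~56% within-family identity — protein
families at this rank are diagnosable yet clearly diverged) with the
constrained motif positions re-emitted per record from the family's
per-position distributions (penultimate H 0.70 for type IIb, NADPH second
position N 0.57, and so on; "frequently" is rendered as 0.8 and "in most
cases" as 0.9). Optional substitution noise is then applied at
`substitution_rate` per background site and
`substitution_rate * motif_rate_multiplier` per motif site.

**Identifiability scrubbing.** A uniform random background occasionally
produces chance motif matches — and almost surely produces histidines in
the inter-Rossmann region, which would make the class G truth label
unusable (the NMO detector would fire on essentially every class G
record). The generator therefore rejection-resamples background residues
so that, on the clean sequence, the implanted offsets are the unique
arrangement the annotator can recover: no FAD-pattern match upstream of
the true FAD site, no FMO-core match (and, for records without an
implanted core, no single-mismatch near-core) other than the implanted
one, no NADPH-pattern match between the FMO slot and the true NADPH site,
and no stray histidine in the inter-Rossmann region of NMO/class G
records. Noise is applied *after* scrubbing, so noise experiments are
untouched. This is the precise sense in which zero-noise tests recover
truth "by construction".

What the generator does **not** emulate: indels and alignment uncertainty
(rows from `evolve_on_tree()` are aligned by construction); realistic
residue composition (uniform background maximises test transparency);
between-family homology — each family is an isolated homology island,
whereas the real families are distantly related members of one
superfamily. Consequently a pattern-constrained search on synthetic data
retrieves only within-family homologs, and passing tests say nothing
about discriminating genuinely related families by similarity alone.

## Search statistics

`run_phi_search()` implements the pattern-hit-initiated contract: a
subject without a pattern occurrence is invisible regardless of
similarity. Scoring uses anchored affine-gap Smith–Waterman (Rcpp): the
best local alignment whose subject span covers the pattern occurrence,
with BLOSUM62, gap open 11, gap extend 1 (a gap of length *k* costs
`open + k*extend`), the best occurrence kept per subject. Bit scores and
e-values use fixed Karlin–Altschul constants (λ = 0.267, K = 0.041, the
standard gapped-BLOSUM62 values) rather than estimated ones: the e-value
*bins* (`[0, 1e-70)`, `[1e-70, 1e-40)`, `[1e-40, threshold]`, default
threshold 1e-5), not absolute e-values, are the reported contract.
Homolog counts are distinct subjects; species counts are distinct species
strings; totals rows are the sums over bins, rendered `N(M)`.

## Trees

Distances are p-distances with pairwise deletion, optionally
Poisson-corrected (`-ln(1 - p)`); saturated pairs are hard errors rather
than silently truncated. `neighbor_joining()` is the standard Saitou–Nei
agglomeration with two declared numerical choices: ties in the Q matrix
are broken by the lexicographically smallest pair of cluster
representatives (the smallest leaf label in each cluster), making the
topology invariant to input order; negative branch lengths are clamped to
zero with the deficit moved to the adjacent branch, preserving the joined
pair's path length. NJ is exact on additive matrices, which is the basis
of the recovery tests. Bootstrap supports (default 100 replicates) are
percentages of replicate trees containing each full-data bipartition;
degenerate replicates are skipped and counted. Outgroup rooting places
the root at the midpoint of the subtending edge, preserving all pairwise
path lengths. Monophyly is a rooting-invariant bipartition test; sister
groups come from the rooted topology.

The default guide tree for clade-structured simulation places YUC-like
FMOs as the sister of the YUCCAs, the type IIb clade far from both, and
class G as the outgroup, with 0.3 substitutions/site between-family
branches and 0.05 within — strong but not saturating signal at 500 sites.

## Problem sizes and numerical choices

The bundled tests and the acceptance script use: 25–200 records per family
for classification (1000 for the 70%/57% fractions, where the binomial
3σ half-width is 4.3 points), 500-site alignments on the 30-leaf guide
tree with 100 bootstrap replicates, 1000 random instances for the
alignment-oracle equivalence and 10,000 for the scanner oracle. All
randomness flows through explicit seeds; alignment scores are integers;
distances are compared at 1e-9 tolerance.

## Known limitations

* **Class G under noise.** At 5% background noise, ~9% of class G records
  acquire a chance histidine inside the NMO detection window and become
  observationally identical to the (legitimate, ~2%) NMO records whose
  FAD and NADPH motifs are all-glycine. Any per-sequence rule that keeps
  zero-noise recall at 1.0 must call these NMO, capping noisy class G
  recall near 0.90. Resolving the ambiguity needs population-level
  evidence (conservation across a family, as in a logo) or tree context,
  not a longer pattern. The classifier flags such calls by demoting
  confidence.
* The six FMO-like groups are intentionally never separated without tree
  evidence.
* Karlin–Altschul constants are fixed, so absolute e-values are nominal;
  only bin membership is meaningful.
* A distance method cannot arbitrate between alternative
  maximum-likelihood or Bayesian topologies; the tree stage tests clade
  recovery on synthetic truth only.
* The curated, published 134-sequence alignment is third-party data and
  is not redistributed; the diagnostic statistics on that set can be
  recomputed with the bundled pipeline once a copy is placed under
  `inst/extdata/` (see `tests/testthat/test-acceptance.R`).
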