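---
title: "Structure-guided antibody humanization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided antibody humanization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abhumanize)
library(dplyr)
```

## The procedure

Humanizing a murine antibody by CDR grafting replaces its framework
regions with those of a human germline V gene while transplanting the
murine complementarity-determining regions (CDRs), then selectively
restores ("back-mutates") the few framework residues whose side chains the
grafted CDR loops actually depend on. `abhumanize` implements that
procedure as a deterministic pipeline:

1. **Kabat numbering** (`assign_kabat_numbering()`): position labels with
   insertion codes so structurally equivalent residues share numbers.
2. **Germline acceptor selection** (`select_germline()`): rank candidate
   human frameworks by upper-hydrophobic-core preservation, then framework
   identity.
3. **CDR grafting** (`graft_cdrs()`): donor CDRs onto the acceptor
   framework, with per-residue provenance.
4. **Contact analysis** (`find_fr_cdr_contacts()`): framework-to-CDR
   residue interactions within 4.2 Å of an Fv structure model, typed by
   distance rules.
5. **Back-mutation recommendation** (`recommend_back_mutations()`): a
   fixed decision cascade per differing framework position.
6. **Interface/affinity profiling** (`interface_profile()`): interfacial
   contacts at 5.5 Å classified by residue polarity, non-interacting
   surface (NIS) percentages from solvent accessibility, and a linear
   binding-free-energy model converted to Kd at 25 °C.

## Kabat numbering engine

The engine aligns an input VH/VL sequence to a packaged consensus
template (one heavy, one kappa) under a *constrained gap model*: gaps may
appear only as N-terminal FR1 truncation, C-terminal FR4 truncation, CDR
length variation, and insertion codes at the canonical Kabat sites (heavy
35, 52, 82, 100; light 27, 95). Because the gap structure is so
constrained, the search space is small enough to enumerate exhaustively,
so the optimum is exact rather than heuristic. Each candidate
segmentation is scored by its **total number of matching framework
columns**; a match-fraction objective was rejected because it rewards
discarding below-average framework blocks (a mutated FR4 would simply be
dropped). Ties break deterministically: more framework columns, fewer
insertions, less truncation, then CDR lengths closest to the template's.

Within a region, residues are numbered by a site-anchored fill rule: the
numbers up to and including the canonical site come first, surplus
residues become insertion codes (82A, 100B, ...), and the numbers after
the site stay anchored at the region's C-terminal end, so deletions in
short loops remove the numbers immediately before that anchor block
(a length-6 CDR-H3 is numbered 95–98, 101, 102). Supported loop-length
ranges per region follow from the rule; specs outside them are rejected
rather than mis-numbered, as are sequences whose best framework identity
falls below 50% ("not an Fv").

The published position lists for the **upper hydrophobic core** — the
residue platform directly underneath the CDRs — disagree between the two
places they are printed (heavy 47–49 appears in one and not the other);
the package defaults to the more complete list (heavy
{2, 4, 24, 27, 29, 47, 48, 49, 69, 71, 78, 94}, light {2, 4, 64, 66, 71})
and the set is configurable per call and per config.

## Contact rules and the recommendation cascade

All distances use heavy atoms only; hydrogens and waters are discarded on
reading. For a residue pair, the interaction class is:

* **hydrogen bond** if any N/O–N/O atom pair lies in 2.7–3.3 Å
  (a purely distance-based criterion — no angles, no donor/acceptor
  chemistry table);
* else **hydrophobic** if any C–C pair lies in 3.3–4.0 Å;
* else **proximal** if the minimum distance is within the 4.2 Å analysis
  cutoff;
* else **none** — both beyond 10 Å, where no interaction force can form,
  and in the 4.2–10 Å band, which the analysis window excludes.

All windows are inclusive at both ends; the shared 3.3 Å boundary resolves
to the tighter class (hydrogen bond). Inclusive comparisons carry a 1e-9 Å
guard because coordinates parsed from 3-decimal PDB fields are not exact
binary numbers, so a pair planted at exactly the cutoff could otherwise
miss it by one ulp.

For each framework position where donor and acceptor differ, the
recommender applies, in order: (1) upper-core position → back-mutate;
(2) no CDR contacts within 4.2 Å → keep human (surface residues distant
from the CDRs do not affect binding); (3) donor and acceptor residues in
the same physicochemical class → keep human (conservative swap, e.g.
Lys↔Arg or Thr↔Ser); (4) contacts but no hydrogen bond and at most
`contact_weight_threshold` contacts (default 1) → keep human (minor
contact); (5) otherwise → back-mutate. The conservative classes
({K,R,H}, {D,E}, {S,T}, {N,Q}, {L,I,V,M}, {F,Y,W}, {A,G}, {C}, {P}) are
the smallest grouping consistent with the published worked cases and are
configurable. The threshold default of 1 is likewise the smallest value
consistent with the published "weak impact" outcomes. Checking the
conservative swap *before* the hydrogen-bond rule is deliberate: the
published light-chain case keeps a Thr→Ser substitution that costs one
hydrogen bond, because of the side chains' similarity.

```{r}
fx <- humanization_fixture()
recommend_back_mutations(fx$heavy$parent, fx$heavy$acceptor,
                         fx$heavy$support)
```

## Affinity model

Interfacial contacts (ICs) are cross-side residue pairs with any
heavy-atom distance within 5.5 Å, bucketed by the unordered polarity
classes of the two residues (charged {D,E,K,R}; polar {C,H,N,Q,S,T,W,Y};
apolar {A,F,G,I,L,M,P,V} — the class membership of H, C, W, Y is not
fixed by first principles and is configurable). The binding free energy
is the linear contact-based model

$$\Delta G = c_1\,\mathrm{IC}_{cc} + c_2\,\mathrm{IC}_{ca} +
c_3\,\mathrm{IC}_{pp} + c_4\,\mathrm{IC}_{pa} +
c_5\,\%\mathrm{NIS}_{apolar} + c_6\,\%\mathrm{NIS}_{charged} + c_0$$

with the default coefficients (−0.09459, −0.10007, +0.19577, −0.22671,
+0.18681, +0.13810, −15.9433) stored in `pipeline_config()`, never in the
function body, so they are inspectable and swappable. Charged–polar and
apolar–apolar contacts deliberately carry no weight. Kd follows as
$K_d = \exp(\Delta G / RT)$ with $R = 1.9872\times10^{-3}$
kcal mol⁻¹ K⁻¹ and $T$ = 298.15 K by default.

**SASA** uses Shrake–Rupley with a 1.4 Å probe, a fixed 960-point
golden-angle (Fibonacci) sphere lattice per atom — deterministic by
construction — and van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80 Å
(1.80 default). A residue's *relative* SASA is its in-context SASA
divided by the SASA of the same atoms computed in isolation. This
self-reference replaces a packaged literature table of per-residue maxima
because the package must handle both full-atom PDB residues and the toy
4–5-pseudo-atom residues of the synthetic generator; a full-atom
reference would make relative values meaningless for the latter, whereas
the self-reference is representation-agnostic and makes an isolated
residue's relative SASA exactly 1. **NIS residues** are residues at or
above 5% relative SASA that belong to no interfacial pair; the model
takes the percentage of them that are apolar and charged. The NIS
denominator (all NIS residues, not all surface residues) is a documented
choice, configurable only by reimplementation.

## What the synthetic generator emulates — and what it does not

The generator (`make_fv_sequence()`, `make_fv_structure()`,
`make_complex()`) exists because neither the antibody sequences (printed
only as a figure image) nor any structure of this study is publicly
deposited. It produces:

* Fv sequences built from the packaged templates, with framework
  substitutions at a configurable per-position rate (default 0.15,
  murine-grade divergence; the recovery fuzz uses 0.12), random CDR loops
  of Kabat-legal lengths, FR3 insertion codes, and terminal truncations —
  with exact ground-truth numbering by construction.
* Toy Fv structures: residues as 4–5 pseudo-atoms (N, CA, C, O, CB) on a
  line at 8 Å spacing, so every unplanted framework–CDR pair is over 6 Å
  apart; each planted contact relocates the CDR residue so a designated
  atom pair (O···N, CB···CB, or O···CA) sits exactly at the target
  distance, with the remaining atoms stacked away along the approach
  direction so no unintended pair lands in a classification window.
* Two-chain complexes with planted interface pairs at controlled
  distances and far-placed extras, so the interfacial-contact composition
  and the NIS set are known from the pair plan alone.

These structures validate the *rules* — distance thresholds, window
classification, counting, SASA monotonicity — which depend only on
interatomic distances and elements. They are deliberately not physical:
no realistic bond geometry, no rotamers, no Ramachandran validity, no
packing. Passing tests therefore demonstrate correctness of the
implemented criteria, not that the criteria themselves predict real
antibody behaviour; the published per-position decisions enter as a
transcribed text fixture (`humanization_fixture()`), whose parent and
germline sequences are synthetic stand-ins constructed to differ at
exactly the residues the published narrative names, with representative
contact distances consistent with the stated interaction types.

## Problem sizes and determinism

The test suite runs at desk scale on one CPU: 1000 fuzzed sequences for
numbering ground-truth recovery, 100 fuzzed toy structures against an
O(n²) brute-force contact oracle, 100 planted complexes for interfacial
counting (with side-swap and rigid-motion invariance), 20 sequences
against the exhaustive placement oracle, and property checks on grafting
round trips and the linear model to 1e-9. Every random draw is seeded;
generators take mandatory seeds and use no hidden global state, so
reports are byte-reproducible.

## Known limitations

* One heavy and one kappa template; lambda light chains and camelid VHH
  domains are out of scope, as are Chothia/IMGT/Martin numbering schemes.
* The germline library shipped with the package is a synthetic
  template-derived stand-in (real germline sequences would be fetched
  from IMGT by the user and supplied as FASTA).
* Hydrogen-bond detection is distance-only; no angular term, no
  protonation logic.
* The structure-to-numbering mapping is an exhaustive ungapped offset
  search — appropriate for contiguous, possibly truncated model chains;
  PDBs with interior deletions map at the best offset with mismatches
  reported rather than being re-aligned with gaps.
* The affinity model is linear and temperature-naive; it ranks related
  complexes rather than predicting absolute affinities, and its
  coefficients assume the 5.5 Å contact definition and the NIS
  definitions above.
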