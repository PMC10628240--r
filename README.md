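# abhumanize

Structure-guided humanization of murine antibody variable domains, as a
deterministic desk-scale pipeline in R.

Therapeutic antibodies raised in mice are immunogenic in humans. CDR
grafting fixes this by transplanting the murine complementarity-
determining regions (CDRs) onto a human germline framework — but a naive
graft often loses affinity, because a handful of framework side chains
prop up the CDR loop conformations. This package is for antibody
engineers who want that analysis to be explicit, scriptable, and
reproducible: which human germline acceptor to take, which framework
positions to revert to the murine residue ("back mutations"), and how an
antibody–antigen interface scores before and after humanization.

## What it computes

* **Kabat numbering** of VH/VL sequences (insertion codes such as 82A,
  100B; region labels FR1–FR4, CDR1–3) by exact global alignment to
  packaged consensus templates under a constrained gap model.
* **Germline acceptor ranking** by (1) preservation of the *upper
  hydrophobic core* — Kabat heavy {2, 4, 24, 27, 29, 47, 48, 49, 69, 71,
  78, 94}, light {2, 4, 64, 66, 71}, the residue platform directly
  underneath the CDRs — then (2) framework identity.
* **CDR grafting** with per-residue provenance and applied back
  mutations.
* **Framework↔CDR contact maps** within 4.2 Å of an Fv model, typed by
  distance: hydrogen bond for N/O–N/O pairs in 2.7–3.3 Å, hydrophobic for
  C–C pairs in 3.3–4.0 Å, proximal otherwise inside the cutoff; beyond
  10 Å no interaction force can form.
* **Back-mutation decisions** per differing framework position via a
  fixed cascade: upper core → revert; no CDR contact → keep human;
  conservative swap (e.g. Lys↔Arg) → keep human; minor contact → keep
  human; otherwise revert.
* **Interface profiles** of two-sided complexes: interfacial contacts
  (ICs) at 5.5 Å in six polarity-class buckets, non-interacting-surface
  (NIS) percentages from Shrake–Rupley solvent accessibility, and

  ΔG = c₁·IC(charged/charged) + c₂·IC(charged/apolar) +
  c₃·IC(polar/polar) + c₄·IC(polar/apolar) + c₅·%NISapolar +
  c₆·%NIScharged + c₀,  Kd = exp(ΔG/RT) at 25 °C.

A synthetic-data module generates Fv sequences with known numbering, toy
structures with contacts planted at exact distances, and complexes with
known interface composition, so the whole pipeline is testable offline.

## Worked example

The packaged case study (`humanization_fixture()`) carries a synthetic
murine VH/VL pair, a small germline library, and a framework↔CDR contact
map transcribed from a published structural analysis:

```r
library(abhumanize)
fx <- humanization_fixture()

report <- run_humanization(
  heavy = chain_sequence(fx$heavy$parent),
  light = chain_sequence(fx$light$parent),
  germline_library = fx$library
)
report
#> <humanization_report>
#>   heavy: acceptor IGHV1-46*01 (identity 0.89, core 7/12)
#>   light: acceptor IGKV1-5*01 (identity 0.95, core 5/5)
```

The light chain finds an acceptor preserving its entire upper core (5/5),
so no reversion is needed there; the heavy acceptor leaves 5 core
positions un-preserved. Feeding the contact map to the recommender:

```r
recommend_back_mutations(fx$heavy$parent, fx$heavy$acceptor,
                         fx$heavy$support)
#>    label parent germline decision    rationale
#>  1 38    K      R        KEEP_HUMAN  CONSERVATIVE_SWAP
#>  2 40    R      A        KEEP_HUMAN  MINOR_CONTACT
#>  3 48    V      M        BACK_MUTATE UPPER_CORE
#>  4 66    K      R        KEEP_HUMAN  CONSERVATIVE_SWAP
#>  5 67    A      V        BACK_MUTATE CONTACT_DISRUPTING
#>  6 69    L      I        BACK_MUTATE UPPER_CORE
#>  7 71    A      R        BACK_MUTATE UPPER_CORE
#>  8 78    A      L        BACK_MUTATE UPPER_CORE
#>  9 82A   R      S        KEEP_HUMAN  MINOR_CONTACT
#> 10 94    G      R        BACK_MUTATE UPPER_CORE
```

Six heavy positions are reverted (the retained upper-core set plus one
contact-disrupting substitution); Lys66→Arg is kept human because both
are positively charged basic residues and the CDR2 contacts survive the
swap. `apply_back_mutations(graft_cdrs(...), plan)` then yields the final
humanized chain with provenance tags.

On the affinity side, a binding free energy of −12.1 kcal/mol converts to

```r
dg_to_kd(-12.1)
#> 1.35e-09   # mol/L at 298.15 K
```

i.e. a low-nanomolar dissociation constant. `interface_profile()` runs
the full IC/NIS/ΔG/Kd chain on any two-sided complex PDB, and
`glance()`/`tidy()`/`autoplot()` methods give tabular and graphical
views of every result type.

A thin command-line wrapper is included at `inst/scripts/humanize.R`.

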