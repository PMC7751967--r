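---
title: "Anti-idiotypic antibody campaign analysis with idiokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-idiotypic antibody campaign analysis with idiokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idiokit)
```

# The problem

A therapeutic antibody (Ab1) in the clinic needs two kinds of bioanalytical
assays: a pharmacokinetic (PK) assay that quantifies circulating drug, and
an anti-drug-antibody (ADA) assay that detects an immune response against
it. Both are built on anti-idiotypic antibodies (anti-IDs, Ab2) — reagent
antibodies that bind the drug's variable region. The useful ones bind the
complementarity-determining regions (CDRs), the only part of a humanized
drug that differs from the patient's own immunoglobulins; framework binders
are swamped by endogenous IgG in serum.

`idiokit` implements the computational stages of an anti-ID discovery
campaign: designing the CDR-grafted *framework control* used as a negative
gate and negative screening antigen, quantifying the CDR-level diversity of
recovered clones, calling ELISA hits, fitting binding kinetics, typing and
binning epitopes, and selecting assay reagent pairs. A synthetic-data
module generates every input with recorded ground truth, so the pipeline is
fully testable without instrument exports.

# Chain numbering and the framework/CDR partition

All sequence operations run on *numbered chains*: each residue carries a
scheme position (an integer, optionally with an insertion letter such as
`100A`) and a region label (`FR1, CDR1, ..., FR4`). Numbering is performed
by global alignment (BLOSUM62; gap opening 10, extension 0.5 — ordinary
protein-alignment penalties, chosen so that indels are localized rather
than scattered) against a packaged pre-numbered template chain per chain
type; the query inherits the template's positions, insertions receive
lettered positions, deletions leave positions absent. A query aligning to
fewer than 70% of the template's framework positions fails numbering: below
that, the transfer of positions is no longer meaningful.

Two deliberate design choices here:

* **Template-based numbering instead of a rule-based engine.** A full
  rule-based Kabat implementation earns its complexity only when numbering
  arbitrary repertoires; for campaign analysis against one drug the
  alignment transfer is behaviourally equivalent, far smaller, and directly
  testable against hand-aligned fixtures. Users can supply their own
  pre-numbered templates (e.g. real germline chains) to `number_chain()`.
* **A single configurable CDR boundary table.** CDR conventions differ
  (Kabat vs Chothia); the packaged default is their union — the wider span
  at each end (light chain 24–34 / 50–56 / 89–97; heavy 26–35 / 50–65 /
  95–102) — because when the goal is keeping hypervariable residues out of
  the "framework", the conservative boundary is the union. The table is an
  argument everywhere, so an exact convention can be substituted.

The packaged templates are synthetic consensus-like sequences written for
this package. No germline database entries are bundled; real germline
panels are a user input.

# Framework-control design

The control Fab carries the *closest human framework* to the drug but
irrelevant donor CDRs. Stages:

1. `build_consensus_framework()` reduces a germline family panel to a
   consensus: at each framework position the most prevalent residue,
   ties broken by the alphabetically smallest residue (deterministic and
   reportable), positions absent from more than half the members dropped.
2. `percent_identity()` scores the Ab1 framework against each consensus
   over the **union** of framework positions present in either chain, so
   indels count as mismatches. Reported identities are rounded to whole
   percent.
3. `select_closest_control()` picks the maximum-identity family per chain
   independently (ties by panel order) and assembles the label, e.g.
   `K1H3`.
4. `graft_cdrs()` puts the donor CDRs (at their own scheme positions) onto
   the chosen consensus frameworks. The round trip is exact:
   `extract_regions()` of a grafted chain returns the donor CDRs and
   acceptor framework verbatim.

Whether published campaign identity tables were computed framework-only or
over the whole V region is not generally stated; this package uses
framework-only, since the framework is the quantity the control is
standing in for.

# CDR diversity and uniqueness

Each clone's six CDRs are concatenated (VL CDR1–3 then VH CDR1–3) and
compared pairwise by global dynamic-programming alignment with **both gap
penalties zero** and BLOSUM62 scores; the difference is
`100 × (mismatched + gap columns) / alignment length`. With zero gap
penalties the optimal alignment can be degenerate; the implementation
fixes the argument orientation so the reported value is exactly symmetric,
and the test suite checks it against an exhaustive enumeration of all
alignments on small strings. For equal-length strings where no gap is
favoured the measure reduces to the Hamming fraction.

A clone is *unique* if it differs by more than 10% from every other unique
clone. Since no clustering method is implied by that rule alone, the
package uses single-linkage clustering at the threshold (any chain of
pairwise differences ≤ 10% merges), with the first clone in input order as
each cluster's representative; uniqueness is `round(100 × clusters /
clones)`. Single linkage is the only agglomerative scheme whose clusters
are invariant to input order at a fixed threshold, which makes the
uniqueness count reproducible.

Unique clones feed a neighbor-joining tree (Saitou–Nei Q criterion) in
percent-difference units. NJ is implemented in the package so its
tie-break (lexicographically smallest label pair when Q ties) and
negative-branch handling (clamped to zero with a warning) are explicit;
`ape::nj` serves as an independent cross-check in the tests, and on
additive matrices the reconstruction is exact (path lengths reproduce the
input matrix).

The distances here are pairwise, not columns of a single multiple
alignment; for CDR strings that diverge by scattered substitutions the two
agree, but heavily indel-ed repertoires could differ.

# Screening thresholds

All OD comparisons are strict, exactly as assay cutoffs are quoted:
primary hits need `OD > 0.25` on the drug Fab **and** `OD < 0.1` on the
framework control (control-reactive wells are *excluded*, not merely
negative — they are framework binders the control was designed to catch);
top clones for molecular cloning need `OD > 1`; recombinant confirmation
needs `OD > 0.3` with both the designed control and a native human-Fab
control under `0.05`. Boundary values fail. No blank subtraction or plate
normalization is applied by default (replicate wells are averaged);
a serum titer is the largest dilution factor still above its cutoff.

An optional ratio criterion (drug signal a fixed fold over control) is
deliberately not part of the default calls: the absolute thresholds are the
stated rules, and a ratio filter would silently re-admit
borderline control-reactive wells.

# 1:1 Langmuir kinetics

The sensorgram model is the closed-form 1:1 Langmuir solution —
association `R(t) = Req (1 − e^{−(kon·C + koff) t})` with
`Req = Rmax·kon·C/(kon·C + koff)`, dissociation `R(t) = R0 e^{−koff t}` —
verified against numerical integration of `dR/dt = kon·C(Rmax − R) −
koff·R` to below 1e−6 RU in the tests. Fitting is **global**: one
(kon, koff, Rmax) triple across the whole concentration series, the
standard practice for surface-plasmon-resonance evaluation; a per-curve
mode exists for diagnostics. Rates are fitted on a log10 scale by
Levenberg–Marquardt with box constraints kon ∈ [1e2, 1e8] 1/(M·s), koff ∈
[1e−6, 1] 1/s; initial values come from a log-linear regression of the
dissociation tail (koff) and the observed-rate-versus-concentration slope
(kon). `KD = koff/kon` holds exactly in every returned fit, and KD is
reported in nM. Bulk refractive-index jumps and mass-transport limitation
are not modelled (the simple model is the target), and fits where every
analyte concentration sits below the fitted KD are flagged
`well_determined = FALSE` rather than trusted.

On noiseless synthetic series the fit recovers all three parameters to
better than 0.1% across KD from ~1 pM to ~100 nM; with 1 RU Gaussian noise
on 100 RU signals the median |log10 KD error| stays under 0.05 over 20
simulated campaigns (both are acceptance-suite tests).

# Epitope typing and groups

Typing uses SPR summary responses, not raw sensorgrams. The theoretical
antigen-binding Rmax is `(MW_Ag / MW_Fab) × (Fab response) ×
stoichiometry` (responses scale with bound mass; stoichiometry defaults to
1 for a monovalent Fab). The *actual* antigen Rmax percentage divides the
post-antigen-injection gain `(post-Ag response − Fab response)` by that
theoretical value; the gain is read as "response after the antigen
injection minus the Fab-only saturation level", the only reading under
which the percentage ranks clones by antigen accessibility. Blocking iff
≤ 0; the boundary belongs to blocking. Complex specificity compares the
Rmax of premixed antigen+Fab against Fab alone: specific iff the ratio
exceeds 10% strictly; when capture levels are provided both Rmax values
are normalized by them first, otherwise matched capture is assumed.

Groups follow mechanically: 1 = non-blocking and complex-specific (can see
target-bound drug: total-drug assays), 2 = non-blocking only (free and
partially bound drug), 3 = blocking (free drug only). The assignment is a
total function of the two flags, so group counts always partition the
panel.

# Epitope binning

Pairwise sandwich competition is normalized per detecting clone
(`raw[i,j]/expected[j]`) and thresholded at 0.2 of the expected response —
competition software keeps this knob internal, so here it is an explicit,
configurable default backed by fixtures. The matrix is symmetrized by
logical OR before binning (a one-way block is still a block; orientation
asymmetries are capture artifacts), configurable off. A *bin* is a set of
clones with an identical blocked-profile row; the competition network has
an edge wherever either direction blocks, and sandwich-compatible pairs
are those free in both directions. On synthetic panels built from latent
1-D epitope intervals (compete iff intervals overlap) the recovered bins
equal the distinct-interval classes exactly at zero noise, including the
bridging-clone geometry where one clone spans two otherwise disjoint
sites.

# Reagent selection

Published pair selections rest on "high signal-to-noise and a robust
dose-response curve"; the package's computable proxy is explicit:
signal-to-noise is the top-dose OD over the zero-analyte blank (blank
floored at 0.001), a pair is *suitable* when the clones sit in different
bins with no mutual competition, S/N ≥ 10 (configurable; no published
numeric cut exists) and the curve is monotone non-decreasing within a 2%
relative tolerance for plate noise. ADA bridging controls are ranked by
the same S/N on single-clone titrations. These are stated stand-ins, not a
reconstruction of any particular laboratory's rule.

# Synthetic data: what it emulates, and what not

Each generator is seeded and bit-for-bit reproducible; `run_campaign()`
fans one campaign seed into per-stage substreams so stages can be
regenerated independently. Defaults mirror the scale of a real campaign:

* germline panels: 4 light and 4 heavy families, 5 members each,
  family/member mutation rates 0.08/0.02 per position — enough divergence
  that closest-family recovery is unambiguous at desk scale;
* repertoire: 34 clones in 24 lineages (the example campaign's cloned /
  unique counts). Lineage founders are mutated ~30% apart; within-lineage
  variants carry at most 3 substitutions of the 61-residue CDR
  concatenation, which keeps the alignment-based difference below the 10%
  rule with margin (an alignment can render k substitutions as 2k gap
  columns, so 3 substitutions bound the difference near 9.4%);
* screening plates: 2000 supernatants, 45% hits, 5% control-reactive,
  with OD distributions placed clear of the thresholds so planted labels
  are recoverable exactly;
* sensorgrams: five-fold dilutions from 100 nM, 180 s association /
  420 s dissociation at 3 s sampling, Rmax 100 RU, Gaussian noise;
* epitope assays: group proportions 5/14/5 out of 24, blocking margin
  −5 RU, non-blocking gain +40 RU, complex ratios 60% vs 2%,
  multiplicative noise;
* competition: three latent interval sites (optionally a bridging clone),
  competed responses at 2% of expected.

What the generators do **not** emulate: somatic hypermutation statistics,
drift/bulk artifacts and mass transport in sensorgrams, plate-position
effects and hook effects in ELISA, partial (graded) competition, or matrix
effects in serum. Passing the recovery tests therefore demonstrates the
*analysis* is correct under its stated model, not that the model captures
every instrument pathology; the module surfaces accept real lab exports
(CSV/FASTA) precisely so the same code runs on data that does.

Problem sizes throughout the test and acceptance suites (tens of clones,
thousands of wells, 20–50 simulation replicates) are chosen as the scale of
one campaign — comfortably exact for the combinatorics being checked.

# Known limitations

* Lambda light chains are an extension point (supply templates and a
  boundary table); only kappa/heavy ship by default.
* The NJ tree is built from pairwise distances, not from a multiple
  alignment.
* ELISA dose-response curves are used only through S/N and monotonicity;
  no 4PL fitting or LLOQ/ULOQ estimation.
* Binning expects pre-referenced response matrices; instrument file formats
  are out of scope.
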