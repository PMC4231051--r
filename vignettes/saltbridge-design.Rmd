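---
title: "Designing thermostabilizing salt bridges from pairing statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing thermostabilizing salt bridges from pairing statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltbridger)
library(dplyr)
```

## The problem

Surface salt bridges — electrostatic contacts between a basic side chain
(Lys NZ; Arg NH1/NH2) and an acidic one (Asp OD1/OD2; Glu OE1/OE2) — are one
of the most consistent structural differences between thermophilic proteins
and their mesophilic homologues. Introducing new ones by mutation is an
attractive stabilization strategy, but most candidate substitutions do
nothing: whether a hypothetical pair actually forms depends on the mutual
orientation of the two residues, their distance, their secondary-structure
context, and whether the site can tolerate a mutation at all.

`saltbridger` addresses this with a purely statistical, structure-based
recipe:

1. **Survey.** Detect salt bridges across a set of X-ray structures. A
   bridge is any basic/acidic residue pair with a qualifying side-chain
   atom pair under 4 Å; His is excluded because its protonation at pH 7 is
   ambiguous, leaving four pair types (K–D, K–E, R–D, R–E). Each bridge is
   characterized by its Cα–Cα distance $r$, the two pseudo-angles
   $\theta_1 = \angle C\beta_1 C\alpha_1 C\alpha_2$ and
   $\theta_2 = \angle C\beta_2 C\alpha_2 C\alpha_1$, the 3-state secondary
   structure of both residues, and its burial state from relative solvent
   accessibility (RSA).
2. **Index.** Bridges in the *exposed* class (one RSA > 35 %, the other
   > 25 %) are binned by (pair type, SS pair, 1-Å distance bin) and the
   empirical frequencies are scaled to weights $w$ summing to 100 — the
   pairing-preference index.
3. **Pre-filter.** Designable positions are polar or charged residues
   (S, T, C, N, Q, K, R, D, E) that are exposed (RSA > 35 %), flexible
   (B-factor z-score > 0), loosely packed (rWCN z-score > 0), and variable
   (ConSurf grade < 4).
4. **Score.** Each surviving position is hypothetically substituted by K,
   R, D and E and scored against every charged residue within 15 Å (any
   chain) by the weighted electrostatic attraction model

   $$E_i \;=\; \sum_{j:\,r_{ij}\le 15\,\text{Å}}
      \mathbb{1}[\,q_i q_j < 0\,]\;
      w\!\left(\text{pair}(i,j),\, \text{SS}_i \text{SS}_j,\, \text{bin}(r_{ij})\right),$$

   where $q$ is +1 for K/R, −1 for D/E and 0 otherwise. Repulsive and
   neutral contacts contribute zero — repulsive pairings were never
   surveyed, so they carry no weight by construction.
5. **Suggest.** Pairs must satisfy the angular envelope observed in the
   survey (for $r > 7$ Å at least one of $\theta_1, \theta_2$ below 110°)
   and a sequence separation of at least 5 residues (pairs across a
   subunit interface always qualify). The predicted pair of a position is
   its highest-scoring qualifying pair; when the globally best pair is a
   short-separation one, a substitution is still accepted if its best
   qualifying pair outscores that same substitution's short pair
   (the *alternative-substitution* rule). Exact score ties emit all tied
   substitutions.

## Descriptors

All per-residue descriptors are computed from Cα atoms only. The weighted
contact number of residue $i$ is $\mathrm{WCN}_i = \sum_{j \ne i}
1/d^2(C\alpha_i, C\alpha_j)$, summed over the **whole assembly**: packing at
subunit interfaces is exactly what distinguishes an interface position from
a surface one, and interface positions are legitimate design targets. rWCN
is its reciprocal, so *high* rWCN means *low* packing. B-factor and rWCN are
standardized per chain; we use the population (divide-by-$n$) standard
deviation, so within a chain the z-scores have exactly zero mean and unit
population spread. The convention is configurable
(`sb_config(sd_type = "sample")`) because published per-protein tables do
not always state theirs; the pre-filter thresholds sit at 0, where the two
conventions differ only by a scale factor and select identical residues.

RSA divides the residue's accessible surface area by the maximal ASA of
that amino acid in an extended Gly–X–Gly tripeptide. We ship the published
Tien et al. (2013) tables as configuration data, with the *theoretical* set
as default and the *empirical* set as an alternative. When a DSSP file is
supplied its ASA and 8-state codes are used verbatim and collapsed as
{H,G,I}→helix, {B,E}→sheet, {T,S,blank}→coil; without DSSP an internal
Shrake–Rupley implementation (Fibonacci sphere sampling, Bondi radii,
1.4 Å probe, 240 points per atom by default) supplies ASA, and a
torsion-based heuristic assigns secondary structure. The fallback exists so
that the full pipeline runs on bare coordinates; DSSP input takes
precedence whenever available because its hydrogen-bond-based assignment is
the reference. In validation the Shrake–Rupley fallback reproduces the
analytic area of an isolated sphere exactly and agrees with an independent
implementation within a few percent; an extended Gly–Ala–Gly peptide built
with ideal geometry lands within 5 % of the empirical reference value,
which is why the empirical table is the natural companion of
fallback-computed ASA.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bridge_atom_cutoff` | 4.0 Å | charged-atom distance defining a bridge |
| `neighbor_radius` | 15 Å | Cα–Cα partner search radius (the longest surveyed surface bridge spans ≈ 14.2 Å) |
| `angle_cutoff`, `angle_distance_gate` | 110°, 7 Å | angular envelope for long pairs |
| `rsa_min`, `z_b_min`, `z_rwcn_min`, `cons_max` | 0.35, 0, 0, 4 | pre-filter cascade |
| `seq_sep_min` | 5 | minimum intra-chain sequence separation |
| `exposure_rsa_hi/lo/buried` | 0.35 / 0.25 / 0.09 | burial classes of surveyed bridges |
| `bin_edges` | 3–15 Å, 1 Å | distance bins of the index |

The distance bins deserve a note: the published form of the index is not
distributed with its bin edges, so the index here is always *rebuilt* from
a survey. One-Å bins over [3, 15] Å cover the observed range of surface
bridges; per-category weights of a rebuilt index therefore approximate, but
need not equal, any previously printed per-pair scores.

## The synthetic-structure generator

`fixture_spec()`/`generate_fixture()` build small PDB files in which every
quantity the pipeline measures is planted: pair type, Cα–Cα distance,
$\theta_1/\theta_2$ (exact by construction of the Cβ direction), minimum
charged-atom distance, secondary structure and accessibility (emitted as a
synthetic DSSP file so planted annotation flows through the same input path
as real DSSP output), per-residue B-factors, and intra- vs inter-chain
placement. Decoy residues — including charged ones spaced > 4 Å apart — are
placed on a compact grid 30 Å away, which doubles as a densely packed
baseline so planted bridge residues are the loosely packed, flexible ones.
`generate_survey_set()` plants category *counts* exactly (largest-remainder
rounding of proportions), which makes index recovery an identity:
`build_pair_index()` on a surveyed set returns 100 × the planted
proportions, to floating-point precision.

What the fixtures deliberately are **not**: physically realistic
conformers. Bond geometry is idealized, side chains are minimal (only atoms
the pipeline reads), and no clash or Ramachandran checking is done. Tests
passing on fixtures therefore validate the *measurement and decision
machinery* — detection thresholds, geometry, binning, z-scores, filter and
suggestion logic — not the biophysical realism of any particular design.
Validation against real crystal structures (reference bridge geometries in
archived PDB entries) is wired into the acceptance tests but requires the
coordinate files, which are fetched into a local cache on first use.

## Numerical choices and degenerate inputs

* Altlocs keep the highest occupancy (ties: first encountered); model 1
  only; MSE is read as Met; waters and other heteroatoms are dropped.
* Residues lacking Cα are excluded with a warning — every descriptor is
  Cα-anchored.
* Gly (and side-chain-truncated residues) get a virtual Cβ from ideal
  tetrahedral backbone geometry, so pair angles remain defined.
* Zero-length Cα–Cβ or Cα–Cα vectors raise a geometry error rather than
  propagating NaN.
* A constant descriptor vector (sd = 0) raises an error rather than
  emitting infinite z-scores.
* Pair-index lookups outside the bin range contribute 0 with a warning;
  unobserved categories score 0 silently.
* Suggestion order is deterministic: (chain, residue number, substitution
  alphabetical); exact score ties are all emitted.
* Residues with no conservation grade fail the conservation filter —
  missing evidence of variability is treated conservatively.
* Canonical pair orientation is (basic, acidic), so K–D ≡ D–K and the SS
  pair is ordered (SS of basic, SS of acidic).
* One bridge record per residue *pair* (minimum over qualifying atom
  pairs), so survey counts are residue-pair counts.

## Problem sizes

The test suite and the acceptance script run on synthetic sets of 100
structures with 300 planted bridges, 50-residue random coordinate sets for
contact-number checks, and 50 random neighbourhoods for scoring-oracle
checks — sizes at which every brute-force oracle (double-loop WCN,
exhaustive score summation, table-walking index lookup) is itself exact and
fast.

## Known limitations

* No side-chain modelling: hypothetical substitutions are scored with the
  native backbone's Cα/Cβ geometry, exactly as surveyed pairs are.
* No repulsion penalty, no charge-network cooperativity, no ΔΔG or ΔTm
  prediction — scores are pairing-preference weights only.
* Conservation grades are consumed, never computed; without them the
  pre-filter intentionally returns nothing.
* The internal secondary-structure fallback is a torsion heuristic; supply
  DSSP files when fidelity to the reference annotation matters.
* The survey consumes a user-supplied structure list; dataset curation
  (resolution, R-factor, redundancy screens) is upstream of this package.

## A worked run

```{r, eval = FALSE}
# survey a directory of structures, build the index, design on a target
sv  <- run_survey("structures/", out = "survey", dssp_dir = "dssp/")
idx <- run_index("survey_bridges.tsv", out = "pair_index.tsv")
sug <- run_design("target.pdb", "pair_index.tsv", out = "suggestions.tsv",
                  conservation = "target_consurf.tsv", explain = TRUE)
```

A fully synthetic end-to-end example, with the numbers it prints, is in the
package README; `scripts/acceptance.R` is the same pipeline instrumented to
report detection, recovery and design-fidelity measurements as JSON.
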