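---
title: "Local-structure template matching: model, parameters, and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-structure template matching: model, parameters, and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitematch)
```

## The model

`sitematch` predicts catalytic residues by local structure comparison. The
underlying assumption is that enzymatic function is carried by a small
constellation of residues whose relative geometry is conserved even when
sequence and global fold are not, so a library of annotated active-site
geometries can be searched against any query structure.

Each residue is reduced to **two points**: the C&alpha; and the *fa*, the
side-chain heavy atom furthest from the C&alpha; (side chain = heavy atoms
excluding N, CA, C, O, OXT). This representation captures both backbone
placement and side-chain orientation at minimal cost. A **template** is the
ordered list of the (C&alpha;, fa) pairs of one enzyme's catalytic
residues; a per-family **master template** is the member minimizing the
mean rigid-superposition RMSD to all family members (the self term, which
is zero, is included in the mean — the normalization is configurable in
principle but immaterial to the argmin).

Matching proceeds in three stages:

1. **Filtering.** Query residues become candidates for a template slot when
   their type equals the slot's type, or is interchangeable with it under
   an optional symmetric, reflexive 0/1 substitution matrix. Residues whose
   fa cannot be derived (all side-chain atoms missing from the file) are
   excluded from candidacy altogether; this is deliberate, because it is
   exactly the failure mode that the subtemplate expansion is designed to
   repair, and matching such residues on C&alpha; alone would silently
   change the geometry being compared.
2. **Emulation and scoring.** Every assignment of distinct candidates to
   slots (a *local structure*) is compared with the template through the
   contact matrix average deviation (CMAD): the mean absolute difference of
   corresponding pairwise distances, computed separately for the C&alpha;
   and the fa point sets. A match requires *every* pairwise deviation in
   both matrices to stay within the CMAD cutoff; since the mean of values
   each below the cutoff is below the cutoff, the per-pair gate implies the
   CMAD gate, and the search can prune a partial assignment as soon as one
   pair deviates — the pruned search is exactly equivalent to exhaustive
   enumeration (a property the test suite checks against a prune-free
   oracle).
3. **Significance.** Accepted matches are superposed by least squares
   (Kabsch, proper rotations only) and the RMSD *R* is converted to a
   p-value via an expectation function `EF(R)` — the estimated number of
   random matches at least as good — with `p = 1 − exp(−EF)`.

### The expectation function

The text contract for the significance model is that EF grows with the
RMSD and with &theta;, the product of the background abundances of the
matched residue types: common residue types and loose geometry are easy to
hit by chance. The functional form shipped with this package is

`EF(R) = θ · exp(a) · R^(b·(n−1))`,

where *n* is the match size. The exponent comes from a degrees-of-freedom
argument: *n* two-point residues contribute 2*n* points, i.e. 6*n* − 6
internal coordinates once rigid motion is removed, so the configuration
volume within RMSD *R* of a target shape scales as `R^(6(n−1))`; `b = 6` is
therefore the geometric default. The scale `exp(a)` was fitted on this
package's own synthetic decoy background (two-residue templates against
150-residue decoy chains, counting matcher output below each RMSD level
and regressing the log-counts with the exponent fixed), giving `a = 5.2`.
Two observations from that calibration drove the choice of form: the free
exponent fitted on the flank is close to the geometric value, and no
random match below 0.31 &angst; RMSD was observed in 200 searches — so a
form that vanishes at `R → 0` is the right behaviour, and a single
exponential in *R* (which does not vanish) would misprice geometrically
exact matches. A consequence worth knowing: an exact match has `EF = 0`
and hence `p = 0` exactly; p-values below machine epsilon are printed as
`<2.3e-16`.

Both constants are data, not code (`inst/extdata/evd_params.yaml`), and
should be refitted if the background of interest differs from the decoy
model — in particular, real non-redundant PDB backgrounds are more
self-similar than random chains, and significance against them will be
somewhat optimistic. The abundance table
(`inst/extdata/swissprot_abundance.tsv`) is the Swiss-Prot composition
normalized to sum to one, also replaceable. Under a substitution matrix,
&theta; uses the *effective* per-slot abundance — the summed frequency of
every type allowed to fill the slot — so that widening the substitution
relation raises &theta; and with it the p-value, which is the documented
cost of the substitution-matrix approach.

### The subtemplate expansion

`expand_library()` adds, for every template of *n* residues, its *n*
subtemplates of *n* − 1 residues (`k = 1`; general *k* removes every
subset of size *k*, at a cost that grows combinatorially as *k* approaches
*n*/2 — single point mutations make `k = 1` the biologically relevant
setting). The library grows by at most `N_T × n_max` entries. Matches of a
subtemplate whose parent also matched a superset of the same residues are
filtered out afterwards; this only removes redundant output. The default
`min_size = 2` keeps the two-residue subtemplates of three-residue sites,
which is what lets a three-residue site survive a single mutation.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `cmad_cutoff` | 1.2 | &angst; | standard acceptance threshold for master-template libraries |
| `cmad_cutoff_extended` | 0.4 | &angst; | trade-off for expanded libraries: small templates hit random geometry more often, and true matches sit well below 0.1 |
| `p_threshold` | 1e-4 | — | significance gate applied after the geometric gates |
| `k` | 1 | residues | subtemplate depth (single point mutations) |
| `min_size` | 2 | residues | smallest subtemplate kept |
| EVD `a`, `b` | 5.2, 6 | — | see the calibration above |

The cutoff sweep facility in `run_benchmark()` exists because sensitivity
as a function of the CMAD cutoff behaves very differently for the two
library types: master-template sensitivity degrades as the cutoff tightens
(real family variation gets rejected), while expanded-library sensitivity
on exact sites is flat from 1.2 down to 0.1 — whenever a subtemplate match
exists at all, its CMAD is far below any reasonable cutoff.

## The synthetic data generator

The fixtures module generates everything the benchmark needs without
downloads:

* **Decoys** (`make_decoy`) are self-avoiding pseudo-chains: consecutive
  C&alpha; spacing 3.8 ± 0.1 &angst;, no two C&alpha; closer than 3.5
  &angst;, types drawn from the background abundance table, fa offsets
  1.8–3.5 &angst; in random directions. They emulate the *geometry and
  composition statistics* that the matcher sees — nothing more. They do not
  emulate secondary structure, rotamer libraries, residue-residue packing
  or sequence plausibility, and decoy side chains are stubs (CB plus the
  type's canonical terminal atom). Consequently, passing tests demonstrate
  the method's discrimination against random geometry of realistic density,
  not against the self-similarity of real protein space, where
  false-positive rates would be higher.
* **Templates** (`make_template`) place 2–6 residues 5–9 &angst; apart with
  fa offsets 2.3–3.8 &angst;; types exclude alanine and glycine so every
  planted residue is a valid alanine-scanning target.
* **Planted sites** (`plant_site`) overwrite sequence-non-adjacent decoy
  residues with a rigidly placed copy of a template, plus optional iid
  Gaussian jitter emulating within-family variation. At zero jitter the
  planted site is geometrically exact, which is the regime the benchmark
  grid uses ("recovery" is then unambiguous).
* **Benchmarks** (`make_benchmark`) assemble the 2×2 grid: non-mutated vs
  alanine-scanned positives, master vs expanded library, plus negative
  decoys, with a manifest and optional on-disk PDB/TSV output.

Everything is deterministic given the seed (R's default Mersenne–Twister,
scoped with `withr::with_seed` so global RNG state is untouched).

### Problem sizes used by the test suite

The acceptance-level tests run a seeded grid of 20 positives (planted
round-robin from a 5-template library of 3-residue sites, zero jitter),
100 negatives, 150 residues per chain; the oracle-equivalence checks use
12 random instances of 2–5 slots against 55-residue decoys; calibration
and property checks use 20–50 seeded repetitions. These sizes were chosen
so each scenario has enough queries for its pass/fail margins to be
meaningful while the whole grid stays a few minutes of compute.

## Numerical and design choices

* **Glycine** has no side-chain heavy atom; its fa is defined as its
  C&alpha;, which keeps distance matrices well-defined and makes
  glycine-containing templates representable. Under the identity
  substitution matrix glycine matches only glycine.
* **fa ties** (e.g. equidistant terminal atoms such as arginine's
  NH1/NH2) break by atom-name order, so the choice is deterministic across
  platforms; coordinates are carried at full precision internally and
  written to PDB at the format's 3 decimals.
* **Altlocs** keep the highest-occupancy alternative (ties: first in file
  order); hydrogens, waters, HETATM and non-standard residues are dropped;
  only the first model of multi-model files is read.
* **Superposition** uses SVD with a determinant guard, so reflections are
  never used and 2-point degenerate configurations are handled; agreement
  with a rotation-scan oracle is tested to 1e-6.
* **Ranking ties** break by p-value, then fa-CMAD, then template id —
  deterministic output for identical inputs.
* **Zero-denominator metrics** report NaN with a warning (sensitivity,
  precision, accuracy) and 0 by convention for the MCC.
* **Master-template selection** excludes family members whose size or type
  sequence disagrees with the family's modal signature, with a warning,
  rather than failing the family outright.
* **Subtemplate identifiers** are derived as `<parent>~minus-<residue>`,
  so lineage survives file round trips and postprocessing is reproducible.

## Known limitations

* The decoy background understates the self-similarity of real structure
  space; EVD constants should be refitted before interpreting absolute
  p-values on real proteomes.
* Candidate enumeration is exponential in template size in the worst case;
  per-pair pruning makes realistic searches fast, but adversarial inputs
  (many same-typed residues in near-regular geometry) can still be slow.
* Sites whose catalytic residues include more than one mutation need
  `k ≥ 2` expansion, with the attendant library growth.
* mmCIF input, nucleic acids, modified residues and biological assemblies
  are out of scope; structures are read from PDB-format ATOM records only.
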