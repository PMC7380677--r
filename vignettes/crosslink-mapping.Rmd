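---
title: "Mapping XL-MS restraints onto structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping XL-MS restraints onto structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlmapper)
```

## The measurement model

A chemical crosslinker bridges two residues only when its reactive groups
can reach them, so every identified crosslink between residues $i$ and
$j$ implies an upper bound on their separation in at least one
conformation the protein visits. `xlmapper` evaluates each restraint
against a structure by the C$\alpha$–C$\alpha$ Euclidean distance

$$ d_{ij} = \lVert \mathbf{r}_i - \mathbf{r}_j \rVert, $$

and classifies it against a spacer-arm threshold $T$:
*satisfied* when $d_{ij} \le T$, *violated* when $d_{ij} > T$. The
inequality is strict on the violated side, so a link exactly at the
threshold is satisfied; classification always uses the full-precision
distance, with rounding to one decimal applied only in CSV output and
labels, so display formatting can never flip a classification.

Assumptions worth keeping in mind:

* **Euclidean, not through-solvent.** The straight-line C$\alpha$
  distance can pass through the protein; solvent-accessible surface
  distances (SASD) are a stricter and sometimes more faithful criterion,
  but orders of magnitude more expensive. This package deliberately
  implements the fast Euclidean criterion only.
* **One distance per link.** A single coordinate model is used
  (selectable via `model_index`), and alternate locations are collapsed
  before any distance is computed.
* **A violated link is not an error.** Crosslinking integrates over the
  solution ensemble; violations frequently indicate genuine inter-domain
  motion or lowly populated states rather than a wrong structure. The
  tool counts and displays; interpretation stays with the user.

A third outcome, *missing*, covers links for which either endpoint has
no usable C$\alpha$ — the residue is absent from the coordinate file
(disordered, unresolved), the chain identifier does not match, or the
residue is present without a C$\alpha$ atom. Missing links are reported
and counted, never silently dropped, since clustered missing links flag
disordered regions that may matter biologically. Mono-links (dead-end
crosslinks) address a single residue; no distance is defined for them,
so they carry only a present/missing state and never enter the
satisfied/violated tallies. In the CSV export, where the status column
has exactly the three values above, a present mono-link is written as
`satisfied` in the sense that its site exists in the structure.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 27 Å | spacer-arm upper bound; 27 Å suits DSBU, whose NHS-ester arms bridge lysines up to roughly 27–30 Å C$\alpha$–C$\alpha$. BS3/DSS users typically set ~30 Å, zero-length chemistry ~12–15 Å. Always overridable. |
| `model_index` | 1 | coordinate model of a multi-model (e.g. NMR) file |
| `include_monolinks` | TRUE | whether mono-links are mapped at all |
| `render_style()` colors | blue / red / green | satisfied / violated / mono-link; any PyMOL color name |
| `dash_width`, `dash_gap`, `sphere_scale` | 2.5 / 0.5 / 0.5 | line and sphere geometry of the generated script |

## Structure indexing policies

Crosslink lists address residues by author chain ID and author residue
number, exactly as deposited, so the reader never renumbers and matches
chains case-sensitively (mmCIF chain IDs can be multi-character, where
case-folding would be unsafe). Decisions that the coordinate formats
force:

* **Altlocs**: the C$\alpha$ with the highest occupancy wins; equal
  occupancies fall back to file order. This is deterministic and matches
  the one-distance-per-link model.
* **Insertion codes**: the crosslink dialect has no insertion-code
  field, so only residues with a blank code are addressable. Residues
  with non-blank codes are skipped with a warning naming them — silently
  picking one of several residues sharing a number would be worse.
* **Non-standard residues**: HETATM records that are modified amino
  acids (MSE and friends) carry a C$\alpha$ and are indexed; waters and
  ligands are not. Calcium ions, whose atom name is also `CA`, are
  excluded by element.
* **Polymer residues without a C$\alpha$** stay in the index with the
  coordinate marked absent, so `ca_status()` can distinguish "residue
  present but unresolved atom" (`ca_missing`) from `residue_missing` and
  `chain_missing`.

Parsing itself is delegated to `bio3d`; the policies above are applied
to its atom table. bio3d's own altloc default (keep altloc `A`) differs
from the occupancy rule, so the reader requests all altlocs and resolves
them itself.

## The crosslink dialect

One entry per line, pipe-delimited: `res1|chain1|res2|chain2|` for a
crosslink, `res|chain|` for a mono-link. The trailing pipe is optional
on input and always written on output; whitespace around fields is
ignored; `#` starts a comment line. Anything else — three fields, five
fields, a score column, a non-integer residue — is a format error naming
the line, not a silent truncation: score-based filtering belongs in the
upstream XL-MS search software, and guessing at malformed lines would
corrupt counts downstream.

Duplicates are detected after canonical endpoint ordering (so
`10|A|20|A|` and `20|A|10|A|` are one link) and removed with a warning;
the first occurrence keeps its file orientation for labels and object
names. Self-links are zero-length restraints with no information content
and are excluded, also with a warning. Every input line is accounted
for: parsed + skipped + deduplicated + self-links = total, and the test
suite asserts this.

## Summary counts and filtering

Reports carry conservation-checked tallies:
$n_{sat} + n_{viol} = n_{disp}$, $n_{disp} + n_{miss} = n_{total}$,
$n_{intra} + n_{inter} = n_{total}$. These identities are recomputed and
asserted every time a report is built or filtered, so a counting bug
cannot produce a report at all. Filtering mirrors interactive viewers'
checkboxes: a link is kept iff its topology flag and its status flag are
both enabled; a missing link is kept while its topology is shown and at
least one status class is shown. Raising the threshold on a fixed
dataset can only move links from violated to satisfied — monotonicity
that the property tests check over random datasets.

## Script generation

The PyMOL script is plain text and fully deterministic: identical inputs
give byte-identical output, which the test suite pins with a golden
file. Each displayable crosslink becomes a `distance` object between
`/object//chain/resi/CA` selections with its label hidden — the
script-level equivalent of a dashed line between C$\alpha$ atoms — named
`xl_{res1}_{chain1}_{res2}_{chain2}` so single links can be toggled from
the PyMOL side. Mono-links become spheres at their C$\alpha$. Links
filtered out are omitted entirely rather than emitted hidden; missing
links appear as comments only, so every selection the script contains is
guaranteed to resolve. Characters outside `[A-Za-z0-9_]` in chain IDs
are sanitized to `_` in object names (with a warning), keeping the names
legal while the atom selections still use the original identifiers.

## The fixture generator, and what passing tests mean

`make_linear_ca_trace()` writes chains as straight C$\alpha$ lines:
residue $i$ of chain $k$ sits at
$((i-1)\,s,\ (k-1)\,c,\ 0)$ for spacing $s$ and chain offset $c$, so
every inter-residue distance has the closed form
$\sqrt{((i-j)s)^2 + ((k-m)c)^2}$. Spacings are chosen exactly
representable at the 3-decimal precision of coordinate fields, so the
closed form is exact to parsing precision; mapped distances are required
to agree within $10^{-6}$ Å. Omitted residues and C$\alpha$-less
residues are injectable to create missing-link cases.

The generator emulates the *bookkeeping* of real structures — chains,
author numbering, unresolved residues, missing atoms — with deliberately
unrealistic geometry (no folding, no side chains, no contacts). Passing
the oracle-equivalence suite (100 random traces, plus randomized
property tests) therefore demonstrates that parsing, indexing, distance
computation, classification, counting, filtering, and script emission
are correct; it says nothing about whether a particular biological
structure satisfies a particular dataset. The policy-specific behaviors
(altlocs, insertion codes, MSE, ions, multi-model files) are covered by
small hand-written PDB/mmCIF fixtures instead. Default test problem
sizes — chains of 3–20 residues, 10–25 links per dataset, 100 random
fixtures in the equivalence sweep, a ~750-residue three-chain assembly
with 450 entries in the acceptance run — keep the whole suite within a
couple of minutes on one CPU while exercising every code path; sizes are
set in one place (the test helpers and `scripts/acceptance.R`) and scale
up freely.

In the acceptance study the crosslink list is 60% short-range
intra-chain contacts (sequence separation ≤ 12, the regime a
lysine-reactive crosslinker actually samples inside a folded monomer)
and 40% uniform long-range/inter-chain pairs, with 15% of referenced
positions beyond the modeled residues; this populates both sides of the
threshold and the missing class at realistic proportions rather than
letting an extended trace make nearly everything violated.

## Known limitations

* Euclidean distances only; no SASD, no side-chain-aware distances.
* Homooligomer ambiguity is the user's to resolve: the tool maps exactly
  the chain pairs written in the file. To survey all candidate subunit
  pairs, list each explicitly — the mapper will happily classify all of
  them side by side.
* No parsing of vendor XL-MS result formats (pLink, xiSEARCH, MeroX,
  mzIdentML); convert to the pipe dialect upstream.
* The published SurA (1M5Y) and OCCM (5V8F) benchmark tallies can be
  re-verified only when those third-party structures and example lists
  are downloaded and placed under `inst/extdata/benchmarks/`; they are
  not redistributed with the package, and the SurA violated-count
  additionally depends on a loop-completed model that was never
  deposited.
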