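---
title: "molkit: data model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molkit: data model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molkit)
```

molkit is a toolkit for analyses that mix molecular structures, sequence
data and electron-density maps. This vignette is the package's own
account of the models and procedures it implements, the parameters that
matter, and the design decisions taken where more than one reasonable
choice existed.

## The handle/view model

A structure is owned by an `EntityHandle`: a tree of chains, residues
and atoms plus a bond list, stored internally as flat tables keyed by
stable integer ids. The handle has *reference semantics* (its state
lives in an environment), which is deliberate: every `EntityView` — a
subset of atoms, their parent residues/chains, and the bonds whose two
endpoints are both included — reads positions and generic properties
*through* the handle, so coordinate edits, trajectory frames and
annotations are immediately visible in every derived view. Views nest
(a selection of a selection is again a view of the same handle), and
chained selections are equivalent to the conjunction of their queries.

Structural edits (atom deletion) invalidate views. Rather than trying
to remap subsets, the handle carries a generation counter; a view
created before the edit raises an error on its next access. This makes
staleness loud instead of silently wrong.

Generic properties are typed key–value annotations (`text`, `real`,
`integer`, `boolean`) attachable at every level. Retrieving a key with
the wrong asserted type, or an absent key without a default, is an
error — annotations feed quantitative pipelines, so silent coercion is
a bug factory. Keys are case sensitive.

```{r}
h <- makePolyalaHelix(6)
ruleBasedProcess(h)
v <- select(h, "aname=CA")
setPositions(h, positions(h) + 1)   # views see the move
head(positions(v), 2)
```

## The selection language

Queries are Boolean combinations of property predicates, with
precedence `not` > `and` > `or`, parentheses, inclusive numeric ranges
(`rnum=10:20`), comma lists (disjunction), and a proximity operator
`R <> [subquery]` or `R <> {x,y,z}` selecting atoms within `R` Å of any
atom matched by the sub-query (or of a literal point). The grammar is
LL(1) and documented as EBNF in `?select`. Dialect decisions, made once
and tested against a naive per-atom oracle:

* Built-in property ids: `aname, rname, rnum, cname, ele, occ, abfac,
  ishetatm, charge`. Relational operators require numeric properties;
  strings compare case-sensitively with `=`/`!=` only.
* Generic properties are addressed with a level prefix (`ga:`, `gr:`,
  `gc:`). An element lacking the key *does not match* rather than
  erroring — this keeps evaluation total over heterogeneous structures
  while leaving annotations queryable.
* `within` measures atom–atom distance and promotes matched atoms only;
  residue-level predicates (e.g. `rname`) match all atoms of matching
  residues because every atom carries its residue's properties. We kept
  strict atom-set semantics (no whole-residue promotion when atom and
  residue predicates mix); a residue-complete view is one further
  selection away.

The evaluator materialises a per-atom property table and reduces the
AST to logical vectors; `within` uses a uniform spatial grid with cell
size equal to the radius, so only the 27 neighbouring cells are
scanned. The contract is exhaustive equality with the brute-force
distance scan, which is what the test suite asserts (500 random ASTs
against a naive filter, plus De Morgan, idempotence and
chaining–conjunction identities).

## Connectivity

Two processors, mirroring the two situations structures arrive in:

* **Rule-based** (`ruleBasedProcess`): intra-residue bonds come from a
  compound library (JSON; bundled entries for the 20 standard amino
  acids, 8 standard (deoxy)ribonucleotides, HOH and HEM, heavy-atom
  topology plus OXT). Inter-residue peptide (C–N) and phosphodiester
  (O3'–P) bonds are created between *consecutive* residues of a chain
  when the distance is ≤ 2.5 Å — the distance gate keeps chain breaks
  from being bridged. Unknown residues/atoms and missing atoms are
  reported as diagnostics; `strict = TRUE` turns unknowns into errors,
  the recommended mode for automated pipelines. The operation is
  idempotent.
* **Heuristic** (`heuristicProcess`): standard residues are bonded by
  table lookup; anything else falls back to a distance rule: bond iff
  `d ≤ r_cov(a) + r_cov(b) + 0.4 Å`, with covalent radii H 0.31, C
  0.77, N 0.71, O 0.66, S 1.05, P 1.07, Fe 1.32, default 1.5 Å, and
  hydrogens limited to one bond (their nearest heavy atom). The radii
  and 0.4 Å tolerance are conventional values; they are package
  constants, not tuned quantities. On complete, ideally built polymers
  the two processors produce identical bond sets (a tested invariant).

## Structure and trajectory I/O

PDB import parses ATOM/HETATM at the v3.3 fixed columns, first MODEL
only, alternate locations resolved to the highest-occupancy conformer
(ties to the lowest altloc letter). An `IOProfile` bundles the
behavioural flags: `strict` (malformed records abort with their line
number — the default, because a nonconforming file in a pipeline is a
latent error), `faultTolerant` (skip and log), `readHetatms`, and which
connectivity processor runs after import. Import-time connectivity
diagnostics are informational; strict *format* checking and strict
*connectivity* checking are deliberately separate concerns, so a strict
profile still reads chemistry the library does not know.

DCD trajectories (CHARMM dialect: 4-byte Fortran record markers, CORD
magic, optional unit-cell records honoured and skipped, float32
coordinates, both endiannesses) load either fully into memory or
*lazily*: the reader computes per-frame byte offsets and fetches frames
on demand through an LRU cache (default 16 frames, configurable), so
trajectories larger than memory stream cleanly. The two modes are
bit-identical on every frame query — a tested observational-equivalence
contract, along with an instrumented fetch counter that verifies the
cache bound. Frame indices are 1-based, as is everything user-facing in
this package: R's native convention wins over the 0-based internal
convention common in C/Python toolkits.

## Sequences, gap lists and attachment

A `SequenceHandle` stores a one-letter-code string with `-` gaps
(`.` normalised on input, case folded) plus a run-length **gap list**.
Mapping an alignment position to a residue index subtracts the number
of gaps before that position; traversing the gap list instead of the
string makes the cost proportional to the number of gap *runs*, which
is usually far smaller than the sequence length. Both mapping
directions expose a `counted = TRUE` mode returning the number of
gap-list entries inspected, so the efficiency claim is a testable bound
rather than folklore.

A structure is linked to its sequence by attaching an `EntityView` with
one residue per non-gap character; one-letter codes are validated
position-wise, with `X` matching anything in either direction (strict
otherwise — a mismatch names the offending position). Alignment
editing is column-wise (insert/remove gap columns; removing a column
containing residues requires `force = TRUE`), preserving equal lengths
and gap-list consistency under arbitrary edit sequences.

File formats: FASTA (read/write, via Biostrings), ClustalW (read;
blocks concatenated in first-block order, ragged blocks rejected) and
PIR (read/write; the two-letter header type is preserved on round
trip).

## Pairwise alignment and conservation

Global (Needleman–Wunsch) and local (Smith–Waterman) alignment use the
three-matrix affine-gap (Gotoh) recursion; a gap of length L costs
`gapOpen + (L−1)·gapExtend`. Defaults are BLOSUM62 (from Biostrings)
with −10/−1 — the common practical choice; the paper-free parameters
are package defaults, not claims. Traceback ties prefer diagonal, then
the gap consuming the first sequence, making emitted alignments
deterministic; every emitted alignment re-scores to the reported
optimum (tested). Local alignment floors the match state at zero and
reports the aligned region's start offsets through the emitted
sequences' offsets; disjoint alphabets yield score 0 and an empty
alignment. The test oracle enumerates *all* alignments recursively on
short sequences (≤ 7 residues globally, ≤ 6 locally), so the DP is
checked against the definition of optimality, not against another DP.

Percent identity divides matching columns by *aligned (both non-gap)
columns* — the most common convention.

Column conservation is the mean over unordered sequence pairs of a
residue-similarity in [0, 1]; gap pairs contribute 0. As the
physico-chemical similarity we use per-pair-normalised BLOSUM62:
`sim(a,b) = clip((B(a,b) − Bmin) / (min(B(a,a), B(b,b)) − Bmin), 0, 1)`.
Global min–max scaling cannot make every identical column score exactly
1 (BLOSUM62 diagonals range 4–11), so the per-pair denominator was
chosen to pin `sim(a,a) = 1` — the anchor "1 iff all residues identical
and non-gap" then holds exactly. The matrix is pluggable
(`similarity =`) for users with a calibrated physico-chemical scale.

## Superposition and annotation transfer

`superpose` is the Kabsch algorithm: SVD of the centred covariance
matrix, with the smallest singular vector's sign flipped when the
determinant would be −1, so the result is always a proper rotation.
**Correspondence is positional** — the i-th atom of the mobile view
pairs with the i-th of the reference, with no name matching. This is
stated loudly because it silently matters: the user chooses equivalent
atom sets via selections (CA traces, ligand atoms, binding-site side
chains — any equally sized views work). Near-collinear references are
flagged with a warning (smallest singular value < 1e−8 of the largest).

`transferAnnotation` composes the pieces: select source residues (e.g.
a `within` query around a ligand), map residue index → alignment column
→ target residue through the gap lists, and set a boolean generic
property on the aligned target residues, skipping columns that are gaps
in the target. The annotated residues are immediately selectable
(`gr:key=true`).

## Images and density maps

An `ImageHandle` wraps a 1/2/3-D buffer with per-axis sampling (Å per
pixel), a spatial origin (first voxel *centre*; 0-based voxel offsets
times sampling — the corner convention), and an active domain flag.
`fftImage` toggles spatial ↔ frequency; the convention is **forward
unscaled, inverse 1/N**, so a round trip is the identity and Parseval
reads `Σ|x|² = Σ|X|²/N`. Transforming a real spatial image marks the
result conjugate-symmetric; transforming that back yields a real image,
while a frequency buffer without the symmetry transforms to a complex
spatial image. Filters (Gaussian blur by `exp(−2π²σ²|k|²)`, which
preserves the DC term and hence the mean; ideal low/high pass at
`|k| = 1/cutoff`) operate in frequency space and return spatial images.

Structure → density places a Gaussian of width σ (default 1.5 Å,
uniform unit amplitudes; optionally element-weighted by atomic number)
at every atom and sums. The Gaussian is separable, so each atom
contributes an outer product of per-axis profiles — this is what makes
the exhaustive all-voxels × all-atoms oracle affordable to check
against. Contributions are truncated at 5σ per atom: truncating at 4σ
leaves relative residuals of `exp(−8) ≈ 3.4e−4`, larger than the 1e−4
agreement the generator is tested to, while 5σ puts truncation
(≈ 3.7e−6) comfortably below it. The computation is real-space only; a
reciprocal-space route is out of scope.

Real-space correlation is the Pearson coefficient over voxels —
invariant under positive affine rescaling of either map, 1 for a map
against itself, −1 against its negation. Maps on different grids are
brought together by trilinear resampling. `scoreFragments` evaluates
each candidate fragment's density on the experimental map's grid and
correlates over the fragment's **footprint** (voxels within 4σ of any
fragment atom, a geometric mask): correlating over the full box would
let empty volume dominate the score. Whether a masked footprint or the
full box is "right" is genuinely open; the footprint is the default and
the `region` argument exposes the choice.

MRC/CCP4 I/O supports mode-2 (float32) maps, honours the
MAPC/MAPR/MAPS axis permutation on read (data are returned in canonical
x,y,z order), derives sampling from cell/grid, uses the MRC2014 ORIGIN
field and falls back to NXSTART-based origins when ORIGIN is zero.
Values are stored as float32, so a first round trip is exact to
float32 resolution and every subsequent one is bit-exact.

## Synthetic fixtures and what they do (not) show

All tests run on fixtures generated in code:

* `makePolyalaHelix` builds an ideal poly-alanine α-helix from standard
  backbone internal coordinates (φ = −57°, ψ = −47°, ω = 180°; N–CA
  1.458, CA–C 1.525, C–N 1.329, C=O 1.231, CA–CB 1.53 Å), giving
  3.80 Å CA–CA steps and 1.33 Å peptide links — ideal input for
  connectivity, superposition and density tests.
* `makePointCloud` produces random entities with mixed chains,
  residues, elements, occupancies and HETATM flags in a 20 Å box —
  the workhorse for query-language and proximity property tests.
* `makeTrajectory` writes DCD files with analytic (sinusoidal rigid
  translation) or seeded Brownian motion, so trajectory readers can be
  checked against closed forms.

These fixtures are deterministic per seed and exercise the *contracts*
(parsers, mappings, optimality, round trips). They do not emulate the
messiness of real data — heterogeneous occupancy/altloc patterns,
chain breaks, non-standard residues at scale, experimental map noise
spectra — so green tests certify the algorithms and formats, not
robustness to every archive file. The one check requiring real data
(the DENV2/DENV3 methyltransferase identity example) runs only when the
two wwPDB entries are supplied locally, and fails visibly otherwise
rather than being skipped.

Problem sizes used by the test suite and the acceptance script (500
random queries on ≤ 300-atom entities, 1000 gapped strings, 200
enumeration-checked alignments, 100 superposition clouds, 16³–32³
maps) were chosen so the whole suite completes in about a minute and a
half on one core while still exercising each property over a broad
random family.

## Known limitations

* mmCIF, multi-MODEL ensembles, CRD/PQR and image formats other than
  MRC/CCP4 are not read; DCD writing exists for fixture generation.
* The compound library ships common residues only; full chemical
  component dictionary coverage is a data, not a code, question.
* No bond orders/aromaticity perception, no protonation, no molecular
  surfaces, no multiple sequence alignment construction, no
  iterative-outlier superposition or TM-score/lDDT-style scores.
* The conservation similarity matrix is a documented BLOSUM62-derived
  stand-in for a calibrated physico-chemical scale (and is pluggable).
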