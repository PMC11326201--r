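---
title: "Methods: variant-to-structure analysis at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant-to-structure analysis at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vustruct)
```

This vignette is the package's own account of its models, algorithms and
design choices: what is computed, under which assumptions, which knobs
matter, and what the synthetic test data can and cannot tell you about
behaviour on real cases.

## The problem

A clinical case presents a handful of missense variants of unknown
significance (VUS). Sequence-level scores compress the biology into one
number; placing a variant in its 3D protein context instead supports
mechanistic hypotheses — destabilisation, interface disruption, spatial
co-location with known pathogenic sites. Doing that reproducibly requires
a chain of unglamorous but error-prone steps: genome-to-protein
consequence calling, transcript/protein record reconciliation, structure
selection, residue mapping, spatial statistics, job orchestration and
reporting. This package implements that chain as a library of small,
separately tested functions, with deterministic stubs standing in for
licensed external calculators, so the whole pipeline runs and is verified
at desk scale.

## Consequence calling

`call_consequence()` handles exactly one class of event: single-nucleotide
substitutions. A transcript model carries its CDS exons as genomic
intervals in transcript order together with forward-strand exon sequences;
the constructor enforces the translation invariant (spliced CDS,
reverse-complemented for minus-strand models, translates to the stored
protein plus one terminal stop), so a corrupt catalog fails at load time
rather than at call time. The caller locates the variant in an exon,
computes the 0-based CDS offset (counting from the 3′-most genomic base
for minus-strand models, with alleles complemented), mutates the one
affected codon and translates both codons with the standard nuclear code.
Positions outside the CDS are `non_coding`; indels and other non-1:1
events are `other` and never advance further. A mismatch between the VCF
reference allele and the catalog base is a data-integrity error — it
signals a stale catalog, which is exactly the situation the reconciliation
phase exists to surface.

Two deliberate consequences of the plain-codon-table choice: a variant in
the initiator codon (e.g. ATG→TTG) is reported as the substitution M1L,
not as an "alternative initiator" synonym; and selenocysteine
recoding is out of scope. The caller is validated against an independent
oracle that rebuilds the *entire* mutated spliced CDS and translates it
with Biostrings; agreement is exact over 1,000 random SNVs per run, on
both strands, and a mirror-image property test (reverse-complement the
chromosome, flip the strand) guards the strand arithmetic specifically.

Isoform expansion maps a change stated on one protein onto a gene's other
curated isoforms by ordinal position: the reference residue is re-checked
at the same position on each isoform, and isoforms that are too short or
carry a different residue are dropped (with a warning for the mismatch
case). This is conservative — a curated alignment between isoforms could
rescue more of them — but it is exact, cheap, and never silently maps a
variant onto the wrong residue.

## Cross-reference reconciliation

Transcript databases and curated protein databases drift against each
other, so every case is gated on a four-way classification per transcript:
`PERFECT` (identical sequences), `SEQ_MISMATCH_SAME_LEN` (first differing
position reported), `LEN_MISMATCH` (both lengths reported), and
`MISSING_XREF` (no curated counterpart). Any non-`PERFECT` record halts
the case. HALT is a case-level status plus a machine-readable report —
not a process abort — so it is testable, and a `force` flag lets the
clean subset proceed while the report is still emitted. Whether a real
deployment should run the clean subset or stop everything is a policy
question; exposing both behaviours behind one flag keeps the library
neutral. Category counts in any real snapshot are database-version
artifacts, so the package treats the categories as definitions and tests
against planted fixtures whose counts are exact by construction.

## Structure selection

Residue mapping prefers the trivial case — the structure's sequence is an
exact substring of the transcript protein, so positions map by offset —
and otherwise computes a global Needleman–Wunsch alignment with match +1,
mismatch −1, linear gap −2, mapping only aligned *and identical* positions
of resolved residues. The traceback tie-break is fixed (diagonal, then gap
in the structure sequence, then gap in the transcript), which makes
residue maps reproducible run to run; candidates whose identity (identical
aligned positions over structure length) falls below 40% are discarded as
unmappable. The aligner is implemented in the package precisely because
the tie-break is part of the contract; tests cross-check its optimal
score against both a memoised recursive oracle and an independent aligner.

Selection is a greedy procedure over a linear score (weights in the
README; variant coverage dominates at weight 4 because a structure that
does not contain the variant is useless for per-variant calculations).
Redundancy is covered-set Jaccard similarity above 0.9 *within a method
class* — a crystal structure and a predicted model of the same region are
not redundant, two near-identical crystal structures are. Ties break
experimental-before-predicted, then lower resolution, then lexicographic
id, so selection is a pure function of the candidate set. For canonical
transcripts an AlphaFold model is always added if one is eligible; when
the guarantee conflicts with coverage (the AlphaFold model does not cover
the variant but something else does), coverage wins — the invariant that
every chosen non-flagged candidate covers the variant is kept. When
nothing covers the variant, all candidates are retained but flagged
"context-only". There is no default cap on the number of structures; the
`max_structures` knob exists for callers that want one.

## Spatial pathogenicity score

For a query residue $q$, pathogenic-labeled sites $P$ and benign-labeled
sites $B$ on one structure (Cα positions, distances in Å):

$$\mathrm{score}(q) = \frac{1}{|P|}\sum_{p \in P} K(d(q,p))
                    - \frac{1}{|B|}\sum_{b \in B} K(d(q,b))$$

The default kernel $K(d) = 1/(1+d)$ equals 1 at contact and decays slowly,
so every labeled site contributes; a Gaussian ($\sigma = 8$ Å, roughly two
residue shells) and a hard shell ($d \le 10$ Å) are available where a
sharper locality notion is wanted. The score is antisymmetric under label
swap and invariant under rigid-body motion (tested to $10^{-9}$).
Homomultimers are handled by taking, per labeled site, the minimum
distance over the chains a position maps to.

Significance uses a label-permutation null: the pathogenic label set is
re-drawn uniformly (size $|P|$) from the observed sites $P \cup B$ and the
score recomputed, giving $p = (1 + \#\{\mathrm{null} \ge
\mathrm{obs}\})/(n_{\mathrm{perm}}+1)$, never below
$1/(n_{\mathrm{perm}}+1)$. Permuting labels over *observed* sites — rather
than placing sites anywhere on the structure — conditions on the observed
site geometry, is exactly enumerable on small sets (the test suite
enumerates all $\binom{|P \cup B|}{|P|}$ relabelings for pools up to 8 and
checks the sampled p within 3 Monte-Carlo standard errors), and makes the
null calibration property meaningful: when $P$ genuinely is a uniform draw
from the pool, the rejection rate at $\alpha = 0.05$ lands in
$[0.03, 0.07]$ over 2,000 simulated cases. Tie comparison uses a
$10^{-9}$ tolerance so floating-point jitter from coordinate transforms
cannot flip a tied permutation. The alternative null (uniform placement
over all mapped residues) is what the clustering diagnostic uses.

The Ripley-style diagnostic counts unordered close pairs within each
radius among a site set and compares against a 95% envelope from uniform
same-size draws over all residues of the structure. The default radii
(4–24 Å) span nearest-neighbour contact to domain scale on the toy
structures. Counts above the upper envelope flag clustering; under
complete spatial randomness the observed curve sits inside the envelope at
≈95% of radii by construction, and the acceptance suite verifies ≥90%
average coverage over 200 simulations.

## Work planning, status protocol, stubs

Planning is a pure function from (case id, variants with selections,
registered calculators) to a job table: one job per variant × chosen
structure × structural calculator plus one digenic job per case, ordered
variant-first, then selection order, then calculator name. Nothing
scheduler-specific enters the plan. Work directories follow
`VUStruct/<case>_<guid>/<transcript>/<source_structureid>/<calc>/work`
with a sibling `status/`; the digenic job uses the placeholder tokens
`case/all`. The status protocol is one flat file per transition
(`01_planned` … `04_complete`/`04_failed`) with legality enforced at write
time, so a mid-run snapshot can never show an illegal history; aggregation
reads only the filesystem, and unreadable status directories are counted
as `unknown` rather than guessed.

The ΔΔG relax cache keys on (coordinate-file content hash, chain,
protocol): the first job per key carries `needs_relax = true`, later jobs
reuse the relaxed structure. A corrupt cache entry degrades to a miss with
a warning — a cache must never turn into a correctness hazard.

Stub executors stand in for the licensed or heavyweight external
calculators (Rosetta ΔΔG, interface-disruption and PTM predictors, trained
digenic models). Each stub writes a result record whose metric is a
deterministic keyed hash of (structure id, mutation, calculator, stub
seed) in a plausible range — e.g. ΔΔG in [−3, 9] REU — so the full
planning/execution/collection/reporting chain is exercised with
reproducible, byte-identical outputs. Two calculations are real, not
stubbed: spatial-proximity jobs run `permutation_pvalue()` on the actual
coordinates, and digenic jobs run the pair enumeration with the
(pluggable, contract-checked) predictor.

## Reporting

Metric collection is append-only over complete jobs; ranges are (min, max)
per variant × metric over all structures and isoforms, with min = max
exactly when one row contributed. Precomputed score tables are exact-key
lookups — per-variant sources on (accession, position, alternate residue),
per-site sources on (accession, position) — and missing keys stay missing;
no interpolation, ever. Rendering is a pure function of its inputs:
re-rendering identical inputs is byte-identical, and the generation
timestamp lives in a separate metadata file. The summary spreadsheet
carries one row per missense variant with identity, inheritance, metric
ranges, precomputed scores, a digenic flag and an empty recommendation
column for the clinician.

## The synthetic data, and what passing tests do not show

`make_toy_transcriptome()` emulates the external databases the real
pipeline queries: random multi-exon CDSs (default 30–60 aa proteins, 1–3
exons, both strands equally likely) placed on private chromosome slices
with 10–30 nt introns, optional frame-preserving exon-skipping "-2"
isoforms, and cross-reference entries planted in the four categories at
exact largest-remainder counts. Planted categories go to canonical
transcripts; isoform entries are always `PERFECT` (a discrepant canonical
record already halts the case, so discrepant isoforms would add test
surface without new behaviour). `make_toy_structure()` writes ideal Cα
traces — an α-helix with 1.5 Å rise, 100° turn and 2.3 Å radius, or a
3.8 Å-spaced line — which are parseable, geometrically controlled, and
nothing like a folded protein. Labeled variant tables plant a pathogenic
cluster inside a window (default 8 sites each; window = protein length
recovers the uniform regime) disjoint from the query and from each other.

Consequently, passing tests demonstrate correctness of the *computations*
— coordinate arithmetic, alignment, statistics, orchestration — under
controlled geometry and clean catalogs. They do not demonstrate that the
stub energies resemble Rosetta, that the toy geometry resembles folded
domains, that real ClinVar/gnomAD label sets behave like planted clusters,
or that the published spatial score's ROC performance is reproduced; all
of that requires the real external calculators and databases and is
explicitly out of scope.

## Numerical and design choices

* Problem sizes in the test and acceptance runs — 1,000 oracle SNVs,
  pools to 8 sites with `n_perm` 10,000, 2,000 calibration cases at
  `n_perm` 199, 200 envelope simulations at `n_perm` 999 — were chosen as
  the smallest sizes at which the checked properties are statistically
  sharp (3 Monte-Carlo SEs, a [0.03, 0.07] calibration band), and run in
  about a minute in total.
* `n_perm = 199` suffices for calibration at α = 0.05 because the
  permutation p-value is then a multiple of 1/200 and the rejection event
  is exactly the top decile rank; report-quality p-values should use 999+.
* Coordinates are 1-based throughout the genomic and protein interfaces;
  CDS offsets are 0-based internally. Structure residue numbering follows
  the coordinate file's author numbering; insertion codes are out of
  scope, and fixtures use plain integers.
* Multi-allelic VCF rows are split one alt at a time before calling.
* GUIDs are RFC-4122 v4 from the session RNG: reproducible under a seeded
  caller (tests pin them), unique in normal use.
* The stub hash maps the first 28 bits of a 128-bit content hash to
  [0, 1); determinism across platforms comes from hashing strings, not
  floats.

## Known limitations

Single-nucleotide substitutions only (no indels, splice-region or UTR
effects); one structural conformer per candidate (no dynamics); ordinal
isoform position mapping (no inter-isoform alignment); no insertion-code
or altloc handling in coordinates; the digenic predictor and the
energy/interface/PTM calculators are deterministic stand-ins whose values
carry no biological meaning.
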