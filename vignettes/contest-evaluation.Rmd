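---
title: "Evaluating small-molecule identification contests with idrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating small-molecule identification contests with idrank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrank)
```

## The evaluation problem

In identification contests for tandem mass spectrometry, organisers release
spectra of unknown compounds ("challenges") and participants return, per
challenge, an ordered candidate list with a numeric score per candidate —
molecular formulas in the formula categories (1 and 3), structures in the
structure categories (2 and 4). The organisers' task afterwards is purely
evaluative: decide which candidates are correct, quantify how well each
scoring scheme placed the correct answer, declare winners, and summarise.
`idrank` implements that evaluation pipeline. It deliberately contains no
identification method: submissions are inputs, not outputs.

## Correctness decisions

**Formulas.** Participants spell formulas freely ("H12C6O6", "CH3CH3"), so
string equality is decided on a canonical form. `parse_formula()` tokenizes
element symbols with optional counts, sums repeated tokens, and prints the
result in Hill order (C, then H, then other elements alphabetically; fully
alphabetical without carbon) — the de-facto display convention, chosen here
as the canonical one. Charged species, adducts (`[M+H]+`) and isotope
labels are rejected rather than guessed at: the ground truth is a neutral
molecular formula, and inferring neutral species from adduct notation is an
identification step, out of scope by design.

**Structures.** Many SMILES denote one molecule, so structure identity runs
through the standard InChI Key (computed with OpenBabel, auto-detecting
InChI input by its `InChI=` prefix). A candidate is correct when the first
key block — 14 letters encoding connectivity — equals the solution's.
Stereochemistry, which tandem MS generally cannot determine, lives in the
second block and is therefore ignored; stereoisomers of the solution count
as correct, positional isomers do not. Distinct molecules can in principle
share a first block; this is rare enough that collisions are accepted as
matches. When a submission carries several stereoisomers of the solution,
the highest-scoring one is the reference for ranking; the others are
ordinary list members and fall into whatever score stratum they occupy.
Unparsable candidate rows are kept (a list's length is part of its
selectivity), warned about, and can never match.

## The metric suite

Relative to the correct candidate's score, a submission partitions into
better/equal/worse counts `(BC, EC, WC)` with `TC = BC + EC + WC`; `EC`
includes the correct candidate, so `EC = 1` means a unique score. Score
comparison is exact floating-point equality — ties in practice come from
identically reported scores, and an epsilon would invent ties that
participants did not submit.

* `worst_case_rank = BC + EC` assumes the correct candidate loses every
  tie. It is pessimistic but realistic: every tied candidate would need to
  be examined in a real identification effort.
* `relative_rank` (RRP) rescales the tie-aware position into [0, 1], 1 being
  best: `RRP = (1 + (WC - BC)/(TC - 1))/2`. It is undefined when the correct
  answer is absent or `TC < 2`, and equals 0.5 under a uniform tie. The
  closed form is fixed by four boundary cases the package tests explicitly:
  `(TC=6, BC=4, WC=1) → 0.20`, `(TC=1423, BC=21, EC=24, WC=1378) → 0.98`,
  `(TC=1356, BC=0, WC=1355) → 1.00`, and the uniform tie → 0.5.
* `normalize_scores` divides by the score total, making differently
  calibrated scoring schemes comparable; `weighted_rrp` then subtracts from
  1 the normalized mass strictly above the correct candidate (`wBC`) and the
  mass tied with it excluding the correct candidate itself (`wEC`). Note the
  deliberate asymmetry with the rank: the rank's `EC` includes the correct
  candidate (a unique top hit has rank `0 + 1 = 1`) while `wEC` excludes it
  (a unique top hit keeps `wRRP = 1`). Negative scores are rejected rather
  than shifted — normalization has no meaning for mixed signs and any shift
  rule would silently change every weight.

## Similarity profiles

To assess how close a submission came when it missed (or what surrounded the
correct answer when it hit), every candidate of a structure submission is
fingerprinted and compared with the solution by the Tanimoto coefficient
`TS = C/(A + B - C)` over set bits. Two empty fingerprints are defined to
have `TS = 0` and warn — a conservative choice that flags degenerate
molecules instead of calling them identical. Per challenge the package emits
plot-ready tables (candidate position in the score-sorted list, TS, correct
and most-similar markers, with a log-scale hint for the candidate axis) and
an optional ggplot renderer; the tabular data, not the rendering, are the
contract.

Fingerprints are backend-pluggable behind one function contract
(`text → fingerprint_bitset`, fixed width, deterministic):

* `fp2_backend()` — OpenBabel's path-based 1024-bit FP2, the default, chosen
  for accessibility from R.
* `cdk_fingerprint_backend()` — a CDK-compatible hashed path fingerprint,
  implemented natively: all simple paths of up to 7 atoms in the
  hydrogen-suppressed graph are encoded as alternating element and bond
  symbols (`-`, `=`, `#`, aromatic `:`), each path string canonicalized to
  the lexicographically larger of itself and its character-wise reverse,
  hashed with the 31-base Java string hash, and mapped to one of 1024 bits
  by the Java LCG (`Random(hash).nextInt(1024)`); bit positions are reported
  1-based. Aromaticity comes from OpenBabel's mol2 perception, so carbonyl
  rings (e.g. the central anthraquinone ring) are correctly non-aromatic.
  This adapter reproduces the reference worked values exactly — ethanol
  `{301, 638, 742, 743, 930}` vs ethane `{638, 743}` (TS = 0.4), and
  TS = 0.842 for 1- vs 2-aminoanthraquinone — and exists for cross-checking
  those published numbers; absolute TS values are always backend-specific
  and should only be compared within one backend.

## Winners and summary tables

A challenge's winners are all eligible participants attaining the minimal
worst-case rank among *original* submissions containing the correct answer;
post-deadline resubmissions (contests recalibrate challenges occasionally)
appear in statistics but never win, and organiser-affiliated "internal"
participants are tabulated but ineligible. The category winner(s) have the
most challenge wins, ties returned as sets.

Summary rows aggregate with conventions that the package pins by test:
`avg_rank`, `avg_BC`, `avg_wRRP` and the average normalized score run over
submissions that contain the correct answer (nine correct submissions at
ranks `{1×8, 2}` print as 1.11); `avg_RRP` runs over submissions where the
RRP is defined; `avg_TC` runs over **all** submissions of the group. Whether
`avg_TC` should instead skip incorrect submissions is not decidable from the
reference tables alone; it is kept at "all submissions" as the more
informative convention. Undefined averages print as a dash. The
"resubmitted-merged" table kind substitutes the resubmission where one
exists and keeps the original elsewhere. A participant who skipped a
challenge contributes no record at all — an abstention is not a
zero-candidate submission.

Missing entirely from the aggregation is any significance testing between
participants: with a handful of participants per category, averages are
dominated by individual submissions, and the records table is the honest
output.

## File formats and the CLI

All inputs and outputs are tab-separated UTF-8 with a header row: a
solutions table (`challenge, categories, formula, smiles_or_inchi, name`;
the declared formula is cross-validated against the structure's InChI
formula layer at load, and a mismatch is a hard error), one submission file
per (participant, category, challenge) named
`<participant>_cat<k>_chal<id>[_resub].tsv` with columns
`candidate, score[, name]`, and a small YAML config listing participants
with external/internal flags. Scores are required; a rank-only file is
converted to descending pseudo-scores with a loud notice, since ranks cannot
express ties. Error messages from the loaders name the file and line.
Records serialize with `%.17g` precision so a read-back reproduces every
metric bit for bit.

The `evaluate`, `summarize`, `plot` and `synth` subcommands of `cli_main()`
(and the installed `inst/cli/idrank.R` wrapper) chain these pieces; exit
codes are 0 (success), 1 (usage error), 2 (data error), and warnings —
absent correct answers, unparsable rows — never change the exit code.

## The synthetic-contest generator

Real contest submissions are not redistributable, so the package tests
itself on synthetic contests whose ground truth is known by construction.
`submission_spec()` fixes the target partition `(TC, BC, EC)`, the score
distribution (`uniform`, `exponential` for heavily skewed schemes, or
`constant` for the all-tied edge case), an `include_correct` switch, a
stereoisomer-duplicate count and a seed. `generate_submission()` draws
distinct descending scores, places the correct payload at position
`BC + 1`, duplicates its score across `EC - 1` neighbours — ties are always
constructed by explicit score duplication, never left to distribution
coincidence, and a spec with `EC > 1` under a continuous distribution must
say `force_ties = TRUE` — and fills the rest with decoys: procedurally
generated CHNO formulas distinct from the solution, or structures drawn from
a bundled list of ~55 valid SMILES (common metabolites and small aromatics,
including the aminoanthraquinone isomer pair) whose skeleton blocks all
differ from each other. Stereoisomer duplicates are available for solutions
whose bundled entry lists stereo variants (same skeleton block, distinct
full keys) and are placed strictly below the correct candidate's score so
the intended partition survives. `generate_contest()` writes a complete
contest directory plus a manifest of intended partitions; identical seeds
yield byte-identical trees.

What the generator emulates is the *combinatorics* of contest submissions —
partitions, ties, duplicates, abstentions, absent answers — under clean
score distributions. It does not emulate realistic scoring-function
behaviour, correlated errors between participants, or mass-spectral data;
green tests certify the evaluation machinery, not any identification
performance on real spectra.

## Numerical and scale choices

Default problem sizes keep the full suite fast: property checks run 1000
random score vectors (length ≤ 50) against a stable-sort rank oracle, 1000
seeded generator specs round-trip their partitions exactly, and the largest
worked partition (TC = 1423) is exercised through the full pipeline in
seconds. Normalized scores must sum to 1 within 1e-9; the worst-case rank is
asserted to lie in `[1, TC]` and `BC + EC + WC = TC` on every evaluation.
Undefined metric values are `NA` throughout (an undefined RRP is a value,
not an error), and display rounding (2 decimals for rank-scale numbers, 3
for unit-interval metrics) happens only in `format_summary()` — underlying
records keep full precision.

## Known limitations

* Structure handling is delegated to OpenBabel; molecules OpenBabel cannot
  parse are flagged rather than recovered, and InChI-related edge cases
  (exotic tautomers, organometallics) follow its behaviour.
* The CDK-compatible fingerprint implements benzenoid aromaticity as
  perceived by OpenBabel's mol2 writer; five-membered heteroaromatic
  perception may differ from other toolkits, which changes absolute TS
  values for such molecules (within-backend comparisons remain valid).
* Formula parsing excludes isotopologue notation, the deuterium shorthand
  `D`, and polymer/repeat notation.
* Stereoisomer-duplicate generation requires bundled stereo variants; the
  generator cannot invent stereoisomers for arbitrary molecules.
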