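# idrank

Evaluation of scored candidate lists from small-molecule identification
contests.

In community contests for compound identification from tandem mass
spectrometry, each *challenge* is one unknown compound; participants submit
an ordered, scored list of candidate answers per challenge — molecular
formulas in the formula categories, structures (SMILES or InChI) in the
structure categories. `idrank` is the organiser-side toolkit that turns a
solutions table plus per-participant submission files into per-submission
metric records, per-challenge winners, category winners, summary tables and
candidate-similarity profiles.

## The metrics

For one submission, let the candidates be partitioned relative to the score
*s* of the correct candidate into

* *BC* — candidates with a strictly **b**etter score,
* *EC* — candidates with an **e**qual score (including the correct candidate
  itself),
* *WC* — candidates with a strictly **w**orse score,

with *TC = BC + EC + WC* total candidates. Higher scores are always better,
and score equality is exact (ties come from identically reported scores).
The package computes:

* **Worst-case rank** — `Rank_WorstCase = BC + EC`, the rank of the correct
  answer if it loses every tie. The winner of a challenge is the eligible
  participant with the smallest worst-case rank on an original (pre-deadline)
  submission; the category winner is the participant with the most challenge
  wins.
* **Relative ranking position (RRP)** —
  `RRP = 1/2 * (1 + (WC - BC) / (TC - 1))`, in [0, 1] with 1 best. Defined
  only when the correct answer is present and *TC* ≥ 2; equals 0.5 when all
  candidates share one score. It rewards selective scoring independently of
  list length.
* **Normalized scores and weighted RRP** — scores are normalized to sum to 1
  (`s̃ᵢ = sᵢ / Σⱼ sⱼ`); with *wBC* the normalized mass scoring strictly above
  the correct candidate and *wEC* the mass tied with it (the correct
  candidate's own mass excluded), `wRRP = 1 - wBC - wEC`. A unique top-ranked
  correct candidate gives `wRRP = 1`; uniform scores give `wRRP = 1/TC`.
* **Structure identity** — a structure candidate is *correct* when the first
  14 characters (connectivity block) of its standard InChI Key equal the
  solution's, so stereoisomers match and positional isomers do not. When a
  submission contains several stereoisomers of the solution, the
  highest-scoring match sets the rank. Formula candidates are compared as
  Hill-order canonical strings.
* **Tanimoto similarity profiles** — every candidate of a structure
  submission is fingerprinted and compared with the solution:
  `TS = C / (A + B - C)` over set bits. The default backend is OpenBabel's
  path-based 1024-bit FP2; a CDK-compatible 1024-bit hashed path fingerprint
  (`cdk_fingerprint_backend()`) reproduces reference bitsets such as ethanol
  → `{301, 638, 742, 743, 930}` and TS = 0.842 for the
  1-/2-aminoanthraquinone positional-isomer pair.

A synthetic-contest generator produces contests with exactly controlled
`(TC, BC, EC, WC)` partitions, tie multiplicities, stereoisomer duplicates
and absent answers, so the entire pipeline is testable without any contest
data.

## Worked example

Metrics for a single scored candidate list — six candidates, the correct
structure matched at positions 3 and 6 (a stereoisomer duplicate), with the
position-3 match tied with one other candidate:

```r
library(idrank)
m <- rank_metrics(scores = c(9.1, 7.4, 7.4, 5.0, 2.2, 1.0),
                  matched_indices = c(3L, 6L))
m
#> <rank_metrics> TC=6 BC=1 EC=2 WC=3 rank=3 RRP=0.700 wRRP=0.486 s~=0.231
```

The highest-scoring match (7.4) is the reference: one candidate scores
better, two share the score (worst-case rank 3 = 1 + 2), the duplicate at
1.0 falls into *WC*. The correct candidate holds normalized score 0.231, and
`wRRP = 1 − wBC − wEC = 1 − 0.283 − 0.231 = 0.486`.

A full contest round trip — generate a synthetic contest, evaluate it, and
summarize by participant:

```r
generate_contest("demo_contest", n_participants = 4, n_challenges = 3,
                 seed = 2026)
cli_main(c("evaluate", "demo_contest", "--out", "records.tsv", "--quiet"))
cli_main(c("summarize", "records.tsv", "--config", "demo_contest/config.yaml",
           "--quiet"))
#> == Category 1 (original, by participant) ==
#> participant  subm  cor(win)  avg_rank  avg_TC  avg_BC  avg_RRP  avg_wRRP  avg_s
#> P01          3     2(1)      3.00      7.0     1.0     0.727    0.706     0.565
#> P02          3     2(1)      2.00      7.3     1.0     0.833    0.888     0.553
#> P03          3     3(1)      3.00      8.3     1.3     0.773    0.716     0.426
#> P04          3     2         4.00      10.3    2.0     0.764    0.585     0.136
#> winner(s): P01, P02, P03
```

`cor(win)` is the number of submissions containing the correct answer with
challenge wins in brackets; `avg_rank`, `avg_BC`, `avg_wRRP` and `avg_s`
average over submissions containing the correct answer, `avg_TC` over all
submissions, and `avg_RRP` over submissions where the RRP is defined. `P04`
is this contest's internal participant: evaluated and tabulated, but
ineligible to win. The same pipeline is scriptable from a shell through the
installed entry point `system.file("cli", "idrank.R", package = "idrank")`
with subcommands `synth`, `evaluate`, `summarize` and `plot`.

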