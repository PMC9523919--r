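---
title: "Methods: discovering and validating chromatin-regulator genetic interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and validating chromatin-regulator genetic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A genetic interaction here is a conditional dependency: knocking out a
*target* gene changes cell viability differently depending on whether a
*partner* gene is mutated. With chromatin regulators (CRs) on at least
one side of the pair, two directions matter clinically:

- **synthetic lethality (CSL)**: partner-mutant cells tolerate the
  knockout *worse* — a drug inhibiting the target is predicted to be
  more effective in partner-mutant tumours;
- **synthetic viability (CSV)**: partner-mutant cells tolerate the
  knockout *better* — predicting drug resistance.

The statistical engine is deliberately simple and rank-based. Per
screen, tissue and pair, the target's viability-oriented dependency
scores are split by partner alteration status and compared with
one-sided Wilcoxon rank-sum tests in both directions. Rank tests make
the analysis invariant to monotone transformations of the score scale,
which is what permits pooling CRISPR CERES scores, Sanger fitness scores
and shRNA dependency scores — after a single orientation step
(`orient_to_viability()`) that negates screens publishing essentiality.

Evidence is combined across screens with Fisher's method,
\(X^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}\), using the directional
p-values from **every screen in which the pair was testable**, not only
the significant ones; combining only the supporting screens would build
selection bias into the combined p-value. A consensus call additionally
requires nominal significance (p < 0.05) in the same direction in at
least two screens. Pairs significant as CSL in one screen and CSV in
another are emitted with `conflict = TRUE` and excluded from consensus
rather than silently resolved.

Multiple testing is deliberately left at nominal p at the per-screen
stage: per-tissue cell-line panels are small, and the design instead
relies on cross-screen consensus, the combined-p threshold and the
downstream pharmacogenomic filter for error control. BH adjustment per
screen and tissue is available (`scan_candidates(adjust = TRUE)`) but
off by default.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | per-screen, per-direction nominal level |
| `min_support` | 2 | screens that must agree for a consensus |
| `alpha_combined` | 0.05 | threshold on the Fisher-combined p |
| `min_lines` | 4 | cell lines a tissue needs (i.e. more than three) |
| `min_group` | 3 | smallest mutant and wild-type group per test |
| `min_mut_freq` | 0.10 | cohort partner mutation frequency, strictly exceeded |
| `fdr` | 0.1 | BH threshold for differential features and pathways |
| `n_perm` | 1000 | PPI permutation replicates |

"Alteration" defaults to any non-silent mutation class; a restricted
class list can be passed to `mutation_catalog()` to study, e.g.,
missense-only stratifications.

## Numerical choices

- **Exact vs approximate rank-sum p.** Exact enumeration (via the exact
  rank-sum distribution) is used when the pooled sample has at most 12
  tie-free observations; otherwise the normal approximation with tie
  correction and continuity correction. The switch is deterministic so
  results are bit-for-bit reproducible; the test suite verifies equality
  with exhaustive enumeration in the exact regime and with the reference
  `wilcox.test` implementation elsewhere.
- **p-value floors.** p-values are clipped to 1e-300 before log
  transforms, so Fisher combination never takes `log(0)`.
- **Median ties.** Wherever patients or cell lines are split at a median
  (target expression, carrier burden), ties go to the *low* group. Low
  target expression is the reference state throughout ("low mimics drug
  inhibition"), so "up-regulated" always means higher in the target-low
  group.
- **Activation rule.** A pair is "activated" in a patient iff the
  partner carries an altering mutation *and* target expression is at or
  below the cohort median. The expression side is configurable
  (`activation_rule("above")`) because the definition is genuinely open;
  every survival report records the rule used.
- **Kaplan–Meier ties.** At tied times, events precede censorings (the
  standard product-limit convention of the survival package).
- **Degenerate inputs** (all-tied groups, zero-variance vectors, groups
  below size thresholds, event-free survival data) are flagged
  explicitly — skipped with a reason or marked `degenerate` — never
  silently converted to p = 1 candidates.
- **PPI contact.** "Indirect contact" means a shortest PPI path of
  exactly 2 (a shared neighbour); the maximum path length is a
  parameter. The permutation p carries a +1 pseudocount,
  \((1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)\), so it is never 0.
- **Two one-sided differential tests.** Differential features use
  separate one-sided tests with BH within each direction, rather than
  one two-sided test, because the reported quantities are directional
  up/down counts.

## What the synthetic data emulates

`sim_config()` defines the study conditions; its defaults are fixed and
are the conditions under which the package's statistical claims are
tested:

- three screens over one shared 100-line panel (one stored
  essentiality-oriented, two viability-oriented), gene-level Gaussian
  noise (σ = 1);
- 20 planted CSL and 10 planted CSV pairs, each shifting the target's
  viability score by 2σ in partner-mutant lines; partners mutated at
  rate 0.3 (≈ 30 mutant / 70 wild-type lines);
- a 200-pair null universe (2 decoy targets × 100 mutated partners).
  This size is a design-time power decision: a nominal-p two-of-three
  consensus has an a-priori false rate of ≈ 1.2% over both directions,
  so 200 null pairs keep the expected false-discovery proportion of the
  planted recovery under 0.1. Calibration experiments build their own
  2000-pair effect-free configuration with exactly 15 mutant lines per
  gene (`mutation_model = "fixed"`);
- drug response matrices with a 2σ sensitivity/resistance shift for the
  drug hitting each planted target, plus unshifted decoy drugs;
- a 200-patient cohort with planted expression/methylation correlation
  ρ = 0.8, partner mutation frequency 0.15, exponential survival with
  the hazard divided (CSL, protective) or multiplied (CSV) by 2.5 for
  activated patients, ≈ 20% independent exponential censoring, and HRD
  / immune-fraction scores shifted by 1 SD in activated patients;
- side data: a sparse random PPI graph guaranteeing a direct edge for
  80% of planted pairs, random pathways plus one set collecting the
  planted partners, and ATC codes shared between drugs with a common
  target.

Gaussian noise is used everywhere because every inferential step is
rank-based, so the noise family does not affect validity — it only makes
power calculations transparent. The generator does **not** emulate
realistic genomic covariance, copy-number structure, lineage-specific
expression programs, or mutual exclusivity between mutations. Passing
tests therefore demonstrate that the machinery is calibrated and
recovers planted effects of the stated size — not that effects of that
size exist in any real screen.

Determinism: each generator derives its RNG stream from
`seed + stage-offset` and restores the caller's RNG state, so bundles
are byte-identical under a fixed seed regardless of call order.

## Design decisions on genuinely open points

- **Combining all testable screens vs only supporting ones** in the
  Fisher step: all testable (see above).
- **Null universe for PPI permutation:** pairs are drawn uniformly
  without replacement (within a replicate, excluding self-pairs) from
  genes having at least one PPI edge, matching the conditional question
  "is this much contact surprising among connected genes".
- **Drug targeting** is strict membership in the drug→target map;
  off-target effects must be encoded in the map itself, keeping the
  semantics auditable.
- **Drug-pair similarity universe** is the partner genes of the relevant
  network, not the genome: the question is whether two drugs share
  partners more than random drugs *in this map* would.
- **Silent mutations** are retained in catalogs but non-altering by
  default (whether they were counted as alterations upstream is
  unknowable from public descriptions; excluding them is the
  conservative choice).
- **Pharmacogenomic datasets are tested independently**, never combined
  across datasets — supporting evidence is reported per dataset.
- **Tissue labels must match exactly** between screens and
  pharmacogenomic data after any user-supplied harmonisation; the
  package does not guess lineage synonyms.

## Problem sizes

The shipped experiments run at desk scale, chosen so the full suite
completes in minutes on one core: 2000-pair calibration panels,
230-pair recovery scans over three 200 × 100 score matrices, 500-feature
differential recovery at 30 + 30 samples, 400 + 100 log-rank
replicates, and 999-replicate PPI permutations. All sizes scale linearly
in code; nothing in the implementation is specialised to them.

## Known limitations

- The consensus stage controls error through agreement, not FDR; with
  very large null universes the false-discovery proportion grows
  accordingly (quantified in the vignette section above).
- Exact rank-sum enumeration is limited to pooled n ≤ 12 without ties;
  beyond that the continuity-corrected normal approximation is used even
  for moderately small groups.
- Survival analysis is log-rank only: no Cox modelling, covariate
  adjustment, stratification or competing risks.
- The hypergeometric drug-similarity p treats partner sets as unordered
  gene sets; tissue context is ignored at that stage.
- Cohort methylation is consumed per gene; probe-level structure is out
  of scope.
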