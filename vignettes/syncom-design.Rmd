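---
title: "Function-based design of synthetic microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function-based design of synthetic microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynComSelect)
```

## The problem

A synthetic community (SynCom) is a defined set of cultured strains
assembled to stand in for a complex microbiota in controlled experiments.
SynComSelect selects a fixed-size SynCom whose *combined functional
repertoire* best represents a group of metagenomes. Function here means a
Pfam protein family: every genome and every metagenome assembly is reduced
to a binary presence/absence vector over Pfam accessions (PF#####), as
produced upstream by `hmmscan --cut_ga` against Pfam. Working at the level
of encoded functions rather than taxonomy lets the method pick strains that
cover what the ecosystem *does*, including low-abundance strains carrying
otherwise-missing functions.

## The model and procedure

**Inputs.** A genome collection $G$ and a sample group $S$, both as binary
matrices over a shared Pfam universe; optionally a second sample group for
differential weighting; a GTDB-style taxonomy for the genomes; and growth
data (simulated or measured) for viability screening.

**Scoring.** For a genome (or combined SynCom) vector $g$ and a sample
vector $s$, the score is

$$\mathrm{score}(g, s) = \sum_{p \in g \cap s} \big(1 + w_p\big),$$

i.e. one point per matching Pfam plus its weight; Pfams in $g$ but not $s$
(mismatches) contribute nothing. Weights are additive per Pfam:

* **core weight** $w_\mathrm{core}$ (default 0.0005) for Pfams present in
  strictly more than 50% of the target group's samples;
* **discriminatory weight** $w_\mathrm{disc}$ (default 0.0012) for Pfams
  whose prevalence differs between the two groups at two-sided Fisher exact
  $p < 0.05$ (no multiple-testing correction by default, matching the
  method's established usage; a BH switch exists).

A Pfam that is both core and discriminatory carries the sum. The defaults
are the values identified by grid scanning (below) as minimizing the
Jaccard distance between selected SynComs and their source samples.

**Step 1 — per-sample greedy selection.** For each sample, genomes are
scored against the *remaining* sample vector, the best scorer is picked
(ties by lexicographically smallest id, for reproducibility), its Pfams are
masked out, and the loop repeats to depth 20. Twenty is deliberately about
twice the knee-point community size, to pull in rarer functions. If all
remaining scores hit zero the loop stops early rather than padding with
useless strains.

**Step 2 — shortlist and enumeration.** Strains selected in at least 33.3%
of the per-sample runs (inclusive ≥) are shortlisted. All
$\binom{n}{k}$ subsets of size $k$ (default 10) are enumerated — an
18-strain shortlist gives 43,758 — and subsets containing two members with
the same nonempty species label are removed (configurable rank; unassigned
labels never collide, otherwise any two unclassified genomes would exclude
each other).

**Step 3 — group scoring.** Each surviving subset's member vectors are
OR-combined into one vector and scored against every sample with the same
match-plus-weight score (full sample vector, no masking); the mean over
samples is the group score, and candidates are ranked by it (ties again
lexicographic). We use the raw mean with no per-sample normalization; the
per-sample scores are retained in the candidate object for inspection.

**Step 4 — viability.** Growth of each member alone, in every pair, and in
the full community (from any simulator honoring the three-CSV growth-table
contract, or the built-in toy simulator) is classified per strain by
relative change $r = (\mathrm{paired} - \mathrm{alone})/\mathrm{alone}$:
positive above +10%, negative below −10%, neutral in between. Effect pairs
map to mutualism (+,+), commensalism (+,0), parasitism (+,−), amensalism
(−,0), neutralism (0,0) and competition (−,−) — competition is absent from
the classical five-label list but the (−,−) case must exist, and we count
it as negative. A SynCom is viable iff (1) strictly more than 50% of its
pairs contain no negative effect, (2) every strain receives at least one
positive effect, and (3) every strain grows in the community run (final
growth strictly above a configurable floor, default 0). The ranked list is
walked until the first viable candidate; simulator failures mark a
candidate inviable and the walk continues. Because "neutral or positive
pairwise iterations" can be read per pair or per effect, the report emits
both percentages; the decision uses the per-pair reading (any pair
containing a negative effect counts as negative).

## Weight estimation

`weight_scan()` evaluates one weighting strategy over a weight grid: for
each grid value each sample gets its own greedy SynCom, compared to the
sample by Jaccard distance and match/mismatch percentages. The grid over
$(0, \mathrm{stop}]$ in steps $s$ has $\mathrm{stop}/s$ points and excludes
the zero baseline (computed once separately; at weight 0 every strategy is
exactly the unweighted selection, which the tests assert bit-for-bit). The
coarse design — 3 strategies × 400 weights ((0,1] step 0.0025) × 60 samples
— is 72,000 evaluations; the fine design — 100 weights ((0,0.01] step
0.0001) × 60 samples — is 6,000. The "genomic" rarity strategy
(up-weighting functions rare in the collection) has no standard rarity
definition; we implement the linear placeholder
$w_p = w\,(1 - \mathrm{prev}_G(p))$, keep it selectable, and exclude it
from defaults since it showed no effect in benchmarking.

## The synthetic world

The generators exist so the whole pipeline builds and tests offline; their
defaults are a fixed stated world, not tuning knobs:

* universe of 2,000 Pfams; 40 genomes, each = a 10% shared core + a 15%
  random accessory subset (equal accessory sizes avoid systematically
  favoring any genome during greedy selection);
* 60 samples per group, each the union of a planted 10-member truth
  community plus 5% of the universe as noise (spec'd benchmark scale:
  60 samples, truth recovery ≥ 9/10 in under 2 minutes — observed ~20 s
  with perfect recovery);
* two-group fixtures plant discriminatory Pfams at exact 18/20 vs 2/20
  prevalence, drawn from outside the truth union and excluded from the
  noise pool so planted prevalences are exact;
* taxonomy gives every genome its own species except two deliberate
  same-species duplicates placed among the *non-truth* genomes, so the
  species filter is exercised without making truth recovery impossible;
* growth fixtures assign each pair a label from a requested interaction mix
  (largest-remainder apportionment) and construct growth values (±20%
  signed, +5% neutral) that classify back to exactly the planted labels at
  the 10% threshold.

What a green test does **not** establish: real metagenomes have Pfam
co-occurrence structure, uneven genome sizes, and samples that are not
unions of any genome subset; the toy simulator is not a metabolic model.
The generators validate the selection logic, not ecological truth.

## Numerical choices and edge cases

* **Fisher exact test**: implemented as the conditional two-sided
  hypergeometric sum with the standard `(1 + 1e-7)` relative tolerance on
  tie detection; verified against full enumeration on every table with
  margins ≤ 12 and against `stats::fisher.test`.
* **Boundary conventions**: core prevalence is strict (>); shortlist
  prevalence is inclusive (≥, "at least"), guarded by a 1e-12 epsilon
  against floating-point division; the 50% viability rule is strict (>),
  so exactly half non-negative fails.
* **Ties**: all selection and ranking ties break on lexicographic ids —
  determinism is a contract, and reruns are byte-identical (timestamps are
  quarantined to a single summary field).
* **Degenerate growth**: a strain with zero growth alone cannot have a
  relative change; it is classified positive if co-culture enables any
  growth, neutral otherwise, with a logged message.
* **Enumeration bounds**: combinations are materialized behind a hard cap
  (default $10^7$) with a clear error advising a higher prevalence
  threshold; ranking keeps a bounded top-K (default 10,000).
* **Null false positives**: on discrete 2×(20,20) tables an exact test is
  conservative, so the realized false-positive rate among null Pfams sits
  at or below α; the property test bounds it by α + 3 binomial SEs rather
  than asserting a symmetric band no exact test could satisfy.

## A worked run

```{r pipeline, eval = FALSE}
spec <- fixture_spec(seed = 1)             # the default stated world
gen  <- generate_genomes(spec)
met  <- generate_metagenomes(gen, spec)
cfg  <- syncom_config(samples = met$groups$A, genomes = gen$profiles,
                      taxonomy = gen$taxonomy, out_dir = "run1", seed = 1)
res  <- run_pipeline(cfg)
res$status                                  # "ok"
res$winner_members                          # the selected 10 strains
```

## Known limitations

Metabolic-model construction and arena simulation are out of scope by
design — only the growth-table contract and the decision rules are
implemented, so viability verdicts are only as good as the growth numbers
supplied. Configuration files are JSON rather than YAML (no YAML parser in
the supported dependency set). Abundance-weighted scoring,
metatranscriptome input, and knee-point estimation of the optimal SynCom
size are not implemented.
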