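---
title: "Screening for seed-specific genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for seed-specific genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscreen)
```

## The screening model

The package implements a two-assay screen for genes expressed specifically
in the developing cereal seed.

**Digital differential display (DDD).** EST libraries are partitioned into
a seed pool A and a non-seed pool B. Under the standard sampling model, a
library of $n$ ESTs is a multinomial draw over genes with probabilities
proportional to relative transcript abundance in that tissue; a gene's
pooled counts $(a, b)$ against pool totals $(A, B)$ then form a 2×2 table
whose null of equal pool fractions is exactly testable. We use the
two-sided Fisher exact test and keep a gene when

1. $p \le \alpha$ (default 0.05),
2. $b/B < 5\times 10^{-5}$ (strict) — an absolute cap on non-seed
   expression, and
3. $a > \text{fold}\cdot b$ (strict; default fold 4, with 3 the
   convention for rice where fewer seed libraries exist).

The fold rule has two first-class bases. `fold_basis = "counts"` compares
raw ESTs, `"fractions"` compares pool fractions. The distinction is
material: with the default catalog, pool B is ~3.1× larger than pool A, so
a count-based 4-fold demands a fraction ratio above $4B/A \approx 12.5$.
The count basis is the default because the selection rule is phrased in
EST quantities; both bases are reported in output metadata.

**Sidedness.** Whether the classical DDD web tool used a one- or
two-sided p ≤ 0.05 is not documented; we default to two-sided — the
conservative choice — because the fold criterion enforces directionality
regardless. One-sided behavior can be emulated by the fold rule alone.

**Array screen.** Probesets suffixed `_s_at`/`_x_at`/`_a_at` (known
cross-hybridizers) or carrying the `.A1` design token (predominantly
wrong-orientation) are discarded before anything else. Replicates are
averaged on the log2 scale — i.e. a geometric mean of intensities, which
differs from an arithmetic intensity mean; since the specificity call uses
a pure ratio the choice only matters under replicate noise, and the
geometric mean is the conventional one for log-scale array data. A
probeset is called seed-specific when its best seed organ exceeds 4× its
best non-seed organ on the linear scale, strictly. Comparing against the
*maximum* non-seed organ is equivalent to demanding the margin against
every organ individually. No variance test is layered on top: the screen
is a fold rule, and we keep it that.

The stage label is that of the seed organ attaining the maximum, ties
broken by organ panel order. At the unigene level a gene whose specific
probesets disagree on stage is reported as `both/other` rather than being
forced into a stage — real screens show such mixtures, and forcing a
binary hides them.

**Integration.** A unigene is array-positive if ≥ 1 retained probeset is
specific (the many-probesets-to-one-unigene direction demands "any", not
"all"). DDD-selected genes with no retained probeset are tracked in a
separate `no_probeset` ledger: they are not evidence for or against seed
specificity, so they are excluded from the combined list and from
sensitivity denominators alike.

**Evaluation.** GO enrichment is the upper-tail hypergeometric
$P(X \ge k)$ with raw $p < 0.05$ — deliberately uncorrected, matching the
screen's established practice; Benjamini-Hochberg q-values are emitted as
an informational column only, and never drive the call. The background set
is an explicit argument: whether to use the whole array or whole gene
catalog as population changes $K$ and $N$, and the package refuses to
guess. Annotations are taken as already propagated over the GO graph.
Cross-species replication bins homolog pairs by percent identity —
HS > 90, MS (70, 90], WS (45, 70], with ≤ 45 excluded; boundaries fall to
the lower-similarity class, applying the strict ">" of the HS definition
uniformly. Specificity = % of the query list replicating in the subject
list; sensitivity = the converse. Both are reported raw and truncated to
one decimal (27/70 → 38.5), whereas whole-number breakdowns round to the
nearest percent with ties away from zero (108/407 → 27, 1/8 → 13): both
conventions appear in published screen reports, so both are implemented
exactly and used where each applies.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which the screen is validated.

* **Library plan.** 17 libraries in two pools: 151,632 seed ESTs vs
  473,145 non-seed ESTs, each tissue group one library. Counts per library
  are a single multinomial draw, so column sums equal the plan exactly.
* **Organ panel.** Seven vegetative/floral organs plus the 3-5 DPA
  caryopsis and the 22 DPA embryo and endosperm; 3 replicates per organ.
* **Truth profiles.** Each gene has a relative weight per tissue (rows sum
  to 1) and a lognormal abundance (`mass`, sdlog = 1) multiplying the
  profile in all sampling probabilities and intensities — this is what
  makes cluster sizes vary so size-binned summaries are informative.
* **Background genes are tissue-flat.** Every non-planted gene has an
  identical relative weight in all tissues, so it is an *exact* null for
  the Fisher test and the fold rule. This is the deliberate calibration
  choice: it lets the type-I behavior of the statistical core be measured
  cleanly (pass rate ≤ 0.05 plus Monte-Carlo error). Real transcriptomes
  have tissue-variable background genes that are genuinely non-null, so
  false-positive rates on real data are higher than on these conditions —
  passing the calibration tests bounds the *test*, not the biology.
* **Planted seed-specific genes** (default 25 of 500) carry full weight in
  every seed tissue and a residual `seed_leak` weight elsewhere (default
  0.002 of the seed weight, uniform-jittered, always capped at
  `1/effect_size`). `effect_size` (default 8) is thus the *guaranteed
  minimum* seed/non-seed ratio, not the realized one. The leak scale is
  the biologically meaningful dial: a gene is only recoverable by the
  pool-fraction rule if its absolute non-seed expression is far below an
  average gene's (with these pool sizes, below 1/40 of average), which is
  what "seed-specific" means for, e.g., storage-protein transcripts that
  are undetectable outside the grain. A gene that is merely 8-fold
  enriched in seed is *not* recoverable by this screen, and the generator
  does not pretend otherwise.
* **Single-assay decoys** (default 20 + 20) emulate the screen's
  documented failure modes. DDD decoys are expressed in seed *and* in
  organs only the array panel measures (anthers, pistil, …): the EST pools
  cannot see the non-seed expression, so DDD selects them and the array
  rejects them. Array decoys are expressed in seed *and* in tissues only
  the EST libraries sample (callus, shoot, …): the array sees a clean
  seed profile while pool B fills with their ESTs. Without these classes
  the intersection could only ever *lose* true genes relative to each
  single screen, and the combined screen's characteristic advantage —
  higher cross-species replication than either assay alone — would be
  unproducible. Their counts are scaled from the roughly-half fraction of
  each single-screen list that fails the other assay in practice. Null
  calibration runs set both decoy counts to zero along with the planted
  count, since decoys are planted non-null structure.
* **Probesets.** ~20% of genes get no probeset (mirroring screened genes
  absent from the chip); of the represented genes, ~20% get an additional
  suffixed probeset duplicating the clean profile with 1.5× noise, so the
  filter changes bookkeeping but not correctness. Intensities are
  `log2(mass · weight + floor) + 12` with additive Gaussian noise
  (`noise_sd`, default 0.3 log2 units) and a linear-scale detection floor
  (`array_floor = 1e-4`) keeping values finite.
* **Homology.** Each query gene is paired with probability
  `homology_fraction` (0.6, matching the ~three-fifths of screened genes
  with counterparts); a paired planted gene maps to a planted counterpart
  with probability `conservation` (0.65, the observed 62-69% replication
  range); identity is uniform on (46, 100] unless a sampler is supplied.
  Expected cross-species specificity of the truth lists is therefore
  ≈ 100·h·c.
* **GO annotation.** A 25-term random vocabulary (mean 2 terms/gene) plus
  one seed-development term annotated to planted genes with probability
  `base + bias(1 − base)` and to background genes with `base(1 − bias)`;
  bias 1 makes it planted-only, bias 0 removes the preference.
* **Determinism.** Every generator sets its own RNG stream derived from
  `rng_seed` (fixed small offsets), so any single table can be regenerated
  without running the others.

## Numerical choices

* Fisher two-sided tie rule: point probabilities within a relative
  $10^{-12}$ of the observed table's probability count as ties and are
  included. The test suite checks agreement with an independent
  `lchoose`-based enumeration oracle to $10^{-10}$ over 1,000 random
  tables, and with `stats::fisher.test` on small tables.
* All three DDD criteria and the array fold rule are strict inequalities;
  boundary cases ($b/B = 5\times10^{-5}$ exactly, 4.00-fold exactly) are
  rejected, and tests pin this.
* Degenerate inputs: genes with zero ESTs in both pools are kept with
  p = 1 (never dropped, so gene bookkeeping is exact); a pool with zero
  total ESTs, an organ without replicate columns, a zero-variance profile
  in `pearson_r`, and a constant row in `hierarchical_cluster` are
  errors, not silent values. `profile_neighbors` silently skips constant
  candidate rows since a correlation to them is undefined rather than
  low.
* Clustering uses distance $1 - r$ with average linkage; linkage is an
  argument because nothing pins it down, and average linkage is the
  common default for correlation-based expression clustering. Leaf order
  is the deterministic `hclust` order.
* Screening uses expression values as given; no normalization is applied,
  so a user's normalization choice can never silently alter specificity
  calls.

## Pipeline composition

`run_pipeline()` generates a query species (fold 4) and a subject species
(fold 3, offset seed), screens both, intersects, and evaluates. The
"array-alone" method list is defined as all unigenes with ≥ 1 specific
retained probeset — a direct panel-wide fold screen. Seeding a
profile-neighbor search with the combined list (as the original web-tool
workflow did) is circular on synthetic data, where correlated profiles
are by construction the planted ones; `profile_neighbors()` is exported
and tested as its own operation instead.

Problem sizes throughout (500 genes, 25 + 40 planted, 625k ESTs, ~480
probesets × 30 samples, 10-seed replication in the acceptance runs) were
chosen so a full pipeline run takes well under a second while every
count-based summary stays in the regime where the asymptotic arguments
above (Poisson-scale pool counts for planted genes, multi-σ array
margins) apply.

## What passing the tests does and does not show

The suite demonstrates: exactness of the statistical core against
independent enumeration; strictness of every threshold; conservation and
determinism of the generator; recovery of planted truth (precision and
sensitivity ≥ 0.8 over ten seeds at effect size 8, noise 0.3); type-I
calibration of both tests under their nulls; and the qualitative ordering
that the combined screen replicates across species at least as well as
either single screen in ≥ 8/10 seeds.

It does not show: performance on real EST/array data (tissue-variable
backgrounds, library composition biases, probeset cross-hybridization
beyond the suffix classes, non-uniform homology detection); correctness
of any normalization; or robustness of the fold rule near the detection
floor, where array ratios are dominated by the floor term. The screen's
known blind spots are inherited by design: genes expressed in tissues
absent from both the EST pools and the array panel are unfalsifiable
seed-specific candidates, and the `no_probeset` ledger only covers the
array side of that gap.
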