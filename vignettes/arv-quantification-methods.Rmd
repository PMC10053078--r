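---
title: "Quantifying AR splice variants from splice junctions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AR splice variants from splice junctions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arvquant)
```

## The measurement model

An AR splice variant (AR-V) that incorporates a cryptic exon or an
alternative first exon produces at least one splice junction — a
donor/acceptor pair of intron boundaries — that the canonical AR transcript
never produces. A spliced RNA-seq alignment crossing that junction (a skip
`N` operation in its CIGAR) is direct, sequence-level evidence for the
variant. `arvquant` quantifies each variant *relative to AR itself*:

$$\mathrm{relexpr}(s, x) \;=\; 100 \cdot
  \frac{\mathrm{SJ}_x(s)}{\mathrm{SJ}_{E1E2}(s)}$$

where $\mathrm{SJ}_x(s)$ is the number of qualifying spliced reads of sample
$s$ supporting variant $x$'s distinctive junction and
$\mathrm{SJ}_{E1E2}(s)$ the support for the canonical exon 1–exon 2 junction
of AR. Exons 1–2 are shared by essentially all AR isoforms, making this
junction a natural within-sample denominator that cancels library size and,
to first order, AR expression level. A widespread transcription of this
ratio renders it inverted (reference over variant); the package implements
the variant-over-reference orientation, which is the only one consistent
with variant expression reported as small percentages of AR.

The ratio is a plug-in estimate of the variant junction fraction. If the
reference junction is covered by $D$ reads and a variant is truly present at
fraction $f$, the estimator's sampling error is approximately binomial,
$\mathrm{SE} \approx 100\sqrt{f(1-f)/D}$; the test suite verifies that the
estimator's RMSE tracks this envelope and shrinks with depth
($D \in \{100, 1000, 10000\}$).

### Edge cases

* $\mathrm{SJ}_{E1E2}(s) = 0$: relative expression is **undefined** for every
  variant in that sample — not 0%. Undefined samples stay in prevalence
  denominators as non-positive by default (cohort prevalence is conventionally
  reported over all samples); a `strict` flag removes them.
* $\mathrm{SJ}_x = 0$ with positive reference support is a genuine 0%.
* A variant with no distinctive junction (AR-V11: its defining structure is
  not captured by any junction absent from other isoforms) is **exempt**:
  every API reports it with an explicit status, never as a silent zero.
* Positivity is called at relative expression $\ge$ 1% (inclusive); the
  threshold is a parameter everywhere it is used.

## Junction extraction

Alignment I/O is delegated to Rsamtools/GenomicAlignments. A record
qualifies when it (a) overlaps the target locus with at least one aligned
block — a read whose skip gap merely spans the window does not count — (b)
contains at least one `N` gap, and (c) passes the filter policy: primary
(secondary and supplementary records excluded), properly paired,
non-duplicate. Junction coordinates are 1-based and intron-anchored: donor =
first intronic base, acceptor = last intronic base, the de facto
splice-junction-table convention, directly convertible to exon borders.

Junction strand is taken from the spliced-strand attribute (`XS` tag, the
dialect emitted by mainstream spliced aligners). Only junctions matching the
locus strand count toward support ("strand-correct"); records lacking the
tag are skipped and tallied in a `n_strand_unresolved` diagnostic rather
than raising an error. Inference of strand from intron dinucleotide motifs
would require the genome sequence, which is not part of the pipeline's
input surface; it was considered and left out — locus-restricted analyses
of a well-annotated gene lose essentially nothing.

No mapping-quality cut is applied: multimappers are handled solely through
the primary-alignment requirement. Mate pairs both spanning a junction count
twice (one per alignment record); this is documented rather than
deduplicated, since the reference junction is counted the same way and the
ratio is unaffected in expectation.

## The recurrence filter and the compendium

A junction is *recurrent* when $\ge$ `min_samples` (default 10) samples each
support it with $\ge$ `min_reads` (default 5) strand-correct reads. We read
the two thresholds as nested per-sample support followed by a sample tally —
the alternative (summed cohort-wide support) is exposed behind
`per_sample = FALSE` but is not the default, because a cohort-sum rule would
let a single deeply covered sample promote a private junction.

The compendium merges the recurrent set with a literature-supplied variant
definition table. Literature definitions are always retained (recurrence is
an annotation, not a gate), each variant is quantified by one designated
primary junction, and alternates are carried but never summed — summing
junctions with different capture efficiencies would make the denominator
comparison incoherent. The bundled GRCh37 table ships the canonical E1–E2
reference junction plus named variant rows as editable placeholders;
coordinates for cryptic exons differ between annotation releases and
curation choices, so they are deliberately a user input. All correctness
testing runs against the synthetic toy model, whose coordinates are fully
specified in code.

## Cohort statistics

* **Prevalence** — positives per variant over all samples, percentage
  rounded to integer.
* **Oncoprint ordering** — variants by descending prevalence; samples by the
  standard memo-sort (the positivity vector in variant order read as a
  binary number, descending), ties broken by identifier, so layouts are
  deterministic and order-invariant to input shuffling.
* **AR expression vs. AR-V status** — two-sided Mann–Whitney test between
  samples with $\ge 1$ positive variant and none. The wrapper uses the exact
  distribution for group sizes $\le 8$ without ties and the tie-corrected
  normal approximation otherwise; tests verify agreement with full rank
  enumeration at (3,3) and (6,6). Normalized AR expression is an input
  column (upstream gene-level normalization is out of scope); any
  square-root transform is presentation only.
* **Variant-count groups** — all pairwise Mann–Whitney comparisons across
  groups defined by the number of positive variants, Benjamini–Hochberg
  adjusted over the pairwise family; singleton groups are skipped with a
  notice.
* **Clinical regressions** — per variant, OLS of relative expression on each
  single covariate over complete cases (univariate screen, flag at
  $p < 0.05$, no multiplicity correction — the screen is explicitly
  exploratory and feeds the next stage), then one multiple regression per
  variant containing every screen hit, reporting features retained at
  $p < 0.05$. Constant covariates and zero-residual-df fits are flagged
  inestimable; collinear features are dropped with a notice. Samples with
  undefined relative expression are excluded per variant. The
  single-treatment subset keeps patients with exactly one prior treatment
  line and retains groups of $\ge 10$ patients.

## The synthetic cohort generator

The generator's job is to make every stage testable without restricted
patient data, with a truth table that is *consistent with the emitted reads
by construction*.

A toy AR-like gene (`chrT`, 8 kb, plus strand) carries canonical exons
E1–E8, an AR45-style alternative first exon in intron 1, and cryptic exons
in introns 2–4 defining AR-V3-, AR-V7-, AR-V9-, AR23- and AR-V1-like
junctions; AR-V11 is included without a junction. Reads are junction-spanning
two-block records (50M *gap* 50M): only junction support enters any
computation in scope, so simulating full transcript fragments would add
realism the pipeline cannot see.

Per sample, each canonical junction draws Poisson(depth) reads and each
active variant Poisson(fraction/100 × depth); a variant is active with its
configured cohort prevalence. Every emitted read is then assigned to
qualifying / duplicate-flagged / secondary-flagged / wrong-strand /
missing-strand-attribute categories by a single multinomial draw, plus
Poisson numbers of unspliced reads and sporadic noise-junction reads. The
truth table records the *qualifying* counts, so the extraction stage should
reproduce them exactly — and the recovery report (bias, RMSE, positivity
confusion) verifies that it does, while the expected fractions anchor the
statistical recovery tests.

Default conditions: 20 samples at reference depth 1000; AR45 5% in 66% of
samples, AR-V3 2% / 41%, AR-V7 3% / 37%, AR-V9 2% / 12%, AR23 1.5% / 8%,
AR-V1 1.5% / 6% — fractions sized so that active samples usually clear the
1% call, with the prevalence ranking of a late-stage mCRPC cohort.
Contamination defaults: 10% duplicates, 5% secondary, 2% wrong-strand, 2%
strand-less, 20% unspliced, 2% noise-junction reads. Clinical covariates:
age $\sim$ round $\mathcal{N}(67, 8^2)$ clipped to 46–85; treatment lines
$1 + \mathrm{Pois}(1.3)$ capped at 8; agents drawn without replacement with
weights following typical mCRPC pre-treatment frequencies (docetaxel most
common); 23% of patients have masked treatment records, 1% masked age.
Treatment effects are injected multiplicatively on the active fraction (the
default doubles AR-V7's fraction under enzalutamide pre-treatment), which
gives the regression stage a recoverable signal with a known target.

What the simulator does *not* emulate: sequence content, base qualities,
alignment errors, fragment-length and GC biases, junction-mapping ambiguity,
or expression outside the target locus. Passing recovery tests therefore
demonstrate the correctness of counting, filtering, quantification and
statistics given a faithful aligner — not robustness to upstream alignment
artefacts.

## Determinism and problem sizes

All simulation randomness flows from one integer seed; draws happen at the
integer count level, so cohorts are bit-reproducible across runs and
platforms, and two pipeline runs with the same seed produce byte-identical
tables (the run manifest echoes the full configuration and per-file MD5
checksums to make this checkable). The test suite uses cohorts of 2–20
samples at depths 60–1000, 100-seed filter-equivalence sweeps, 300–1000
replicate calibration loops for the regression machinery, and a
three-decade depth sweep for estimator consistency — sizes chosen so the
whole suite exercises every stage, including SAM round-trips, in well under
a minute of simulation time.

## Known limitations

* Quantification uses one distinctive junction per variant; isoforms whose
  evidence is spread over several junctions (or none, as AR-V11) are not
  deconvolved — no EM over shared junctions is attempted.
* Relative expression compares variant to canonical junction *support*, not
  molar transcript ratios; junction capture efficiency differences are not
  modelled.
* The recurrence filter's defaults (5 reads / 10 samples) are calibrated for
  cohorts of hundreds of samples at moderate depth; small cohorts should
  lower `min_samples` deliberately rather than trust the default.
* Clinical regressions are exploratory association models on observational
  pre-treatment indicators; nothing here supports causal interpretation.
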