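---
title: "IsomiR calling and comparison: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IsomiR calling and comparison: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirkit)
```

This vignette is the package's own account of the science it implements:
the decomposition model and its assumptions, the parameters that matter,
what the synthetic-data generators do and do not emulate, and the design
choices made where the design was genuinely open.

## 1. The reference model

A mature miRNA is represented as an interval inside its parental hairpin
(pre-miRNA), in 0-based half-open coordinates on the hairpin's 5′→3′
strand. All offsets elsewhere in the package inherit this frame, which
keeps trim/extension arithmetic free of fencepost ambiguity. Sequences
are held internally in the RNA alphabet (`U`, never `T`); FASTA/FASTQ
input in either alphabet is accepted and normalized on load, because
miRBase distributes RNA while sequencers emit DNA.

The minimal miRBase distribution is a hairpin FASTA plus a mature FASTA
with no coordinates, so mature intervals are recovered by exact
substring search (`locate_mature()`), with an optional GFF3-style reader
(`read_mature_gff3()`) that overrides the search when hairpin-relative
coordinates are available. When a mature occurs more than once in a
hairpin, the leftmost occurrence is used and a warning is issued — in
practice a 20–24 nt exact repeat inside one hairpin is vanishingly rare.

One consequential boundary: the **hairpin is the templated universe**.
A 3′ base beyond the mature end is "templated" exactly when it matches
the hairpin at that position; genomic flank beyond the hairpin is not
modelled. The templated/non-templated argument for isomiR biogenesis is
phrased on the parental hairpin gene (imprecise cleavage produces
templated ends; nucleotidyl transferases add non-templated tails), and
extending the universe to the genome would require genome-level mapping
that is out of scope here. A read whose extension is templated in the
genome but not in the hairpin would therefore be called `Plus` rather
than `Ext`; users with genomic context can supply a longer "hairpin"
record to widen the universe.

## 2. The anchored decomposition

`decompose()` is a normative algorithm, not a heuristic aligner: given
the same inputs it always returns the same call, and the whole caller is
specified tightly enough to be checked against a brute-force enumeration
oracle (the test suite does exactly that on 1,000 random
reference/read pairs).

For each candidate 5′ shift `shift5 ∈ [−max_5p_shift, +max_5p_shift]`
the read is anchored at hairpin position `mature_start + shift5` and
compared base-by-base:

* within the **core anchor region** (default mature positions 1–17,
  0-based, clamped to the mature length) mismatches are forbidden;
* elsewhere in the mature-overlapping span, up to `max_mismatch`
  substitutions are recorded;
* the read's 3′ overhang beyond the mature end is split by **greedy
  maximal templated matching** against the downstream hairpin context:
  the matched prefix becomes the templated extension `ext3` (capped at
  `max_3p_ext`), the remainder the non-templated tail;
* a read ending before the mature end yields the trim length `trim3`.

Each surviving candidate is scored by total edits,
`|shift5| + trim3 + ext3 + |tail| + n_sub`, and the minimum wins; ties
break by smaller `|shift5|`, then smaller `|tail|`, then lexicographic
mature id, then signed `shift5`. The tie-break order does real work:
a read one base longer than the mature whose extra base matches the
hairpin admits two minimum-edit readings (templated `Ext+1` with empty
tail, or empty extension with a 1-base tail); "smaller `|tail|`"
resolves this in favour of the templated reading, which is the
biologically conservative choice — a tail is only called when the
hairpin cannot explain the base. The greedy split makes the
decomposition unique and yields the invariant that no produced tail
begins with the next templated base unless the extension budget or the
hairpin itself is exhausted.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `max_5p_shift` | 2 | maximum 5′ offset, both directions (nt) |
| `max_3p_trim` | 5 | maximum 3′ trim (nt) |
| `max_3p_ext` | 5 | maximum templated extension and maximum tail (nt) |
| `max_mismatch` | 1 | substitutions tolerated outside the core |
| `core_start`, `core_end` | 1, 18 | core anchor region, 0-based within the mature |
| `allow_mixed_trim_tail` | `FALSE` | permit trim-then-tail compound calls |

These are operational tolerances chosen for reproducibility, not
biological constants: 3′ isomiRs observed in heart tissue span at most
±3 nt around the canonical end, so ±5 is permissive; one substitution
accommodates a sequencing error without letting random reads map. The
core region must contain the seed (mature positions 1–7, 0-based), so
no accepted call ever carries a seed substitution — 3′ isomiRs share
the canonical seed by construction, which is what makes comparing their
regulatory output meaningful.

Mixed trim-plus-tail calls (`Trim AG;Plus CC`) are representable but
disabled by default: the commonly reported isoform vocabulary never
combines them, and under edit-count minimization a mixed reading is
usually dominated by a substitution reading anyway. When enabled, a
mixed tail must begin with a base that differs from the hairpin at the
trimmed position (otherwise it would align as template) and may not
reach into the core anchor.

### Labels

Calls are labelled in the field's vocabulary: `canonical`;
`Plus <tail>` for a pure non-templated addition; `Trim <bases>` for a
pure trim with the removed bases listed from the 3′ terminus inward
(a mature ending `...UGA` trimmed by two is `Trim AG`); `Ext+<n>` for a
templated extension; a `5p±<n>` prefix for 5′ variants; and a
`;sub<pos><ref>><alt>` suffix per substitution (1-based read position).
Compound labels concatenate 5′, 3′ and substitution parts in that
order. Reads are assigned whole — no fractional multi-mapping — with
multi-mature ties resolved by the same deterministic candidate
ordering.

## 3. QC and collapsing

The QC window keeps reads of 15–30 nt: shorter sequences are degradation
background, longer ones are not mature-miRNA material. The mean-Phred
floor (default ≥ 20) is a conventional quality cutoff; quality scoring
rules differ across platforms, so the threshold is an explicit,
configurable parameter rather than a hidden constant, and it is applied
before collapsing (qualities are per-read; collapsed unique sequences no
longer have one). Adapter trimming is assumed done upstream — inventing
an adapter algorithm would add an unspecified degree of freedom.
Filtering statistics partition the input exactly (`kept + too_short +
too_long + low_quality = n`), with length checked before quality so each
read has one rejection reason.

## 4. Profiles and comparison

`call_sample()` decomposes each unique sequence once and accumulates
read counts per (mature, label); unassigned reads are counted, not
discarded silently. Abundance is reported both as raw counts and as
**RPM over assigned reads** (summing to 10^6), and cross-sample
comparison uses RPM because library sizes differ. Comparison
(`compare_profiles()`) is deliberately descriptive — shared labels,
side-by-side abundance, top-n rank agreement — with no significance
test: differential isomiR *usage* inference is a different model with
its own assumptions, and bolting a test onto descriptive comparison
invites over-reading.

Cross-species relations reuse the caller: `relabel_against()` is
`decompose()` applied to one species' mature sequence against another
species' reference, so e.g. a mature that equals another minus its
terminal base is exactly that species' single-base trim isoform. Because
it *is* the same code path, the relation inherits every caller
guarantee.

## 5. Gene-set machinery

`de_sets()` implements the standard reporting rule "fold change ≥ 1.5
with adjusted p < 0.05": the fold-change comparator is inclusive and the
adjusted-p comparator strict, with an `padj_inclusive` flag because both
conventions circulate. The fold-change test is evaluated on the log2
scale (`log2fc ≥ log2(1.5)`), which makes the boundary exact in floating
point. Tables that already carry adjusted p-values (e.g. exported from a
dedicated DE tool) are used as-is; otherwise `bh_adjust()` (a validated
wrapper over `stats::p.adjust(method = "BH")`) fills them in from raw
p-values.

`venn_partition()` produces all 2^k − 1 disjoint regions of 2–3 named
sets, and `diff_vs_reference()` the three-way shared/only split used
when comparing an isomiR's regulated genes against the canonical
miRNA's. `ddct_fold_change()` is the 2^(−ΔΔCt) method with group means
of per-row ΔCt.

`naive_count_test()` exists so the synthetic pipeline runs end to end:
per-gene log2 fold change of CPM means plus a Welch t-test on
log2(CPM + 1). It is plumbing — no dispersion modelling, no shrinkage —
and is documented as such; real differential expression belongs to a
negative-binomial framework. Its degenerate-input rule (both groups
zero-variance: p = 0 if means differ, 1 if equal) exists so that
noise-free simulated counts, where every replicate is identical, still
yield a defined answer.

## 6. What the generators emulate — and what they do not

`make_reference()` builds a random hairpin as 5′ flank + mature + 3′
flank with two guarantees: the mature's 3′ suffix is forced (default
`UGA`) so trim classes have well-defined removed-base names, and the
first base of the 3′ flank differs from the tail nucleotide so
`Plus A` reads are non-templated *by construction*. No secondary
structure is modelled: the caller uses only sequence and coordinates, so
thermodynamic realism would add nothing to the tests.

`sample_reads()` draws each read's class from the configured
proportions. The defaults —

```{r}
sim_config()$isomir_proportions
```

— emulate a heart-like repertoire in which the canonical form and its
single-base 3′ variants dominate, trimmed forms rival the canonical, and
a minor templated-extension class is present. Sequencing noise is
**substitution-only** at a per-base rate (default 0, typical test value
0.005) with Phred qualities from a truncated normal clamped to [2, 41]:
indel errors are deliberately excluded because they would conflate with
genuine trim/extension classes — a limitation to keep in mind for
platforms with appreciable indel rates. Passing the recovery tests
therefore shows the caller is exact under substitution noise; it says
nothing about indel robustness, adapter artefacts, or ligation bias, and
real libraries also violate the independence of errors across positions.

`simulate_counts()` plants a concordance structure across five
treatments against a mimic control: three concordant treatments (`miR`,
`PlusA`, `TrimA`) share a large core of regulated genes with small
private sets, two divergent treatments (`TrimAG`, `TrimAGU`) share a
separate block connected to the trio only by a 10-gene bridge. Counts
are negative-binomial around log-normal gene baselines; `dispersion = 0`
gives deterministic rounded means, the regime in which Venn-region
recovery must be (and is) exact. Replicate correlation beyond NB
dispersion is not modelled.

## 7. Numerical and degenerate-input choices

* Duplicate FASTA ids, non-ACGU characters (with position), truncated
  FASTQ records (with record index) and inconsistent call fields are
  hard errors — silent repair would corrupt counts downstream.
* `reconstruct()` re-derives the read from the reference and the call
  and errors on any inconsistency; the identity
  `reconstruct(decompose(r)) == r` holds exactly for every error-free
  read and is enforced in the test suite across all planted classes.
* Collapsing orders by count (descending) then sequence
  (lexicographic); ranking breaks count ties lexicographically by
  label. Every ordering in the package is total, so outputs are
  byte-stable across runs and platforms.
* All generators are seed-deterministic; the same configuration writes
  byte-identical FASTQ.

## 8. Problem sizes used in the checks

The shipped tests and the acceptance script use 10,000 reads per
simulated library, 1,000 random reference/read pairs for the oracle
comparison, 1,000 random p-vectors (lengths 1–500) for the BH check,
1,000 random set triples for the partition invariants, and 2,000-gene
count matrices in triplicate across six groups. These sizes give
binomial standard errors small enough to detect class-proportion biases
of well under one percentage point while keeping the whole suite quick
to run on a laptop.

## 9. Known limitations

* Templated status stops at the hairpin boundary (§1); no genomic
  flank.
* Substitution-only error model; indel noise is out of scope.
* No EM or fractional assignment for multi-mapping read families; reads
  are assigned whole, deterministically.
* `naive_count_test()` is not a differential-expression method.
* No isomiR-level significance testing; comparison is descriptive.
* Secondary structure, arm switching and target re-prediction for
  5′-shifted variants are out of scope.
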