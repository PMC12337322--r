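---
title: "Methods: simulating and decoding duplex CpG states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding duplex CpG states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexCpG)
```

## The duplex state model

A CpG dyad has a cytosine on each strand, and each cytosine is unmodified
(C), 5-methylcytosine (M) or 5-hydroxymethylcytosine (H). The ordered pair
(plus strand first) gives nine duplex states: `MM, CC, MC, CM, HC, CH, HM,
MH, HH`. `HC` carries hmC on the plus strand, `CH` on the minus strand.

Hairpin-linked library chemistry reads each strand twice. The two original
strands are covalently tethered by a hairpin adapter; a copy strand is
synthesized against each original; a maintenance methyltransferase
copy-methylates the copy strand only opposite mC (glucosylated hmC blocks
it); mC and hmC are then protected and every unmodified C is enzymatically
deaminated. Each of the four cytosines at a dyad therefore yields a binary
call — 1 if the base survives as C, 0 if it reads as T — ordered
`(a, d, b, c)`: original plus, copy of plus, original minus, copy of minus.

Per strand, only three call pairs can arise: M gives (1, 1), H gives
(1, 0), C gives (0, 0). A methylated copy over an unmodified original,
(0, 1), has no chemical path. Crossing the two strands, 9 of the 16
possible quads decode to a state and the remaining 7 are implausible;
implausible quads are tallied per site as a quality signal and excluded
from state fractions. `all_call_quads()` materializes the full table and
the property tests assert the 9/7 split, the encode/decode bijection, and
the strand-mirror symmetry (swapping `(a, d)` with `(b, c)` maps `HC` to
`CH`, etc.).

## The forward simulator

`simulate_reads()` draws fragments (truncated-normal lengths, default mean
100 bp, s.d. 10 bp, clipped to [40, 200] bp — the assay's sonication and
size-selection regime), runs the chemistry forward per fragment, and emits
paired reads with a fixed layout:

* Read 1 = insert `a` + intact hairpin adapter + insert `b` + trailing
  cleavage remnant;
* Read 2 = insert `c` + cleavage remnant + insert `d` + trailing intact
  adapter;

both truncated at the read length (default 250 bp, matching a 2 x 250
paired-end run). Adapters appear in deaminated read space. The default
adapters are synthetic 26-mers, C-free, at Hamming distance 23 from each
other, so their read-space form equals their configured form and parsing
can never confuse them; real adapter sequences can be supplied through the
configuration. The cleavage remnant is modeled as a fixed 20 nt suffix of
the cleavable adapter. The remnant functions as a parsing delimiter; at 20
nt the probability of a chance approximate match (2 mismatches) inside a
~100 nt three-letter insert is far below one in a million per read, so the
"exactly one occurrence" retention rule does not erode target yield. A
shorter remnant (say 10 nt) would chance-match in a few percent of reads
and silently discard targets as "ambiguous".

### Error model

`chemistry_errors()` carries one probability per failure mode. Defaults:

| parameter | default | meaning |
|---|---|---|
| `p_fail_deam` | 0.002 | unmodified C escapes deamination (any strand, any context) |
| `p_overdeam_m` | 0.005 | a protected mC reads as T |
| `p_overdeam_h` | 0.01 | a protected (glucosylated) hmC reads as T |
| `p_copy_fail` | 0.01 | maintenance copy-methylation misses a hemi-mCpG |
| `p_copy_spurious` | 0.002 | copy-strand CpG methylated despite C/hmC template |
| `p_seq_err` | 0.001 | per-base substitution on the final reads |
| `dup_rate` | 0.122 | read pair re-emitted (PCR/cluster duplication) |
| `side_product_rate` | 0.165 | pair is a ligation side product |

The duplication and side-product defaults are the two rates the assay
itself quantifies (12.2% average duplication; side products averaging
16.5% of raw reads). The per-step enzymatic efficiencies are not published
for the kit, so those defaults are free parameters chosen at the
conservative end of what the spike-in call-rate floor (every state called
with >94% accuracy) implies: under these defaults the simulated confusion
matrix has its minimum diagonal around 0.96-0.98, comfortably above the
floor, with hmC-containing states the least accurate — the ordering one
expects when hmC protection is the weakest step. They are documented as
free parameters with no claimed fidelity to any particular kit lot.

One ordering subtlety matters: protection (oxidation + glucosylation) acts
*after* copy-methylation, so a methylated copy-strand C is subject to the
same over-deamination risk as an original mC. The copy call is therefore 1
iff copy-methylation occurred *and* the copy mC survives protection.
Without this, mC over-deamination could only produce (0, 1) — implausible
— per-strand pairs and the confusion matrix could never show the MM to
MH/HM leakage that motivates the spike-in correction. With it, MM leaks to
MH + HM at `2 * eps * (1 - eps)^3` (exact per-strand enumeration), which
is the familiar `2 * eps * (1 - eps)` to first order. The internal
`analytic_confusion()` computes the exact 9 x 9 + implausible matrix
implied by any error setting, and the tests hold the sampler to it at
3-s.d. binomial tolerances.

Side products (two adapters of the same type; only single-stranded
information) are emitted as `a` + adapter + `b` with the mate read its
reverse complement; they lack the intact-adapter-in-R1 / remnant-in-R2
configuration and are removed by the filter. Quality strings are constant
Phred 37 — the pipeline never consumes qualities.

## The decoding pipeline

**Filtering and extraction.** A pair is a target iff Read 1 contains the
intact adapter at exactly one position and Read 2 the remnant at exactly
one position, each within 2 substitutions (Hamming matching at every
offset; no indels, since the simulator introduces none — indel tolerance
would be needed for real data). Rejection reasons (`no_adapter`,
`ambiguous`, `incomplete_quad`) are disjoint and logged. Inserts are cut
at the adapter matches; trailing adapters truncated by the read end are
trimmed by longest-prefix match with a mismatch budget that scales with
the matched length (0 mismatches below 8 nt, 1 below 12 nt, then the
configured allowance) so short chance overlaps are not trimmed. Because
the 3'-most inserts (`b`, `d`) can be truncated on long fragments, a dyad
is called only when all four inserts cover it; pairs yielding any empty
insert are discarded.

**Alignment.** Deaminated reads live in a three-letter alphabet, so the
aligner seeds with exact k-mers (default k = 16) on the C-to-T-collapsed
reference — plus strand for `a`, reverse complement for `b` — at up to
three read offsets, then scores candidates full-length under the
asymmetric rule: read T matches reference C or T, read C matches only
reference C, A/G exact. Inserts `c` and `d` are scored at the candidate
locus for complementary consistency but do not seed (the originals
determine the locus). A candidate is accepted if its total mismatch count
is within 10% of scored bases and it is the unique best; ties (for
example a fragment from a perfect repeat) are unaligned rather than
guessed. This is a deliberate desk-scale design: a few-megabase reference
at most, no gapped alignment, no mapping-quality model. The property suite
holds it equal to an exhaustive every-offset scan on small genomes.

**Deduplication.** Coordinate-based, one representative per fragment
interval, the lexicographically smallest read name — deterministic and
idempotent. With duplication on, the post-dedup fragment count equals the
number of distinct true fragment intervals.

**Calling and compilation.** For each deduplicated fragment and each fully
covered dyad, the four insert bases at the dyad's cytosine positions give
the quad (C is 1, T is 0; any other base — a sequencing error to A or G —
skips the dyad for that fragment and is counted). Quads decode to states;
per site the nine state counts, the implausible count, and the
double-stranded depth (their sum — one fragment is one duplex observation,
i.e. two single-strand observations) are tabulated.

## Spike-ins, the confusion matrix, and the linear correction

The spike-in panel is one synthetic ~150 bp duplex per state, four CpGs
each, all dyads of a duplex carrying that duplex's state, sequences free
of adapter substrings. (The real assay's control oligo sequences are not
published in the main text; this panel is synthetic by design.) All CpG
sites of the spike-ins enter the call-rate matrix — no depth or error
filtering, matching how the controls are used.

`build_confusion()` is column-stochastic over the nine called states:
entry (i, j) is the rate at which true state j is called i, conditioned on
a valid (non-implausible) call; the implausible rate is reported per true
state alongside. The orientation is chosen so the correction reads exactly
as the observation model `O = P T`: each observed state fraction is the
additive contribution of all true states through their call rates. Whether
implausible calls belong inside P was genuinely open; they are excluded
here because they are discarded from the observed fractions too, keeping
both sides of the equation on the same support.

`correct_fractions()` solves the 9-equation system by direct `solve()`,
then clamps negative entries to zero. The clamped vector is deliberately
*not* renormalized — the stated procedure is clamping only — and the sum
is reported so the deficit is visible. The estimated condition number of P
is reported; near-singular matrices (more spike-in depth needed) are
refused rather than inverted. Recovery on synthetic systems (random
column-stochastic P with diagonal above 0.9, random simplex T) is exact to
1e-8 in the property tests.

## Site filters and region summaries

`filter_sites()` applies, in documented order: double-stranded depth below
5 (default); overlap with a blacklist BED; more than one implausible quad.
"Multiple calling errors" is interpreted as 2 or more, with the threshold
exposed as a flag; each removed site is counted once under the first
criterion it fails, so the removal reasons partition the removed set.

`site_fractions()` reports per-site percentages over valid calls plus the
grouped asymmetric totals (MC + CM, HC + CH, HM + MH). `region_means()`
averages site percentages within regions; regions containing no CpG are
missing, not zero. `shuffled_background()` re-places each region uniformly
within its own contig, length preserved — plain uniform placement that
does not avoid blacklists or other regions, the shuffle tool's default
behavior. `binned_profile()` anchors at region midpoints (200 bp bins by
default) or rescales bodies to a fixed pseudo-length (5 kb) with unscaled
flanks; empty bins propagate as missing so CpG-sparse regions do not drag
profiles toward zero.

## What the generator does and does not emulate

The synthetic genome plants non-overlapping CpG dyads at a target density
on a CG-free background, so every dyad is known and controlled; states are
assigned i.i.d. from a target composition (the fixture default is shaped
like a primed mESC methylome: 70% MM, 15% CC, small hemi- and
hmC-containing fractions). Real methylomes violate the i.i.d. assumption
— states autocorrelate along chromatin domains, CpG islands are unmethylated
in blocks, and SNPs/indels perturb alignment — and none of that is
simulated. Passing the suite therefore demonstrates that the decoding
chain is correct *given its own read model*; it does not certify accuracy
on real libraries, where indel errors, adapter chimeras and mappability
would need the heavier standard tools.

## Numerical and determinism choices

Every stochastic entry point takes a `seed` and restores the caller's RNG
state, so library code never perturbs a session's stream. Fixture
generation is byte-identical given a seed (uncompressed FASTQ precisely so
that archive timestamps cannot break identity). Tie-breaks are by
lexicographic read name (dedup) or refusal (alignment). Degenerate inputs
fail loud and early: compositions must sum to 1 within 1e-9, adapters
sharing a 12-mer are refused at configuration time, a spike-in state with
zero valid calls names itself in the error.

Problem sizes in the tests and acceptance script were chosen as the
smallest that make the statistical assertions sharp: ~5,600 error-free
read pairs per state for the call-rate floor (binomial noise on a
diagonal entry is then well under a percentage point), 100,000 pairs for
the side-product rate (3 s.d. ~ 0.35 percentage points), 8-10 kb genomes
for end-to-end identity, and 2.5-3 kb genomes where an exhaustive aligner
oracle is the comparator.

## Known limitations

* No CHG/CHH contexts, no 5fC/5caC marks (the chemistry cannot resolve
  them in its current form).
* The aligner is desk-scale by design; real-data work should swap in a
  production bisulfite-style aligner behind the same quad interface.
* The confusion correction is the plain solve-and-clamp; a
  simplex-constrained estimator would be a natural extension but is
  intentionally not the default behavior.
* Side products are modeled as same-adapter constructs carrying only the
  original strands; the real side-product spectrum is broader.
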