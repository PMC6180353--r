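---
title: "Methods: encrypted cohort compression and top-K chi-squared SNP search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: encrypted cohort compression and top-K chi-squared SNP search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptsnp)
```

## The problem

A case-control association screen asks which SNPs differ most in frequency
between genomes of affected (*case*) and unaffected (*control*) individuals.
`cryptsnp` implements this screen for a multi-party setting in which variant
files are compressed and encrypted by their owners and a computation server
processes them while decrypting only inside a narrow trust boundary. The
package models that boundary as an explicit five-call engine interface;
it does not emulate trusted-execution hardware, attestation or key exchange.
What it does implement, end to end and testably, is everything the data
passes through: the variant dialect, the binary packing, the authenticated
block format, the streaming counting engine, the χ² ranking, and a
leakage-conscious survival function.

## The variant dialect

Input files are a restricted 8-column VCF: `##` meta lines, one
`#CHROM POS ID REF ALT QUAL FILTER TYPE` header, then one whitespace-separated
data line per SNP. REF and ALT are distinct symbols from `{A, C, G, T, N}`,
TYPE is `heterozygous` or `homozygous`, QUAL and FILTER are carried but
ignored, and lines are sorted by chromosome then position. The parser accepts
both spaces and tabs and emits tabs; sortedness is enforced as *non*-strict
so that multi-allelic records (equal chromosome and position, different
REF/ALT) are legal. Chromosome symbols map to the 5-bit codes 1–25
("1"–"22", "X" = 23, "Y" = 24, "MT" = 25); positions are taken verbatim
(1-based, as in VCF) and never converted.

## Binary packing (10 bytes per SNP)

Each record packs into an 80-bit word, most significant field first:

| field | bits | content |
|---|---|---|
| CHROM | 5 | chromosome code 1–25 |
| POS | 32 | position |
| ID | 37 | numeric part of the rsID |
| REF&ALT | 5 | ordered-pair code 0–19 |
| TYPE | 1 | 0 = heterozygous, 1 = homozygous |

Bytes serialize big-endian. Two consequences are deliberate: comparing packed
records as unsigned byte strings sorts them by (chromosome, position), and a
file of *m* SNPs always occupies exactly 10·*m* payload bytes. The 20 ordered
non-equal base pairs are enumerated lexicographically in alphabet order
(A, C, G, T, N): `(A,C) = 0, (A,G) = 1, (A,T) = 2, (A,N) = 3, (C,A) = 4, …,
(N,T) = 19`. Any fixed bijection would work; this one is canonical, and it is
part of the on-disk format. IDs that are not numeric rsIDs below 2^37 are
rejected loudly rather than encoded lossily — the dialect only contains
rsIDs, and silently truncating foreign IDs would corrupt data.

## Authenticated block format

Packed SNPs group into blocks of `block_size` consecutive records (default
2080, a common multiple of the 10-byte SNP size and the 16-byte AES block
size; all blocks are full except possibly the last). Each block is encrypted
with AES-128-GCM under a per-block 12-byte IV drawn from the OS random
source, and serializes as

```
count (4 bytes, little-endian) ‖ IV (12) ‖ MAC (16) ‖ ciphertext (10·n)
```

for 32 + 10·*n* bytes total. The count field is authenticated as associated
data: the format leaves it outside the ciphertext, and binding it closes the
trivial attack of truncating a block while rewriting its count. Decryption
either returns the exact payload or raises an authentication error — corrupt
data is never partially returned. The AES-GCM primitive is OpenSSL's
`libcrypto` (EVP), verified in the test suite against the published AES-128
GCM reference vector with associated data.

## The counter tables

Presence counts live in two bounded open-addressing hash tables (CTRL_CNT
and CASE_CNT) keyed by the 42-bit packing of CHROM ‖ POS ‖ REF&ALT — the
rsID and zygosity deliberately do not enter the key, so two lines differing
only in zygosity aggregate into one counter (with increments 1 and 2). Slot
placement is Fibonacci hashing: the key is XOR-ed with a 64-bit mask drawn
once per table, multiplied by `0x9E3779B97F4A7C15`, and the top 22 bits of
the product are reduced modulo the capacity; collisions probe linearly. The
random mask re-randomizes physical slot placement on every run so that
memory access patterns are not repeatable across executions, while the
key → count mapping is provably mask-invariant (tested). Each slot carries
the element state machine empty → update → wait that a concurrent
implementation would synchronize on; execution here is sequential, and the
observable contract — final contents independent of increment order — is
tested directly.

The default capacity of 282914 slots keeps a table (state, key, count per
slot) within a typical 8 MB L3 cache at a moderate fill ratio for
range-sized workloads. Capacity is a performance parameter, never a
correctness bound: a table that fills completely rehashes into twice the
capacity with a warning rather than failing, since other datasets may not
respect the tuning.

## The chi-squared statistic

With `N_ctrl` and `N_case` twice the cohort file counts (each genome carries
two chromosome copies; a homozygous variant counts twice), and pooled
frequency `f = (n_ctrl + n_case) / (N_ctrl + N_case)`, the statistic is
`Σ (O − E)² / E` over

```
O = (n_ctrl, n_case, N_ctrl − n_ctrl, N_case − n_case)
E = (N_ctrl·f, N_case·f, N_ctrl·(1 − f), N_case·(1 − f))
```

which is algebraically the standard 2×2 Pearson statistic
`N (ad − bc)² / ((a+b)(c+d)(a+c)(b+d))` with one degree of freedom — the
test suite checks agreement to 1e-9 relative over random tables, plus label
symmetry and the exact-doubling scale property. Degenerate tables (`f` of 0
or 1) carry no discriminative information and are defined to score 0.
Ranking is by *largest* statistic, i.e. smallest p-value, the standard
significance direction; `ranking = "smallest_stat"` flips it for
completeness, and the output TSV header always records which convention
produced it. No continuity correction or multiple-testing adjustment is
applied — the method reports raw per-SNP statistics.

## The survival function and its access pattern

P-values require the df = 1 χ² survival function, which has no closed form
usable under a no-data-dependent-branching constraint. The package tabulates
it at `n_grid` equally spaced points on `[0, x_max]` and answers queries by
locating the bracketing cell and integrating the residual with the
trapezoidal rule in the transformed variable `t = √x`, where the integrand
becomes the half-normal density `√(2/π)·exp(−t²/2)` — the substitution
removes the `x^(−1/2)` singularity of the density at the origin.

Two numerical choices matter:

- **Uniform-in-t build refinement.** The x-grid is uniform, so cell widths in
  t shrink like `1/√x`; integrating every cell with the same number of
  sub-steps would concentrate error in the wide head cells and — because grid
  values accumulate — bury the tiny tail values under ~3e-7 of head error.
  The build therefore spends its sub-step budget uniformly in t (equal step
  size everywhere, same total work), which keeps the absolute error under
  1e-6 everywhere on the grid and the tail floor near 4e-12. Tail values are
  additionally accumulated from the far end so they stay strictly decreasing
  down to `x_max` in double precision.
- **Fixed-step oblivious queries.** Every query scans the full grid and
  selects its base value by branch-free arithmetic weighting, then refines
  with exactly `refine_steps` trapezoid sub-steps, whatever the input: the
  sequence of table positions touched and the arithmetic step count are
  input-independent (exposed and tested via `access_log = TRUE`).

Defaults are `x_max = 64` (true survival ≈ 1e-15, far below any ranking
difference of interest), `n_grid = 1024`, and `refine_steps = 64` — 64
rather than a smaller count because the composite trapezoid error of a query
in the widest (first) cell scales with the square of its sub-step width, and
32 sub-steps would leave the worst-case absolute error marginally above the
package's 1e-6 accuracy contract. Consequences to know: reported p-values
are absolutely accurate to ~2e-7 near the head and floor at ~4e-12 in the
deep tail, so extremely significant SNPs may print near-identical p-values.
Ranking is unaffected — it orders by the statistic and computes p-values
only for the final K entries, exactly once, after the scan terminates.

## The streaming engine

The engine mirrors a five-call interface: create (`snp_engine()`), register
(`register_cohort()`), then per iteration begin/run/end
(`next_range()` / `consume_range()` / `end_range()`), driven to exhaustion by
`run_search()`. Registration memorizes file paths with their control/case
flags, indexes each file's block framing, and fixes `N_ctrl`/`N_case`.

Each main-loop iteration processes one horizontal SNP range. The first
registered file is the reference: a range spans up to `range_blocks`
(default 4) of its blocks, starting at its first unconsumed SNP and ending
*inclusively* at the (chromosome, position) of the last SNP of the last
block — inclusive so that multi-allelic records at the boundary position in
other files are not split from their locus. Every file is then consumed up
to the range end. Cursors store a block index *plus an intra-block offset*:
ranges are defined by one file's positions, so a block of another file can
straddle the boundary, and the offset lets it be split logically without
re-counting on resume. Two rules the range definition forces:

- **Final sweep.** SNPs in other files positioned after the reference file's
  last SNP (or on chromosomes it lacks) belong to no reference range; after
  the reference file is exhausted, one terminal open-ended range sweeps up
  everything remaining. Without it such SNPs would silently never be
  counted.
- **Exactly-once counting.** Because ranges partition (chromosome, position)
  space and cursors never move backwards, each SNP line contributes exactly
  once; the suite checks total counted mass against the sum of per-file
  `2·hom + het` line counts.

At `end_range()` every key present in either table is scored (a key absent
from one cohort counts 0 there), merged into the global top-K — ties broken
by ascending (chromosome, position, REF&ALT code), which the 42-bit key
order gives directly — and both tables are cleared. The result is invariant
to block size, range width, table capacity and hash mask; the suite asserts
byte-identical outputs across block sizes {13, 160, 2080} × range widths
{1, 4, 7} and agreement with a naive oracle that decrypts everything up
front and builds one global pair of maps.

## The synthetic cohort generator

`generate_cohort()` emulates the shape of a real screening dataset: a shared
template of `n_snps` sorted, rs-numbered sites on chromosomes 1–22 with
random non-equal REF/ALT pairs; each file includes site *i* independently
with its cohort's carrier probability, homozygous with probability
`hom_fraction`, independently per file. `n_planted` sites receive
cohort-specific carrier probabilities; the rest share a background
probability. The truth table records, per site, the exact expected presence
counts `files · p · (1 + hom_fraction)` (a carrier contributes 1 if
heterozygous, 2 if homozygous) and the χ² statistic evaluated at those
expectations, which predicts the ranking of planted against background
sites. The seed fully determines the output, byte for byte.

Defaults (50 + 50 files, 1000 sites, 5 planted at 0.1 vs 0.9 carrier
probability, 0.3 background, 0.3 homozygous fraction) describe a cohort in
which planted effects clearly dominate sampling noise; the recovery property
the suite checks — the planted site ranks first in ≥ 99 of 100 seeded runs
at 100 sites per template — runs at exactly those carrier conditions.

What the generator does *not* model, and what passing tests therefore do not
show about real data: linkage disequilibrium between sites, realistic
allele-frequency spectra, population stratification, genotyping error, or
indels and multi-nucleotide variants. The analysis itself uses none of that
structure, but real-data significance claims would need to account for it.

## Problem sizes and runtime choices

The test suite exercises: codec round trips over 10^4 random records;
1000 random bit-flips over 50 blocks (100% rejection required); counter
workloads of 10^5 operations against a naive map; 10^4 random contingency
tables against the closed form; 50 random cohorts of 5–40 files and
100–5000 sites against the full-decrypt oracle; the 3 × 3 partition
invariance grid on a 3000-site cohort; and 100 seeded planted-effect runs
at 50 + 50 files. These sizes were chosen so the complete suite runs in a
few minutes on one CPU while every property is exercised well past its
interesting regime (multiple blocks per file, multiple ranges per run,
straddling blocks, hash collisions, rehashing).

## Known limitations

- The binary format is lossy outside the dialect: non-rsID identifiers and
  contigs beyond the 25 codes are rejected, not encoded.
- Keys are held in ordinary R memory; key hygiene (zeroization, hardware
  sealing) is out of scope, and passing keys on a command line is
  acceptable only for research use.
- Obliviousness claims are algorithmic (position sequences and step counts),
  not micro-architectural; no cache- or timing-level guarantees are made or
  measured.
- The engine is sequential; the counter table's element states express the
  synchronization contract a threaded port would need, but no threaded
  execution path is provided.
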