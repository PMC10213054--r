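---
title: "Coding and decoding DNA data storage from CTC posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding and decoding DNA data storage from CTC posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligostore)
```

## The storage model

A byte stream is stored as a pool of short synthetic oligonucleotides and
read back by nanopore sequencing. Two error processes dominate: per-base
errors inside a read (substitutions, insertions, deletions at several
percent), and the loss of whole oligos (synthesis dropout, sampling).
The package layers two codes against them:

* **Inner code, per oligo.** Each segment message — a fixed-width index,
  a data field, and an 8-bit CRC — is encoded by a feed-forward
  convolutional code of memory $m$ (state = the last $m$ input bits) at a
  mother rate of 1/2, punctured up to rate $r \in \{1/2, 2/3, 3/4, 5/6,
  7/8\}$, then mapped to bases at 2 bits/base (00:A, 01:C, 10:G, 11:T).
  Decoding failures that survive the convolutional decoder are caught by
  the CRC and the read discarded, which turns residual read errors into
  erasures.
* **Outer code, across oligos.** Each byte position across the $k$ data
  segments of a block is a Reed–Solomon codeword over GF(256) extended by
  $p$ parity bytes, so any $k$ of $k+p$ segments recover the block.
  Erasure-only decoding is implemented by Lagrange interpolation; blocks
  are interleaved round-robin over segment indices so a run of adjacent
  dropouts spreads across blocks.

Payloads are whitened (XOR with a seeded LCG keystream) before
segmentation. This stands in for the compression-plus-encryption a real
archive would apply: it makes the encoder input look random and keeps
mapped bases free of long homopolymers. It is invertible and adds no
secrecy.

## Decoding directly from CTC posteriors

The decoder's input is not a basecalled string but the basecaller's CTC
posterior: a $T \times 5$ row-stochastic matrix over (blank, A, C, G, T).
A base sequence's probability is the sum over all state paths that
collapse to it (runs of equal states merge, blanks separate runs). The
core routine, `conv_ctc_list_decode()`, runs a dynamic program over joint
trellis states *(convolutional-code state, position in the base
sequence)*: at each time step a state's candidates may absorb a blank,
repeat their last base, or extend by one base — but only by bases
consistent with some input-bit extension of the code. Per state the top
$L$ candidate message prefixes are kept, each with separate blank-ending
and non-blank-ending path masses merged by logsumexp as paths recombine.
At the end, the $L$ best full-length messages ending in the all-zero
state are returned and CRC-checked; `crc_filter()` accepts the best
passing candidate. $L = 8$ is the default; the list buys a second chance
when the single best path is wrong, at linear cost in $L$.

Puncturing makes the correspondence between encoder steps and bases
non-uniform: one base (2 transmitted bits) can span two encoder steps,
leaving one "pending" transmitted bit that is folded into the node
identity of the next position (`build_base_trellis()`). When the
transmitted bit count is odd, the final base is completed with a fixed
pad bit, recorded in the manifest.

### Numerical choices

* Probabilities are floored at $10^{-12}$ before the log transform so a
  structural zero cannot poison a whole path.
* Ties in candidate score break toward the lexicographically smaller
  message; the hard-decision Viterbi decoder keeps the smaller
  predecessor state, so a fully erased input decodes to the all-zero
  message. Both rules make lists reproducible.
* Beam/list pruning happens after, never before, the blank/non-blank
  merge of a step.
* The search front is bounded by `prune_margin` (drop candidates more
  than that many log units below the step's best; default 25) and
  `max_active` (hard cap, default 50,000). Both are exactness knobs, not
  model parameters: set them to `Inf` for exact list decoding on small
  problems, as the oracle-equivalence tests do. The experiment studies
  in the test suite use a margin of 18–20, which costs a few points of
  decoded fraction but keeps a 500-read study in minutes on one CPU.

### Why the CRC init is 0xFF

A CRC with polynomial 0x07 and *zero* initial value is shift-invariant:
if $f(x)$ is a multiple of the generator then so is $x\,f(x)$ when the
shifted-out bit is zero. Misaligned payload windows — a trimming error of
one base — make the list decoder produce exactly such bit-shifted frames,
and during development these passed the zero-init CRC far above the
$2^{-8}$ collision floor (about 17% of failed decodes in one seeded run).
A nonzero init term scales with $x^{\mathrm{len}}$ and breaks the
invariance, so the default is init 0xFF, polynomial 0x07, final XOR 0 —
still configurable per experiment and recorded in the manifest. The
two-CRC-per-oligo variant (one per half, a read usable when either half
verifies) is implemented as `crc_spec(segments = 2)` but off by default;
it gave only marginal gains in practice.

## Trimming

Primers (25 nt on both flanks) are located on the greedy basecall by
local alignment (match +1, mismatch −1, gap open −2, extend −1). Primer
bases missing from the alignment are penalized at 0.5 per base — *except*
bases that fall off the read boundary, which instead shrink the
attainable score the 60%-of-maximum acceptance threshold is measured
against. This keeps genuinely clipped primers on truncated reads while
rejecting spurious short matches in the read interior. A forward hit
starting more than 30 nt into the read flags
`start_late_chimera_suspect` (chimeric reads carry a foreign fragment
before the true start) but is still trimmed at that hit. The posterior
rows between the trimmed primer bases — including the flanking blank
rows — form the decoder's window. Coordinates are 0-based, half-open
throughout.

## The synthetic channel

`simulate_posterior()` models the *basecaller's output*, not raw current:
the decoder consumes posteriors, so this is the interface that matters,
and it keeps everything desk-scale. Per true base the channel draws a
geometric dwell (mean `dwell_mean = 2.5` rows) of rows favoring that
base; a blank row separates equal neighbours always (so the collapse
cannot merge them) and different neighbours with probability
`blank_bias = 0.5`. Substitution, insertion and deletion events
(`sub_rate`, `ins_rate = 0.013`, `del_rate = 0.019`) perturb which base a
dwell favors or whether it exists; by default the three rates sum to
`target_error_rate = 0.055`. Rows are softmax draws with a logit
advantage of 6.5 for the favored state plus Gaussian noise scaled by
`confusion_temperature` (default 1, at which the soft noise adds almost
nothing); raising the temperature flattens rows and raises the greedy
error monotonically. The defaults were chosen once by a Monte-Carlo
calibration so the mean greedy-basecall edit error over 1,000 synthetic
100-nt reads falls inside 4.5–7%, the window reported for the targeted
flowcells; the suite asserts the window, not a point value.

Coverage skew is lognormal (log-sd 0.5) by default, emulating the
elevated coverage variance of bead-bound pools; `uniform` emulates an
aqueous control. Dropout zeroes an oligo's weight with probability
`dropout_prob`; chimeras prepend a random fragment of another oligo to a
`chimera_rate` fraction of reads.

What the channel does *not* model: raw-signal artifacts with long-range
structure, pore-specific context biases, quality drift over a run, and
strand effects (the simulator emits forward-strand reads; a
reverse-complement pre-pass is available behind a flag). Passing tests
on this channel show the coding stack is correct and well-behaved under
calibrated synthetic noise — not that real-flowcell performance numbers
are reproduced.

## Combinatorial barcode addresses

`design_barcode_set()` rejection-samples random 20-mers so that no two of
the 55 accepted sequences (48 barcodes + 7 scaffolds) share any 9-mer;
every 20-mer then contributes exactly 12 distinct 9-mers. Barcodes are
assigned 8 per subunit in order; a 6-digit octal address selects one
barcode per subunit, flanked by the constant scaffolds
(`assemble_cba()`), giving $8^6 = 262{,}144$ addresses from 48 subunit
oligos. Decoding counts shared 9-mers between each subunit window and its
8 candidate barcodes; windows are cut between consecutive scaffold anchor
midpoints with ±5 nt slack (the anchor positions come from scaffold
k-mer hits, with missing anchors interpolated from the designed layout —
window extraction is a package choice, as is forward-strand-only k-mer
matching after orientation by trimming). The *strict* inclusion
criterion — every other candidate must score zero k-mers at every
subunit — is the rule used to build ground-truth lookup tables; best-match
mode calls the argmax with ties refused. From an observed full-address
success rate $s$ over $n$ independent subunits,
`per_subunit_failure()` inverts the independence model as $1 -
s^{1/n}$.

Hierarchical retrieval is modeled as a deterministic gain/leak
recurrence, not PCR biochemistry: each of the six rounds multiplies
matching constructs by `gain` (default 500) and non-matching ones by
`gain * leak` (default leak 0.05), then renormalizes to mimic dilution.
With the defaults, a uniform pool of 10,000 random addresses enriches
the target by more than four orders of magnitude over the median — the
same regime as the bead experiments the model abstracts.

## Costs

Writing cost is bases synthesized per information bit, reading cost is
bases sequenced per information bit, primers excluded from the oligo
length; coverage = reading ÷ writing, coding density = 1 ÷ writing. (One
printed formula in the source literature computes the reciprocal,
bits/base; the prose convention — bases per bit — is the one implemented,
with density exposed separately.) `min_reads_for_decode()` subsamples the
decoded read set on a geometric grid (×1.25) refined by bisection, with
$N = 10$ seeded trials per size; the minimum is the smallest size at
which *all* trials recover the file byte-exactly — the strictest reading
of "minimum required coverage", fixed here deliberately.

## Problem sizes used by the test suite

The suite is sized for a single CPU: round-trip properties run 1,000
messages across the full $m \times r$ grid; oracle equivalence uses
$m = 2$ codes with 12-bit frames so all 4,096 codewords can be scored
exhaustively (100 seeded instances); the monotonicity study uses a
24-byte payload, 48-bit frames and 500 reads per configuration; channel
calibration uses 1,000 reads of 100 nt; end-to-end cost experiments use
128-byte payloads at 150–200 reads. The cost experiment at memory 8,
rate 3/4 lands at a writing cost near 1.2 bases/bit and a single-digit
reading cost; the slower memory-11, rate-3/4 code reaches reading costs
near 4.6 bases/bit at 3.8× coverage in the same setup.

## Known limitations

* The exact generator polynomials and puncturing patterns of the
  original pipeline live in prior work; this package uses published
  maximum-free-distance polynomials (133/171, 561/753, 5537/6131 octal)
  and standard rate-compatible patterns, so bitstream parity with any
  particular historical pool is not promised — only the architecture.
* Reed–Solomon decoding is erasure-only by design; CRC-failed reads are
  discarded rather than error-corrected.
* The trellis assumes a two-stream (rate-1/2) mother code.
* `min_reads` depends on the decoded read set's composition; with heavy
  coverage skew the subsample curve can be noisy near the threshold.
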