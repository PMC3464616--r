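---
title: "The SOLiD two-base and Exact Call Chemistry code: model, decoding and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SOLiD two-base and Exact Call Chemistry code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solidecc)
```

## The code behind the chemistry

The SOLiD platform does not read bases.  Each ligation probe interrogates a
window of the template and fluoresces with one of four colors, so the primary
output is a *color sequence* — an encoded form of the nucleotide sequence.
`solidecc` treats this encoding as what it mathematically is: a punctured
convolutional code over the four-element field GF(4).

Bases `A, C, G, T`, colors `0–3` and field elements `0, 1, alpha, beta` are
three labellings of the same four objects (internally coded as integers 0–3).
With this labelling, addition is XOR — the field has characteristic 2, so
every error is removed by applying it a second time — and multiplication is a
4×4 table.  Additive error offsets have concrete meaning in base space: `+1`
preserves amino/keto class ("transcomplement"), `+alpha` is a transition,
`+beta` a complementation.

A probe set is summarised by its **probe generator**, five GF(4) coefficients
`p1..p5`: the probe covering window `b` reports the color `sum(p_i * b_i)`.
The two-base chemistry is `11000` (adjacent-pair sums); the Exact Call
Chemistry (ECC) round is `1b0b0`, interrogating positions 1, 2 and 4 of each
five-base block and emitted only once per block (puncturing period 5).

A `k`-base read therefore becomes `n = 6k/5` colors: `k` two-base colors (the
first formed against the known adapter base) plus `k/5` second-stream colors.
Per five-base block, five *data colors* `c1..c5` determine the block's bases
through an invertible 5×5 block generator (columns 1–4 are the within-block
adjacent-pair sums, column 5 the probe coefficients); the junction colors
straddling neighbouring blocks are *parity colors* (`p-`/`p+`).  The block
generator is invertible exactly when the GF(4) sum of the probe coefficients
is nonzero, and its inverse has a closed form which the package uses and
verifies against Gaussian elimination in the test suite.

```{r}
gen <- block_generator(ecc_probe())
gf4_to_colors(encode_block("ACGAT", gen))
gf4_to_bases(decode_block("13233", gen))
```

Stacking block generators block-diagonally and appending one parity column
per junction gives the full generator `G = [G* | P]`; the parity-check matrix
`H` inverts the observation block by block, recomputes the junction colors the
putative decoding implies, and adds the observed ones.  A valid codeword has
the all-zero syndrome, and because the code is linear the syndrome depends on
the error pattern only.

### Coordinates and conventions

* All user-facing coordinates are 1-based.  Codeword positions run data
  colors first (block-major, `c1..c5` per block), then junction parities
  `j1..jm`.
* The first two-base color is formed against the adapter base (default `T`,
  the CSFASTA convention; configurable, since the platform's choice is a
  run-level detail).  Its known offset is subtracted before any syndrome
  computation, which makes the adapter junction an honest upstream parity
  check for block 1 while keeping `G` a pure function of the source.
* Read lengths must be multiples of 5; partial blocks are rejected rather
  than padded, matching the platform's 50/75-base reads.
* Matrix orientation is row-vector times matrix throughout (`c = s G`,
  `sigma = x H`).

## Syndrome analysis

Each block interacts with exactly two syndrome components — the junctions
overlapping its first and last base — so single-error behaviour is a
per-block question.  `single_error_syndrome()` gives the (upstream,
downstream) pair for any position and error type; `equivalence_classes()`
groups positions that share a pair.  Singleton classes are unambiguously
correctable; for the ECC generator only `{c5}` is a singleton, while
`{c1, c4, p+}` and `{c2, c3}` can only be localised to two or three
positions.  Three of the fifteen nonzero pairs go unused by the ECC
generator, which is why alternative probe generators (`1b010` uses all
fifteen and splits the big class) can correct more.

When an ambiguous error is "corrected" at the wrong position, the decoded
bases differ from the truth by `d %*% inverse`, where `d` is the data-color
difference — a pattern that depends only on the two positions and the shared
error type, never on the sequence.  `miscorrection_pattern()` and
`analyze_code()` reproduce the full pattern tables; for the ECC generator the
patterns are `00100`, `00001`, the triple `01110` and the quadruple `01111`
(scaled by the error type), and no pattern ever touches the first base of a
block.

```{r}
analyze_code("1b0b0")$patterns
```

### Hard-decision decoding

`build_syndrome_table()` enumerates error vectors of weight 1 then weight 2
over the whole codeword and maps every reachable syndrome to its
minimal-weight candidates.  Weight 2 is the default depth: single errors per
block are the analysis unit, weight-2 entries expose the cross-block
ambiguity structure, and deeper enumeration grows combinatorially while the
reads the code can genuinely rescue are the sparse-error ones anyway.
`syndrome_decode()` then:

* applies a unique minimal-weight candidate directly;
* on ties, uses per-color qualities when available (the candidate whose
  positions are least reliable wins — the same information MAP decoding
  uses), otherwise applies the first candidate in deterministic (position,
  offset) order and flags the block `ambiguous`;
* flags syndromes absent from the table `uncorrectable` and returns the
  uncorrected block-wise decoding.

Two behaviours deserve explicit documentation because they bound what
correction can achieve.  First, the **final block** has no downstream
junction; single errors at its `c1` or `c4` produce an identically zero
syndrome and are invisible to the parity check, not merely ambiguous.
Second, errors in **adjacent blocks** interact through their shared junction:
two `c5` errors in neighbouring blocks produce a composite syndrome with
several weight-2 explanations, so the "one error per block is fine" intuition
holds cleanly only for blocks that do not share a junction.  The test suite
pins both behaviours down.

## Soft-information trellis decoding

Quality scores carry the information hard decoding throws away.  The decoder
runs on a trellis whose state is the four most recently emitted bases (256
states once the read is under way); each transition appends a base, emits the
two-base color against the previous base, and every fifth step additionally
emits the second-stream color of the completed block.  Observed colors enter
through `eps = 10^(-Q/10)`: a call matches the emitted color with probability
`1 - eps` and is otherwise uniform over the three wrong colors.  Missing
calls (`.` in CSFASTA) contribute a flat likelihood.

* `viterbi_decode()` returns the maximum-likelihood sequence.  It runs a
  backward max pass followed by a forward greedy pass that always takes the
  smallest base still admitting an optimal completion, so ties resolve to the
  lexicographically smallest optimal sequence (base order `A < C < G < T`).
  Ties are structural, not numerical: two candidate sequences can mismatch
  the observation at exactly the same positions.  Optimality is compared with
  an additive tolerance of 1e-9 because floating-point sums accumulated in
  different orders tie only approximately.
* `posterior_decode()` runs scaled forward–backward under a uniform prior
  over source sequences (the prior is not specified by the chemistry; uniform
  is the natural choice and is documented here) and returns exact per-position
  marginals, the argmax call and a Phred-scaled confidence
  `-10 log10(1 - p_max)`, rounded and capped at 60 — beyond that the
  distinction is numerically meaningless at read scale.
* Error probabilities are clamped to `(1e-10, 1 - 1e-10)` so log-likelihoods
  stay finite at read length 75; accumulation is done in the log domain
  (Viterbi) or with per-step normalisation (forward–backward).
* The first transitions constrain only bases actually in the read: the state
  is seeded from the known adapter base alone, and the second-stream emission
  first fires at step 5, when a full block exists.

Both decoders are verified against brute-force enumeration of all `4^k`
candidate sequences at `k = 5` (marginals to 1e-9) and spot-checked at
`k = 10`.

## Coding bounds

The bounds module asks what any code with the ECC's dimensions could achieve.
All arithmetic is exact: quantities such as `4^90` overflow doubles, so the
module carries a small exact integer layer (base-1e7 limb vectors with add,
multiply, exact small division, compare and power) rather than floating
point.

* **Hamming**: the largest `t` with `V(n, t) <= q^(n-k)`, where `V` is the
  Hamming-ball volume.  For 50 bases in 60 colors no code guarantees more
  than 3 corrections; for 75 in 90, no more than 4.
* **Gilbert**: the package uses the Gilbert form of the existence bound — a
  code of size `M` exists when `M * V(n, d-1) <= q^n` — because it is the
  form whose conclusions are stated for these parameters (distance 4 at
  (60, 50): correct one error while detecting two; distance 5 at (90, 75):
  detect and correct any two).  The strictly stronger Varshamov linear-code
  form is also provided, clearly labelled, and gives distance 5 at (60, 50).
* **Johnson**: the bound family has several variants and the variant in use
  is documented in the function: the anticode/Plotkin recursion
  `A_q(n,d) <= q^(n-n0) * floor(qd / (qd - (q-1) n0))` with
  `n0 = floor((qd-1)/(q-1))`.  It is exact on tiny checkable cases
  (`A_2(4,4) = 2`) and never the binding bound for the parameter sets of
  interest; the Hamming bound is, and the test suite checks that rather than
  assuming it.
* `distance_capabilities()` translates a minimum distance into guaranteed
  correction/detection counts (`floor((d-1)/2)`, `d-1`, and the simultaneous
  pairs `c + e <= d - 1`).

```{r}
bounds_table(60, 50, 4)
```

## The read simulator

`simulate_reads()` follows a five-step scheme: sample fragments uniformly
from the positive strand of a reference; mutate bases independently
("generalised error" — pre-encoding damage such as polymerase error, which no
code can correct and which caps platform accuracy); encode; attach per-color
qualities; miscall each color with the probability its quality implies,
drawing the wrong color uniformly from the three alternatives.

Default study conditions, fixed once:

* fragment length 50 bases (10 blocks), reference length 10,000;
* generalised error `10^-3.4` per base — the Q34 equivalent typical of
  prepared samples;
* a synthetic quality profile declining linearly from Phred 30 on the first
  ligation cycle to 15 on the last, with configurable per-round offsets
  (defaults 0).  Errors concentrate in late cycles on the real instrument but
  no profile is published, so the decline is a modelling choice; real QUAL
  files can be supplied instead, in which case one quality vector is sampled
  per read (per-read sampling keeps within-read cycle structure intact,
  which per-position pooling would destroy);
* the substituted base in a generalised error is uniform over the three
  alternatives (the substitution kernel is otherwise unspecified);
* a mandatory seed from which every random draw flows, making reruns
  byte-identical.

`run_experiment()` decodes the simulated reads (syndrome, Viterbi, MAP, or
nothing) and tallies per-read errors directly against the known truth — the
original fragment in base space, its clean encoding in color space — so
generalised errors count as errors, as they would against a reference.
Evaluation by alignment to a real genome is deliberately out of scope:
mapping percentages depend on the genome, the aligner and real run files, and
direct truth comparison measures the same correction behaviour without those
confounders.

```{r}
res <- run_experiment(sim_config(n_fragments = 500, seed = 1), "syndrome")
res
```

The undecoded base-space row shows why the encoding exists at all: naive
integration of the two-base stream turns one early color error into errors at
every downstream base, while ECC decoding confines damage to block-local
patterns.

### What the simulator does and does not emulate

It emulates independent per-color miscalls at realistic, cycle-declining
rates, pre-encoding mutations, and the puncturing/block structure of the
chemistry.  It does **not** simulate insertions or deletions (rare, and
mostly sample-preparation artefacts), correlated or burst errors (bad washes,
round failures), genomic repeat structure (the synthetic reference is
i.i.d.), or the physical round/cycle interleaving of the instrument.  Passing
simulation tests therefore demonstrates the coding-theoretic behaviour of the
decoders under the stated error model — not end-to-end accuracy on real runs,
where error correlation within rounds is the main unmodelled threat and would
degrade correction (bursts within a block are exactly what the code cannot
fix).

## Problem sizes and numerical choices, in one place

* Test and demonstration runs use `k = 5..50` and 150–2,000 reads per
  condition (10 × 1,000 for the paired-seed correction comparison); these
  sizes give stable fractions while keeping the whole suite fast.
* Syndrome tables default to weight 2; entries are ordered (position, then
  offset), so candidate choice is deterministic.
* The all-zero syndrome is never a correction target; it is what "valid"
  means.
* Exact integer arithmetic in bounds; XOR-based field arithmetic elsewhere;
  the only tolerances in the package are the trellis tie tolerance (1e-9)
  and the epsilon clamp (1e-10), both discussed above.

## Known limitations

* Final-block `c1`/`c4` single errors are undetectable, and adjacent-block
  error pairs can defeat correction (both documented above and pinned in
  tests).
* Hard-decision decoding beyond weight-2 syndromes reports `uncorrectable`
  rather than searching deeper.
* Probes longer than five bases, more than one extra round, unpunctured
  second streams, and syndrome-guided trellis pruning are out of scope.
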