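---
title: "Strand-concordant SNV calling for multiplexed nanopore construct verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-concordant SNV calling for multiplexed nanopore construct verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoverify)
```

## The problem

Synthetic-biology build pipelines assemble hundreds of multi-kilobase DNA
constructs per week, and every construct must be sequence-verified before it
is used. Nanopore sequencing of barcoded PCR amplicons is cheap and fast,
but single-pass nanopore reads carry 5–15% error. Simple pooled consensus
removes most random error at modest depth, yet *systematic* miscalls — bases
that the basecaller gets wrong reproducibly in a given sequence context —
survive arbitrary depth and masquerade as single-nucleotide variants.

The key empirical observation this package builds on is that systematic
miscalls are strongly *strand-biased*: the two strands of an amplicon
traverse the pore as different sequences, so a context that confuses the
basecaller on the forward strand is usually read correctly on the reverse
strand. A genuine mutation, by contrast, is present in the molecule itself
and appears concordantly on both strands.

## The model

For each target position and each strand $s \in \{\mathrm{fwd},
\mathrm{rev}\}$ the aligner produces counts $k_b^{(s)}$ over the five
symbols $b \in \{A, C, G, T, \texttt{-}\}$ (deletion is a first-class
symbol), with strand depth $n_s = \sum_b k_b^{(s)}$. Under the hypothesis
that the true base is $b$, each observation is correct with probability
$1 - e$ and otherwise one of the four other symbols, uniformly:

$$\log L_s(b) = k_b^{(s)} \log(1 - e) \;+\; \bigl(n_s - k_b^{(s)}\bigr)
\log(e/4).$$

This is the binomial collapse of the per-strand multinomial; the
combinatorial coefficient is constant across hypotheses and omitted. Depth
enters the log-likelihood linearly, so each strand's evidence is implicitly
weighted by its read count. With a prior $\pi(b)$ (uniform by default) the
per-strand posterior is $P_s(b) \propto \pi(b) L_s(b)$.

Calls are then gated categorically:

* **LOW_DEPTH** — either strand below `min_depth` (default 5): template
  base retained.
* **STRAND_BIASED** — the strand argmax bases disagree (or tie within a
  strand): this is the signature of a systematic error; the template base
  is retained because the template is the most likely explanation of
  discordant data.
* Concordant strands are combined,
  $P(b) \propto P_{\mathrm{fwd}}(b)\,P_{\mathrm{rev}}(b)$, and a
  non-reference base is reported as an **SNV** only when $P(b) \ge \tau$
  (default 0.99). A concordant non-reference base below $\tau$ is kept as
  REFERENCE with a `subthreshold` flag.

Runs of concordant deletion calls are merged into single indel records.
Insertions have no per-position count slot in the pileup, so they use a
separate concordance rule: an inserted sequence is reported only when seen
on both strands at ≥ 50% of the respective strand depth at its anchor.

### Parameter defaults

| parameter | default | meaning |
|---|---|---|
| `e` | 0.10 | per-base error rate; midpoint of the 5–15% nanopore range. `estimate_error_rate()` offers run-internal calibration from concordant-reference positions. |
| `tau` | 0.99 | combined posterior needed to report an SNV |
| `min_depth` | 5 /strand | below this, no call is attempted |
| `max_dist` | 6 | per-barcode edit tolerance in demux (25% of a 24-mer) |
| `min_margin` | 2 | required gap to the runner-up sample in demux |
| match/mismatch/gap open/gap ext | +2/−3/−4/−2 | long-read-tolerant semi-global scoring |

## Barcode design and demultiplexing

Plate/well identity is encoded by a pairwise (asymmetric) scheme: the
forward primer carries a 24-nt plate barcode, the reverse primer a 24-nt
well barcode, each followed by a universal binding site, so 6 × 96 barcodes
address 576 wells (12 × 96 = 1152 with extra plate barcodes). Candidates
are drawn at random within 30–70% GC, ranked by a secondary-structure
proxy, and selected greedily under a pairwise Levenshtein-distance
constraint (≥ 8 of 24 by default) that is not part of the original design
procedure but is what makes error-tolerant demultiplexing provably
separable at nanopore error rates.

The structure score substitutes for a nearest-neighbour folding
calculation: it enumerates maximal self-complementary stems (length ≥ 4)
and scores −2 per stem base pair, −3 extra for stems touching a sequence
terminus. The terminal penalty applies at *either* terminus so that the
score is invariant under reverse complement — a 3′-only penalty would break
that symmetry, because reverse complementing maps the 3′ end onto the 5′
end. The score is a ranking device, not a free energy; it orders sequences
by hairpin/dimer propensity and nothing more.

Demultiplexing aligns each barcode semi-globally (infix Levenshtein)
against a terminal window of the read in both read orientations, and
assigns the sample with the lowest combined distance only if both barcode
distances are within `max_dist` *and* the runner-up combination is at least
`min_margin` edits worse. Ties are never guessed: for verification work a
lost read is cheap and a misassigned read is expensive. Note the margin
rule guarantees separation only while the true barcodes are themselves
readable; a read whose own barcode accrues more than `max_dist` errors can,
very rarely (order 1 in 10⁴ at 15% error), chance-match a different
barcode. This tail is documented rather than hidden.

## Alignment

Reads are trimmed of primer sequence using the demux match offsets and
aligned with an internal banded, ends-free, affine-gap aligner (gap of
length $k$ costs $-4 - 2k$; leading/trailing gaps in either sequence are
free). The band is centred on the main diagonal and widened automatically
(up to 4× the initial width) if the optimal path touches the band edge.
The banded implementation is checked against an unbanded full-matrix DP
oracle in the test suite. SAM files from an external aligner can be
imported (`import_sam()`) for parity with a BWA-MEM-based toolchain.

## What the simulator emulates — and what it does not

`simulate_reads()` produces full-length amplicon passes with flat,
independent per-base substitution/insertion/deletion rates, exact
per-strand read counts, true variants applied to both strands, and
systematic error sites that fire at a configurable rate on one strand
only. That is precisely the structure the caller exploits, so a green test
establishes that the statistical machinery does what it claims *under this
error model*. Real nanopore data additionally show homopolymer-dependent
indel inflation, correlated errors, chimeras and quality-score structure —
none of which are modelled, and none of which the calling model consumes.
Conclusions about real-data performance therefore rest on the published
experiments, not on these simulations.

Simulation defaults mirror the stated experimental world: 23 forward + 23
reverse reads (the lowest depth observed to verify a construct was 46
total), 10% total error split 7% substitution / 1.5% insertion / 1.5%
deletion, 2 kb desk-scale templates. The strand-bias rejection benchmark
uses 250-nt templates carrying 8 single-strand sites at rates 0.85–1.0
with independent per-strand depths 10–50: high-frequency single-strand
miscalls with realistic strand imbalance. Site placement guarantees the
single-strand premise: two opposite-strand *deletion* sites inside one
homopolymer run would align to the same canonical gap position and merge
into genuinely concordant evidence, so such placements are re-drawn as
substitutions. Under this premise the concordance gate structurally cannot
produce a false SNV (the unaffected strand is clean), and the test suite
confirms zero across 1000 replicates. The naive pooled-majority
comparator, by contrast, miscalls whenever some site satisfies
$n_s(2r-1) > n_{\bar s}$; because all sites in a replicate share one depth
pair, this is governed by the strand-imbalance distribution and occurs in
roughly nine out of ten replicates here — a large but not total failure
rate, which is exactly what bounded strand imbalance predicts for strictly
single-strand errors.

## Numerical choices and edge cases

* Posteriors are computed in log space with max-subtraction;
  normalisation is asserted to 1 ± 1e−9.
* Within-strand argmax ties (probability difference < 1e−12) are treated
  as discordant — conservative, template retained.
* At depth 0 the posterior equals the prior; `min_depth` ≥ 1 means such
  positions are always LOW_DEPTH.
* Strong concordant evidence saturates double precision (posterior
  numerically 1), so thresholds `tau` arbitrarily close to 1 cannot
  suppress deep concordant variants — correctly so, since the true
  posterior exceeds any representable `tau < 1`.
* Terminal target positions (outermost ~2 bases) cannot host a verifiable
  SNV: an ends-free aligner soft-clips a terminal mismatch whenever the
  prefix score $2p - 3 < 0$. This is a property of all local/soft-clipping
  aligners, including the original toolchain's.
* `call_sample()` is vectorised across positions; the scalar
  `call_position()` is the reference implementation and the suite asserts
  their equivalence position by position.

## Open design points resolved here

* The exact likelihood, thresholds and demux algorithm are not specified
  in the source description of the workflow; the choices above are the
  simplest consistent with per-strand binomial weighting and categorical
  concordance, and are recorded with their rationale.
* Identity is defined as
  $(L - \text{mutated positions} - \text{indel positions}) / L$; uncovered
  positions reduce `coverage` but not identity, and both are reported.
  An insertion counts one position (its anchor); a deletion counts its
  span.
* Whether both barcodes must be found for a read to count (adopted: yes)
  follows the original read-accounting convention.
* Candidate barcodes are not screened for cross-dimerisation against the
  universal binding sites; at these lengths the pairwise-distance filter
  dominates demux behaviour, and the binding sites are user-supplied.
* Config files are JSON rather than YAML: the target environment ships no
  YAML parser for R, and the manifest/config content is identical.

## Known limitations

Desk-scale aligner (no FM-index seeding): reference panels beyond a few
dozen kilobases per sample are out of scope. Quality scores are carried but
not used by the model. Insertion calling uses a frequency rule, not the
binomial model. The cost utility is unit-agnostic arithmetic
(`cost_per_kb(2.20, 6.6)` = 0.33), provided for workflow accounting only.
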