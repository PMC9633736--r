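---
title: "Streaming sequence reductions: model, counting, and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming sequence reductions: model, counting, and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msrtools)
```

## The transformation model

A *streaming sequence reduction* (SSR) of order $\ell$ is the string
transformation obtained by sliding a window of length $\ell$ over a DNA
sequence and concatenating the outputs of a window function
$g : \Sigma^\ell \to \Sigma \cup \{\varepsilon\}$, after copying the first
$\ell - 1$ characters verbatim:

$$f(x) \;=\; x[1,\ell-1]\cdot g(x[1,\ell])\cdot g(x[2,\ell+1])\cdots
g(x[|x|-\ell+1,\,|x|]).$$

Homopolymer compression (HPC) is the order-2 special case with
$g(x_1x_2) = x_2$ when $x_1 \ne x_2$ and $\varepsilon$ otherwise; it
collapses every run of identical bases to one occurrence, which removes
the dominant error mode of nanopore sequencing (homopolymer expansion and
contraction) before read mapping. The package generalizes this: any total
table from the $4^\ell$ $\ell$-mers to $\{A,C,G,T,\varepsilon\}$ is a
valid `reduction`, and `apply_reduction()` implements $f$ together with a
position map for coordinate lift-over.

```{r}
apply_reduction(reduction_hpc(), "AAAGGTTA")$seq
```

Strings shorter than $\ell$ pass through unchanged (the formula
degenerates to the copied prefix). Lowercase input is uppercased. A
character outside `{A,C,G,T}` acts as a context break: every window
containing it emits nothing and the character itself is emitted verbatim
exactly once. This policy is a package decision — the model is defined
over the four-letter alphabet only — chosen because it is deterministic
and keeps landmarks such as `N` runs visible in the reduced sequence.

## Reverse complements

Mappers compare reads against both strands, so useful reductions must
interact predictably with reverse complementation. $f$ is
*RC-insensitive* when $f(RC(x)) = RC(f(x))$ for all $x$; HPC has this
property. The property quantifies over all strings, so
`is_rc_insensitive()` is implemented as a *bounded verifier*: it checks
the identity exhaustively for every string up to a configurable length
(default 8). A pass is evidence, not proof; a fail is a counterexample.

The weaker, constructive property used for enumeration is
*RC-core-insensitivity*: $g$ must send every reverse-complement pair of
$\ell$-mers to complementary outputs, or both to $\varepsilon$, and every
self-reverse-complementary $\ell$-mer to $\varepsilon$ (a single
nucleotide cannot be its own reverse complement). For such reductions the
strict identity fails only at the copied prefix: dropping the first
$\ell-1$ characters of $f(RC(r))$ and the last $\ell-1$ characters of
$RC(f(r))$ yields equal strings. For long reads and $\ell = 2$ this
edge effect is immaterial. The package tests this near-commutation
property exhaustively for all strings up to length 8 across a random
sample of 50 enumerated reductions.

## Counting and enumerating restricted SSRs

At order 2, four dinucleotides (`AT`, `TA`, `GC`, `CG`) are their own
reverse complement and are forced to $\varepsilon$; the remaining 12 form
$i(2) = 6$ free pairs, each carrying one degree of freedom. In general
$i(\ell) = 4^\ell/2$ for odd $\ell$ and $(4^\ell - 4^{\ell/2})/2$ for
even $\ell$.

An RC-core-insensitive reduction is equivalently a partition of the free
canonical $\ell$-mers into $S_0$ (deleted) plus $k$ non-empty parts and
an injective assignment of output letters to parts. Two reductions are
*equivalent* when their $S_0$ agree, their parts align under a
permutation, and the Watson–Crick complement pattern among output letters
is preserved — swapping A/T with C/G outputs, for example, produces an
equivalent reduction. The number of injection classes $o(k)$ is computed
by enumerating all injections and grouping by complement pattern (never
hard-coded, so the published values become a test): $o(1..4) = 1,2,3,3$.

The number of partitions $C(\ell, k)$ sums, over the count $j$ of free
$\ell$-mers deleted into $S_0$, a Stirling-number term at $j = 0$, a
binomial-times-Stirling term for $1 \le j \le i(\ell)-k$, and zero
beyond. The total number of class representatives is
$N(\ell) = \sum_{k=1}^{4} C(\ell,k)\,o(k)$.

```{r}
count_table(2)
as.numeric(count_restricted(2))
bigint_signif(count_restricted(3))
```

Three numerical decisions here:

* **Exact arithmetic.** $C(3,k)$ involves Stirling numbers of 32 items
  and $C(4,k)$ of 120, far beyond double precision, so the counting layer
  carries a small exact big-integer type (base-$10^4$ limb vectors with
  addition, multiplication and power). Stirling numbers use the
  division-free recurrence $S(n,k) = k\,S(n-1,k) + S(n-1,k-1)$ rather
  than the inclusion–exclusion sum, which would require exact division by
  $k!$; the inclusion–exclusion form serves as an independent oracle in
  the tests at small $n$. Binomials come from Pascal's triangle
  (additions only).
* **Order-4 magnitude.** Exact evaluation gives $N(4)$ with a leading
  mantissa of 9.4 at $10^{82}$; the package reports the exact integer.
* **Representative rule.** Enumeration (order 2 only; the order-3 space
  already holds $\sim 2.9\times10^{21}$ classes) yields one
  representative per class: among the injections realizing a class, the
  one whose serialized table (`reduction_key()`) is lexicographically
  smallest. Any deterministic rule is equally valid; this one is
  canonical and stable across runs. Enumeration order is dimension, then
  partition encoding, then complement pattern.

`enumerate_restricted(2)` yields exactly 2135 representatives, equal to
the closed-form count — the two routes are independent, and their
agreement is asserted in the test suite and the acceptance script.

## Coordinate lift-over

Reduction deletes characters, so mapping results on a reduced reference
must be translated back. `apply_reduction()` anchors every emitted
character to a 0-based original position: copied prefix characters to
their own index, window outputs to the index of the window's **last**
character (for HPC, the output is the window's second character, so this
is the natural choice). All intervals are 0-based half-open.

`lift_to_reduced()` rounds inward: the translated start is the first
reduced position anchored at or past the original start; the translated
end is one past the last reduced position anchored before the original
end. An interval covering only deleted positions becomes empty. Inward
rounding keeps the lifted interval inside the image of the original one,
which is conservative for the overlap-based correctness criterion below.
`lift_to_original()` is exact on anchors, and the round trip
reduced → original → reduced is the identity.

Reductions are applied to the forward reference and to the reads; the
mapper handles strand, so lift-over never reverse-complements
coordinates. Per-target maps serialize as a run-length encoded TSV
sidecar.

## Evaluation and selection

A mapped read is *correct* when its mapped target matches its simulated
origin target and the intersection of the two intervals is at least 10%
of their union. For a mapq threshold $t$, the curve reports the fraction
of all simulated reads with a primary alignment of mapq $\ge t$ and the
error rate among those alignments. Conventions, each flagged in the
output where relevant:

* secondary alignments (`tp:A:S`) are dropped; untagged records count as
  primary; duplicate primaries keep the highest mapq;
* reads whose reduced form is empty remain in the denominator of the
  mapped fraction — they were simulated, they can never be mapped;
* the error rate with zero mapped reads at a threshold is reported as 0
  and flagged (`no_mapped`), avoiding undefined points on sparse curves;
* truth intervals are compared in reduced coordinate space (lifted onto
  the reduced reference), matching the direction of the pipeline.

Selection against the HPC reference point (its curve at mapq 60) uses
the *respective threshold*: the highest $t$ at which a candidate has
**strictly** higher mapped fraction and **strictly** lower error rate
than the reference; candidates with no such $t$ are discarded. Three
top-20 lists are ranked — mapped fraction at the respective threshold,
error rate there, and the percentage of thresholds $1..60$ (denominator
exactly 60; threshold 0 excluded) where the candidate strictly beats the
reference — and their union is the selected MSR set. Ties break by
metric then candidate id. Strict inequality and the $1..60$ range are
package decisions where the selection prose allows either reading; the
strict reading matches the "strictly better" framing of the reference
region, and excluding threshold 0 makes the stated denominator exact.

The three published MSRs (E, F, P) are defined only graphically in their
source, so the package does not hard-code their tables;
`check_msr_constraints()` instead verifies the textual facts that
identify them (RC-core-insensitivity; MSR_E maps AA→T hence TT→A; MSR_E
and MSR_P delete the CC/GG pair; MSR_P assigns exactly two free pairs,
MSR_E and MSR_F exactly one, to a G/C output) against any user-supplied
candidate table.

## The synthetic data generator

`sim_config()` describes the fixture world: by default a two-chromosome
100 kb genome with homopolymer enrichment 0.3 (a base copies its
predecessor with that probability, giving mean run lengths between an
iid sequence and homopolymer-rich real genomes), one tandem array of ten
200 bp repeat copies at 2% divergence (a miniature of the repeat
structure that makes centromeric mapping hard), 2,000 reads of mean
length 2 kb (sd 500, minimum 200 — nanopore-scale lengths scaled to the
genome), 1% substitutions, a 50% chance of a ±1 expansion or contraction
per homopolymer run, and half the reads on the reverse strand. Truth is
the error-free origin interval on the forward reference, encoded in each
read name as `id!target!start!end!strand`.

`synth_mappings()` plays the role of a mapper when none is configured:
one primary PAF record per read, displaced to a random non-overlapping
locus with a configurable probability, with mapq drawn from a pluggable
model (uniform, or confidence-coupled so that errors concentrate at low
mapq, the realistic shape). This makes the evaluation layer testable
with exactly known ground truth: the injected wrong-placement rate must
be recovered at threshold 0 within binomial noise.

What the generator does **not** emulate: trained sequencing error
profiles, quality-score realism, chimeric or split reads, and
genome-scale repeat complexity. Passing tests therefore demonstrate the
correctness of the transformation, counting, lift-over and evaluation
machinery under controlled conditions — not mapping performance on real
genomes, which additionally depends on the external mapper. An external
mapper can be plugged into the pipeline as a command template (e.g.
`minimap2 -x map-ont -c {ref} {reads} > {out}`, the conventional
long-read setting); the package never links against one.

Problem sizes in the shipped tests — exhaustive string checks to length
8, 2,000-read pipeline runs, 10,000-read recovery experiments — were
chosen as the smallest sizes at which each property is meaningfully
exercised (binomial tolerances at 10,000 reads separate the tested rates
cleanly), and every stochastic test fixes its seed.

## Known limitations

* Enumeration is order-2 only, matching the tractability boundary of the
  restricted space; higher orders are counted exactly but not searched.
* The bounded RC-insensitivity verifier cannot prove the universal
  property, only refute it.
* Base-level alignment detail (CIGAR/cs tags) is not translated between
  coordinate spaces; the evaluation concerns read placement only.
* RC-insensitive reductions outside the RC-core-insensitive construction
  (HPC itself is one) are representable and applicable but not
  enumerable by this package.
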