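---
title: "De novo peptide sequencing by symmetric-difference spectrum scoring"
author: "SymDiffDeNovo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo peptide sequencing by symmetric-difference spectrum scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SymDiffDeNovo)
```

## The problem and the scoring model

A peptide is a string `S` over an alphabet of amino-acid residues with
positive monoisotopic masses; its residue-sum mass is `m(S)` (the intact
peptide additionally carries one water, 18.010565 Da, which the cleaning
step removes). Fragmentation produces prefix and suffix fragments, so an
ideal experiment measures the *theoretical spectrum*
`TS(S) = {m(T) | T a prefix or suffix of S}`, which always contains 0
and `M = m(S)`. Real measurements lose some of these masses and gain
spurious ones. De novo sequencing asks for a string of mass `M` that
explains the measured mass set `X` as well as possible.

Maximizing the shared peaks count `|TS(S) ∩ X|` ignores the explained
masses that were never measured, which makes splitting a residue into
lighter isobaric pieces (glutamine into glycine + alanine) free of
charge. The model implemented here scores every explained mass:

\[
score(S, X) \;=\; \sum_{m \in TS(S)} f_\Delta(m, X), \qquad
f_\Delta(m, X) = \begin{cases} +1 & m \in X\\ -1 & m \notin X,\end{cases}
\]

and maximizing it minimizes the symmetric difference `|TS(S) Δ X|`
(identity: `|TS Δ X| = |X| − score`, asserted exactly in the tests).
Four per-mass scores are available in `scoringConfig()`: `scp`,
`symdiff`, and the intensity-weighted `wscp` / `wsymdiff`, where matched
masses contribute the measured intensity and, under `wsymdiff`,
unmatched predictions cost a constant penalty (default −2500; the
intensity scale this value suits is the simulator's log-normal model
with median 1000, and it is exposed as a parameter because the
meaningful magnitude depends on the instrument's intensity units).

## The dynamic program

The spectrum multigraph has vertices at every candidate prefix mass
`{m, M − m | m ∈ X}` and, for each ordered vertex pair and each string
of length at most `pMax` whose mass matches the gap, one labeled edge;
parallel edges carry the different strings of equal mass, and a loop
edge at 0 with the empty label is the base case. Two paths from vertex 0
are grown in tandem — one spells the prefix, the other the reversed
suffix — always extending the path of smaller mass. Because of this
schedule, the masses newly explained by appending edge `(w, w')`, namely
`TSe((w,w'), M) = {m(T)+w, M−(m(T)+w)}` over nonempty label prefixes
`T`, can only overlap previously explained masses inside the other
path's last edge's TSe set. A DP state `(w, (a, b))` therefore stores
the best score of any path pair ending at vertex `w` and edge `(a, b)`;
extensions add `gain = Σ f_Δ` over `TSe(new) \ TSe(other)`. States with
`w + b = M` are terminal, and backpointer traceback emits the prefix
label concatenated with the reversed suffix label.

One accounting subtlety: for an edge ending at vertex `M` the literal
TSe set contains the masses 0 and `M`, which the base entry (the empty
string explains 0 and M, value 2 under `symdiff` on a cleaned record)
has already credited. `tseMasses()` therefore excludes values within
tolerance of 0 or `M`; with this reading the hand-traced toy optima
agree with direct string scoring, and the invariant *base value + summed
gains = score of the reconstructed string* holds along every extension
path (tested on random walks through the matrix graph, not only at
optima).

### k best candidates

The reachable DP states with their extension edges form the *matrix
graph*, a DAG whose source is the base state, whose terminals are the
states with `w + b = M`, and whose edge weights are the extension gains.
Every source-to-terminal path spells a candidate of score base + path
weight, so the k best candidates are the k longest paths. Any correct
k-shortest-paths routine on a DAG satisfies this contract; the package
uses the standard per-node top-k dynamic program over the topological
order (vertex, then edge), rather than an implicit-heap algorithm,
because the graphs at hand are small and the routine must tolerate
signed weights. Enumerated paths are converted to strings, duplicate
strings collapse to their best score (two extension interleavings can
spell the same peptide, and duplicate paths would distort
rank-of-truth statistics), and enumeration continues until k distinct
strings or exhaustion. The optional score floor keeps candidates with
score at least `max − (1 − f)·|max|`; the absolute value makes the
`f = 0.9` convention well defined for non-positive maxima, degenerating
to co-optimal-only at `max = 0`.

## Offset-aware sequencing

Real fragments carry ion-type offsets: on the fragment-neutral scale a b
ion's mass is the prefix residue sum, while a y ion's is the suffix
residue sum plus one water. Given offset sets `O_p` (prefixes) and `O_s`
(suffixes), a prefix of mass `m` explains
`OM(m, M) = {m + δ | δ ∈ O_p} ∪ {M − m + δ' | δ' ∈ O_s}`, and the
extended theoretical spectrum `TS_x(S)` is the union over all prefixes.
`TS_x` is generally not reversal-symmetric, so the offset-aware DP
tracks which of its two paths is the prefix (two role layers per state).
The newly explained masses of an extension subtract, besides the other
path's last-edge set, the offset readings of both paths' anchor
vertices, because under offsets the readings of nearby vertices can
collide. This bookkeeping is valid for *2-basic* offset sets — maximal
pairwise offset difference `γ < 2μ`, with `μ` the smallest residue mass
(for the standard alphabet and b/y offsets, `γ = 18.011 < 2 × 57.021`)
— and construction refuses anything wider.

Two design points where the package had to make a call:

* **Vertex placement.** Each measured mass `m` is interpreted under
  every offset `δ ∈ O_p ∪ O_s`, and both the direct reading `m − δ` and
  its complement `M − (m − δ)` become candidate vertices. The one-sided
  placement (only `m − δ_p` and `M − m + δ_s`) looks natural but leaves
  the reversed-suffix path without vertices at suffix-mass coordinates:
  on a clean b/y ladder the alternating extension schedule then
  deadlocks and no terminal state is reachable. The two-sided set
  reduces exactly to the mirrored vertex set `{m, M − m}` at zero
  offsets (the tests assert table-level equality with the simple
  program there) and lets either path anchor on either ion series.
* **Role seeding.** At the base state both paths are empty and the
  extension-order tie is broken by designating either as the prefix;
  both seedings are explored, which costs a factor two in states and
  guarantees every prefix/suffix decomposition is reachable.

k-best enumeration is implemented for the simple program only; the
offset-aware sequencer reports its co-optimal set by traceback.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `tolerance` (ε) | 0.02 (scoring); 0 in exact tests | Da | peak matching, vertex clustering, terminal condition |
| `pMax` | 2 | residues | maximal edge-label length; 2 bridges one missing peak, `ceiling(M/μ)` guarantees completeness |
| `k` | 10 | — | distinct candidates enumerated |
| `floorFraction` | off (0.9 when used) | — | score floor relative to the maximum |
| `penalty` | −2500 | intensity units | unmatched-mass cost under `wsymdiff` |
| offsets | `O_p = {0}`, `O_s = {18.010565}` in b/y mode | Da | ion-type readings |

Mass constants are monoisotopic: water 18.010565 Da (the nominal "18"
is shorthand that real spectra cannot afford), proton 1.007276 Da.
Fragments are assumed singly charged; multiply charged fragment
deconvolution is upstream preprocessing, not replicated here. The
default residue table is the 20 standard amino acids; isoleucine and
leucine are isobaric, indistinguishable by any mass-based method, and
collapse to `L` by default. Post-translational modifications and
average (non-monoisotopic) masses are out of scope.

## Numerical choices

* Two tolerances are deliberately distinct: the measurement tolerance ε
  (a `ScoringConfig` parameter) and a pure numeric merge epsilon of
  1e-9 Da used to deduplicate values inside a single computed mass set.
  Exact-arithmetic tests run with ε = 0; the merge epsilon also floors
  the edge-label matching so that last-bit rounding from vertex
  clustering cannot delete exact edges.
* Peak matching returns the measured mass minimizing `|m − x|` within
  ε; equidistant ties go to the smaller mass. Vertex clustering merges
  peaks within ε into their intensity-weighted mean (degenerate
  clusters of identical values keep the exact value).
* Cleaning inserts 0 and M into X; their virtual intensity is the
  median measured intensity, since the data give no intensity for the
  termini. Offset-space records keep masses up to `M + max(O_s)` (a y
  fragment neutral exceeds M by one water).
* Equal-score candidates are ordered lexicographically; DP ties keep
  the first-computed backpointer (one per entry), with the k-best
  machinery supplying alternatives.
* Degenerate inputs: an empty measured set is rejected; a graph without
  0→M connectivity warns at construction and sequencing returns an
  empty candidate list; label enumeration may legitimately return no
  strings for a gap, and `M` not representable over the alphabet yields
  an empty result rather than an error.

## Evaluation conventions

The recall of a reported sequence is the fraction of the true sequence's
prefix masses it reproduces (ε-tolerant intersection); 0 and M count as
shared by construction, and an internal-only variant is available for
sensitivity analysis. Recall is 1 exactly when every prefix mass of the
truth is reproduced. `rankOfTrue()` is the positional 1-based index of
the truth in the (score-descending, lexicographic) candidate list after
I/L collapse. For aggregate identification, ties favor the truth: a
spectrum counts as identified when the truth attains the maximal score.
The positional convention cannot be used there, because on an ideal
spectrum the truth always ties with its reversal (which explains the
same mass set), and symmetric residue arrangements can add further
exact co-optimal rearrangements — resolving ties by the candidate of
highest recall, as the summary does for the recall column, is
equivalent to favoring the truth.

## The synthetic data generator

`simulationParams()` defines the simulated study conditions; its
defaults are the benchmark conditions used throughout the package: 200
spectra, uniform random tryptic peptides (last residue K or R) of
length 7–12, each internal fragment peak dropped independently with
probability q = 0.3, 10 spurious peaks drawn uniformly over the
fragment m/z range, Gaussian mass jitter of 0.005 Da, and log-normal
intensities (median 1000, log-sd 1). Peaks are encoded as singly
charged m/z either at the theoretical prefix/suffix masses (`none`) or
as b/y series (`by`). A seed fully determines the emitted MGF and truth
table.

What the generator emulates is exactly the noise structure the scoring
model reasons about: missing fragment masses and additional spurious
masses, plus bounded mass error. What it does not emulate: position- and
residue-dependent fragmentation efficiency, isotope envelopes, multiply
charged fragments, co-eluting peptides, or correlated noise. Passing
benchmarks on these simulations therefore demonstrates the correctness
and the directional behavior of the scoring models under the assumed
noise structure, not instrument-grade identification rates; on real
data the achievable rates additionally depend on peak picking and
intensity modeling, which are out of scope.

## Problem sizes in the shipped tests

The exhaustive-oracle suites run on toy alphabets of 3–4 symbols with
integer residue masses drawn from 4..13 and total masses 15–30, with
`pMax = ceiling(M/μ)` so every composition of M is representable; these
sizes keep exhaustive string enumeration (the independent oracle)
comfortable on one CPU while still producing multigraphs with hundreds
of parallel-edge states. The standard-alphabet suites use 200 peptides
of length 7–12 for ideal-spectrum recovery and 200 corrupted spectra
for the paired benchmark of the two scoring models.

## Known limitations

* Runtime is polynomial but far from the throughput of production
  de novo tools; the goal is a faithful, testable implementation of the
  scoring model, not speed.
* The offset-aware variant supports one offset interpretation per
  vertex after clustering; heavily overlapping offset readings within
  the matching tolerance are merged.
* The 90%-of-max floor and the candidate-list conventions assume scores
  on the additive `f_Δ` scale; mixing variants within one ranked list
  is not meaningful.
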