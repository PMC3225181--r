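---
title: "Graph-clique motif discovery: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-clique motif discovery: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A transcription factor (TF) binds a family of similar short DNA segments —
its binding sites; the family is called a motif. Given a set of unaligned
intergenic or promoter sequences thought to share a regulator, de novo
motif discovery asks for the overrepresented set of similar k-mers. Most
probabilistic tools detect sites whose nucleotide composition contrasts
with the background. Many real binding sites, however, have a composition
very close to their background (a small *sum of squared distance*, SSD,
between the site's base frequencies and the background's), and those are
systematically hard for composition-contrast methods. `cliquemotif`
approaches the problem combinatorially instead: mutually similar sites form
a clique in a k-mer similarity graph regardless of how background-like
their composition is.

## The model

### Windows instead of k-mers

Each input sequence is decomposed into windows of length 2(k−1) taken every
k−1 bases, so adjacent windows overlap by k−1 bases and **every k-mer of the
sequence lies in exactly one window**. The last window may be shorter, down
to length k. Windows, not k-mers, are the graph's vertices: this cuts the
vertex count by a factor of about k−1, and it is robust to the fact that
two true sites can share fewer matches than a site shares with its own
shifted neighbor — the window weight takes a maximum over all contained
k-mer pairs, so the best local gapless alignment wins.

### The similarity graph

For two windows u and v with admissible k-mer sets K_u and K_v, the edge
weight is

  w(u, v) = max { M(a, b) : a ∈ K_u, b ∈ K_v },

where M(a, b) counts matching positions. An edge is kept when w(u, v) ≥ α.
Window pairs from the same sequence are allowed, including adjacent
overlapping windows; no special casing is applied.

A k-mer is *admissible* when it passes three composition filters, each
reflecting what curated binding-site collections overwhelmingly look like:

* SSD against the background composition ≤ 0.3 (tunable via `ssd_cutoff`;
  lower it to ~0.06 to target strongly background-like motifs),
* longest single-base run ≤ 60% of k,
* at least 3 of the 4 bases present.

The background composition {q(b)} is pooled from the input sequences unless
a separate background FASTA is supplied.

### Choosing α

α is calibrated per dataset by sampling. N = max(10, ⌈n/4⌉) k-mers are
drawn uniformly from all k-mer positions of the n input sequences; each is
scanned against the n−1 other sequences, keeping the best match count per
sequence. After trimming the smallest 5% of these (n−1)·N values, their
mean μ̄ estimates the best match a *random* k-mer finds in an unrelated
sequence. True sites should beat that, so the default cutoff is
α = ⌊μ̄⌋ + 1. Because match counts are integers and the density-control
loop moves α in unit steps, one unit above the trimmed background mean is
the smallest margin that separates signal from background; the
`"degenerate"` stringency drops the margin and uses α = ⌊μ̄⌋, admitting
more degenerate sites at the cost of specificity. Both are capped at k.
The sampling is seeded and, at realistic input sizes, highly stable across
redraws.

Graph density is controlled as D = |E|/|V| (the mean number of edges a
vertex carries): while D exceeds `max_density` (default 20), α is raised by
one and the edges re-thresholded. This keeps the clique stage near-linear
in practice.

### One greedy maximal clique per vertex

Enumerating all maximal cliques is exponential and finding the maximum
clique is NP-hard, so the package finds exactly one maximal weighted clique
*associated with each vertex* v, inside the neighborhood subgraph N(v)
induced by v and its neighbors. The greedy rule deletes the minimum-degree
vertex among v's neighbors, breaking degree ties by the smaller sum of
incident edge weights, until the remainder is a clique. Two boundary cases
the deletion rule alone does not settle are resolved deterministically:

* the seed v is never deleted (otherwise the clique would not be
  associated with v); if v itself is the unique minimum, the next-ranked
  neighbor goes instead;
* the remainder can become degree-regular without being complete (a
  chordless cycle, for example), so deletion simply continues under the
  same rule until completeness holds, with the lowest vertex id as the
  final tie-break; afterwards any outside vertex adjacent to all members
  is re-added in id order, making maximality unconditional.

Running this for all |V| vertices guarantees every vertex lies in at least
one clique — the search cannot be trapped by a single bad local optimum.
Duplicate member sets from different seeds are collapsed before merging.

### Merging cliques

Binding sites of one TF are often split across sub-motifs, hence across
cliques. The clique with the largest total edge weight becomes the core C;
every other clique C′ is tested once against the core with two overlap
rates,

  r = |C ∩ C′| / |C′|  and  R = |C ∩ C′| / |C|,

and absorbed when r ≥ γ or R ≥ β. The defaults (γ, β) = (3/4, 3/5) have a
concrete reading: a 4-vertex clique sharing a triangle with the core, or a
5-vertex core sharing a triangle with the candidate, merges. γ > β because
candidates are usually no larger than the core. Since every candidate is
compared to the fixed core, traversal order cannot change membership; the
implementation traverses in descending weight order for determinism.

### Refinement

The merged group's windows still carry spurious k-mers. A multipartite
graph G′ connects any two admissible k-mers from *different* windows whose
match count reaches α — the same cutoff as edge construction, which keeps
the refinement consistent with the graph it came from. The motif is the
largest closed neighborhood N\* over the vertices of G′ (hub plus
neighbors); ties go to the neighborhood with the larger induced edge-weight
sum, then the lower vertex id. Each window contributes at most one site —
the member k-mer best matching the hub, leftmost on ties — so a motif never
stacks overlapping sites from a single window. If G′ has no edges the group
is degenerate and is skipped.

For the top-N motifs the merge–refine cycle repeats after removing the
merged cliques from the candidate pool; a window may legitimately appear in
several reported motifs, but two motifs cannot overlap at a large scale
because their cliques were separated by the merging step.

Note a consequence of frame freedom: with 2(k−1)-mer windows the recovered
motif can surface in a frame shifted by a base or two relative to the
planted/annotated sites, with random flanks absorbed into the k-mer. This
is why site-level scoring uses the standard 50%-overlap rule rather than
exact coordinates.

## The synthetic benchmark generator

`generate_benchmark()` emulates a planted-motif protocol: 20 binding-site
instances are implanted into 20 background sequences of 400–1,000 bases in
"any number of repetitions" mode — each site picks a uniformly random
sequence and offset independently, so some sequences receive several sites
and some none. The implanted segment *replaces* background of the same
length; total length is conserved, and the truth table records every
placement. Offsets colliding with an earlier implant are redrawn (up to
1,000 times; the generator fails loudly rather than silently overlapping
truth sites).

Backgrounds come from a third-order Markov model. `fit_markov3()` estimates
one from a real corpus (4-mer counts with add-one smoothing; unseen
contexts fall back to uniform so sampling never stalls). When no corpus is
available, `iid_markov3()` provides a stationary composition-only model;
the bundled default composition A = T = 0.31, C = G = 0.19 mimics AT-rich
intergenic DNA such as yeast promoters. The default benchmark motif is 20
copies of the 8-mer consensus `TGACTCAT` (an AP-1-like word with balanced
composition and SSD ≈ 0.02 against that background — deliberately in the
background-like regime the method targets), each carrying 0 or 1 point
mutations drawn uniformly.

What the generator does *not* emulate: higher-order repeat structure,
composition heterogeneity along real promoters, correlated site positions
(e.g. tandem arrangements), and indels within sites. Passing the planted
benchmarks therefore demonstrates the combinatorial machinery under
controlled signal-to-noise, not performance on any particular genome.

## Scoring

A truth site counts as recovered when at least 50% of its bases (ceiling on
odd lengths) overlap a predicted site — the denominator is the truth site's
length. TP counting uses greedy one-to-one matching in motif-rank then
coordinate order, so one prediction spanning two truth sites scores a
single TP. From TP/FP/FN come Sn, Sp, PC = TP/(TP+FP+FN) and
F = 2·Sn·Sp/(Sn+Sp), with 0/0 defined as 0. For incompletely annotated
real data, `lb_specificity()` gives recovered-known/predicted as a lower
bound on Sp, and `log_odds_ratio()` measures complementarity of two
finders as ln[P(A∩B)/(P(A)P(B))] over sites found by at least one panel
member and missed by at least one (restricting to that universe is what
makes the ratio informative for two strong finders; natural log is used —
the base only rescales).

## Numerical and interface choices

* Coordinates are 0-based half-open internally; reports print 1-based
  inclusive coordinates and say so in their header.
* Only the forward strand is scanned by default; `revcomp = TRUE` adds
  reverse-complement windows as extra vertices whose sites are reported
  with strand "−" and forward-strand coordinates.
* k-mers containing IUPAC ambiguity codes are silently inadmissible:
  match counting is defined only over concrete bases.
* Rounding conventions: N = ⌈n/4⌉; the trim count is
  ⌊0.05·(n−1)·N⌋ on the raw value multiset (no deduplication).
* Edge thresholding is inclusive (w ≥ α); α already embeds the +1 margin,
  and inclusiveness keeps the degenerate stringency meaningfully weaker.
* All tie-breaks (clique deletion, core selection, hub selection, site
  choice per window) end at the lowest id / leftmost coordinate, so a run
  is a pure function of the input and the seed.

## Problem sizes used in the shipped checks

The package's own test suite verifies each stage against brute-force
oracles at small scale (exhaustive k-mer pair maximization on 1,000 random
window pairs; maximal-clique verification on 500 random graphs of up to 15
vertices; an independent reimplementation of the α sampling protocol), and
end-to-end recovery on 10 replicates of the 20×400-base planted design,
where the top motif attains mean site-level Sn ≥ 0.8 and Sp ≥ 0.6 and
adding 25% background-only sequences costs at most 0.15 of Sn. These sizes
keep the whole suite within a few minutes on a single core while leaving
the statistics comfortably away from their thresholds.

## Known limitations

* k is fixed per run; there is no width auto-selection.
* No PSSM polishing of the final site set (e.g. EM refinement) and no
  scanning of new sequences with the derived count matrix.
* The greedy clique is not the maximum clique of N(v); the per-vertex
  enumeration compensates in aggregate but individual cliques can be
  suboptimal.
* Very short sequences (length < k) contribute nothing and only raise a
  warning.
* The α calibration assumes the inputs are mostly background; if nearly
  every k-mer is signal (tiny, highly enriched inputs), μ̄ saturates and
  the cutoff loses its margin.
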