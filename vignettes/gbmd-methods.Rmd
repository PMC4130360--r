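---
title: "Canonical graph-based molecular descriptors: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical graph-based molecular descriptors: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmd)
```

## The problem

Ligand-based virtual screening ranks a compound database by structural
similarity to a known active, betting on the similar-property principle:
molecules with similar 2D structure tend to share bioactivity. Line
notations are attractive for this because text is compact, hashable and
comparable with sequence tools — but a line notation is only useful for
identity checks and similarity search if it is *canonical*: a molecule
must map to one string no matter how its connection table happens to be
numbered. Renumbering a table of $N$ atoms in all $N!$ ways and testing
identity is infeasible, so the ordering itself must be made canonical.

This package implements such a descriptor. A molecule is modeled as a
labeled undirected graph $G = (V, E)$ — vertices carry element symbols,
edges carry bond orders 1/2/3 — and rendered as a token string by:

1. **Morgan extended connectivity.** $EC^0(v) = \deg(v)$ and
   $EC^{i}(v) = \sum_{u \in N(v)} EC^{i-1}(u)$, iterated while the number
   of distinct values strictly increases; the assignment in force before
   the count stops increasing is kept. This is the classic stopping rule
   for the Morgan relaxation.
2. **Canonical root and order.** The root maximizes the composite key
   (final EC descending, element symbol ascending, order of the bond to
   the already-numbered region descending). Remaining atoms are numbered
   by a depth-first traversal that always expands the neighbor with the
   best key.
3. **Spanning tree and ring marks.** The traversal's parent links form a
   spanning tree $T$ per component; every edge of $G$ outside $T$ is a
   *breaking arc*, one per independent ring (per component,
   $|E| - |V| + 1$ arcs).
4. **Back-and-forth emission.** The string is an Euler tour of $T$:
   visiting $v$ emits its element symbol; each child $c$ contributes the
   bond glyph of $(v,c)$, the recursive emission of $c$, the bond glyph
   again, and the symbol of $v$ once more. A component of $n$ atoms thus
   produces exactly $2n - 1$ atom tokens and every tree bond appears
   twice — the redundancy is what makes the descriptor sensitive to
   small structural edits. At the first emission of an atom, one `/` is
   emitted per incident breaking arc, so every ring contributes exactly
   two `/` marks. Bond glyphs are `-`, `=`, `#` for orders 1, 2, 3;
   disconnected components are emitted independently and joined with
   `.`, larger components first, ties by text.

```{r aspirin}
asp <- parse_sdf(system.file("extdata", "aspirin.sdf", package = "gbmd"))[[1]]
generate_gbmd(asp, flatten_bonds = TRUE)
```

## Tie-breaking: why the extra machinery

EC values, element symbols and bond orders do not always separate
candidates — symmetric molecules (benzene, stars, twin branches) leave
genuine ties. Choosing "the first one in input order" would silently
break canonicality. Residual ties are therefore resolved by iterative
partition refinement: atoms start colored by (EC, element) and colors
are repeatedly split by the multiset of (bond order, neighbor color)
signatures until the class count stabilizes. During traversal, every
already-numbered atom is individualized (given a unique color from its
rank), so the refinement propagates *where* the numbered region sits in
the graph and separates candidates that are only superficially
equivalent. Candidates still tied after anchored refinement are, for
chemical-scale graphs, interchangeable under an automorphism that fixes
the numbered region — either choice emits the same string. For root
selection the same refinement is used, and if several root candidates
survive, the string is emitted from each and the lexicographically
smallest kept.

This refinement is a 1-dimensional Weisfeiler–Lehman scheme with
individualization. It is not a complete graph-isomorphism decider in
theory; constructions that defeat it (strongly regular graphs with
identical labels) are far outside the space of molecular graphs, and the
package's property suite (500 random graphs × 10 relabelings,
byte-identical output required) exercises the guarantee empirically.

## Degenerate inputs and small conventions

* Single atom: EC value 0, one class, descriptor = the bare symbol.
* Empty graph: empty descriptor string.
* An isolated atom next to a larger component renders after it
  (`C-C-C-O-C.Na`).
* Two-letter element symbols end in lower case, which is what makes the
  tokenizer unambiguous; the en-dash seen in print for single bonds is
  normalized to ASCII `-`.
* Bond glyphs for tree edges come from the actual bond order;
  `flatten_bonds = TRUE` renders every bond as `-`. The flag exists
  because printed example strings for molecules with carbonyl groups
  show only single-bond glyphs; faithful emission is the default.
* Hydrogens: explicit H atoms in an input file are kept by the parser
  and never added. The worked aspirin example uses the heavy-atom
  skeleton, which supports treating the descriptor as heavy-atom-based;
  `strip_hydrogens()` (CLI `--strip-h`) removes explicit H before
  emission when a file carries them.
* Aromatic bond code 4 in MOL files is rejected with a request to
  kekulize — the grammar defines orders 1/2/3 only.

## Similarity scoring

Descriptor strings are compared by exact Smith–Waterman local alignment
on token sequences (match $+2$, mismatch $-1$, linear gap $-1$ by
default, all configurable). Exact DP is used rather than a seeded
heuristic: heuristics pay off on genome-scale databases, while
descriptor strings are tens of tokens long, and the exact local score is
precisely the quantity a seeded search approximates. Scores are
normalized by $\text{match} \cdot \max(|a|, |b|)$ so 1 means the longer
sequence aligns end-to-end without penalty; ranking, not the absolute
value, is the meaningful output. Fingerprint screening uses the Tanimoto
coefficient $T = c/(a + b - c)$ on externally computed binary
fingerprints; two all-zero fingerprints score 0 by convention.

## Screening protocol and table statistics

A screening run searches a database once per reference structure,
excluding the query itself from the ranked list (retrieving the query is
uninformative and inflates recall). Recall at a top-$f$ cutoff uses
$k = \mathrm{round}(f N)$ (half-up) and, as the denominator, the class
actives remaining in the searched database — the class size minus the
excluded query. Per-class results average over the references
(conventionally 10 per class).

Result tables are summarized three ways:

* **Column means** over activity classes, computed at full precision and
  rounded half-up to 2 decimals only for rendering.
* **Bold cells**: a cell is bold iff it equals its row maximum (ties all
  bold), and the mean row is scanned along with the class rows. This is
  the convention under which the published bold-cell totals of the
  shipped tables are reproduced exactly; comparisons use full-precision
  values, which is why a mean row showing two equal rounded values can
  still have a unique winner.
* **Kendall W** with activity classes as judges and descriptors as
  objects: per-judge average ranks for ties,
  $W = 12 S / (m^2 (n^3 - n) - m \sum_j T_j)$ with
  $T_j = \sum (t^3 - t)$ over tie groups, significance via
  $\chi^2 = m (n - 1) W$ on $n - 1$ degrees of freedom. The ranking
  string joins equal mean ranks with `=`, ordered between themselves by
  mean recall.

```{r kendall}
t4 <- mddr_recall_matrix("ds1", 1)
mean_row(t4, digits = 2)
kendall_w(t4)
```

One finding worth flagging: on the shipped DS3 top-1% matrix the
coefficient ($W = 0.189$, 10 judges × 7 objects) yields
$\chi^2 = 11.31$ on 6 df, $p = 0.079$ — *not* significant at the 0.01
level the source tables claim for every row. The package reports the
computed value; the acceptance suite records the discrepancy rather than
adjusting either side.

## The synthetic benchmark: what it emulates, what it does not

The reference evaluation database (MDDR) is proprietary, so the package
ships generators instead. `random_molgraph()` builds a random recursive
spanning tree over `n_atoms` atoms plus `n_rings` ring-closing edges,
with elements drawn from (C 0.70, N 0.10, O 0.15, S 0.05) and bond
orders from (single 0.80, double 0.15, triple 0.05) — weights chosen
once as a caricature of organic drug-like composition.
`make_benchmark()` emulates the activity-class structure of a screening
database: each class is a seed molecule plus actives obtained by
`edits_per_active` random structure edits (element substitution, atom
addition, connectivity-preserving bond rewire), decoys are independent
random graphs, and 10 references per class are drawn without
replacement. A small edit radius yields structurally homogeneous
classes; a large one, heterogeneous classes. Defaults are 5 classes × 15
actives + 80 decoys with molecules of 8–16 atoms and 0–2 rings — large
enough for stable recall statistics at a 10% cutoff, small enough that
the full suite runs in seconds.

What passing tests on this generator shows: canonicality, the token-law
arithmetic, ranking/recall mechanics, and that descriptor text
similarity separates edit-radius-1 classes from random decoys. What it
does not show: performance on real pharmacology. The generator has no
valence model, no aromaticity, no functional-group chemistry and no
realistic scaffold distribution, so absolute recall values on it say
nothing about screening a real database — only the published recall
tables speak to that.

All generators take an explicit integer seed, use one local RNG stream,
and restore the caller's RNG state; identical seeds reproduce benchmarks
byte-for-byte.

## Known limitations

* **Ring-closure bond order is silent.** A breaking arc renders only as
  two `/` marks; its bond order appears nowhere in the string. An edit
  that changes only an arc's order — without perturbing any traversal
  priority — leaves the descriptor unchanged. Element edits and
  tree-bond order edits always show.
* **`/` marks do not pair.** With two or more fused rings the grammar
  does not say which `/` belongs to which arc, so the string is not
  designed to be parsed back into a graph; no decoder is provided.
* The emitted string's visit multiset (each atom appears once plus once
  per child) depends on the tree shape, so atom-token counts are a
  structural invariant but per-element token counts are not simply the
  molecular formula.
* Charges, isotopes and stereochemistry are parsed past and discarded;
  the descriptor is strictly 2D-topological.

## Problem sizes used by the shipped checks

The test suite's canonicality sweep uses 500 random graphs of 5–30
atoms and 0–4 rings, 10 relabelings each; the alignment oracle is
exhaustive over all token pairs of lengths up to 4 on a 3-symbol
alphabet (14641 pairs) plus seed-fixed random pairs up to length 8,
checked against a column-enumeration oracle and an independent
sequence-alignment library.
`scripts/acceptance.R` re-derives the table statistics from the shipped
CSVs and repeats the property sweeps at 100 graphs × 5 relabelings,
which keeps a full run in the tens of seconds on one core.
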