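---
title: "Pseudoknot topology: genus, primitive components and shadow enumeration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudoknot topology: genus, primitive components and shadow enumeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pktopo)
```

## The model

An RNA secondary structure is a set of base pairs over a backbone; drawn
as arcs above a line, pseudoknots are exactly the crossing arcs. The
topological complexity of such a chord diagram is its genus: fatten the
diagram into a ribbon graph and count the boundary cycles *L* ("closed
loops"). With *P* base pairs,

$$ g = \frac{P - L + 1}{2}. $$

`pktopo` computes *L* two ways. The normative formulation is
permutation-algebraic: place the 2*P* paired positions at ranks
1..2*P*, let σ be the involution exchanging the two endpoints of every
pair and τ the cyclic successor (rank 2*P* wraps to 1); *L* is the
number of cycles of τ∘σ. The default path (`count_loops(d)`) is an
explicit graph traversal — cross a base-pair arc, step along the
backbone, repeat until the walk returns — which must agree with the
cycle count; the suite checks agreement exhaustively over all 945
matchings of up to five arcs plus generated structures. Closing the
backbone into a cycle is required for the single arc to come out at
*g* = 0 (two loops), which anchors the convention that *g* = 0 holds
exactly for pseudoknot-free diagrams.

The affine constants in the genus relation are not taken on faith: the
test suite derives them by requiring agreement with fifteen classified
pattern tokens of genus 1–5 and the genus-1 status of the H-pseudoknot,
kissing hairpin and pseudotrefoil. `(P - L + 1)/2` is the unique affine
form in (P, L) consistent with all of them.

## Decomposition

Genus is additive, so comparisons between structures should be made on
*primitive components*:

1. **Irreducible split** (`split_irreducible`): cut the backbone
   wherever no pair spans the cut — the positions where every
   bracket-family counter returns to zero in dot-bracket notation.
2. **Non-nested closure** (`nonnested_closure`): within an irreducible
   component, seed with the leftmost arc and repeatedly add every arc
   crossing a member. Irreducibility guarantees the closure is the full
   non-nested arc set.
3. **Recursion** (`extract_primitive`): the closure is one primitive
   component; the remaining (nested) arcs are re-split and recursed.
   Arcs are conserved: the components partition the input pairs.

Components keep their original coordinates; the gaps left by extracted
nested parts are rank gaps and semantically inert. A closure that
crosses nothing (a plain helix level) is reported as a genus-0
component and excluded from pseudoknot tallies downstream.

Genus is evaluated on the *uncollapsed* component — stems are not
first reduced to effective pairs — while the subclass name is the
pattern token of the stem-collapsed shadow. The two conventions are
mutually consistent because genus is invariant under stem collapse,
which the suite asserts on every generated structure.

## Stem collapse and pattern tokens

`collapse_stems` merges arc pairs (i, j), (k, l) with i < k ≤ l < j and
no *paired* endpoint strictly between i and k nor between l and j, to a
fixpoint; unpaired bulges between stacked pairs do not block the merge,
matching what one would visually call a stem. One consequence worth
stating: in `{(1,4), (2,6), (3,5)}` the pairs (2,6) and (3,5) stack
directly and merge even though (1,4) crosses both — the token alphabet
has no word for a "stem crossed through its loop" distinct from the
collapsed form, the merge preserves genus, and the three-arc census
(two shadows: pseudotrefoil and kissing hairpin) confirms that diagrams
containing the adjacent pattern `...YX...XY...` are not counted as
distinct shadows.

`pattern_token` letters arcs A, B, C, ... in order of first endpoint
(beyond 26 arcs: a1, a2, ...); the token is canonical, so it can serve
as the subclass key. `token_diagram` inverts it.

## Enumerating primitive shadows

`count_by_genus(n)` counts all distinct primitive pseudoknot shadows
with *n* arcs, binned by genus — the table a(g, n), supported on
2g ≤ n ≤ 6g − 2. The generator is a depth-first tree over partial
tokens, one endpoint per level (leaf level 2*n*), implemented in C++
for speed. At each node the children are: open a fresh symbol (allowed
while fewer than *n* symbols are in play; symbols are named in opening
order, which *is* the canonical labelling, so every token arises on
exactly one path), or close an open symbol, subject to three prunings:

* **Rule 1** — a symbol becomes right-eligible only one level after its
  left end was emitted: no zero-length arc (p, p+1).
* **Rule 2** — closing a symbol must not complete a crossing-connected
  component with no open symbol left in it. Closed arcs can never be
  crossed by arcs placed later (their interval content is fixed), so
  such a component would force a reducible or nested leaf. The check
  uses only *determined* crossings — closed–closed, and closed–open
  (an open symbol whose left end lies strictly inside a closed arc will
  close outside it, hence crosses it); open–open crossings are still
  undetermined but irrelevant to liveness. This pruning is exact: it
  never rejects a prefix of a valid shadow, and by induction every
  component always holds an open symbol, so the last closure
  necessarily connects everything — which is why no separate check is
  needed at the leaf.
* **Rule 3** — closing a symbol must not create the collapsible
  adjacent pattern `...YX...XY...` (two arcs that would form one stem).

In the three-arc tree this reproduces the worked trace: prefix `ABCB`
cannot take `A` (Rule 3) nor `C` (Rule 2), `ABCAC` cannot take `B`
(Rule 3), and the leaves are exactly `ABCABC` and `ABACBC`. Leaves are
folded into per-genus counters immediately, so memory is O(n).

Correctness is not argued rule by rule — it is enforced by a second,
fully independent route: `brute_force_counts(n)` enumerates all
(2n−1)!! perfect matchings in pure R, filters by the definitions
(irreducible; closure covers all arcs; no collapsible adjacent pair)
and bins by genus. The suite requires exact agreement for n ≤ 7
(135 135 matchings). The pseudoknot-free primitive convention — the
empty structure and the single arc, one each — supplies the 0- and
1-arc totals in `totals_per_arc`.

One reading choice: the tree description ties fresh-symbol injection to
the node level. Read as "only while level < n", tokens whose k-th left
end sits at position ≥ n (e.g. `ABACBDCD`) could never be generated and
the four-arc census would come out short; read as "exactly n symbols
are introduced, one available per level", every census value matches
the oracle. The second reading is implemented.

## Classification pipeline

`classify_dataset` runs decomposition over a dataset, drops genus-0
components, and groups the rest by token. Conventions, each recorded in
the output or here because the choice was genuinely open:

* subclass letters within a genus follow decreasing structure count;
  ties break by larger arc count, then token order — a documented
  convention, since observed subclass tables are consistent with
  arc-count-descending but no rule is stated anywhere;
* `n_sequences` counts distinct source structures; an instance count is
  emitted alongside for structures containing a motif twice;
* span length is end-to-end, including both terminal paired
  nucleotides; the standard deviation is the population form (divide by
  n);
* canonical filtering keeps Watson–Crick plus G·U wobble — standard
  practice for RNA secondary structure; the admitted set travels in the
  `canonical_set` attribute and the CLI's JSON sidecar so results are
  comparable under either convention;
* deduplication keeps the first record per identical sequence — a
  deterministic stand-in for an arbitrary choice.

## The fixture generator

`generate_fixture` plants chosen pattern tokens into synthetic
structures: each arc becomes a stem of 1–20 parallel pairs (uniform in
the requested range), optionally interrupted by 1–2 nt bulges at a
per-stack rate, with 3–6 nt unpaired spacers between blocks and
optional plain-hairpin decoys nested in the gaps. Paired positions
receive random canonical bases. It emulates the *topology* of
pseudoknotted molecules — stems, bulges, nesting, concatenation — not
their thermodynamics, sequence composition biases, non-canonical pairs
or lengths; pipeline tests passing on fixtures therefore demonstrate
correct decomposition, naming and counting, not predictive claims about
real molecules. Planted tokens must be canonical shadows; a token whose
stems would merge after expansion is rejected at generation time.
Generation is byte-deterministic for a seed and restores the caller's
RNG state.

## Problem sizes and limits

The default suite covers enumeration n ≤ 9 against the printed census
values (n = 9 takes ~30 s in the compiled core), oracle equivalence
n ≤ 7, and exhaustive loop-count agreement to five arcs — all chosen as
comfortable desk-scale sizes. Counts for n ≥ 10 grow steeply (the
twelve-arc genus-6 cell is ~2.3 × 10^10 leaves) and sit behind
`allow_long = TRUE`; they are not asserted anywhere. The brute-force
oracle is capped at n = 7 by (2n−1)!! growth. Known limitations: no
closed-form or generating-function computation of a(g, n); no
surface embedding or drawing; no annotation of non-canonical pair
geometry; real-database classification requires the user to supply the
structure files.
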