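---
title: "Designing dense binding-site arrays: the model behind densepack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing dense binding-site arrays: the model behind densepack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Natural cis-regulatory regions often carry many overlapping protein binding
sites, and engineered promoter libraries benefit from the same density.
Given a collection $R$ of exact binding-site strings over the DNA alphabet
and a target length $L$, the task is to construct a sequence of length at
most $L$ that contains as many members of $R$ as possible as contiguous
substrings, on either strand.  This is the maximization counterpart of the
Shortest Common Superstring problem and is NP-hard, so `densepack` does not
search sequence space directly: it reduces the task to an Orienteering
Problem on a small graph and solves that exactly as an integer linear
program.

## The shift metric and the overlap graph

For ordered strings $(a, b)$ the shift distance $d_{ab}$ is the smallest
number of positions $b$ must be shifted right so that its prefix matches a
suffix of $a$ *and* $b$ reaches or passes the end of $a$.  The mandatory
overhang is what makes paths compose: after placing $b$ the construction can
continue from $b$ alone, and the metric satisfies the triangle inequality.
If no overlap exists the distance falls back to `nchar(a)` (plain
concatenation).  Examples: $d(\mathrm{AGC},\mathrm{CAG}) = 2$,
$d(\mathrm{CAG},\mathrm{AGC}) = 1$, $d(\mathrm{CGT},\mathrm{CAG}) = 3$, and
$d(\mathrm{AGCAG},\mathrm{GC}) = 4$ — the internal GC match is rejected
because GC would end before AGCAG does.

Each site becomes a graph vertex (in double-strand mode, two vertices: the
site and its reverse complement), plus a start vertex at distance 0 to every
site and an end vertex at distance `nchar(site)` from each site.  A path
from start to end corresponds exactly to a legal overlay of sites, its
summed edge weights equal the constructed sequence length, and maximizing
the number of vertices visited within budget $L$ is the Orienteering
Problem.

## The integer linear program

`build_model()` materializes the Miller–Tucker–Zemlin formulation: binary
edge variables $x_{ij}$ over indices $0..n$ (index 0 plays both start and
end; $x_{00}$ is the "nothing fits" edge), which gives $n^2 + n + 1$
binaries; degree, flow-conservation and budget rows; and integer order
variables $u_i \in [1, n]$ with the $n(n-1)$ MTZ rows
$u_i - u_j + 1 \le n(1 - x_{ij})$ that forbid disconnected subtours.  The
objective maximizes $\sum c_{ij} x_{ij}$ over edges entering internal
vertices, with all $c_{ij} = 1$ by default.  In double-strand mode one
extra row per site caps the combined in-degree of a site and its own
reverse complement at one; two *different* sites that happen to be reverse
complements of each other may still both be counted, matching the stated
exclusion rule.

Solutions are decoded by walking the active edges from the start vertex,
overlaying the oriented site strings at cumulative-distance offsets
(`reconstruct()`), and re-verifying every model constraint independently of
the solver.  An exact substring scan (`verify_occurrences()`) reports
incidental occurrences too: a site contained inside another counts in the
scan but not in the ILP score, and both numbers are reported.

## Positions, promoter elements, side biases

Absolute coordinates enter through $n$ integer variables
$p_i \in [0, L-1]$ (0-based start offsets) linked to the edges by
$d_{ij} x_{ij} - (L-1)(1 - x_{ij}) \le p_j - p_i \le d_{ij} x_{ij} +
(L-1)(1 - x_{ij})$ with $p_0 = 0$, so the first site of the path sits at
offset 0 and every chosen edge forces the exact spacing.  The big-M
constant is $L - 1$, the width of the position domain.

A fixed element (say the $\sigma^{70}$ -35 box TTGACA) is added to the
collection as a forward-strand-only vertex, required by
$\sum_i x_{ik} \ge 1$, and its position confined to the window
$[\alpha, \beta]$.  For an element pair the downstream partner is required
likewise and the spacer window links the two positions.  Two conventions
are supported because the published inequality
$\alpha \le p_l - \mathrm{length}_l - p_k \le \beta$ measures the spacer
with the *downstream* element's length, which with start-offset positions
equals the biological gap only when both elements have the same length.
The default `"gap"` convention implements the gap
($p_l - p_k - \mathrm{length}_k$); `spacer_convention = "printed"`
reproduces the published formula verbatim.  For the -35/-10 pairs used in
the promoter studies both elements are 6 bp, where the two coincide.

Side biases add $\pm p_i / K$ to the objective (upstream $-$, downstream
$+$).  With the default $K = 2 n (L-1)$ the summed perturbation cannot
leave $[-0.5, 0.5]$, so solutions with different site counts are never
reordered; only ties are broken.  Because the position of a site *not* on
the path is unconstrained, the solver can park unvisited biased positions
at their favorable bound; this is inherent to the published formulation
and harmless for the base score, but it means the bias expresses a
preference among optima rather than a strict per-site guarantee.

## Enumerating distinct optima and steering their diversity

Collections typically admit many optimal arrays.  `enumerate_optimal()`
finds one optimum, pins the base score to it, and after every solution adds
a no-good cut $\sum_{\text{active}} x_{ij} \le |\text{active}| - 1$ that
excludes exactly that path.  Edge-distinct paths occasionally assemble the
same nucleotide string; the stream is de-duplicated at the string level, so
the user receives distinct sequences.

In solver order, which optimum comes next is an artifact of the backend's
internal tie-breaking and typically over-uses a few strongly overlapping
sites.  Diversity-driven order maintains per-site usage counts and, before
every re-solve, sets the weight of edges entering sites used *strictly
less* than the mean to $1 + \epsilon$ (others stay 1).  Any
$0 < \epsilon < 1/n$ leaves the base score dominant; the default is
$0.5/n$, halved to $0.25/n$ when side biases are active at the same time
(and $K$ doubled) so the two perturbations together still stay below 0.5
and the integer score remains recoverable by rounding.  Progress is
summarized by the Shannon entropy (natural log) of the usage frequencies,
bounded by $\log |R|$, attained only at perfectly uniform usage.

## The greedy baseline

`greedy_pack()` implements the classical polynomial-time heuristic:
repeatedly merge the ordered pair of strings with the largest overlap
(ties to the smallest pair indices, contained strings absorbed whole) into
a superstring, then either return it whole (when it fits $L$, it is an
optimal packing) or slide a length-$L$ window and keep the leftmost window
containing the most sites.  Its count never exceeds the ILP optimum and
degrades as collections grow at fixed $L$, which is the baseline's purpose:
quantifying what exact optimization buys.

## Brute-force references

Two independent oracles validate the pipeline on small instances.  The
path oracle enumerates every simple start-to-end path within budget by
depth-first search (no MTZ, no solver, at most 9 internal vertices) and
returns all optimal sequences; the sequence oracle enumerates every string
of length $L$ (alphabet sizes capped at $10^7$ strings) and counts
contained sites, which also credits incidental containments the path
formulation cannot see.  `count_simple_paths()` evaluates
$\sum_{k=0}^n n!/(n-k)!$ in exact big-integer arithmetic (base $10^4$,
recurrence $a(n) = n\,a(n-1) + 1$) — for 50 sites about $10^{65}$ paths,
versus the $4^{200} \approx 10^{120}$ raw sequences at $L = 200$ — the
gap that motivates the graph reduction.

## Deciding element-constrained feasibility exactly

Heavily constrained promoter designs are sometimes impossible, and
branch-and-bound is a poor tool for proving that on this model: the big-M
position rows give a weak linear relaxation, so a proof of absence must
exhaust an enormous search tree, and even finding a rare satisfying
solution can defeat the solver's heuristics.
`decide_element_feasibility()` answers the same question exactly by
searching the space the model actually describes: chains of placements that start at offset 0, advance by
exact shift distances, respect once-only and strand-exclusion rules, and
visit every element inside its (exactly linked) window.  The search is
pruned by a sound relaxation — per-vertex arrival-offset sets computed by
dynamic programming with site reuse allowed — so a branch is abandoned as
soon as some pending element becomes unreachable even under reuse.
Exhaustion proves infeasibility; any surviving chain is re-validated from
scratch (`verify_element_chain()`) and certifies feasibility.  A node
budget (default $3 \times 10^5$) turns pathological cases into an explicit
"undecided" instead of an open-ended run; the promoter feasibility study
falls back to the MILP solver's feasibility screen for those.

## Synthetic data and what the studies show

`random_collection()` generates the study conditions: $n$ sites with
lengths i.i.d. uniform on an inclusive range (5–15 bp by default, the span
of typical protein-DNA footprints) and i.i.d. uniform bases, or a "ladder"
with exactly one site per length.  All harnesses are seeded and
deterministic given (seed, backend).  The packing regimes exercised by the
tests use collections of ten 10-bp sites at $L = 50$ (double strand), the
5–14 bp ladder at $L = 50$, and the three-promoter constraint set
(TTGACA/TATAAT at 40–60 bp with 16–18 bp spacer, TTGACA/TATACT at 50–70,
TGGCAGG/TTGCA at 60–80 with 3–5 bp spacer) on twenty-site collections at
$L = 100$.

Because the sites are uniform random strings, these studies probe the
combinatorics of overlap, not the biology of real motifs: genuine binding
sites are non-uniform in composition, often palindromic or degenerate, and
overlap each other more richly than random strings do.  Passing tests
therefore demonstrate the correctness of the optimizer and the qualitative
phenomena (usage bias, entropy gains from diversity-driven order, greedy
degradation), not quantitative predictions for any particular motif
database.

One quantitative note on the ladder regime: one site of each length
5–14 bp sums to 45 bp for the six shortest sites, so at $L = 50$ a correct
optimizer always packs at least six sites (they chain with zero overlap),
and with random overlaps typically seven.  The harness reports what the
model yields.

## Numerical and design choices

* Coordinates are 0-based start offsets; intervals are half-open; the end
  vertex's implied position equals the used length.
* Degenerate inputs need no special-casing: a site longer than $L$ keeps
  its vertex and is simply unreachable under the budget; `L` smaller than
  every site yields the empty packing via $x_{00}$.
* Duplicate site sequences are legal and stay distinct vertices (distance
  0 between them); a site identical to another site's reverse complement
  is likewise kept distinct, and the exclusion rule only pairs a site with
  its *own* reverse complement.
* The backend is GLPK (`glpsol`), driven through CPLEX-LP files.  Because
  no single branching/cut configuration is fast on every instance, each
  solve runs a small restart portfolio (pseudocost branching, then
  pseudocost with cut generation, then the defaults, then most-fractional
  branching), splitting the time limit across configurations; pure
  feasibility screens additionally drop the objective and enable the
  feasibility pump so the first incumbent ends the search.  GLPK is
  deterministic, so runs are reproducible per backend; other backends
  would enumerate equal-score optima in a different order, which is
  inherent to "solver order".
* Default per-solve time limit: 60 s; enumeration aborts cleanly on
  timeout and returns the partial stream.
* Test and study problem sizes are chosen so the whole suite runs on a
  single desktop core in minutes: oracle sweeps use at most nine internal
  vertices, enumeration fixtures keep optimal sets small by holding the
  budget below the summed site length, and the promoter study uses 30
  seeded collections.

## Known limitations

* Sites are exact strings; position-weight matrices and degenerate motifs
  are out of scope (choose representative exact sites upstream).
* Helical-phase constraints (10.5 bp periodicity) and spaced-dyad motifs
  are not modeled.
* The ILP base score counts path sites only; incidental containments are
  reported by the verification scan but not optimized for.
* Solve time grows steeply with collection size and with the number of
  side constraints; the exact feasibility decider covers the promoter
  screen, but proving optimality on heavily constrained large instances
  can exceed desk-scale patience with the GLPK backend.
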