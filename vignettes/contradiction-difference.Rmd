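---
title: "Measuring topological contradiction and auditing combined-evidence analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring topological contradiction and auditing combined-evidence analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treecontrast)
```

## The problem

Morphological and molecular character data frequently support different
phylogenetic hypotheses for the same taxa. Diagnosing *how much* they
disagree is harder than it sounds when each analysis is reported as a
summary topology — a majority-rule consensus of most-parsimonious trees, or
the half-compatibility summary of a Bayesian posterior — because summaries
contain polytomies, and classical tree distances conflate two very
different things: *conflict* (the trees segregate overlapping taxon sets
differently) and *resolution* (one tree simply says less). A star tree has
maximal Robinson–Foulds distance to a fully resolved tree while asserting
nothing that contradicts it.

`treecontrast` separates the two. It implements the contradiction
difference (CD) and, around it, everything needed to run a
combined-evidence incongruence audit offline: consensus construction,
partitioned NEXUS matrices, informativeness filtering, missing-data
accounting, consistency-index profiling, a perfect-character sensitivity
simulator, and a synthetic-data module.

## The measure

For rooted topologies $A$ and $B$, both pruned to their $n$ shared tips
($n \ge 3$):

* a split (rooted clade) of $A$ is **contradicted** if at least one clade of
  $B$ overlaps it without either containing the other;
* with $N_{AB}$ and $N_{BA}$ the per-tree counts of contradicted splits,

$$\mathrm{CD}(A,B) \;=\; \frac{N_{AB} + N_{BA}}{2\,(n-2)}.$$

The denominator is the largest possible number of conflicting splits: a
fully resolved rooted tree on $n$ tips has $n-2$ internal non-root nodes,
and both trees contribute. Properties, all property-tested in the suite:

* symmetry, $\mathrm{CD}(A,A)=0$, range $[0,1]$;
* blindness to resolution: collapsing a non-conflicting clade never
  increases CD, and a star tree scores 0 against everything;
* invariance to unshared tips (pruning happens first) and to tip-label
  permutations applied to both trees;
* the triangle inequality **fails** by design — many mutually conflicting
  resolved trees are all CD 0 from the same star tree. CD is an
  incongruence indicator, not a metric. Between fully resolved trees it
  behaves like a symmetrized, rescaled Robinson–Foulds distance.

Two conflict readings are offered. The default treats trees as rooted and
tests clade pairs directly (overlap without nesting). The `"unrooted"` mode
uses the classical four-intersection split-compatibility test, under which
a clade and its complement-nested counterpart do not conflict. Both
readings give identical values on the package's worked examples (e.g. a
single three-taxon rearrangement between two resolved 18-tip trees gives
$2/32 = 0.0625$, printed as 0.06); the rooted reading is the default
because every analysis in the intended workflow is rooted at a fixed
outgroup split and summaries count non-root nodes.

Two further conventions, chosen where the definition is silent:

* clades of size $n-1$ (a root child covering all but one tip) are
  conflict-eligible like any other non-root clade; the alternative
  (excluding them) only matters in the rooted reading and is not exposed;
* pairs sharing fewer than three tips have no defined CD (the denominator
  would vanish); `cd_matrix` reports such pairs as undefined rather than 0.

Values are stored at full precision; the two-decimal rounding seen in
rendered tables (`format_cd_matrix`) is applied only at render time.

## Summary trees

`majority_rule()` implements the "supported by at least half" rule with a
deliberate refinement: the default keeps clades with frequency **strictly**
greater than the threshold (0.5), because clades at exactly 0.5 can be
mutually incompatible and a literal $\ge$ rule can therefore fail to define
a tree. The MrBayes-style behavior is available as `rule = "halfcompat"`:
clades at $\ge 0.5$ are admitted in order of decreasing frequency (ties by
first occurrence), each only if compatible with those already kept. Clade
frequencies are weighted (per-tree weights default to 1) and attached to
the consensus as node labels. A read-time burn-in fraction is available for
posterior `.t` files; it defaults to 0 since no principled general value
exists.

## Character matrices

`char_matrix` objects store state symbols with two distinct sentinel cells:
MISSING (`?`) and INAPPLICABLE (`-`). The distinction is preserved for
round-tripping NEXUS files, but *all computations* (informativeness,
parsimony, missing-data percentages) treat them identically, following the
genus-level coding rule that a character is missing when unknown **or**
inapplicable. In DNA partitions, IUPAC ambiguity codes are recoded to
MISSING at parse time (a strict partial-information mode is deliberately
not implemented); polymorphic cells `(01)` are likewise read as MISSING.

A column is parsimony informative iff at least two states each occur in at
least two taxa — exactly the condition under which its minimum length
varies across topologies, which the tests verify by brute-force
enumeration of all rooted topologies on small cases. Column ids are 1-based
and stable across filtering and taxon subsetting, so character numbers
cited in an analysis remain addressable after columns are dropped;
restriction to a taxon subset can only shrink the informative set, and
re-filtering is idempotent.

`replicate_columns(x, k)` implements integer character weighting by
contiguous repetition (54 columns × 53 = 2862), and
`combine_partitions()` unions taxa across partitions, filling MISSING for
taxa absent from one of them — the mechanics behind a combined matrix where
only a subset of taxa have sequence data.

## Parsimony and consistency

Lengths use Hartigan's generalization of the Fitch count, which is exact on
multifurcating trees for unordered characters: at a node whose children's
state sets contain state $s$ in $k(s)$ children, with $K = \max_s k(s)$,
the node adds (children $- K$) changes. Polytomies are *hard* — changes are
counted on the tree as given — because the intended use is profiling
characters on a half-compatibility summary that genuinely contains
polytomies. Missing tips carry the full state set and can never force a
change; consequently adding missing data never increases a column's length,
which is also why characters with much missing data show artificially
inflated consistency. The implementation is verified against brute-force
minimization over all internal-node assignments and against an independent
parsimony implementation on resolved trees, and is rerooting-invariant.

The consistency index of a column is $m/s$ with $m$ = distinct observed
states minus one and $s$ = its length on the tree; the ensemble (composite)
index of a column set is $\sum m / \sum s$. Columns with $s = 0$ are
excluded from ensembles and flagged; autapomorphic columns (CI 1 by
construction) are flagged as uninformative, and `ci_report()` accepts an
explicit exclusion list so the effect of high-consistency missing-data
artifacts on a composite value can be quantified.

## Perfect characters and the sensitivity workflow

To ask whether a morphological partition of a given *size* — independent of
its quality — can influence a combined analysis, the package generates
binary characters that perfectly support a chosen topology: one state
shift on one internal node each, no homoplasy, no stochastic model.
Eligible nodes are internal, non-root, with clade size in $[2, n-2]$; a
shift on a clade of size $n-1$ would yield an autapomorphic, uninformative
column, so such nodes are excluded. Given $c$ characters and $k$ eligible
nodes, every node receives $\lfloor c/k \rfloor$ characters
deterministically and the remainder $r$ is placed on $r$ distinct nodes
drawn uniformly under an explicit seed — with 54 characters and 13 nodes,
52 even and 2 random. `sensitivity_workflow()` regenerates the remainder
per replicate, combines each perfect matrix with the molecular partition,
and exports analysis-ready NEXUS; the Bayesian or parsimony inference
itself is external software's job, and its tree samples re-enter through
`read_trees_nexus()`.

One subtlety, established by enumeration during development: the shifts
mark nodes of the *unrooted* topology, so every rooting of the generating
tree is equally parsimonious. Recovery guarantees are therefore split-level
statements — every maximum-parsimony optimum contains every allocated
split as a clade or its complement — rather than rooted-clade statements.

## The synthetic world

`make_study_like_dataset()` emulates the shape of a combined
morphological/molecular dataset so that every operation in the package can
be exercised offline. Its defaults are fixed once and are not tuning knobs:

* 26 species in 25 genera: 4 inarticulate-like outgroups forming a clade
  sister to everything else, 2 terebratulide-like outgroups, 19 ingroup
  genera, one of which carries a congeneric species pair given *identical*
  morphological rows (via `expand_genus_to_species`) but independent
  sequence data;
* 66 morphological columns, unordered, with per-column state counts drawn
  as 2/3/4 with probabilities 0.80/0.15/0.05 — matching a 66-character
  matrix holding ~147 states — evolved under a symmetric Mk process
  conditioned on parsimony-informativeness by rejection;
* 3435 molecular sites over the 18 covered species, 4-state, unconditioned
  (so most sites are invariant, as in real rDNA), expected 0.3 changes per
  site;
* per-taxon missingness echoing the empirical profile: outgroup morphology
  68–77% missing, three covered taxa missing >50% of sequence, i.i.d. per
  cell (a block-deletion mode exists for realism but is off by default);
* NNI-perturbed tree samples standing in for posterior/MP tree sets.

The Mk simulator weights all branches equally and scales a Poisson event
rate so the expected number of substitution events per character equals
`expected_changes`; each event moves to a uniformly chosen different
state. This reasons directly in homoplasy levels rather than raw rates.
One consequence worth knowing: conditioning on informativeness *rejects*
the single-terminal-change draws that dominate a low-rate process, so the
surviving columns are enriched for multi-change histories and the ensemble
CI at `expected_changes = 1` sits around 0.65–0.7 rather than near 1. The
reliable, tested statement is monotone: ensemble CI on the generating tree
decreases as `expected_changes` grows.

What a green test on this fixture establishes: that the pipeline's
operations compose correctly at realistic shapes and missingness levels.
What it does not establish: anything about real brachiopod data — there is
no alignment structure, no rate heterogeneity across sites or lineages, no
correlated character evolution, and the generating tree is known. The
empirical reference matrices and summary topologies live in a public
repository and are not bundled; tests that would compare against their
printed values run the same machinery on the synthetic stand-in instead.

## Numerical and interface conventions

* All stochastic functions require an explicit seed, restore the caller's
  RNG state, and are fully determined by (arguments, seed); the CLI
  refuses stochastic subcommands without `--seed` and writes a JSON
  manifest per run.
* Trees are canonicalized on entry: unary nodes suppressed, children
  ordered by smallest contained tip label, branch lengths dropped
  (every computation is purely topological). Serialization of a
  canonical tree is therefore deterministic and byte-stable.
* Tip-label matching is exact and case-sensitive; `normalize_labels()`
  (trim, underscores to spaces) exists but is never applied implicitly.
* Rejection sampling in the Mk simulator caps at 1000 tries per column
  and fails loudly rather than silently degrading.
* `exhaustive_mp_search()` refuses more than 7 taxa by default; it is an
  oracle, not a search tool.

## Known limitations

Ordered and step-matrix characters, codon/amino-acid alphabets, retention
or rescaled consistency indices, consensus networks, and any form of tree
*inference* beyond the exhaustive small-instance oracle are out of scope.
The NEXUS dialect coverage is the pragmatic core (DATA/CHARACTERS with
FORMAT and MIXED datatypes, TREES with TRANSLATE, CHARSET commands);
exotic constructs such as step matrices or nested comment annotations
inside cells are not supported.
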