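---
title: "Tiered consensus reconstruction of metabolic networks from paired databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered consensus reconstruction of metabolic networks from paired databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemmerge)
```

## The problem

Genome-scale metabolic reconstructions are usually assembled from a single
reaction database, inheriting that database's errors: generic metabolite
classes standing in for specific compounds, missing or wrong cofactors,
unbalanced stoichiometries, and idiosyncratic metabolite naming.  If two
*independently curated* databases describe the same organism, errors are
unlikely to repeat across both, so the intersection of the two is a
substantially more reliable reconstruction than either source alone.  The
obstacle is that the two sources share no identifier namespace: deciding
that compound `C00036` of one database and `OAA` of the other are the same
molecule is itself an inference problem.

`gemmerge` implements a semi-automated pipeline for this integration.  Its
output is not one model but three nested ones, ordered by confidence:

* **core** — compounds matched in both databases and reactions described
  identically (up to protons and orientation) in both;
* **intermediate** — additionally, reactions found in only one source whose
  full substrate side or full product side consists of core compounds;
  these are plausibly valid but unconfirmed, and the same chemistry may
  enter twice (once per source);
* **complete** — everything else from either source.

## Compound matching

Matching proceeds through independent evidence channels, combined
conservatively.

**Seeds.** Explicit cross-references (one record citing the other source's
identifier, or both citing the same ChEBI/CAS/PubChem entry) and exact
shared synonyms (after normalization: case, Greek letters, separator and
punctuation unification) create the initial matched set.  Any one-to-many
pattern is quarantined to the review queue — the matching is injective at
all times.

**Name similarity.** A logistic-regression scorer estimates the probability
that two name strings denote one compound.  Its features are symmetric in
the pair: character-bigram Dice similarity; normalized common prefix and
suffix lengths; agreement of digit-token multisets (locants and chain
lengths, so `atp` vs `gtp` agree on digits but differ sharply in bigrams);
acronym compatibility; common and differing token counts; substring
containment; and equality, bigram Dice and normalized edit similarity after
canonicalizing the acid/conjugate-base suffix (`-ic acid` ~ `-ate`), which
is the single most characteristic transformation between chemical synonym
vocabularies.  Training data come from within-database synonym sets: all
pairs of names listed for one compound are positives, and negatives are
sampled name pairs from compounds whose formulas differ in a non-hydrogen
element, which guarantees the negative label without manual annotation.
One deliberate filter applies: synonym pairs with bigram Dice below 0.3
(formula abbreviations like `H2O`, trivial-versus-systematic aliases like
`citric acid` vs `2-hydroxypropane-1,2,3-tricarboxylate`) are excluded from
the positive class.  No string model can or should resolve such pairs —
they are handled by the exact-synonym and cross-reference channels — and
keeping them in training only teaches the model that arbitrary strings may
be synonyms.  The model is fit by ridge-penalized maximum likelihood
(penalty 1.0 scaled by the sample size); training is deterministic given
the seed.

**Structure comparison ladder.** Where structures are available the
comparison proceeds from strict to permissive: identical canonical SMILES
(an exact match, the only tier accepted automatically); identity after
purging stereo descriptors; identity of a tautomer-invariant key; identity
after recalculating protonation at pH 7.4; and finally ECFP4 circular
fingerprint Tanimoto similarity above a review threshold (default 0.8).
Every tier below exact flags the pair for manual checking.  All molecule
normalization is delegated to OpenBabel: canonical SMILES, the pH 7.4
protonation model, and ECFP4 fingerprints are computed by `obabel` in
batches.  Tautomer invariance uses the standard InChI with stereo layers
dropped: InChI's mobile-hydrogen convention canonicalizes
heteroatom-to-heteroatom tautomers (lactam/lactim, amidine, phosphate
proton positions), which covers the tautomeric variation actually observed
between curated databases; carbon-centred keto-enol shifts are *not*
merged, a known limitation.  The charge tier accepts either equal pH-7.4
canonical SMILES or equal InChI after dropping protonation layers.
Compounds lacking structures fall back to hydrogen-blind formula equality.

**Reaction-driven propagation.** Reactions are where the channels combine.
For every pair of unmatched reactions across the sources, participants are
mapped through the current matching (free protons removed first, both
orientations tried, coefficients compared exactly).  If everything maps and
the EC annotations are compatible, the reactions are recorded as matched.
If the participant counts agree and exactly one participant on
corresponding sides of each reaction is unmatched, that pair becomes a
candidate identity, accepted only when three criteria concur: the host
reactions share an EC number at full four-level precision; the best
synonym-pair name score reaches the acceptance threshold (default 0.9);
and the structures match exactly (or, with a structure missing, the
formulas agree outside hydrogen).  Candidates meeting some but not all
criteria enter the review queue; a curator's accept/reject decisions can be
injected into the next run, mirroring the semi-automatic loop.  Iteration
continues until nothing new is found; termination is guaranteed because the
matched sets only grow and are bounded.  Within an iteration candidates are
collected before being applied and conflicting acceptances are diverted to
review, which makes the fixpoint independent of record order.

### Protons

There is no pH consistency between databases, and one of the two sources
typically does not write protons at all.  The pipeline therefore never
represents free protons: they are removed from every reaction side before
comparison and absent from all outputs, and proton-count differences
between molecular formulas are ignored (`formula_equal_ignoring_h`).
Hydrogen balance is consequently not a property of the reconstructions, and
molecular hydrogen may legitimately fail the consistency check; the
validator flags it rather than silently excluding it, with an explicit
exclusion list available.

## Stoichiometric consistency validation

A reconstruction is stoichiometrically consistent if every metabolite can
receive a strictly positive molecular mass conserved by every reaction:
there exists $v \ge 1$ (after scaling) with $v^\top N = 0$, where $N$ is
the metabolite-by-reaction net stoichiometry matrix.  Inconsistency is
diagnosed at three levels: **non-conserved metabolites** (entries forced to
zero in every non-negative conservation vector, found by maximizing each
$v_i$ subject to $v \ge 0$, $v \le 1$, $v^\top N = 0$), **minimal
inconsistent net stoichiometries** for a given metabolite (support-minimal
combinations $y$ with $N y \ge 0$ and $(Ny)_i > 0$ — a net conversion of
nothing into something), and **elementary leakage modes** (support-minimal
$y$ with $N y \ge 0$, $N y \ne 0$); the network is consistent exactly when
no leakage mode exists.

All certificates are computed with an exact rational two-phase simplex
(Bland's rule, so termination is guaranteed; numerators and denominators
are kept reduced at every pivot and the implementation refuses instances
whose exact representation would leave the double-precision integer range).
Columns are pre-scaled to coprime integers, which changes no verdict, and
combinations are mapped back to the original column scale before being
reported.  The floating path runs the same pivoting with a $10^{-9}$
feasibility tolerance and is the default above 20 metabolites.  Mode
enumeration searches supports in order of increasing cardinality, skipping
supersets of feasible supports; it is exponential in the number of
reactions and therefore capped (default 14 reactions), with the
per-metabolite operation available for larger instances.  Modes are
canonicalized to coprime integer vectors under positive scaling only — the
cone $Ny \ge 0$, $Ny \ne 0$ fixes the sign pattern, so no sign convention
is needed or legitimate.

On the classic two-reaction example ($R_1: A \leftrightarrow B$,
$R_2: A \leftrightarrow B + C$) the validator reports inconsistency,
non-conserved set $\{C\}$, the net stoichiometry
$\varnothing \leftrightarrow C$ and the single elementary leakage mode
$(-1, +1)$:

```{r toy}
toy <- structure(list(
  mat = matrix(c(-1, 1, 0, -1, 1, 1), 3, 2,
               dimnames = list(c("A", "B", "C"), c("R1", "R2"))),
  metabolites = c("A", "B", "C"), reactions = c("R1", "R2")),
  class = "gm_stoich")
consistency_report(toy)
```

## Network topology

The graph representation makes compounds nodes and reactions edges: all
substrates of a reaction connect to all products (never substrate to
co-substrate), directions are dropped (reaction directionality is generally
ambiguous), duplicate pairs collapse, self-loops are retained and counted
separately, and isolated compounds are excluded.  Ubiquitous currency
metabolites (water, ATP, NAD) are deliberately *not* removed.  The metric
panel comprises node and edge counts, density, heterogeneity, clustering,
components, diameter, centralisation, average path length and average
connectivity, plus per-node betweenness
$C_b(n) = \tfrac{2}{(N-1)(N-2)} \sum_{s \ne n \ne t} \sigma_{st}(n)/\sigma_{st}$
and closeness $C_c(n) = (N-1) / \sum_{m \ne n} L(m, n)$, each normalized by
the node count $N$ of the component containing $n$.

Several conventions are pinned by internal identities rather than taste:
self-loops are excluded from degrees, so average connectivity is
$2(E-L)/N$ and density $2(E-L)/(N(N-1))$ — with $E$ the edge count and $L$
the self-loop count — which is the only convention that keeps the
node/edge/connectivity triplet of a network mutually consistent.
Heterogeneity is the coefficient of variation of the degree distribution
(population variance) and centralisation is
$\tfrac{N}{N-2}\bigl(\tfrac{k_{max}}{N-1} - \text{density}\bigr)$, the
standard forms used by interactive network-analysis tools; nodes of degree
below two contribute zero to the mean clustering coefficient; average path
length is taken over reachable pairs only.  These choices are recorded in
the report metadata.

## Synthetic data: what it emulates and what it does not

Because the original database snapshots are not redistributable, the
package carries a deterministic generator of paired synthetic databases
built over a bundled library of about sixty real small molecules (valid
SMILES or curated formulas) and forty elementally balanced reactions of
central carbon and nitrogen metabolism.  Since every bundled reaction
balances on non-hydrogen elements and every compound contains at least one
non-hydrogen atom, the summed atomic counts form a hidden positive
conserved mass vector: planted core subnetworks are stoichiometrically
consistent by construction, and the validator must agree.

The generator emits two views of a sampled reaction set and plants the
discrepancy classes seen between real curated sources, each with ground
truth: disjoint synonym variants resolvable only through reaction context
plus the classifier (assigned so that no reaction carries more than one
such compound, keeping the planted instance solvable — real databases
rarely disagree about everything at once); explicit-proton and
formula-proton disagreements (expected to remain core); ATP/ADP reactions
duplicated with GTP/GDP in one source (expected intermediate); generic
compound classes (expected complete); functional-group deletions in one
source's structures; and private reactions, half anchored to
cross-referenced compounds (intermediate) and half floating (complete).
Default conditions: 25 shared reactions, 5 private per source, synonym
perturbation 0.3, proton discrepancy 0.2, cofactor swap 0.15, generic rate
0.1, structure error 0.1, cross-reference coverage 0.4 — values chosen once
as representative of two independently curated organism databases of
moderate annotation density.

Two hand-coded fixtures complement the generator: six canonical
discrepancy cases covering the full tier logic, and a two-database encoding
of the tricarboxylic-acid and glyoxylate cycles in which most of the cycle
reaches the core, the succinate dehydrogenase quinones suffer a
generic-versus-specific ambiguity (the quinone pair is cross-referenced,
the quinol pair deliberately is not, so the reaction anchors to the core
through its substrate side and lands in the intermediate tier while the
quinol pair waits in the review queue), the direct ketoglutarate
dehydrogenase step is private to one source, the three-step route via the
lipoamide intermediates is private to the other (its later steps reach only
the complete tier), and the oxalosuccinate route is one-sided.

Passing on these fixtures demonstrates that the engine implements the
intended logic, including its review mechanics.  It does not demonstrate
robustness to the full messiness of real exports — malformed structures,
polymer pseudo-compounds, compartment suffixes, instance/class hierarchies
— which the flat-file dialect assumes have been resolved upstream.

## Numerical and design notes

* Coefficients are parsed exactly (integers, fractions, decimals); exact
  rational arithmetic underlies the consistency certificates, with
  continued-fraction rationalization used to certify floating witnesses.
* EC compatibility is asymmetric by design: full four-level agreement is
  required to *accept* a candidate compound, while partial or absent EC
  annotation routes to review rather than rejection; for whole-reaction
  matching, EC sets are compared only when both sides carry annotations.
* Multiple surviving candidates for one slot are never auto-resolved; all
  go to review (ties broken by a human, not a heuristic).
* Local identifiers are assigned deterministically (seed matches first,
  then acceptance order, then tier additions in sorted source order), so
  repeated runs write byte-identical outputs.
* SBML export is Level 3 Version 1 with SBO terms and MIRIAM-style
  controlled-vocabulary URIs; identifiers are escaped reversibly where SBML
  demands it.  Re-import reproduces the stoichiometry matrix exactly.
* Test problem sizes: oracle suites use 50 random graphs of up to 12 nodes
  against a naive BFS implementation, an exhaustive sweep of 2-by-2
  stoichiometries with coefficients in $\{-2..2\}$ plus seeded random
  3-by-3 and 4-by-4 instances against bounded integer certificate search,
  and the default generator conditions for end-to-end recovery.

## Known limitations

* Keto-enol tautomers and other carbon-centred proton shifts are not
  unified by the tautomer key.
* The ECFP4 Tanimoto "similar" tier rarely fires for very small molecules
  at the default 0.8 threshold (small fingerprints make single-group edits
  look dissimilar); the threshold is configurable and the tier only ever
  feeds the review queue.
* Mode enumeration is exponential and capped; genome-scale conserved-moiety
  analysis is out of scope.
* Generic compound classes are never resolved to specific members
  automatically; they are exactly what the complete tier is for.
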