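---
title: "Methods: transcriptomics-informed metabolic target prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomics-informed metabolic target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxtarget)
```

# Overview

`fluxtarget` ranks metabolic drug-repurposing candidates by intersecting
four lines of evidence computed on context-specific genome-scale metabolic
models: reaction essentiality under flux balance analysis (FBA), linkage to
tumor-upregulated genes, recurrence as an *extended choke point* across a
family of FBA optima, and PageRank centrality on the reaction graph. This
vignette documents the model assumptions, every tunable parameter, the
numerical choices, what the synthetic fixtures do and do not emulate, and
the design decisions taken where the method leaves room.

# Constraint-based core

A metabolic model is a stoichiometric matrix $S$ (metabolites × reactions),
flux bounds $lb \le v \le ub$ in mmol·gDW⁻¹·h⁻¹, and per-reaction boolean
gene–protein–reaction (GPR) rules (AND = complex subunits, OR = isozymes).
FBA assumes steady state, $S v = 0$, and optimizes a linear objective. The
direction convention is fixed once: with $v_j > 0$, column $j$ consumes
metabolites with $S_{ij} < 0$ and produces those with $S_{ij} > 0$;
negative flux reverses the roles. All downstream modules inherit it.

Maximizing a *yield* objective (biomass, ATP) at fixed uptake bounds is
implemented as maximizing the corresponding reaction flux — yield is
proportional to flux when uptake is pinned, which is the standard FBA
reading of named objective reactions. Objective reactions are located by
exact id through `objective_tags` (roles `biomass`, `atp`, `pi4p`,
`oxygen_uptake`); no name heuristics are applied, so any model can be used
by tagging the appropriate reactions.

## Linear programming

All FBA, flux-variability and knockout problems are solved by an internal
dense two-phase primal simplex with Bland's anti-cycling rule
(`R/lp_simplex.R`). These LPs are tiny (tens of variables) but highly
degenerate — many vertices share an objective value — and Bland's rule
guarantees finite termination there. Variables with zero-width bounds are
presolved out, boxes become slack rows, and equality rows are sign-flipped
to the non-negative right-hand-side standard form. The solver is exercised
in the test suite against brute-force vertex enumeration on randomized
problems and hand-solved flux chains. FBA optima are generally non-unique;
determinism comes from the fixed pivoting rule, and any scientific claim
tied to one particular optimum should be read with that in mind (the
flux-sum minimization test is the principled way to select a parsimonious
representative).

## Oxygen uptake cap

A cap of `oxygen_ub` (default 2 mmol·gDW⁻¹·h⁻¹, a standard setting for
cancer models) is applied at FBA time to the reaction tagged
`oxygen_uptake`. The uptake direction is auto-detected from the exchange
stoichiometry: if the tagged column produces the oxygen species into the
network (import-positive convention) the cap tightens the upper bound,
otherwise it tightens the lower bound at `-oxygen_ub`. The cap is applied
during model analysis only, not during contextualization, keeping the
context extraction purely expression-driven.

# Expression processing

**Binarization.** A gene is *maybe active* in a tumor sample iff its value
passes both an inclusive global threshold (the `global_quantile` = 0.25
quantile, "Q1", of all values over all genes and tumor samples) and an
inclusive local threshold (the gene's mean across tumor samples). The
quantile convention is R type 7 (linear interpolation), the R default;
it is configurable (`quantile_type`) because different conventions move
the threshold between order statistics.

A structural property worth knowing: for a gene whose values are i.i.d.
around a single mode, the local mean threshold splits samples roughly in
half regardless of the noise level (and for right-skewed noise, more than
half fall below the mean). The binarization is therefore informative for
genes that differ between sample subgroups — which is exactly what the
downstream clustering consumes — and noisy for uniformly expressed genes.

**Clustering.** PAM (k-medoids) on the binary signatures under Manhattan
distance, which equals the Hamming count on 0/1 vectors; the method leaves
the distance open and Manhattan is the natural choice for binary data. The
number of clusters is chosen by the mean silhouette width over a small
candidate range (ties broken toward the smaller k; all-identical inputs
return the smallest candidate with a warning). `cluster::pam` provides the
BUILD+SWAP optimization; the suite checks its objective against exhaustive
search over all medoid pairs on separated fixtures.

**Upregulation.** A supplied differential table (`gene`, `logFC`,
`pvalue`) is filtered with inclusive thresholds `logfc_min` = 1.5 and
`pvalue_max` = 1e-16. Computing the differential statistics themselves is
out of scope — real data should come from an established count-based
pipeline. A convenience helper `logfc_table()` (log2 ratio of cohort means
with a pseudocount of 1, Welch t-test p) exists for synthetic data only and
is documented as non-canonical.

# Contextualization

The generic model is first reduced to its flux-consistent subnetwork:
the maximal reaction set in which every reaction can carry
$|v| \ge$ `flux_tol` in some steady-state solution. The contract — and the
test oracle — is per-reaction flux variability (maximize and minimize each
flux; keep if $\max \ge$ tol or $\min \le -$tol), iterated to a fixed
point, which makes the operation idempotent.

Per medoid, reactions whose GPR evaluates to 0 are removed (reactions with
no gene annotation always survive), and the consistent subnetwork is
re-extracted so every surviving reaction still carries flux. This is a
deliberately simple, fully specified substitute for weighted core/non-core
extraction schemes (FASTCORE/rFASTCORMICS): it preserves the same
input→output role (medoid → consistent condition-specific model) with a
contract that can be checked exactly. Missing medoid genes are a strict
error by default (`missing_gene = "inactive"` downgrades them to 0). If
the biomass reaction does not survive, the model is returned with a
warning and growth objectives will fail downstream.

# The objective design

The three objectives (biomass, ATP, PI4P production) are scalarized by the
weighted global criterion: maximize $w_1 v_{biomass} + w_2 v_{atp} + w_3
v_{pi4p}$ for every weight vector of the simplex lattice $\{q=3, m=4\}$ —
all vectors with entries in non-negative multiples of 1/4 summing to 1,
$\binom{6}{4} = 15$ problems — plus one flux-sum minimization, 16 tests in
total.

The flux-sum minimization needs an anchor: unconstrained, its optimum is
the trivial $v = 0$. The default (`min_flux_anchor = "biomass"`) follows
the parsimonious-FBA convention and fixes biomass at its single-objective
maximum before minimizing $\sum_j |v_j|$ (absolute values via flux
splitting into non-negative parts, applied to reversible columns).
`"none"` solves the unanchored problem and flags the result degenerate.

Optima are deduplicated greedily in input order at L∞ tolerance
`dedup_tol` (1e-6): a solution within tolerance of an already-kept one is
redundant. All occurrence statistics are computed over the non-redundant
set.

**Essentiality** is assessed once per model against the biomass objective:
knock out each reaction ($lb = ub = 0$), re-maximize biomass under the
oxygen cap, and call the reaction essential when the optimum drops by at
least `essentiality_drop` (5%). An infeasible knockout counts as a 100%
drop. Two readings of scope are possible — once per model versus once per
objective mixture; the package evaluates essentiality once per
contextualized model under the biomass objective, matching the anchoring
of the criterion to the biomass flux, and exposes the per-model screen so
a per-test analysis can be assembled if wanted. Essentiality is
context-dependent: a redundant reaction in the generic model can become
essential in a contextualized model that lost its partner.

# Topology of one optimum

Each non-redundant optimum induces a *reduced network*: reactions with
$|v| >$ `flux_tol`, each column multiplied by the sign of its flux so the
matrix always reads forward, and metabolites that lost all reactions
dropped. Only coefficient signs matter for topology; magnitudes are
ignored. Exchange/boundary reactions count as producers and consumers like
any other column, so a metabolite fed only by an exchange has a
well-defined sole producer. No currency-metabolite filter is applied by
default — the classification operates on the network as given; callers can
remove currency metabolites beforehand if desired.

**Choke points.** A reaction is *single consuming* if some metabolite has
it as sole consumer, *single producing* mirror-wise, *double* if both. The
**extended** class sharpens *double*: for some witness pair (a metabolite
the reaction exclusively consumes, one it exclusively produces), its
neighborhood must consist of *strict* single choke points — every producer
of the consumed witness must be the sole producer of **each** metabolite
it produces, and every consumer of the produced witness the sole consumer
of each metabolite it consumes. The strict reading of the neighbor test is
the package's definition: with the weaker "∃ some exclusively-produced
metabolite" reading, a neighbor feeding a second, shared metabolite would
still qualify and the double and extended classes would collapse on the
canonical motifs; strictness is what makes "surrounded by single choke
points" a genuinely more stringent criterion. The quantifier over the
neighbor set is configurable (`extended_rule`): `"all"` (default,
stringent) or `"exists"`; both are covered by the brute-force oracle in
the test suite. Labels report the most specific class.

**Reaction graph and centrality.** Reactions become nodes; a directed
edge $i \to j$ exists iff some metabolite is produced by $i$ and consumed
by $j$ in the oriented network (the reaction-centric transpose of the
usual metabolite graph). PageRank uses damping 0.85 — the conventional
default, adopted here as the method does not state one — with uniform
teleportation and uniform redistribution from dangling nodes, via
`igraph::page_rank`; the suite checks it against an independent dense
power iteration to 1e-10.

# Prioritization

Per medoid model: a reaction's *occurrence* is the count of non-redundant
optima in which it is extended; it is occurrence-selected when occurrence
$\ge \lceil$ `occurrence_fraction` $\times n \rceil$ (ceiling implements
"at least half" literally for odd counts). Its *centrality* is the sum of
PageRank scores over the optima (0 when inactive); the top
$\lfloor$ `centrality_top_fraction` $\times n_{ranked} \rfloor$ reactions
by summed centrality are topology-selected, with ties at the cutoff
included (the inclusive policy favors recall, consistent with the union
of criteria downstream). Ranking on the *summed* centrality, rather than
per-optimum ranking followed by aggregation, is the package's choice where
both readings are possible.

Medoid results are combined by summing occurrence and centrality over the
models where a reaction exists, and OR-ing the selection flags. Reactions
of interest are the intersection: essential ∧ (GPR references ≥1
upregulated gene) ∧ (occurrence-selected ∨ topology-selected).

**Gene scores.** A gene's raw occurrence (centrality) is the sum over the
reactions of interest whose GPR references it. Each component is
max-normalized to [0, 1] across genes — the normalization method is not
pinned down by the method description; max-normalization keeps the two
components on a common scale regardless of how many optima or reactions
exist, and the raw sums are always emitted alongside so either convention
can be recomputed. An all-zero component stays zero (no 0/0). Relevance =
sum of the two normalized components ∈ [0, 2].

**Drug ranking.** Chemical–gene interaction snapshots (DGIdb/CTD-style
TSV exports) are joined case-sensitively to the gene scores; duplicate
(chemical, gene) pairs from multiple sources count once; unmatched rows
are dropped with a reported count. A chemical's relevance is the sum of
its matched genes' relevance; interaction direction (activity vs
expression change) is carried through for reporting but never weights the
score, since the ranking is by gene coverage. Ties sort alphabetically
for reproducibility.

# Synthetic fixtures

The generator emulates the two inputs the workflow needs, with planted
ground truth:

* **Model** — a carbon backbone (exchange at 10 mmol·gDW⁻¹·h⁻¹ → chained
  blocks → biomass sink) with the five choke-point motif shapes spliced in,
  plus oxygen-coupled ATP and capacity-limited PI4P branches so the
  objective mixtures trade off against biomass. Capacity limits inside the
  motif blocks force every planted reaction to be active at *any* biomass
  optimum, so the planted classes are realized by the designed forward
  direction regardless of which optimal vertex the solver returns; tests
  still verify the realized orientation before asserting classes (alternate
  optima guard). Planted essentiality: chain and motif-focal reactions are
  essential (capacity-limited bypasses cannot absorb the full flux),
  redundant parallel pairs are not.
* **Expression** — tumor samples drawn from two planted binary activity
  profiles; model genes active in both (except one parallel branch toggled
  off in profile B, so the two contextualized models differ), filler genes
  active in exactly one profile (this carries the cluster signal). Active
  and inactive values are 100 and 1 times a log-normal factor
  $e^{\sigma Z}$. Normal-cohort means equal the tumor mean except for the
  planted upregulated genes (the target genes plus filler up to
  `upregulated_fraction` = 0.2 of the universe), which are reduced by
  `effect_size` = 2.5 log2 units — comfortably above the 1.5 threshold
  after the pseudocount.

Default sizes — 36 reactions, 60 genes, 30 tumor and 15 normal samples —
keep every stage exact and the full pipeline around a couple of seconds,
while still exercising every rule (all five motif classes, redundancy,
cluster recovery, drug ranking).

The default noise is $\sigma = 0$, the idealized limit in which the
mean-threshold binarization is exact; as noted above, any i.i.d. noise
makes uniformly active genes binarize to roughly half the samples, which a
hard-removal contextualization then amplifies. Nonzero `noise_sigma` is
available to study that degradation. Consequently, passing the recovery
tests demonstrates the correctness of the machinery — thresholds, lattice,
classification, ranking — not robustness to the biological and technical
variability of real RNA-Seq, nor the behaviors of genome-scale models
(compartments, currency metabolites, thermodynamically infeasible loops at
scale), which the fixtures deliberately do not imitate.

# Numerical choices and degenerate inputs

* `flux_tol` = 1e-6 (activity/consistency), `dedup_tol` = 1e-6 (optimum
  identity): absolute tolerances on fluxes of order 1–10 in the fixtures.
* LP pivot tolerance 1e-9; phase-1 feasibility at 1e-7; infinite bounds are
  clamped to ±1e6 internally, and an explicit error is raised when an
  objective reaction has an infinite upper bound (unbounded problem).
* Empty flux distributions reduce to an empty network with a warning and
  are skipped by the topology stages; an infeasible model yields an empty
  consistent subnetwork with a warning.
* PAM ties and silhouette ties resolve to the smallest index/k;
  deduplication keeps the first of equals (input order is the
  deterministic design order); drug ties sort alphabetically. Two runs
  with identical inputs, configuration and seed write byte-identical TSVs
  (numeric formatting is fixed at `%.10g`).

# Limitations

* The contextualization is a contracted substitute for published weighted
  core-extraction methods; on real data it is more aggressive (hard
  removal) and interacts with the noise sensitivity of mean-threshold
  binarization described above.
* Essentiality, occurrence and centrality all depend on the particular
  optima returned for degenerate LPs; the design (16 tests, deduplication,
  occurrence over non-redundant optima) mitigates but does not remove
  this.
* The SBML reader covers the Level 3 + FBC v2 subset the writer emits
  (bounds as parameters, nested gene associations); it is not a general
  SBML implementation.
* Interaction tables are static snapshots; no live database access, no
  literature triage — the ranked list is the hand-off point to manual
  review.
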