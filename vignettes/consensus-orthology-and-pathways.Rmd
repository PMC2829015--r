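---
title: "Consensus ortholog groups and pathway conservation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ortholog groups and pathway conservation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthopath)
```

## The problem

Transferring enzymatic function between genomes requires ortholog groups one
can trust. No single orthology method is infallible: similarity-based
methods (reciprocal best hits, Markov clustering of similarity graphs,
inparalog-aware pairwise comparison) and phylogeny-based methods disagree
substantially on real proteomes, and each brings specific information.
`orthopath` implements a consensus strategy: run several methods, keep the
*intersection* of their predictions as conservative reference groups, then
win back the sensitivity the intersection costs by enriching each reference
group with a profile HMM. Final groups carry a 0–10 confidence score
measuring how well each input method agrees with them. Complete EC numbers
are then transferred to groups from an annotated reference set and mapped
onto pathway definitions to quantify metabolic conservation per species and
per taxonomic group, and to expose pathway holes.

## The filtered best-reciprocal-hit method

The package's native orthology detector refines the classical BRH approach
with two per-hit filters, each applied symmetrically to both aligned
sequences:

* **alignment percentage** `100 · aln_len / len`, computed against each
  sequence's full length, must exceed **60%** — this discards hits that
  reflect only local conservation (one shared domain);
* **score ratio** `raw_score / self_score`, the alignment score relative to
  each sequence's score against itself (its maximum attainable score), must
  exceed **0.2**.

Both are strict inequalities, and the minimum over the two sequences must
pass (the conservative reading of thresholds stated in the plural). After
filtering, `p` and `q` in different species form a BRH pair iff each is
among the other's maximal-raw-score hits into its species; score ties are
all co-best, so the output never depends on input order. Within-species
hits are never candidates: BRH by construction does not see inparalogs.

Groups are the **maximal cliques** of the BRH graph, not its connected
components: one missing reciprocal link inside four related proteins yields
two overlapping triangles rather than one loose cluster, which is exactly
the multi-link behaviour that distinguishes this method from single-link
ones. Clique enumeration is capped (default 200 vertices per connected
component) and aborts loudly rather than hang on pathological inputs.

## Tree-based orthology

Homolog families are single-linkage components of hits with E-value below
`0.001` covering at least `70%` of the shorter protein. Gene trees for the
families are consumed as Newick (leaf dialect `proteinID|species`); rooting
uses the midpoint criterion, which is deterministic and standard. Ortholog
groups are extracted with the **species-overlap rule**: a node is a
duplication iff two of its child subtrees share a species, and groups are
the leaf sets of maximal duplication-free subtrees. The original automated
tree analysis this stands in for is not published in algorithmic detail;
because the rule is a documented stand-in, the module equally accepts
externally produced group files, so any tree-orthology tool can be
substituted at the GroupSet interface.

## Consensus, enrichment, confidence

A grouping is formalized as its **co-membership relation** (the set of
protein pairs sharing a group). The crude intersection is the conjunction
of the methods' relations, the crude union their disjunction; groups are
connected components of size ≥ 2. Components — rather than cliques — match
the observed behaviour that intersection groups are small but non-trivial.

Reference groups seed profile HMMs. To avoid biasing a profile towards
species rich in inparalogs, **one representative per genome** is kept: the
member with the highest mean raw similarity to the rest of the group
(lexicographic tie-break). Profiles are built from a MAFFT alignment with
HMMER's `hmmbuild`, concatenated into one database, and every sequence not
placed in a reference group is searched against the database
(`hmmsearch`). A sequence joins the group of its single best-scoring
profile iff the best E-value is below **10⁻¹⁰**; a tie for best hit leaves
it unassigned — specificity over sensitivity. Enrichment is single-pass;
profiles are not rebuilt from enriched groups for re-assignment.

The confidence score of a final group \(F\) over methods \(i = 1..m\) is

\[ S \;=\; \frac{10}{m}\sum_{i=1}^{m} \frac{I_{F,i}}{O_F \, G_i} \]

where \(O_F = |F|\), \(G_i\) is the number of method *i*'s groups
intersecting \(F\), and \(I_{F,i}\) the number of \(F\)'s members covered
by those groups (component 0 when \(G_i = 0\)). A method that predicts the
attested group contributes exactly 1; splitting \(F\) into two covering
halves contributes \(1/2\); diluting or truncating it contributes less.
The published prose fixes this formula's boundary behaviour (1 on the
attested group, otherwise in \((0,1]\), mean rescaled by 10) without
displaying its body; the form above is the simplest one satisfying all
three conditions, and the package treats it as the definition. Note the
restriction to \(F\): a method placing all of \(F\) inside one larger group
also scores 1, since restricted to \(F\) its prediction *is* \(F\).

```{r confidence}
F5 <- paste0("prot", 1:5)
one_method <- group_set(list(gA = F5, gB = c("u1", "u2")), method = "m1")
confidence_score(F5, list(one_method))$components
confidence_score(F5, replicate(4, one_method, simplify = FALSE))$score
```

## EC transfer and pathway conservation

Only **complete four-digit EC numbers** are handled; partial
classifications are rejected at load (strict mode) or skipped with a
warning (lenient mode). Each final group's profile is searched against the
annotated reference sequences; if the best hit's E-value is ≤ **10⁻⁸⁰**,
all of that sequence's ECs transfer to every group member. The threshold
relaxes to **10⁻²⁰** per EC already carried by at least one group member —
prior knowledge inside the group lowers the evidence bar for confirming
the same activity. Tightening the strict threshold can only remove
transfers (anti-monotone), a property the tests assert.

Pathways are ordered lists of EC steps (KEGG-reference or MetaCyc-style,
or user-defined in a simplified YAML/JSON format). A species possesses an
EC iff some group annotated with it contains one of the species' proteins;
counts of sequences per species are kept alongside presence so inparalog
expansions remain visible. From the EC × species matrix the package
derives per-taxon step conservation (denominators are the manifest's
species counts, so unannotated species count as absent), per-species
pathway completeness, ECs specific to a single pathway, and pathway holes;
when every pathway-specific EC is missing in a scope the pathway is
flagged *possibly absent* — the alternative reading to a run of
independent holes.

## The synthetic-data generator

`simulate_orthologs()` emulates the inputs the pipeline consumes in real
use: per-species proteome FASTAs, an all-vs-all similarity table, gene
trees, and (via `assign_true_ecs()`) an annotated reference set and EC
truth. A random bifurcating species tree is drawn; each family starts from
a random peptide (default 300 residues) and evolves along the tree with
per-branch duplication (default 0.07) and loss (default 0.02) and per-site
substitution (default 0.02 per branch). The defaults were chosen once so
that families average roughly 1.3 homologs per genome — the regime in
which orthology/paralogy resolution is interesting — and are the
conditions under which the acceptance checks run.

Similarity is scored by exact positional identity: `raw = 2 · matches`,
`E = L · 2^(−raw/8)`, alignment length `L`. This deterministic,
documented scheme separates family members (typically E ≪ 10⁻³) from
unrelated pairs (E > 10, below the reporting threshold, hence absent from
the table) and makes expected filter behaviour computable by hand. It does
**not** model indels, rate heterogeneity, or realistic substitution
matrices, and alignment length is always full-length — so passing tests
demonstrate the pipeline's combinatorial and threshold logic, not
robustness to genuinely hard alignment artefacts. Profile E-values in
tests are asserted only as threshold crossings with generous margins
(near-identical vs. random sequences), never as exact values, which belong
to the engine's calibration.

Method disagreement is simulated by `perturb_groups()`: each true group
independently suffers at most one event — a split in two (probability
`split_p`), a merge with a random other group (`merge_p`), or the loss of
one member (`drop_p`).

## Numerical and degenerate-input choices

* Score ratios may exceed 1 only through floating noise and are clamped.
* Representative selection and enrichment break exact ties
  lexicographically or by refusing to assign, respectively — never by
  input order.
* Group output is canonicalized (members sorted, groups sorted), so all
  stages are invariant under permutation of their inputs.
* A reference group reduced to one representative still gets a
  (single-sequence) profile, with a warning; a zero-diameter tree cannot
  be midpoint-rooted and keeps its read topology, with a warning.
* All simulator randomness flows from one integer seed; fixture sets are
  reproducible byte for byte.

## Problem sizes

The test-suite simulations use 4–6 species and 5–13 families of ~300
residues, sizes at which brute-force oracles (exhaustive clique
enumeration over vertex subsets, exhaustive pair conjunctions) remain
exact and the whole suite, including every external HMMER invocation,
completes in about a minute.

## Known limitations

* The consensus trades recall for precision on *split* groups: a family
  split by **any** input method stays split in the intersection, and
  single-pass enrichment can re-add only proteins that fell out of the
  reference entirely — it never rejoins two surviving halves. Under mild
  simulated noise the final grouping is therefore reliably better than the
  *average* input method but not always better than the luckiest single
  one; the corresponding acceptance check is reported honestly as seed-
  dependent.
* The species-overlap duplication rule is a stand-in for reconciliation-
  based tree analysis and is sensitive to gene-tree topology errors.
* EC matching is exact at four digits; wildcard matching of partial ECs
  is deliberately excluded.
* One EC per pathway step; alternative enzymes for one step are encoded
  as pathway variants.
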