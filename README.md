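# orthopath

Consensus ortholog groups across multiple proteomes, and the metabolic
conservation picture they imply.

## What it does, and for whom

Comparative genomicists reconstructing metabolism from newly sequenced
genomes face two coupled problems: no single orthology-prediction method is
reliable on its own, and enzymatic annotations can only be transferred
safely along trustworthy ortholog groups. `orthopath` addresses both:

1. **Orthology.** It natively implements a *filtered best-reciprocal-hit*
   (BRH) detector — hits must have a score ratio (alignment score over each
   sequence's self-score) over 0.2 and alignment percentages (alignment
   length over each sequence's full length) above 60%, and groups are
   maximal cliques of the reciprocal-best graph — and consumes any number of
   externally produced groupings (OrthoMCL-style group files, or its own
   gene-tree module using the species-overlap duplication rule).
2. **Consensus.** The *crude intersection* of all methods' co-membership
   relations yields conservative reference groups; each is summarised by a
   profile HMM built (MAFFT + HMMER `hmmbuild`) from one representative per
   genome, and every unplaced sequence is assigned to its single best
   profile when the `hmmsearch` E-value is below 10⁻¹⁰. Each final group
   gets a confidence score

   $$S = \frac{10}{m}\sum_{i=1}^{m}\frac{I_{F,i}}{O_F\,G_i}$$

   over the `m` input methods, where `O_F` is the group's size, `G_i` the
   number of method *i*'s groups intersecting it and `I_F,i` the number of
   members those groups cover: 10 means every method attests the group.
3. **Function and pathways.** Complete four-digit EC numbers transfer from
   an annotated reference set to a group when the best profile hit reaches
   E ≤ 10⁻⁸⁰ (relaxed to 10⁻²⁰ for an EC some group member already
   carries), and the resulting EC × species presence matrix drives
   per-taxon step conservation, per-species pathway completeness,
   pathway-specific ECs, and pathway-hole reports.

A deterministic simulator of gene-family evolution (duplication, loss,
substitution, plus split/merge/drop noise on groups) generates full fixture
sets with known truth, so the entire pipeline is testable offline.

## Worked example

```r
library(orthopath)

sim  <- simulate_orthologs(sim_config(seed = 42))   # 6 species, 12 families
lens <- setNames(Biostrings::width(sim$seqs), names(sim$seqs))

brh <- brh_orthologs(sim$hits, lens, sim$species)
#> GroupSet 'BRH': 16 group(s), 82 member slot(s) (overlapping)

methods   <- c(list(brh), lapply(1:3, function(i)
  perturb_groups(sim$truth, 0.1, 0.05, 0.1, seed = i, method = paste0("m", i))))
reference <- intersect_groupsets(methods)
#> GroupSet 'intersection': 14 group(s), 69 member slot(s)

reps  <- lapply(reference$groups, select_representatives,
                species = sim$species, hits = sim$hits)
db    <- build_profiles(reps, sim$seqs)
final <- finalize_groups(reference, assign_unplaced(sim$seqs, db, reference))
head(score_final_groups(final, methods), 3)
#>   group_id size confidence  BRH m1        m2        m3
#> 1  ref0001    6   9.166667 1.00  1 0.8333333 0.8333333
#> 2  ref0002    6  10.000000 1.00  1 1.0000000 1.0000000
#> 3  ref0003   10   8.125000 0.25  1 1.0000000 1.0000000
```

`ref0002` is attested identically by all four methods (confidence 10).
`ref0003` is a 10-member family with inparalogs: the perturbed single-link
methods find it whole, while BRH — blind to within-species links — covers
it with several overlapping cliques, giving a component of 0.25 and an
overall score of 8.1. Enrichment added 10 sequences the intersection had
left unplaced; the final grouping reaches pairwise F1 = 0.91 against the
simulated truth.

Annotation transfer and pathway analysis continue from there:

```r
ann <- assign_true_ecs(sim, seed = 42)          # synthetic reference set
fdb <- build_profiles(final$groups, sim$seqs)
gec <- transfer_annotations(fdb, ann$ref_seqs, ann$ec_table, final)
head(gec, 3)
#>   group_id       ec   rule
#> 1  ref0001  6.3.4.9 strict
#> 2  ref0002 6.3.4.11 strict
#> 3  ref0003 6.3.4.15 strict

mat <- ec_presence(gec, final, sim$species, sim$manifest$species)
pathway_conservation(example_pathways()[["biotinylation"]], mat)$per_species
#> sp01 sp02 sp03 sp04 sp05 sp06
#>  100  100  100  100  100  100
```

The four-step biotinylation ligase pathway (EC 6.3.4.9/.10/.11/.15) is
fully conserved in every simulated species, as planted.

A command-line front end with subcommands (`simulate`, `brh`, `families`,
`treeortho`, `consensus`, `annotate`, `compare-ec`, `pathway`, `run`) is
installed at `inst/cli/orthopath.R`.

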