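fixture_matrix <- function() {
  # four species, hand-built annotations
  final <- finalize_groups(group_set(list(
    g1 = c("a1", "b1", "c1"),          # spA, spB, spC
    g2 = c("a2", "d1"),                # spA, spD
    g3 = c("b2", "b3")                 # two spB inparalogs
  ), method = "intersection"))
  species <- c(a1 = "spA", a2 = "spA", b1 = "spB", b2 = "spB", b3 = "spB",
               c1 = "spC", d1 = "spD")
  group_ec <- data.frame(group_id = c("g1", "g2", "g3"),
                         ec = c("1.1.1.1", "2.2.2.2", "1.1.1.1"))
  list(final = final, species = species, group_ec = group_ec,
       mat = ec_presence(group_ec, final, species,
                         c("spA", "spB", "spC", "spD")))
}

test_that("presence is the union over groups; counts see inparalogs", {
  fx <- fixture_matrix()
  m <- fx$mat
  # 1.1.1.1 via g1 (spA,spB,spC) and g3 (spB) -> union of species
  expect_identical(unname(m$presence["1.1.1.1", ]),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(unname(m$presence["2.2.2.2", ]),
                   c(TRUE, FALSE, FALSE, TRUE))
  # spB carries three 1.1.1.1 sequences (b1 + the two inparalogs), present once
  expect_equal(m$counts["1.1.1.1", "spB"], 3L)
  expect_true(m$presence["1.1.1.1", "spB"])
})

test_that("taxon and pathway percentages follow the manifest denominators", {
  fx <- fixture_matrix()
  taxa <- c(spA = "T1", spB = "T1", spC = "T2", spD = "T2")
  pct <- step_conservation(fx$mat, taxa)
  expect_equal(pct["1.1.1.1", "T1"], 100)   # both T1 species present
  expect_equal(pct["1.1.1.1", "T2"], 50)
  expect_equal(pct["2.2.2.2", "T1"], 50)
  expect_true(all(pct >= 0 & pct <= 100))

  pw <- pathway("toy", "user", c("1.1.1.1", "2.2.2.2", "9.9.9.9",
                                 "8.8.8.8"))
  cons <- pathway_conservation(pw, fx$mat)
  expect_equal(unname(cons$per_species["spA"]), 50)   # 2 of 4 steps
  expect_equal(unname(cons$per_species["spC"]), 25)
  expect_equal(unname(cons$per_step["9.9.9.9"]), 0)   # absent EC: 0%, no error
  expect_equal(unname(cons$per_step["1.1.1.1"]), 75)
  # internal consistency: completeness = mean of per-step indicators x 100
  for (sp in colnames(fx$mat$presence)) {
    ind <- vapply(unique(pw$steps), function(ec)
      ec %in% rownames(fx$mat$presence) && fx$mat$presence[ec, sp], TRUE)
    expect_equal(unname(cons$per_species[sp]), 100 * mean(ind))
  }

  # duplicate steps are deduplicated in the denominator
  dup <- pathway("dup", "user", c("1.1.1.1", "1.1.1.1", "2.2.2.2"))
  expect_equal(pathway_conservation(dup, fx$mat)$n_steps, 2)
})

test_that("adding an annotation never decreases conservation", {
  fx <- fixture_matrix()
  taxa <- c(spA = "T1", spB = "T1", spC = "T2", spD = "T2")
  before <- step_conservation(fx$mat, taxa)
  more <- rbind(fx$group_ec, data.frame(group_id = "g2", ec = "1.1.1.1"))
  after <- step_conservation(
    ec_presence(more, fx$final, fx$species, colnames(fx$mat$presence)),
    taxa)
  expect_true(all(after[rownames(before), ] >= before))
})

test_that("pathway-specific ECs are those appearing in exactly one pathway", {
  coll <- pathway_collection(list(
    pathway("P1", "kegg", c("1.1.1.1", "2.2.2.2")),
    pathway("P2", "kegg", c("2.2.2.2", "3.3.3.3"))))
  spec <- pathway_specific_ecs(coll)
  expect_identical(spec$P1, "1.1.1.1")
  expect_identical(spec$P2, "3.3.3.3")    # 2.2.2.2 shared: specific to neither
  solo <- pathway_collection(list(pathway("only", "user",
                                          c("4.4.4.4", "5.5.5.5"))))
  expect_setequal(pathway_specific_ecs(solo)$only, c("4.4.4.4", "5.5.5.5"))
  # invariant under reordering
  rev_coll <- pathway_collection(rev(unclass(coll)))
  expect_identical(pathway_specific_ecs(rev_coll)[names(spec)], spec)
})

test_that("holes are scope-dependent and flag possibly absent pathways", {
  fx <- fixture_matrix()
  pw <- pathway("toy", "user", c("1.1.1.1", "2.2.2.2"))
  h_spB <- find_pathway_holes(pw, fx$mat, "species", target = "spB")
  expect_identical(h_spB$holes, "2.2.2.2")     # absent in spB, present elsewhere
  h_glob <- find_pathway_holes(pw, fx$mat, "global")
  expect_length(h_glob$holes, 0)

  taxa <- c(spA = "T1", spB = "T1", spC = "T2", spD = "T2")
  h_t2 <- find_pathway_holes(pw, fx$mat, "taxon", target = "T2", taxa = taxa)
  expect_length(h_t2$holes, 0)                 # spD has 2.2.2.2, spC has 1.1.1.1

  # all specific ECs absent in a species -> possibly absent pathway
  coll <- pathway_collection(list(pw, pathway("other", "kegg", "1.1.1.1")))
  h <- find_pathway_holes(pw, fx$mat, "species", target = "spC",
                          collection = coll)
  expect_identical(h$holes, "2.2.2.2")         # the pathway-specific EC
  expect_true(h$possibly_absent)
  h2 <- find_pathway_holes(pw, fx$mat, "species", target = "spA",
                           collection = coll)
  expect_false(h2$possibly_absent)
})

test_that("EC-to-pathway lookup reports names grouped by source", {
  coll <- pathway_collection(list(
    pathway("K1", "kegg", c("1.1.1.1", "2.2.2.2")),
    pathway("K2", "kegg", "1.1.1.1"),
    pathway("M1", "metacyc", "1.1.1.1")))
  got <- pathways_containing_ec(coll, "1.1.1.1")
  expect_identical(got$kegg, c("K1", "K2"))
  expect_identical(got$metacyc, "M1")
  none <- pathways_containing_ec(coll, "9.9.9.9")
  expect_length(unlist(none), 0)
})

test_that("the tabular report ties presence, counts and completeness", {
  fx <- fixture_matrix()
  coll <- pathway_collection(list(pathway("toy", "user",
                                          c("1.1.1.1", "2.2.2.2"))))
  rep <- pathway_report(coll, fx$mat)
  expect_equal(nrow(rep), 2 * 4)
  row <- rep[rep$step_ec == "1.1.1.1" & rep$species == "spB", ]
  expect_true(row$present)
  expect_equal(row$count, 3L)
  expect_equal(row$species_completeness_pct, 50)
})
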