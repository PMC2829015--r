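test_that("hit statistics compute alignment percentages and clamped ratios", {
  st <- hit_statistics(aln_len = 60, len_q = 100, len_s = 120,
                       raw_score = 50, self_q = 100, self_s = 200)
  expect_equal(st$aln_pct_q, 60.0)
  expect_equal(st$aln_pct_s, 50.0)
  expect_equal(st$ratio_q, 0.5)
  expect_equal(st$ratio_s, 0.25)

  ident <- hit_statistics(100, 100, 100, 300, 300, 300)
  expect_equal(ident$ratio_q, 1.0)
  expect_equal(ident$ratio_s, 1.0)
  expect_equal(ident$aln_pct_q, 100.0)

  noisy <- hit_statistics(100, 100, 100, 300 * (1 + 1e-15), 300, 300)
  expect_lte(noisy$ratio_q, 1)             # floating noise clamped

  expect_error(hit_statistics(60, 100, 120, 50, 0, 200), "self-alignment")
  expect_error(hit_statistics(60, 0, 120, 50, 100, 200), "strictly positive")
})

test_that("both thresholds are strict and applied to both sequences", {
  species <- c(p = "spA", q = "spB")
  lengths <- c(p = 100, q = 100)
  mk <- function(raw, aln, self_p = 1000, self_q = 1000) {
    data.frame(query = c("p", "q", "p"), subject = c("p", "q", "q"),
               pident = 90, aln_len = c(100, 100, aln), evalue = 1e-30,
               raw_score = c(self_p, self_q, raw))
  }
  surv <- function(h, ...) nrow(filter_hits(h, lengths, species, ...))

  # one alignment percentage at the threshold (60 not > 60) -> removed
  expect_equal(surv(mk(raw = 500, aln = 60)), 0)
  # one ratio exactly 0.2 -> removed ("over 0.2" is strict)
  expect_equal(surv(mk(raw = 200, aln = 90, self_p = 1000, self_q = 220)), 0)
  # all four statistics strictly above -> kept
  expect_equal(surv(mk(raw = 210, aln = 61)), 1)
  # min-rule: failing on the subject side alone is enough
  expect_equal(surv(mk(raw = 500, aln = 90, self_q = 2600)), 0)

  # self-hits and within-species hits never survive
  h <- mk(raw = 500, aln = 90)
  same_sp <- c(p = "spA", q = "spA")
  expect_equal(nrow(filter_hits(h, lengths, same_sp)), 0)
  expect_false(any(filter_hits(h, lengths, species)$query ==
                     filter_hits(h, lengths, species)$subject))

  # raising either threshold never increases survivors
  set.seed(7)
  big <- data.frame(query = "p", subject = "q", pident = 90,
                    aln_len = sample(50:100, 40, TRUE), evalue = 1e-30,
                    raw_score = sample(100:900, 40, TRUE))
  big <- rbind(mk(500, 90)[1:2, ], big)
  n1 <- surv(big, score_ratio_min = 0.2, aln_pct_min = 60)
  n2 <- surv(big, score_ratio_min = 0.5, aln_pct_min = 60)
  n3 <- surv(big, score_ratio_min = 0.2, aln_pct_min = 80)
  expect_lte(n2, n1)
  expect_lte(n3, n1)

  expect_error(filter_hits(mk(500, 90)[3, ], lengths, species),
               "self-alignment score")
})

test_that("reciprocal best hits honour ties and non-reciprocity", {
  species <- c(p = "spA", q = "spB", q2 = "spB", r = "spA")
  filtered <- data.frame(
    query = c("p", "q"), subject = c("q", "p"), pident = 95,
    aln_len = 100, evalue = 1e-40, raw_score = 250,
    ratio_q = 0.5, ratio_s = 0.5, aln_pct_q = 100, aln_pct_s = 100)
  expect_equal(find_brh_pairs(filtered, species),
               data.frame(a = "p", b = "q"))

  # q's best in spA is r, not p -> no pair
  nonrec <- data.frame(
    query = c("p", "q", "q"), subject = c("q", "p", "r"), pident = 95,
    aln_len = 100, evalue = 1e-40, raw_score = c(250, 250, 300))
  expect_equal(nrow(find_brh_pairs(nonrec, species)), 0)

  # tie: p -> q and p -> q2 both at 250, both reciprocate -> two pairs
  tie <- data.frame(
    query = c("p", "p", "q", "q2"), subject = c("q", "q2", "p", "p"),
    pident = 95, aln_len = 100, evalue = 1e-40, raw_score = 250)
  got <- find_brh_pairs(tie, species)
  expect_equal(got, data.frame(a = c("p", "p"), b = c("q", "q2")))
})

test_that("a missing BRH link yields two overlapping clique groups", {
  # four related proteins, the A2-A4 link absent
  pairs <- data.frame(a = c("A1", "A1", "A2", "A1", "A3"),
                      b = c("A2", "A3", "A3", "A4", "A4"))
  gs <- build_brh_groups(pairs)
  expect_identical(group_keys(gs), c("A1 A2 A3", "A1 A3 A4"))
  expect_true(gs$overlapping)

  expect_identical(group_keys(build_brh_groups(
    data.frame(a = "p", b = "q"))), "p q")

  full <- t(combn(paste0("v", 1:5), 2))
  k5 <- build_brh_groups(data.frame(a = full[, 1], b = full[, 2]))
  expect_identical(group_keys(k5), paste(paste0("v", 1:5), collapse = " "))

  expect_error(build_brh_groups(data.frame(a = full[, 1], b = full[, 2]),
                                max_component = 4), "cap")
})

test_that("clique groups match brute-force enumeration on random graphs", {
  set.seed(11)
  for (rep in 1:40) {
    nv <- sample(3:9, 1)
    verts <- paste0("x", seq_len(nv))
    cmb <- t(combn(verts, 2))
    keep <- runif(nrow(cmb)) < 0.45
    if (!any(keep)) next
    pairs <- data.frame(a = cmb[keep, 1], b = cmb[keep, 2])
    expect_identical(group_keys(build_brh_groups(pairs)),
                     brute_force_max_cliques(pairs))
  }
})

test_that("BRH output is invariant under permutation of input hits", {
  set.seed(23)
  sim <- simulate_orthologs(sim_config(n_species = 4, n_families = 5,
                                       seed = 5))
  lens <- stats::setNames(Biostrings::width(sim$seqs), names(sim$seqs))
  base <- brh_orthologs(sim$hits, lens, sim$species)
  shuf <- brh_orthologs(sim$hits[sample(nrow(sim$hits)), ], lens,
                        sim$species)
  expect_identical(group_keys(base), group_keys(shuf))
  # every pair in every group spans two species (groups are cross-species
  # cliques)
  for (g in base$groups)
    expect_gte(length(unique(sim$species[g])), 2)
})
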