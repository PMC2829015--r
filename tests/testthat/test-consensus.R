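test_that("co-membership formalizes groups as a pair relation", {
  expect_identical(co_membership(group_set(list(c("a", "b", "c")))),
                   c("a|b", "a|c", "b|c"))
  over <- group_set(list(c("a", "b"), c("b", "c")), overlapping = TRUE)
  expect_identical(co_membership(over), c("a|b", "b|c"))  # not a|c
  expect_length(co_membership(group_set(list())), 0)
})

test_that("crude intersection and union behave as conjunction/disjunction", {
  m1 <- group_set(list(c("a", "b", "c")), method = "m1")
  m2 <- group_set(list(c("a", "b"), c("c", "z")), method = "m2")
  inter <- intersect_groupsets(list(m1, m2))
  expect_identical(group_keys(inter), "a b")

  same <- replicate(4, group_set(list(c("a", "b", "c"))), simplify = FALSE)
  expect_identical(group_keys(intersect_groupsets(same)), "a b c")
  expect_identical(group_keys(union_groupsets(same)), "a b c")

  # disjoint groupings of the same universe -> no reference groups
  d1 <- group_set(list(c("a", "b"), c("c", "d")))
  d2 <- group_set(list(c("a", "c"), c("b", "d")))
  expect_length(intersect_groupsets(list(d1, d2)), 0)
  # ...but the union chains everything together
  expect_identical(group_keys(union_groupsets(list(d1, d2))), "a b c d")
})

test_that("intersection and union match brute force on random GroupSets", {
  set.seed(101)
  universe <- paste0("p", 1:9)
  for (rep in 1:80) {
    sets <- replicate(sample(2:4, 1), random_groupset(universe),
                      simplify = FALSE)
    rel_and <- Reduce(intersect, lapply(sets, function(s)
      brute_force_pairs(s$groups)))
    rel_or <- Reduce(union, lapply(sets, function(s)
      brute_force_pairs(s$groups)))
    expect_identical(group_keys(intersect_groupsets(sets)),
                     brute_force_components(rel_and))
    expect_identical(group_keys(union_groupsets(sets)),
                     brute_force_components(rel_or))
    # relation containments
    for (s in sets) {
      expect_true(all(co_membership(intersect_groupsets(sets)) %in%
                        co_membership(s)))
      expect_true(all(co_membership(s) %in%
                        co_membership(union_groupsets(sets))))
    }
    # largest union group at least as large as largest intersection group
    big <- function(gs) if (length(gs)) max(lengths(gs$groups)) else 0
    expect_gte(big(union_groupsets(sets)), big(intersect_groupsets(sets)))
  }
})

test_that("one representative per genome maximizes mean similarity", {
  species <- c(x1 = "spX", x2 = "spX", y1 = "spY")
  hits <- data.frame(query = c("x1", "x2"), subject = c("y1", "y1"),
                     pident = 90, aln_len = 100, evalue = 1e-40,
                     raw_score = c(180, 120))
  reps <- select_representatives(c("x1", "x2", "y1"), species, hits)
  expect_identical(reps[["spX"]], "x1")
  expect_identical(reps[["spY"]], "y1")    # single member kept

  tie <- transform(hits, raw_score = c(150, 150))
  expect_identical(select_representatives(c("x1", "x2", "y1"), species,
                                          tie)[["spX"]], "x1")
})

test_that("finalization records provenance and never loses reference members", {
  ref <- group_set(list(r1 = c("a", "b")), method = "intersection")
  fin <- finalize_groups(ref, c(c1 = "r1"))
  expect_setequal(fin$groups$r1, c("a", "b", "c1"))
  expect_identical(unname(fin$provenance$r1[c("a", "b", "c1")]),
                   c("reference", "reference", "enriched"))

  unchanged <- finalize_groups(ref)
  expect_identical(unchanged$groups$r1, c("a", "b"))
  expect_true(all(ref$groups$r1 %in% fin$groups$r1))
})

test_that("confidence components follow the agreement formula", {
  F5 <- paste0("f", 1:5)
  exact <- group_set(list(F5, c("u", "v")), method = "exact")
  cs <- confidence_score(F5, list(exact))
  expect_equal(unname(cs$components), 1)   # attested group -> component 1
  expect_equal(cs$score, 10)

  four <- replicate(4, exact, simplify = FALSE)
  expect_equal(confidence_score(F5, four)$score, 10)

  # O = 4, method splits F into two groups of two: s = 4 / (4 * 2) = 0.5
  F4 <- paste0("f", 1:4)
  split2 <- group_set(list(F4[1:2], F4[3:4]), method = "split")
  cs2 <- confidence_score(F4, list(split2))
  expect_equal(unname(cs2$components), 0.5)
  expect_equal(cs2$score, 5)

  # method missing the group entirely -> component 0
  far <- group_set(list(c("u", "v")), method = "far")
  expect_equal(unname(confidence_score(F5, list(far))$components), 0)

  expect_error(confidence_score(character(0), list(exact)), "empty")
})

test_that("components stay in [0, 1] and reach 10 only on exact agreement", {
  set.seed(57)
  universe <- paste0("q", 1:10)
  for (rep in 1:60) {
    sets <- replicate(3, random_groupset(universe), simplify = FALSE)
    fin <- random_groupset(universe, method = "Final")
    for (gid in names(fin$groups)) {
      members <- fin$groups[[gid]]
      cs <- confidence_score(members, sets)
      expect_true(all(cs$components >= 0 & cs$components <= 1))
      # restricted to F, a method agrees exactly iff a single one of its
      # groups touches F and that group covers all of F
      exact_everywhere <- all(vapply(sets, function(s) {
        touching <- Filter(function(g) length(intersect(g, members)) > 0,
                           s$groups)
        length(touching) == 1 && all(members %in% touching[[1]])
      }, TRUE))
      expect_identical(cs$score == 10, exact_everywhere)
    }
  }
})

test_that("GroupSet comparison counts identical and specific groups", {
  A <- group_set(list(c("a", "b"), c("c", "d")), method = "A")
  B <- group_set(list(c("a", "b"), c("c", "e")), method = "B")
  cmp <- compare_groupsets(A, B, denominator = "union")
  expect_equal(cmp$identical_count, 1)
  expect_equal(cmp$specific_to_a, 1)
  expect_equal(cmp$specific_to_b, 1)
  expect_equal(cmp$denominator, 3)
  expect_equal(cmp$pct_identical, 100 / 3)

  self <- compare_groupsets(A, A, denominator = "a")
  expect_equal(self$identical_count, 2)
  expect_equal(self$specific_to_a, 0)
  expect_equal(self$pct_identical, 100)

  disjoint <- compare_groupsets(A, group_set(list(c("x", "y"))))
  expect_equal(disjoint$identical_count, 0)
})
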