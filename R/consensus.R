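#' Co-membership relation of a GroupSet
#'
#' Two proteins are co-members iff some group of the set contains both.
#' Formalizing a grouping as this symmetric, irreflexive relation is what
#' makes union and intersection of methods well defined even when one method
#' produces overlapping groups.
#'
#' @param gs a [group_set()].
#' @return character vector of canonical pair keys `"p|q"` with `p < q`,
#'   sorted and unique.
#' @export
co_membership <- function(gs) {
  stopifnot(inherits(gs, "group_set"))
  pairs <- character(0)
  for (g in gs$groups) {
    if (length(g) < 2) next
    g <- sort(g)
    cmb <- utils::combn(g, 2)
    pairs <- c(pairs, paste(cmb[1, ], cmb[2, ], sep = "|"))
  }
  sort(unique(pairs))
}

pairs_to_groups <- function(pairs, method, prefix = "g") {
  if (!length(pairs)) return(group_set(list(), method = method))
  m <- do.call(rbind, strsplit(pairs, "|", fixed = TRUE))
  g <- igraph::graph_from_data_frame(as.data.frame(m), directed = FALSE)
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- canonicalize_groups(groups[lengths(groups) >= 2])
  names(groups) <- sprintf("%s%04d", prefix, seq_along(groups))
  group_set(groups, method = method)
}

#' Crude intersection of method GroupSets
#'
#' The reference groups of the consensus pipeline: connected components
#' (size >= 2) of the conjunction of the methods' co-membership relations.
#' A protein pair survives only if every method places the two proteins in a
#' common group, so the result is conservative and disjoint.
#'
#' @param groupsets list of at least two [group_set()] objects.
#' @return a disjoint [group_set()] with `method = "intersection"`.
#' @export
intersect_groupsets <- function(groupsets) {
  stopifnot(length(groupsets) >= 2)
  rel <- Reduce(intersect, lapply(groupsets, co_membership))
  pairs_to_groups(rel, "intersection", prefix = "ref")
}

#' Crude union of method GroupSets
#'
#' Connected components of the disjunction of co-membership relations: a pair
#' is related if any method groups it.  Merges aggressively (chains across
#' methods), which is why the pipeline enriches the intersection instead.
#'
#' @param groupsets list of [group_set()] objects.
#' @return a disjoint [group_set()] with `method = "union"`.
#' @export
union_groupsets <- function(groupsets) {
  stopifnot(length(groupsets) >= 1)
  rel <- Reduce(union, lapply(groupsets, co_membership))
  pairs_to_groups(rel, "union", prefix = "uni")
}

#' Select one representative per genome
#'
#' To avoid biasing a group's HMM profile towards species with many
#' inparalogs, only one member per species seeds the profile: the member with
#' the highest mean raw similarity score against the other group members
#' (ties broken towards the lexicographically smallest id; a species' single
#' member is kept as is).
#'
#' @param members character vector of the group's protein ids.
#' @param species named character vector, protein id -> species.
#' @param hits similarity data.frame (raw scores used; direction ignored).
#' @return named character vector, species -> representative protein id.
#' @export
select_representatives <- function(members, species, hits) {
  members <- sort(unique(members))
  sp <- species[members]
  if (anyNA(sp))
    stop("no species for member(s): ",
         paste(members[is.na(sp)], collapse = ", "))
  sub <- hits[hits$query %in% members & hits$subject %in% members &
                hits$query != hits$subject, , drop = FALSE]
  score_of <- function(m) {
    s <- c(sub$raw_score[sub$query == m], sub$raw_score[sub$subject == m])
    if (length(s)) mean(s) else 0
  }
  reps <- vapply(split(members, sp), function(ms) {
    if (length(ms) == 1) return(ms)
    sc <- vapply(ms, score_of, 0)
    ms <- ms[sc == max(sc)]
    min(ms)              # lexicographic tie-break
  }, "")
  reps
}

#' Enrich reference groups into final groups
#'
#' Adds profile-assigned proteins to their reference groups.  Final members
#' are the union of reference members and assigned members, each carrying a
#' provenance flag; groups left with fewer than two members are dropped.
#'
#' @param reference a disjoint [group_set()] of reference groups.
#' @param assignments named character vector, protein id -> group id, from
#'   [assign_unplaced()].
#' @return a `final_groups` object: a [group_set()] with `method = "Final"`
#'   plus a `provenance` field (list of named character vectors,
#'   member -> `"reference"`/`"enriched"`).
#' @export
finalize_groups <- function(reference, assignments = character(0)) {
  stopifnot(inherits(reference, "group_set"))
  groups <- reference$groups
  prov <- lapply(groups, function(g) stats::setNames(rep("reference",
                                                         length(g)), g))
  for (p in names(assignments)) {
    gid <- assignments[[p]]
    if (!gid %in% names(groups)) stop("assignment to unknown group: ", gid)
    if (p %in% groups[[gid]]) next
    groups[[gid]] <- c(groups[[gid]], p)
    prov[[gid]][p] <- "enriched"
  }
  keep <- lengths(groups) >= 2
  groups <- lapply(groups[keep], sort)
  prov <- lapply(names(groups), function(gid) prov[[gid]][groups[[gid]]])
  names(prov) <- names(groups)
  out <- group_set(groups, method = "Final", overlapping = FALSE)
  out$provenance <- prov
  class(out) <- c("final_groups", class(out))
  out
}

#' @export
print.final_groups <- function(x, ...) {
  NextMethod()
  enriched <- sum(vapply(x$provenance,
                         function(p) sum(p == "enriched"), 0L))
  cat(sprintf("  %d enriched member(s)\n", enriched))
  invisible(x)
}

#' Confidence score of a final group
#'
#' Measures agreement between a final group `F` and the `m` method
#' predictions it was built from.  For method `i`, let `G_i` be the number of
#' that method's groups intersecting `F`, and `I_i` the number of `F`'s
#' members that those groups cover; with `O = |F|` the per-method component
#' is `s_i = I_i / (O * G_i)` (0 when no group of the method touches `F`).
#' A method that predicts exactly `F` scores 1; splitting, truncating or
#' diluting `F` scores in `(0, 1)`.  The overall score is the mean component
#' rescaled to 0-10: `S = 10 * mean(s_i)`, so `S = 10` iff every method
#' predicts the attested group.
#'
#' @param members character vector: the final group's protein ids.
#' @param method_sets list of [group_set()] objects, one per method.
#' @return list with `score` (`S`, in `(0, 10]` whenever some method touches
#'   the group) and `components` (named by method).
#' @export
confidence_score <- function(members, method_sets) {
  members <- unique(as.character(members))
  if (!length(members)) stop("empty final group")
  stopifnot(length(method_sets) >= 1)
  o_f <- length(members)
  comp <- vapply(method_sets, function(gs) {
    touching <- Filter(function(g) length(intersect(g, members)) > 0,
                       gs$groups)
    g_i <- length(touching)
    if (g_i == 0) return(0)
    i_f <- length(intersect(unique(unlist(touching, use.names = FALSE)),
                            members))
    i_f / (o_f * g_i)
  }, 0)
  names(comp) <- vapply(method_sets, `[[`, "", "method")
  list(score = 10 * mean(comp), components = comp)
}

#' Score every final group against the input methods
#'
#' @param final a `final_groups` object (or any [group_set()]).
#' @param method_sets list of method [group_set()] objects.
#' @return data.frame with one row per group: `group_id`, `size`,
#'   `confidence`, plus one component column per method.
#' @export
score_final_groups <- function(final, method_sets) {
  rows <- lapply(names(final$groups), function(gid) {
    cs <- confidence_score(final$groups[[gid]], method_sets)
    c(list(group_id = gid, size = length(final$groups[[gid]]),
           confidence = cs$score), as.list(cs$components))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(df) <- NULL
  df
}

#' Compare two GroupSets
#'
#' Counts groups identical as member sets, and groups specific to each side
#' (identical to no group of the other).  Percentages are computed against a
#' caller-chosen denominator, since "relative percentage" is ambiguous when
#' the two sets differ in size.
#'
#' @param a,b [group_set()] objects.
#' @param denominator `"a"`, `"b"` or `"union"` (count of distinct groups
#'   across both sets).
#' @return list with `identical_count`, `specific_to_a`, `specific_to_b`,
#'   `pct_identical`, `pct_specific_a`, `pct_specific_b`, `denominator`.
#' @export
compare_groupsets <- function(a, b, denominator = c("a", "b", "union")) {
  denominator <- match.arg(denominator)
  key <- function(gs) unique(vapply(gs$groups,
                                    function(g) paste(sort(g), collapse = " "),
                                    ""))
  ka <- key(a); kb <- key(b)
  ident <- length(intersect(ka, kb))
  den <- switch(denominator, a = length(ka), b = length(kb),
                union = length(union(ka, kb)))
  pct <- function(n) if (den == 0) NA_real_ else 100 * n / den
  list(identical_count = ident,
       specific_to_a = length(setdiff(ka, kb)),
       specific_to_b = length(setdiff(kb, ka)),
       pct_identical = pct(ident),
       pct_specific_a = pct(length(setdiff(ka, kb))),
       pct_specific_b = pct(length(setdiff(kb, ka))),
       denominator = den)
}
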