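#' Construct a GroupSet
#'
#' A GroupSet is a labelled collection of ortholog groups produced by one
#' prediction method or one pipeline stage.  Groups are character vectors of
#' protein identifiers.  Sets from single-link methods (Inparanoid-like,
#' OrthoMCL-like, tree-based, crude intersection) are disjoint; the filtered
#' best-reciprocal-hit method builds groups as maximal cliques, so one protein
#' may legitimately belong to several groups and `overlapping = TRUE` must be
#' set for such sets.
#'
#' @param groups list of character vectors of protein ids (one per group).
#'   Unnamed groups receive ids `g1, g2, ...` in order.
#' @param method label of the producing method (e.g. `"BRH"`, `"Final"`).
#' @param overlapping logical; may one protein appear in several groups?
#' @return an object of class `group_set`.
#' @export
group_set <- function(groups, method = "unknown", overlapping = FALSE) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) as.character(g))
  for (g in groups) {
    if (anyDuplicated(g))
      stop("duplicate member within one group: ",
           paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  if (is.null(names(groups)) && length(groups))
    names(groups) <- paste0("g", seq_along(groups))
  if (!overlapping && length(groups)) {
    all_members <- unlist(groups, use.names = FALSE)
    if (anyDuplicated(all_members))
      stop("groups overlap but overlapping = FALSE; offending member(s): ",
           paste(utils::head(unique(all_members[duplicated(all_members)]), 5),
                 collapse = ", "))
  }
  structure(list(method = method, groups = groups, overlapping = overlapping),
            class = "group_set")
}

#' @export
print.group_set <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat(sprintf("GroupSet '%s': %d group(s), %d member slot(s)%s\n",
              x$method, length(x$groups), sum(sizes),
              if (x$overlapping) " (overlapping)" else ""))
  if (length(sizes))
    cat(sprintf("  group sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.group_set <- function(x) length(x$groups)

#' All protein ids appearing in a GroupSet
#' @param gs a `group_set`.
#' @return character vector of unique member ids, sorted.
#' @export
group_members <- function(gs) {
  stopifnot(inherits(gs, "group_set"))
  sort(unique(unlist(gs$groups, use.names = FALSE)))
}

# Canonical order: members sorted within groups, groups sorted lexicographically
# by their member string.  Makes outputs invariant to input ordering.
canonicalize_groups <- function(groups) {
  groups <- lapply(groups, function(g) sort(unique(as.character(g))))
  keys <- vapply(groups, paste, "", collapse = " ")
  groups[order(keys)]
}

#' Pairwise F1 between two group collections
#'
#' Precision/recall/F1 on co-membership pairs: a pair of proteins counts as
#' predicted (or true) if some group of the respective set contains both.
#' The standard scalar summary for comparing an ortholog clustering against a
#' known truth.
#'
#' @param predicted,truth `group_set` objects.
#' @return list with `precision`, `recall`, `f1` (all in `[0, 1]`; `f1 = 0`
#'   when either set has no pairs).
#' @export
group_f1 <- function(predicted, truth) {
  pp <- co_membership(predicted)
  tp <- co_membership(truth)
  if (!length(pp) || !length(tp))
    return(list(precision = 0, recall = 0, f1 = 0))
  hit <- length(intersect(pp, tp))
  prec <- hit / length(pp)
  rec <- hit / length(tp)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1)
}
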