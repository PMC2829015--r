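#' Build families of homologous proteins
#'
#' Keeps hits with an E-value below `e_max` and an alignment extending over at
#' least `min_frac_shorter` of the length of the shorter matching protein,
#' then takes single-linkage connected components of the kept-hit graph.
#' Families of size >= 2 are returned; these are the units gene trees are
#' inferred from.
#'
#' @param hits data.frame from [read_similarity_table()].
#' @param lengths named numeric vector, protein id -> residue count.
#' @param e_max E-value cutoff (default 0.001, exclusive).
#' @param min_frac_shorter minimum fraction of the shorter protein covered by
#'   the alignment (default 0.70, inclusive).
#' @return a [group_set()] with `method = "families"`.
#' @export
build_homolog_families <- function(hits, lengths, e_max = 0.001,
                                   min_frac_shorter = 0.70) {
  cross <- hits[hits$query != hits$subject, , drop = FALSE]
  ids <- unique(c(cross$query, cross$subject))
  miss <- ids[!ids %in% names(lengths)]
  if (length(miss))
    stop("no sequence length for protein(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  shorter <- pmin(lengths[cross$query], lengths[cross$subject])
  keep <- cross$evalue < e_max & cross$aln_len >= min_frac_shorter * shorter
  kept <- cross[keep, , drop = FALSE]
  if (!nrow(kept))
    return(group_set(list(), method = "families"))
  g <- igraph::graph_from_data_frame(kept[, c("query", "subject")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  fams <- split(names(comp$membership), comp$membership)
  fams <- canonicalize_groups(fams[lengths(fams) >= 2])
  names(fams) <- sprintf("fam%04d", seq_along(fams))
  group_set(fams, method = "families")
}

#' Midpoint-root a gene tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path
#' (deterministic for a fixed input).  A zero-diameter tree cannot be
#' midpoint-rooted; the topology is kept as read, rooted at its first
#' internal node, with a warning.
#'
#' @param tree an [ape] `phylo` object with branch lengths.
#' @return a rooted `phylo`; leaf id/species attributes are re-derived when
#'   the labels follow the `proteinID|species` dialect.
#' @export
root_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("midpoint rooting requires branch lengths")
  if (max(ape::cophenetic.phylo(tree)) == 0) {
    warning("zero-diameter tree: keeping root at first internal node")
    out <- tree
  } else {
    out <- phangorn::midpoint(tree)
  }
  if (all(grepl("|", out$tip.label, fixed = TRUE)))
    out <- annotate_leaf_species(out)
  out
}

#' Extract ortholog groups from a rooted gene tree
#'
#' Internal nodes are labelled by the species-overlap rule: a node is a
#' duplication iff at least two of its child subtrees share a species
#' (descendants of a speciation node must live in disjoint species sets).
#' Ortholog groups are the leaf sets of the maximal subtrees containing no
#' duplication node; only groups of size >= 2 are reported, so a
#' same-species cherry (a pair of inparalogs) emits nothing on its own.
#'
#' @param tree a rooted `phylo` whose leaves are labelled `proteinID|species`
#'   (or carrying `leaf_id`/`leaf_species` attributes from
#'   [read_gene_tree()]).
#' @param method label for the output set (default `"Phylogeny"`).
#' @return a [group_set()] of disjoint groups of protein ids.
#' @export
extract_ortholog_groups <- function(tree, method = "Phylogeny") {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(attr(tree, "leaf_species"))) tree <- annotate_leaf_species(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ids <- attr(tree, "leaf_id")
  sps <- attr(tree, "leaf_species")
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])

  species_below <- vector("list", ntip + tree$Nnode)
  dup_free <- logical(ntip + tree$Nnode)     # no duplication in the subtree
  is_dup <- logical(ntip + tree$Nnode)

  # post-order over nodes
  walk <- function(node) {
    if (node <= ntip) {
      species_below[[node]] <<- sps[node]
      dup_free[node] <<- TRUE
      return(invisible())
    }
    kids <- children[[as.character(node)]]
    for (k in kids) walk(k)
    sets <- lapply(kids, function(k) unique(species_below[[k]]))
    shared <- FALSE
    if (length(sets) > 1) {
      for (i in seq_along(sets)[-length(sets)])
        for (j in seq((i + 1), length(sets)))
          if (length(intersect(sets[[i]], sets[[j]]))) shared <- TRUE
    }
    is_dup[node] <<- shared
    species_below[[node]] <<- unique(unlist(sets))
    dup_free[node] <<- !shared && all(dup_free[kids])
    invisible()
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  walk(root)

  groups <- list()
  collect <- function(node) {
    if (dup_free[node]) {
      leaves <- tips_below(tree, node, ntip, children)
      if (length(leaves) >= 2) groups[[length(groups) + 1]] <<- ids[leaves]
      return(invisible())
    }
    for (k in children[[as.character(node)]]) collect(k)
    invisible()
  }
  collect(root)
  groups <- canonicalize_groups(groups)
  names(groups) <- if (length(groups)) sprintf("tg%04d", seq_along(groups))
  group_set(groups, method = method)
}

# tip indices below a node (node itself if a tip)
tips_below <- function(tree, node, ntip, children) {
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    if (n <= ntip) out <- c(out, n)
    else stack <- c(stack, children[[as.character(n)]])
  }
  out
}

#' Tree-based orthology over a directory of gene trees
#'
#' Roots each Newick tree at its midpoint, extracts duplication-free ortholog
#' groups, and pools them into one GroupSet.
#'
#' @param paths character vector of Newick files.
#' @param known_species optional vector of valid species labels.
#' @return a [group_set()] with `method = "Phylogeny"`.
#' @export
tree_orthologs <- function(paths, known_species = NULL) {
  groups <- list()
  for (p in paths) {
    tr <- read_gene_tree(p, known_species)
    if (!ape::is.rooted(tr) && !is.null(tr$edge.length))
      tr <- root_tree(tr)
    gs <- extract_ortholog_groups(tr)
    groups <- c(groups, unname(gs$groups))
  }
  groups <- canonicalize_groups(groups)
  names(groups) <- if (length(groups)) sprintf("tg%04d", seq_along(groups))
  group_set(groups, method = "Phylogeny")
}
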