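# Independent brute-force oracles and small fixture builders used across the
# suite.  The oracles enumerate exhaustively and never share code with the
# implementation paths they check.

# All maximal cliques (size >= 2) of an undirected graph given as a two-column
# edge data.frame, by enumeration of every vertex subset.
brute_force_max_cliques <- function(pairs) {
  verts <- sort(unique(c(pairs$a, pairs$b)))
  edge_key <- paste(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b))
  is_clique <- function(vs) {
    if (length(vs) < 2) return(TRUE)
    cmb <- combn(vs, 2)
    all(paste(pmin(cmb[1, ], cmb[2, ]), pmax(cmb[1, ], cmb[2, ])) %in%
          edge_key)
  }
  cliques <- list()
  n <- length(verts)
  for (mask in seq_len(2^n - 1)) {
    vs <- verts[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(vs) >= 2 && is_clique(vs)) cliques[[length(cliques) + 1]] <- vs
  }
  # keep only maximal ones
  keys <- vapply(cliques, function(v) paste(sort(v), collapse = " "), "")
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j)
      i != j && all(cliques[[i]] %in% cliques[[j]]), TRUE))
  }, TRUE)
  sort(unique(keys[maximal]))
}

group_keys <- function(gs) {
  sort(unname(vapply(gs$groups,
                     function(g) paste(sort(g), collapse = " "), "")))
}

# Brute-force co-membership pairs of a list of member vectors.
brute_force_pairs <- function(groups) {
  out <- character(0)
  for (g in groups) {
    g <- sort(unique(g))
    if (length(g) < 2) next
    for (i in seq_along(g)[-length(g)])
      for (j in seq((i + 1), length(g)))
        out <- c(out, paste(g[i], g[j], sep = "|"))
  }
  sort(unique(out))
}

# Connected components (size >= 2) of a pair-key relation, by iterative
# label propagation over an explicit membership map.
brute_force_components <- function(pair_keys) {
  if (!length(pair_keys)) return(character(0))
  m <- do.call(rbind, strsplit(pair_keys, "|", fixed = TRUE))
  verts <- sort(unique(c(m[, 1], m[, 2])))
  label <- stats::setNames(seq_along(verts), verts)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(m))) {
      a <- m[r, 1]; b <- m[r, 2]
      lo <- min(label[a], label[b])
      if (label[a] != lo || label[b] != lo) {
        label[c(a, b)] <- lo
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comps <- split(names(label), label)
  comps <- comps[lengths(comps) >= 2]
  sort(unname(vapply(comps, function(v) paste(sort(v), collapse = " "), "")))
}

# A toy similarity table in which every protein is its own species unless a
# species map says otherwise; full-length alignments, strong E-values.
toy_hits <- function(edges, score = 250, len = 100) {
  ids <- sort(unique(c(edges$a, edges$b)))
  self <- data.frame(query = ids, subject = ids, pident = 100,
                     aln_len = len, evalue = 0, raw_score = score + 50)
  cross <- data.frame(query = c(edges$a, edges$b),
                      subject = c(edges$b, edges$a), pident = 95,
                      aln_len = len, evalue = 1e-50,
                      raw_score = rep(if (length(score) == nrow(edges))
                        score else rep(score, nrow(edges)), 2))
  rbind(self, cross)
}

# Random disjoint GroupSet over a fixed universe.
random_groupset <- function(universe, method = "rnd") {
  n <- length(universe)
  k <- sample(1:max(1, n %/% 2), 1)
  label <- sample(k, n, replace = TRUE)
  groups <- split(universe, label)
  groups <- groups[lengths(groups) >= 2]
  names(groups) <- if (length(groups)) paste0("g", seq_along(groups))
  group_set(groups, method = method)
}
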