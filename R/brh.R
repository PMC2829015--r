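#' Per-hit filter statistics
#'
#' For one local-alignment hit, computes the statistics the BRH filters act
#' on: the alignment percentage of each sequence (alignment length divided by
#' its total length, avoiding purely local conservation) and the score ratio
#' of each sequence (raw alignment score divided by the raw score of that
#' sequence aligned against itself, i.e. its maximum attainable score).
#' Ratios may exceed 1 only through floating-point noise and are clamped to 1.
#'
#' @param aln_len alignment length (columns), shared by both sequences.
#' @param len_q,len_s residue counts of query and subject.
#' @param raw_score raw alignment score of the hit.
#' @param self_q,self_s raw self-alignment scores of query and subject.
#' @return list with `aln_pct_q`, `aln_pct_s` (percent) and `ratio_q`,
#'   `ratio_s` (in `(0, 1]`).  All arguments vectorize.
#' @export
hit_statistics <- function(aln_len, len_q, len_s, raw_score, self_q, self_s) {
  if (any(len_q <= 0) || any(len_s <= 0))
    stop("sequence lengths must be strictly positive")
  if (any(self_q <= 0) || any(self_s <= 0))
    stop("self-alignment scores must be strictly positive")
  list(aln_pct_q = 100 * aln_len / len_q,
       aln_pct_s = 100 * aln_len / len_s,
       ratio_q = pmin(raw_score / self_q, 1),
       ratio_s = pmin(raw_score / self_s, 1))
}

#' Filter similarity hits for BRH detection
#'
#' Keeps a cross-species hit iff both score ratios strictly exceed
#' `score_ratio_min` and both alignment percentages strictly exceed
#' `aln_pct_min` ("over 0.2", "above 60%": strict inequalities, applied
#' symmetrically to the two sequences).  Self-hits and within-species hits are
#' removed from the survivor set; self-hits supply the self-scores first.
#'
#' @param hits data.frame from [read_similarity_table()].
#' @param lengths named numeric vector, protein id -> residue count.
#' @param species named character vector, protein id -> species label.
#' @param score_ratio_min minimum score ratio (default 0.2, exclusive).
#' @param aln_pct_min minimum alignment percentage (default 60, exclusive).
#' @param self_scores optional named vector of raw self-scores; when `NULL`
#'   they are taken from the self-hits (`query == subject`) of `hits`.
#' @return the surviving rows of `hits`, with statistics columns
#'   `aln_pct_q`, `aln_pct_s`, `ratio_q`, `ratio_s` appended.
#' @export
filter_hits <- function(hits, lengths, species,
                        score_ratio_min = 0.2, aln_pct_min = 60,
                        self_scores = NULL) {
  stopifnot(score_ratio_min > 0, score_ratio_min <= 1,
            aln_pct_min > 0, aln_pct_min <= 100)
  if (is.null(self_scores)) {
    self <- hits[hits$query == hits$subject, , drop = FALSE]
    self_scores <- vapply(split(self$raw_score, self$query), max, 0)
  }
  cross <- hits[hits$query != hits$subject, , drop = FALSE]
  ids <- unique(c(cross$query, cross$subject))
  miss_len <- ids[!ids %in% names(lengths)]
  if (length(miss_len))
    stop("no sequence length for protein(s): ",
         paste(utils::head(miss_len, 5), collapse = ", "))
  miss_self <- ids[!ids %in% names(self_scores)]
  if (length(miss_self))
    stop("no self-alignment score for protein(s): ",
         paste(utils::head(miss_self, 5), collapse = ", "))
  miss_sp <- ids[!ids %in% names(species)]
  if (length(miss_sp))
    stop("no species for protein(s): ",
         paste(utils::head(miss_sp, 5), collapse = ", "))
  if (!nrow(cross)) return(cbind(cross, aln_pct_q = numeric(0),
                                 aln_pct_s = numeric(0), ratio_q = numeric(0),
                                 ratio_s = numeric(0)))
  st <- hit_statistics(cross$aln_len,
                       lengths[cross$query], lengths[cross$subject],
                       cross$raw_score,
                       self_scores[cross$query], self_scores[cross$subject])
  keep <- pmin(st$ratio_q, st$ratio_s) > score_ratio_min &
    pmin(st$aln_pct_q, st$aln_pct_s) > aln_pct_min &
    species[cross$query] != species[cross$subject]
  out <- cbind(cross, as.data.frame(st))[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find best-reciprocal-hit pairs
#'
#' For each protein and each target species, the best hits are the surviving
#' hits of maximal raw score into that species (score ties are all co-best:
#' no arbitrary tie-breaking, so output is independent of input order).
#' Proteins `p`, `q` of different species form a BRH pair iff each is among
#' the other's best hits in its species.
#'
#' @param filtered surviving hits from [filter_hits()].
#' @param species named character vector, protein id -> species.
#' @return data.frame with columns `a`, `b` (unordered pairs, `a < b`),
#'   sorted; zero rows if none.
#' @export
find_brh_pairs <- function(filtered, species) {
  empty <- data.frame(a = character(), b = character())
  if (!nrow(filtered)) return(empty)
  key <- paste(filtered$query, species[filtered$subject])
  best_score <- tapply(filtered$raw_score, key, max)
  is_best <- filtered$raw_score == best_score[key]
  bq <- filtered$query[is_best]
  bs <- filtered$subject[is_best]
  fwd <- paste(bq, bs)
  rev <- paste(bs, bq)
  mutual <- fwd %in% rev
  if (!any(mutual)) return(empty)
  a <- pmin(bq[mutual], bs[mutual])
  b <- pmax(bq[mutual], bs[mutual])
  pairs <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Build BRH ortholog groups as maximal cliques
#'
#' BRH pairs form an undirected graph; ortholog groups are its maximal
#' cliques of size >= 2.  A missing reciprocal link inside a related set
#' therefore yields several overlapping groups rather than one loose
#' single-link cluster, which is exactly the multi-link behaviour that
#' distinguishes this method from single-link ones.
#'
#' @param pairs data.frame from [find_brh_pairs()] (columns `a`, `b`).
#' @param max_component clique enumeration aborts with an error if any
#'   connected component has more vertices than this cap (default 200);
#'   guards against pathological dense inputs.
#' @return a [group_set()] with `method = "BRH"`, `overlapping = TRUE`;
#'   members sorted within groups, groups sorted lexicographically.
#' @export
build_brh_groups <- function(pairs, max_component = 200) {
  if (!nrow(pairs))
    return(group_set(list(), method = "BRH", overlapping = TRUE))
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
  comp <- igraph::components(g)
  if (max(comp$csize) > max_component)
    stop("BRH graph component with ", max(comp$csize),
         " vertices exceeds the cap of ", max_component,
         "; refusing to enumerate cliques")
  cl <- igraph::max_cliques(g, min = 2)
  groups <- canonicalize_groups(lapply(cl, function(v) names(v)))
  names(groups) <- sprintf("brh%04d", seq_along(groups))
  group_set(groups, method = "BRH", overlapping = TRUE)
}

#' Filtered best-reciprocal-hit orthology, end to end
#'
#' Convenience wrapper chaining [filter_hits()], [find_brh_pairs()] and
#' [build_brh_groups()].
#'
#' @inheritParams filter_hits
#' @inheritParams build_brh_groups
#' @return a [group_set()] of overlapping BRH groups.
#' @export
brh_orthologs <- function(hits, lengths, species,
                          score_ratio_min = 0.2, aln_pct_min = 60,
                          max_component = 200) {
  surv <- filter_hits(hits, lengths, species,
                      score_ratio_min = score_ratio_min,
                      aln_pct_min = aln_pct_min)
  build_brh_groups(find_brh_pairs(surv, species),
                   max_component = max_component)
}
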