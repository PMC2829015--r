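#' Transfer EC annotations to final groups by profile search
#'
#' Each final group's profile is searched against an annotated reference set
#' (Swiss-Prot-like: every sequence carries complete four-digit EC numbers).
#' Two transfer routes apply, both to all members of the group:
#' \itemize{
#'   \item strict: if the best reference hit has E-value `<= e_strict`
#'     (default `1e-80`), all ECs of that best-hit sequence transfer;
#'   \item relaxed: an EC already carried by at least one group member also
#'     transfers if some reference sequence bearing that same EC hits the
#'     profile with E-value `<= e_relaxed` (default `1e-20`).
#' }
#'
#' @param db `profile_db` built over the final groups (profile names =
#'   group ids), from [build_profiles()].
#' @param ref_seqs [Biostrings::AAStringSet] of annotated reference
#'   sequences, named by id.
#' @param ref_ec data.frame (`id`, `ec`) of the reference annotations;
#'   complete ECs only (enforce with [read_ec_table()] strict mode).
#' @param final the final [group_set()] (members used for the relaxed rule).
#' @param member_ec optional data.frame (`id`, `ec`) of prior annotations of
#'   group members, enabling the relaxed route.
#' @param e_strict,e_relaxed the two E-value thresholds; `e_relaxed` must be
#'   the more permissive (larger) of the two.
#' @return data.frame with columns `group_id`, `ec`, `rule`
#'   (`"strict"`/`"relaxed"`); zero rows when nothing transfers.
#' @export
transfer_annotations <- function(db, ref_seqs, ref_ec, final,
                                 member_ec = NULL,
                                 e_strict = 1e-80, e_relaxed = 1e-20) {
  stopifnot(e_relaxed > e_strict, e_strict > 0)
  ref_ec$ec <- parse_ec(ref_ec$ec, strict = TRUE)
  bad <- setdiff(unique(ref_ec$id), names(ref_seqs))
  if (length(bad))
    stop("EC table references unknown sequence id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  hits <- search_profiles(db, ref_seqs)
  ec_of <- split(ref_ec$ec, ref_ec$id)
  out <- list()
  for (gid in db$group_ids) {
    h <- hits[hits$group == gid & hits$target %in% ref_ec$id, , drop = FALSE]
    ecs_strict <- character(0)
    ecs_relaxed <- character(0)
    if (nrow(h)) {
      best <- min(h$evalue)
      if (best <= e_strict) {
        top <- sort(h$target[h$evalue == best])[1]   # deterministic on ties
        ecs_strict <- unique(ec_of[[top]])
      }
      if (!is.null(member_ec) && gid %in% names(final$groups)) {
        members <- final$groups[[gid]]
        prior <- unique(member_ec$ec[member_ec$id %in% members])
        for (ec in prior) {
          carriers <- ref_ec$id[ref_ec$ec == ec]
          e_ec <- h$evalue[h$target %in% carriers]
          if (length(e_ec) && min(e_ec) <= e_relaxed)
            ecs_relaxed <- c(ecs_relaxed, ec)
        }
      }
    }
    ecs_relaxed <- setdiff(unique(ecs_relaxed), ecs_strict)
    if (length(ecs_strict))
      out[[length(out) + 1]] <- data.frame(group_id = gid, ec = ecs_strict,
                                           rule = "strict")
    if (length(ecs_relaxed))
      out[[length(out) + 1]] <- data.frame(group_id = gid, ec = ecs_relaxed,
                                           rule = "relaxed")
  }
  if (!length(out))
    return(data.frame(group_id = character(), ec = character(),
                      rule = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' First differing EC field
#'
#' Position (1-4) of the first differing field between two complete EC
#' numbers, or 0 if identical.  A difference limited to position 4 means the
#' reaction class is agreed and only the substrate-level serial differs —
#' the dominant disagreement pattern between annotation sources.
#'
#' @param x,y complete EC number strings (vectorized, recycled).
#' @return integer vector in `0:4`.
#' @export
ec_diff_position <- function(x, y) {
  x <- parse_ec(x); y <- parse_ec(y)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  xf <- strsplit(x, ".", fixed = TRUE)
  yf <- strsplit(y, ".", fixed = TRUE)
  vapply(seq_len(n), function(i) {
    d <- which(xf[[i]] != yf[[i]])
    if (!length(d)) 0L else as.integer(d[1])
  }, 0L)
}

#' Compare two ID-EC sets
#'
#' An ID-EC is a (protein id, EC number) pair, the comparison unit between
#' annotation sources.  IDs are partitioned into: identical (at least one
#' exact ID-EC match), same id with entirely different ECs (disjoint EC sets;
#' histogrammed by the first differing field of the closest EC pair), and
#' ids annotated in only one set.
#'
#' @param a,b data.frames with columns `id`, `ec`.
#' @return list with `identical_idec` (count of shared ID-EC pairs),
#'   `same_id_diff_ec`, `specific_a`, `specific_b` (id counts), and
#'   `digit_histogram` (named integer vector over positions 1-4 for the
#'   same-id-different-EC ids).
#' @export
compare_idec_sets <- function(a, b) {
  a$ec <- parse_ec(a$ec); b$ec <- parse_ec(b$ec)
  ka <- unique(paste(a$id, a$ec)); kb <- unique(paste(b$id, b$ec))
  ids_a <- unique(a$id); ids_b <- unique(b$id)
  shared_ids <- intersect(ids_a, ids_b)
  ec_a <- split(a$ec, a$id); ec_b <- split(b$ec, b$id)
  diff_ids <- shared_ids[vapply(shared_ids, function(i)
    !length(intersect(ec_a[[i]], ec_b[[i]])), TRUE)]
  hist <- stats::setNames(integer(4), as.character(1:4))
  for (i in diff_ids) {
    # closest pair = longest shared prefix, i.e. latest first-differing field
    pos <- max(outer(ec_a[[i]], ec_b[[i]], ec_diff_position))
    hist[as.character(pos)] <- hist[as.character(pos)] + 1L
  }
  list(identical_idec = length(intersect(ka, kb)),
       same_id_diff_ec = length(diff_ids),
       specific_a = length(setdiff(ids_a, ids_b)),
       specific_b = length(setdiff(ids_b, ids_a)),
       digit_histogram = hist)
}

#' Per-protein ID-EC records implied by group annotations
#'
#' Every member of an annotated group inherits all the group's ECs.
#'
#' @param group_ec data.frame (`group_id`, `ec`) from
#'   [transfer_annotations()].
#' @param final the final [group_set()].
#' @return data.frame with columns `id`, `ec`.
#' @export
expand_group_annotations <- function(group_ec, final) {
  rows <- lapply(seq_len(nrow(group_ec)), function(i) {
    gid <- group_ec$group_id[i]
    if (!gid %in% names(final$groups)) return(NULL)
    data.frame(id = final$groups[[gid]], ec = group_ec$ec[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(id = character(), ec = character()))
  out <- unique(out)
  rownames(out) <- NULL
  out
}
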