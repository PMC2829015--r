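#' EC presence/absence matrix across species
#'
#' A species possesses an EC iff some group annotated with that EC contains
#' at least one of the species' proteins.  Sequence counts per species are
#' recorded alongside presence (several inparalogs count once for presence).
#'
#' @param group_ec data.frame (`group_id`, `ec`) of group annotations.
#' @param final the final [group_set()] (members give the species content).
#' @param species named character vector, protein id -> species.
#' @param species_list character vector of all species under study (from the
#'   manifest); species without annotations are explicit absent columns.
#' @return a `conservation_matrix`: list with `presence` (logical EC x
#'   species matrix) and `counts` (integer matrix of sequence counts).
#' @export
ec_presence <- function(group_ec, final, species, species_list) {
  ecs <- sort(unique(group_ec$ec))
  counts <- matrix(0L, nrow = length(ecs), ncol = length(species_list),
                   dimnames = list(ecs, species_list))
  for (i in seq_len(nrow(group_ec))) {
    gid <- group_ec$group_id[i]
    if (!gid %in% names(final$groups)) next
    sp <- species[final$groups[[gid]]]
    if (anyNA(sp))
      stop("no species for member(s) of group ", gid)
    tab <- table(sp)
    counts[group_ec$ec[i], names(tab)] <-
      counts[group_ec$ec[i], names(tab)] + as.integer(tab)
  }
  structure(list(presence = counts > 0, counts = counts),
            class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat(sprintf("conservation_matrix: %d EC number(s) x %d species\n",
              nrow(x$presence), ncol(x$presence)))
  invisible(x)
}

#' Per-EC conservation by taxonomic group
#'
#' For each EC and each taxon, the percentage of the taxon's species
#' possessing the EC.  Denominators come from the manifest's species counts,
#' so species with no annotation at all count as absent.
#'
#' @param matrix a `conservation_matrix` from [ec_presence()].
#' @param taxa named character vector, species -> taxon label.
#' @return numeric EC x taxon matrix of percentages in `[0, 100]`.
#' @export
step_conservation <- function(matrix, taxa) {
  stopifnot(inherits(matrix, "conservation_matrix"))
  sp <- colnames(matrix$presence)
  miss <- sp[!sp %in% names(taxa)]
  if (length(miss))
    stop("species without a taxon: ", paste(miss, collapse = ", "))
  tx <- sort(unique(taxa[sp]))
  out <- sapply(tx, function(t) {
    cols <- sp[taxa[sp] == t]
    100 * rowSums(matrix$presence[, cols, drop = FALSE]) / length(cols)
  })
  out <- base::matrix(out, nrow = nrow(matrix$presence),
                      dimnames = list(rownames(matrix$presence), tx))
  out
}

#' Pathway conservation per species and per step
#'
#' Per-species completeness is the percentage of the pathway's (distinct)
#' EC steps the species possesses; per-step global presence is the
#' percentage of all species possessing that step.  Steps whose EC is absent
#' from every annotation simply score 0%.
#'
#' @param pathway a [pathway()] object.
#' @param matrix a `conservation_matrix`.
#' @return list with `per_species` (named percentages), `per_step` (named by
#'   EC, global percentages) and `n_steps` (distinct ECs in the pathway).
#' @export
pathway_conservation <- function(pathway, matrix) {
  stopifnot(inherits(pathway, "pathway"),
            inherits(matrix, "conservation_matrix"))
  steps <- unique(pathway$steps)          # dedup for denominators
  sp <- colnames(matrix$presence)
  pres <- base::matrix(FALSE, length(steps), length(sp),
                       dimnames = list(steps, sp))
  known <- steps[steps %in% rownames(matrix$presence)]
  pres[known, ] <- matrix$presence[known, , drop = FALSE]
  list(per_species = 100 * colSums(pres) / length(steps),
       per_step = 100 * rowSums(pres) / length(sp),
       n_steps = length(steps))
}

#' ECs specific to a single pathway
#'
#' An EC is specific to pathway `P` iff it appears among `P`'s steps and in
#' no other pathway of the collection.  Absence of all of a pathway's
#' specific ECs is the strongest evidence the pathway itself is absent.
#'
#' @param collection a `pathway_collection`.
#' @return named list, pathway name -> character vector of specific ECs
#'   (possibly empty).
#' @export
pathway_specific_ecs <- function(collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  all_steps <- unlist(lapply(collection, function(p) unique(p$steps)))
  counts <- table(all_steps)
  uniq <- names(counts)[counts == 1]
  lapply(collection, function(p) intersect(unique(p$steps), uniq))
}

#' Find pathway holes
#'
#' A hole is a pathway step whose EC is absent in the requested scope
#' (one species, one taxon — absent from every species of the taxon — or
#' globally absent).  When the collection is supplied and every
#' pathway-specific EC is among the holes, the pathway is flagged
#' `"possibly absent pathway"`: the alternative reading to a set of
#' independent holes.
#'
#' @param pathway a [pathway()] object.
#' @param matrix a `conservation_matrix`.
#' @param scope `"species"`, `"taxon"` or `"global"`.
#' @param target the species or taxon examined (ignored for global scope).
#' @param taxa named character vector, species -> taxon (taxon scope only).
#' @param collection optional `pathway_collection` for the specific-EC flag.
#' @return list with `holes` (character vector of missing step ECs),
#'   `scope`, `target` and `possibly_absent` (logical).
#' @export
find_pathway_holes <- function(pathway, matrix,
                               scope = c("species", "taxon", "global"),
                               target = NULL, taxa = NULL,
                               collection = NULL) {
  scope <- match.arg(scope)
  steps <- unique(pathway$steps)
  sp <- colnames(matrix$presence)
  cols <- switch(scope,
    species = {
      if (is.null(target) || !target %in% sp)
        stop("unknown or missing target species")
      target
    },
    taxon = {
      if (is.null(target) || is.null(taxa)) stop("taxon scope needs target and taxa")
      cols <- sp[taxa[sp] == target]
      if (!length(cols)) stop("no species in taxon ", target)
      cols
    },
    global = sp)
  present <- vapply(steps, function(ec) {
    ec %in% rownames(matrix$presence) &&
      any(matrix$presence[ec, cols, drop = TRUE])
  }, TRUE)
  holes <- steps[!present]
  possibly_absent <- FALSE
  if (!is.null(collection)) {
    spec <- pathway_specific_ecs(collection)[[pathway$name]]
    possibly_absent <- length(spec) > 0 && all(spec %in% holes)
  }
  list(holes = holes, scope = scope,
       target = if (scope == "global") NA_character_ else target,
       possibly_absent = possibly_absent)
}

#' Pathways containing an EC number
#'
#' Exact four-digit match over the step lists, reported by pathway source.
#'
#' @param collection a `pathway_collection`.
#' @param ec a complete EC number.
#' @return named list, source -> sorted character vector of pathway names
#'   (unknown EC gives empty vectors).
#' @export
pathways_containing_ec <- function(collection, ec) {
  stopifnot(inherits(collection, "pathway_collection"))
  ec <- parse_ec(ec)
  hits <- Filter(function(p) ec %in% p$steps, collection)
  srcs <- c("kegg", "metacyc", "user")
  out <- lapply(srcs, function(s)
    sort(unname(vapply(Filter(function(p) p$source == s, hits),
                       `[[`, "", "name"))))
  names(out) <- srcs
  out
}

#' Tabular pathway conservation report
#'
#' One row per (pathway, step EC, species): presence, sequence count, and
#' the species' overall pathway completeness.
#'
#' @param collection a `pathway_collection`.
#' @param matrix a `conservation_matrix`.
#' @return data.frame with columns `pathway`, `source`, `step_ec`, `species`,
#'   `present`, `count`, `species_completeness_pct`.
#' @export
pathway_report <- function(collection, matrix) {
  rows <- list()
  for (p in collection) {
    cons <- pathway_conservation(p, matrix)
    for (ec in unique(p$steps)) {
      for (sp in colnames(matrix$presence)) {
        pres <- ec %in% rownames(matrix$presence) && matrix$presence[ec, sp]
        cnt <- if (ec %in% rownames(matrix$counts)) matrix$counts[ec, sp]
               else 0L
        rows[[length(rows) + 1]] <- data.frame(
          pathway = p$name, source = p$source, step_ec = ec, species = sp,
          present = pres, count = as.integer(cnt),
          species_completeness_pct = unname(cons$per_species[sp]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
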