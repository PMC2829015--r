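#' Read a proteome FASTA file
#'
#' Reads one species' protein sequences.  The record id is the first
#' whitespace-delimited token of the header; the remainder of the header is
#' ignored.  Sequences are uppercased.  Gap characters and empty sequences are
#' rejected, as are duplicate ids.
#'
#' @param path FASTA file.
#' @param species species label attached to every record (species is supplied
#'   per file by the manifest, never parsed from headers).
#' @return an [Biostrings::AAStringSet] named by protein id, with the species
#'   label stored in `metadata(x)$species` and as attribute `"species"`.
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate protein id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0))
    stop("empty sequence(s) in ", path, ": ",
         paste(ids[Biostrings::width(seqs) == 0], collapse = ", "))
  chars <- Biostrings::uniqueLetters(seqs)
  if (any(chars %in% c("-", ".")))
    stop("gap characters found in ", path, "; ungapped sequences required")
  seqs <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  attr(seqs, "species") <- species
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs an [Biostrings::AAStringSet] named by protein id.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "XStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a species manifest
#'
#' YAML mapping each species to its proteome file and taxonomic group:
#' ```yaml
#' spA: {fasta: spA.fasta, taxon: Ascomycota}
#' spB: {fasta: spB.fasta, taxon: Basidiomycota}
#' ```
#' Every species belongs to exactly one taxon.
#'
#' @param path manifest YAML file.
#' @return data.frame with columns `species`, `fasta`, `taxon`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  y <- yaml::read_yaml(path)
  if (!length(y)) stop("empty manifest: ", path)
  df <- data.frame(
    species = names(y),
    fasta = vapply(y, function(e) as.character(e$fasta %||% NA), ""),
    taxon = vapply(y, function(e) as.character(e$taxon %||% NA), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  if (anyDuplicated(df$species))
    stop("species listed more than once in manifest: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  if (anyNA(df$taxon)) stop("manifest entries missing a taxon")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load all proteomes listed in a manifest
#'
#' @param manifest data.frame from [read_manifest()].
#' @param base_dir directory FASTA paths are relative to.
#' @return list with `seqs` (combined [Biostrings::AAStringSet]) and `species`
#'   (named character vector, protein id -> species label).
#' @export
load_proteomes <- function(manifest, base_dir = ".") {
  all_seqs <- NULL
  species_of <- character(0)
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$fasta[i]
    if (!file.exists(p)) p <- file.path(base_dir, manifest$fasta[i])
    s <- read_fasta(p, species = manifest$species[i])
    species_of[names(s)] <- manifest$species[i]
    all_seqs <- if (is.null(all_seqs)) s else c(all_seqs, s)
  }
  if (anyDuplicated(names(all_seqs)))
    stop("protein id(s) shared between proteomes: ",
         paste(unique(names(all_seqs)[duplicated(names(all_seqs))]),
               collapse = ", "))
  list(seqs = all_seqs, species = species_of)
}

#' Read an all-vs-all similarity table
#'
#' Tab-separated, one local-alignment hit per line, columns
#' `query, subject, pident, aln_len, evalue, raw_score` (the first six columns
#' of BLAST `-outfmt 6` reduced to the fields the filters use; raw score in
#' place of bit score).  Extra trailing columns are tolerated and ignored.
#' Self-hits are retained: they carry the self-scores the score-ratio filter
#' needs.
#'
#' @param path TSV file.
#' @return data.frame with columns `query`, `subject`, `pident`, `aln_len`,
#'   `evalue`, `raw_score`, in file order.
#' @export
read_similarity_table <- function(path) {
  if (!file.exists(path)) stop("similarity table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(query = character(), subject = character(),
                      pident = numeric(), aln_len = integer(),
                      evalue = numeric(), raw_score = numeric()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  if (any(n < 6))
    stop("similarity table line ", which(n < 6)[1], ": fewer than 6 columns")
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", col)))
    if (anyNA(v))
      stop("similarity table line ", which(is.na(v))[1],
           ": non-numeric ", what)
    v
  }
  data.frame(
    query = vapply(parts, `[[`, "", 1L),
    subject = vapply(parts, `[[`, "", 2L),
    pident = num(3L, "percent identity"),
    aln_len = as.integer(num(4L, "alignment length")),
    evalue = num(5L, "E-value"),
    raw_score = num(6L, "raw score"),
    stringsAsFactors = FALSE)
}

#' Write a similarity table
#' @param hits data.frame as returned by [read_similarity_table()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_similarity_table <- function(hits, path) {
  utils::write.table(
    hits[, c("query", "subject", "pident", "aln_len", "evalue", "raw_score")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write ortholog group files
#'
#' OrthoMCL-style dialect, one group per line: `group_id: member1 member2 ...`.
#' Groups on different lines may share members (required to carry BRH clique
#' output); a duplicate member within one line is an error.
#'
#' @param path group file.
#' @param method method label for the resulting set.
#' @param overlapping logical; passed to [group_set()].  With the default
#'   `NULL` the flag is inferred from the file contents.
#' @return a [group_set()].
#' @export
read_group_file <- function(path, method = NULL, overlapping = NULL) {
  if (!file.exists(path)) stop("group file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  groups <- list()
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3)
      stop("group file line ", i, ": expected 'group_id: m1 m2 ...'")
    gid <- trimws(m[2])
    members <- strsplit(trimws(m[3]), "\\s+")[[1]]
    members <- members[nzchar(members)]
    if (anyDuplicated(members))
      stop("group file line ", i, ": duplicate member ",
           paste(unique(members[duplicated(members)]), collapse = ", "))
    groups[[gid]] <- members
  }
  if (is.null(overlapping)) {
    all_m <- unlist(groups, use.names = FALSE)
    overlapping <- anyDuplicated(all_m) > 0
  }
  group_set(groups, method = method %||% basename(path),
            overlapping = overlapping)
}

#' @rdname read_group_file
#' @param gs a [group_set()] to write.
#' @export
write_group_file <- function(gs, path) {
  stopifnot(inherits(gs, "group_set"))
  lines <- vapply(seq_along(gs$groups), function(i) {
    paste0(names(gs$groups)[i], ": ",
           paste(sort(gs$groups[[i]]), collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Parse and validate EC numbers
#'
#' A complete EC number has four positive integer fields `a.b.c.d`.  Partial
#' classifications containing `-` are rejected in strict mode: the pipeline
#' works only with complete EC numbers.
#'
#' @param x character vector of EC strings.
#' @param strict if `TRUE` (default) partial/malformed ECs raise an error;
#'   otherwise they become `NA` with one warning listing the skipped values.
#' @return character vector of normalized EC strings (`NA` for skipped
#'   entries in lenient mode).
#' @export
parse_ec <- function(x, strict = TRUE) {
  x <- trimws(as.character(x))
  ok <- grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", x)
  if (any(!ok)) {
    bad <- unique(x[!ok])
    if (strict)
      stop("incomplete or malformed EC number(s): ",
           paste(bad, collapse = ", "),
           " (complete four-digit EC numbers required)")
    warning("skipping incomplete/malformed EC number(s): ",
            paste(bad, collapse = ", "))
    x[!ok] <- NA_character_
  }
  x
}

#' Read a protein-to-EC annotation table
#'
#' TSV with columns `protein id`, `EC number`; a protein with several
#' activities appears on several lines.  Partial ECs (fields containing `-`)
#' are an error in strict mode and are skipped with a warning in lenient mode.
#'
#' @param path TSV file.
#' @param strict reject (vs. skip-and-warn) incomplete EC numbers.
#' @return data.frame with columns `id`, `ec` (complete ECs only).
#' @export
read_ec_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("EC table not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "ec"),
                          colClasses = "character", quote = "")
  df$ec <- parse_ec(df$ec, strict = strict)
  df <- df[!is.na(df$ec), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a pathway collection
#'
#' Simplified pathway format (YAML or JSON): a list of entries
#' `{name, source, steps}` where `source` is one of `kegg`, `metacyc`, `user`
#' and `steps` is the ordered list of complete EC numbers catalysing the
#' pathway's reactions.  A top-level `pathways:` key wrapping the list is also
#' accepted.
#'
#' @param path YAML/JSON file.
#' @return a `pathway_collection`: list of pathways, each a list with `name`,
#'   `source`, `steps` (character vector of ECs, order preserved).
#' @export
read_pathways <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  y <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (!is.null(y$pathways)) y <- y$pathways
  pathway_collection(lapply(y, function(p) {
    pathway(name = p$name, source = p$source %||% "user",
            steps = unlist(p$steps, use.names = FALSE))
  }))
}

#' Construct a single pathway
#' @param name pathway name.
#' @param source origin of the definition: `"kegg"`, `"metacyc"` or `"user"`.
#' @param steps ordered character vector of complete EC numbers.
#' @return a `pathway` object.
#' @export
pathway <- function(name, source = "user", steps) {
  source <- match.arg(source, c("kegg", "metacyc", "user"))
  steps <- parse_ec(steps, strict = TRUE)
  if (!length(steps)) stop("pathway '", name, "' has no steps")
  structure(list(name = name, source = source, steps = steps),
            class = "pathway")
}

#' Bundle pathways into a collection
#' @param pathways list of [pathway()] objects.
#' @return a `pathway_collection`.
#' @export
pathway_collection <- function(pathways) {
  stopifnot(all(vapply(pathways, inherits, TRUE, "pathway")))
  names(pathways) <- vapply(pathways, `[[`, "", "name")
  structure(pathways, class = "pathway_collection")
}

#' Write a pathway collection to YAML
#' @param collection a `pathway_collection`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_pathways <- function(collection, path) {
  y <- lapply(unname(collection), function(p)
    list(name = p$name, source = p$source, steps = as.list(p$steps)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a gene tree in Newick format
#'
#' Leaf labels follow the dialect `proteinID|species`.  Every species suffix
#' must appear in `known_species` when that vector is supplied.
#'
#' @param path Newick file (first tree used).
#' @param known_species optional character vector of valid species labels.
#' @return an [ape::read.tree()] `phylo` object; the parsed id/species of each
#'   leaf are attached as attributes `"leaf_id"` and `"leaf_species"`.
#' @export
read_gene_tree <- function(path, known_species = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  annotate_leaf_species(tr, known_species)
}

# Split "proteinID|species" leaf labels; validate against the species map.
annotate_leaf_species <- function(tr, known_species = NULL) {
  parts <- strsplit(tr$tip.label, "|", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("leaf label(s) not of the form 'proteinID|species': ",
         paste(tr$tip.label[lengths(parts) != 2], collapse = ", "))
  ids <- vapply(parts, `[[`, "", 1L)
  sps <- vapply(parts, `[[`, "", 2L)
  if (!is.null(known_species) && any(!sps %in% known_species))
    stop("unknown species in leaf label(s): ",
         paste(unique(sps[!sps %in% known_species]), collapse = ", "))
  attr(tr, "leaf_id") <- ids
  attr(tr, "leaf_species") <- sps
  tr
}
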