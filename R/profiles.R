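# Profile engine: one profile HMM per group, built from a multiple alignment
# of the group's representative sequences and searched with E-values.  The
# engine contract is build-from-MSA + E-valued search; this implementation
# shells out to MAFFT and HMMER 3 (hmmbuild/hmmsearch), the field-standard
# tools, which must be on the PATH.

tool_path <- function(tool) {
  p <- Sys.which(tool)
  if (!nzchar(p)) stop("required external tool not found on PATH: ", tool)
  p
}

run_tool <- function(tool, args) {
  out <- suppressWarnings(system2(tool_path(tool), args, stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0)
    stop(tool, " failed (exit ", status, "):\n",
         paste(utils::tail(out, 15), collapse = "\n"))
  out
}

# Align sequences with MAFFT (identity when a single sequence, or when all
# sequences have equal length and --trivial is acceptable).
align_sequences <- function(seqs, workdir) {
  if (length(seqs) == 1) return(seqs)
  fin <- file.path(workdir, "msa_in.fasta")
  fout <- file.path(workdir, "msa_out.fasta")
  write_fasta(seqs, fin)
  out <- run_tool("mafft", c("--auto", "--quiet", "--amino", shQuote(fin)))
  writeLines(out, fout)
  aln <- Biostrings::readAAStringSet(fout)
  names(aln) <- sub("\\s.*$", "", names(aln))
  aln
}

#' Build a profile database for a set of groups
#'
#' For each group, the representative sequences are aligned (MAFFT) and a
#' profile HMM is built (`hmmbuild`); all profiles are concatenated into one
#' database file, searchable in a single pass.  A group reduced to one
#' representative still yields a (single-sequence) profile, with a warning.
#'
#' @param groups named list, group id -> character vector of sequence ids to
#'   seed the profile (typically one representative per species, see
#'   [select_representatives()]), or a [group_set()].
#' @param seqs [Biostrings::AAStringSet] holding all sequences, named by id.
#' @param dir directory for the database files (created; default a fresh
#'   temporary directory).
#' @return a `profile_db` object (fields `hmm_file`, `group_ids`, `dir`).
#' @export
build_profiles <- function(groups, seqs, dir = tempfile("profiledb")) {
  if (inherits(groups, "group_set")) groups <- groups$groups
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hmm_file <- file.path(dir, "profiles.hmm")
  if (file.exists(hmm_file)) file.remove(hmm_file)
  singles <- names(groups)[lengths(groups) == 1]
  if (length(singles))
    warning("group(s) with a single representative sequence: ",
            paste(singles, collapse = ", "))
  for (gid in names(groups)) {
    ids <- groups[[gid]]
    miss <- ids[!ids %in% names(seqs)]
    if (length(miss))
      stop("no sequence for id(s): ", paste(miss, collapse = ", "))
    aln <- align_sequences(seqs[ids], dir)
    aln_file <- file.path(dir, "group_msa.fasta")
    write_fasta(aln, aln_file)
    hmm_one <- file.path(dir, "group.hmm")
    run_tool("hmmbuild", c("--amino", "-n", shQuote(gid), shQuote(hmm_one),
                           shQuote(aln_file)))
    file.append(hmm_file, hmm_one)
  }
  structure(list(hmm_file = hmm_file, group_ids = names(groups), dir = dir),
            class = "profile_db")
}

#' @export
print.profile_db <- function(x, ...) {
  cat(sprintf("profile_db: %d profile(s) in %s\n",
              length(x$group_ids), x$hmm_file))
  invisible(x)
}

#' Search sequences against a profile database
#'
#' Runs `hmmsearch` of every profile against the supplied sequences and
#' returns all reported hits with their full-sequence E-values and bit
#' scores.
#'
#' @param db a `profile_db` from [build_profiles()].
#' @param seqs [Biostrings::AAStringSet] of target sequences, named by id.
#' @param e_report report hits up to this E-value (default `1e3`; downstream
#'   rules apply their own, stricter cutoffs).
#' @return data.frame with columns `group` (profile/group id), `target`
#'   (sequence id), `evalue`, `bit_score`.
#' @export
search_profiles <- function(db, seqs, e_report = 1e3) {
  stopifnot(inherits(db, "profile_db"))
  if (!length(seqs))
    return(data.frame(group = character(), target = character(),
                      evalue = numeric(), bit_score = numeric()))
  fa <- file.path(db$dir, "search_targets.fasta")
  tbl <- file.path(db$dir, "search_hits.tbl")
  write_fasta(seqs, fa)
  run_tool("hmmsearch", c("--noali", "-E", format(e_report),
                          "--tblout", shQuote(tbl),
                          shQuote(db$hmm_file), shQuote(fa)))
  lines <- readLines(tbl)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(group = character(), target = character(),
                      evalue = numeric(), bit_score = numeric()))
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(
    group = vapply(parts, `[[`, "", 3L),
    target = vapply(parts, `[[`, "", 1L),
    evalue = as.numeric(vapply(parts, `[[`, "", 5L)),
    bit_score = as.numeric(vapply(parts, `[[`, "", 6L)),
    stringsAsFactors = FALSE)
}

#' Assign unplaced sequences to reference groups by profile search
#'
#' "Unplaced" sequences are those not a member of exactly one reference
#' group — both never-grouped proteins and proteins ambiguous across
#' overlapping inputs.  Each unplaced sequence is compared against the whole
#' profile database and assigned to the group of its single best-scoring
#' profile iff that best E-value is below `evalue_max`; a tie for best hit
#' leaves the sequence unassigned (specificity over sensitivity).
#'
#' @param seqs [Biostrings::AAStringSet] of all sequences, named by id.
#' @param db `profile_db` over the reference groups.
#' @param reference the reference [group_set()] (used to determine who is
#'   unplaced); pass `NULL` and supply `unplaced` directly instead.
#' @param evalue_max assignment threshold (default `1e-10`, exclusive).
#' @param unplaced optional explicit character vector of sequence ids to
#'   (re)assign.
#' @return named character vector, sequence id -> group id (possibly empty).
#' @export
assign_unplaced <- function(seqs, db, reference = NULL, evalue_max = 1e-10,
                            unplaced = NULL) {
  stopifnot(evalue_max > 0)
  if (is.null(unplaced)) {
    if (is.null(reference))
      stop("either 'reference' or 'unplaced' must be supplied")
    counts <- table(unlist(reference$groups, use.names = FALSE))
    placed_once <- names(counts)[counts == 1]
    unplaced <- setdiff(names(seqs), placed_once)
  }
  if (!length(unplaced)) return(stats::setNames(character(0), character(0)))
  hits <- search_profiles(db, seqs[unplaced])
  assignments <- character(0)
  for (id in unique(hits$target)) {
    h <- hits[hits$target == id, , drop = FALSE]
    best <- min(h$evalue)
    if (best >= evalue_max) next
    top <- h$group[h$evalue == best]
    if (length(unique(top)) > 1) {
      message("sequence ", id, ": tie between profiles ",
              paste(unique(top), collapse = ", "), "; left unassigned")
      next
    }
    assignments[id] <- top[1]
  }
  assignments
}
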