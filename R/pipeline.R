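#' Pipeline configuration
#'
#' Collects every stage threshold with its published default: BRH score
#' ratio 0.2 and alignment percentage 60, homolog-family E-value 0.001 and
#' shorter-protein coverage 0.70, profile enrichment E-value 1e-10, and the
#' strict/relaxed annotation-transfer E-values 1e-80/1e-20.
#'
#' @param score_ratio_min,aln_pct_min BRH filters.
#' @param family_e_max,family_min_frac homolog-family filters.
#' @param enrich_evalue profile-enrichment assignment threshold.
#' @param annot_e_strict,annot_e_relaxed annotation-transfer thresholds.
#' @param max_component BRH clique-enumeration vertex cap.
#' @param seed integer seed recorded in the run manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(score_ratio_min = 0.2, aln_pct_min = 60,
                            family_e_max = 0.001, family_min_frac = 0.70,
                            enrich_evalue = 1e-10,
                            annot_e_strict = 1e-80, annot_e_relaxed = 1e-20,
                            max_component = 200, seed = 1) {
  structure(list(score_ratio_min = score_ratio_min,
                 aln_pct_min = aln_pct_min,
                 family_e_max = family_e_max,
                 family_min_frac = family_min_frac,
                 enrich_evalue = enrich_evalue,
                 annot_e_strict = annot_e_strict,
                 annot_e_relaxed = annot_e_relaxed,
                 max_component = max_component,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full construction pipeline
#'
#' Chains the stages: filtered-BRH orthology on the similarity table, loading
#' of externally produced method GroupSets, crude intersection into reference
#' groups, one-representative-per-genome profile construction, profile
#' enrichment of unplaced sequences, final-group confidence scoring, EC
#' annotation transfer (when a reference set is given) and pathway
#' conservation reporting (when a pathway collection is given).  Per-stage
#' TSV outputs and a machine-readable `run_manifest.json` (resolved config,
#' input checksums, package version) are written under `out_dir`.
#'
#' @param manifest_path species manifest YAML ([read_manifest()]).
#' @param hits_path all-vs-all similarity TSV ([read_similarity_table()]).
#' @param group_paths character vector of external group files (each one
#'   method's output, [read_group_file()]); combined with the internal BRH
#'   set they form the method ensemble.
#' @param out_dir output directory (created).
#' @param base_dir directory FASTA paths in the manifest are relative to
#'   (default: the manifest's directory).
#' @param ec_table_path,ref_fasta_path annotated reference set for EC
#'   transfer (both or neither).
#' @param pathway_path pathway collection YAML/JSON for conservation
#'   reporting (requires the reference set).
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results: `methods`,
#'   `reference`, `final`, `scores`, `group_ec`, `conservation`, `report`.
#' @export
run_pipeline <- function(manifest_path, hits_path, group_paths = character(0),
                         out_dir, base_dir = dirname(manifest_path),
                         ec_table_path = NULL, ref_fasta_path = NULL,
                         pathway_path = NULL, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(manifest_path, hits_path, group_paths, ec_table_path,
              ref_fasta_path, pathway_path)
  for (p in inputs) if (!file.exists(p)) stop("input file not found: ", p)

  manifest <- stage("manifest", read_manifest(manifest_path))
  prot <- stage("proteomes", load_proteomes(manifest, base_dir))
  hits <- stage("hits", read_similarity_table(hits_path))
  lengths <- stats::setNames(Biostrings::width(prot$seqs), names(prot$seqs))

  brh <- stage("brh", brh_orthologs(
    hits, lengths, prot$species,
    score_ratio_min = config$score_ratio_min,
    aln_pct_min = config$aln_pct_min,
    max_component = config$max_component))
  write_group_file(brh, file.path(out_dir, "brh_groups.txt"))

  external <- stage("load-groups",
                    lapply(group_paths, read_group_file))
  methods <- c(list(brh), external)
  if (length(methods) < 2)
    stop("consensus needs at least two methods; supply external group files")

  reference <- stage("consensus", intersect_groupsets(methods))
  write_group_file(reference, file.path(out_dir, "reference_groups.txt"))

  reps <- stage("representatives", lapply(
    reference$groups, select_representatives,
    species = prot$species, hits = hits))
  db <- stage("profiles",
              suppressWarnings(build_profiles(reps, prot$seqs)))
  assignments <- stage("enrich", assign_unplaced(
    prot$seqs, db, reference, evalue_max = config$enrich_evalue))
  final <- stage("finalize", finalize_groups(reference, assignments))
  scores <- stage("score", score_final_groups(final, methods))

  final_df <- do.call(rbind, lapply(names(final$groups), function(gid)
    data.frame(group_id = gid, member = final$groups[[gid]],
               provenance = unname(final$provenance[[gid]]),
               confidence = scores$confidence[scores$group_id == gid])))
  utils::write.table(final_df, file.path(out_dir, "final_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scores, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  group_ec <- NULL; conservation <- NULL; report <- NULL
  if (!is.null(ec_table_path) || !is.null(ref_fasta_path)) {
    if (is.null(ec_table_path) || is.null(ref_fasta_path))
      stop("EC transfer needs both ec_table_path and ref_fasta_path")
    ref_ec <- stage("ec-table", read_ec_table(ec_table_path, strict = TRUE))
    ref_seqs <- stage("ref-fasta", read_fasta(ref_fasta_path, "reference"))
    final_db <- stage("final-profiles", suppressWarnings(
      build_profiles(final$groups, prot$seqs)))
    group_ec <- stage("annotate", transfer_annotations(
      final_db, ref_seqs, ref_ec, final,
      e_strict = config$annot_e_strict,
      e_relaxed = config$annot_e_relaxed))
    utils::write.table(group_ec, file.path(out_dir, "group_ec.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pathway_path)) {
      collection <- stage("pathways", read_pathways(pathway_path))
      conservation <- stage("conservation", ec_presence(
        group_ec, final, prot$species, manifest$species))
      report <- stage("pathway-report",
                      pathway_report(collection, conservation))
      utils::write.table(report, file.path(out_dir, "pathway_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  run_manifest <- list(
    package = "orthopath",
    version = as.character(utils::packageVersion("orthopath")),
    config = unclass(config),
    config_hash = digest_config(config),
    inputs = lapply(stats::setNames(inputs, basename(inputs)),
                    function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(methods = methods, reference = reference, final = final,
                 scores = scores, group_ec = group_ec,
                 conservation = conservation, report = report))
}

digest_config <- function(config) {
  s <- paste(names(config), vapply(config, format, ""), collapse = ";",
             sep = "=")
  # small rolling hash; stable across sessions, no extra dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
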