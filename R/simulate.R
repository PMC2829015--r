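# Deterministic simulator of gene-family evolution: a random species tree, a
# duplication/loss birth-death of gene lineages along it, sequences mutated
# from a random root peptide under a uniform substitution model, and an
# all-vs-all similarity table scored by exact positional identity.  The
# ground truth (families = true ortholog groups, true gene trees, true EC per
# family) is retained so every pipeline stage can be validated end to end.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a multi-genome fungal
#' dataset at desk scale: a handful of genomes in two taxonomic groups,
#' moderate sequence divergence, and a duplication rate tuned so that final
#' groups average roughly 1.3 homologs per genome.
#'
#' @param n_species number of genomes.
#' @param n_families number of gene families (true ortholog groups).
#' @param duplication_prob per-lineage probability of duplication on each
#'   species-tree branch.
#' @param loss_prob per-lineage probability of loss on each branch.
#' @param substitution_rate per-site substitution probability per branch.
#' @param seq_length root peptide length (residues).
#' @param split_p,merge_p,drop_p group-noise probabilities used by
#'   [perturb_groups()] when simulating noisy method outputs.
#' @param seed integer seed fixing all randomness end to end.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 6, n_families = 12,
                       duplication_prob = 0.07, loss_prob = 0.02,
                       substitution_rate = 0.02, seq_length = 300,
                       split_p = 0, merge_p = 0, drop_p = 0, seed = 1) {
  probs <- c(duplication_prob, loss_prob, substitution_rate,
             split_p, merge_p, drop_p)
  stopifnot(all(probs >= 0), all(probs <= 1),
            n_species >= 2, n_families >= 1, seq_length >= 10)
  structure(list(n_species = n_species, n_families = n_families,
                 duplication_prob = duplication_prob, loss_prob = loss_prob,
                 substitution_rate = substitution_rate,
                 seq_length = seq_length, split_p = split_p,
                 merge_p = merge_p, drop_p = drop_p, seed = as.integer(seed)),
            class = "sim_config")
}

mutate_seq <- function(seq, rate) {
  hit <- stats::runif(length(seq)) < rate
  if (any(hit))
    seq[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  seq
}

#' Simulate proteomes with known orthology
#'
#' Samples a random bifurcating species tree, evolves each family along it
#' (per-branch duplication and loss, per-site substitution), and derives the
#' all-vs-all similarity table from exact positional identity:
#' `raw_score = 2 * matches`, `aln_len = seq_length`, and
#' `evalue = seq_length * 2^(-raw_score / 8)` — a documented simple scheme
#' under which related sequences fall far below the homology filters'
#' cutoffs and unrelated ones far above.  Hits with E-value above 10 are not
#' reported (mimicking an aligner's reporting threshold); self-hits always
#' are.
#'
#' @param config a [sim_config()].
#' @return a `sim_data` list: `seqs` ([Biostrings::AAStringSet]), `species`
#'   (named vector id -> species), `manifest` (species/taxon data.frame;
#'   species split into two taxa), `hits` (similarity data.frame), `truth`
#'   (disjoint [group_set()] of families with >= 2 genes), `gene_trees`
#'   (named Newick strings, leaf labels `id|species`), `species_tree`
#'   (`phylo`), `config`.
#' @export
simulate_orthologs <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_species
  species <- sprintf("sp%02d", seq_len(n))
  stree <- ape::rtree(n, rooted = TRUE, br = NULL)
  stree$tip.label <- species
  stree$edge.length <- rep(1, nrow(stree$edge))
  children <- split(stree$edge[, 2], stree$edge[, 1])
  root <- n + 1L

  all_tips <- list()
  gene_trees <- character(0)
  truth <- list()

  for (f in seq_len(config$n_families)) {
    fam <- sprintf("fam%02d", f)
    counter <- new.env(parent = emptyenv())
    root_seq <- sample(AA_ALPHABET, config$seq_length, replace = TRUE)

    sim_node <- function(seq, node) {
      if (node <= n) {
        sp <- species[node]
        k <- (get0(sp, envir = counter) %||% 0L) + 1L
        assign(sp, k, envir = counter)
        id <- sprintf("%s_%sg%d", sp, fam, k)
        return(list(nwk = sprintf("%s|%s:1", id, sp),
                    tips = list(list(id = id, species = sp, seq = seq))))
      }
      subs <- list()
      for (child in children[[as.character(node)]]) {
        r <- sim_edge(seq, child)
        if (!is.null(r)) subs[[length(subs) + 1]] <- r
      }
      if (!length(subs)) return(NULL)
      if (length(subs) == 1) return(subs[[1]])
      list(nwk = sprintf("(%s):1",
                         paste(vapply(subs, `[[`, "", "nwk"),
                               collapse = ",")),
           tips = do.call(c, lapply(subs, `[[`, "tips")))
    }
    sim_edge <- function(seq, child) {
      if (stats::runif(1) < config$loss_prob) return(NULL)
      if (stats::runif(1) < config$duplication_prob) {
        a <- sim_node(mutate_seq(seq, config$substitution_rate), child)
        b <- sim_node(mutate_seq(seq, config$substitution_rate), child)
        if (is.null(a)) return(b)
        if (is.null(b)) return(a)
        return(list(nwk = sprintf("(%s,%s):1", a$nwk, b$nwk),
                    tips = c(a$tips, b$tips)))
      }
      sim_node(mutate_seq(seq, config$substitution_rate), child)
    }

    res <- sim_node(root_seq, root)
    if (is.null(res)) next
    all_tips <- c(all_tips, res$tips)
    if (length(res$tips) >= 2) {
      truth[[fam]] <- vapply(res$tips, `[[`, "", "id")
      nwk <- res$nwk
      nwk <- sub(":1$", "", nwk)                # no length on the root
      if (!startsWith(nwk, "(")) nwk <- sprintf("(%s)", nwk)
      gene_trees[fam] <- paste0(nwk, ";")
    }
  }
  if (!length(all_tips)) stop("simulation produced empty proteomes")

  ids <- vapply(all_tips, `[[`, "", "id")
  sp_of <- stats::setNames(vapply(all_tips, `[[`, "", "species"), ids)
  seq_mat <- do.call(rbind, lapply(all_tips, `[[`, "seq"))
  seqs <- Biostrings::AAStringSet(apply(seq_mat, 1, paste, collapse = ""))
  names(seqs) <- ids

  hits <- similarity_from_identity(seq_mat, ids, config$seq_length)

  manifest <- data.frame(
    species = species,
    fasta = paste0(species, ".fasta"),
    taxon = ifelse(seq_len(n) <= ceiling(n / 2), "TaxonA", "TaxonB"),
    stringsAsFactors = FALSE)

  structure(list(seqs = seqs, species = sp_of, manifest = manifest,
                 hits = hits, truth = group_set(truth, method = "truth"),
                 gene_trees = gene_trees, species_tree = stree,
                 config = config),
            class = "sim_data")
}

# score = 2 * positional matches; E = L * 2^(-score/8); report E <= 10 or self
similarity_from_identity <- function(seq_mat, ids, len, e_report = 10) {
  n <- length(ids)
  qs <- character(0); ss <- character(0)
  pid <- numeric(0); ev <- numeric(0); raw <- numeric(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      m <- sum(seq_mat[i, ] == seq_mat[j, ])
      score <- 2 * m
      e <- len * 2^(-score / 8)
      if (i != j && e > e_report) next
      qs <- c(qs, ids[i]); ss <- c(ss, ids[j])
      pid <- c(pid, 100 * m / len); ev <- c(ev, e); raw <- c(raw, score)
      if (i != j) {               # emit the reciprocal direction too
        qs <- c(qs, ids[j]); ss <- c(ss, ids[i])
        pid <- c(pid, 100 * m / len); ev <- c(ev, e); raw <- c(raw, score)
      }
    }
  }
  data.frame(query = qs, subject = ss, pident = pid,
             aln_len = rep(len, length(qs)), evalue = ev, raw_score = raw,
             stringsAsFactors = FALSE)
}

#' Perturb a true grouping into one simulated "method" output
#'
#' Each group independently suffers at most one event: a split into two
#' random halves (probability `split_p`), a merge with a randomly chosen
#' other group (`merge_p`), or the loss of one random member (`drop_p`).
#' Groups falling below two members vanish.  Four perturbations with
#' different seeds stand in for the disagreement of four orthology methods.
#'
#' @param truth a [group_set()] of true groups.
#' @param split_p,merge_p,drop_p event probabilities (sum <= 1).
#' @param seed integer seed.
#' @param method label for the output set.
#' @return a disjoint [group_set()].
#' @export
perturb_groups <- function(truth, split_p = 0.1, merge_p = 0.05,
                           drop_p = 0.1, seed = 1, method = "perturbed") {
  stopifnot(inherits(truth, "group_set"),
            split_p + merge_p + drop_p <= 1)
  set.seed(as.integer(seed))
  groups <- truth$groups
  out <- list()
  merge_into <- integer(0)          # index in `out` the group merges with
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    u <- stats::runif(1)
    if (u < split_p && length(g) >= 2) {
      cut <- sample(length(g) - 1, 1)
      idx <- sample(length(g))
      out[[length(out) + 1]] <- g[idx[seq_len(cut)]]
      out[[length(out) + 1]] <- g[idx[-seq_len(cut)]]
    } else if (u < split_p + merge_p && length(groups) >= 2) {
      merge_into[length(merge_into) + 1] <- gi
    } else if (u < split_p + merge_p + drop_p && length(g) >= 1) {
      out[[length(out) + 1]] <- g[-sample(length(g), 1)]
    } else {
      out[[length(out) + 1]] <- g
    }
  }
  for (gi in merge_into) {
    if (!length(out)) { out[[1]] <- groups[[gi]]; next }
    k <- sample(length(out), 1)
    out[[k]] <- union(out[[k]], groups[[gi]])
  }
  out <- canonicalize_groups(out[lengths(out) >= 2])
  names(out) <- if (length(out)) sprintf("p%04d", seq_along(out))
  group_set(out, method = method)
}

#' Built-in example pathway collection
#'
#' A small collection mixing sources, including the biotinylation ligase
#' steps (EC 6.3.4.9/.10/.11/.15) as a four-step pathway.
#'
#' @return a `pathway_collection` of three pathways.
#' @export
example_pathways <- function() {
  pathway_collection(list(
    pathway("biotinylation", "kegg",
            c("6.3.4.9", "6.3.4.10", "6.3.4.11", "6.3.4.15")),
    pathway("biotin biosynthesis", "kegg",
            c("2.3.1.47", "2.6.1.62", "6.2.1.14", "2.8.1.6", "6.3.3.3")),
    pathway("glycolysis core", "metacyc",
            c("2.7.1.1", "5.3.1.9", "2.7.1.11", "4.1.2.13"))))
}

#' Assign true EC numbers to simulated families
#'
#' Draws one complete EC per selected family from the collection's steps and
#' emits, per EC, one annotated reference sequence (a lightly mutated copy of
#' a family member) playing the role of a curated database entry.
#'
#' @param sim a `sim_data` object from [simulate_orthologs()].
#' @param collection a `pathway_collection` supplying the EC pool.
#' @param seed integer seed.
#' @param ref_mutation_rate per-site mutation applied to the reference copy.
#' @return list with `family_ec` (named vector, family id -> EC), `ec_table`
#'   (data.frame `id`, `ec` for the reference sequences) and `ref_seqs`
#'   ([Biostrings::AAStringSet]).
#' @export
assign_true_ecs <- function(sim, collection = example_pathways(), seed = 1,
                            ref_mutation_rate = 0.02) {
  stopifnot(inherits(sim, "sim_data"))
  if (!length(collection)) stop("no pathways loaded")
  set.seed(as.integer(seed))
  ecs <- unique(unlist(lapply(collection, `[[`, "steps")))
  fams <- names(sim$truth$groups)
  k <- min(length(ecs), length(fams))
  fam_sel <- fams[seq_len(k)]
  ec_sel <- ecs[seq_len(k)]
  refs <- character(k)
  ref_ids <- sprintf("REF%03d", seq_len(k))
  for (i in seq_len(k)) {
    member <- sim$truth$groups[[fam_sel[i]]][1]
    s <- strsplit(as.character(sim$seqs[[member]]), "")[[1]]
    refs[i] <- paste(mutate_seq(s, ref_mutation_rate), collapse = "")
  }
  ref_seqs <- Biostrings::AAStringSet(refs)
  names(ref_seqs) <- ref_ids
  list(family_ec = stats::setNames(ec_sel, fam_sel),
       ec_table = data.frame(id = ref_ids, ec = ec_sel,
                             stringsAsFactors = FALSE),
       ref_seqs = ref_seqs)
}

#' Write a fixture set to disk
#'
#' Emits the manifest, per-species FASTA files, the similarity table, the
#' true groups, the gene trees, and — when `annotations` is supplied — the
#' reference FASTA, EC table and pathway collection, all as plain text.
#'
#' @param sim a `sim_data` object.
#' @param dir output directory (created).
#' @param annotations optional result of [assign_true_ecs()].
#' @param collection pathway collection to write alongside annotations.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(sim, dir, annotations = NULL,
                           collection = example_pathways()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in sim$manifest$species) {
    ids <- names(sim$species)[sim$species == sp]
    write_fasta(sim$seqs[ids], file.path(dir, paste0(sp, ".fasta")))
  }
  y <- lapply(seq_len(nrow(sim$manifest)), function(i)
    list(fasta = sim$manifest$fasta[i], taxon = sim$manifest$taxon[i]))
  names(y) <- sim$manifest$species
  yaml::write_yaml(y, file.path(dir, "manifest.yaml"))
  write_similarity_table(sim$hits, file.path(dir, "hits.tsv"))
  write_group_file(sim$truth, file.path(dir, "truth_groups.txt"))
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  for (fam in names(sim$gene_trees))
    writeLines(sim$gene_trees[[fam]],
               file.path(dir, "trees", paste0(fam, ".nwk")))
  if (!is.null(annotations)) {
    write_fasta(annotations$ref_seqs, file.path(dir, "ref.fasta"))
    utils::write.table(annotations$ec_table, file.path(dir, "ec_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    write_pathways(collection, file.path(dir, "pathways.yaml"))
  }
  invisible(dir)
}
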