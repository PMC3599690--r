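# End-to-end pipeline: scan -> classify -> phylogeny -> gene context ->
# sequence properties, with a reproducible report bundle.

#' Pipeline configuration
#'
#' Inputs may be file paths (FASTA / GFF3 / TSV) or in-memory objects
#' (named sequence vectors, gene tables, a [reference_panel()]).
#'
#' @param proteins proteome: named character vector or protein-FASTA path.
#' @param genes gene table: data.frame or GFF3 path (optional; context
#'   analysis is skipped without it).
#' @param genome contig DNA: named character vector or FASTA path
#'   (optional; G+C content is skipped without it).
#' @param panel reference panel: [reference_panel()] data.frame, or a
#'   protein-FASTA path plus `panel_labels` TSV (columns `id`, `family`).
#' @param panel_labels labels TSV path when `panel` is a FASTA path.
#' @param mode scanner strictness, `"strict"` or `"relaxed"`.
#' @param scoring a [scoring_scheme()].
#' @param thresholds family/subfamily identity thresholds, strictly
#'   increasing fractions in (0, 1).
#' @param window gene-rank window for context analysis.
#' @param seed integer recorded in outputs (the analysis itself is
#'   deterministic; the seed also drives any downstream resampling).
#' @param out_dir report directory.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(proteins, genes = NULL, genome = NULL,
                            panel = NULL, panel_labels = NULL,
                            mode = c("strict", "relaxed"),
                            scoring = scoring_scheme(),
                            thresholds = c(0.40, 0.55), window = 2,
                            seed = 1L, out_dir = tempfile("cypminer_run_")) {
  mode <- match.arg(mode)
  if (!(length(thresholds) == 2 && thresholds[1] > 0 &&
        thresholds[1] < thresholds[2] && thresholds[2] < 1))
    stop("thresholds must satisfy 0 < family < subfamily < 1", call. = FALSE)
  stopifnot(window >= 1)
  structure(list(proteins = proteins, genes = genes, genome = genome,
                 panel = panel, panel_labels = panel_labels, mode = mode,
                 scoring = scoring, thresholds = thresholds,
                 window = as.integer(window), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

resolve_proteins <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x))
    read_fasta(x, "protein") else x
}
resolve_genes <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && file.exists(x)) read_gff3(x) else x
}
resolve_genome <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) && file.exists(x))
    read_fasta(x, "dna") else x
}
resolve_panel <- function(panel, labels) {
  if (is.null(panel) || is.data.frame(panel)) return(panel)
  seqs <- read_fasta(panel, "protein")
  lab <- read_tsv_plain(labels)
  reference_panel(seqs, lab$family[match(names(seqs), lab$id)])
}

# extract gene DNA (revcomp on minus strand) for genes with coordinates
gene_dna_from_contigs <- function(genes, contigs) {
  out <- character()
  for (r in seq_len(nrow(genes))) {
    ctg <- contigs[[genes$contig[r]]]
    if (is.null(ctg)) next
    s <- substr(ctg, genes$start[r], genes$end[r])
    if (genes$strand[r] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    out[genes$gene_id[r]] <- s
  }
  out
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full CYP-mining pipeline
#'
#' Stages: motif scan over the proteome; family assignment of candidates
#' against the reference panel; identity-distance neighbor-joining paralog
#' tree; gene-neighborhood census (candidate genes are treated as the
#' `cyp` role); per-candidate sequence properties. Writes `hits.tsv`,
#' `assignments.tsv`, `tree.nwk`, `clusters.tsv`, `props.tsv`,
#' `summary.tsv` and `run_log.txt` into `config$out_dir`; every TSV starts
#' with comment lines recording the seed and configuration hash, so two
#' runs of the same configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `calls`, `candidates`, `assignments`,
#'   `tree`, `census`, `props`, `summary`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  proteins <- run_stage("input", resolve_proteins(config$proteins))
  genes <- run_stage("input", resolve_genes(config$genes))
  genome <- run_stage("input", resolve_genome(config$genome))
  panel <- run_stage("input", resolve_panel(config$panel, config$panel_labels))

  hash <- config_hash(list(proteins, genes, genome, panel, config$mode,
                           config$scoring$matrix_name, config$scoring$gap_open,
                           config$scoring$gap_extend, config$thresholds,
                           config$window, config$seed))
  hdr <- c(sprintf("# cypminer %s", as.character(utils::packageVersion("cypminer"))),
           sprintf("# seed=%d config_hash=%s", config$seed, hash))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)

  calls <- run_stage("scan", scan_proteome(proteins, scan_config(config$mode)))
  call_tbl <- cyp_call_table(calls)
  candidates <- call_tbl$protein_id[call_tbl$candidate]
  hits <- motif_hits_table(calls[candidates])
  write_tsv_plain(hits, p("hits.tsv"), hdr)

  assignments <- NULL
  if (!is.null(panel) && length(candidates)) {
    assignments <- run_stage("classify",
      assign_families(proteins[candidates], panel, scoring = config$scoring,
                      thresholds = config$thresholds))
    write_tsv_plain(assignments, p("assignments.tsv"), hdr)
  }

  tree <- NULL
  if (length(candidates) >= 3L) {
    tree <- run_stage("phylo", {
      D <- distance_matrix(proteins[candidates], config$scoring)
      neighbor_joining(D)
    })
    write_newick(tree, p("tree.nwk"))
  }

  census <- NULL
  if (!is.null(genes)) {
    census <- run_stage("context", {
      g <- genes
      g$role[g$gene_id %in% candidates] <- "cyp"
      # genes labeled cyp that the scan did not confirm lose the label
      g$role[g$role == "cyp" & !(g$gene_id %in% candidates)] <- "other:unconfirmed_cyp"
      cluster_census(g, config$window)
    })
    write_tsv_plain(census$reports, p("clusters.tsv"), hdr)
  }

  gene_dna <- if (!is.null(genes) && !is.null(genome))
    gene_dna_from_contigs(genes[genes$gene_id %in% candidates, , drop = FALSE],
                          genome) else NULL
  props <- run_stage("props",
    protein_properties(proteins[candidates], gene_dna = gene_dna))
  write_tsv_plain(props, p("props.tsv"), hdr)

  fam_counts <- if (!is.null(assignments)) table(assignments$family) else table(character())
  exceptions <- call_tbl[call_tbl$candidate & nzchar(call_tbl$notes),
                         c("protein_id", "notes")]
  summary_df <- rbind(
    data.frame(key = "n_candidates", value = as.character(length(candidates))),
    data.frame(key = paste0("family_", names(fam_counts)),
               value = as.character(as.integer(fam_counts))),
    if (!is.null(census))
      data.frame(key = paste0("clusters_", names(census$counts)),
                 value = as.character(census$counts)),
    if (nrow(exceptions))
      data.frame(key = paste0("exception_", exceptions$protein_id),
                 value = exceptions$notes))
  write_tsv_plain(summary_df, p("summary.tsv"), hdr)

  writeLines(c(hdr,
               sprintf("# mode=%s matrix=%s gap_open=%g gap_extend=%g",
                       config$mode, config$scoring$matrix_name,
                       config$scoring$gap_open, config$scoring$gap_extend),
               sprintf("# thresholds=%g,%g window=%d", config$thresholds[1],
                       config$thresholds[2], config$window),
               sprintf("# n_proteins=%d n_candidates=%d", length(proteins),
                       length(candidates))),
             p("run_log.txt"))

  invisible(list(calls = calls, candidates = candidates,
                 assignments = assignments, tree = tree, census = census,
                 props = props, summary = summary_df,
                 files = file.path(config$out_dir,
                                   c("hits.tsv", "assignments.tsv", "tree.nwk",
                                     "clusters.tsv", "props.tsv",
                                     "summary.tsv", "run_log.txt"))))
}
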