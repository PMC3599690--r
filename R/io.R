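# Readers and writers for the standard formats touched: FASTA (protein and
# nucleotide), GFF3 gene tables with a `role=` attribute, and plain TSV.
# FASTA parsing/writing goes through Biostrings; GFF3 parsing goes through
# rtracklayer. All coordinates are 1-based inclusive (GFF3 convention).

#' Read a FASTA file
#'
#' @param path file path.
#' @param type `"protein"` or `"dna"`.
#' @return named character vector of sequences; ids are the first
#'   whitespace-delimited token of each header. Duplicate ids are an error.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  set <- if (type == "protein") Biostrings::readAAStringSet(path)
  else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(out))
  if (anyDuplicated(names(out)))
    stop("duplicate sequence id in ", path, ": ",
         names(out)[duplicated(names(out))][1], call. = FALSE)
  out
}

#' Write a FASTA file (60-column wrapping)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param type `"protein"` or `"dna"`.
#' @export
write_fasta <- function(seqs, path, type = c("protein", "dna")) {
  type <- match.arg(type)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids", call. = FALSE)
  set <- if (type == "protein") Biostrings::AAStringSet(seqs)
  else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a GFF3 gene table
#'
#' Parses with rtracklayer and returns the package's gene-table layout.
#' The functional label is read from the `role` attribute (configurable);
#' any other attributes are passed through as extra columns.
#'
#' @param path GFF3 file.
#' @param role_attribute attribute key holding the role label.
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"."`), `role`, plus pass-through attribute
#'   columns.
#' @export
read_gff3 <- function(path, role_attribute = "role") {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(gr)
  strand <- as.character(mc$strand)
  strand[strand == "*"] <- "."
  meta <- mc[, setdiff(names(mc), c("seqnames", "start", "end", "width",
                                    "strand", "source", "type", "score",
                                    "phase")), drop = FALSE]
  id <- if ("ID" %in% names(meta)) as.character(meta$ID) else
    sprintf("gene%05d", seq_len(nrow(mc)))
  role <- if (role_attribute %in% names(meta))
    as.character(meta[[role_attribute]]) else NA_character_
  out <- data.frame(gene_id = id, contig = as.character(mc$seqnames),
                    start = mc$start, end = mc$end, strand = strand,
                    role = role, stringsAsFactors = FALSE)
  extra <- setdiff(names(meta), c("ID", role_attribute))
  for (e in extra) out[[e]] <- as.character(meta[[e]])
  check_genes_coords(out)
  out
}

check_genes_coords <- function(genes) {
  if (any(genes$start > genes$end))
    stop("gene with start > end: ",
         genes$gene_id[which(genes$start > genes$end)[1]], call. = FALSE)
  invisible(genes)
}

escape_gff3 <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write a gene table as GFF3
#'
#' One `gene` feature per row; `ID=` and `role=` attributes carry the id
#' and functional label; extra columns become additional attributes.
#'
#' @param genes gene table (see [read_gff3()]).
#' @param path output path.
#' @param extra_attributes optional character vector (one per gene, NA to
#'   skip) of preformatted `key=value` attribute strings.
#' @param header_lines optional comment lines written after the
#'   `##gff-version 3` pragma.
#' @export
write_gff3 <- function(genes, path, extra_attributes = NULL,
                       header_lines = NULL) {
  check_genes_coords(genes)
  core <- c("gene_id", "contig", "start", "end", "strand", "role")
  extra_cols <- setdiff(names(genes), c(core, "rank", "rank_offset",
                                        "same_strand"))
  attrs <- paste0("ID=", escape_gff3(genes$gene_id),
                  ";role=", escape_gff3(genes$role))
  for (e in extra_cols) {
    v <- as.character(genes[[e]])
    add <- ifelse(is.na(v), "", paste0(";", e, "=", escape_gff3(v)))
    attrs <- paste0(attrs, add)
  }
  if (!is.null(extra_attributes)) {
    add <- ifelse(is.na(extra_attributes), "",
                  paste0(";", extra_attributes))
    attrs <- paste0(attrs, add)
  }
  lines <- paste(genes$contig, "cypminer", "gene", genes$start, genes$end,
                 ".", genes$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", header_lines, lines), path)
  invisible(path)
}

# TSV writer used for ground-truth and report tables; optional comment
# header lines ("# ..." ) precede the column header.
write_tsv_plain <- function(df, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
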