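# Pairwise global alignment identity and family/subfamily assignment.
#
# P450 nomenclature assigns two sequences to the same family when they share
# more than 40% amino-acid identity and to the same subfamily above 55%
# (strict "more than": 40% exactly is NOT the same family). Identity is
# computed on an affine-gap global alignment, counting identical columns over
# all columns after trimming terminal-gap columns, which approximates the
# local-overlap identities that database searches report.

#' Alignment scoring scheme
#'
#' @param matrix name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend non-negative gap penalties; a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @return a `scoring_scheme` object.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be non-negative", call. = FALSE)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  mat <- get(matrix, envir = e)
  if (!isTRUE(all.equal(mat, t(mat))))
    stop("substitution matrix must be symmetric", call. = FALSE)
  structure(list(matrix_name = matrix, matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman–Wunsch with affine gaps, delegated to
#' [Biostrings::pairwiseAlignment()] (deterministic traceback).
#'
#' @param a,b protein sequences (single strings, non-empty).
#' @param scoring a [scoring_scheme()].
#' @return a `cyp_alignment`: list with `aligned_a`, `aligned_b` (gapped
#'   strings of equal length) and `score`.
#' @export
global_align <- function(a, b, scoring = scoring_scheme()) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  a <- check_protein(a, what = "first sequence")
  b <- check_protein(b, what = "second sequence")
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("cannot align an empty sequence", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  structure(list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
                 aligned_b = as.character(Biostrings::alignedSubject(aln)),
                 score = Biostrings::score(aln)),
            class = "cyp_alignment")
}

# Fraction of identical columns between two equal-length gapped rows, after
# trimming columns outside the region where both rows have residues.
identity_from_rows <- function(ra, rb) {
  a <- seq_chars(ra); b <- seq_chars(rb)
  if (length(a) != length(b)) stop("aligned rows differ in length", call. = FALSE)
  res <- a != "-" & b != "-"
  if (!any(res)) stop("undefined identity: no aligned residue columns", call. = FALSE)
  from <- which(res)[1]; to <- which(res)[sum(res)]
  cols <- from:to
  sum(a[cols] == b[cols] & a[cols] != "-") / length(cols)
}

#' Percent identity of an alignment
#'
#' Identical columns divided by alignment columns, after discarding
#' terminal-gap columns (columns before the first or after the last position
#' where both rows carry a residue). Returns a fraction in \[0, 1\].
#'
#' @param alignment a `cyp_alignment` from [global_align()].
#' @return numeric fraction in \[0, 1\].
#' @export
percent_identity <- function(alignment) {
  stopifnot(inherits(alignment, "cyp_alignment"))
  identity_from_rows(alignment$aligned_a, alignment$aligned_b)
}

# Vectorised query-vs-references identities (one pairwiseAlignment call).
# The aligned-region accessors pattern()/subject() already exclude
# terminal-gap columns, matching the percent_identity() definition, and are
# far cheaper than the padded alignedPattern()/alignedSubject() pair.
identity_many <- function(query, refs, scoring = scoring_scheme()) {
  if (!length(refs)) return(numeric())
  aln <- Biostrings::pairwiseAlignment(
    unname(refs), query, type = "global", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pa <- as.character(Biostrings::pattern(aln))
  sa <- as.character(Biostrings::subject(aln))
  vapply(seq_along(pa), function(i) identity_from_rows(pa[i], sa[i]), numeric(1))
}

#' Family/subfamily verdict from a best identity
#'
#' Strict "more than" semantics: identity > 55% places the query in the best
#' reference's subfamily, > 40% in its family (new subfamily), and 40% or
#' less means a new family. 0.40 exactly is a new family.
#'
#' @param identity best identity fraction in \[0, 1\].
#' @param thresholds numeric length-2, `c(family, subfamily)` fractions;
#'   must satisfy `0 < family < subfamily < 1`.
#' @return one of `"same_subfamily"`, `"same_family_new_subfamily"`,
#'   `"new_family"`.
#' @export
family_verdict <- function(identity, thresholds = c(0.40, 0.55)) {
  stopifnot(length(thresholds) == 2, thresholds[1] > 0,
            thresholds[1] < thresholds[2], thresholds[2] < 1)
  if (identity > thresholds[2]) "same_subfamily"
  else if (identity > thresholds[1]) "same_family_new_subfamily"
  else "new_family"
}

#' Build a labeled reference panel
#'
#' @param seqs named character vector of reference protein sequences.
#' @param families character vector of family labels, parallel to `seqs`
#'   (NA marks an unlabeled reference).
#' @return data.frame with columns `id`, `seq`, `family`.
#' @export
reference_panel <- function(seqs, families) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            length(families) == length(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate reference ids in panel", call. = FALSE)
  data.frame(id = names(seqs), seq = unname(seqs),
             family = as.character(families), stringsAsFactors = FALSE)
}

#' Assign a query protein to a CYP family by best panel identity
#'
#' The query is globally aligned to every panel reference; the verdict is
#' [family_verdict()] applied to the best identity. The family label is
#' copied from the best reference, unless the verdict is `new_family` or the
#' best reference carries no label — an unlabeled best hit yields
#' `new_family` with a cross-reference note regardless of identity, since a
#' family name cannot be inherited from an unnamed sequence.
#'
#' @param query a single protein sequence (named, or supply `id`).
#' @param panel a [reference_panel()].
#' @param id query identifier.
#' @param scoring a [scoring_scheme()].
#' @param thresholds family/subfamily identity thresholds (fractions).
#' @return one-row data.frame: `query_id`, `best_ref`, `best_identity`,
#'   `verdict`, `family`, `note`.
#' @export
assign_family <- function(query, panel, id = NULL, scoring = scoring_scheme(),
                          thresholds = c(0.40, 0.55)) {
  if (!is.data.frame(panel) || !nrow(panel))
    stop("reference panel is empty", call. = FALSE)
  if (is.null(id)) id <- if (!is.null(names(query))) names(query)[1] else "query"
  q <- check_protein(query, what = "query")
  ids <- identity_many(q, panel$seq, scoring)
  best <- which.max(ids)
  verdict <- family_verdict(ids[best], thresholds)
  note <- ""
  fam <- panel$family[best]
  if (is.na(fam)) {
    if (verdict != "new_family")
      note <- sprintf("best hit %s (%.0f%%) is unlabeled; treated as a new family",
                      panel$id[best], 100 * ids[best])
    verdict <- "new_family"
    fam <- "new"
  } else if (verdict == "new_family") {
    fam <- "new"
  }
  data.frame(query_id = id, best_ref = panel$id[best],
             best_identity = ids[best], verdict = verdict, family = fam,
             note = note, stringsAsFactors = FALSE)
}

#' Assign every query in a set to a family
#'
#' @param queries named character vector of query proteins.
#' @inheritParams assign_family
#' @return data.frame with one [assign_family()] row per query.
#' @export
assign_families <- function(queries, panel, scoring = scoring_scheme(),
                            thresholds = c(0.40, 0.55)) {
  stopifnot(is.character(queries), !is.null(names(queries)))
  out <- do.call(rbind, lapply(names(queries), function(id)
    assign_family(queries[[id]], panel, id = id, scoring = scoring,
                  thresholds = thresholds)))
  rownames(out) <- NULL
  out
}
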