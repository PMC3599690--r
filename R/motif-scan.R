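# Signature-motif scanning.
#
# Three sequence signatures identify most bacterial P450s:
#   * I-helix  : a 5-residue window around the oxygen-activating threonine
#                ([AGFT]-x-x-[TSAIP]-[TV]; canonical when position 4 is Thr)
#   * K-helix  : the E-x-x-R salt bridge (relaxed E-x(2,3)-W variants occur,
#                notably in family CYP157)
#   * heme     : the Cys pocket G-x-x-x-C-x-G; relaxed form is a Cys with a
#                Gly within 4 residues on at least one side
#
# All scanners return 1-based inclusive spans, resolve overlapping matches
# leftmost-first, and flag each hit canonical/atypical. "X" in the input
# matches wildcard positions only, never a conserved position.

MOTIF_KINDS <- c("I_helix", "K_helix", "heme")

I_HELIX_POS1 <- c("A", "G", "F", "T")
I_HELIX_POS4 <- c("T", "S", "A", "I", "P")
I_HELIX_POS5 <- c("T", "V")

motif_hit <- function(kind, start, end, matched, canonical, conserved_ok) {
  data.frame(kind = kind, start = as.integer(start), end = as.integer(end),
             matched = matched, canonical = canonical,
             conserved_ok = conserved_ok, stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             matched = character(), canonical = logical(),
             conserved_ok = logical(), stringsAsFactors = FALSE)
}

#' Locate the heme-binding cysteine pocket
#'
#' Scans for the canonical G-x-x-x-C-x-G signature (all non-overlapping
#' matches, leftmost first). When no canonical match exists, a relaxed scan
#' reports every cysteine that has a glycine within 4 residues on at least
#' one side (`canonical = FALSE`); relaxed spans cover the would-be
#' G-x-x-x-C-x-G window clipped to the sequence.
#'
#' @param seq a protein sequence (single string over the 20 residues; "X"
#'   tolerated at wildcard positions).
#' @return a data.frame of motif hits (`kind`, `start`, `end`, `matched`,
#'   `canonical`, `conserved_ok`), ordered by `start`; zero rows if none.
#' @examples
#' find_heme_motif("HLAFSHGIHQCLG")  # canonical, matched "GIHQCLG"
#' @export
find_heme_motif <- function(seq) {
  s <- check_protein(seq)
  n <- nchar(s)
  if (n == 0L) return(empty_hits())
  ch <- seq_chars(s)
  hits <- list()
  i <- 1L
  while (i <= n - 6L) {
    if (ch[i] == "G" && ch[i + 4L] == "C" && ch[i + 6L] == "G") {
      hits[[length(hits) + 1L]] <-
        motif_hit("heme", i, i + 6L, substr(s, i, i + 6L), TRUE, TRUE)
      i <- i + 7L
    } else i <- i + 1L
  }
  if (length(hits)) return(do.call(rbind, hits))
  # relaxed: Cys flanked by a Gly within 4 residues on at least one side
  for (c0 in which(ch == "C")) {
    left <- if (c0 > 1L) ch[max(1L, c0 - 4L):(c0 - 1L)] else character()
    right <- if (c0 < n) ch[(c0 + 1L):min(n, c0 + 4L)] else character()
    if (any(left == "G") || any(right == "G")) {
      from <- max(1L, c0 - 4L); to <- min(n, c0 + 2L)
      hits[[length(hits) + 1L]] <-
        motif_hit("heme", from, to, substr(s, from, to), FALSE, TRUE)
    }
  }
  if (length(hits)) do.call(rbind, hits) else empty_hits()
}

# K-helix scan over a subrange [from, to] of the sequence (1-based, inclusive).
k_scan <- function(s, from, to) {
  n <- nchar(s)
  from <- max(1L, from); to <- min(n, to)
  if (to - from + 1L < 4L) return(empty_hits())
  ch <- seq_chars(s)
  hits <- list()
  i <- from
  while (i <= to - 3L) {                       # canonical E-x-x-R
    if (ch[i] == "E" && ch[i + 3L] == "R") {
      hits[[length(hits) + 1L]] <-
        motif_hit("K_helix", i, i + 3L, substr(s, i, i + 3L), TRUE, TRUE)
      i <- i + 4L
    } else i <- i + 1L
  }
  if (length(hits)) return(do.call(rbind, hits))
  i <- from                                    # relaxed E-x(2,3)-W
  while (i <= to - 3L) {
    if (ch[i] == "E" && ch[i + 3L] == "W") {
      hits[[length(hits) + 1L]] <-
        motif_hit("K_helix", i, i + 3L, substr(s, i, i + 3L), FALSE, FALSE)
      i <- i + 4L
    } else if (ch[i] == "E" && i + 4L <= to && ch[i + 4L] == "W") {
      hits[[length(hits) + 1L]] <-
        motif_hit("K_helix", i, i + 4L, substr(s, i, i + 4L), FALSE, FALSE)
      i <- i + 5L
    } else i <- i + 1L
  }
  if (length(hits)) do.call(rbind, hits) else empty_hits()
}

#' Locate the K-helix EXXR motif
#'
#' Canonical matches are E-x-x-R (Glu/Arg checked literally). When none
#' exist, relaxed E-x-x-W and E-x-x-x-W matches — the CYP157-style EXXW
#' variants — are reported with `canonical = FALSE`.
#'
#' @inheritParams find_heme_motif
#' @return a data.frame of motif hits (see [find_heme_motif()]).
#' @examples
#' find_k_helix("ELLR")   # canonical
#' find_k_helix("EVLW")   # CYP157-style, non-canonical
#' @export
find_k_helix <- function(seq) {
  s <- check_protein(seq)
  if (nchar(s) == 0L) return(empty_hits())
  k_scan(s, 1L, nchar(s))
}

#' Locate the I-helix oxygen-activation window
#'
#' Matches the residue-class window \[AGFT\]-x-x-\[TSAIP\]-\[TV\], a
#' generalisation of the "GXXTT" consensus covering the variant windows seen
#' in real streptomycete CYPs (GHETT, FAPTT, GHQPT, GVIST, ...). A hit is
#' canonical (`conserved_ok = TRUE`) only when position 4 is the conserved
#' threonine; other matches are reported but flagged atypical.
#'
#' @inheritParams find_heme_motif
#' @return a data.frame of motif hits (see [find_heme_motif()]).
#' @examples
#' find_i_helix("GFDTT")  # canonical, Thr at position 4
#' find_i_helix("GHEAT")  # hit, atypical
#' @export
find_i_helix <- function(seq) {
  s <- check_protein(seq)
  n <- nchar(s)
  if (n == 0L) return(empty_hits())
  ch <- seq_chars(s)
  hits <- list()
  i <- 1L
  while (i <= n - 4L) {
    if (ch[i] %in% I_HELIX_POS1 && ch[i + 3L] %in% I_HELIX_POS4 &&
        ch[i + 4L] %in% I_HELIX_POS5) {
      ok <- ch[i + 3L] == "T"
      hits[[length(hits) + 1L]] <-
        motif_hit("I_helix", i, i + 4L, substr(s, i, i + 4L), ok, ok)
      i <- i + 5L
    } else i <- i + 1L
  }
  if (length(hits)) do.call(rbind, hits) else empty_hits()
}

#' Scanner settings
#'
#' @param mode `"strict"` keeps canonical hits only (the conservative default
#'   used for candidate discovery); `"relaxed"` additionally admits the
#'   documented exception forms (EXXW K-helices, non-canonical heme pockets,
#'   I-helix windows without the conserved threonine).
#' @return a `scan_config` object.
#' @export
scan_config <- function(mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "scan_config")
}

#' Call a protein as a CYP candidate from its signature motifs
#'
#' Runs the three scanners and applies the candidacy rule: a heme-pocket hit
#' is required, plus at least one of an I-helix or K-helix hit. The K-helix
#' is searched between the best I-helix hit and the best heme hit when both
#' exist (the structural order of the three motifs), otherwise over the whole
#' sequence. Kinds without any hit are reported as missing ("Unidentified");
#' every non-canonical or atypical best hit generates an exception note.
#'
#' In `"strict"` mode only canonical hits count; in `"relaxed"` mode the
#' exception forms count too, but are flagged.
#'
#' @param seq a protein sequence (single string).
#' @param id protein identifier (defaults to the sequence's name).
#' @param config a [scan_config()].
#' @return a `cyp_call` object: list with `protein_id`, `hits` (best hit per
#'   kind), `missing`, `candidate` and `exception_notes`.
#' @export
call_cyp <- function(seq, id = NULL, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (is.null(id)) id <- if (!is.null(names(seq))) names(seq)[1] else "protein"
  s <- check_protein(seq)
  strict <- config$mode == "strict"
  keep <- function(h) if (strict) h[h$canonical, , drop = FALSE] else h

  heme <- keep(find_heme_motif(s))
  ih <- keep(find_i_helix(s))
  best_heme <- if (nrow(heme)) heme[1, , drop = FALSE] else NULL
  best_i <- if (nrow(ih)) ih[1, , drop = FALSE] else NULL

  if (!is.null(best_i) && !is.null(best_heme)) {
    kh <- keep(k_scan(s, best_i$end + 1L, best_heme$start - 1L))
  } else {
    kh <- keep(k_scan(s, 1L, nchar(s)))
  }
  best_k <- if (nrow(kh)) kh[1, , drop = FALSE] else NULL

  best <- do.call(rbind, Filter(Negate(is.null), list(best_i, best_k, best_heme)))
  if (is.null(best)) best <- empty_hits()
  missing <- setdiff(MOTIF_KINDS, best$kind)

  notes <- character()
  for (r in seq_len(nrow(best))) {
    h <- best[r, ]
    if (h$kind == "I_helix" && !h$conserved_ok)
      notes <- c(notes, sprintf("I-helix window %s lacks the conserved Thr", h$matched))
    if (h$kind == "K_helix" && !h$canonical)
      notes <- c(notes, sprintf("K-helix EXXW-type variant %s (no Arg)", h$matched))
    if (h$kind == "heme" && !h$canonical)
      notes <- c(notes, sprintf("heme pocket %s does not follow GXXXCXG", h$matched))
  }

  candidate <- !is.null(best_heme) && (!is.null(best_i) || !is.null(best_k))
  structure(list(protein_id = id, hits = best, missing = missing,
                 candidate = candidate, exception_notes = notes),
            class = "cyp_call")
}

#' @export
print.cyp_call <- function(x, ...) {
  cat(sprintf("<cyp_call> %s: %s\n", x$protein_id,
              if (x$candidate) "CYP candidate" else "not a candidate"))
  if (nrow(x$hits)) print(x$hits, row.names = FALSE)
  if (length(x$missing)) cat("missing:", paste(x$missing, collapse = ", "), "\n")
  for (nt in x$exception_notes) cat("note:", nt, "\n")
  invisible(x)
}

#' Scan a whole proteome for CYP candidates
#'
#' @param proteins named character vector of protein sequences.
#' @param config a [scan_config()].
#' @return a list of [call_cyp()] results, named by protein id.
#' @seealso [cyp_call_table()], [motif_hits_table()]
#' @export
scan_proteome <- function(proteins, config = scan_config()) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  if (anyDuplicated(names(proteins)))
    stop("duplicate protein ids in proteome", call. = FALSE)
  out <- lapply(names(proteins), function(id)
    call_cyp(proteins[[id]], id = id, config = config))
  names(out) <- names(proteins)
  out
}

#' Summarise proteome scan calls as a table
#'
#' @param calls result of [scan_proteome()].
#' @return data.frame with one row per protein: `protein_id`, `candidate`,
#'   `missing` (comma-separated), `notes`.
#' @export
cyp_call_table <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(protein_id = cl$protein_id, candidate = cl$candidate,
               missing = paste(cl$missing, collapse = ","),
               notes = paste(cl$exception_notes, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
}

#' Tabulate best motif hits across a proteome scan
#'
#' @param calls result of [scan_proteome()].
#' @return data.frame mirroring the classic motif-comparison table layout:
#'   one row per (protein, kind) best hit with span, matched string and flags.
#' @export
motif_hits_table <- function(calls) {
  rows <- lapply(calls, function(cl) {
    if (!nrow(cl$hits)) return(NULL)
    cbind(protein_id = cl$protein_id, cl$hits)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- cbind(protein_id = character(), empty_hits())
  rownames(out) <- NULL
  out
}
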