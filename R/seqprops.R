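# Per-sequence properties: nucleotide G+C content, protein length, average
# molecular weight, isoelectric point.
#
# The isoelectric point follows the Bjellqvist convention (the pKa set
# behind the ExPASy Compute pI/MW tool): residue-specific terminal pKa
# values plus the ionizable side chains D, E, C, Y, H, K, R, with the root
# of the Henderson-Hasselbalch net-charge function found by bisection.
# Molecular weights use average (not monoisotopic) residue masses.

# ExPASy-style average residue masses (Da)
AVERAGE_RESIDUE_MASSES <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS <- 18.0153

#' Average-mass table for molecular-weight computation
#'
#' @param residue_masses named numeric vector of average residue masses (Da)
#'   for the 20 amino acids.
#' @param water mass of one water molecule (Da), added once per chain.
#' @return a `mass_table` object.
#' @export
mass_table <- function(residue_masses = AVERAGE_RESIDUE_MASSES,
                       water = WATER_MASS) {
  stopifnot(all(residue_masses > 0), water > 0)
  missing <- setdiff(AA20, names(residue_masses))
  if (length(missing))
    stop("mass table lacks residues: ", paste(missing, collapse = ","),
         call. = FALSE)
  structure(list(residue_masses = residue_masses, water = water),
            class = "mass_table")
}

#' G+C content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` is excluded from numerator and
#' denominator. The full-precision percentage is returned; round to the
#' nearest integer for conventional reporting.
#'
#' @param dna nucleotide sequence over A, C, G, T, N (case-insensitive).
#' @return percentage in \[0, 100\].
#' @export
gc_content <- function(dna) {
  if (!is.character(dna) || length(dna) != 1L || is.na(dna))
    stop("dna must be a single character string", call. = FALSE)
  ch <- seq_chars(toupper(dna))
  bad <- which(!(ch %in% c("A", "C", "G", "T", "N")))
  if (length(bad))
    stop(sprintf("non-nucleotide character '%s' at position %d",
                 ch[bad[1]], bad[1]), call. = FALSE)
  acgt <- ch[ch != "N"]
  if (!length(acgt))
    stop("G+C content undefined: no unambiguous bases", call. = FALSE)
  100 * sum(acgt %in% c("G", "C")) / length(acgt)
}

#' Average molecular weight of a protein, in kDa
#'
#' Sum of average residue masses plus one water mass.
#'
#' @param protein protein sequence over the 20 residues.
#' @param masses a [mass_table()].
#' @return molecular weight in kDa (full precision; report to 2 decimals).
#' @export
molecular_weight <- function(protein, masses = mass_table()) {
  stopifnot(inherits(masses, "mass_table"))
  s <- check_protein(protein, allow_x = FALSE, what = "protein")
  if (nchar(s) == 0L) stop("empty protein sequence", call. = FALSE)
  ch <- seq_chars(s)
  (sum(masses$residue_masses[ch]) + masses$water) / 1000
}

# Bjellqvist/ExPASy pKa convention
BJELLQVIST_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
BJELLQVIST_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
BJELLQVIST_NTERM <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                      V = 7.44, E = 7.7, G = 7.5)
BJELLQVIST_CTERM <- c(D = 4.55, E = 4.75)

#' pKa set for isoelectric-point computation
#'
#' Defaults to the Bjellqvist values used by the ExPASy Compute pI/MW tool,
#' including residue-specific N-terminal (and D/E C-terminal) pKa values.
#' All values must lie in (0, 14).
#'
#' @param positive named numeric: pKa of the positively ionizable groups;
#'   must contain `Nterm` and may contain side chains `K`, `R`, `H`.
#' @param negative named numeric: pKa of the negatively ionizable groups;
#'   must contain `Cterm` and may contain side chains `D`, `E`, `C`, `Y`.
#' @param nterm_by_residue,cterm_by_residue optional residue-specific
#'   terminal pKa overrides.
#' @return a `pka_set` object.
#' @export
pka_set <- function(positive = BJELLQVIST_POSITIVE,
                    negative = BJELLQVIST_NEGATIVE,
                    nterm_by_residue = BJELLQVIST_NTERM,
                    cterm_by_residue = BJELLQVIST_CTERM) {
  vals <- c(positive, negative, nterm_by_residue, cterm_by_residue)
  if (any(vals <= 0 | vals >= 14))
    stop("all pKa values must lie in (0, 14)", call. = FALSE)
  if (!"Nterm" %in% names(positive) || !"Cterm" %in% names(negative))
    stop("positive needs an 'Nterm' entry and negative a 'Cterm' entry",
         call. = FALSE)
  structure(list(positive = positive, negative = negative,
                 nterm_by_residue = nterm_by_residue,
                 cterm_by_residue = cterm_by_residue),
            class = "pka_set")
}

# Net protein charge at a given pH under Henderson-Hasselbalch
net_charge <- function(pH, counts, nterm_pk, cterm_pk, pkas) {
  pos_side <- intersect(names(pkas$positive), names(counts))
  neg_side <- intersect(names(pkas$negative), names(counts))
  pos <- 1 / (1 + 10^(pH - nterm_pk)) +
    sum(counts[pos_side] / (1 + 10^(pH - pkas$positive[pos_side])))
  neg <- 1 / (1 + 10^(cterm_pk - pH)) +
    sum(counts[neg_side] / (1 + 10^(pkas$negative[neg_side] - pH)))
  pos - neg
}

#' Isoelectric point of a protein
#'
#' pH at which the net charge — the Henderson–Hasselbalch sum over the two
#' termini and the ionizable side chains — crosses zero, located by
#' bisection on \[0, 14\]. If the charge does not cross zero inside the
#' interval the boundary value is returned with a warning.
#'
#' @param protein protein sequence over the 20 residues.
#' @param pkas a [pka_set()].
#' @param tol bisection stopping width in pH units.
#' @return pI as full-precision pH (report to 2 decimals).
#' @export
isoelectric_point <- function(protein, pkas = pka_set(), tol = 1e-4) {
  stopifnot(inherits(pkas, "pka_set"))
  s <- check_protein(protein, allow_x = FALSE, what = "protein")
  if (nchar(s) == 0L) stop("empty protein sequence", call. = FALSE)
  ch <- seq_chars(s)
  counts <- table(factor(ch, levels = AA20))
  counts <- setNames(as.numeric(counts), names(counts))
  first <- ch[1]; last <- ch[length(ch)]
  nterm_pk <- if (first %in% names(pkas$nterm_by_residue))
    pkas$nterm_by_residue[[first]] else pkas$positive[["Nterm"]]
  cterm_pk <- if (last %in% names(pkas$cterm_by_residue))
    pkas$cterm_by_residue[[last]] else pkas$negative[["Cterm"]]
  f <- function(pH) net_charge(pH, counts, nterm_pk, cterm_pk, pkas)
  lo <- 0; hi <- 14
  if (f(lo) <= 0) {
    warning("net charge never positive in [0, 14]; returning 0")
    return(0)
  }
  if (f(hi) >= 0) {
    warning("net charge never negative in [0, 14]; returning 14")
    return(14)
  }
  # iterate on interval width and on residual charge: for long chains the
  # charge slope is steep, so a width criterion alone can leave a visible
  # residual at the returned pH
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (hi - lo <= tol && abs(fm) <= 1e-3) break
    if (fm > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-protein (and optionally per-gene) property table
#'
#' @param proteins named character vector of protein sequences.
#' @param gene_dna optional named character vector of nucleotide gene
#'   sequences (same names as `proteins` where available) used for G+C
#'   content.
#' @param masses a [mass_table()].
#' @param pkas a [pka_set()].
#' @return data.frame with `id`, `length_aa`, `mw_kda` (2 dp), `pi` (2 dp)
#'   and, when DNA is supplied, `gc_percent` (full precision) and
#'   `gc_percent_rounded`.
#' @export
protein_properties <- function(proteins, gene_dna = NULL,
                               masses = mass_table(), pkas = pka_set()) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  out <- data.frame(
    id = names(proteins),
    length_aa = nchar(proteins),
    mw_kda = round(vapply(proteins, molecular_weight, numeric(1),
                          masses = masses), 2),
    pi = round(vapply(proteins, isoelectric_point, numeric(1),
                      pkas = pkas), 2),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(gene_dna)) {
    gc <- rep(NA_real_, nrow(out))
    have <- out$id %in% names(gene_dna)
    gc[have] <- vapply(gene_dna[out$id[have]], gc_content, numeric(1))
    out$gc_percent <- gc
    out$gc_percent_rounded <- round(gc)
  }
  out
}
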