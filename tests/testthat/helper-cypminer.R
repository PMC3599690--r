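# Shared test helpers: random sequences, independent brute-force oracles
# for the motif scanners, an exhaustive affine-gap alignment enumerator,
# and random additive trees for neighbor-joining checks.

AA <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

random_protein <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

# --- independent regex-based motif oracles ------------------------------
# gregexpr gives non-overlapping leftmost-first matches, the same overlap
# semantics the scanners document, via an entirely different mechanism.
AA_CLASS <- "[ACDEFGHIKLMNPQRSTVWYX]"

oracle_heme_canonical <- function(seq) {
  m <- gregexpr(paste0("G", AA_CLASS, "{3}C", AA_CLASS, "G"), seq)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

oracle_k_canonical <- function(seq) {
  m <- gregexpr(paste0("E", AA_CLASS, "{2}R"), seq)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

oracle_i_window <- function(seq) {
  m <- gregexpr(paste0("[AGFT]", AA_CLASS, "{2}[TSAIP][TV]"), seq)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

# --- exhaustive affine-gap global alignment score -----------------------
# Plain recursion over all alignment paths, tracking whether the previous
# column opened a gap in either row; gap of length k costs open + k*extend.
brute_force_align_score <- function(a, b, mat, open = 10, extend = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb))
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, 0L))
    if (i <= length(ca)) {  # gap in b
      cost <- if (state == 1L) extend else open + extend
      best <- max(best, -cost + rec(i + 1, j, 1L))
    }
    if (j <= length(cb)) {  # gap in a
      cost <- if (state == 2L) extend else open + extend
      best <- max(best, -cost + rec(i, j + 1, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# --- random additive distance matrices ----------------------------------
# A random binary tree with positive branch lengths; returns its exact
# leaf-to-leaf path-length matrix.
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
  D <- ape::cophenetic.phylo(tr)
  D[order(rownames(D)), order(colnames(D))]
}

# small ready-made gene table builder: roles in order on one contig
gene_table <- function(roles, contig = "c1", strand = NULL) {
  n <- length(roles)
  if (is.null(strand)) strand <- rep("+", n)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), contig = contig,
             start = 1L + (seq_len(n) - 1L) * 1500L,
             end = 1000L + (seq_len(n) - 1L) * 1500L,
             strand = strand, role = roles, stringsAsFactors = FALSE)
}

# tiny synthetic spec for fast whole-layout tests
small_spec <- function(seed = 1L) {
  synthetic_spec(
    rng_seed = seed, n_cyp = 4L, n_background = 20L, protein_length = 200L,
    families = data.frame(family = c("FAMA", "FAMB"), n_members = c(2L, 2L),
                          target_identity = 0.60, stringsAsFactors = FALSE),
    layout_plan = list(c("cyp", "ferredoxin"),
                       c("ferredoxin_reductase", "ferredoxin", "cyp")),
    motif_profiles = list())
}
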