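# Distance-based phylogeny: identity distances, Saitou–Nei neighbor joining,
# Newick serialization.
#
# Distances are defined as 1 - global pairwise identity (see
# percent_identity()); this is a declared choice, not an attribution to any
# particular alignment program. Neighbor joining is implemented from the
# standard Q-criterion recursion; ties in the Q minimisation are broken on
# the lexicographically smallest pair of cluster labels, so the result does
# not depend on input order.

#' Pairwise identity distance matrix
#'
#' `d(i, j) = 1 - percent_identity(global_align(i, j))`, symmetric with a
#' zero diagonal.
#'
#' @param proteins named character vector of at least 3 protein sequences.
#' @param scoring a [scoring_scheme()].
#' @return symmetric numeric matrix with the protein ids as dimnames.
#' @export
distance_matrix <- function(proteins, scoring = scoring_scheme()) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  n <- length(proteins)
  if (n < 3L) stop("need at least 3 sequences for a distance matrix", call. = FALSE)
  if (anyDuplicated(names(proteins)))
    stop("duplicate sequence ids", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n - 1L)) {
    idx <- (i + 1L):n
    ids <- tryCatch(
      identity_many(proteins[[i]], proteins[idx], scoring),
      error = function(e) stop(sprintf("identity undefined for pair (%s, *): %s",
                                       names(proteins)[i], conditionMessage(e)),
                               call. = FALSE))
    D[i, idx] <- 1 - ids
    D[idx, i] <- 1 - ids
  }
  D
}

check_distance_matrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (!all(is.finite(D))) stop("distances must be finite", call. = FALSE)
  if (any(abs(diag(D)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric", call. = FALSE)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration: at each step the pair (i, j) minimising
#' `Q(i, j) = (m - 2) d(i, j) - r_i - r_j` is joined; branch lengths follow
#' the standard formulas and negative lengths are clamped to zero with a
#' warning. The returned tree is unrooted (trifurcating root node) in
#' `ape::phylo` form.
#'
#' @param D symmetric distance matrix (n >= 3) with labeled dimnames, or a
#'   `dist` object.
#' @return an object of class `phylo` (compatible with the ape package).
#' @export
neighbor_joining <- function(D) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  labs <- rownames(D)

  # active clusters: node = subtree (recursive list), label = min leaf label
  active <- lapply(seq_len(n), function(i)
    list(sub = list(tip = i), label = labs[i]))
  W <- D
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(W)
    Q <- (m - 2) * W - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    eps <- 1e-12 * (1 + abs(qmin))
    cand <- which(Q <= qmin + eps, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest sorted label pair
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(active[[ij[1]]]$label, active[[ij[2]]]$label))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]

    dij <- W[i, j]
    bi <- clamp(0.5 * dij + (r[i] - r[j]) / (2 * (m - 2)))
    bj <- clamp(dij - (0.5 * dij + (r[i] - r[j]) / (2 * (m - 2))))
    newsub <- list(children = list(active[[i]]$sub, active[[j]]$sub),
                   lengths = c(bi, bj))
    newlab <- min(active[[i]]$label, active[[j]]$label)

    dk <- 0.5 * (W[i, -c(i, j)] + W[j, -c(i, j)] - dij)
    keep <- setdiff(seq_len(m), c(i, j))
    W <- W[keep, keep, drop = FALSE]
    W <- rbind(cbind(W, dk), c(dk, 0))
    active <- c(active[keep], list(list(sub = newsub, label = newlab)))
  }

  # join the final three clusters at the (trifurcating) root
  if (length(active) == 3L) {
    d12 <- W[1, 2]; d13 <- W[1, 3]; d23 <- W[2, 3]
    b1 <- clamp((d12 + d13 - d23) / 2)
    b2 <- clamp((d12 + d23 - d13) / 2)
    b3 <- clamp((d13 + d23 - d12) / 2)
    root <- list(children = lapply(active, `[[`, "sub"),
                 lengths = c(b1, b2, b3))
  } else stop("internal error: unexpected cluster count")  # nocov
  if (clamped) warning("negative branch length(s) clamped to 0")

  # flatten to ape's edge-matrix representation (root = n + 1, preorder)
  n_internal <- count_internal(root)
  edge <- matrix(0L, 0L, 2L)
  edge_len <- numeric()
  next_internal <- n + 1L
  emit <- function(sub) {
    if (!is.null(sub$tip)) return(sub$tip)
    me <- next_internal
    next_internal <<- next_internal + 1L
    for (k in seq_along(sub$children)) {
      child <- emit(sub$children[[k]])
      edge <<- rbind(edge, c(me, child))
      edge_len <<- c(edge_len, sub$lengths[k])
    }
    me
  }
  # emit() appends child edges after recursion into each child, giving a
  # valid parent-before-child numbering for internal nodes
  edge <- edge; emit_root <- emit(root)
  tree <- list(edge = edge, edge.length = edge_len, tip.label = labs,
               Nnode = n_internal)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

count_internal <- function(sub) {
  if (!is.null(sub$tip)) return(0L)
  1L + sum(vapply(sub$children, count_internal, integer(1)))
}

quote_newick_label <- function(lab) {
  if (grepl("[][ ()':;,]", lab)) {
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  } else lab
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with 6 decimal places; labels containing
#' Newick metacharacters are single-quoted per the standard (embedded quotes
#' doubled).
#'
#' @param tree a `phylo` object (e.g. from [neighbor_joining()]).
#' @param file optional path; when given the Newick string is also written
#'   there (single line plus newline).
#' @param digits decimal places for branch lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- paste0("%.", digits, "f")
  rec <- function(node) {
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2]
      paste0(rec(child), ":", sprintf(fmt, tree$edge.length[r]))
    }, character(1))
    if (node <= ntip) quote_newick_label(tree$tip.label[node])
    else paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(rec(root), ";")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
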