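# Gene-neighborhood context: co-localization of CYP genes with
# electron-transfer partners (ferredoxin, ferredoxin reductase),
# ATP/GTP-binding proteins and transcriptional regulators.
#
# Adjacency is measured in gene ranks (counts of intervening genes), not
# base pairs: published neighborhood reports are qualitative ("adjacent to",
# "lies next to"), so a rank window (default 2) is the faithful primitive.
# Strand is recorded (same_strand flag) but never required to match, and no
# operon inference is attempted — these are co-localization reports only.

ROLE_FIXED <- c("cyp", "ferredoxin", "ferredoxin_reductase", "atp_gtp_binding")

role_ok <- function(role) {
  role %in% ROLE_FIXED | grepl("^regulator:.+$", role) | grepl("^other:.+$", role)
}

check_genes <- function(genes) {
  need <- c("gene_id", "contig", "start", "end", "strand", "role")
  if (!is.data.frame(genes) || !all(need %in% names(genes)))
    stop("genes must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(genes$start > genes$end))
    stop("gene with start > end: ",
         genes$gene_id[which(genes$start > genes$end)[1]], call. = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids", call. = FALSE)
  bad <- which(!role_ok(genes$role))
  if (length(bad))
    stop("unknown role label '", genes$role[bad[1]], "' for gene ",
         genes$gene_id[bad[1]], call. = FALSE)
  genes
}

# TRUE where role matches a filter entry; filters may be exact roles,
# "regulator:*" / "other:*" wildcards, or the bare prefixes "regulator" /
# "other" (equivalent to the wildcard).
role_matches <- function(roles, filter) {
  hit <- rep(FALSE, length(roles))
  for (f in filter) {
    if (f %in% c("regulator", "regulator:*")) hit <- hit | grepl("^regulator:", roles)
    else if (f %in% c("other", "other:*")) hit <- hit | grepl("^other:", roles)
    else hit <- hit | roles == f
  }
  hit
}

check_role_filter <- function(filter) {
  ok <- filter %in% c(ROLE_FIXED, "regulator", "regulator:*", "other", "other:*") |
    grepl("^regulator:.+$", filter) | grepl("^other:.+$", filter)
  if (!all(ok))
    stop("unknown role in filter: ", filter[!ok][1], call. = FALSE)
  filter
}

# genes of one contig in rank order (by start, ties by id), with rank index
rank_genes <- function(genes, contig) {
  g <- genes[genes$contig == contig, , drop = FALSE]
  g <- g[order(g$start, g$gene_id), , drop = FALSE]
  g$rank <- seq_len(nrow(g))
  g
}

#' Genes within a rank window of a focal gene
#'
#' @param gene_id focal gene identifier.
#' @param genes gene table: data.frame with columns `gene_id`, `contig`,
#'   `start`, `end`, `strand`, `role` (1-based inclusive coordinates).
#' @param window number of genes on each side (>= 1).
#' @return data.frame of neighbor genes on the same contig with extra
#'   columns `rank_offset` (signed) and `same_strand` (NA when either strand
#'   is "."), ordered by offset.
#' @export
neighborhood <- function(gene_id, genes, window = 2) {
  genes <- check_genes(genes)
  stopifnot(window >= 1)
  row <- genes[genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(row)) stop("gene not found: ", gene_id, call. = FALSE)
  g <- rank_genes(genes, row$contig[1])
  r0 <- g$rank[g$gene_id == gene_id]
  nb <- g[abs(g$rank - r0) <= window & g$rank != r0, , drop = FALSE]
  nb$rank_offset <- nb$rank - r0
  s0 <- row$strand[1]
  nb$same_strand <- ifelse(s0 %in% c("+", "-") & nb$strand %in% c("+", "-"),
                           nb$strand == s0, NA)
  nb <- nb[order(nb$rank_offset), , drop = FALSE]
  rownames(nb) <- NULL
  nb
}

# One tidy report block for a cyp gene and its matched partners.
cluster_rows <- function(cyp_id, partners, cluster_type) {
  data.frame(cyp_gene = cyp_id,
             partner_gene = partners$gene_id, partner_role = partners$role,
             rank_offset = partners$rank_offset,
             same_strand = partners$same_strand,
             cluster_type = cluster_type, stringsAsFactors = FALSE)
}

empty_clusters <- function() {
  data.frame(cyp_gene = character(), partner_gene = character(),
             partner_role = character(), rank_offset = integer(),
             same_strand = logical(), cluster_type = character(),
             stringsAsFactors = FALSE)
}

# Exclusive cluster type from the set of partner role categories present.
type_from_categories <- function(has_fd, has_fr, has_atp, has_reg) {
  redox <- has_fd || has_fr
  if (redox && !has_atp && !has_reg) {
    if (has_fd && has_fr) "ferredoxin_plus_reductase" else "ferredoxin_only"
  } else if (has_atp && !redox && !has_reg) {
    "atp_gtp"
  } else if (has_reg && !redox && !has_atp) {
    "regulator"
  } else "mixed"
}

#' Redox-partner clusters around CYP genes
#'
#' Reports every gene with role `cyp` that has at least one ferredoxin or
#' ferredoxin reductase within the rank window. `cluster_type` is
#' `ferredoxin_plus_reductase` when both partner kinds are present, else
#' `ferredoxin_only` (a reductase-only neighborhood also reports as
#' `ferredoxin_only`, with the reductase visible in `partner_role`).
#'
#' @inheritParams neighborhood
#' @return data.frame with one row per (cyp, partner) pair: `cyp_gene`,
#'   `partner_gene`, `partner_role`, `rank_offset`, `same_strand`,
#'   `cluster_type`.
#' @export
find_redox_clusters <- function(genes, window = 2) {
  genes <- check_genes(genes)
  out <- list()
  for (cyp in genes$gene_id[genes$role == "cyp"]) {
    nb <- neighborhood(cyp, genes, window)
    p <- nb[nb$role %in% c("ferredoxin", "ferredoxin_reductase"), , drop = FALSE]
    if (!nrow(p)) next
    type <- if (all(c("ferredoxin", "ferredoxin_reductase") %in% p$role))
      "ferredoxin_plus_reductase" else "ferredoxin_only"
    out[[cyp]] <- cluster_rows(cyp, p, type)
  }
  if (length(out)) {
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  } else empty_clusters()
}

#' Functional-neighbor clusters around CYP genes, by role filter
#'
#' Like [find_redox_clusters()] but for an arbitrary role filter, e.g.
#' `"atp_gtp_binding"`, `"regulator:*"` (any regulator family),
#' `"regulator:LuxR"`, or `"other:alcohol_dehydrogenase"`. `cluster_type`
#' summarises the matched partner categories: `atp_gtp`, `regulator`,
#' `ferredoxin_only`, `ferredoxin_plus_reductase`, `mixed`, or `other` when
#' only free-text `other:` partners matched.
#'
#' @inheritParams neighborhood
#' @param roles character vector of role filters (see above). Unknown role
#'   names raise a configuration error.
#' @return data.frame as in [find_redox_clusters()].
#' @export
find_functional_neighbors <- function(genes, window = 2, roles) {
  genes <- check_genes(genes)
  check_role_filter(roles)
  out <- list()
  for (cyp in genes$gene_id[genes$role == "cyp"]) {
    nb <- neighborhood(cyp, genes, window)
    p <- nb[role_matches(nb$role, roles), , drop = FALSE]
    if (!nrow(p)) next
    has_fd <- any(p$role == "ferredoxin")
    has_fr <- any(p$role == "ferredoxin_reductase")
    has_atp <- any(p$role == "atp_gtp_binding")
    has_reg <- any(grepl("^regulator:", p$role))
    type <- if (!has_fd && !has_fr && !has_atp && !has_reg) "other"
    else type_from_categories(has_fd, has_fr, has_atp, has_reg)
    out[[cyp]] <- cluster_rows(cyp, p, type)
  }
  if (length(out)) {
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  } else empty_clusters()
}

#' Cluster census over all CYP genes
#'
#' For every `cyp` gene, partners of the four tracked categories
#' (ferredoxin, ferredoxin reductase, ATP/GTP-binding, regulator) within the
#' window are collected and an exclusive cluster type is assigned:
#' `ferredoxin_plus_reductase` (both redox kinds), `ferredoxin_only`,
#' `atp_gtp`, `regulator`, or `mixed` (categories spanning more than one
#' group). CYPs with no tracked partner are not reported, so the type counts
#' sum to the number of clustered CYPs.
#'
#' @inheritParams neighborhood
#' @return list with `reports` (tidy per-partner table including the
#'   exclusive `cluster_type`) and `counts` (named integer vector over the
#'   five types).
#' @export
cluster_census <- function(genes, window = 2) {
  genes <- check_genes(genes)
  out <- list()
  for (cyp in genes$gene_id[genes$role == "cyp"]) {
    nb <- neighborhood(cyp, genes, window)
    sel <- nb$role %in% c("ferredoxin", "ferredoxin_reductase", "atp_gtp_binding") |
      grepl("^regulator:", nb$role)
    p <- nb[sel, , drop = FALSE]
    if (!nrow(p)) next
    type <- type_from_categories(any(p$role == "ferredoxin"),
                                 any(p$role == "ferredoxin_reductase"),
                                 any(p$role == "atp_gtp_binding"),
                                 any(grepl("^regulator:", p$role)))
    out[[cyp]] <- cluster_rows(cyp, p, type)
  }
  reports <- if (length(out)) {
    r <- do.call(rbind, out); rownames(r) <- NULL; r
  } else empty_clusters()
  types <- c("ferredoxin_only", "ferredoxin_plus_reductase", "atp_gtp",
             "regulator", "mixed")
  per_cyp <- unique(reports[, c("cyp_gene", "cluster_type")])
  counts <- vapply(types, function(t) sum(per_cyp$cluster_type == t), integer(1))
  list(reports = reports, counts = counts)
}
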