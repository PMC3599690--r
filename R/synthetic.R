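# Synthetic proteomes, reference panels and gene layouts with known ground
# truth: implanted signature motifs, families at controlled pairwise
# identity, and planned gene neighborhoods. Everything is driven by one RNG
# seed, so identical specifications give byte-identical outputs.
#
# Background residues are drawn uniformly from the 20 amino acids, with two
# rejection rules that keep the ground truth exact: no accidental canonical
# heme pocket anywhere, and no accidental canonical I-/K-window overlapping
# an implanted span (which could otherwise shadow an implant under the
# leftmost-first overlap rule). No biological realism is claimed for the
# substitution process.

CANONICAL_I_VARIANTS <- c("GHETT", "GFDTT", "GLDTT", "GVETT", "GHKTT")
CANONICAL_K_VARIANTS <- c("ELLR", "ETLR", "EMLR", "ESLR")

MOTIF_SPAN <- c(I_helix = 5L, K_helix = 4L, heme = 7L)

# vectorised detectors; return start positions
starts_heme_canonical <- function(ch) {
  n <- length(ch)
  if (n < 7L) return(integer())
  i <- seq_len(n - 6L)
  i[ch[i] == "G" & ch[i + 4L] == "C" & ch[i + 6L] == "G"]
}
starts_i_window <- function(ch) {
  n <- length(ch)
  if (n < 5L) return(integer())
  i <- seq_len(n - 4L)
  i[ch[i] %in% I_HELIX_POS1 & ch[i + 3L] %in% I_HELIX_POS4 &
      ch[i + 4L] %in% I_HELIX_POS5]
}
starts_k_canonical <- function(ch) {
  n <- length(ch)
  if (n < 4L) return(integer())
  i <- seq_len(n - 3L)
  i[ch[i] == "E" & ch[i + 3L] == "R"]
}

spans_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# windows that must not exist: any canonical heme pocket away from the
# heme implant and, in motif-carrying proteins, any accidental I-window or
# canonical K match away from its implant (so implants are the only
# signature matches and ground-truth positions are exactly recoverable)
unwanted_windows <- function(ch, truth) {
  bad <- list()
  t_of <- function(kind) truth[truth$kind == kind, , drop = FALSE]
  th <- t_of("heme"); ti <- t_of("I_helix"); tk <- t_of("K_helix")
  for (s in starts_heme_canonical(ch)) {
    if (!nrow(th) || s != th$start[1])
      bad[[length(bad) + 1L]] <- c(s, s + 6L)
  }
  if (nrow(truth)) {
    for (s in starts_i_window(ch)) {
      if (nrow(ti) && s == ti$start[1]) next
      bad[[length(bad) + 1L]] <- c(s, s + 4L)
    }
    for (s in starts_k_canonical(ch)) {
      if (nrow(tk) && s == tk$start[1]) next
      bad[[length(bad) + 1L]] <- c(s, s + 3L)
    }
  }
  bad
}

in_any_span <- function(pos, truth) {
  if (!nrow(truth)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= truth$start & p <= truth$end), logical(1))
}

# pattern-determining offsets within a violating window (the conserved /
# residue-class positions; wildcard positions can never break a match)
critical_positions <- function(w) {
  len <- w[2] - w[1] + 1L
  off <- switch(as.character(len),
                "7" = c(0L, 4L, 6L),   # heme G...C.G
                "5" = c(0L, 3L, 4L),   # I-helix class window
                "4" = c(0L, 3L),       # K-helix E..R
                seq_len(len) - 1L)
  w[1] + off
}

# resample residues (uniformly) at free pattern-critical positions of
# violating windows until no unwanted pattern remains
scrub_patterns <- function(ch, truth, editable = NULL, max_iter = 200L) {
  for (it in seq_len(max_iter)) {
    bad <- unwanted_windows(ch, truth)
    if (!length(bad)) return(ch)
    for (w in bad) {
      pos <- critical_positions(w)
      pos <- pos[!in_any_span(pos, truth)]
      if (!is.null(editable)) pos <- pos[pos %in% editable]
      if (!length(pos)) {       # fall back to any free window position
        pos <- (w[1]:w[2])[!in_any_span(w[1]:w[2], truth)]
        if (!is.null(editable)) pos <- pos[pos %in% editable]
      }
      if (!length(pos)) next
      p <- pos[[1L]]
      ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
    }
  }
  stop("could not scrub accidental motif matches", call. = FALSE)  # nocov
}

#' Generate a synthetic CYP protein with implanted signature motifs
#'
#' Implants the requested motifs (canonical variants) at realistic relative
#' positions — I-helix near 55% of the chain, K-helix near 68%, heme pocket
#' in the C-terminal third — with small random jitter, on a uniform random
#' background. The background is rejection-resampled so that the implants
#' are the only signature matches: no accidental canonical heme pocket
#' exists anywhere, and no accidental canonical I/K window overlaps an
#' implanted span.
#'
#' @param length protein length in residues (>= 60).
#' @param profile character subset of `c("I_helix", "K_helix", "heme")`:
#'   which motifs to implant.
#' @param seed optional integer; when given, output is a pure function of it.
#' @return a single character sequence with attribute `motif_truth`, a
#'   data.frame of implanted spans (`kind`, `start`, `end`, `matched`).
#' @export
generate_cyp_protein <- function(length, profile = MOTIF_KINDS, seed = NULL) {
  stopifnot(all(profile %in% MOTIF_KINDS))
  L <- as.integer(length)
  if (L < 60L) stop("length too short to host signature motifs (need >= 60)",
                    call. = FALSE)
  with_seed(seed, {
    jit <- function(x) x + sample(-3L:3L, 1L)
    i_start <- max(6L, jit(round(0.55 * L)))
    k_start <- max(i_start + 6L, jit(round(0.68 * L)))
    heme_start <- max(k_start + 5L, as.integer(ceiling(2 * L / 3)),
                      jit(round(0.85 * L)))
    if (heme_start + 6L > L)
      stop("length too short to host signature motifs in order", call. = FALSE)

    wild <- function(k) sample(setdiff(AA20, c("C", "G")), k, replace = TRUE)
    motifs <- list(
      I_helix = list(start = i_start, str = sample(CANONICAL_I_VARIANTS, 1L)),
      K_helix = list(start = k_start, str = sample(CANONICAL_K_VARIANTS, 1L)),
      heme = list(start = heme_start,
                  str = paste0(c("G", wild(3L), "C", wild(1L), "G"),
                               collapse = "")))

    ch <- sample(AA20, L, replace = TRUE)
    rows <- list()
    for (kind in MOTIF_KINDS) {
      if (!(kind %in% profile)) next
      m <- motifs[[kind]]
      span <- m$start:(m$start + nchar(m$str) - 1L)
      ch[span] <- seq_chars(m$str)
      rows[[kind]] <- data.frame(kind = kind, start = m$start,
                                 end = m$start + nchar(m$str) - 1L,
                                 matched = m$str, stringsAsFactors = FALSE)
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(kind = character(), start = integer(), end = integer(),
                 matched = character(), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    ch <- scrub_patterns(ch, truth)
    out <- paste(ch, collapse = "")
    attr(out, "motif_truth") <- truth
    out
  })
}

#' Generate a motif-free background protein
#'
#' Uniform random sequence with accidental canonical heme pockets
#' rejection-resampled away, so strict-mode scans never call it.
#'
#' @inheritParams generate_cyp_protein
#' @export
generate_background_protein <- function(length, seed = NULL) {
  generate_cyp_protein(length, profile = character(0), seed = seed)
}

#' Mutate a sequence to a target pairwise identity
#'
#' Ungapped point substitutions at uniformly chosen unprotected sites;
#' implanted motif spans (from the `motif_truth` attribute, or an explicit
#' `protected` vector of positions) are never touched. The number of
#' substitutions is tuned in a short search so that the identity measured by
#' [percent_identity()] on a [global_align()] of seed and mutant lands
#' within `tol` of the target.
#'
#' @param seed_seq the seed protein (ideally from [generate_cyp_protein()]).
#' @param target_identity fraction in (0, 1].
#' @param seed optional RNG seed for reproducibility.
#' @param protected optional integer positions that must not mutate
#'   (defaults to the seed's implanted motif spans).
#' @param scoring a [scoring_scheme()] used for the identity measurement.
#' @param tol acceptable |realized - target| (default 0.03).
#' @return mutant sequence (same length, same `motif_truth` attribute).
#' @export
mutate_to_identity <- function(seed_seq, target_identity, seed = NULL,
                               protected = NULL, scoring = scoring_scheme(),
                               tol = 0.03) {
  if (!(target_identity > 0 && target_identity <= 1))
    stop("target_identity must be in (0, 1]", call. = FALSE)
  s <- check_protein(seed_seq)
  truth <- attr(seed_seq, "motif_truth")
  if (is.null(truth))
    truth <- data.frame(kind = character(), start = integer(),
                        end = integer(), matched = character(),
                        stringsAsFactors = FALSE)
  n <- nchar(s)
  ch0 <- seq_chars(s)
  if (is.null(protected)) {
    protected <- unlist(lapply(seq_len(nrow(truth)),
                               function(r) truth$start[r]:truth$end[r]))
  }
  free <- setdiff(seq_len(n), protected)
  if (target_identity == 1) return(seed_seq)

  with_seed(seed, {
    perm <- if (length(free) > 1L) sample(free) else free
    repl <- vapply(perm, function(p) sample(setdiff(AA20, ch0[p]), 1L),
                   character(1))

    apply_k <- function(k) {
      ch <- ch0
      if (k > 0L) ch[perm[seq_len(k)]] <- repl[seq_len(k)]
      # deterministic scrub restricted to mutated sites
      edit <- perm[seq_len(k)]
      for (it in 1:50) {
        bad <- unwanted_windows(ch, truth)
        if (!length(bad)) break
        fixed_any <- FALSE
        for (w in bad) {
          pos <- intersect(critical_positions(w), edit)
          if (!length(pos)) pos <- intersect(w[1]:w[2], edit)
          if (!length(pos)) next
          p <- pos[1]
          alt <- setdiff(AA20, c(ch[p], ch0[p]))
          ch[p] <- alt[1L + (it - 1L) %% length(alt)]
          fixed_any <- TRUE
        }
        if (!fixed_any) break
      }
      ch
    }
    measure <- function(ch)
      identity_many(s, paste(ch, collapse = ""), scoring)

    k <- min(length(perm), max(0L, round((1 - target_identity) * n)))
    lo <- 0L; hi <- length(perm)
    best_ch <- NULL; best_err <- Inf; best_pid <- NA_real_
    for (iter in 1:15) {
      ch <- apply_k(k)
      pid <- measure(ch)
      err <- abs(pid - target_identity)
      if (err < best_err) { best_err <- err; best_ch <- ch; best_pid <- pid }
      if (err <= min(0.02, tol)) break
      if (pid > target_identity) lo <- k + 1L else hi <- k - 1L
      if (lo > hi) break
      k_lin <- if (pid < 1) round(k * (1 - target_identity) / (1 - pid)) else k + 10L
      k <- min(max(k_lin, lo), hi)
    }
    if (best_err > tol) {
      if (best_pid > target_identity)
        stop(sprintf(paste0("target identity %.2f not reachable: protected ",
                            "positions floor realized identity at %.2f"),
                     target_identity, best_pid), call. = FALSE)
      stop(sprintf("could not calibrate identity to %.2f (best %.2f)",
                   target_identity, best_pid), call. = FALSE)
    }
    out <- paste(best_ch, collapse = "")
    attr(out, "motif_truth") <- truth
    out
  })
}

#' Default synthetic family structure
#'
#' Thirteen named families plus one new-family singleton, with member counts
#' patterned on a streptomycete CYPome census (5 + 11 + 1 + 1 + 1 + 1 + 1 +
#' 2 + 1 + 3 + 4 + 1 + 1 = 33) and 0.60 within-family identity.
#'
#' @return data.frame with columns `family`, `n_members`, `target_identity`.
#' @export
default_families <- function() {
  data.frame(
    family = c("CYP105", "CYP107", "CYP121", "CYP124", "CYP147", "CYP152",
               "CYP154", "CYP157", "CYP185", "CYP191", "CYP197", "CYP247",
               "CYPNEW"),
    n_members = c(5L, 11L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 3L, 4L, 1L, 1L),
    target_identity = 0.60,
    stringsAsFactors = FALSE)
}

#' Default neighborhood layout plan
#'
#' Templates are character vectors of role labels in gene order; the string
#' `"cyp"` marks the CYP slot and is filled with generated CYP ids in order.
#' Templates without a `"cyp"` place standalone partner genes. The default
#' mirrors a streptomycete census: 3 ferredoxin-only neighborhoods, 1
#' ferredoxin + reductase, 3 ATP/GTP-binding, 4 regulator (LysR, LuxR, AraC,
#' TetR), 1 mixed (ATP-binding + regulator), 4 other functional genes, and
#' standalone partners bringing the totals to 7 ferredoxins and 3
#' reductases. CYPs not referenced by a template are placed in isolation.
#'
#' @return list of character templates.
#' @export
default_layout_plan <- function() {
  c(
    rep(list(c("cyp", "ferredoxin")), 3),
    list(c("ferredoxin_reductase", "ferredoxin", "cyp")),
    rep(list(c("cyp", "atp_gtp_binding")), 3),
    list(c("cyp", "regulator:LysR"), c("cyp", "regulator:LuxR"),
         c("cyp", "regulator:AraC"), c("cyp", "regulator:TetR"),
         c("cyp", "atp_gtp_binding", "regulator:TetR"),
         c("cyp", "other:alcohol_dehydrogenase"), c("cyp", "other:dioxygenase"),
         c("cyp", "other:mbth_like"), c("cyp", "other:abc_transporter")),
    rep(list("ferredoxin"), 3),
    rep(list("ferredoxin_reductase"), 2))
}

#' Default per-family motif profiles
#'
#' Every family carries all three motifs except two singletons that emulate
#' documented exceptions: the new-family singleton lacks the I-helix and one
#' other singleton lacks the K-helix. Both keep the heme pocket plus one
#' partner motif, so all synthetic CYPs satisfy the candidacy rule.
#'
#' @return named list: family -> character subset of the motif kinds.
#' @export
default_motif_profiles <- function() {
  list(CYPNEW = c("K_helix", "heme"),
       CYP121 = c("I_helix", "heme"))
}

#' Specification for a synthetic genome
#'
#' @param rng_seed integer; fully determines the generated data.
#' @param n_cyp number of CYP proteins (must equal the family member total).
#' @param n_background number of motif-free filler genes.
#' @param protein_length residues per protein (default 400).
#' @param families data.frame as [default_families()].
#' @param layout_plan list of templates as [default_layout_plan()].
#' @param motif_profiles named list as [default_motif_profiles()]; families
#'   not listed carry all three motifs.
#' @return a validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(rng_seed = 1L, n_cyp = 33L, n_background = 244L,
                           protein_length = 400L,
                           families = default_families(),
                           layout_plan = default_layout_plan(),
                           motif_profiles = default_motif_profiles()) {
  stopifnot(is.data.frame(families),
            all(c("family", "n_members", "target_identity") %in% names(families)))
  if (sum(families$n_members) != n_cyp)
    stop("n_cyp must equal the sum of family member counts", call. = FALSE)
  if (!all(families$target_identity > 0 & families$target_identity <= 1))
    stop("target_identity must be in (0, 1]", call. = FALSE)
  n_slots <- sum(vapply(layout_plan, function(t) sum(t == "cyp"), integer(1)))
  if (n_slots > n_cyp)
    stop("layout plan references more CYPs than generated", call. = FALSE)
  bad_roles <- unlist(layout_plan)
  bad_roles <- bad_roles[!role_ok(bad_roles)]
  if (length(bad_roles))
    stop("unknown role in layout plan: ", bad_roles[1], call. = FALSE)
  structure(list(rng_seed = as.integer(rng_seed), n_cyp = as.integer(n_cyp),
                 n_background = as.integer(n_background),
                 protein_length = as.integer(protein_length),
                 families = families, layout_plan = layout_plan,
                 motif_profiles = motif_profiles),
            class = "synthetic_spec")
}

#' Generate a synthetic annotated genome with ground truth
#'
#' Produces, deterministically from `spec$rng_seed`:
#' * one family "ancestor" CYP and per-family seed sequences (full-profile
#'   seeds are ancestor mutants retaining ~48% identity, giving ~25%
#'   identity between families; exception-profile singletons are generated
#'   fresh),
#' * family members mutated to the family's target identity with motif
#'   spans protected,
#' * a labeled reference panel (one seed per family),
#' * motif-free proteins for every partner and filler gene,
#' * a single-contig gene layout realising the neighborhood templates with
#'   filler genes spread evenly between blocks (fixed 50 bp intergenic
#'   gaps, mixed strands, 1-based inclusive coordinates),
#' * contig DNA at streptomycete-like ~70% G+C,
#' * ground-truth tables for motifs, families and planned clusters.
#'
#' @param spec a [synthetic_spec()].
#' @return a `cyp_layout` list: `genes`, `proteins`, `panel`, `contig`,
#'   `truth` (list of `motifs`, `families`, `clusters`), `spec`.
#' @export
generate_genome_layout <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$protein_length
  with_seed(spec$rng_seed, {
    ancestor <- generate_cyp_protein(L, MOTIF_KINDS)
    full <- sort(MOTIF_KINDS)

    cyp_ids <- sprintf("cyp%03d", seq_len(spec$n_cyp))
    fam_of <- rep(spec$families$family, spec$families$n_members)
    tid_of <- rep(spec$families$target_identity, spec$families$n_members)

    panel_seqs <- character(); panel_fams <- character()
    proteins <- character(); truth_motifs <- list()
    seeds <- list()
    for (r in seq_len(nrow(spec$families))) {
      fam <- spec$families$family[r]
      prof <- spec$motif_profiles[[fam]]
      if (is.null(prof)) prof <- MOTIF_KINDS
      seeds[[fam]] <- if (identical(sort(prof), full))
        mutate_to_identity(ancestor, 0.48) else generate_cyp_protein(L, prof)
      panel_seqs[paste0(fam, "_ref")] <- as.character(seeds[[fam]])
      panel_fams <- c(panel_fams, fam)
    }
    for (i in seq_len(spec$n_cyp)) {
      fam <- fam_of[i]
      mem <- mutate_to_identity(seeds[[fam]], tid_of[i])
      proteins[cyp_ids[i]] <- as.character(mem)
      tm <- attr(mem, "motif_truth")
      if (nrow(tm)) truth_motifs[[cyp_ids[i]]] <- cbind(protein_id = cyp_ids[i], tm)
    }
    panel <- reference_panel(panel_seqs, panel_fams)

    # realise the layout plan as ordered blocks of (role, id)
    plan <- spec$layout_plan
    n_slots <- sum(vapply(plan, function(t) sum(t == "cyp"), integer(1)))
    plan <- c(plan, rep(list("cyp"), spec$n_cyp - n_slots))
    counters <- new.env()
    next_id <- function(prefix) {
      k <- (get0(prefix, envir = counters, ifnotfound = 0L)) + 1L
      assign(prefix, k, envir = counters)
      sprintf("%s%03d", prefix, k)
    }
    role_prefix <- function(role) {
      if (role == "ferredoxin") "fd"
      else if (role == "ferredoxin_reductase") "fr"
      else if (role == "atp_gtp_binding") "atp"
      else if (grepl("^regulator:", role)) "reg"
      else "oth"
    }
    cyp_cursor <- 0L
    blocks <- lapply(plan, function(tmpl) {
      ids <- character(length(tmpl))
      for (k in seq_along(tmpl)) {
        if (tmpl[k] == "cyp") {
          cyp_cursor <<- cyp_cursor + 1L
          ids[k] <- cyp_ids[cyp_cursor]
        } else ids[k] <- next_id(role_prefix(tmpl[k]))
      }
      data.frame(gene_id = ids, role = tmpl, stringsAsFactors = FALSE)
    })

    # planned-cluster ground truth, from template roles
    truth_clusters <- list()
    for (b in blocks) {
      if (!any(b$role == "cyp") || nrow(b) < 2L) next
      cyp <- b$gene_id[b$role == "cyp"][1]
      partners <- b[b$role != "cyp", , drop = FALSE]
      type <- type_from_categories(any(partners$role == "ferredoxin"),
                                   any(partners$role == "ferredoxin_reductase"),
                                   any(partners$role == "atp_gtp_binding"),
                                   any(grepl("^regulator:", partners$role)))
      if (all(grepl("^other:", partners$role))) type <- "other"
      truth_clusters[[cyp]] <- data.frame(
        cyp_gene = cyp, cluster_type = type,
        partner_roles = paste(partners$role, collapse = ","),
        stringsAsFactors = FALSE)
    }

    # interleave filler genes evenly between blocks
    nb <- spec$n_background
    nblk <- length(blocks)
    filler_per_gap <- diff(floor(seq(0, nb, length.out = nblk + 2L)))
    order_rows <- list()
    emit_filler <- function(k) {
      if (k <= 0L) return(NULL)
      data.frame(gene_id = vapply(seq_len(k), function(i) next_id("bg"),
                                  character(1)),
                 role = "other:hypothetical", stringsAsFactors = FALSE)
    }
    order_rows[[1]] <- emit_filler(filler_per_gap[1])
    for (b in seq_len(nblk)) {
      order_rows[[length(order_rows) + 1L]] <- blocks[[b]]
      order_rows[[length(order_rows) + 1L]] <- emit_filler(filler_per_gap[b + 1L])
    }
    layout_tbl <- do.call(rbind, Filter(Negate(is.null), order_rows))

    # coordinates (1-based inclusive), fixed 50 bp gaps, mixed strands
    glen <- 3L * L + 3L
    ngene <- nrow(layout_tbl)
    starts <- 1L + (seq_len(ngene) - 1L) * (glen + 50L)
    genes <- data.frame(gene_id = layout_tbl$gene_id, contig = "contig_1",
                        start = starts, end = starts + glen - 1L,
                        strand = sample(c("+", "-"), ngene, replace = TRUE),
                        role = layout_tbl$role, stringsAsFactors = FALSE)

    # motif-free proteins for every non-CYP gene
    for (id in genes$gene_id[genes$role != "cyp"])
      proteins[id] <- as.character(generate_background_protein(L))
    proteins <- proteins[genes$gene_id]   # genome order

    total_len <- max(genes$end) + 50L
    contig <- paste(sample(c("A", "C", "G", "T"), total_len, replace = TRUE,
                           prob = c(0.15, 0.35, 0.35, 0.15)), collapse = "")

    truth <- list(
      motifs = {
        m <- do.call(rbind, truth_motifs); rownames(m) <- NULL; m
      },
      families = data.frame(protein_id = cyp_ids, family = fam_of,
                            target_identity = tid_of, stringsAsFactors = FALSE),
      clusters = {
        cl <- do.call(rbind, truth_clusters); rownames(cl) <- NULL; cl
      })

    structure(list(genes = genes, proteins = proteins, panel = panel,
                   contig = c(contig_1 = contig), truth = truth, spec = spec),
              class = "cyp_layout")
  })
}

#' Write a synthetic genome layout to disk
#'
#' Emits `proteins.faa`, `genome.fna`, `genes.gff3` (column 3 "gene", with
#' `role=` and, for CYPs, `truth_family=` attributes), the labeled reference
#' panel (`panel.faa`, `panel_labels.tsv`) and ground-truth TSV tables.
#' Output is deterministic: the same layout writes byte-identical files.
#'
#' @param layout a `cyp_layout` from [generate_genome_layout()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_synthetic_genome <- function(layout, dir) {
  stopifnot(inherits(layout, "cyp_layout"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(layout$proteins, p("proteins.faa"), type = "protein")
  write_fasta(layout$contig, p("genome.fna"), type = "dna")
  genes <- layout$genes
  fam <- setNames(layout$truth$families$family, layout$truth$families$protein_id)
  attrs <- ifelse(genes$gene_id %in% names(fam),
                  paste0("truth_family=", fam[genes$gene_id]), NA)
  write_gff3(genes, p("genes.gff3"), extra_attributes = attrs,
             header_lines = sprintf("#!rng_seed %d", layout$spec$rng_seed))
  write_fasta(setNames(layout$panel$seq, layout$panel$id), p("panel.faa"),
              type = "protein")
  write_tsv_plain(data.frame(id = layout$panel$id, family = layout$panel$family),
                  p("panel_labels.tsv"))
  write_tsv_plain(layout$truth$motifs, p("truth_motifs.tsv"))
  write_tsv_plain(layout$truth$families, p("truth_families.tsv"))
  write_tsv_plain(layout$truth$clusters, p("truth_clusters.tsv"))
  invisible(vapply(c("proteins.faa", "genome.fna", "genes.gff3", "panel.faa",
                     "panel_labels.tsv", "truth_motifs.tsv",
                     "truth_families.tsv", "truth_clusters.tsv"), p,
                   character(1)))
}
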