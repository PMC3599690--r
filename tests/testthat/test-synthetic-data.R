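test_that("implanted motifs are found at their recorded positions", {
  p <- generate_cyp_protein(400, seed = 101)
  truth <- attr(p, "motif_truth")
  expect_equal(sort(truth$kind), sort(c("I_helix", "K_helix", "heme")))
  cl <- call_cyp(as.character(p), id = "syn")
  expect_true(cl$candidate)
  hits <- setNames(cl$hits$start, cl$hits$kind)
  for (k in truth$kind)
    expect_equal(unname(hits[k]), truth$start[truth$kind == k])
  # heme implant lies in the C-terminal third
  expect_gte(truth$start[truth$kind == "heme"], ceiling(2 * 400 / 3))
})

test_that("partial motif profiles are reported as missing kinds", {
  no_i <- generate_cyp_protein(400, profile = c("K_helix", "heme"), seed = 7)
  cl <- call_cyp(as.character(no_i), id = "noI")
  expect_true(cl$candidate)
  expect_equal(cl$missing, "I_helix")

  none <- generate_cyp_protein(400, profile = character(0), seed = 7)
  expect_false(call_cyp(as.character(none), id = "none")$candidate)

  expect_error(generate_cyp_protein(40), "too short")
})

test_that("generators are pure functions of their seed", {
  expect_identical(generate_cyp_protein(300, seed = 5),
                   generate_cyp_protein(300, seed = 5))
  s <- generate_cyp_protein(300, seed = 5)
  expect_identical(mutate_to_identity(s, 0.45, seed = 9),
                   mutate_to_identity(s, 0.45, seed = 9))
  expect_false(identical(as.character(mutate_to_identity(s, 0.45, seed = 9)),
                         as.character(mutate_to_identity(s, 0.45, seed = 10))))
})

test_that("mutants hit their identity target", {
  s <- generate_cyp_protein(400, seed = 13)
  expect_identical(mutate_to_identity(s, 1.0, seed = 1), s)
  m <- mutate_to_identity(s, 0.60, seed = 2)
  expect_equal(nchar(m), 400L)                 # ungapped point substitutions
  pid <- percent_identity(global_align(as.character(s), as.character(m)))
  expect_gte(pid, 0.57); expect_lte(pid, 0.63)
  # motif spans are protected
  t0 <- attr(s, "motif_truth")
  for (r in seq_len(nrow(t0)))
    expect_equal(substr(as.character(m), t0$start[r], t0$end[r]), t0$matched[r])
})

test_that("an unreachable identity target raises a parameter error", {
  s <- generate_cyp_protein(80, seed = 3)
  expect_error(
    mutate_to_identity(s, 0.10, seed = 1, protected = seq_len(75)),
    "not reachable")
  expect_error(mutate_to_identity(s, 0), "must be in")
})

test_that("identity calibration error stays within 0.03 on average", {
  s <- generate_cyp_protein(300, seed = 21)
  devs <- vapply(1:20, function(i) {
    m <- mutate_to_identity(s, 0.60, seed = 100 + i)
    abs(percent_identity(global_align(as.character(s), as.character(m))) - 0.60)
  }, numeric(1))
  expect_lte(mean(devs), 0.03)
})

test_that("scan recalls implanted CYPs with zero background false calls", {
  # 20 seeds; canonical implants, default (strict) scanner settings
  for (seed in 1:20) {
    lay <- generate_genome_layout(small_spec(seed))
    calls <- scan_proteome(lay$proteins)
    tbl <- cyp_call_table(calls)
    is_cyp <- tbl$protein_id %in% lay$truth$families$protein_id
    expect_true(all(tbl$candidate[is_cyp]),
                label = sprintf("all implanted CYPs called (seed %d)", seed))
    expect_false(any(tbl$candidate[!is_cyp]),
                 label = sprintf("no background called (seed %d)", seed))
  }
})

test_that("planned neighborhoods are recovered from the layout", {
  lay <- generate_genome_layout(small_spec(2))
  redox <- find_redox_clusters(lay$genes, window = 2)
  truth <- lay$truth$clusters
  expect_equal(sort(unique(redox$cyp_gene)), sort(truth$cyp_gene))
  got <- unique(redox[, c("cyp_gene", "cluster_type")])
  expect_equal(setNames(got$cluster_type, got$cyp_gene)[truth$cyp_gene],
               setNames(truth$cluster_type, truth$cyp_gene))
})

test_that("the same specification writes byte-identical files", {
  d1 <- tempfile("lay1_"); d2 <- tempfile("lay2_")
  f1 <- write_synthetic_genome(generate_genome_layout(small_spec(4)), d1)
  f2 <- write_synthetic_genome(generate_genome_layout(small_spec(4)), d2)
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("specification invariants are validated", {
  expect_error(synthetic_spec(n_cyp = 10), "member counts")
  fam <- data.frame(family = "F", n_members = 2L, target_identity = 1.5)
  expect_error(synthetic_spec(n_cyp = 2, families = fam), "target_identity")
  expect_error(
    synthetic_spec(n_cyp = 33, layout_plan = list(c("cyp", "bogus_role"))),
    "unknown role")
})
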