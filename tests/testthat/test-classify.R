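test_that("identity of an alignment is counted over trimmed columns", {
  aln <- global_align("ACDEFG", "ACDEFG")
  expect_equal(percent_identity(aln), 1.0)
  expect_false(grepl("-", aln$aligned_a))

  aln2 <- structure(list(aligned_a = "ACDEFG", aligned_b = "ACDEYG",
                         score = 0), class = "cyp_alignment")
  expect_equal(percent_identity(aln2), 5 / 6)

  # terminal-gap columns are excluded from the denominator
  aln3 <- structure(list(aligned_a = "AC-DEFG", aligned_b = "-CKDEF-",
                         score = 0), class = "cyp_alignment")
  expect_equal(percent_identity(aln3), 4 / 5)

  aln4 <- structure(list(aligned_a = "AAA---", aligned_b = "---AAA",
                         score = 0), class = "cyp_alignment")
  expect_error(percent_identity(aln4), "undefined")
})

test_that("alignment degapped rows reproduce the inputs and score is symmetric", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      a <- random_protein(sample(10:40, 1))
      b <- random_protein(sample(10:40, 1))
      aln <- global_align(a, b)
      expect_equal(gsub("-", "", aln$aligned_a), a)
      expect_equal(gsub("-", "", aln$aligned_b), b)
      expect_equal(aln$score, global_align(b, a)$score)
      expect_equal(percent_identity(aln),
                   percent_identity(global_align(b, a)))
    }
  })
  expect_error(global_align("", "ACD"), "empty")
})

test_that("alignment scores match exhaustive enumeration for short pairs", {
  sc <- scoring_scheme()
  withr::with_seed(9, {
    for (rep in 1:25) {
      a <- random_protein(sample(2:8, 1))
      b <- random_protein(sample(2:8, 1))
      expect_equal(global_align(a, b, sc)$score,
                   brute_force_align_score(a, b, sc$matrix, sc$gap_open,
                                           sc$gap_extend),
                   tolerance = 1e-9)
    }
  })
})

test_that("family verdicts follow strict more-than threshold semantics", {
  expect_equal(family_verdict(0.40), "new_family")
  expect_equal(family_verdict(0.41), "same_family_new_subfamily")
  expect_equal(family_verdict(0.55), "same_family_new_subfamily")
  expect_equal(family_verdict(0.56), "same_subfamily")
  # monotone: raising identity never moves the verdict toward new_family
  rank <- c(new_family = 1, same_family_new_subfamily = 2, same_subfamily = 3)
  ids <- seq(0.05, 0.95, by = 0.05)
  v <- rank[vapply(ids, family_verdict, character(1))]
  expect_true(all(diff(v) >= 0))
})

test_that("assignment copies the family label from the best named reference", {
  withr::with_seed(13, {
    seed <- generate_cyp_protein(300)
    near <- mutate_to_identity(seed, 0.66)
    far <- random_protein(300)
    panel <- reference_panel(c(refA = as.character(seed), refB = far),
                             families = c("CYP105", "CYP107"))
    a <- assign_family(as.character(near), panel, id = "q1")
    expect_equal(a$best_ref, "refA")
    expect_equal(a$verdict, "same_subfamily")
    expect_equal(a$family, "CYP105")
    expect_equal(a$best_identity, 0.66, tolerance = 0.031)

    # an unlabeled best reference cannot donate a family name
    panel2 <- reference_panel(c(refA = as.character(seed), refB = far),
                              families = c(NA, "CYP107"))
    a2 <- assign_family(as.character(near), panel2, id = "q2")
    expect_equal(a2$verdict, "new_family")
    expect_equal(a2$family, "new")
    expect_match(a2$note, "unlabeled")
  })
  expect_error(assign_family("ACDE", data.frame()), "empty")
})

test_that("synthetic families are perfectly partitioned against one representative each", {
  withr::with_seed(17, {
    for (rep in 1:3) {
      anc <- generate_cyp_protein(250)
      seeds <- lapply(1:3, function(i) mutate_to_identity(anc, 0.48))
      panel <- reference_panel(
        setNames(vapply(seeds, as.character, ""), paste0("fam", 1:3, "_ref")),
        families = paste0("FAM", 1:3))
      queries <- character()
      truth <- character()
      for (f in 1:3) for (m in 1:3) {
        id <- sprintf("q%d_%d", f, m)
        queries[id] <- as.character(mutate_to_identity(seeds[[f]], 0.60))
        truth[id] <- paste0("FAM", f)
      }
      res <- assign_families(queries, panel)
      expect_equal(setNames(res$family, res$query_id), truth)
      expect_true(all(res$verdict == "same_subfamily"))
    }
  })
})
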