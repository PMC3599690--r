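test_that("identity distances are symmetric, zero-diagonal and bounded", {
  withr::with_seed(3, {
    s <- generate_cyp_protein(150)
    prots <- c(a = as.character(s),
               b = as.character(mutate_to_identity(s, 0.7)),
               c = random_protein(150),
               dup = as.character(s))
    D <- distance_matrix(prots)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 4))
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D["a", "dup"], 0)
    expect_true(D["a", "b"] < D["a", "c"])
  })
  expect_error(distance_matrix(c(a = "ACD", b = "ACD")), "at least 3")
})

test_that("three equidistant taxa give a star with equal branches", {
  D <- matrix(2, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tr$edge.length, rep(1, 3))
  expect_equal(write_newick(tr), "(A:1.000000,B:1.000000,C:1.000000);")
})

test_that("an additive four-taxon matrix is reconstructed exactly", {
  # path lengths of the tree ((A:1,B:2):1,(C:3,D:4))
  taxa <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- neighbor_joining(D)
  P <- ape::cophenetic.phylo(tr)[taxa, taxa]
  expect_equal(P, D, tolerance = 1e-12)
  # AB|CD split: A and B are sisters
  mrca_ab <- ape::getMRCA(tr, c("A", "B"))
  expect_false(identical(mrca_ab, ape::getMRCA(tr, c("A", "C"))))
})

test_that("neighbor joining recovers random additive matrices to 1e-9", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- sample(4:12, 1)
      D <- random_additive_matrix(n)
      tr <- neighbor_joining(D)
      P <- ape::cophenetic.phylo(tr)
      P <- P[rownames(D), colnames(D)]
      expect_lt(max(abs(P - D)), 1e-9)
      expect_equal(sort(tr$tip.label), sort(rownames(D)))
    }
  })
})

test_that("taxon order does not change the tree", {
  withr::with_seed(19, {
    D <- random_additive_matrix(8)
    # add mild noise so the matrix is non-additive but untied
    noise <- matrix(runif(64, 0, 0.01), 8, 8)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    D <- D + noise
    t1 <- neighbor_joining(D)
    perm <- sample(8)
    t2 <- neighbor_joining(D[perm, perm])
    expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
    p1 <- ape::cophenetic.phylo(t1); p2 <- ape::cophenetic.phylo(t2)
    expect_equal(p1[rownames(D), rownames(D)], p2[rownames(D), rownames(D)],
                 tolerance = 1e-9)
  })
})

test_that("results agree with an independent neighbor-joining implementation", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- sample(5:10, 1)
      D <- random_additive_matrix(n)
      noise <- matrix(runif(n * n, 0, 0.05), n, n)
      noise <- (noise + t(noise)) / 2; diag(noise) <- 0
      D <- D + noise
      ours <- neighbor_joining(D)
      ref <- ape::nj(D)
      expect_equal(phangorn::RF.dist(ape::unroot(ours), ape::unroot(ref)), 0)
    }
  })
})

test_that("branch lengths are never negative", {
  withr::with_seed(29, {
    for (rep in 1:5) {
      n <- 6
      M <- matrix(runif(n * n, 0.1, 1), n, n)
      D <- (M + t(M)) / 2; diag(D) <- 0
      dimnames(D) <- list(letters[1:n], letters[1:n])
      tr <- suppressWarnings(neighbor_joining(D))
      expect_true(all(tr$edge.length >= 0))
    }
  })
})

test_that("newick output round-trips through an independent parser", {
  withr::with_seed(37, {
    for (rep in 1:8) {
      n <- sample(4:10, 1)
      D <- random_additive_matrix(n)
      tr <- neighbor_joining(D)
      txt <- write_newick(tr)
      back <- ape::read.tree(text = txt)
      expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(back)), 0)
      p1 <- ape::cophenetic.phylo(tr); p2 <- ape::cophenetic.phylo(back)
      expect_equal(p2[rownames(p1), colnames(p1)], p1, tolerance = 1e-5)
    }
  })
})

test_that("labels with metacharacters are quoted", {
  D <- matrix(2, 3, 3); diag(D) <- 0
  dimnames(D) <- list(c("sp. Mg1", "B", "C"), c("sp. Mg1", "B", "C"))
  txt <- write_newick(neighbor_joining(D))
  expect_match(txt, "'sp. Mg1':", fixed = TRUE)
})

test_that("co-family groups are monophyletic in the paralog tree", {
  withr::with_seed(41, {
    for (rep in 1:3) {
      anc <- generate_cyp_protein(200)
      fams <- list()
      prots <- character()
      for (f in 1:3) {
        seed <- mutate_to_identity(anc, 0.48)
        ids <- sprintf("F%d_m%d", f, 1:4)
        for (id in ids)
          prots[id] <- as.character(mutate_to_identity(seed, 0.60))
        fams[[f]] <- ids
      }
      tr <- neighbor_joining(distance_matrix(prots))
      rooted <- ape::root(tr, outgroup = fams[[3]][1], resolve.root = TRUE)
      for (f in 1:2)
        expect_true(ape::is.monophyletic(rooted, fams[[f]]))
    }
  })
})
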