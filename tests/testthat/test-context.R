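test_that("neighborhood returns rank-window genes with boundary handling", {
  g <- gene_table(c("other:a", "cyp", "ferredoxin", "other:b", "regulator:LysR"))
  nb <- neighborhood("g02", g, window = 1)
  expect_equal(nb$gene_id, c("g01", "g03"))
  expect_equal(nb$rank_offset, c(-1L, 1L))

  nb_first <- neighborhood("g01", g, window = 2)
  expect_true(all(nb_first$rank_offset > 0))
  expect_equal(nb_first$gene_id, c("g02", "g03"))

  nb_all <- neighborhood("g03", g, window = 100)
  expect_equal(nrow(nb_all), 4L)
  expect_error(neighborhood("nope", g), "not found")
})

test_that("redox clusters follow the ferredoxin/reductase typing rules", {
  g1 <- gene_table(c("cyp", "ferredoxin"))
  r1 <- find_redox_clusters(g1, window = 1)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$cluster_type, "ferredoxin_only")

  g2 <- gene_table(c("cyp", "other:x", "ferredoxin"))
  expect_equal(nrow(find_redox_clusters(g2, window = 1)), 0L)

  g3 <- gene_table(c("ferredoxin_reductase", "ferredoxin", "cyp"))
  r3 <- find_redox_clusters(g3, window = 2)
  expect_equal(unique(r3$cluster_type), "ferredoxin_plus_reductase")
  expect_equal(sort(r3$partner_role),
               c("ferredoxin", "ferredoxin_reductase"))
})

test_that("functional-neighbor search supports regulator-family filters", {
  g <- gene_table(c("regulator:LuxR", "cyp", "other:x", "cyp", "atp_gtp_binding"))
  reg <- find_functional_neighbors(g, window = 1, roles = "regulator:*")
  expect_equal(reg$cyp_gene, "g02")
  expect_equal(reg$cluster_type, "regulator")

  luxr <- find_functional_neighbors(g, window = 1, roles = "regulator:LuxR")
  expect_equal(nrow(luxr), 1L)
  expect_equal(nrow(find_functional_neighbors(g, window = 1,
                                              roles = "regulator:TetR")), 0L)

  atp <- find_functional_neighbors(g, window = 1, roles = "atp_gtp_binding")
  expect_equal(atp$cyp_gene, "g04")
  expect_equal(atp$cluster_type, "atp_gtp")

  expect_error(find_functional_neighbors(g, roles = "nonsense_role"),
               "unknown role")
})

test_that("census typing is exclusive and counts sum to clustered CYPs", {
  roles <- c("cyp", "ferredoxin", "other:gap1",
             "ferredoxin_reductase", "ferredoxin", "cyp", "other:gap2",
             "cyp", "atp_gtp_binding", "other:gap3",
             "regulator:TetR", "cyp", "other:gap4",
             "cyp", "atp_gtp_binding", "regulator:AraC", "other:gap5",
             "other:gap6", "cyp")
  cen <- cluster_census(gene_table(roles), window = 2)
  expect_equal(unname(cen$counts["ferredoxin_only"]), 1L)
  expect_equal(unname(cen$counts["ferredoxin_plus_reductase"]), 1L)
  expect_equal(unname(cen$counts["atp_gtp"]), 1L)
  expect_equal(unname(cen$counts["regulator"]), 1L)
  expect_equal(unname(cen$counts["mixed"]), 1L)
  expect_equal(sum(cen$counts), length(unique(cen$reports$cyp_gene)))
})

test_that("reversing gene order and strands leaves the census unchanged", {
  withr::with_seed(43, {
    roles <- sample(c("cyp", "ferredoxin", "ferredoxin_reductase",
                      "atp_gtp_binding", "regulator:LysR", "other:x"),
                    40, replace = TRUE)
    g <- gene_table(roles, strand = sample(c("+", "-"), 40, replace = TRUE))
    cen <- cluster_census(g, window = 2)

    L <- max(g$end) + 1L
    rev_g <- g
    rev_g$start <- L - g$end
    rev_g$end <- L - g$start
    rev_g$strand <- ifelse(g$strand == "+", "-", "+")
    cen_rev <- cluster_census(rev_g, window = 2)
    expect_equal(cen_rev$counts, cen$counts)
    expect_equal(sort(unique(cen_rev$reports$cyp_gene)),
                 sort(unique(cen$reports$cyp_gene)))
  })
})

test_that("enlarging the window never removes a reported cluster", {
  withr::with_seed(47, {
    roles <- sample(c("cyp", "ferredoxin", "atp_gtp_binding", "other:x"),
                    30, replace = TRUE)
    g <- gene_table(roles)
    for (w in 1:4) {
      small <- cluster_census(g, window = w)
      big <- cluster_census(g, window = w + 1)
      expect_true(all(unique(small$reports$cyp_gene) %in%
                        unique(big$reports$cyp_gene)))
      expect_true(all(paste(small$reports$cyp_gene, small$reports$partner_gene)
                      %in% paste(big$reports$cyp_gene, big$reports$partner_gene)))
    }
  })
})

test_that("strand '.' yields an undefined same_strand flag", {
  g <- gene_table(c("cyp", "ferredoxin"), strand = c("+", "."))
  r <- find_redox_clusters(g, window = 1)
  expect_true(is.na(r$same_strand))
})
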