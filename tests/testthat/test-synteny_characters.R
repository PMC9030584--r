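test_that("cluster orientation anchors on swnK and is idempotent", {
  lay <- cluster_layout("x", data.frame(
    gene = c("swnK", "swnH2"), contig = "c1",
    start = c(100L, 10000L), end = c(9000L, 11000L),
    strand = c("-", "-")))
  flipped <- orient_cluster(lay)
  expect_equal(flipped$annotations$gene, c("swnH2", "swnK"))
  expect_equal(flipped$annotations$strand, c("+", "+"))

  plus <- cluster_layout("y", data.frame(
    gene = c("swnK", "swnH2"), contig = "c1",
    start = c(100L, 10000L), end = c(9000L, 11000L),
    strand = c("+", "-")))
  expect_identical(orient_cluster(plus), plus)

  set.seed(5)
  for (rep in 1:20) {
    lay <- random_layout(paste0("r", rep))
    once <- orient_cluster(lay)
    expect_identical(orient_cluster(once), once)
  }
})

test_that("adjacency derivation yields n-1 pairs with correct spans", {
  lay <- cluster_layout("ps", data.frame(
    gene = c("swnK", "swnH2", "swnH1", "swnN", "swnR"), contig = "c1",
    start = c(1L, 9001L, 11001L, 13001L, 15001L),
    end = c(8000L, 10000L, 12000L, 14000L, 16000L),
    strand = "+"))
  adj <- derive_adjacencies(lay)
  expect_equal(nrow(adj), 4L)
  pair_key <- paste(pmin(adj$left_gene, adj$right_gene),
                    pmax(adj$left_gene, adj$right_gene))
  expect_setequal(pair_key, c("swnH2 swnK", "swnH1 swnH2",
                              "swnH1 swnN", "swnN swnR"))
  expect_equal(adj$ig_length_nt, c(1000L, 1000L, 1000L, 1000L))

  single <- cluster_layout("s", data.frame(
    gene = "swnK", contig = "c", start = 1L, end = 100L, strand = "+"))
  expect_equal(nrow(derive_adjacencies(single)), 0L)

  # overlap: left gene ends after right gene starts
  ov <- cluster_layout("o", data.frame(
    gene = c("swnK", "swnR"), contig = "c",
    start = c(1L, 90L), end = c(100L, 200L), strand = "+"))
  a <- derive_adjacencies(ov)
  expect_true(a$overlap)
  expect_equal(a$ig_length_nt, 0L)

  set.seed(6)
  for (rep in 1:20) {
    lay <- orient_cluster(random_layout(paste0("p", rep)))
    adj <- derive_adjacencies(lay)
    n <- nrow(lay$annotations)
    expect_equal(nrow(adj), n - 1L)
    counts <- table(c(adj$left_gene, adj$right_gene))
    inner <- lay$annotations$gene[-c(1L, n)]
    expect_true(all(counts[inner] == 2L))
    expect_true(all(counts[lay$annotations$gene[c(1L, n)]] == 1L))
  }
})

test_that("orientation typing matches canonical order and is an involution", {
  adj <- data.frame(taxon = "x", left_gene = "swnH2", right_gene = "swnK",
                    ig_start = 1L, ig_end = 10L, ig_length_nt = 10L,
                    overlap = FALSE)
  cl <- classify_orientation(adj)
  expect_equal(cl$adjacencies$character_id, 0L)
  expect_equal(cl$adjacencies$orientation, "A")
  rev <- adj
  rev[c("left_gene", "right_gene")] <- rev[c("right_gene", "left_gene")]
  expect_equal(classify_orientation(rev)$adjacencies$orientation, "B")

  set.seed(9)
  for (rep in 1:30) {
    pair <- sample(swn_genes(), 2L)
    a <- data.frame(taxon = "t", left_gene = pair[1L], right_gene = pair[2L],
                    ig_start = 1L, ig_end = 5L, ig_length_nt = 5L,
                    overlap = FALSE)
    b <- a
    b[c("left_gene", "right_gene")] <- b[c("right_gene", "left_gene")]
    ca <- classify_orientation(a)
    cb <- classify_orientation(b, definitions = ca$definitions)
    expect_false(ca$adjacencies$orientation == cb$adjacencies$orientation)
    expect_equal(ca$adjacencies$character_id, cb$adjacencies$character_id)
  }
})

test_that("novel pairs register fresh ids and non-SWN pairs are skipped", {
  adj <- data.frame(taxon = "x",
                    left_gene = c("swnK", "hypo1"),
                    right_gene = c("swnN", "swnK"),
                    ig_start = 1L, ig_end = 5L, ig_length_nt = 5L,
                    overlap = FALSE)
  cl <- classify_orientation(adj)
  expect_equal(nrow(cl$adjacencies), 1L)
  expect_gte(cl$adjacencies$character_id, 13L)
  expect_equal(cl$adjacencies$orientation, "A")
  expect_equal(attr(cl, "report")$pair, "hypo1-swnK")
})

test_that("cluster typing distinguishes pure and mixed orientation", {
  expect_equal(classify_cluster_type(c("A", "A")), "A")
  expect_equal(classify_cluster_type(c("B")), "B")
  expect_equal(classify_cluster_type(c("A", "B", "A")), "A/B")
  expect_error(classify_cluster_type(character()), "no adjacencies")
})

test_that("fixture matrix reproduces the printed organism types and sharing", {
  t2 <- load_table2_fixture()
  m <- build_character_matrix(t2)
  expect_equal(dim(m), c(14L, 13L))
  expect_equal(unname(m$taxon_type[names(t2$taxon_type)]),
               unname(t2$taxon_type))
  expect_equal(sum(m$presence[, "c0"]), 13L)
  expect_false(m$presence["Clohesyomyces aquaticus", "c0"])
  expect_equal(rownames(m$presence)[m$presence[, "c12"]],
               "Periconia macrospinosa")
  s <- character_summary(m)
  expect_equal(s$partner_sets$swnH2,
               sort(c("swnK", "swnT", "swnR", "swnH1", "swnA")))
  expect_equal(s$partner_sets$swnK, c("swnH2", "swnR"))
  expect_equal(as.integer(s$type_counts[c("A", "B", "A/B")]), c(6L, 2L, 6L))
})

test_that("layout-derived matrices: duplicates identical, mirror invariant", {
  lay1 <- cluster_layout("a", data.frame(
    gene = c("swnK", "swnH2", "swnN"), contig = "c",
    start = c(1L, 9001L, 11001L), end = c(8000L, 10000L, 12000L),
    strand = c("+", "-", "+")))
  lay2 <- cluster_layout("b", lay1$annotations)
  m <- build_character_matrix(list(lay1, lay2))
  expect_equal(m$presence["a", ], m$presence["b", ], ignore_attr = TRUE)
  expect_equal(m$inverted["a", ], m$inverted["b", ], ignore_attr = TRUE)
  expect_error(build_character_matrix(list(lay1, lay1)), "duplicate taxon")

  # mirroring a whole layout: same characters present, all orientations flip
  set.seed(12)
  for (rep in 1:10) {
    lay <- orient_cluster(random_layout(paste0("m", rep)))
    a <- lay$annotations
    hi <- max(a$end)
    mirrored <- cluster_layout(lay$taxon, data.frame(
      gene = a$gene, contig = a$contig,
      start = hi - a$end + 1L, end = hi - a$start + 1L,
      strand = ifelse(a$strand == "+", "-", "+")))
    cl1 <- classify_orientation(derive_adjacencies(lay))
    cl2 <- classify_orientation(derive_adjacencies(mirrored),
                                definitions = cl1$definitions)
    o1 <- cl1$adjacencies[order(cl1$adjacencies$character_id), ]
    o2 <- cl2$adjacencies[order(cl2$adjacencies$character_id), ]
    expect_equal(o1$character_id, o2$character_id)
    expect_true(all(o1$orientation != o2$orientation))
    expect_equal(o1$ig_length_nt, o2$ig_length_nt)
  }
})
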