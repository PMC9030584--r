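test_that("Fitch length handles constant, singleton and missing characters", {
  set.seed(71)
  tr <- ape::rtree(8, br = NULL)
  tr$tip.label <- paste0("t", 1:8)
  m <- cbind(const = rep(TRUE, 8), single = c(TRUE, rep(FALSE, 7)))
  rownames(m) <- tr$tip.label
  fl <- fitch_length(tr, m)
  expect_equal(unname(fl$per_character), c(0L, 1L))
  expect_equal(fl$total, 1L)
  # missing data can only lower the length
  m2 <- cbind(x = c(TRUE, TRUE, NA, FALSE, FALSE, NA, TRUE, FALSE))
  rownames(m2) <- tr$tip.label
  m3 <- m2
  m3[is.na(m3)] <- TRUE
  expect_lte(fitch_length(tr, m2)$total, fitch_length(tr, m3)$total)
  bad <- m
  rownames(bad)[1] <- "zz"
  expect_error(fitch_length(tr, bad), "differ")
})

test_that("Fitch equals the internal-assignment oracle on random matrices", {
  set.seed(81)
  for (rep in 1:25) {
    n <- sample(5:8, 1L)
    tr <- ape::rtree(n, br = NULL)
    tr$tip.label <- paste0("t", seq_len(n))
    m <- random_binary_matrix(n, 6L)
    if (rep %% 5 == 0) m[sample(length(m), 3L)] <- NA
    fl <- fitch_length(tr, m)
    for (j in seq_len(ncol(m))) {
      want <- oracle_fitch_binary(tr, setNames(m[, j], rownames(m)))
      expect_equal(unname(fl$per_character[j]), want)
    }
  }
})

test_that("Fitch agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(91)
  for (rep in 1:10) {
    n <- sample(6:12, 1L)
    tr <- ape::rtree(n, br = NULL)
    tr$tip.label <- paste0("t", seq_len(n))
    m <- random_binary_matrix(n, 15L)
    dat <- phangorn::phyDat(ifelse(m, "1", "0"), type = "USER",
                            levels = c("0", "1"))
    expect_equal(fitch_length(tr, m)$total,
                 as.integer(phangorn::parsimony(tr, dat, method = "fitch")))
  }
})

test_that("Fitch length is invariant under rerooting and taxon permutation", {
  set.seed(101)
  tr <- ape::rtree(9, br = NULL)
  tr$tip.label <- paste0("t", 1:9)
  m <- random_binary_matrix(9, 10L)
  base <- fitch_length(tr, m)$total
  for (node in c(3L, 7L)) {
    rerooted <- ape::root(tr, outgroup = tr$tip.label[node], resolve.root = TRUE)
    expect_equal(fitch_length(rerooted, m)$total, base)
  }
  perm <- m[sample(nrow(m)), ]
  expect_equal(fitch_length(tr, perm)$total, base)
})

test_that("exhaustive search finds the unique 4-taxon split", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), "s"))
  res <- search_mp(m, mp_settings("exhaustive", seed = 1))
  expect_equal(res$score, 1L)
  expect_length(res$trees, 1L)
  expect_equal(rf_distance(res$trees[[1L]],
                           ape::read.tree(text = "((A,B),(C,D));")), 0L)
})

test_that("search recovers a 6-taxon topology from homoplasy-free splits", {
  set.seed(111)
  for (rep in 1:5) {
    tr <- ape::rtree(6, br = NULL)
    tr$tip.label <- paste0("t", 1:6)
    utr <- ape::unroot(tr)
    # one homoplasy-free binary character per non-trivial clade of a rooting
    n <- 6L
    chars <- list()
    rtr <- ape::root(utr, outgroup = "t1", resolve.root = TRUE)
    for (node in (n + 1L):(n + rtr$Nnode)) {
      tips <- ape::extract.clade(rtr, node)$tip.label
      if (length(tips) >= 2L && length(tips) <= n - 2L)
        chars[[length(chars) + 1L]] <- rtr$tip.label %in% tips
    }
    m <- do.call(cbind, chars)
    rownames(m) <- rtr$tip.label
    colnames(m) <- paste0("e", seq_len(ncol(m)))
    res <- search_mp(m, mp_settings("exhaustive", seed = rep))
    expect_equal(res$score, ncol(m))
    expect_true(any(vapply(res$trees, rf_distance, 0L, t2 = utr) == 0L))
  }
})

test_that("branch and bound returns the exhaustive optimum set", {
  set.seed(121)
  for (rep in 1:5) {
    m <- random_binary_matrix(7, 8L)
    ex <- search_mp(m, mp_settings("exhaustive", seed = 1))
    bb <- search_mp(m, mp_settings("branch_and_bound", seed = 1))
    expect_equal(bb$score, ex$score)
    expect_equal(length(bb$trees), length(ex$trees))
    rf0 <- function(a, bs) any(vapply(bs, rf_distance, 0L, t1 = a) == 0L)
    expect_true(all(vapply(bb$trees, rf0, NA, bs = ex$trees)))
  }
})

test_that("NNI hill climbing reaches the exact optimum on small matrices", {
  set.seed(131)
  hits <- 0L
  for (rep in 1:20) {
    m <- random_binary_matrix(7, 8L)
    ex <- search_mp(m, mp_settings("branch_and_bound", seed = 1))
    hc <- search_mp(m, mp_settings("hill_climb_nni", replicates = 10,
                                   seed = rep))
    expect_gte(hc$score, ex$score)
    hits <- hits + (hc$score == ex$score)
  }
  expect_gte(hits, 18L)
})

test_that("search is deterministic given a seed and respects guards", {
  m <- random_binary_matrix(8, 10L)
  a <- search_mp(m, mp_settings("hill_climb_nni", seed = 5))
  b <- search_mp(m, mp_settings("hill_climb_nni", seed = 5))
  expect_equal(a$score, b$score)
  expect_equal(lapply(a$trees, ape::write.tree),
               lapply(b$trees, ape::write.tree))
  big <- random_binary_matrix(10, 4L)
  expect_error(search_mp(big, mp_settings("exhaustive")), "at most 9")
  expect_error(search_mp(random_binary_matrix(13, 4L),
                         mp_settings("branch_and_bound")), "at most 12")
  expect_error(search_mp(random_binary_matrix(3, 4L), mp_settings()),
               "at least 4 taxa")
})

test_that("uninformative characters never change the optimal tree set", {
  set.seed(141)
  m <- random_binary_matrix(6, 6L)
  ex1 <- search_mp(m, mp_settings("exhaustive", seed = 1))
  m2 <- cbind(m, const = rep(TRUE, 6), single = c(TRUE, rep(FALSE, 5)))
  ex2 <- search_mp(m2, mp_settings("exhaustive", seed = 1))
  expect_equal(ex2$score, ex1$score + 1L)
  expect_equal(length(ex2$trees), length(ex1$trees))
  rf0 <- function(a, bs) any(vapply(bs, rf_distance, 0L, t1 = a) == 0L)
  expect_true(all(vapply(ex2$trees, rf0, NA, bs = ex1$trees)))
})

test_that("character change mapping flags unique changes only", {
  m <- build_character_matrix(load_table2_fixture())
  res <- search_mp(m, mp_settings("hill_climb_nni", replicates = 5, seed = 2))
  ch <- map_character_changes(res$trees[[1L]], m)
  fl <- fitch_length(res$trees[[1L]], m)
  expect_equal(ch$min_changes, unname(fl$per_character))
  expect_equal(ch$unique, unname(fl$per_character) == 1L)
  expect_equal(ch$character_id, 0:12)
  # bound: a character in k of n taxa changes at most min(k, n-k) times
  k <- colSums(m$presence)
  expect_true(all(ch$min_changes <= pmin(k, nrow(m$presence) - k)))
  # singleton character is always unique
  expect_true(ch$unique[ch$character_id == 12L])
})

test_that("RF distance matches an independent implementation", {
  expect_equal(rf_distance(ape::read.tree(text = "((A,B),(C,D));"),
                           ape::read.tree(text = "((A,B),(C,D));")), 0L)
  expect_equal(rf_distance(ape::read.tree(text = "((A,B),(C,D));"),
                           ape::read.tree(text = "((A,C),(B,D));")), 2L)
  expect_error(rf_distance(ape::read.tree(text = "((A,B),(C,E));"),
                           ape::read.tree(text = "((A,B),(C,D));")),
               "different leaf sets")
  skip_if_not_installed("phangorn")
  set.seed(151)
  for (rep in 1:20) {
    n <- sample(5:15, 1L)
    t1 <- ape::rtree(n)
    t2 <- ape::rtree(n)
    expect_equal(rf_distance(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
    expect_equal(rf_distance(t1, t1), 0L)
  }
})
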