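# Maximum parsimony over discrete character matrices.
#
# Internal tree representation during search: an integer (parent, child)
# edge matrix; tips 1..n, root n+1 with a basal trichotomy (the standard
# unrooted encoding), internal nodes numbered upwards as created.  Scoring is
# delegated to the compiled Fitch kernel, which accepts edges in any row
# order and missing tip data as full state-set bitmasks.

# Coerce a character matrix into tip-state bitmasks (rows = taxa).
# Accepts a swn_character_matrix (binary presence), a logical matrix, or an
# integer matrix of states 0..31; NA means missing (full state set).
state_bitmasks <- function(matrix) {
  m <- if (inherits(matrix, "swn_character_matrix")) matrix$presence
       else if (is.data.frame(matrix)) as.matrix(matrix)
       else matrix
  if (is.null(rownames(m))) stopf("character matrix needs taxon rownames")
  if (is.logical(m)) m <- m + 0L
  if (!is.numeric(m)) stopf("character matrix must be logical or integer")
  nstate <- max(2L, max(m, na.rm = TRUE) + 1L)
  if (nstate > 32L) stopf("at most 32 states supported")
  full <- bitwShiftL(1L, nstate) - 1L
  bits <- matrix(full, nrow(m), ncol(m), dimnames = dimnames(m))
  obs <- !is.na(m)
  bits[obs] <- bitwShiftL(1L, as.integer(m[obs]))
  bits
}

character_ids_of <- function(matrix) {
  if (inherits(matrix, "swn_character_matrix")) matrix$characters$character_id
  else colnames(matrix) %||% seq_len(ncol(matrix))
}

check_leaf_match <- function(tree, taxa) {
  extra <- setdiff(tree$tip.label, taxa)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(extra) || length(missing))
    stopf("tree leaves and matrix taxa differ (only in tree: %s; only in matrix: %s)",
          paste(extra, collapse = ", ") %e% "none",
          paste(missing, collapse = ", ") %e% "none")
}

`%e%` <- function(a, b) if (nzchar(a)) a else b

#' Fitch parsimony length of a tree
#'
#' Computes the minimum number of state changes (small parsimony) of each
#' character on a fixed tree with the Fitch state-set algorithm, and their
#' sum.  The score is invariant to rooting.  Missing cells (`NA`) contribute
#' the full state set at the tip.
#'
#' @param tree An `ape::phylo`; leaves must match the matrix taxa.
#' @param matrix A `swn_character_matrix`, or a logical/integer matrix with
#'   taxon rownames (integer states 0..31).
#' @return List with `total` (integer) and `per_character` (named integer
#'   vector).
#' @export
#' @examples
#' m <- build_character_matrix(load_table2_fixture())
#' tr <- ape::rtree(14, tip.label = rownames(m$presence), br = NULL)
#' fitch_length(tr, m)$total
fitch_length <- function(tree, matrix) {
  stopifnot(inherits(tree, "phylo"))
  bits <- state_bitmasks(matrix)
  check_leaf_match(tree, rownames(bits))
  n <- length(tree$tip.label)
  states <- bits[match(tree$tip.label, rownames(bits)), , drop = FALSE]
  edge <- tree$edge
  storage.mode(edge) <- "integer"
  per <- fitch_lengths_cpp(edge, n, states)
  names(per) <- colnames(bits)
  list(total = sum(per), per_character = per)
}

#' Map character changes on a tree
#'
#' For each character, its minimum change count on the tree and whether the
#' character changes at exactly one spot (a "unique" change, drawn as a
#' closed circle on the published binary tree; open circles mark homoplasy).
#'
#' @inheritParams fitch_length
#' @return Data frame with columns `character_id`, `min_changes`, `unique`.
#' @export
map_character_changes <- function(tree, matrix) {
  fl <- fitch_length(tree, matrix)
  data.frame(character_id = character_ids_of(matrix),
             min_changes = unname(fl$per_character),
             unique = unname(fl$per_character) == 1L)
}

# search ---------------------------------------------------------------------

#' Maximum-parsimony search settings
#'
#' @param method `"hill_climb_nni"` (random-addition starting trees plus NNI
#'   hill climbing), `"branch_and_bound"` (exact, up to 12 taxa) or
#'   `"exhaustive"` (full enumeration of all (2n-5)!! topologies, up to 9
#'   taxa).
#' @param replicates Random-addition replicates for the heuristic.
#' @param max_trees Retain at most this many equally parsimonious trees.
#' @param seed Seed for addition order and tie-breaking.
#' @return A `mp_settings` list.
#' @export
mp_settings <- function(method = c("hill_climb_nni", "branch_and_bound",
                                   "exhaustive"),
                        replicates = 10L, max_trees = 100L, seed = 42L) {
  method <- match.arg(method)
  stopifnot(replicates >= 1L, max_trees >= 1L)
  structure(list(method = method, replicates = as.integer(replicates),
                 max_trees = as.integer(max_trees), seed = as.integer(seed)),
            class = "mp_settings")
}

insert_tip <- function(edge, eidx, tip, newnode) {
  child <- edge[eidx, 2L]
  edge[eidx, 2L] <- newnode
  rbind(edge, c(newnode, child), c(newnode, tip))
}

base_edge <- function(n, tips = 1:3) {
  matrix(c(n + 1L, tips[1L], n + 1L, tips[2L], n + 1L, tips[3L]),
         ncol = 2L, byrow = TRUE)
}

score_trees <- function(edges, n, states, weights) {
  as.integer(fitch_total_many_cpp(edges, n, states, weights))
}

# Exact search by stepwise-addition enumeration.  With prune = TRUE this is
# branch and bound: a partial tree's Fitch length never decreases as taxa
# are added, so subtrees whose partial score exceeds the incumbent cannot
# contain an optimal tree and the retained optimum set is identical to the
# exhaustive one.
mp_exact <- function(states, n, weights, max_trees, prune) {
  best <- .Machine$integer.max
  best_trees <- list()
  truncated <- FALSE
  rec <- function(edge, k, newnode) {
    if (k > n) {
      sc <- score_trees(list(edge), n, states, weights)
      if (sc < best) {
        best <<- sc
        best_trees <<- list(edge)
        truncated <<- FALSE
      } else if (sc == best) {
        if (length(best_trees) < max_trees)
          best_trees[[length(best_trees) + 1L]] <<- edge
        else truncated <<- TRUE
      }
      return()
    }
    if (prune && score_trees(list(edge), n, states, weights) > best) return()
    for (i in seq_len(nrow(edge)))
      rec(insert_tip(edge, i, k, newnode), k + 1L, newnode + 1L)
  }
  rec(base_edge(n), 4L, n + 2L)
  list(score = best, trees = best_trees, truncated = truncated)
}

nni_neighbors <- function(edge, n) {
  out <- list()
  for (ei in which(edge[, 2L] > n)) {
    u <- edge[ei, 1L]
    v <- edge[ei, 2L]
    ve <- which(edge[, 1L] == v)
    ce <- setdiff(which(edge[, 1L] == u), ei)[1L]
    for (ae in ve) {
      e2 <- edge
      e2[ae, 1L] <- u
      e2[ce, 1L] <- v
      out[[length(out) + 1L]] <- e2
    }
  }
  out
}

random_addition_tree <- function(states, n, weights) {
  ord <- sample.int(n)
  edge <- base_edge(n, ord[1:3])
  newnode <- n + 2L
  for (k in seq_len(n)[-(1:3)]) {
    cands <- lapply(seq_len(nrow(edge)), function(i)
      insert_tip(edge, i, ord[k], newnode))
    sc <- score_trees(cands, n, states, weights)
    pick <- which(sc == min(sc))
    if (length(pick) > 1L) pick <- sample(pick, 1L)
    edge <- cands[[pick]]
    newnode <- newnode + 1L
  }
  edge
}

nni_hill_climb <- function(edge, states, n, weights) {
  cur_sc <- score_trees(list(edge), n, states, weights)
  repeat {
    nb <- nni_neighbors(edge, n)
    if (!length(nb)) break
    sc <- score_trees(nb, n, states, weights)
    if (min(sc) >= cur_sc) break
    pick <- which(sc == min(sc))
    if (length(pick) > 1L) pick <- sample(pick, 1L)
    edge <- nb[[pick]]
    cur_sc <- min(sc)
  }
  list(edge = edge, score = cur_sc)
}

# Canonical key of the unrooted topology: sorted non-trivial splits, each
# written as the sorted tip set not containing tip 1.
edge_split_key <- function(edge, n) {
  kids <- split(edge[, 2L], edge[, 1L])
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  below <- list()
  rec <- function(v) {
    if (v <= n) return(v)
    s <- sort(unlist(lapply(kids[[as.character(v)]], rec)))
    below[[as.character(v)]] <<- s
    s
  }
  rec(root)
  keys <- character()
  for (v in names(below)) {
    side <- below[[v]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (1L %in% side) side <- setdiff(seq_len(n), side)
    keys <- c(keys, paste(side, collapse = "."))
  }
  paste(sort(unique(keys)), collapse = "|")
}

edge_to_phylo <- function(edge, labels) {
  storage.mode(edge) <- "integer"
  tr <- structure(list(edge = edge, tip.label = labels,
                       Nnode = max(edge) - length(labels)),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Search for maximum-parsimony trees
#'
#' Finds minimum-length unrooted binary trees for a discrete character
#' matrix.  `"exhaustive"` enumerates all `(2n-5)!!` topologies (n <= 9);
#' `"branch_and_bound"` prunes the same enumeration with the incumbent score
#' and returns the identical optimal set (n <= 12); `"hill_climb_nni"` runs
#' seeded random-addition starting trees refined by nearest-neighbour
#' interchange until no move improves the score, pooling the best trees
#' across replicates.  All equally parsimonious trees are retained up to
#' `max_trees`.
#'
#' @param matrix As in [fitch_length()]; at least 4 taxa.
#' @param settings An [mp_settings()] object.
#' @return Object of class `mp_result`: list with `trees` (class
#'   `multiPhylo`), `score`, `consensus` (strict consensus when several
#'   trees), `method`, `seed`, `truncated`.
#' @export
#' @examples
#' m <- build_character_matrix(load_table2_fixture())
#' res <- search_mp(m, mp_settings("hill_climb_nni", replicates = 3, seed = 1))
#' res$score
search_mp <- function(matrix, settings = mp_settings()) {
  stopifnot(inherits(settings, "mp_settings"))
  bits <- state_bitmasks(matrix)
  taxa <- rownames(bits)
  n <- length(taxa)
  if (n < 4L) stopf("need at least 4 taxa, got %d", n)
  if (settings$method == "exhaustive" && n > 9L)
    stopf("exhaustive search supports at most 9 taxa (got %d); use branch_and_bound or hill_climb_nni", n)
  if (settings$method == "branch_and_bound" && n > 12L)
    stopf("branch and bound supports at most 12 taxa (got %d); use hill_climb_nni", n)
  # compress duplicate character patterns into weights
  pat <- apply(bits, 2L, paste, collapse = ",")
  upat <- !duplicated(pat)
  weights <- as.integer(table(factor(pat, levels = pat[upat])))
  states <- bits[, upat, drop = FALSE]
  set.seed(settings$seed)
  if (settings$method %in% c("exhaustive", "branch_and_bound")) {
    res <- mp_exact(states, n, weights, settings$max_trees,
                    prune = settings$method == "branch_and_bound")
    edges <- res$trees
    score <- res$score
    truncated <- res$truncated
  } else {
    pool <- list()
    scores <- integer()
    for (r in seq_len(settings$replicates)) {
      hc <- nni_hill_climb(random_addition_tree(states, n, weights),
                           states, n, weights)
      pool[[r]] <- hc$edge
      scores[r] <- hc$score
    }
    score <- min(scores)
    edges <- pool[scores == score]
    keys <- vapply(edges, edge_split_key, "", n = n)
    edges <- edges[!duplicated(keys)]
    truncated <- length(edges) > settings$max_trees
    edges <- edges[seq_len(min(length(edges), settings$max_trees))]
  }
  trees <- lapply(edges, edge_to_phylo, labels = taxa)
  class(trees) <- "multiPhylo"
  cons <- if (length(trees) > 1L) ape::consensus(trees, p = 1) else trees[[1L]]
  structure(list(trees = trees, score = score, consensus = cons,
                 method = settings$method, seed = settings$seed,
                 truncated = truncated),
            class = "mp_result")
}

#' @export
print.mp_result <- function(x, ...) {
  cat("<mp_result> ", length(x$trees), " tree(s), score ", x$score,
      " (", x$method, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# tree comparison ------------------------------------------------------------

phylo_splits <- function(phy) {
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")$edge
  below <- vector("list", max(po))
  for (i in seq_len(n)) below[[i]] <- phy$tip.label[i]
  keys <- character()
  ref <- sort(phy$tip.label)[1L]
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]
    ch <- po[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
    if (ch <= n) next
    side <- below[[ch]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (ref %in% side) side <- setdiff(phy$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees.  Zero iff the unrooted topologies are identical; for two
#' binary trees on n leaves the maximum is 2(n-3).
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Integer distance.
#' @export
#' @examples
#' rf_distance(ape::read.tree(text = "((A,B),(C,D));"),
#'             ape::read.tree(text = "((A,C),(B,D));"))  # 2
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stopf("trees have different leaf sets (only in first: %s; only in second: %s)",
          paste(setdiff(t1$tip.label, t2$tip.label), collapse = ", ") %e% "none",
          paste(setdiff(t2$tip.label, t1$tip.label), collapse = ", ") %e% "none")
  s1 <- phylo_splits(t1)
  s2 <- phylo_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
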