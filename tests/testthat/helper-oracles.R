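# Independent oracles used across the suite.  These deliberately share no
# code with the package implementation they check.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# Brute-force ORF scan of one strand: for every in-frame ATG, take the first
# in-frame stop after it, then keep only the longest ORF per stop.
oracle_scan_strand <- function(s) {
  L <- nchar(s)
  empty <- data.frame(frame = integer(), start = integer(), end = integer(),
                      length_aa = integer())
  if (L < 6L) return(empty)
  pos <- 1:(L - 2L)
  cods <- substring(s, pos, pos + 2L)
  starts <- pos[cods == "ATG"]
  stops <- pos[cods %in% ORACLE_STOPS]
  out <- list()
  for (f in 0:2) {
    sf <- starts[(starts - 1L) %% 3L == f]
    tf <- stops[(stops - 1L) %% 3L == f]
    if (!length(sf) || !length(tf)) next
    idx <- findInterval(sf, tf) + 1L
    ok <- idx <= length(tf)
    if (!any(ok)) next
    sf <- sf[ok]
    st <- tf[idx[ok]]
    df <- data.frame(frame = f, start = sf, end = st + 2L,
                     length_aa = (st - sf) %/% 3L)
    df <- df[order(df$end, df$start), , drop = FALSE]
    df <- df[!duplicated(df$end), , drop = FALSE]
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

oracle_orfs <- function(seq, min_aa, both_strands = TRUE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  fwd <- oracle_scan_strand(seq)
  hits <- if (nrow(fwd)) cbind(strand = "+", fwd)
          else data.frame(strand = character(), frame = integer(),
                          start = integer(), end = integer(),
                          length_aa = integer())
  if (both_strands) {
    rev <- oracle_scan_strand(oracle_revcomp(seq))
    if (nrow(rev))
      hits <- rbind(hits, data.frame(strand = "-", frame = rev$frame,
                                     start = L - rev$end + 1L,
                                     end = L - rev$start + 1L,
                                     length_aa = rev$length_aa))
  }
  hits <- hits[hits$length_aa >= min_aa, , drop = FALSE]
  hits <- hits[order(hits$start, hits$end, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Exhaustive internal-state-assignment parsimony length of one binary
# character on a tree: minimise the number of state-changing edges over all
# 0/1 assignments to internal nodes (and to missing tips).
oracle_fitch_binary <- function(tree, tip_states) {
  edge <- tree$edge
  n <- length(tree$tip.label)
  nn <- max(edge)
  fixed <- rep(NA_integer_, nn)
  fixed[seq_len(n)] <- as.integer(tip_states[tree$tip.label])
  free <- which(is.na(fixed))
  k <- length(free)
  combos <- as.matrix(expand.grid(rep(list(0:1), k)))
  best <- Inf
  states <- fixed
  for (r in seq_len(nrow(combos))) {
    states[free] <- combos[r, ]
    best <- min(best, sum(states[edge[, 1L]] != states[edge[, 2L]]))
  }
  best
}

# Random cluster layout: subset of SWN genes (always swnK) in random order
# with random strands and plausible spacing.
random_layout <- function(taxon, n_genes = sample(2:7, 1L)) {
  genes <- c("swnK", sample(setdiff(swn_genes(), "swnK"), n_genes - 1L))
  genes <- sample(genes)
  lens <- sample(800:3000, n_genes, replace = TRUE)
  gaps <- sample(0:1500, n_genes, replace = TRUE)
  start <- cumsum(c(1L, (lens + gaps)[-n_genes]))
  cluster_layout(taxon, data.frame(
    gene = genes, contig = paste0(taxon, "_c"), start = start,
    end = start + lens - 1L,
    strand = sample(c("+", "-"), n_genes, replace = TRUE)))
}

random_binary_matrix <- function(n_taxa, n_char, p = 0.5) {
  m <- matrix(stats::runif(n_taxa * n_char) < p, n_taxa, n_char,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("k", seq_len(n_char))))
  m
}

descendant_tips <- function(tree, branch_label) {
  n <- length(tree$tip.label)
  if (branch_label %in% tree$tip.label) return(branch_label)
  node <- as.integer(sub("node", "", branch_label))
  ape::extract.clade(tree, node)$tip.label
}

table2_pleosporales <- function() {
  t1 <- load_table1_fixture()
  t2 <- load_table2_fixture()
  intersect(t1$taxon[t1$order_label == "Pleosporales"], names(t2$taxon_type))
}
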