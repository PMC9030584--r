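test_that("intergenic extraction honours the coordinate convention", {
  contig <- paste(rep("A", 120), collapse = "")
  substr(contig, 101, 103) <- "CGT"
  adj <- data.frame(taxon = "x", left_gene = "swnK", right_gene = "swnR",
                    ig_start = 101L, ig_end = 103L, ig_length_nt = 3L,
                    overlap = FALSE)
  expect_equal(extract_intergenic_sequence(contig, adj), "CGT")
  ov <- adj
  ov$overlap <- TRUE
  expect_warning(s <- extract_intergenic_sequence(contig, ov), "overlap")
  expect_equal(s, "")
  out <- adj
  out$ig_end <- 500L
  expect_error(suppressWarnings(extract_intergenic_sequence(contig, out)),
               "outside contig")
})

test_that("simulated contigs decompose into genes plus intergenic spans", {
  p <- sim_params(n_taxa = 4, seed = 21, planted_orf_rate = 0)
  evo <- evolve_cluster(simulate_tree(p), params = p)
  fa <- withr::local_tempfile(fileext = ".fasta")
  emit_sequences(evo$layouts, p, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  for (lay in evo$layouts) {
    a <- lay$annotations
    s <- as.character(seqs[[a$contig[1L]]])
    expect_equal(nchar(s), max(a$end))
    adj <- derive_adjacencies(lay)
    pieces <- character()
    for (i in seq_len(nrow(a))) {
      pieces <- c(pieces, substr(s, a$start[i], a$end[i]))
      if (i < nrow(a))
        pieces <- c(pieces, extract_intergenic_sequence(s, adj[i, ]))
    }
    expect_equal(paste(pieces, collapse = ""), s)
  }
})

test_that("ORF finder handles canonical examples", {
  one <- find_orfs("ATGAAATAA", min_aa = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$strand, "+")
  expect_equal(one$length_aa, 2L)
  expect_equal(c(one$start, one$end), c(1L, 9L))
  expect_equal(nrow(find_orfs("CCCCCC", min_aa = 1)), 0L)
  expect_equal(nrow(find_orfs("", min_aa = 1)), 0L)
  # N poisons start and stop codons
  expect_equal(nrow(find_orfs("ATGNAATAA", min_aa = 1)), 1L)
  expect_equal(nrow(find_orfs("ANGAAATAA", min_aa = 1)), 0L)
  expect_error(find_orfs("ATGXXXTAA"), "alphabet")
})

test_that("ORF finder matches the brute-force scanner on random sequence", {
  set.seed(31)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
    for (ma in c(1L, 5L, 25L)) {
      got <- find_orfs(s, min_aa = ma)
      want <- oracle_orfs(s, min_aa = ma)
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("reported ORFs translate to Met-led stop-free peptides", {
  set.seed(41)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
             collapse = "")
  hits <- find_orfs(s, min_aa = 5)
  expect_gt(nrow(hits), 0L)
  for (i in seq_len(nrow(hits))) {
    sub <- substr(s, hits$start[i], hits$end[i])
    if (hits$strand[i] == "-")
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
    expect_equal(nchar(aa) - 1L, hits$length_aa[i])
  }
})

test_that("ORF counts are symmetric under reverse complement", {
  set.seed(51)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    r1 <- orf_report(list(x = s), min_aa = 5)
    r2 <- orf_report(list(x = rc), min_aa = 5)
    expect_equal(r1$n_orfs, r2$n_orfs)
    expect_equal(r1$n_short, r2$n_short)
  }
})

test_that("planted ORFs are recovered and T-free filler yields none", {
  p0 <- sim_params(n_taxa = 3, seed = 61, planted_orf_rate = 0)
  evo <- evolve_cluster(simulate_tree(p0), params = p0)
  fa <- withr::local_tempfile(fileext = ".fasta")
  emit_sequences(evo$layouts, p0, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  for (lay in evo$layouts) {
    adj <- derive_adjacencies(lay)
    s <- as.character(seqs[[lay$annotations$contig[1L]]])
    for (i in seq_len(nrow(adj))) {
      ig <- extract_intergenic_sequence(s, adj[i, ])
      if (nzchar(ig)) expect_equal(nrow(find_orfs(ig, min_aa = 1)), 0L)
    }
  }
  p1 <- sim_params(n_taxa = 3, seed = 62, planted_orf_rate = 2)
  evo <- evolve_cluster(simulate_tree(p1), params = p1)
  out <- emit_sequences(evo$layouts, p1, fa)
  expect_gt(nrow(out$planted), 0L)
  seqs <- Biostrings::readDNAStringSet(fa)
  for (i in seq_len(nrow(out$planted))) {
    pl <- out$planted[i, ]
    s <- as.character(seqs[[paste0(pl$taxon, "_contig")]])
    hits <- find_orfs(s, min_aa = 10, both_strands = FALSE)
    match <- hits[hits$end == pl$end, ]
    expect_equal(nrow(match), 1L)
    expect_gte(match$length_aa, pl$length_aa)
  }
})
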