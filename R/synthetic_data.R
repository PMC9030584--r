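NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1L, paste, collapse = ""),
  STOP_CODONS)

#' Simulation parameters for cluster evolution
#'
#' Event rates are per unit branch length; intergenic lengths at the leaves
#' are drawn from a log-normal with the given median (nt) and log-scale
#' sigma, approximating the spread observed in real clusters (most spans
#' 500-2000 nt).  `swnK` is never lost, mirroring its use as the inclusion
#' criterion for real taxa.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param birth_rate Yule speciation rate.
#' @param loss_rate Gene losses per unit branch length.
#' @param inversion_rate Adjacent-pair inversions per unit branch length.
#' @param transposition_rate Single-gene relocations per unit branch length.
#' @param ig_median_nt Median intergenic length (nt) at the leaves.
#' @param ig_sigma Log-scale standard deviation of intergenic lengths.
#' @param planted_orf_rate Expected planted ORFs per kb of intergenic
#'   sequence in [emit_sequences()].
#' @param planted_inversions Number of forced inversion events placed on
#'   uniformly chosen branches (in addition to rate-driven events).
#' @param seed Integer seed; all simulator outputs are reproducible given it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_taxa = 8L, birth_rate = 1, loss_rate = 0.3,
                       inversion_rate = 0.3, transposition_rate = 0,
                       ig_median_nt = 800, ig_sigma = 0.6,
                       planted_orf_rate = 1, planted_inversions = 0L,
                       seed = 1L) {
  stopifnot(n_taxa >= 2L, birth_rate > 0, loss_rate >= 0,
            inversion_rate >= 0, transposition_rate >= 0, ig_median_nt >= 1,
            ig_sigma >= 0, planted_orf_rate >= 0, planted_inversions >= 0L)
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 loss_rate = loss_rate, inversion_rate = inversion_rate,
                 transposition_rate = transposition_rate,
                 ig_median_nt = ig_median_nt, ig_sigma = ig_sigma,
                 planted_orf_rate = planted_orf_rate,
                 planted_inversions = as.integer(planted_inversions),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a Yule tree
#'
#' Pure-birth tree with `n_taxa` leaves labelled `T1..Tn`, seeded and
#' reproducible.
#'
#' @param params A [sim_params()] object.
#' @return An `ape::phylo` with branch lengths.
#' @export
simulate_tree <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  if (params$n_taxa == 2L) {
    tr <- ape::read.tree(text = "(T1:1,T2:1);")
    tr$edge.length <- stats::rexp(2L, rate = params$birth_rate)
    return(tr)
  }
  tr <- ape::rphylo(params$n_taxa, birth = params$birth_rate, death = 0)
  tr$tip.label <- paste0("T", seq_len(params$n_taxa))
  tr
}

#' Default ancestral cluster layout
#'
#' A seven-gene layout in the reference gene order swnA, swnH1, swnT, swnN,
#' swnR, swnK, swnH2, all on the plus strand, with realistic gene lengths
#' and uniform intergenic gaps.
#'
#' @param gap_nt Intergenic gap between consecutive genes (nt).
#' @return A [cluster_layout].
#' @export
default_ancestral_layout <- function(gap_nt = 800L) {
  genes <- c("swnA", "swnH1", "swnT", "swnN", "swnR", "swnK", "swnH2")
  lens <- c(1500L, 1400L, 1700L, 1300L, 1200L, 7800L, 1400L)
  start <- integer(7L)
  pos <- 1L
  for (i in seq_along(genes)) {
    start[i] <- pos
    pos <- pos + lens[i] + as.integer(gap_nt)
  }
  cluster_layout("ancestor", data.frame(
    gene = genes, contig = "anc_contig", start = start,
    end = start + lens - 1L, strand = "+"))
}

# internal gene-order state: data.frame(gene, length, strand)
state_from_layout <- function(layout) {
  a <- layout$annotations
  data.frame(gene = a$gene, length = a$end - a$start + 1L,
             strand = a$strand, stringsAsFactors = FALSE)
}

apply_sim_event <- function(state, kind, detail) {
  g <- state$gene
  if (kind == "loss") {
    state[g != detail, , drop = FALSE]
  } else if (kind == "inversion") {
    pair <- strsplit(detail, "+", fixed = TRUE)[[1L]]
    i <- match(pair[1L], g)
    if (is.na(i) || i >= nrow(state) || state$gene[i + 1L] != pair[2L])
      stopf("inversion event '%s' does not match an adjacent pair", detail)
    idx <- seq_len(nrow(state))
    idx[c(i, i + 1L)] <- c(i + 1L, i)
    state <- state[idx, , drop = FALSE]
    state$strand[c(i, i + 1L)] <-
      ifelse(state$strand[c(i, i + 1L)] == "+", "-", "+")
    state
  } else if (kind == "transposition") {
    part <- strsplit(detail, ">", fixed = TRUE)[[1L]]
    gene <- part[1L]
    pos <- as.integer(part[2L])
    row <- state[g == gene, , drop = FALSE]
    if (!nrow(row)) stopf("transposition of absent gene '%s'", gene)
    rest <- state[g != gene, , drop = FALSE]
    pos <- min(pos, nrow(rest) + 1L)
    out <- rbind(rest[seq_len(pos - 1L), , drop = FALSE], row,
                 if (pos <= nrow(rest)) rest[pos:nrow(rest), , drop = FALSE])
    rownames(out) <- NULL
    out
  } else stopf("unknown event kind '%s'", kind)
}

layout_from_state <- function(taxon, state, gaps) {
  n <- nrow(state)
  stopifnot(length(gaps) == max(0L, n - 1L))
  start <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    start[i] <- pos
    pos <- pos + state$length[i] + if (i < n) gaps[i] else 0L
  }
  cluster_layout(taxon, data.frame(
    gene = state$gene, contig = paste0(taxon, "_contig"), start = start,
    end = start + state$length - 1L, strand = state$strand))
}

draw_branch_events <- function(state_ngenes, len, params) {
  kinds <- c(loss = params$loss_rate, inversion = params$inversion_rate,
             transposition = params$transposition_rate)
  out <- data.frame(kind = character(), time = numeric())
  for (k in names(kinds)) {
    nev <- if (kinds[[k]] > 0) rpois(1L, kinds[[k]] * len) else 0L
    if (nev > 0L)
      out <- rbind(out, data.frame(kind = k, time = runif(nev) * len))
  }
  out[order(out$time), , drop = FALSE]
}

#' Evolve a gene cluster along a tree
#'
#' Plays gene losses, adjacent-pair inversions and single-gene
#' transpositions as Poisson processes along each branch, starting from an
#' ancestral layout.  Losses never remove `swnK`.  At each leaf the final
#' gene order is laid out on a fresh contig with log-normal intergenic gaps.
#' Every event (including each leaf's gap draw) is recorded in an event log
#' from which [replay_event_log()] reproduces the leaf layouts exactly.
#'
#' @param tree An `ape::phylo` with branch lengths, e.g. [simulate_tree()].
#' @param ancestral Ancestral [cluster_layout].
#' @param params A [sim_params()] object (its `seed` drives all draws).
#' @return Object of class `cluster_evolution`: list with `layouts` (named
#'   list of leaf [cluster_layout]s), `events` (data frame `branch`, `time`,
#'   `kind`, `detail`), `tree`, `ancestral`.
#' @export
evolve_cluster <- function(tree, ancestral = default_ancestral_layout(),
                           params = sim_params()) {
  stopifnot(inherits(tree, "phylo"), inherits(ancestral, "cluster_layout"),
            inherits(params, "sim_params"))
  if (is.null(tree$edge.length)) stopf("tree needs branch lengths")
  set.seed(params$seed)
  n <- length(tree$tip.label)
  node_label <- function(v) if (v <= n) tree$tip.label[v] else paste0("node", v)
  planted_edges <- if (params$planted_inversions > 0L)
    sample.int(nrow(tree$edge), params$planted_inversions, replace = TRUE)
  else integer()
  events <- list()
  layouts <- list()
  add_event <- function(branch, time, kind, detail)
    events[[length(events) + 1L]] <<-
      data.frame(branch = branch, time = time, kind = kind, detail = detail)
  root <- n + 1L
  recurse <- function(node, state) {
    for (ei in which(tree$edge[, 1L] == node)) {
      child <- tree$edge[ei, 2L]
      len <- tree$edge.length[ei]
      st <- state
      ev <- draw_branch_events(nrow(st), len, params)
      for (k in which(planted_edges == ei))
        ev <- rbind(ev, data.frame(kind = "inversion", time = len / 2))
      ev <- ev[order(ev$time), , drop = FALSE]
      for (j in seq_len(nrow(ev))) {
        kind <- ev$kind[j]
        detail <- NA_character_
        if (kind == "loss") {
          cand <- setdiff(st$gene, "swnK")
          if (!length(cand) || nrow(st) <= 1L) next
          detail <- if (length(cand) == 1L) cand else sample(cand, 1L)
        } else if (kind == "inversion") {
          if (nrow(st) < 2L) next
          i <- if (nrow(st) == 2L) 1L else sample.int(nrow(st) - 1L, 1L)
          detail <- paste(st$gene[i], st$gene[i + 1L], sep = "+")
        } else if (kind == "transposition") {
          if (nrow(st) < 2L) next
          gi <- sample.int(nrow(st), 1L)
          pos <- sample.int(nrow(st), 1L)
          detail <- paste0(st$gene[gi], ">", pos)
        }
        st <- apply_sim_event(st, kind, detail)
        add_event(node_label(child), ev$time[j], kind, detail)
      }
      if (child <= n) {
        taxon <- tree$tip.label[child]
        gaps <- if (nrow(st) > 1L)
          pmax(0L, as.integer(round(rlnorm(nrow(st) - 1L,
                                           meanlog = log(params$ig_median_nt),
                                           sdlog = params$ig_sigma))))
        else integer()
        add_event(taxon, len, "layout", paste(gaps, collapse = ","))
        layouts[[taxon]] <<- layout_from_state(taxon, st, gaps)
      } else {
        recurse(child, st)
      }
    }
  }
  recurse(root, state_from_layout(ancestral))
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(branch = character(), time = numeric(),
                        kind = character(), detail = character())
  structure(list(layouts = layouts[tree$tip.label], events = ev,
                 tree = tree, ancestral = ancestral),
            class = "cluster_evolution")
}

#' @export
print.cluster_evolution <- function(x, ...) {
  cat("<cluster_evolution> ", length(x$layouts), " leaf layouts, ",
      sum(x$events$kind != "layout"), " events\n", sep = "")
  invisible(x)
}

#' Replay an event log
#'
#' Re-applies the recorded events (in branch order along the tree, by
#' recorded time) to the ancestral layout and rebuilds every leaf layout.
#' This is a purely deterministic function of the log: it is the simulator's
#' correctness oracle, and `replay_event_log(tree, anc, evo$events)` must
#' equal `evo$layouts` exactly.
#'
#' @param tree The tree the log was generated on.
#' @param ancestral The ancestral [cluster_layout].
#' @param events Event log data frame from [evolve_cluster()].
#' @return Named list of leaf [cluster_layout]s.
#' @export
replay_event_log <- function(tree, ancestral, events) {
  n <- length(tree$tip.label)
  node_label <- function(v) if (v <= n) tree$tip.label[v] else paste0("node", v)
  layouts <- list()
  recurse <- function(node, state) {
    for (ei in which(tree$edge[, 1L] == node)) {
      child <- tree$edge[ei, 2L]
      lab <- node_label(child)
      ev <- events[events$branch == lab & events$kind != "layout", , drop = FALSE]
      ev <- ev[order(ev$time), , drop = FALSE]
      st <- state
      for (j in seq_len(nrow(ev)))
        st <- apply_sim_event(st, ev$kind[j], ev$detail[j])
      if (child <= n) {
        lay <- events[events$branch == lab & events$kind == "layout", , drop = FALSE]
        if (nrow(lay) != 1L) stopf("missing layout event for leaf %s", lab)
        gaps <- if (nzchar(lay$detail))
          as.integer(strsplit(lay$detail, ",", fixed = TRUE)[[1L]])
        else integer()
        layouts[[lab]] <<- layout_from_state(lab, st, gaps)
      } else {
        recurse(child, st)
      }
    }
  }
  recurse(n + 1L, state_from_layout(ancestral))
  layouts[tree$tip.label]
}

#' Write simulated layouts as GFF3 and TSV
#'
#' One GFF3 `gene` feature per annotation (attributes `ID`, `Name`, `taxon`)
#' plus the equivalent TSV annotation table; both round-trip through
#' [read_cluster_annotations()].
#'
#' @param layouts Named list of [cluster_layout]s.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, a list with the `gff3` and `tsv` paths.
#' @export
emit_annotations <- function(layouts, dir, prefix = "clusters") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff3 <- file.path(dir, paste0(prefix, ".gff3"))
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  glines <- "##gff-version 3"
  trows <- list()
  for (lay in layouts) {
    a <- lay$annotations
    if (!nrow(a)) next
    glines <- c(glines, sprintf(
      "%s\tswnsyn\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;taxon=%s",
      a$contig, a$start, a$end, a$strand,
      paste(lay$taxon, a$gene, sep = "_"), a$gene, lay$taxon))
    trows[[length(trows) + 1L]] <-
      data.frame(taxon = lay$taxon, gene = a$gene, contig = a$contig,
                 start = a$start, end = a$end, strand = a$strand)
  }
  writeLines(glines, gff3)
  write.table(do.call(rbind, trows), tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(gff3 = gff3, tsv = tsv))
}

random_codons <- function(n) {
  paste(sample(NONSTOP_CODONS, n, replace = TRUE), collapse = "")
}

plant_orf_string <- function(aa) {
  paste0("ATG", random_codons(aa - 1L),
         sample(STOP_CODONS, 1L))
}

#' Write simulated contig sequences with planted intergenic ORFs
#'
#' Gene bodies are filled with random stop-free codons; intergenic spans are
#' filled with T-free filler (which can contain no start or stop codon on
#' either strand, so detected intergenic ORFs are exactly the planted ones)
#' into which ATG..stop ORFs of 10-60 aa are planted at
#' `params$planted_orf_rate` per kb, non-overlapping, on the plus strand.
#'
#' @param layouts Named list of [cluster_layout]s.
#' @param params A [sim_params()] (seed and planting rate).
#' @param fasta Output FASTA path.
#' @return Invisibly, a list with `fasta` and `planted` (data frame: taxon,
#'   adjacency index, contig start/end of each planted ORF, aa length).
#' @export
emit_sequences <- function(layouts, params, fasta) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  seqs <- character()
  planted <- list()
  for (lay in layouts) {
    a <- lay$annotations
    if (!nrow(a)) next
    parts <- character()
    pos <- 1L
    for (i in seq_len(nrow(a))) {
      glen <- a$end[i] - a$start[i] + 1L
      parts <- c(parts, substr(random_codons(ceiling(glen / 3)), 1L, glen))
      pos <- a$end[i] + 1L
      if (i < nrow(a)) {
        gap <- a$start[i + 1L] - a$end[i] - 1L
        if (gap < 0L) stopf("overlapping genes cannot be emitted as sequence")
        filler <- paste(sample(c("A", "C", "G"), gap, replace = TRUE),
                        collapse = "")
        if (params$planted_orf_rate > 0 && gap >= 36L) {
          k <- rpois(1L, params$planted_orf_rate * gap / 1000)
          occupied <- integer()
          for (o in seq_len(k)) {
            aa <- sample(10:60, 1L)
            nt <- 3L * (aa + 1L)
            if (nt > gap) next
            for (try in 1:20) {
              s <- sample.int(gap - nt + 1L, 1L)
              if (!any(occupied %in% s:(s + nt - 1L))) {
                substr(filler, s, s + nt - 1L) <- plant_orf_string(aa)
                occupied <- c(occupied, s:(s + nt - 1L))
                planted[[length(planted) + 1L]] <- data.frame(
                  taxon = lay$taxon, adjacency = i,
                  start = pos + s - 1L, end = pos + s + nt - 2L,
                  length_aa = aa)
                break
              }
            }
          }
        }
        parts <- c(parts, filler)
      }
    }
    seqs[[a$contig[1L]]] <- paste(parts, collapse = "")
  }
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, fasta)
  invisible(list(fasta = fasta,
                 planted = if (length(planted)) do.call(rbind, planted)
                           else data.frame(taxon = character(),
                                           adjacency = integer(),
                                           start = integer(), end = integer(),
                                           length_aa = integer())))
}

#' Topology-recovery experiment
#'
#' Simulates replicate cluster histories, derives the adjacency character
#' matrix from the leaf layouts, searches for maximum-parsimony trees and
#' measures how often the true topology is recovered (Robinson-Foulds
#' distance 0 to some MP tree), alongside precision/recall of the inversion
#' (type B) flags against the event-log replay.
#'
#' @param params A [sim_params()]; replicate r uses seed `params$seed + r`.
#' @param n_reps Number of replicates.
#' @param settings [mp_settings()]; default: exhaustive search for up to 9
#'   taxa, NNI hill climbing otherwise.
#' @return Object of class `recovery_report`: data frame with one row per
#'   replicate (`rep`, `seed`, `n_informative`, `uninformative`,
#'   `best_score`, `n_mp_trees`, `min_rf`, `recovered`, `inv_precision`,
#'   `inv_recall`) and a `summary` attribute.
#' @export
recovery_experiment <- function(params = sim_params(), n_reps = 20L,
                                settings = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(settings))
    settings <- mp_settings(
      if (params$n_taxa <= 9L) "exhaustive" else "hill_climb_nni",
      seed = params$seed)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    p <- params
    p$seed <- params$seed + r
    tree <- simulate_tree(p)
    evo <- evolve_cluster(tree, default_ancestral_layout(), p)
    mat <- build_character_matrix(unname(evo$layouts))
    bin <- mat$presence
    informative <- apply(bin, 2L, function(x) min(sum(x), sum(!x)) >= 2L)
    truth <- replay_event_log(tree, evo$ancestral, evo$events)
    mat2 <- build_character_matrix(unname(truth))
    flags1 <- mat$inverted[order(rownames(mat$inverted)),
                           order(colnames(mat$inverted))]
    flags2 <- mat2$inverted[order(rownames(mat2$inverted)),
                            order(colnames(mat2$inverted))]
    tp <- sum(flags1 & flags2, na.rm = TRUE)
    inv_precision <- if (sum(flags1, na.rm = TRUE)) tp / sum(flags1, na.rm = TRUE) else NA_real_
    inv_recall <- if (sum(flags2, na.rm = TRUE)) tp / sum(flags2, na.rm = TRUE) else NA_real_
    if (!any(informative)) {
      rows[[r]] <- data.frame(rep = r, seed = p$seed,
                              n_informative = 0L, uninformative = TRUE,
                              best_score = NA_integer_, n_mp_trees = NA_integer_,
                              min_rf = NA_integer_, recovered = NA,
                              inv_precision = inv_precision,
                              inv_recall = inv_recall)
      next
    }
    st <- settings
    st$seed <- p$seed
    res <- search_mp(mat, st)
    true_tr <- ape::unroot(tree)
    rfs <- vapply(res$trees, rf_distance, 0L, t2 = true_tr)
    rows[[r]] <- data.frame(rep = r, seed = p$seed,
                            n_informative = sum(informative),
                            uninformative = FALSE, best_score = res$score,
                            n_mp_trees = length(res$trees),
                            min_rf = min(rfs), recovered = min(rfs) == 0L,
                            inv_precision = inv_precision,
                            inv_recall = inv_recall)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    recovery_fraction = mean(out$recovered, na.rm = TRUE),
    mean_min_rf = mean(out$min_rf, na.rm = TRUE),
    uninformative_fraction = mean(out$uninformative))
  class(out) <- c("recovery_report", class(out))
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<recovery_report> ", nrow(x), " replicates; recovery ",
      signif(s$recovery_fraction, 3), "; mean min RF ",
      signif(s$mean_min_rf, 3), "\n", sep = "")
  invisible(x)
}
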