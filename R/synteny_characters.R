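#' Canonical adjacency character definitions
#'
#' The thirteen adjacency characters of the SWN cluster, numbered 0-12, each
#' an ordered (left, right) gene pair in its canonical (type A) orientation.
#' Character 0 is swnH2-swnK.  Novel pairs observed in user data receive
#' fresh ids starting at 13; ids 0-12 are reserved and stable.
#'
#' @return Data frame with columns `character_id`, `left`, `right`.
#' @export
#' @examples
#' swn_character_definitions()
swn_character_definitions <- function() {
  data.frame(
    character_id = 0:12,
    left  = c("swnH2", "swnR", "swnK", "swnH1", "swnN", "swnT", "swnT",
              "swnH2", "swnH1", "swnA", "swnA", "swnN", "swnR"),
    right = c("swnK", "swnN", "swnR", "swnT", "swnH1", "swnN", "swnH2",
              "swnR", "swnH2", "swnH2", "swnH1", "swnA", "swnH1"),
    stringsAsFactors = FALSE)
}

#' Orient a cluster layout by its anchor gene
#'
#' Fixes the polarity of a cluster so that orientation (type A/B) calls are
#' reproducible from raw coordinates: if the highest-priority anchor gene
#' present lies on the minus strand, the whole layout is mirrored in
#' coordinate space (positions reflected about the occupied span, strands
#' flipped, order reversed); otherwise the layout is returned unchanged.
#' The operation is idempotent.
#'
#' @param layout A [cluster_layout].
#' @param anchor_priority Gene names in decreasing anchor priority; the
#'   default starts at `swnK`, which is present in every cluster.
#' @param contig_length Optional contig length used as the mirror span;
#'   defaults to the span covered by the annotations.
#' @return The oriented [cluster_layout].
#' @export
orient_cluster <- function(layout,
                           anchor_priority = c("swnK", "swnH2", "swnR", "swnN",
                                               "swnH1", "swnT", "swnA"),
                           contig_length = NA) {
  stopifnot(inherits(layout, "cluster_layout"))
  a <- layout$annotations
  anchors <- anchor_priority[anchor_priority %in% a$gene]
  if (!length(anchors))
    stopf("no SWN anchor gene in layout for %s", layout$taxon)
  anchor <- anchors[1L]
  if (a$strand[a$gene == anchor] == "+") return(layout)
  lo <- if (is.na(contig_length)) min(a$start) else 1L
  hi <- if (is.na(contig_length)) max(a$end) else as.integer(contig_length)
  new_start <- lo + hi - a$end
  new_end <- lo + hi - a$start
  a$start <- new_start
  a$end <- new_end
  a$strand <- ifelse(a$strand == "+", "-", "+")
  cluster_layout(layout$taxon, a, layout$order_label)
}

#' Derive adjacencies between consecutive SWN genes
#'
#' Walks the (already oriented) layout left to right and emits one adjacency
#' per pair of coordinate-consecutive SWN genes; intervening non-SWN genes
#' are ignored (treated as intergenic content).  The intergenic span runs
#' from one past the left gene's end to one before the right gene's start;
#' a negative span is recorded as an overlap with length 0.
#'
#' @param layout A [cluster_layout], normally the output of
#'   [orient_cluster()].
#' @return Data frame with one row per adjacency: `taxon`, `left_gene`,
#'   `right_gene` (observed left-to-right order), `ig_start`, `ig_end`,
#'   `ig_length_nt`, `overlap`.
#' @export
derive_adjacencies <- function(layout) {
  stopifnot(inherits(layout, "cluster_layout"))
  a <- layout$annotations
  a <- a[is_swn_gene(a$gene), , drop = FALSE]
  n <- nrow(a)
  if (n < 2L)
    return(data.frame(taxon = character(), left_gene = character(),
                      right_gene = character(), ig_start = integer(),
                      ig_end = integer(), ig_length_nt = integer(),
                      overlap = logical()))
  i <- seq_len(n - 1L)
  ig_start <- a$end[i] + 1L
  ig_end <- a$start[i + 1L] - 1L
  len <- ig_end - ig_start + 1L
  overlap <- len < 0L
  data.frame(taxon = layout$taxon,
             left_gene = a$gene[i], right_gene = a$gene[i + 1L],
             ig_start = ifelse(overlap, NA_integer_, ig_start),
             ig_end = ifelse(overlap, NA_integer_, ig_end),
             ig_length_nt = pmax(len, 0L), overlap = overlap,
             stringsAsFactors = FALSE)
}

#' Classify adjacency orientation against canonical characters
#'
#' Matches each adjacency's unordered gene pair against the character
#' definitions and types its orientation: A when the observed left-to-right
#' order equals the canonical pair, B when it is the reverse.  Pairs not yet
#' defined are registered with fresh ids (>= 13) in their observed order, so
#' the first observer of a novel pair is type A.  Adjacencies involving a
#' non-SWN gene are skipped and listed in the `report` attribute.
#'
#' @param adjacencies Data frame from [derive_adjacencies()].
#' @param definitions Character definitions; defaults to the canonical 13.
#' @return List with `adjacencies` (input plus `character_id` and
#'   `orientation` columns, skipped rows removed) and `definitions`
#'   (possibly extended); the `report` attribute lists skipped pairs.
#' @export
classify_orientation <- function(adjacencies,
                                 definitions = swn_character_definitions()) {
  adj <- adjacencies
  ok <- is_swn_gene(adj$left_gene) & is_swn_gene(adj$right_gene)
  report <- if (any(!ok)) {
    data.frame(taxon = adj$taxon[!ok],
               pair = paste(adj$left_gene[!ok], adj$right_gene[!ok], sep = "-"),
               reason = "non-SWN gene in pair")
  } else NULL
  adj <- adj[ok, , drop = FALSE]
  defs <- definitions
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  adj$character_id <- NA_integer_
  adj$orientation <- NA_character_
  for (i in seq_len(nrow(adj))) {
    k <- key(adj$left_gene[i], adj$right_gene[i])
    hit <- which(key(defs$left, defs$right) == k)
    if (!length(hit)) {
      new_id <- max(12L, defs$character_id) + 1L
      defs <- rbind(defs, data.frame(character_id = new_id,
                                     left = adj$left_gene[i],
                                     right = adj$right_gene[i]))
      hit <- nrow(defs)
    }
    adj$character_id[i] <- defs$character_id[hit]
    adj$orientation[i] <-
      if (adj$left_gene[i] == defs$left[hit] &&
          adj$right_gene[i] == defs$right[hit]) "A" else "B"
  }
  structure(list(adjacencies = adj, definitions = defs), report = report)
}

#' Classify a cluster's orientation type
#'
#' A cluster whose adjacencies are all in canonical orientation is type
#' `"A"`, all inverted is `"B"`, and a mixture is `"A/B"`.
#'
#' @param orientations Character vector of `"A"`/`"B"` calls, or the
#'   `adjacencies` data frame returned by [classify_orientation()].
#' @return `"A"`, `"B"` or `"A/B"`.
#' @export
classify_cluster_type <- function(orientations) {
  if (is.data.frame(orientations)) orientations <- orientations$orientation
  if (!length(orientations)) stopf("no adjacencies to classify")
  if (!all(orientations %in% c("A", "B"))) stopf("orientations must be A or B")
  u <- unique(orientations)
  if (length(u) == 2L) "A/B" else u
}

# the matrix container -------------------------------------------------------

new_character_matrix <- function(presence, characters, inverted, taxon_type) {
  stopifnot(is.matrix(presence),
            identical(dim(presence), dim(inverted)),
            nrow(characters) == ncol(presence))
  structure(list(presence = presence, characters = characters,
                 inverted = inverted, taxon_type = taxon_type),
            class = "swn_character_matrix")
}

#' @export
print.swn_character_matrix <- function(x, ...) {
  cat("<swn_character_matrix> ", nrow(x$presence), " taxa x ",
      ncol(x$presence), " characters\n", sep = "")
  if (!all(is.na(x$taxon_type))) print(table(x$taxon_type))
  invisible(x)
}

#' @export
dim.swn_character_matrix <- function(x) dim(x$presence)

#' Build the binary adjacency character matrix
#'
#' The taxa-by-characters presence matrix underlying the binary parsimony
#' analysis, with per-cell orientation (inversion) flags and per-taxon
#' orientation types.  Dispatches on input: a list of [cluster_layout]s is
#' oriented, decomposed into adjacencies and classified; a `swn_t2_fixture`
#' (see [load_table2_fixture()]) is rearranged directly.
#'
#' @param x List of [cluster_layout] objects, or a `swn_t2_fixture`.
#' @param ... Passed on to methods.
#' @return Object of class `swn_character_matrix`: `presence` (logical
#'   matrix), `characters` (definitions data frame), `inverted` (logical
#'   matrix, `NA` where absent), `taxon_type` (named vector).
#' @export
#' @examples
#' m <- build_character_matrix(load_table2_fixture())
#' dim(m)  # 14 x 13
build_character_matrix <- function(x, ...) UseMethod("build_character_matrix")

#' @rdname build_character_matrix
#' @param anchor_priority Passed to [orient_cluster()].
#' @param definitions Starting character definitions.
#' @export
build_character_matrix.list <- function(x,
                                        anchor_priority = c("swnK", "swnH2",
                                                            "swnR", "swnN",
                                                            "swnH1", "swnT",
                                                            "swnA"),
                                        definitions = swn_character_definitions(),
                                        ...) {
  if (length(x) < 2L) stopf("need at least 2 taxa")
  taxa <- vapply(x, `[[`, "", "taxon")
  if (anyDuplicated(taxa))
    stopf("duplicate taxon label '%s'", taxa[duplicated(taxa)][1L])
  defs <- definitions
  rows <- vector("list", length(x))
  types <- setNames(rep(NA_character_, length(x)), taxa)
  for (i in seq_along(x)) {
    adj <- derive_adjacencies(orient_cluster(x[[i]], anchor_priority))
    cl <- classify_orientation(adj, defs)
    defs <- cl$definitions
    rows[[i]] <- cl$adjacencies
    types[i] <- if (nrow(cl$adjacencies)) classify_cluster_type(cl$adjacencies)
                else NA_character_
  }
  ids <- defs$character_id
  pres <- matrix(FALSE, length(x), length(ids),
                 dimnames = list(taxa, sprintf("c%d", ids)))
  inv <- matrix(NA, length(x), length(ids), dimnames = dimnames(pres))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    j <- match(r$character_id, ids)
    pres[i, j] <- TRUE
    inv[i, j] <- r$orientation == "B"
  }
  new_character_matrix(pres, defs, inv, types)
}

#' @rdname build_character_matrix
#' @export
build_character_matrix.swn_t2_fixture <- function(x, ...) {
  rec <- x$records
  taxa <- names(x$taxon_type)
  defs <- swn_character_definitions()
  defs <- defs[defs$character_id %in% rec$character_id, , drop = FALSE]
  ids <- defs$character_id
  pres <- matrix(FALSE, length(taxa), length(ids),
                 dimnames = list(taxa, sprintf("c%d", ids)))
  inv <- matrix(NA, length(taxa), length(ids), dimnames = dimnames(pres))
  i <- match(rec$taxon, taxa)
  j <- match(rec$character_id, ids)
  pres[cbind(i, j)] <- TRUE
  inv[cbind(i, j)] <- rec$inverted
  new_character_matrix(pres, defs, inv, x$taxon_type)
}

#' Summarise a character matrix
#'
#' Per-character presence counts, per-gene partner sets (the genes a gene is
#' found adjacent to in any present character) and the tally of per-taxon
#' orientation types.
#'
#' @param matrix A `swn_character_matrix`.
#' @return List with `character_counts` (named integer vector, names
#'   `c<id>`), `partner_sets` (named list of character vectors per gene) and
#'   `type_counts` (table of A/B/A-B labels).
#' @export
character_summary <- function(matrix) {
  stopifnot(inherits(matrix, "swn_character_matrix"))
  if (!nrow(matrix$presence) || !ncol(matrix$presence))
    stopf("empty character matrix")
  counts <- colSums(matrix$presence, na.rm = TRUE)
  present_any <- counts > 0L
  defs <- matrix$characters[present_any, , drop = FALSE]
  genes <- sort(unique(c(defs$left, defs$right)))
  partners <- lapply(setNames(genes, genes), function(g) {
    sort(unique(c(defs$right[defs$left == g], defs$left[defs$right == g])))
  })
  list(character_counts = counts, partner_sets = partners,
       type_counts = table(matrix$taxon_type))
}
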