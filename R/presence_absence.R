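#' Build a gene presence/absence matrix
#'
#' Rearranges per-taxon presence records (as returned by
#' [load_table1_fixture()] or a user table in the same column layout) into a
#' taxa-by-genes logical matrix with per-taxon order labels and producer
#' flags.
#'
#' @param records Data frame with columns `taxon`, `order_label`,
#'   `swainsonine_producer` and one logical/0-1 column per SWN gene.
#' @return Object of class `swn_presence_matrix`: list with `presence`
#'   (logical matrix), `order_label` and `swainsonine_producer` (named
#'   vectors aligned to taxa).
#' @export
#' @examples
#' pm <- build_presence_matrix(load_table1_fixture())
#' dim(pm$presence)  # 36 x 7
build_presence_matrix <- function(records) {
  if (!nrow(records)) stopf("no presence records")
  miss <- setdiff(swn_genes(), names(records))
  if (length(miss))
    stopf("records lack gene column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(records$taxon)) stopf("duplicate taxon in records")
  m <- sapply(swn_genes(), function(g) as.logical(records[[g]]))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L, dimnames = list(NULL, swn_genes()))
  rownames(m) <- records$taxon
  if (anyNA(m)) stopf("missing presence cell")
  structure(list(
    presence = m,
    order_label = setNames(records$order_label, records$taxon),
    swainsonine_producer = setNames(as.logical(records$swainsonine_producer),
                                    records$taxon)),
    class = "swn_presence_matrix")
}

#' @export
print.swn_presence_matrix <- function(x, ...) {
  cat("<swn_presence_matrix> ", nrow(x$presence), " taxa x ",
      ncol(x$presence), " genes\n", sep = "")
  print(gene_frequency(x))
  invisible(x)
}

#' Per-gene presence counts
#'
#' @param matrix A `swn_presence_matrix`.
#' @return Named integer vector: for each SWN gene, the number of taxa in
#'   which it is present.
#' @export
#' @examples
#' gene_frequency(build_presence_matrix(load_table1_fixture()))
gene_frequency <- function(matrix) {
  stopifnot(inherits(matrix, "swn_presence_matrix"))
  colSums(matrix$presence)
}

#' Count distinct order labels
#'
#' Counts the distinct taxonomic order labels represented in the matrix,
#' optionally excluding taxa (e.g. the plant taxon, which is not a fungal
#' order).  Labels are counted verbatim, so a class-level label such as
#' "Leotiomycetes" counts as one group alongside true orders.
#'
#' @param matrix A `swn_presence_matrix`.
#' @param exclude Character vector of taxon names whose labels should not
#'   contribute.
#' @return Integer count of distinct labels.
#' @export
distinct_orders <- function(matrix, exclude = character()) {
  stopifnot(inherits(matrix, "swn_presence_matrix"))
  keep <- setdiff(rownames(matrix$presence), exclude)
  length(unique(matrix$order_label[keep]))
}
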