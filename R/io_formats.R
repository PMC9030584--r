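#' Construct a cluster layout
#'
#' A cluster layout is one taxon's ordered, stranded gene annotations on a
#' single contig.  Annotations are re-sorted by ascending start; SWN gene
#' names must be unique within the layout.
#'
#' @param taxon Taxon label (non-empty string).
#' @param annotations Data frame with columns `gene`, `contig`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`); 1-based inclusive coordinates.
#' @param order_label Optional taxonomic order label.
#' @return An object of class `cluster_layout`.
#' @export
#' @examples
#' cluster_layout("taxA", data.frame(
#'   gene = c("swnK", "swnH2"), contig = "c1",
#'   start = c(100, 10000), end = c(9000, 11000), strand = c("+", "-")))
cluster_layout <- function(taxon, annotations, order_label = NA_character_) {
  if (!is.character(taxon) || length(taxon) != 1L || !nzchar(taxon))
    stopf("taxon must be a non-empty string")
  need <- c("gene", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stopf("annotations lack column(s): %s", paste(miss, collapse = ", "))
  a <- as.data.frame(annotations)[need]
  a$start <- as.integer(a$start)
  a$end <- as.integer(a$end)
  if (nrow(a)) {
    if (any(!nzchar(a$gene))) stopf("empty gene name in layout for %s", taxon)
    if (any(a$start < 1L) || any(a$start > a$end))
      stopf("malformed coordinates in layout for %s", taxon)
    if (length(unique(a$contig)) > 1L)
      stopf("layout for %s spans several contigs", taxon)
    if (!all(a$strand %in% c("+", "-")))
      stopf("strand must be '+' or '-' (taxon %s)", taxon)
    dup <- a$gene[is_swn_gene(a$gene)]
    dup <- dup[duplicated(dup)]
    if (length(dup))
      stopf("duplicate SWN gene %s for taxon %s", dup[1L], taxon)
    a <- a[order(a$start, a$end), , drop = FALSE]
    rownames(a) <- NULL
  }
  structure(list(taxon = taxon, order_label = order_label, annotations = a),
            class = "cluster_layout")
}

#' @export
print.cluster_layout <- function(x, ...) {
  cat("<cluster_layout> ", x$taxon, ": ", nrow(x$annotations), " gene(s) on ",
      if (nrow(x$annotations)) x$annotations$contig[1L] else "<no contig>",
      "\n", sep = "")
  if (nrow(x$annotations)) print(x$annotations)
  invisible(x)
}

#' Read cluster annotations from TSV or GFF3
#'
#' The TSV dialect has header columns `taxon, gene, contig, start, end,
#' strand`.  The GFF3 dialect reads `gene`-type features, taking the gene name
#' from a configurable attribute key (default `Name`) and the taxon from a
#' `taxon` attribute when present, otherwise from the seqid.  Records with
#' malformed coordinates (start < 1 or start > end) are dropped and listed in
#' the `"report"` attribute of the result; a duplicated SWN gene within one
#' taxon/contig is a hard error.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param name_attr GFF3 attribute key holding the gene name.
#' @return List of [cluster_layout] objects, one per (taxon, contig), with a
#'   `report` attribute (data frame of rejected records).
#' @export
read_cluster_annotations <- function(path, dialect = c("tsv", "gff3"),
                                     name_attr = "Name") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- if (dialect == "tsv") read_annotation_tsv(path)
         else read_annotation_gff3(path, name_attr)
  if (nrow(tab) == 0L) {
    warnf("no annotation records in %s", path)
    return(structure(list(), report = empty_report()))
  }
  bad <- is.na(tab$start) | is.na(tab$end) | tab$start < 1L | tab$start > tab$end
  report <- if (any(bad)) {
    data.frame(taxon = tab$taxon[bad], gene = tab$gene[bad],
               reason = "malformed coordinates")
  } else empty_report()
  tab <- tab[!bad, , drop = FALSE]
  key <- paste(tab$taxon, tab$contig, sep = "\r")
  layouts <- lapply(split(tab, factor(key, levels = unique(key))), function(d) {
    cluster_layout(d$taxon[1L], d[c("gene", "contig", "start", "end", "strand")])
  })
  names(layouts) <- vapply(layouts, `[[`, "", "taxon")
  structure(unname(layouts), report = report)
}

empty_report <- function() {
  data.frame(taxon = character(), gene = character(), reason = character())
}

read_annotation_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxon", "gene", "contig", "start", "end", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("annotation TSV lacks column(s): %s", paste(miss, collapse = ", "))
  tab$start <- suppressWarnings(as.integer(tab$start))
  tab$end <- suppressWarnings(as.integer(tab$end))
  tab[need]
}

read_annotation_gff3 <- function(path, name_attr) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(taxon = character(), gene = character(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stopf("malformed GFF3 line in %s", path)
  f <- do.call(rbind, f)
  keep <- f[, 3L] == "gene"
  f <- f[keep, , drop = FALSE]
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  gene <- attr_get(f[, 9L], name_attr)
  if (anyNA(gene))
    stopf("GFF3 gene feature without '%s' attribute in %s", name_attr, path)
  taxon <- attr_get(f[, 9L], "taxon")
  taxon <- ifelse(is.na(taxon), f[, 1L], taxon)
  data.frame(taxon = taxon, gene = gene, contig = f[, 1L],
             start = suppressWarnings(as.integer(f[, 4L])),
             end = suppressWarnings(as.integer(f[, 5L])),
             strand = f[, 7L], stringsAsFactors = FALSE)
}

# packaged fixtures ----------------------------------------------------------

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "swnsyn")
  if (!nzchar(p)) stopf("packaged fixture %s not found", file)
  p
}

#' Load the curated gene-presence table (36 taxa x 7 SWN genes)
#'
#' Transcription of the published homologue survey: per taxon, its taxonomic
#' order, whether it has been reported to produce swainsonine, and
#' presence/absence of each of the seven SWN genes.  `swnK` is present in
#' every taxon because presence of `swnK` was the inclusion criterion.
#'
#' @param path Fixture file; defaults to the packaged table.
#' @return Data frame with columns `taxon`, `order_label`,
#'   `swainsonine_producer` (logical) and one logical column per SWN gene.
#' @export
#' @examples
#' t1 <- load_table1_fixture()
#' nrow(t1)  # 36
load_table1_fixture <- function(path = fixture_path("table1_swn_homologues.tsv")) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("taxon", "order_label", "swainsonine_producer", swn_genes())
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("presence fixture lacks column(s): %s", paste(miss, collapse = ", "))
  for (g in c("swainsonine_producer", swn_genes())) tab[[g]] <- tab[[g]] == 1L
  if (anyDuplicated(tab$taxon)) stopf("duplicate taxon in presence fixture")
  if (!all(tab$swnK)) stopf("presence fixture corrupt: swnK must be universal")
  if (identical(path, fixture_path("table1_swn_homologues.tsv")) &&
      nrow(tab) != 36L)
    stopf("packaged presence fixture corrupt: expected 36 taxa, got %d",
          nrow(tab))
  tab[c("taxon", "order_label", "swainsonine_producer", swn_genes())]
}

#' Load the curated intergenic-region character table (14 taxa)
#'
#' Transcription of the published intergenic-region survey: one row per
#' present adjacency character, with intergenic length (nt), overlap and
#' inversion flags, the count of ORFs with database matches and their match
#' classes (F fungus, B bacteria, A amoeba), plus the printed per-organism
#' orientation type (A, B or A/B).
#'
#' @param path Fixture file; defaults to the packaged table.
#' @return Object of class `swn_t2_fixture`: list with `records` (data frame)
#'   and `taxon_type` (named character vector of A/B/A-B labels).
#' @export
#' @examples
#' t2 <- load_table2_fixture()
#' length(t2$taxon_type)  # 14
load_table2_fixture <- function(path = fixture_path("table2_intergenic_characters.tsv")) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("taxon", "taxon_type", "character_id", "ig_length_nt", "overlap",
            "inverted", "orf_count", "match_classes", "blast_status")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopf("character fixture lacks column(s): %s", paste(miss, collapse = ", "))
  tab$overlap <- tab$overlap == 1L
  tab$inverted <- tab$inverted == 1L
  tab$match_classes[is.na(tab$match_classes)] <- ""
  if (any(tab$character_id < 0L | tab$character_id > 12L))
    stopf("character fixture corrupt: character_id outside 0..12")
  if (any(tab$overlap & !is.na(tab$ig_length_nt) & tab$ig_length_nt > 0L))
    stopf("character fixture corrupt: overlap with positive length")
  if (!all(tab$blast_status %in% c("matched", "none", "low", "not_applicable")))
    stopf("character fixture corrupt: unknown blast_status")
  types <- tapply(tab$taxon_type, tab$taxon, function(x) x[1L])
  types <- setNames(as.character(types), names(types))
  types <- types[unique(tab$taxon)]
  if (!all(types %in% c("A", "B", "A/B")))
    stopf("character fixture corrupt: unknown taxon type")
  if (identical(path, fixture_path("table2_intergenic_characters.tsv"))) {
    if (length(types) != 14L)
      stopf("packaged character fixture corrupt: expected 14 taxa")
    if (length(unique(tab$character_id)) != 13L)
      stopf("packaged character fixture corrupt: expected 13 characters")
  }
  structure(list(records = tab, taxon_type = types), class = "swn_t2_fixture")
}

#' @export
print.swn_t2_fixture <- function(x, ...) {
  cat("<swn_t2_fixture> ", length(x$taxon_type), " taxa, ",
      length(unique(x$records$character_id)), " characters, ",
      nrow(x$records), " present cells\n", sep = "")
  invisible(x)
}

# trees ----------------------------------------------------------------------

#' Read and write Newick trees
#'
#' Thin, validating wrappers around the `ape` Newick parser/serialiser.
#' Reading rejects unparsable strings and duplicate leaf labels; writing
#' rounds branch lengths to 6 significant digits so that write/read
#' round-trips are stable.
#'
#' @param path File path.
#' @param tree An `ape::phylo` tree.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`
#'   invisibly.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tr)) stopf("cannot parse Newick in %s", path)
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate leaf label '%s' in %s",
          tr$tip.label[duplicated(tr$tip.label)][1L], path)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

# character matrix serialisation ---------------------------------------------

#' Write a character matrix to TSV or NEXUS
#'
#' The TSV dialect is taxa rows by character columns of 0/1 (missing `?`),
#' readable back with [read_character_matrix()].  The NEXUS dialect emits a
#' `DATA` block with `DATATYPE=STANDARD SYMBOLS="01" MISSING=?`; taxon labels
#' containing whitespace are quoted.
#'
#' @param matrix A `swn_character_matrix` (see [build_character_matrix()]).
#' @param path Output file.
#' @param dialect `"tsv"` or `"nexus"`.
#' @param header Optional comment lines (TSV only) written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(matrix, path, dialect = c("tsv", "nexus"),
                                   header = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(matrix, "swn_character_matrix"))
  m <- matrix$presence
  if (nrow(m) == 0L || ncol(m) == 0L) stopf("refusing to write an empty matrix")
  cell <- ifelse(is.na(m), "?", ifelse(m, "1", "0"))
  if (dialect == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (h in header) writeLines(paste0("# ", h), con)
    writeLines(paste(c("taxon", colnames(m)), collapse = "\t"), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(c(rownames(m)[i], cell[i, ]), collapse = "\t"), con)
  } else {
    lab <- rownames(m)
    lab <- ifelse(grepl("\\s", lab), paste0("'", lab, "'"), lab)
    lines <- c("#NEXUS", "BEGIN DATA;",
               sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
               "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
               "MATRIX",
               sprintf("%s %s", format(lab), apply(cell, 1, paste, collapse = "")),
               ";", "END;")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a character matrix from the TSV dialect
#'
#' @param path File written by [write_character_matrix()] with
#'   `dialect = "tsv"`.
#' @return A `swn_character_matrix` (presence cells only; orientation flags
#'   and taxon types are not serialised in this dialect).
#' @export
read_character_matrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#", colClasses = "character")
  if (!"taxon" %in% names(tab)) stopf("matrix TSV lacks 'taxon' column")
  ids <- setdiff(names(tab), "taxon")
  m <- as.matrix(tab[ids])
  pres <- matrix(NA, nrow(m), ncol(m), dimnames = list(tab$taxon, ids))
  pres[m == "1"] <- TRUE
  pres[m == "0"] <- FALSE
  char_ids <- suppressWarnings(as.integer(sub("^c", "", ids)))
  canon <- swn_character_definitions()
  idx <- match(char_ids, canon$character_id)
  defs <- data.frame(character_id = char_ids, left = canon$left[idx],
                     right = canon$right[idx], stringsAsFactors = FALSE)
  new_character_matrix(pres, defs,
                       inverted = array(NA, dim(pres), dimnames(pres)),
                       taxon_type = setNames(rep(NA_character_, nrow(pres)),
                                             rownames(pres)))
}
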