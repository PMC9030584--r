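STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Extract the intergenic sequence of an adjacency
#'
#' Cuts the span between the two genes of an adjacency out of the contig
#' sequence.  Overlapping adjacencies yield an empty string (with a
#' warning); a span outside the contig is a hard error.
#'
#' @param contig_seq Contig nucleotide sequence (character string or
#'   `Biostrings::DNAString`), alphabet ACGTN.
#' @param adj One-row adjacency data frame from [derive_adjacencies()].
#' @return Uppercase nucleotide string of length `ig_length_nt`.
#' @export
extract_intergenic_sequence <- function(contig_seq, adj) {
  stopifnot(nrow(adj) == 1L)
  if (isTRUE(adj$overlap)) {
    warnf("adjacency %s-%s overlaps; empty intergenic sequence",
          adj$left_gene, adj$right_gene)
    return("")
  }
  s <- toupper(as.character(contig_seq))
  if (adj$ig_length_nt == 0L) return("")
  if (adj$ig_start < 1L || adj$ig_end > nchar(s))
    stopf("intergenic span %d..%d outside contig (length %d)",
          adj$ig_start, adj$ig_end, nchar(s))
  substr(s, adj$ig_start, adj$ig_end)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Scan one strand of a sequence for ATG..stop ORFs; returns coordinates on
# the scanned string.  Per (frame, stop) only the longest ORF is kept, i.e.
# the first in-frame ATG after the previous stop.  Codons containing N never
# match start or stop.
scan_strand_orfs <- function(seq) {
  L <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    p <- seq.int(f + 1L, by = 3L, length.out = max(0L, (L - f) %/% 3L))
    if (!length(p)) next
    codons <- substring(seq, p, p + 2L)
    starts <- which(codons == "ATG")
    stops <- which(codons %in% STOP_CODONS)
    if (!length(starts) || !length(stops)) next
    prev <- 0L
    for (j in stops) {
      cand <- starts[starts > prev & starts < j]
      if (length(cand)) {
        i <- cand[1L]
        out[[length(out) + 1L]] <-
          c(frame = f, start = p[i], end = p[j] + 2L, length_aa = j - i)
      }
      prev <- j
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      length_aa = integer()))
  as.data.frame(do.call(rbind, out))
}

#' Find open reading frames
#'
#' Scans a nucleotide sequence for ORFs: an in-frame `ATG` followed by a
#' stop codon (`TAA`/`TAG`/`TGA`) entirely inside the sequence.  Per
#' (strand, frame, stop) only the longest ORF — the first in-frame start
#' after the preceding stop — is reported.  Codons containing `N` never
#' match a start or stop.  Coordinates are 1-based inclusive on the forward
#' strand of the input and include the stop codon; `length_aa` counts codons
#' between start and stop, the start (Met) included, the stop excluded.
#'
#' @param seq Nucleotide string (alphabet ACGTN, case-insensitive).
#' @param min_aa Minimum `length_aa` to report (default 25, mirroring common
#'   ORF-finder defaults).
#' @param both_strands Scan the reverse complement as well (default TRUE).
#' @return Data frame sorted by `start` with columns `strand` (`"+"`/`"-"`),
#'   `frame` (0-2 within strand), `start`, `end`, `length_aa`.
#' @export
#' @examples
#' find_orfs("ATGAAATAA", min_aa = 1)
find_orfs <- function(seq, min_aa = 25, both_strands = TRUE) {
  if (min_aa < 1) stopf("min_aa must be >= 1")
  seq <- toupper(as.character(seq))
  empty <- data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      length_aa = integer())
  if (!nzchar(seq)) return(empty)
  if (grepl("[^ACGTN]", seq)) stopf("sequence alphabet must be ACGTN")
  L <- nchar(seq)
  fwd <- scan_strand_orfs(seq)
  hits <- if (nrow(fwd)) cbind(strand = "+", fwd) else empty
  if (both_strands) {
    rev <- scan_strand_orfs(revcomp(seq))
    if (nrow(rev)) {
      rev2 <- data.frame(strand = "-", frame = rev$frame,
                         start = L - rev$end + 1L, end = L - rev$start + 1L,
                         length_aa = rev$length_aa)
      hits <- rbind(hits, rev2)
    }
  }
  hits <- hits[hits$length_aa >= min_aa, , drop = FALSE]
  hits <- hits[order(hits$start, hits$end, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Count ORFs per intergenic region
#'
#' Applies [find_orfs()] to each intergenic sequence and reports the total
#' ORF count and the count of short ORFs below a cutoff — short intergenic
#' ORFs are the ones that tend to show database matches, so they are
#' reported separately (default cutoff 30 aa).
#'
#' @param sequences Named character vector (or list) of intergenic
#'   nucleotide sequences, e.g. from [extract_intergenic_sequence()].
#' @param min_aa Detection floor passed to [find_orfs()].
#' @param short_aa_cutoff Report ORFs with `length_aa` strictly below this.
#' @param both_strands Passed to [find_orfs()].
#' @return Data frame with one row per input sequence: `id`, `n_orfs`,
#'   `n_short`.
#' @export
orf_report <- function(sequences, min_aa = 25, short_aa_cutoff = 30,
                       both_strands = TRUE) {
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  rows <- lapply(seq_along(sequences), function(i) {
    hits <- find_orfs(sequences[[i]], min_aa = min_aa,
                      both_strands = both_strands)
    data.frame(id = ids[i], n_orfs = nrow(hits),
               n_short = sum(hits$length_aa < short_aa_cutoff))
  })
  do.call(rbind, rows)
}
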