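# Protein alignments and parsimony-informative sites.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a protein multiple alignment
#'
#' Reads an aligned FASTA file into a character matrix (rows = sequences,
#' columns = alignment sites). Residues are upper-cased; sequence IDs are
#' the first whitespace-delimited token of each header.
#'
#' @param path path to an aligned FASTA file with at least two records.
#' @return a character matrix with unique rownames.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) < 2L)
    stop("alignment needs at least 2 sequences: ", path, call. = FALSE)
  w <- Biostrings::width(aa)
  if (length(unique(w)) != 1L)
    stop("sequences have unequal lengths (not an alignment): ", path,
         call. = FALSE)
  if (unique(w) == 0L) stop("alignment has zero columns: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate sequence IDs in ", path, call. = FALSE)
  m <- as.matrix(aa)
  m[] <- toupper(m)
  rownames(m) <- ids
  m
}

#' Write a protein alignment to FASTA
#'
#' @param aln a character matrix as returned by [read_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  seqs <- Biostrings::AAStringSet(apply(aln, 1L, paste, collapse = ""))
  names(seqs) <- rownames(aln)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Count parsimony-informative sites
#'
#' A column is parsimony-informative iff, counting only unambiguous
#' amino-acid residues, it contains at least two distinct residues each
#' occurring in at least two sequences. Gaps (`-`), `X` and any other
#' non-standard symbol are ignored when counting states.
#'
#' @param aln a character matrix alignment (rows = sequences).
#' @param gene_id optional identifier stored in the result.
#' @return a one-row data.frame with `gene_id`, `n_pis`, `n_columns`.
#' @examples
#' aln <- rbind(s1 = c("A", "A", "A"), s2 = c("A", "A", "A"),
#'              s3 = c("G", "A", "G"), s4 = c("G", "G", "-"))
#' count_pis(aln)$n_pis  # 1: only the first column is informative
#' @export
count_pis <- function(aln, gene_id = NA_character_) {
  stopifnot(is.matrix(aln), nrow(aln) >= 2L, ncol(aln) >= 1L)
  codes <- matrix(match(aln, AA20), nrow = nrow(aln))
  informative <- vapply(seq_len(ncol(codes)), function(j) {
    v <- codes[, j]
    v <- v[!is.na(v)]
    if (length(v) < 4L) return(FALSE)
    sum(tabulate(v, nbins = 20L) >= 2L) >= 2L
  }, logical(1L))
  data.frame(gene_id = gene_id, n_pis = sum(informative),
             n_columns = ncol(aln), stringsAsFactors = FALSE)
}
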