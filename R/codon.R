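# Codon-level utilities: translation, variable-site counts, and the
# codon tables shared by the selection tests and the simulator.

.BASES <- c("A", "C", "G", "T")

# codon -> amino acid lookup (standard genetic code, '*' for stops)
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc), names(gc))
})

codon_aa <- function(codons) unname(.codon_table[codons])

# split sequences into a codon matrix (rows = sequences, cols = codons)
codon_matrix <- function(sequences) {
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("ragged alignment")
  if (L %% 3L != 0L) stop("alignment length not a multiple of 3")
  n_codons <- L / 3L
  t(vapply(sequences, function(s) {
    substring(s, 3L * (seq_len(n_codons) - 1L) + 1L, 3L * seq_len(n_codons))
  }, character(n_codons)))
}

#' Translate an in-frame nucleotide alignment
#'
#' Standard genetic code; an internal stop codon is an error naming the
#' sequence and codon position (a coding MHC exon must translate cleanly).
#'
#' @param alleles Character vector of equal-length, in-frame nucleotide
#'   sequences (length a multiple of 3), optionally named.
#' @return Character vector of amino-acid sequences (one letter per
#'   codon), same names as the input.
#' @export
#' @examples
#' translate_alignment(c("ATGGCT"))  # "MA"
translate_alignment <- function(alleles) {
  cm <- codon_matrix(alleles)
  aa <- matrix(codon_aa(cm), nrow = nrow(cm))
  stops <- which(aa == "*", arr.ind = TRUE)
  if (nrow(stops) > 0L) {
    nm <- if (!is.null(names(alleles))) names(alleles)[stops[1, 1]] else
      paste0("sequence ", stops[1, 1])
    stop("internal stop codon in ", nm, " at codon ", stops[1, 2])
  }
  setNames(apply(aa, 1L, paste, collapse = ""), names(alleles))
}

#' Count variable sites in an alignment
#'
#' @param alignment Character vector of equal-length sequences
#'   (nucleotide or amino acid).
#' @param level \code{"nt"} or \code{"aa"}; with \code{"aa"} and
#'   nucleotide input, the alignment is translated first.
#' @return Integer count of columns with two or more observed states.
#' @export
#' @examples
#' variable_sites(c("AAT", "AGT"))            # 1
variable_sites <- function(alignment, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (length(alignment) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(alignment))) != 1L) stop("ragged alignment")
  if (level == "aa" && grepl("^[ACGT]+$", alignment[1]) &&
      nchar(alignment[1]) %% 3L == 0L)
    alignment <- translate_alignment(alignment)
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}
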