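# Built-in synthetic reference exon and default configuration.
#
# The reference exon shipped here is a SYNTHETIC 267 bp (89 codon) coding
# sequence with no internal stop codons. It stands in for the true DQB
# exon 2 reference so that every stage of the pipeline can run and be
# tested without restricted study data; analyses of real data should supply
# the genuine reference through the config.

.REF_EXON <- paste0(
  "GAAAGTGATCTAATTTACGCCGGATGCCTTTCTAGGATAGCGCGGCCCGTAGGAATCACG",
  "TATCGGTCTACATTAGACACCAGTCCGGCATGCTGCGTGATATCATCGGACTTCATTCGA",
  "TTGTCTAGTGATGAATCTATCCCGATAGATAGTTGTTGGCATCAGGAGATGCGAGTCCAC",
  "AGAAACCCGCACTCACGAGAGCACATCCATTCCGGTTACCCACCGGTCCATGACCGCCAT",
  "AGAATTACAGCCGCTGAGGTCGTATCG")

# Peptide-contact codon positions of the class II beta-1 domain, following
# the human DRB1-derived antigen-binding-site assignment (24 codons within
# the 89-codon exon). User-overridable via the config.
.DEFAULT_PABS <- c(9L, 11L, 13L, 26L, 28L, 30L, 32L, 37L, 38L, 47L,
                   56L, 57L, 60L, 61L, 65L, 67L, 68L, 70L, 71L, 72L,
                   74L, 76L, 78L, 81L)

#' Default pipeline configuration
#'
#' Returns the configuration list used throughout the pipeline: the
#' reference exon, the antigen-binding-site (pABS) codon partition, the
#' primer pair used for the amplification-bias analysis, and filtering
#' thresholds. The shipped reference exon and primer pair are synthetic
#' placeholders so the pipeline is runnable end-to-end without restricted
#' study data; real analyses should override them (see
#' \code{\link{read_config}}).
#'
#' @details The primer pair targets windows inside the exon delimiting a
#'   141 bp partial-exon amplicon (the design of the earlier partial-exon
#'   study this pipeline's bias analysis emulates): forward primer at exon
#'   positions 61-78 (sense strand), reverse primer the reverse complement
#'   of positions 184-201.
#'
#' @return A named list with components \code{reference_exon},
#'   \code{pabs_codons}, \code{primers} (list with \code{forward},
#'   \code{reverse}, and sense-strand site coordinates), and thresholds
#'   \code{max_artifact_count}, \code{max_nt_diff}, \code{min_individuals},
#'   \code{min_clones}.
#' @export
#' @examples
#' cfg <- default_config()
#' length(cfg$pabs_codons)  # 24 pABS codons of the 89-codon exon
default_config <- function() {
  list(
    reference_exon = .REF_EXON,
    pabs_codons = .DEFAULT_PABS,
    primers = list(
      forward = substr(.REF_EXON, 61L, 78L),
      reverse = revcomp(substr(.REF_EXON, 184L, 201L)),
      forward_start = 61L,
      reverse_start = 184L
    ),
    max_artifact_count = 2L,
    max_nt_diff = 2L,
    min_individuals = 2L,
    min_clones = 1L,
    trim_discard = "trailing"
  )
}

#' Read or write a pipeline configuration in YAML
#'
#' @param path Path to a YAML file.
#' @param config Configuration list (as from \code{\link{default_config}}).
#'
#' @details \code{read_config} fills unspecified fields from
#'   \code{default_config()}, so a config file only needs the fields that
#'   deviate from the defaults.
#'
#' @return \code{read_config} returns the completed configuration list;
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg$pabs_codons <- as.integer(cfg$pabs_codons)
  validate_partition(cfg$pabs_codons, n_codons = nchar(cfg$reference_exon) / 3L)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Codon partition into pABS and non-pABS codons
#'
#' Splits the 1-based codon indices of an in-frame exon into the putative
#' antigen-binding-site (pABS) codons and their complement. Codons are
#' attributed whole: a codon is either pABS or non-pABS, never split.
#'
#' @param pabs_codons Integer vector of 1-based pABS codon indices
#'   (default: the shipped 24-codon DRB1-derived assignment).
#' @param n_codons Total codon count of the exon (default 89).
#' @return List with integer vectors \code{pabs} and \code{non_pabs};
#'   together they partition \code{1:n_codons}.
#' @export
#' @examples
#' part <- codon_partition()
#' length(part$pabs); length(part$non_pabs)  # 24 and 65
codon_partition <- function(pabs_codons = default_config()$pabs_codons,
                            n_codons = 89L) {
  pabs_codons <- validate_partition(as.integer(pabs_codons), n_codons)
  list(pabs = sort(pabs_codons),
       non_pabs = setdiff(seq_len(n_codons), pabs_codons))
}

validate_partition <- function(pabs_codons, n_codons) {
  if (anyDuplicated(pabs_codons))
    stop("duplicated pABS codon indices")
  if (any(pabs_codons < 1L | pabs_codons > n_codons))
    stop("pABS codon indices must lie in 1..", n_codons)
  pabs_codons
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
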