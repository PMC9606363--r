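# Readers and writers for the formats the pipeline touches: FASTA clone
# libraries and allele catalogs (via Biostrings), CSV genotype / pedigree /
# microsatellite / colony tables, and Newick trees (via ape).

#' Read a clone library from FASTA
#'
#' One record per sequenced clone. The individual of origin is encoded in
#' the FASTA header as a delimited field; by default the first
#' pipe-delimited token is the individual ID and the full header is the
#' clone ID.
#'
#' @param path Path to a FASTA file.
#' @param id_delimiter Character separating header fields (default
#'   \code{"|"}).
#' @param id_field Which delimited field holds the individual ID
#'   (default 1).
#' @return A data frame of class \code{clone_records} with columns
#'   \code{clone_id}, \code{individual_id}, \code{sequence}, in file order.
#'   Empty files yield an empty data frame with a warning.
#' @export
read_clone_fasta <- function(path, id_delimiter = "|", id_field = 1L) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    warning("no FASTA records in ", path)
    return(clone_records(character(0), character(0), character(0)))
  }
  headers <- names(seqs)
  parts <- strsplit(headers, id_delimiter, fixed = TRUE)
  ind <- vapply(parts, function(p) {
    if (length(p) < id_field || !nzchar(p[id_field])) NA_character_
    else p[id_field]
  }, character(1))
  if (anyNA(ind)) {
    stop("FASTA headers lacking the individual-ID field: ",
         paste(headers[is.na(ind)], collapse = ", "))
  }
  clone_records(headers, ind, as.character(seqs))
}

clone_records <- function(clone_id, individual_id, sequence) {
  out <- data.frame(clone_id = clone_id, individual_id = individual_id,
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("clone_records", "data.frame")
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector of nucleotide sequences, or a
#'   clone-record / allele-catalog data frame (names are taken from
#'   \code{clone_id} resp. \code{name}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    nm <- if ("name" %in% names(sequences)) sequences$name else
      paste(sequences$individual_id, sequences$clone_id, sep = "|")
    if ("clone_id" %in% names(sequences)) nm <- sequences$clone_id
    sequences <- setNames(sequences$sequence, nm)
  }
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Trim an amplicon to the exon reading frame
#'
#' Locates the coding exon inside a (possibly longer) amplicon sequence and
#' returns exactly the exon-length coding substring. Placement is
#' alignment-free when the 15-mer flanks of the reference exon match
#' exactly; otherwise the best placement under a mismatch budget is found
#' with \code{Biostrings::matchPattern} (substitutions only, then
#' substitutions plus indels as a last resort).
#'
#' @param sequence Amplicon nucleotide string (A/C/G/T).
#' @param reference_exon Reference coding exon (default the shipped
#'   synthetic reference, 267 bp).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction between the
#'   reference exon and its placement (default 0.1).
#' @return The trimmed coding sequence, same length as
#'   \code{reference_exon}, with the 1-based placement offset in attribute
#'   \code{"offset"}.
#' @export
#' @examples
#' cfg <- default_config()
#' amp <- paste0("GATTACA", cfg$reference_exon, "TTGACA")
#' nchar(trim_to_reading_frame(amp))  # 267
trim_to_reading_frame <- function(sequence,
                                  reference_exon = default_config()$reference_exon,
                                  max_mismatch_frac = 0.1) {
  L <- nchar(reference_exon)
  if (nchar(sequence) < L)
    stop("sequence (", nchar(sequence), " nt) shorter than reference exon (",
         L, " nt); cannot trim")
  if (!grepl("^[ACGT]+$", sequence))
    stop("sequence contains characters outside A/C/G/T")
  left <- substr(reference_exon, 1L, 15L)
  right <- substr(reference_exon, L - 14L, L)
  start <- NA_integer_
  i <- regexpr(left, sequence, fixed = TRUE)
  if (i > 0L) {
    j <- regexpr(right, sequence, fixed = TRUE)
    if (j > 0L && (j + 15L - 1L) - i + 1L == L) start <- as.integer(i)
  }
  if (is.na(start)) {
    budget <- floor(max_mismatch_frac * L)
    hits <- Biostrings::matchPattern(reference_exon,
                                     Biostrings::DNAString(sequence),
                                     max.mismatch = budget,
                                     with.indels = FALSE)
    if (length(hits) == 0L)
      hits <- Biostrings::matchPattern(reference_exon,
                                       Biostrings::DNAString(sequence),
                                       max.mismatch = budget,
                                       with.indels = TRUE)
    if (length(hits) == 0L)
      stop("reference exon not found within mismatch budget; un-trimmable")
    if (any(BiocGenerics::width(hits) != L))
      stop("best placement of the reference exon introduces an internal gap")
    start <- BiocGenerics::start(hits)[1L]
  }
  out <- substr(sequence, start, start + L - 1L)
  attr(out, "offset") <- start
  out
}

#' Validate clone records against the pipeline invariants
#'
#' Checks sequence length (exactly the exon length), alphabet (A/C/G/T
#' only; ambiguity codes are rejected) and non-empty individual IDs.
#'
#' @param clones Clone-record data frame.
#' @param exon_length Required sequence length (default 267).
#' @return \code{clones}, invisibly, if valid; otherwise an error.
#' @export
validate_clones <- function(clones, exon_length = 267L) {
  bad_len <- nchar(clones$sequence) != exon_length
  if (any(bad_len))
    stop(sum(bad_len), " clone(s) not ", exon_length, " bp: ",
         paste(utils::head(clones$clone_id[bad_len], 5L), collapse = ", "))
  bad_alpha <- !grepl("^[ACGT]*$", clones$sequence)
  if (any(bad_alpha))
    stop("clone(s) with non-ACGT characters: ",
         paste(utils::head(clones$clone_id[bad_alpha], 5L), collapse = ", "))
  if (any(!nzchar(clones$individual_id)))
    stop("empty individual_id in clone records")
  invisible(clones)
}

#' Read and write genotype tables
#'
#' Genotype tables are UTF-8 CSV with one row per individual and columns
#' \code{individual_id}, \code{colony}, \code{alleles} (allele names joined
#' with \code{";"}) and \code{status} (\code{"ok"} or
#' \code{"multi_allele_flag"}).
#'
#' @param path CSV path.
#' @param genotypes Genotype data frame.
#' @return \code{read_genotypes}: the genotype data frame;
#'   \code{write_genotypes}: \code{path} invisibly.
#' @export
read_genotypes <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "colony", "alleles")
  if (!all(req %in% names(g)))
    stop("genotype CSV must have columns: ", paste(req, collapse = ", "))
  if (is.null(g$status)) {
    n <- lengths(allele_sets(g))
    g$status <- ifelse(n >= 1L & n <= 2L, "ok", "multi_allele_flag")
  }
  g
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(genotypes, path) {
  write.csv(genotypes, path, row.names = FALSE)
  invisible(path)
}

#' Allele sets of a genotype table
#'
#' @param genotypes Genotype data frame (see \code{\link{read_genotypes}}).
#' @return Named list mapping individual ID to its character vector of
#'   allele names.
#' @export
allele_sets <- function(genotypes) {
  out <- strsplit(genotypes$alleles, ";", fixed = TRUE)
  out <- lapply(out, function(a) a[nzchar(a)])
  names(out) <- genotypes$individual_id
  out
}

#' Read a mother-pup pedigree table
#'
#' CSV with columns \code{mother_id}, \code{pup_id}, \code{colony}. Each
#' pup may appear at most once and never as its own mother.
#'
#' @param path CSV path.
#' @return Pedigree data frame.
#' @export
read_pedigree <- function(path) {
  p <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("mother_id", "pup_id")
  if (!all(req %in% names(p)))
    stop("pedigree CSV must have columns: ", paste(req, collapse = ", "))
  if (any(p$mother_id == p$pup_id)) stop("pedigree row with mother_id == pup_id")
  if (anyDuplicated(p$pup_id)) stop("pup appearing more than once in pedigree")
  p
}

#' Read and write a microsatellite genotype table
#'
#' Long-format UTF-8 CSV: one row per individual and locus, columns
#' \code{individual_id}, \code{locus}, \code{allele1}, \code{allele2}.
#' Missing genotypes are empty cells (both alleles missing together).
#'
#' @param path CSV path.
#' @param microsats Microsatellite data frame.
#' @return \code{read_microsats}: the data frame; \code{write_microsats}:
#'   \code{path} invisibly.
#' @export
read_microsats <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(allele1 = "character", allele2 = "character"))
  req <- c("individual_id", "locus", "allele1", "allele2")
  if (!all(req %in% names(m)))
    stop("microsatellite CSV must have columns: ", paste(req, collapse = ", "))
  m$allele1[!nzchar(m$allele1)] <- NA_character_
  m$allele2[!nzchar(m$allele2)] <- NA_character_
  half <- xor(is.na(m$allele1), is.na(m$allele2))
  if (any(half))
    stop("half-missing diploid genotypes at rows: ",
         paste(utils::head(which(half), 5L), collapse = ", "))
  m
}

#' @rdname read_microsats
#' @export
write_microsats <- function(microsats, path) {
  write.csv(microsats, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a results bundle to a directory
#'
#' Writes each table as CSV, each tree as Newick, an optional allele
#' catalog as FASTA, and a JSON run manifest recording the seed and a hash
#' of the configuration.
#'
#' @param tables Named list of data frames.
#' @param trees Named list of \code{phylo} objects.
#' @param outdir Output directory (created if absent).
#' @param catalog Optional allele catalog to write as FASTA.
#' @param config Configuration list recorded (hashed) in the manifest.
#' @param seed Seed recorded in the manifest.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(tables = list(), trees = list(), outdir,
                          catalog = NULL, config = default_config(),
                          seed = NA_integer_) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], f, row.names = FALSE)
    written <- c(written, f)
  }
  for (nm in names(trees)) {
    f <- file.path(outdir, paste0(nm, ".nwk"))
    ape::write.tree(trees[[nm]], file = f)
    written <- c(written, f)
  }
  if (!is.null(catalog)) {
    f <- file.path(outdir, "allele_catalog.fasta")
    write_fasta(setNames(catalog$sequence, catalog$name), f)
    written <- c(written, f)
  }
  manifest <- list(
    seed = seed,
    config_hash = config_hash(config),
    files = basename(written),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  f <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, f))
}

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  # small polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
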