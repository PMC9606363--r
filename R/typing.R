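# Clone typing: variant tallies, artifact filtering, allele calling,
# genotype assignment and Mendelian QC.

#' Tally distinct sequence variants in a clone library
#'
#' @param clones Clone-record data frame (all sequences the same length).
#' @return Data frame (class \code{variant_tally}) with one row per
#'   distinct sequence: \code{sequence}, \code{total_count},
#'   \code{n_individuals}, and a list column \code{per_individual}
#'   (named integer vector of clone counts per individual). Rows are
#'   ordered by decreasing \code{total_count}, ties broken lexicographically
#'   by sequence.
#' @export
tally_variants <- function(clones) {
  if (length(unique(nchar(clones$sequence))) > 1L)
    stop("clone sequences are not all the same length")
  split_ind <- split(clones$individual_id, clones$sequence)
  seqs <- names(split_ind)
  per <- lapply(split_ind, function(x) {
    t <- table(x)
    setNames(as.integer(t), names(t))
  })
  total <- vapply(per, sum, integer(1))
  o <- order(-total, seqs)
  out <- data.frame(sequence = seqs[o], total_count = unname(total[o]),
                    n_individuals = vapply(per[o], length, integer(1)),
                    stringsAsFactors = FALSE)
  out$per_individual <- unname(per[o])
  rownames(out) <- NULL
  class(out) <- c("variant_tally", "data.frame")
  out
}

#' Hamming distance between equal-length strings
#'
#' @param a,b Character strings of equal length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Filter putative PCR/cloning artifacts from variant tallies
#'
#' A low-count variant is classified as an artifact and discarded iff its
#' total clone count is at most \code{max_artifact_count} and it lies
#' within \code{max_nt_diff} nucleotides (Hamming) of a strictly more
#' common retained sequence. Candidates are examined from most to least
#' common so that chains of artifacts collapse onto the true allele they
#' derive from. Low-count variants with no near neighbour are retained
#' and flagged rather than discarded.
#'
#' With \code{doubleton_same_individual_only = TRUE}, a variant
#' represented by exactly two clones is only discardable when both clones
#' come from the same individual (the pattern observed in the study data
#' this rule derives from). The default leaves this off: identical PCR
#' point errors can arise independently in two individuals, and such
#' coincidences should not be promoted to alleles.
#'
#' @param tallies Output of \code{\link{tally_variants}}.
#' @param max_artifact_count Maximum clone count of a discardable variant
#'   (default 2).
#' @param max_nt_diff Maximum Hamming distance to a strictly more common
#'   retained sequence (default 2).
#' @param doubleton_same_individual_only Restrict discardable doubletons
#'   to single-individual ones (default \code{FALSE}).
#' @return List with data frames \code{retained} (with logical column
#'   \code{low_count_flag}) and \code{discarded}; together they partition
#'   the input rows.
#' @export
filter_artifacts <- function(tallies, max_artifact_count = 2L,
                             max_nt_diff = 2L,
                             doubleton_same_individual_only = FALSE) {
  n <- nrow(tallies)
  if (n == 0L)
    return(list(retained = cbind(tallies, low_count_flag = logical(0)),
                discarded = tallies))
  keep <- rep(TRUE, n)
  # rows already ordered by decreasing count; candidates in that order
  for (i in seq_len(n)) {
    ct <- tallies$total_count[i]
    if (ct > max_artifact_count) next
    if (doubleton_same_individual_only && ct == 2L &&
        tallies$n_individuals[i] > 1L) next
    ref_idx <- which(keep & tallies$total_count > ct)
    ref_idx <- setdiff(ref_idx, i)
    if (length(ref_idx) == 0L) next
    d <- vapply(tallies$sequence[ref_idx], hamming, integer(1),
                b = tallies$sequence[i])
    if (any(d <= max_nt_diff)) keep[i] <- FALSE
  }
  retained <- tallies[keep, , drop = FALSE]
  retained$low_count_flag <- retained$total_count <= max_artifact_count
  discarded <- tallies[!keep, , drop = FALSE]
  rownames(retained) <- rownames(discarded) <- NULL
  list(retained = retained, discarded = discarded)
}

#' Call alleles from retained variant tallies
#'
#' A retained variant is promoted to an allele when it was cloned from at
#' least \code{min_individuals} individuals and is represented by at least
#' \code{min_clones} clone sequences. Alleles are named
#' \code{<prefix>01}, \code{<prefix>02}, ... in order of decreasing clone
#' count (ties broken lexicographically by sequence).
#'
#' @param retained \code{retained} component of
#'   \code{\link{filter_artifacts}}.
#' @param min_individuals Minimum number of distinct individuals
#'   (default 2).
#' @param min_clones Minimum clone count (default 1).
#' @param prefix Allele name prefix (default \code{"ArGa-DQB*"}).
#' @return Data frame of class \code{allele_catalog}: \code{name},
#'   \code{sequence}, \code{clone_count}, \code{individual_count}; the
#'   mean clone count per allele is in attribute
#'   \code{"mean_clones_per_allele"}. Empty input yields an empty catalog
#'   with a warning.
#' @export
call_alleles <- function(retained, min_individuals = 2L, min_clones = 1L,
                         prefix = "ArGa-DQB*") {
  sel <- retained$n_individuals >= min_individuals &
    retained$total_count >= min_clones
  hits <- retained[sel, , drop = FALSE]
  if (nrow(hits) == 0L) {
    warning("no variants meet the allele-calling thresholds; empty catalog")
    out <- data.frame(name = character(0), sequence = character(0),
                      clone_count = integer(0), individual_count = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("allele_catalog", "data.frame")
    return(out)
  }
  o <- order(-hits$total_count, hits$sequence)
  hits <- hits[o, , drop = FALSE]
  out <- data.frame(
    name = sprintf("%s%02d", prefix, seq_len(nrow(hits))),
    sequence = hits$sequence,
    clone_count = hits$total_count,
    individual_count = hits$n_individuals,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mean_clones_per_allele") <- mean(out$clone_count)
  class(out) <- c("allele_catalog", "data.frame")
  out
}

#' @export
print.allele_catalog <- function(x, ...) {
  cat("Allele catalog:", nrow(x), "alleles,",
      sum(x$clone_count), "clones (mean",
      format(attr(x, "mean_clones_per_allele"), digits = 4),
      "clones per allele)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Assign per-individual genotypes from the catalog
#'
#' An individual's allele set is the set of catalog alleles observed in at
#' least one of its retained clones. Individuals with more than two
#' alleles are retained but flagged (\code{status = "multi_allele_flag"});
#' individuals with no retained catalog clone are reported untyped.
#'
#' @param catalog Allele catalog from \code{\link{call_alleles}}.
#' @param clones Clone-record data frame (typically all clones; clones
#'   whose sequence is not in the catalog are ignored).
#' @param colonies Optional named vector or data frame
#'   (\code{individual_id}, \code{colony}) giving colony labels.
#' @return List with \code{genotypes} (data frame: \code{individual_id},
#'   \code{colony}, \code{alleles}, \code{status}) and \code{untyped}
#'   (character vector of individuals without any catalog clone).
#' @export
assign_genotypes <- function(catalog, clones, colonies = NULL) {
  name_of <- setNames(catalog$name, catalog$sequence)
  inds <- unique(clones$individual_id)
  col_of <- NULL
  if (!is.null(colonies)) {
    if (is.data.frame(colonies))
      col_of <- setNames(colonies$colony, colonies$individual_id)
    else col_of <- colonies
  }
  rows <- lapply(inds, function(ind) {
    sq <- clones$sequence[clones$individual_id == ind]
    al <- sort(unique(name_of[sq[sq %in% names(name_of)]]))
    data.frame(individual_id = ind,
               colony = if (is.null(col_of)) NA_character_ else
                 unname(col_of[ind]),
               alleles = paste(al, collapse = ";"),
               status = if (length(al) == 0L) "untyped" else
                 if (length(al) <= 2L) "ok" else "multi_allele_flag",
               stringsAsFactors = FALSE)
  })
  genotypes <- do.call(rbind, rows)
  untyped <- genotypes$individual_id[genotypes$status == "untyped"]
  if (length(untyped))
    message(length(untyped), " individual(s) untyped: ",
            paste(untyped, collapse = ", "))
  list(genotypes = genotypes[genotypes$status != "untyped", , drop = FALSE],
       untyped = untyped)
}

#' Mendelian compatibility of mother-pup pairs
#'
#' A pair is compatible when the two allele sets intersect. Pairs with an
#' untyped member are excluded from the summary fraction and reported.
#'
#' @param genotypes Genotype data frame.
#' @param pedigree Pedigree data frame (\code{mother_id}, \code{pup_id}).
#' @return List with \code{pairs} (data frame: \code{mother_id},
#'   \code{pup_id}, \code{compatible}), \code{fraction} (compatible /
#'   evaluated), \code{n_compatible}, \code{n_evaluated} and
#'   \code{excluded} (pair indices with an untyped member).
#' @export
check_mendelian <- function(genotypes, pedigree) {
  sets <- allele_sets(genotypes)
  ok <- pedigree$mother_id %in% names(sets) & pedigree$pup_id %in% names(sets)
  if (any(!ok))
    message(sum(!ok), " pair(s) excluded (untyped member)")
  pairs <- pedigree[ok, c("mother_id", "pup_id"), drop = FALSE]
  pairs$compatible <- mapply(function(m, p) {
    length(intersect(sets[[m]], sets[[p]])) > 0L
  }, pairs$mother_id, pairs$pup_id, USE.NAMES = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs,
       fraction = if (nrow(pairs)) mean(pairs$compatible) else NA_real_,
       n_compatible = sum(pairs$compatible),
       n_evaluated = nrow(pairs),
       excluded = which(!ok))
}

#' Summary statistics of a typed clone dataset
#'
#' @param retained \code{retained} component of
#'   \code{\link{filter_artifacts}}.
#' @param catalog Allele catalog.
#' @return List with \code{n_clones_retained},
#'   \code{n_individuals}, \code{mean_clones_per_individual},
#'   \code{n_alleles} and \code{mean_clones_per_allele}.
#' @export
typing_summary <- function(retained, catalog) {
  per_ind <- Reduce(function(a, b) {
    all_names <- union(names(a), names(b))
    setNames(ifelse(is.na(a[all_names]), 0L, a[all_names]) +
               ifelse(is.na(b[all_names]), 0L, b[all_names]), all_names)
  }, retained$per_individual, integer(0))
  list(n_clones_retained = sum(retained$total_count),
       n_individuals = length(per_ind),
       mean_clones_per_individual = mean(per_ind),
       n_alleles = nrow(catalog),
       mean_clones_per_allele = attr(catalog, "mean_clones_per_allele"))
}
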