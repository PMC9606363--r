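# Primer-binding-site mismatch analysis and bootstrap allele-detection
# curves: how many alleles a primer pair would recover as a function of
# sample size and of the tolerated number of primer-template mismatches.

#' Count primer-template mismatches for an allele
#'
#' The forward primer is compared with its sense-strand window and the
#' reverse primer is reverse-complemented and compared with its
#' sense-strand window; the result combines the two site counts
#' (\code{mode = "sum"}, default) or takes the larger one
#' (\code{mode = "max"}). Windows are taken at the configured coordinates
#' when the primer set carries them, otherwise at the minimum-Hamming
#' placement over all offsets.
#'
#' @param allele Allele nucleotide sequence.
#' @param primer_set List with \code{forward} and \code{reverse} (both as
#'   synthesized, 5'->3') and optionally 1-based sense-strand site starts
#'   \code{forward_start} and \code{reverse_start}.
#' @param mode \code{"sum"} or \code{"max"}.
#' @return Total mismatch count (integer).
#' @export
primer_mismatch_count <- function(allele, primer_set, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  fwd <- primer_set$forward
  rev_sense <- revcomp(primer_set$reverse)
  site <- function(primer, start) {
    L <- nchar(primer)
    if (L > nchar(allele)) stop("primer longer than sequence")
    if (!is.null(start))
      return(hamming(substr(allele, start, start + L - 1L), primer))
    offs <- seq_len(nchar(allele) - L + 1L)
    min(vapply(offs, function(o) {
      hamming(substr(allele, o, o + L - 1L), primer)
    }, integer(1)))
  }
  mf <- site(fwd, primer_set$forward_start)
  mr <- site(rev_sense, primer_set$reverse_start)
  if (mode == "sum") mf + mr else max(mf, mr)
}

#' Compare primer mismatches between shared and study-unique alleles
#'
#' Mean primer-binding-site mismatch counts for the alleles shared with an
#' earlier study versus those unique to the current catalog, the
#' unique/shared ratio, and a per-allele table annotated with allele
#' frequency (clone-count share) for plotting.
#'
#' @param catalog Allele catalog (\code{name}, \code{sequence}, and
#'   optionally \code{clone_count} for the frequency annotation).
#' @param shared_allele_names Names of the catalog alleles also found by
#'   the earlier study (subset of \code{catalog$name}).
#' @param primer_set Primer set (see
#'   \code{\link{primer_mismatch_count}}).
#' @param mode Mismatch combination mode, forwarded.
#' @return List with \code{mean_shared}, \code{mean_unique},
#'   \code{ratio} (unique/shared; \code{NA} when a group is empty or the
#'   shared mean is 0) and \code{per_allele} (data frame: \code{name},
#'   \code{group}, \code{mismatches}, \code{freq}).
#' @export
compare_mismatch_groups <- function(catalog, shared_allele_names, primer_set,
                                    mode = "sum") {
  if (!all(shared_allele_names %in% catalog$name))
    stop("shared_allele_names not all in catalog")
  mm <- vapply(catalog$sequence, primer_mismatch_count, numeric(1),
               primer_set = primer_set, mode = mode, USE.NAMES = FALSE)
  grp <- ifelse(catalog$name %in% shared_allele_names, "shared", "unique")
  freq <- if (!is.null(catalog$clone_count))
    catalog$clone_count / sum(catalog$clone_count) else NA_real_
  per_allele <- data.frame(name = catalog$name, group = grp,
                           mismatches = mm, freq = freq,
                           stringsAsFactors = FALSE)
  ms <- if (any(grp == "shared")) mean(mm[grp == "shared"]) else NA_real_
  mu <- if (any(grp == "unique")) mean(mm[grp == "unique"]) else NA_real_
  ratio <- if (is.na(ms) || is.na(mu) || ms == 0) NA_real_ else mu / ms
  list(mean_shared = ms, mean_unique = mu, ratio = ratio,
       per_allele = per_allele)
}

#' Bootstrap allele-detection curves under mismatch thresholds
#'
#' For each sample size n and mismatch threshold t: draw n individuals
#' with replacement \code{n_rep} times and count, per replicate, the
#' distinct catalog alleles present in the drawn genotypes whose
#' primer-binding-site mismatch count is at most t. The sampling unit is
#' the individual genotype (both alleles enter together); flagged
#' multi-allele individuals contribute all their alleles.
#'
#' @param genotypes Genotype data frame.
#' @param catalog Allele catalog.
#' @param primer_set Primer set (see
#'   \code{\link{primer_mismatch_count}}).
#' @param thresholds Mismatch thresholds (default 1:6).
#' @param n_range Sample sizes (default 1 to the number of genotyped
#'   individuals).
#' @param n_rep Bootstrap replicates per cell (default 999).
#' @param seed Seed.
#' @param mode Mismatch combination mode, forwarded.
#' @return Data frame of class \code{detection_curve}: \code{n},
#'   \code{threshold}, \code{mean_detected}, \code{sd_detected} (the
#'   bootstrap standard deviation across replicates).
#' @export
allele_detection_curve <- function(genotypes, catalog, primer_set,
                                   thresholds = 1:6, n_range = NULL,
                                   n_rep = 999L, seed = 1L, mode = "sum") {
  sets <- allele_sets(genotypes)
  if (length(sets) == 0L) stop("empty genotype set")
  if (is.null(n_range)) n_range <- seq_len(length(sets))
  mm <- vapply(catalog$sequence, primer_mismatch_count, numeric(1),
               primer_set = primer_set, mode = mode, USE.NAMES = FALSE)
  names(mm) <- catalog$name
  # incidence matrix: individuals x alleles
  inc <- t(vapply(sets, function(a) catalog$name %in% a,
                  logical(nrow(catalog))))
  inc <- matrix(inc, nrow = length(sets),
                dimnames = list(names(sets), catalog$name))
  set.seed(seed)
  n_ind <- nrow(inc)
  out <- list()
  for (n in n_range) {
    draws <- matrix(sample.int(n_ind, n * n_rep, replace = TRUE),
                    nrow = n, ncol = n_rep)
    # per replicate, which alleles are present in the drawn genotypes
    present <- vapply(seq_len(n_rep), function(b) {
      colSums(inc[draws[, b], , drop = FALSE]) > 0L
    }, logical(ncol(inc)))
    present <- matrix(present, nrow = ncol(inc))
    for (t in thresholds) {
      within <- mm <= t
      counts <- colSums(present & within)
      out[[length(out) + 1L]] <- data.frame(
        n = n, threshold = t,
        mean_detected = mean(counts), sd_detected = sd(counts))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("detection_curve", "data.frame")
  res
}
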