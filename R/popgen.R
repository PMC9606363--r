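# Colony-level population genetics: Weir-Cockerham theta with permutation
# test, per-population diversity summaries, Queller-Goodnight pairwise
# relatedness and standardised multilocus heterozygosity.
#
# Internal genotype representation for these estimators: a list of loci,
# each a 2-column character matrix of allele labels (rows = individuals,
# NA = missing), plus a population label per individual.

# convert the package's tables to the internal per-locus representation
as_locus_list <- function(x, individuals = NULL) {
  if (is.data.frame(x) && all(c("locus", "allele1") %in% names(x))) {
    if (is.null(individuals)) individuals <- unique(x$individual_id)
    loci <- split(x, x$locus)
    lapply(loci, function(d) {
      m <- matrix(NA_character_, nrow = length(individuals), ncol = 2L,
                  dimnames = list(individuals, NULL))
      idx <- match(d$individual_id, individuals)
      keep <- !is.na(idx)
      m[idx[keep], 1L] <- d$allele1[keep]
      m[idx[keep], 2L] <- d$allele2[keep]
      m
    })
  } else if (is.data.frame(x) && "alleles" %in% names(x)) {
    # MHC genotype table: one locus; only unflagged (1-2 allele) genotypes
    # are diploid-interpretable, homozygotes doubled
    g <- x[x$status == "ok", , drop = FALSE]
    sets <- allele_sets(g)
    m <- t(vapply(sets, function(a) {
      if (length(a) == 1L) c(a, a) else a[1:2]
    }, character(2)))
    rownames(m) <- g$individual_id
    list(MHC = m)
  } else stop("unrecognised genotype input")
}

pop_of <- function(x, locus_list) {
  inds <- rownames(locus_list[[1]])
  if (is.data.frame(x) && !is.null(x$colony))
    setNames(x$colony, x$individual_id)[inds]
  else if (!is.data.frame(x)) x[inds]
  else stop("pop_labels required (no colony column in genotype input)")
}

# Weir-Cockerham (1984) variance components for one locus and one allele.
# Returns c(a, b, c): among-population, among-individual-within-population
# and within-individual components.
wc_components <- function(geno, pops, allele) {
  typed <- !is.na(geno[, 1])
  geno <- geno[typed, , drop = FALSE]
  pops <- pops[typed]
  pop_ids <- unique(pops)
  r <- length(pop_ids)
  n_i <- vapply(pop_ids, function(p) sum(pops == p), numeric(1))
  if (any(n_i == 0) || r < 2L) return(c(0, 0, 0))
  p_i <- vapply(pop_ids, function(p) {
    g <- geno[pops == p, , drop = FALSE]
    mean(g == allele)
  }, numeric(1))
  h_i <- vapply(pop_ids, function(p) {
    g <- geno[pops == p, , drop = FALSE]
    mean(xor(g[, 1] == allele, g[, 2] == allele))
  }, numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

#' Multi-locus Weir-Cockerham FST (theta)
#'
#' Variance-components estimator of FST for diploid genotypes, combined
#' across alleles and loci as the ratio of summed components
#' (ratio-of-sums, the standard multi-locus estimator). For MHC genotype
#' tables, individuals flagged as carrying more than two alleles are
#' excluded (diploid statistics are undefined for them).
#'
#' @param genotypes Either a long-format microsatellite data frame (see
#'   \code{\link{read_microsats}}) or an MHC genotype data frame.
#' @param pop_labels Population label per individual: a named vector, or
#'   \code{NULL} to use the \code{colony} column of an MHC genotype table.
#' @return Theta (scalar); \code{NA} with a warning when the dataset is
#'   monomorphic. Component sums are in attribute \code{"components"}.
#' @export
weir_cockerham_fst <- function(genotypes, pop_labels = NULL) {
  loci <- as_locus_list(genotypes)
  pops <- if (is.null(pop_labels)) pop_of(genotypes, loci) else
    pop_labels[rownames(loci[[1]])]
  if (length(unique(pops)) < 2L) stop("need at least 2 populations")
  tot <- c(0, 0, 0)
  for (geno in loci) {
    alleles <- unique(as.vector(geno))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) < 2L) next
    for (al in alleles) tot <- tot + wc_components(geno, pops, al)
  }
  denom <- sum(tot)
  if (denom == 0) {
    warning("monomorphic dataset; theta undefined")
    return(NA_real_)
  }
  theta <- tot[1] / denom
  attr(theta, "components") <- c(a = tot[1], b = tot[2], c = tot[3])
  theta
}

#' Permutation test of population differentiation
#'
#' Permutes individuals' population labels and recomputes theta;
#' \code{p = (1 + #[theta_perm >= theta_obs]) / (n_perm + 1)}.
#'
#' @inheritParams weir_cockerham_fst
#' @param n_perm Number of permutations (default 9999).
#' @param seed Seed for the permutations.
#' @return List with \code{theta}, \code{p} and \code{n_perm}.
#' @export
fst_permutation_test <- function(genotypes, pop_labels = NULL,
                                 n_perm = 9999L, seed = 1L) {
  loci <- as_locus_list(genotypes)
  inds <- rownames(loci[[1]])
  pops <- if (is.null(pop_labels)) pop_of(genotypes, loci) else
    pop_labels[inds]
  theta_of <- function(pp) {
    tot <- c(0, 0, 0)
    for (geno in loci) {
      alleles <- unique(as.vector(geno)); alleles <- alleles[!is.na(alleles)]
      if (length(alleles) < 2L) next
      for (al in alleles) tot <- tot + wc_components(geno, pp, al)
    }
    if (sum(tot) == 0) 0 else tot[1] / sum(tot)
  }
  obs <- theta_of(pops)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) theta_of(sample(pops)),
                 numeric(1))
  list(theta = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Per-population diversity summary
#'
#' Sample size, private alleles, rarefied allelic richness (hypergeometric
#' expectation at the smallest population's gene count), observed
#' heterozygosity, Nei's unbiased expected heterozygosity and
#' \code{Fis = 1 - Ho/He}, per population and locus-averaged.
#'
#' @inheritParams weir_cockerham_fst
#' @return Data frame with one row per population: \code{population},
#'   \code{n}, \code{private_alleles}, \code{allelic_richness}, \code{Ho},
#'   \code{He}, \code{Fis} (locus means; \code{He}/\code{Fis} are
#'   \code{NA} for single-individual populations).
#' @export
diversity_summary <- function(genotypes, pop_labels = NULL) {
  loci <- as_locus_list(genotypes)
  pops <- if (is.null(pop_labels)) pop_of(genotypes, loci) else
    pop_labels[rownames(loci[[1]])]
  pop_ids <- unique(pops)
  # rarefaction size: smallest typed gene count over populations and loci
  gmin <- min(vapply(loci, function(geno) {
    min(vapply(pop_ids, function(p) {
      2L * sum(!is.na(geno[pops == p, 1L]))
    }, integer(1)))
  }, integer(1)))
  rows <- lapply(pop_ids, function(p) {
    per_locus <- vapply(loci, function(geno) {
      gp <- geno[pops == p, , drop = FALSE]
      gp <- gp[!is.na(gp[, 1]), , drop = FALSE]
      others <- geno[pops != p, , drop = FALSE]
      n <- nrow(gp)
      if (n == 0L) return(c(NA, NA, NA, NA, NA))
      counts <- table(as.vector(gp))
      priv <- sum(!names(counts) %in% as.vector(others))
      # hypergeometric rarefied richness at gmin genes
      Ntot <- sum(counts)
      rich <- sum(1 - choose(Ntot - counts, min(gmin, Ntot)) /
                    choose(Ntot, min(gmin, Ntot)))
      ho <- mean(gp[, 1] != gp[, 2])
      if (n < 2L) return(c(priv, rich, ho, NA, NA))
      pfreq <- counts / Ntot
      he <- (Ntot / (Ntot - 1)) * (1 - sum(pfreq^2))
      fis <- if (he > 0) 1 - ho / he else NA
      c(priv, rich, ho, he, fis)
    }, numeric(5))
    data.frame(population = p,
               n = sum(pops == p),
               private_alleles = sum(per_locus[1, ], na.rm = TRUE),
               allelic_richness = mean(per_locus[2, ], na.rm = TRUE),
               Ho = mean(per_locus[3, ], na.rm = TRUE),
               He = mean(per_locus[4, ]),
               Fis = mean(per_locus[5, ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Queller-Goodnight pairwise relatedness
#'
#' Locus-wise Queller-Goodnight estimator with reference allele
#' frequencies computed over all individuals (the focal pair included);
#' numerators and denominators are summed over loci before the ratio is
#' taken, and the final value is the mean of the two directional
#' estimates.
#'
#' @param microsats Long-format microsatellite data frame.
#' @return Symmetric matrix of pairwise r (class
#'   \code{relatedness_matrix}); the diagonal is \code{NA}, as is any pair
#'   with no overlapping typed loci.
#' @export
queller_goodnight_r <- function(microsats) {
  loci <- as_locus_list(microsats)
  inds <- rownames(loci[[1]])
  n <- length(inds)
  freqs <- lapply(loci, function(geno) {
    t <- table(as.vector(geno))
    t / sum(t)
  })
  num <- den <- matrix(0, n, n)  # directional: row = focal x
  for (l in seq_along(loci)) {
    geno <- loci[[l]]; f <- freqs[[l]]
    typed <- !is.na(geno[, 1])
    for (x in which(typed)) {
      a <- geno[x, 1]; b <- geno[x, 2]
      pa <- f[[a]]; pb <- f[[b]]
      for (y in which(typed)) {
        if (x == y) next
        cdy <- geno[y, ]
        shared <- 0.5 * (mean(a == cdy) + mean(b == cdy)) * 2
        # shared = 0.5*(I(a==c)+I(a==d)) + 0.5*(I(b==c)+I(b==d))
        num[x, y] <- num[x, y] + shared - pa - pb
        den[x, y] <- den[x, y] + 1 + (a == b) - pa - pb
      }
    }
  }
  rdir <- num / den
  rdir[den == 0] <- NA
  r <- (rdir + t(rdir)) / 2
  diag(r) <- NA
  dimnames(r) <- list(inds, inds)
  class(r) <- c("relatedness_matrix", class(r))
  r
}

#' Standardised multilocus heterozygosity (sMLH)
#'
#' For individual i, the proportion of its typed loci that are
#' heterozygous, divided by the mean over those same loci of the
#' population mean heterozygosity. With complete data the population mean
#' of sMLH is exactly 1.
#'
#' @param microsats Long-format microsatellite data frame.
#' @return Named numeric vector of per-individual sMLH (\code{NA} for
#'   individuals typed at no locus).
#' @export
smlh <- function(microsats) {
  loci <- as_locus_list(microsats)
  inds <- rownames(loci[[1]])
  het <- vapply(loci, function(geno) {
    ifelse(is.na(geno[, 1]), NA, geno[, 1] != geno[, 2])
  }, logical(length(inds)))
  het <- matrix(het, nrow = length(inds),
                dimnames = list(inds, names(loci)))
  locus_mean <- colMeans(het, na.rm = TRUE)
  out <- vapply(seq_along(inds), function(i) {
    typed <- !is.na(het[i, ])
    if (!any(typed)) return(NA_real_)
    mean(het[i, typed]) / mean(locus_mean[typed])
  }, numeric(1))
  setNames(out, inds)
}
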