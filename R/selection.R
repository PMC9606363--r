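# Codon-partitioned selection analysis: mean pairwise amino-acid
# divergence, modified Nei-Gojobori dN/dS with Jukes-Cantor correction,
# codon-based Z-tests with bootstrap variances, and the paired region
# contrast. The per-codon bookkeeping (potential sites, pathway-averaged
# observed differences) is precomputed per codon pair so that the
# column-bootstrap reduces to matrix sums.

# ---- potential synonymous sites per codon (modified NG, weight R) -------

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# S-site content of one codon: at each position, the weighted fraction of
# non-stop single-base changes that are synonymous (transition weight R,
# transversion weight 1); positions sum to <= 1 each, codon total in [0,3]
codon_syn_sites <- function(codon, R) {
  b <- strsplit(codon, "", fixed = TRUE)[[1]]
  aa0 <- codon_aa(codon)
  s <- 0
  for (p in 1:3) {
    wsum <- 0; wsyn <- 0
    for (alt in setdiff(.BASES, b[p])) {
      nb <- b; nb[p] <- alt
      cand <- paste(nb, collapse = "")
      if (codon_aa(cand) == "*") next
      w <- if (is_transition(b[p], alt)) R else 1
      wsum <- wsum + w
      if (codon_aa(cand) == aa0) wsyn <- wsyn + w
    }
    if (wsum > 0) s <- s + wsyn / wsum
  }
  s
}

# cache of S-sites for all 61 sense codons at a given R
syn_site_table <- function(R) {
  key <- sprintf("R=%.6g", R)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  codons <- names(.codon_table)[.codon_table != "*"]
  tab <- setNames(vapply(codons, codon_syn_sites, numeric(1), R = R), codons)
  .ng_cache[[key]] <- tab
  tab
}
.ng_cache <- new.env(parent = emptyenv())

# ---- observed differences: equal-weight average over minimal pathways ---

# all orderings of the differing positions define the minimal substitution
# pathways; pathways passing through a stop codon are excluded (unless all
# do, in which case all are used); returns c(syn, nonsyn)
codon_path_diffs <- function(c1, c2) {
  b1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  b2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  diffpos <- which(b1 != b2)
  k <- length(diffpos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1L) list(diffpos) else
    lapply(asplit(perms_of(k), 1L), function(o) diffpos[o])
  paths <- lapply(perms, function(ord) {
    cur <- b1
    steps <- matrix("", nrow = length(ord), ncol = 2L)
    valid <- TRUE
    for (s in seq_along(ord)) {
      nxt <- cur; nxt[ord[s]] <- b2[ord[s]]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (codon_aa(to) == "*") valid <- FALSE
      steps[s, ] <- c(from, to)
      cur <- nxt
    }
    list(steps = steps, valid = valid)
  })
  use <- Filter(function(p) p$valid, paths)
  if (length(use) == 0L) use <- paths
  counts <- vapply(use, function(p) {
    syn <- sum(codon_aa(p$steps[, 1]) == codon_aa(p$steps[, 2]))
    c(syn, nrow(p$steps) - syn)
  }, numeric(2))
  c(syn = mean(counts[1, ]), nonsyn = mean(counts[2, ]))
}

perms_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- perms_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# pathway-diff cache keyed by codon pair
codon_pair_diffs <- function(c1, c2) {
  key <- if (c1 < c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- .pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- codon_path_diffs(c1, c2)
  .pair_cache[[key]] <- val
  val
}
.pair_cache <- new.env(parent = emptyenv())

#' Jukes-Cantor distance correction
#'
#' \code{d = -(3/4) log(1 - (4/3) p)}; proportions of 0.75 or more are
#' beyond the correction's range and return \code{NA}.
#'
#' @param p Proportion(s) of differing sites.
#' @return Corrected distance(s).
#' @export
jukes_cantor <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

# per-pair, per-codon arrays for a codon subset: Sd, Nd (pathway-averaged
# observed differences) and S, N (potential sites averaged over the pair)
ng_arrays <- function(sequences, codon_subset, tstv_ratio) {
  cm <- codon_matrix(sequences)[, codon_subset, drop = FALSE]
  if (any(codon_aa(cm) == "*")) stop("internal stop codon in alignment")
  stab <- syn_site_table(tstv_ratio)
  n <- nrow(cm); nc <- ncol(cm)
  pairs <- combn(n, 2L)
  np <- ncol(pairs)
  Sd <- Nd <- S <- N <- matrix(0, nrow = np, ncol = nc)
  for (p in seq_len(np)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    for (c in seq_len(nc)) {
      d <- codon_pair_diffs(cm[i, c], cm[j, c])
      Sd[p, c] <- d[["syn"]]; Nd[p, c] <- d[["nonsyn"]]
      S[p, c] <- (stab[[cm[i, c]]] + stab[[cm[j, c]]]) / 2
      N[p, c] <- 3 - S[p, c]
    }
  }
  list(Sd = Sd, Nd = Nd, S = S, N = N, pairs = pairs)
}

# overall-average dN and dS from the arrays over a set of codon columns
ng_point <- function(arr, cols) {
  Sdp <- rowSums(arr$Sd[, cols, drop = FALSE])
  Ndp <- rowSums(arr$Nd[, cols, drop = FALSE])
  Sp <- rowSums(arr$S[, cols, drop = FALSE])
  Np <- rowSums(arr$N[, cols, drop = FALSE])
  dS <- jukes_cantor(Sdp / Sp)
  dN <- jukes_cantor(Ndp / Np)
  c(dN = mean(dN), dS = mean(dS))
}

#' Modified Nei-Gojobori dN/dS with Jukes-Cantor correction
#'
#' Per sequence pair, potential synonymous/nonsynonymous sites are
#' weighted by the transition/transversion ratio \code{tstv_ratio}
#' (modified Nei-Gojobori); observed synonymous and nonsynonymous
#' differences are averaged with equal weight over all minimal
#' substitution pathways between differing codons (pathways through stop
#' codons excluded); the resulting proportions are Jukes-Cantor corrected
#' and averaged over all unordered pairs (overall average). Standard
#' errors are bootstrap standard deviations over codon columns within the
#' tested subset.
#'
#' @param sequences Equal-length, in-frame nucleotide sequences.
#' @param codon_subset 1-based codon indices to analyse (default: all).
#' @param tstv_ratio Transition/transversion ratio R (default 2).
#' @param n_boot Bootstrap replicates for the standard errors (default
#'   999); 0 skips them.
#' @param seed Seed for the bootstrap.
#' @return Object of class \code{dnds_result}: list with \code{dN},
#'   \code{dS}, \code{dN_se}, \code{dS_se}, \code{n_codons},
#'   \code{n_pairs}, \code{tstv_ratio}. Proportions beyond the
#'   Jukes-Cantor range propagate as \code{NA}.
#' @export
nei_gojobori_dnds <- function(sequences, codon_subset = NULL,
                              tstv_ratio = 2, n_boot = 999L, seed = 1L) {
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  n_codons_total <- nchar(sequences[1]) / 3L
  if (is.null(codon_subset)) codon_subset <- seq_len(n_codons_total)
  if (length(codon_subset) == 0L) stop("empty codon subset")
  arr <- ng_arrays(sequences, codon_subset, tstv_ratio)
  nc <- length(codon_subset)
  pt <- ng_point(arr, seq_len(nc))
  se <- c(dN = NA_real_, dS = NA_real_)
  if (n_boot > 0L) {
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(b) {
      ng_point(arr, sample.int(nc, nc, replace = TRUE))
    }, numeric(2))
    se <- c(dN = sd(boots["dN", ], na.rm = TRUE),
            dS = sd(boots["dS", ], na.rm = TRUE))
  }
  out <- list(dN = unname(pt["dN"]), dS = unname(pt["dS"]),
              dN_se = unname(se["dN"]), dS_se = unname(se["dS"]),
              n_codons = nc, n_pairs = ncol(arr$pairs),
              tstv_ratio = tstv_ratio)
  class(out) <- "dnds_result"
  out
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dN = %.3f +/- %.3f, dS = %.3f +/- %.3f (%d codons, %d pairs, R = %g)\n",
              x$dN, x$dN_se, x$dS, x$dS_se, x$n_codons, x$n_pairs,
              x$tstv_ratio))
  invisible(x)
}

#' Codon-based Z-test of selection
#'
#' Bootstrap (over codon columns) variances of the overall-average dN and
#' dS give \code{Z = (dN - dS) / sqrt(Var(dN) + Var(dS))}; the p-value is
#' standard normal, two-tailed for the neutrality alternative
#' (\code{dN != dS}) or one-tailed for positive selection
#' (\code{dN > dS}).
#'
#' @inheritParams nei_gojobori_dnds
#' @param alternative \code{"two_sided"} (neutrality test) or
#'   \code{"dn_greater"} (positive selection).
#' @return List with \code{Z}, \code{p}, \code{dN}, \code{dS},
#'   \code{alternative}. Degenerate cases (no variance and dN = dS, or
#'   identical sequences) return \code{Z = NA, p = 1}.
#' @export
codon_z_test <- function(sequences, codon_subset = NULL,
                         alternative = c("two_sided", "dn_greater"),
                         tstv_ratio = 2, n_boot = 999L, seed = 1L) {
  alternative <- match.arg(alternative)
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  n_codons_total <- nchar(sequences[1]) / 3L
  if (is.null(codon_subset)) codon_subset <- seq_len(n_codons_total)
  arr <- ng_arrays(sequences, codon_subset, tstv_ratio)
  nc <- length(codon_subset)
  pt <- ng_point(arr, seq_len(nc))
  dN <- pt["dN"]; dS <- pt["dS"]
  if (is.na(dN) || is.na(dS))
    return(list(Z = NA_real_, p = NA_real_, dN = unname(dN), dS = unname(dS),
                alternative = alternative))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    ng_point(arr, sample.int(nc, nc, replace = TRUE))
  }, numeric(2))
  v <- var(boots["dN", ], na.rm = TRUE) + var(boots["dS", ], na.rm = TRUE)
  if (!is.finite(v) || v == 0) {
    if (dN == dS) return(list(Z = NA_real_, p = 1, dN = unname(dN),
                              dS = unname(dS), alternative = alternative))
    v <- .Machine$double.eps
  }
  Z <- (dN - dS) / sqrt(v)
  p <- if (alternative == "two_sided") 2 * pnorm(-abs(Z)) else pnorm(-Z)
  list(Z = unname(Z), p = unname(p), dN = unname(dN), dS = unname(dS),
       alternative = alternative)
}

#' Mean pairwise amino-acid divergence over a codon subset
#'
#' Mean over all unordered sequence pairs of the per-pair amino-acid
#' p-distance restricted to the subset (optionally Poisson-corrected);
#' the standard error is the bootstrap standard deviation over codon
#' columns.
#'
#' @param aa_alignment Equal-length amino-acid sequences (or in-frame
#'   nucleotide sequences, which are translated first).
#' @param codon_subset 1-based residue indices (default: all).
#' @param correction \code{"none"} (p-distance, default) or
#'   \code{"poisson"} (\code{-log(1 - p)}).
#' @param n_boot Bootstrap replicates (default 999); 0 skips the SE.
#' @param seed Seed for the bootstrap.
#' @return List with \code{d}, \code{se}, and \code{per_pair} (the
#'   per-pair distances, for downstream paired contrasts).
#' @export
mean_pairwise_divergence <- function(aa_alignment, codon_subset = NULL,
                                     correction = c("none", "poisson"),
                                     n_boot = 999L, seed = 1L) {
  correction <- match.arg(correction)
  if (grepl("^[ACGT]+$", aa_alignment[1]) && nchar(aa_alignment[1]) %% 3L == 0L)
    aa_alignment <- translate_alignment(aa_alignment)
  m <- do.call(rbind, strsplit(aa_alignment, "", fixed = TRUE))
  if (is.null(codon_subset)) codon_subset <- seq_len(ncol(m))
  if (length(codon_subset) == 0L) stop("empty codon subset")
  m <- m[, codon_subset, drop = FALSE]
  pairs <- combn(nrow(m), 2L)
  diff_mat <- vapply(seq_len(ncol(pairs)), function(p) {
    m[pairs[1, p], ] != m[pairs[2, p], ]
  }, logical(ncol(m)))
  diff_mat <- matrix(diff_mat, nrow = ncol(m))  # codons x pairs
  corr <- function(p) if (correction == "poisson") -log(1 - p) else p
  per_pair <- corr(colMeans(diff_mat))
  se <- NA_real_
  if (n_boot > 0L) {
    set.seed(seed)
    nc <- nrow(diff_mat)
    bo <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nc, nc, replace = TRUE)
      mean(corr(colMeans(diff_mat[idx, , drop = FALSE])))
    }, numeric(1))
    se <- sd(bo)
  }
  list(d = mean(per_pair), se = se, per_pair = per_pair)
}

#' Paired contrast of per-pair divergence between two codon regions
#'
#' Paired t-test over sequence pairs of the difference in per-pair
#' divergence between two regions (e.g. pABS vs non-pABS). Sequence pairs
#' are treated as the unit of replication.
#'
#' @param per_pair_d_region1,per_pair_d_region2 Per-pair divergences over
#'   the same sequence pairs (as returned in \code{per_pair} by
#'   \code{\link{mean_pairwise_divergence}}).
#' @return List with \code{t}, \code{df}, \code{p} (two-sided) and
#'   \code{mean_diff}.
#' @export
divergence_region_test <- function(per_pair_d_region1, per_pair_d_region2) {
  if (length(per_pair_d_region1) != length(per_pair_d_region2))
    stop("per-pair vectors must cover the same sequence pairs")
  if (length(per_pair_d_region1) < 2L) stop("need at least 2 pairs")
  dd <- per_pair_d_region1 - per_pair_d_region2
  if (all(dd == 0))
    return(list(t = 0, df = length(dd) - 1L, p = 1, mean_diff = 0))
  ht <- t.test(per_pair_d_region1, per_pair_d_region2, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Codon-partitioned selection table
#'
#' Runs \code{\link{nei_gojobori_dnds}} and both \code{\link{codon_z_test}}
#' alternatives for the whole exon, the pABS codons and the non-pABS
#' codons, mirroring the conventional three-row dN/dS summary table.
#'
#' @param sequences Equal-length, in-frame nucleotide sequences.
#' @param partition Codon partition from \code{\link{codon_partition}}.
#' @inheritParams nei_gojobori_dnds
#' @return Data frame with one row per region: dN, dS, their SEs, and Z/p
#'   for the neutrality and positive-selection tests.
#' @export
selection_table <- function(sequences, partition = codon_partition(),
                            tstv_ratio = 2, n_boot = 999L, seed = 1L) {
  regions <- list(exon = NULL, pABS = partition$pabs,
                  non_pABS = partition$non_pabs)
  rows <- lapply(names(regions), function(rg) {
    est <- nei_gojobori_dnds(sequences, regions[[rg]], tstv_ratio,
                             n_boot = n_boot, seed = seed)
    zt2 <- codon_z_test(sequences, regions[[rg]], "two_sided", tstv_ratio,
                        n_boot = n_boot, seed = seed)
    zt1 <- codon_z_test(sequences, regions[[rg]], "dn_greater", tstv_ratio,
                        n_boot = n_boot, seed = seed)
    data.frame(region = rg, dN = est$dN, dN_se = est$dN_se, dS = est$dS,
               dS_se = est$dS_se, Z_neutral = zt2$Z, p_neutral = zt2$p,
               Z_positive = zt1$Z, p_positive = zt1$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
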