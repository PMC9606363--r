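# Allele tree and MHC-vs-background association: neighbour-joining tree on
# nucleotide p-distances, unweighted UniFrac between individuals' allele
# sets, a mixed model of UniFrac on relatedness and a binomial GLM of MHC
# heterozygosity on sMLH.

#' Neighbour-joining tree of catalog alleles
#'
#' Saitou-Nei neighbour joining (\code{ape::nj}) on the pairwise
#' nucleotide p-distance matrix. Negative branch-length estimates are
#' clamped to zero (with a message), as UniFrac requires non-negative
#' lengths; duplicate sequences collapse to zero-length branches with a
#' warning.
#'
#' @param alleles Allele catalog data frame (\code{name},
#'   \code{sequence}) or named character vector of sequences.
#' @return Unrooted \code{phylo} tree with the allele names as tips.
#' @export
build_nj_tree <- function(alleles) {
  if (is.data.frame(alleles)) alleles <- setNames(alleles$sequence, alleles$name)
  if (length(alleles) < 3L) stop("need at least 3 alleles")
  if (anyDuplicated(alleles))
    warning("duplicate sequences collapse to zero-length branches")
  n <- length(alleles)
  ch <- do.call(rbind, strsplit(alleles, "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(names(alleles), names(alleles)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- mean(ch[i, ] != ch[j, ])
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    message(sum(tree$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# unweighted UniFrac between two leaf sets on one tree: fraction of the
# branch length of the subtree spanning the union that is not on both
# sets' own spanning subtrees; root-invariant by construction
unifrac_pair <- function(tree, set_a, set_b) {
  u <- union(set_a, set_b)
  miss <- setdiff(u, tree$tip.label)
  if (length(miss))
    stop("allele(s) missing from tree: ", paste(miss, collapse = ", "))
  if (setequal(set_a, set_b)) return(0)
  if (length(u) == 1L) return(0)
  sub <- ape::keep.tip(tree, u)
  # tips below each edge of the (arbitrary-rooted) pruned tree
  n_tip <- length(sub$tip.label)
  desc <- vector("list", n_tip + sub$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- sub$tip.label[i]
  for (e in rev(seq_len(nrow(sub$edge)))) {
    p <- sub$edge[e, 1L]; ch <- sub$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  total <- sum(sub$edge.length)
  if (total == 0) return(0)
  shared <- 0
  all_tips <- sub$tip.label
  for (e in seq_len(nrow(sub$edge))) {
    below <- desc[[sub$edge[e, 2L]]]
    above <- setdiff(all_tips, below)
    in_a <- any(below %in% set_a) && any(above %in% set_a)
    in_b <- any(below %in% set_b) && any(above %in% set_b)
    if (in_a && in_b) shared <- shared + sub$edge.length[e]
  }
  (total - shared) / total
}

#' Pairwise unweighted UniFrac distances between individuals
#'
#' For individuals with allele sets A and B, the fraction of the branch
#' length of the tree spanning A union B that is exclusive to one of the
#' two sets (unweighted UniFrac). An edge is shared when it lies on both
#' sets' spanning subtrees, a criterion based on the leaf bipartition the
#' edge induces and therefore invariant to rooting. Homozygotes contribute
#' singleton sets; identical allele sets are at distance 0.
#'
#' @param tree Allele tree (\code{phylo}) whose tips cover every genotype
#'   allele.
#' @param genotypes Genotype data frame.
#' @param branch_lengths \code{"tree"} (default) uses the tree's branch
#'   lengths; \code{"unit"} sets every branch to 1 (topological UniFrac).
#' @return Symmetric matrix in [0,1] with individuals as dimnames and a
#'   zero diagonal.
#' @export
unifrac_matrix <- function(tree, genotypes,
                           branch_lengths = c("tree", "unit")) {
  branch_lengths <- match.arg(branch_lengths)
  if (branch_lengths == "unit")
    tree$edge.length <- rep(1, nrow(tree$edge))
  sets <- allele_sets(genotypes)
  n <- length(sets)
  m <- matrix(0, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- unifrac_pair(tree, sets[[i]], sets[[j]])
  m
}

# unordered pairs of a square matrix as a data frame
pairs_frame <- function(m) {
  inds <- rownames(m)
  idx <- combn(length(inds), 2L)
  data.frame(id1 = inds[idx[1, ]], id2 = inds[idx[2, ]],
             value = m[cbind(idx[1, ], idx[2, ])],
             stringsAsFactors = FALSE)
}

#' Mixed model of pairwise UniFrac on pairwise relatedness
#'
#' Linear mixed model over unordered pairs (each pair enters once):
#' response = pairwise MHC UniFrac, fixed effect = pairwise relatedness,
#' crossed random intercepts for the identities of the two pair members
#' (controlling the non-independence of pairwise observations). The fixed
#' effect is tested with the mixed-model F-test (Satterthwaite
#' denominator degrees of freedom via \pkg{lmerTest}).
#'
#' @param unifrac Square UniFrac matrix (from
#'   \code{\link{unifrac_matrix}}).
#' @param relatedness Square relatedness matrix over the same individuals
#'   (from \code{\link{queller_goodnight_r}}).
#' @return List with \code{slope}, \code{F}, \code{df1}, \code{df2},
#'   \code{p}, \code{n_pairs} and the fitted model in \code{fit}.
#' @export
fit_unifrac_lme <- function(unifrac, relatedness) {
  inds <- intersect(rownames(unifrac), rownames(relatedness))
  if (length(inds) < 3L) stop("need at least 3 individuals")
  uf <- pairs_frame(unifrac[inds, inds])
  rl <- pairs_frame(relatedness[inds, inds])
  d <- data.frame(unifrac = uf$value, relatedness = rl$value,
                  id1 = uf$id1, id2 = uf$id2, stringsAsFactors = FALSE)
  d <- d[is.finite(d$relatedness) & is.finite(d$unifrac), , drop = FALSE]
  if (var(d$unifrac) == 0)
    return(list(slope = 0, F = 0, df1 = 1, df2 = nrow(d) - 2, p = 1,
                n_pairs = nrow(d), fit = NULL))
  fit <- lmerTest::lmer(unifrac ~ relatedness + (1 | id1) + (1 | id2),
                        data = d,
                        control = lme4::lmerControl(
                          check.conv.singular = lme4::.makeCC(
                            action = "ignore", tol = 1e-4)))
  an <- anova(fit)
  list(slope = unname(lme4::fixef(fit)["relatedness"]),
       F = an["relatedness", "F value"],
       df1 = an["relatedness", "NumDF"],
       df2 = an["relatedness", "DenDF"],
       p = an["relatedness", "Pr(>F)"],
       n_pairs = nrow(d), fit = fit)
}

#' Binomial GLM of MHC heterozygosity on sMLH
#'
#' Logistic regression of individual MHC heterozygosity (1 =
#' heterozygous, 0 = homozygous) on standardised multilocus
#' heterozygosity; the slope is tested with a likelihood-ratio chi-square
#' test.
#'
#' @param mhc_het Named 0/1 vector (or logical) of MHC heterozygosity.
#' @param smlh_values Named numeric vector of sMLH (see
#'   \code{\link{smlh}}); matched to \code{mhc_het} by name.
#' @return List with \code{coefficient} (log-odds slope), \code{chi2},
#'   \code{df}, \code{p}, \code{n} and the fitted model in \code{fit}.
#'   Degenerate designs (constant response or constant predictor) return
#'   a flag instead of a test: \code{separation_flag} or
#'   \code{inestimable_flag} set to \code{TRUE} with \code{p = NA}.
#' @export
fit_het_glm <- function(mhc_het, smlh_values) {
  ids <- intersect(names(mhc_het), names(smlh_values))
  if (length(ids) == 0L) {  # unnamed: positional
    ids <- seq_along(mhc_het)
    het <- as.numeric(mhc_het); sm <- as.numeric(smlh_values)
  } else {
    het <- as.numeric(mhc_het[ids]); sm <- as.numeric(smlh_values[ids])
  }
  keep <- is.finite(het) & is.finite(sm)
  het <- het[keep]; sm <- sm[keep]
  if (all(het == 0) || all(het == 1))
    return(list(coefficient = NA_real_, chi2 = NA_real_, df = NA, p = NA,
                n = length(het), separation_flag = TRUE, fit = NULL))
  if (var(sm) == 0)
    return(list(coefficient = NA_real_, chi2 = NA_real_, df = NA, p = NA,
                n = length(het), inestimable_flag = TRUE, fit = NULL))
  fit <- glm(het ~ sm, family = binomial())
  chi2 <- fit$null.deviance - fit$deviance
  list(coefficient = unname(coef(fit)["sm"]),
       chi2 = chi2, df = 1L, p = 1 - pchisq(chi2, 1L),
       n = length(het), fit = fit)
}
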