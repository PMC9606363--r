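# Shared fixtures: all built in code at test time.

# a clone-record data frame from sequences, counts and individual labels:
# counts[i] clones of sequences[i], distributed over individuals[[i]]
make_clones <- function(sequences, counts, individuals) {
  rows <- list()
  k <- 0L
  for (i in seq_along(sequences)) {
    inds <- rep(individuals[[i]], length.out = counts[i])
    for (ind in inds) {
      k <- k + 1L
      rows[[k]] <- data.frame(clone_id = sprintf("%s|c%04d", ind, k),
                              individual_id = ind,
                              sequence = sequences[i],
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# short distinct random sequences for typing tests (not tied to the exon)
random_seqs <- function(n, len = 30L, seed = 1L) {
  set.seed(seed)
  replicate(n, paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
}

# mutate a sequence at k distinct positions
mutate_at <- function(seq, pos, bases = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_along(pos)) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[pos[i]])
    ch[pos[i]] <- if (is.null(bases)) alt[1] else bases[i]
  }
  paste(ch, collapse = "")
}

# small study config for fast end-to-end runs
quick_config <- function(seed = 1L, ...) {
  sim_config(n_mothers_per_colony = 8L, n_pairs_per_colony = 5L,
             n_extra_pups_per_colony = 1L, n_microsat_loci = 12L,
             seed = seed, ...)
}

# genotype table from a named list of allele sets
genotypes_from_sets <- function(sets, colony = "A") {
  data.frame(individual_id = names(sets),
             colony = rep_len(colony, length(sets)),
             alleles = unname(vapply(sets, paste, character(1),
                                     collapse = ";")),
             status = unname(ifelse(lengths(sets) <= 2L, "ok",
                                    "multi_allele_flag")),
             stringsAsFactors = FALSE, row.names = NULL)
}

# long-format microsatellite table from per-locus genotype matrices
microsats_from_matrices <- function(mats) {
  do.call(rbind, lapply(names(mats), function(l) {
    m <- mats[[l]]
    data.frame(individual_id = rownames(m), locus = l,
               allele1 = m[, 1], allele2 = m[, 2],
               stringsAsFactors = FALSE)
  }))
}

# exact conditional Hardy-Weinberg test (biallelic): two-sided p by
# summing probabilities of heterozygote counts no more likely than the
# observed one, conditional on the allele count nA among n diploids
hwe_exact_p <- function(n, nA, n_het_obs) {
  na <- 2L * n - nA
  n12s <- seq(nA %% 2L, min(nA, na), by = 2L)
  logp <- vapply(n12s, function(n12) {
    n11 <- (nA - n12) / 2L
    n22 <- n - n11 - n12
    lgamma(n + 1) - lgamma(n11 + 1) - lgamma(n12 + 1) - lgamma(n22 + 1) +
      n12 * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(n12s == n_het_obs)
  sum(p[p <= p[obs] + 1e-12])
}
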