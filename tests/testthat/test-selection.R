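test_that("translation follows the standard code and rejects stops", {
  expect_equal(unname(translate_alignment("ATGGCT")), "MA")
  expect_error(translate_alignment(c(ok = "ATGGCTAAA",
                                     bad = "ATGTAAAAA")), "codon 2")
  expect_error(translate_alignment("ATGGC"), "multiple of 3")
})

test_that("variable site counts", {
  expect_equal(variable_sites(c("ACGTAC", "ACGTAC")), 0L)
  expect_equal(variable_sites(c("ACGTAC", "TCGTGG")), 3L)
  # aa level on nucleotide input translates first: syn change is invisible
  expect_equal(variable_sites(c("TTTACT", "TTCACT"), "aa"), 0L)
  expect_equal(variable_sites(c("TTTACT", "TTAACT"), "aa"), 1L)
  expect_error(variable_sites("ACGT"), "at least 2")
  expect_error(variable_sites(c("AC", "ACG")), "ragged")
})

test_that("mean pairwise divergence matches hand enumeration", {
  # identical sequences
  r0 <- mean_pairwise_divergence(c("MAMAW", "MAMAW"), n_boot = 0)
  expect_equal(r0$d, 0)
  # 2 sequences, 1 of 10 subset residues differing: d = 0.1
  a <- strrep("M", 12); b <- paste0(strrep("M", 11), "W")
  r1 <- mean_pairwise_divergence(c(a, b), codon_subset = 3:12, n_boot = 0)
  expect_equal(r1$d, 0.1)
  # 3 toy peptides over a 5-residue subset: hand-enumerated pair mean
  p1 <- "MAWQK"; p2 <- "MTWQK"; p3 <- "MTWEK"
  # pairs: (p1,p2)=1/5, (p1,p3)=2/5, (p2,p3)=1/5 -> mean = 4/15
  r3 <- mean_pairwise_divergence(c(p1, p2, p3), codon_subset = 1:5,
                                 n_boot = 0)
  expect_equal(r3$d, 4 / 15)
  expect_equal(sort(r3$per_pair), sort(c(1, 2, 1) / 5))
  # poisson correction is -log(1-p)
  rp <- mean_pairwise_divergence(c(p1, p2), correction = "poisson",
                                 n_boot = 0)
  expect_equal(rp$d, -log(1 - 0.2))
  expect_error(mean_pairwise_divergence(c(p1, p2), integer(0)), "empty")
})

test_that("Nei-Gojobori pathway counts match brute-force enumeration", {
  # single-difference codons classify directly by translation
  expect_equal(unname(mhctyper:::codon_path_diffs("TTT", "TTC")), c(1, 0))
  expect_equal(unname(mhctyper:::codon_path_diffs("TTT", "TTA")), c(0, 1))
  # two-difference pair TTT->GTA: pathways via GTT (nonsyn+syn) and
  # TTA (nonsyn+nonsyn): average syn 0.5, nonsyn 1.5
  expect_equal(unname(mhctyper:::codon_path_diffs("TTT", "GTA")), c(0.5, 1.5))

  # independent brute-force oracle for <= 2-difference pairs: enumerate
  # position orderings explicitly and classify each step by translation
  oracle <- function(c1, c2) {
    gc <- Biostrings::GENETIC_CODE
    b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
    dp <- which(b1 != b2)
    if (length(dp) == 0) return(c(0, 0))
    ords <- if (length(dp) == 1) list(dp) else list(dp, rev(dp))
    res <- NULL
    for (o in ords) {
      cur <- b1; syn <- 0; non <- 0; valid <- TRUE
      for (pos in o) {
        nxt <- cur; nxt[pos] <- b2[pos]
        if (gc[[paste(nxt, collapse = "")]] == "*") valid <- FALSE
        if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]])
          syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      if (valid) res <- cbind(res, c(syn, non))
    }
    if (is.null(res)) return(NULL)  # all pathways hit a stop
    rowMeans(res)
  }
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  checked <- 0L
  for (c1 in sense) for (c2 in sense) {
    if (hamming(c1, c2) %in% 1:2) {
      exp_val <- oracle(c1, c2)
      if (is.null(exp_val)) next
      expect_equal(unname(mhctyper:::codon_path_diffs(c1, c2)),
                   unname(exp_val))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 1000L)
})

test_that("pathway counts conserve the nucleotide Hamming distance", {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  set.seed(4)
  for (i in 1:200) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    d <- mhctyper:::codon_path_diffs(c1, c2)
    expect_equal(sum(d), hamming(c1, c2))
  }
})

test_that("potential-site counts follow the weighted closed forms", {
  # TTT at R = 2: only position 3 T->C (transition) is synonymous:
  # s3 = 2/(2+1+1) = 0.5; positions 1-2 contribute 0
  expect_equal(mhctyper:::codon_syn_sites("TTT", 2), 0.5)
  expect_equal(mhctyper:::codon_syn_sites("TTT", 1), 1 / 3)
  # 4-fold degenerate third position (GGG): s3 = 1 at any R
  expect_equal(mhctyper:::codon_syn_sites("GGG", 2), 1)
  expect_equal(mhctyper:::codon_syn_sites("GGG", 0.5), 1)
  # methionine ATG: no synonymous single-base change at any position
  expect_equal(mhctyper:::codon_syn_sites("ATG", 2), 0)
})

test_that("site counts are additive over the codon partition", {
  pool <- generate_allele_pool(sim_config(seed = 23))
  part <- codon_partition()
  arr_all <- mhctyper:::ng_arrays(pool$sequence, 1:89, 2)
  arr_p <- mhctyper:::ng_arrays(pool$sequence, part$pabs, 2)
  arr_n <- mhctyper:::ng_arrays(pool$sequence, part$non_pabs, 2)
  expect_equal(rowSums(arr_all$S), rowSums(arr_p$S) + rowSums(arr_n$S))
  expect_equal(rowSums(arr_all$Nd), rowSums(arr_p$Nd) + rowSums(arr_n$Nd))
})

test_that("dN/dS estimates behave on anchor cases", {
  r <- nei_gojobori_dnds(c("TTTGCT", "TTTGCT"), n_boot = 0)
  expect_equal(r$dN, 0); expect_equal(r$dS, 0)
  # one synonymous difference only: dN = 0, dS > 0
  r2 <- nei_gojobori_dnds(c("TTTGCT", "TTCGCT"), n_boot = 0)
  expect_equal(r2$dN, 0)
  expect_gt(r2$dS, 0)
  # hand value: Sd=1; S sites at R=2 for TTT,GCT: TTT 0.5, GCT 1,
  # TTC 0.5, pairwise S = (1.5 + 1.5)/2 = 1.5; pS = 2/3; JC(2/3)
  expect_equal(r2$dS, -0.75 * log(1 - (4 / 3) * (2 / 3)))
  expect_error(nei_gojobori_dnds(c("TTTG", "TTCG")), "multiple of 3")
})

test_that("Jukes-Cantor correction: closed form, range, monotonicity", {
  p <- seq(0, 0.74, by = 0.01)
  expect_equal(jukes_cantor(p), -0.75 * log(1 - 4 * p / 3))
  expect_true(all(diff(jukes_cantor(p)) > 0))
  expect_true(is.na(jukes_cantor(0.75)))
  expect_equal(jukes_cantor(0), 0)
})

test_that("codon Z-test handles degenerate and directional cases", {
  z0 <- codon_z_test(c("TTTGCT", "TTTGCT"), n_boot = 49)
  expect_true(is.na(z0$Z))
  expect_equal(z0$p, 1)
  # strong nonsynonymous excess at pABS is detected with high power
  part <- codon_partition()
  rej <- vapply(1:30, function(s) {
    pool <- generate_allele_pool(sim_config(seed = s,
                                            pabs_nonsyn_multiplier = 5))
    z <- codon_z_test(pool$sequence, part$pabs, "dn_greater",
                      tstv_ratio = 1, n_boot = 199, seed = s)
    isTRUE(z$p < 0.05)
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("region divergence contrast matches a hand paired t-test", {
  # identical regions: t = 0, p = 1
  r0 <- divergence_region_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  # constant positive offset with tiny jitter: large positive t
  set.seed(2)
  d2 <- c(0.1, 0.2, 0.3, 0.15)
  r1 <- divergence_region_test(d2 + 0.2 + rnorm(4, 0, 1e-4), d2)
  expect_gt(r1$t, 100)
  expect_lt(r1$p, 1e-4)
  # 4-sequence toy set: against a by-hand paired t computation
  seqs <- c("ATGGCTTTTAAA", "ATGGCTTTCAAA", "ATGACTTTTAGA", "ATGGCATTAAAA")
  aa <- translate_alignment(seqs)
  d_a <- mean_pairwise_divergence(aa, 1:2, n_boot = 0)$per_pair
  d_b <- mean_pairwise_divergence(aa, 3:4, n_boot = 0)$per_pair
  got <- divergence_region_test(d_a, d_b)
  dd <- d_a - d_b
  t_hand <- mean(dd) / (sd(dd) / sqrt(length(dd)))
  expect_equal(got$t, t_hand)
  expect_equal(got$df, length(dd) - 1)
  expect_equal(got$p, 2 * pt(-abs(t_hand), length(dd) - 1))
  expect_error(divergence_region_test(0.1, c(0.1, 0.2)), "same sequence")
})

test_that("selection table covers the three regions deterministically", {
  pool <- generate_allele_pool(sim_config(seed = 31))
  tab <- selection_table(pool$sequence, n_boot = 99, seed = 2)
  expect_equal(tab$region, c("exon", "pABS", "non_pABS"))
  tab2 <- selection_table(pool$sequence, n_boot = 99, seed = 2)
  expect_identical(tab, tab2)
  expect_true(all(tab$dN >= 0 & tab$dS >= 0, na.rm = TRUE))
})
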