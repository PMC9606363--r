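test_that("theta vanishes for duplicated populations and is 1 for fixed ones", {
  # duplicate a sizeable table as two 'populations': the among-population
  # variance component is exactly 0 and theta is pinned near 0 by the
  # finite-sample correction terms (it is not exactly 0 for this
  # estimator; the residual shrinks as 1/n)
  st <- simulate_study(sim_config(seed = 41, n_microsat_loci = 6L))
  ms <- st$microsats
  ms2 <- ms; ms2$individual_id <- paste0(ms2$individual_id, "_dup")
  both <- rbind(ms, ms2)
  inds <- unique(ms$individual_id)
  pops <- setNames(c(rep("P1", length(inds)), rep("P2", length(inds))),
                   c(inds, paste0(inds, "_dup")))
  th <- weir_cockerham_fst(both, pops)
  expect_lt(abs(as.numeric(th)), 0.02)
  expect_lte(as.numeric(th), 0)  # correction terms act downward

  # exact hand value on a tiny duplicated table: per allele
  # a = -(1/(n-1))(pq - h/4), b and c as in the component definitions;
  # with p = 0.5, h = 0.5, n = 4: theta = -1/6
  m1 <- matrix(c("a", "b", "a", "a", "b", "b", "a", "b"), 4, 2,
               dimnames = list(paste0("i", 1:4), NULL))
  tiny <- microsats_from_matrices(list(L1 = m1))
  tiny2 <- tiny; tiny2$individual_id <- paste0(tiny2$individual_id, "_d")
  tpops <- setNames(rep(c("P1", "P2"), each = 4),
                    c(paste0("i", 1:4), paste0("i", 1:4, "_d")))
  expect_equal(as.numeric(weir_cockerham_fst(rbind(tiny, tiny2), tpops)),
               -1 / 6, tolerance = 1e-12)

  # two populations fixed for different alleles
  mfix <- matrix(c(rep("a", 4), rep("b", 4), rep("a", 4), rep("b", 4)),
                 8, 2, dimnames = list(paste0("i", 1:8), NULL))
  msf <- microsats_from_matrices(list(L1 = mfix))
  popf <- setNames(rep(c("P1", "P2"), each = 4), paste0("i", 1:8))
  expect_equal(as.numeric(weir_cockerham_fst(msf, popf)), 1)

  # monomorphic data: undefined with a warning
  mono <- microsats_from_matrices(list(L1 = matrix("a", 4, 2,
    dimnames = list(paste0("i", 1:4), NULL))))
  expect_warning(
    expect_true(is.na(weir_cockerham_fst(mono,
      setNames(rep(c("P1", "P2"), 2), paste0("i", 1:4))))),
    "monomorphic")
})

test_that("theta matches a nested-ANOVA variance-component oracle", {
  # balanced toy dataset: 2 pops x 4 individuals x 2 gene copies
  m <- matrix(c("A", "A", "A", "B", "B", "B", "A", "B",
                "A", "B", "A", "B", "B", "A", "B", "B"), 8, 2,
              dimnames = list(paste0("i", 1:8), NULL))
  ms <- microsats_from_matrices(list(L1 = m))
  pops <- setNames(rep(c("P1", "P2"), each = 4), paste0("i", 1:8))
  th <- weir_cockerham_fst(ms, pops)

  # independent route: method-of-moments from aov mean squares on the
  # allele-A indicator over gene copies (genes nested in individuals
  # nested in populations)
  y <- as.numeric(t(m) == "A")          # gene copies, individual-major
  ind <- rep(rownames(m), each = 2)
  pp <- rep(c("P1", "P2"), each = 8)
  fit <- aov(y ~ pp + Error(ind))
  MSP <- summary(fit)[[1]][[1]]["pp", "Mean Sq"]
  MSI <- summary(fit)[[1]][[1]]["Residuals", "Mean Sq"]
  MSG <- summary(fit)[[2]][[1]]["Residuals", "Mean Sq"]
  a <- (MSP - MSI) / 8   # 8 gene copies per population
  b <- (MSI - MSG) / 2   # 2 gene copies per individual
  cc <- MSG
  expect_equal(as.numeric(th), a / (a + b + cc), tolerance = 1e-12)
})

test_that("permutation test calibrates at the extremes", {
  mfix <- matrix(c(rep("a", 5), rep("b", 5), rep("a", 5), rep("b", 5)),
                 10, 2, dimnames = list(paste0("i", 1:10), NULL))
  msf <- microsats_from_matrices(list(L1 = mfix))
  popf <- setNames(rep(c("P1", "P2"), each = 5), paste0("i", 1:10))
  res <- fst_permutation_test(msf, popf, n_perm = 199, seed = 1)
  expect_equal(res$theta, 1)
  # perfect differentiation: only label permutations reproducing the
  # split reach theta_obs; p is near its attainable minimum
  expect_lt(res$p, 0.05)
  expect_gte(res$p, 1 / 200)
})

test_that("diversity summary matches small-sample formulas and rarefaction", {
  # one heterozygote pair AB/AB: Ho = 1; unbiased He = (4/3)*0.5 = 2/3
  m <- matrix(c("A", "A", "B", "B"), 2, 2,
              dimnames = list(c("i1", "i2"), NULL))
  ms <- microsats_from_matrices(list(L1 = m))
  ds <- diversity_summary(ms, setNames(c("P1", "P1"), c("i1", "i2")))
  expect_equal(ds$Ho, 1)
  expect_equal(ds$He, (4 / 3) * 0.5)
  expect_equal(ds$Fis, 1 - 1 / ((4 / 3) * 0.5))

  # all identical homozygotes: He = 0, Fis undefined
  m0 <- matrix("A", 3, 2, dimnames = list(paste0("i", 1:3), NULL))
  ds0 <- diversity_summary(microsats_from_matrices(list(L1 = m0)),
                           setNames(rep("P1", 3), paste0("i", 1:3)))
  expect_equal(ds0$Ho, 0); expect_equal(ds0$He, 0)
  expect_true(is.na(ds0$Fis))

  # rarefied richness equals exhaustive subsample enumeration
  m6 <- matrix(c("a", "a", "b", "c", "c", "d",
                 "a", "b", "b", "c", "d", "d"), 6, 2,
               dimnames = list(paste0("i", 1:6), NULL))
  pops <- setNames(c(rep("P1", 4), rep("P2", 2)), paste0("i", 1:6))
  ds6 <- diversity_summary(microsats_from_matrices(list(L1 = m6)), pops)
  g <- min(table(pops)) * 2  # rarefaction size: smallest gene count
  brute_rich <- function(genes, g) {
    combos <- combn(length(genes), g)
    mean(apply(combos, 2, function(ix) length(unique(genes[ix]))))
  }
  genes_p1 <- as.vector(m6[1:4, ]); genes_p2 <- as.vector(m6[5:6, ])
  expect_equal(ds6$allelic_richness[ds6$population == "P1"],
               brute_rich(genes_p1, g))
  expect_equal(ds6$allelic_richness[ds6$population == "P2"],
               brute_rich(genes_p2, g))
  # private alleles: P1 has {a,b} private? b appears in P2? P2 genes c,d,d,d
  expect_equal(ds6$private_alleles, c(2, 1))
})

test_that("Queller-Goodnight r anchors at clones, strangers and kin", {
  # identical homozygotes in a mixed background: r near 1
  set.seed(3)
  n_bg <- 30
  mats <- lapply(1:8, function(l) {
    m <- matrix(sample(letters[1:6], 2 * (n_bg + 2), TRUE), n_bg + 2, 2)
    rownames(m) <- c("x", "y", paste0("bg", 1:n_bg))
    m["x", ] <- c("a", "a"); m["y", ] <- c("a", "a")
    m
  })
  names(mats) <- paste0("L", 1:8)
  r <- queller_goodnight_r(microsats_from_matrices(mats))
  expect_gt(r["x", "y"], 0.9)
  expect_true(all(abs(r - t(r)) < 1e-12, na.rm = TRUE))
  expect_true(all(is.na(diag(r))))

  # two individuals sharing no alleles at near-uniform frequencies: r < 0
  mats2 <- lapply(1:8, function(l) {
    m <- matrix(sample(letters[1:4], 2 * (n_bg + 2), TRUE), n_bg + 2, 2)
    rownames(m) <- c("x", "y", paste0("bg", 1:n_bg))
    m["x", ] <- c("a", "b"); m["y", ] <- c("c", "d")
    m
  })
  names(mats2) <- paste0("L", 1:8)
  r2 <- queller_goodnight_r(microsats_from_matrices(mats2))
  expect_lt(r2["x", "y"], 0)
})

test_that("parent-offspring relatedness is recovered near 0.5", {
  vals <- unlist(lapply(1:10, function(s) {
    st <- simulate_study(sim_config(seed = s, n_microsat_loci = 30L))
    r <- queller_goodnight_r(st$microsats)
    mapply(function(m, p) r[m, p], st$pedigree$mother_id, st$pedigree$pup_id)
  }))
  expect_equal(length(vals), 200L)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.5), 2 * se + 0.02)
})

test_that("sMLH standardisation: anchors and unit mean", {
  # fully homozygous individual scores 0
  m <- matrix(c("a", "b", "c", "d",
                "a", "a", "c", "c",
                "a", "b", "c", "d"), 3, 4, byrow = TRUE,
              dimnames = list(paste0("i", 1:3), NULL))
  mats <- list(L1 = m[, 1:2], L2 = m[, 3:4])
  sm <- smlh(microsats_from_matrices(mats))
  expect_equal(unname(sm["i2"]), 0)
  # population mean is exactly 1 with complete data
  expect_equal(mean(sm), 1)
  st <- simulate_study(quick_config(seed = 19))
  expect_equal(mean(smlh(st$microsats)), 1, tolerance = 1e-12)
  # an average individual scores ~1
  expect_true(all(sm[c("i1", "i3")] > 1))  # both heterozygous everywhere
})

test_that("simulated null colonies show negligible structure", {
  res <- vapply(1:20, function(s) {
    st <- simulate_study(quick_config(seed = 100 + s))
    pops <- setNames(st$genotypes$colony, st$genotypes$individual_id)
    f <- fst_permutation_test(st$genotypes, n_perm = 99, seed = s)
    c(theta = f$theta, p = f$p)
  }, numeric(2))
  expect_lt(abs(mean(res["theta", ])), 0.05)
  expect_gte(mean(res["p", ] > 0.05), 0.8)
})
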