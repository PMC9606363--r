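# Synthetic-data generator: allele pools with elevated nonsynonymous
# variability at antigen-binding codons, Hardy-Weinberg genotypes in two
# colonies with maternal transmission to pups, clone libraries with
# per-clone PCR point-error artifacts and primer-mismatch amplification
# bias, and pedigree-consistent microsatellite genotypes.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with defaults
#' matching the study conditions the pipeline targets: 19 alleles
#' segregating in two colonies of 16 mothers each, 10 sequenced
#' mother-pup pairs plus 2 motherless pups per colony (56 individuals),
#' clone libraries of 7-32 clones per individual, roughly a fifth of
#' clones carrying 1-2 PCR point errors, and no amplification bias
#' (intronic primers).
#'
#' @param n_alleles Number of distinct alleles in the pool.
#' @param allele_freqs Probability vector of length \code{n_alleles}
#'   (must sum to 1), or \code{NULL} to draw once from a Dirichlet with
#'   concentration \code{dirichlet_alpha}, sorted decreasing so low-index
#'   alleles are common and high-index alleles rare.
#' @param dirichlet_alpha Dirichlet concentration used when
#'   \code{allele_freqs} is \code{NULL}.
#' @param n_mothers_per_colony Mothers simulated per colony.
#' @param n_pairs_per_colony Mother-pup pairs per colony (pups linked to
#'   distinct mothers; must not exceed \code{n_mothers_per_colony}).
#' @param n_extra_pups_per_colony Pups without a sequenced mother.
#' @param pabs_nonsyn_multiplier Relative weight (>= 1) with which
#'   substitutions are directed to pABS codons, where they are forced to
#'   be nonsynonymous.
#' @param mean_mutations Mean number of substitutions separating a derived
#'   allele from the founder (1 + Poisson(\code{mean_mutations} - 1)).
#' @param clones_per_individual Integer range \code{c(lo, hi)}; per-
#'   individual clone counts are uniform on it.
#' @param artifact_rate Per-clone probability of carrying 1-2 PCR point
#'   errors.
#' @param bias_beta Amplification-bias strength: a clone's template allele
#'   is drawn with weight proportional to
#'   \code{exp(-bias_beta * mismatches(allele, primers))}. 0 disables bias.
#' @param n_microsat_loci Number of simulated microsatellite loci.
#' @param microsat_alleles_range Range of allele counts per locus.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including the seed.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_alleles = 19L,
                       allele_freqs = NULL,
                       dirichlet_alpha = 1,
                       n_mothers_per_colony = 16L,
                       n_pairs_per_colony = 10L,
                       n_extra_pups_per_colony = 2L,
                       pabs_nonsyn_multiplier = 5,
                       mean_mutations = 2,
                       clones_per_individual = c(7L, 32L),
                       artifact_rate = 0.2,
                       bias_beta = 0,
                       n_microsat_loci = 41L,
                       microsat_alleles_range = c(4L, 10L),
                       seed = 1L) {
  stopifnot(n_alleles >= 1L,
            pabs_nonsyn_multiplier >= 1,
            length(clones_per_individual) == 2L,
            clones_per_individual[1] >= 1L,
            clones_per_individual[2] >= clones_per_individual[1],
            artifact_rate >= 0, artifact_rate <= 1,
            bias_beta >= 0,
            n_pairs_per_colony <= n_mothers_per_colony)
  if (!is.null(allele_freqs)) {
    if (length(allele_freqs) != n_alleles)
      stop("allele_freqs must have length n_alleles")
    if (abs(sum(allele_freqs) - 1) > 1e-12)
      stop("allele_freqs must sum to 1")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic allele pool
#'
#' Derives \code{n_alleles} distinct 267 bp coding alleles from a founder
#' sequence by placing random substitutions, with placement favouring the
#' pABS codons by factor \code{pabs_nonsyn_multiplier}; substitutions
#' landing in a pABS codon are forced to change the encoded amino acid,
#' emulating the elevated nonsynonymous variability that balancing
#' selection leaves at antigen-contact positions. No allele contains an
#' internal stop codon.
#'
#' @param config A \code{\link{sim_config}}.
#' @param founder Founder coding sequence (default: shipped reference exon).
#' @param pabs_codons 1-based pABS codon indices.
#' @return Data frame (class \code{allele_pool}) with columns \code{name}
#'   (\code{SIM-DQB*01} ...), \code{sequence} and \code{freq}.
#' @export
generate_allele_pool <- function(config = sim_config(),
                                 founder = default_config()$reference_exon,
                                 pabs_codons = default_config()$pabs_codons) {
  set.seed(config$seed)
  n <- config$n_alleles
  n_codons <- nchar(founder) / 3L
  stopifnot(n_codons == floor(n_codons))
  freqs <- config$allele_freqs
  if (is.null(freqs)) {
    g <- stats::rgamma(n, shape = config$dirichlet_alpha)
    freqs <- sort(g / sum(g), decreasing = TRUE)
  }
  w <- rep(1, n_codons)
  w[pabs_codons] <- config$pabs_nonsyn_multiplier
  seqs <- character(n)
  seqs[1] <- founder
  # when nonsynonymous diversity is enforced (multiplier > 1), alleles are
  # also required to translate into unique peptides, as a classical MHC
  # allele series does; under the neutral null (multiplier = 1) no
  # constraint beyond nucleotide distinctness is imposed, so synonymous
  # variants are not selected against
  enforce_pep <- config$pabs_nonsyn_multiplier > 1
  peps <- translate_alignment(founder)
  if (n > 1L) {
    for (i in 2:n) {
      ok <- FALSE
      for (attempt in 1:200) {
        cand <- mutate_coding(founder, w, pabs_codons, config$mean_mutations)
        pep <- translate_alignment(cand)
        if (!cand %in% seqs[seq_len(i - 1L)] &&
            (!enforce_pep || !pep %in% peps)) {
          seqs[i] <- cand; peps <- c(peps, pep); ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place requested allele diversity without ",
                    "stop codons or duplicates after bounded retries")
    }
  }
  pool <- data.frame(name = sprintf("SIM-DQB*%02d", seq_len(n)),
                     sequence = seqs, freq = freqs,
                     stringsAsFactors = FALSE)
  class(pool) <- c("allele_pool", "data.frame")
  pool
}

# one derived allele: n_mut substitutions placed with pABS-weighted codon
# choice; within a pABS codon, nonsynonymous changes are favoured by the
# same multiplier (multiplier 1 => fully uniform mutation, a neutral
# null); stop codons excluded everywhere
mutate_coding <- function(founder, codon_weights, pabs_codons, mean_mutations,
                          multiplier = max(codon_weights)) {
  s <- strsplit(founder, "", fixed = TRUE)[[1]]
  n_codons <- length(s) / 3L
  n_mut <- 1L + rpois(1L, max(mean_mutations - 1, 0))
  placed <- 0L
  guard <- 0L
  while (placed < n_mut && guard < 500L) {
    guard <- guard + 1L
    cd <- sample.int(n_codons, 1L, prob = codon_weights)
    idx <- (3L * (cd - 1L) + 1L):(3L * cd)
    codon <- paste(s[idx], collapse = "")
    cands <- codon_neighbours(codon)
    cands <- cands[!codon_aa(cands) %in% "*"]
    if (length(cands) == 0L) next
    w <- rep(1, length(cands))
    if (cd %in% pabs_codons)
      w[codon_aa(cands) != codon_aa(codon)] <- multiplier
    new_codon <- cands[sample.int(length(cands), 1L, prob = w)]
    s[idx] <- strsplit(new_codon, "", fixed = TRUE)[[1]]
    placed <- placed + 1L
  }
  paste(s, collapse = "")
}

# all 9 single-base neighbours of a codon
codon_neighbours <- function(codon) {
  b <- strsplit(codon, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (p in 1:3) for (alt in setdiff(c("A", "C", "G", "T"), b[p])) {
    nb <- b; nb[p] <- alt
    out <- c(out, paste(nb, collapse = ""))
  }
  out
}

#' Simulate genotypes and a pedigree for two colonies
#'
#' Mothers receive two independent alleles drawn from the pool frequencies
#' (Hardy-Weinberg); each pup inherits one uniformly chosen maternal allele
#' plus one paternal allele drawn from the pool frequencies. Both colonies
#' share the same allele-frequency law (the null of no structure).
#'
#' @param pool Allele pool from \code{\link{generate_allele_pool}}.
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{genotypes} (data frame: \code{individual_id},
#'   \code{colony}, \code{alleles}, \code{status}) and \code{pedigree}
#'   (data frame: \code{mother_id}, \code{pup_id}, \code{colony}).
#' @export
simulate_population <- function(pool, config = sim_config()) {
  stopifnot(nrow(pool) >= 1L)
  set.seed(config$seed + 1L)
  draw <- function(k) sample(pool$name, k, replace = TRUE, prob = pool$freq)
  rows <- list(); ped <- list()
  for (colony in c("SSB", "FWB")) {
    nm <- config$n_mothers_per_colony
    mothers <- sprintf("%s-M%02d", colony, seq_len(nm))
    mg <- lapply(seq_len(nm), function(i) draw(2L))
    for (i in seq_len(nm))
      rows[[length(rows) + 1L]] <- list(mothers[i], colony, mg[[i]])
    for (i in seq_len(config$n_pairs_per_colony)) {
      pup <- sprintf("%s-P%02d", colony, i)
      al <- c(mg[[i]][sample.int(2L, 1L)], draw(1L))
      rows[[length(rows) + 1L]] <- list(pup, colony, al)
      ped[[length(ped) + 1L]] <- data.frame(mother_id = mothers[i],
                                            pup_id = pup, colony = colony,
                                            stringsAsFactors = FALSE)
    }
    for (i in seq_len(config$n_extra_pups_per_colony)) {
      pup <- sprintf("%s-X%02d", colony, i)
      rows[[length(rows) + 1L]] <- list(pup, colony, draw(2L))
    }
  }
  genotypes <- data.frame(
    individual_id = vapply(rows, `[[`, character(1), 1L),
    colony = vapply(rows, `[[`, character(1), 2L),
    alleles = vapply(rows, function(r) paste(sort(unique(r[[3]])), collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  genotypes$status <- "ok"
  # keep the underlying diploid draw (with duplicates) for clone simulation
  genotypes$diploid <- vapply(rows, function(r) paste(r[[3]], collapse = ";"),
                              character(1))
  list(genotypes = genotypes,
       pedigree = if (length(ped)) do.call(rbind, ped) else
         data.frame(mother_id = character(0), pup_id = character(0),
                    colony = character(0)))
}

#' Simulate a clone library from genotypes
#'
#' Per individual, a clone count uniform on
#' \code{config$clones_per_individual}; each clone's template allele is
#' drawn from the individual's diploid genotype with weight proportional to
#' \code{exp(-bias_beta * mismatches(allele, primers))} (uniform over the
#' two gene copies when \code{bias_beta = 0} or \code{primers} is
#' \code{NULL}); with probability \code{artifact_rate} the clone then
#' receives 1-2 substitutions at uniform positions with Jukes-Cantor
#' uniform base choice.
#'
#' @param genotypes Genotype data frame from
#'   \code{\link{simulate_population}}.
#' @param pool Allele pool (for sequences and mismatch counts).
#' @param config A \code{\link{sim_config}}.
#' @param primers Optional primer set (list with \code{forward},
#'   \code{reverse}); needed only when \code{bias_beta > 0}.
#' @return List with \code{clones} (clone-record data frame) and
#'   \code{truth} (data frame: \code{clone_id}, \code{individual_id},
#'   \code{source_allele}, \code{is_artifact}).
#' @export
simulate_clone_library <- function(genotypes, pool, config = sim_config(),
                                   primers = NULL) {
  set.seed(config$seed + 2L)
  seq_of <- setNames(pool$sequence, pool$name)
  bias_w <- setNames(rep(1, nrow(pool)), pool$name)
  if (config$bias_beta > 0) {
    if (is.null(primers))
      stop("bias_beta > 0 requires a primer set")
    mm <- vapply(pool$sequence, primer_mismatch_count, numeric(1),
                 primer_set = primers)
    bias_w <- setNames(exp(-config$bias_beta * mm), pool$name)
  }
  lo <- config$clones_per_individual[1]; hi <- config$clones_per_individual[2]
  diploids <- strsplit(if (!is.null(genotypes$diploid)) genotypes$diploid
                       else genotypes$alleles, ";", fixed = TRUE)
  out <- list(); truth <- list()
  for (i in seq_len(nrow(genotypes))) {
    ind <- genotypes$individual_id[i]
    copies <- diploids[[i]]
    w <- bias_w[copies]
    if (all(w == 0))
      stop("all amplification weights zero for individual ", ind)
    k <- sample(lo:hi, 1L)
    templates <- copies[sample.int(length(copies), k, replace = TRUE, prob = w)]
    for (j in seq_len(k)) {
      sq <- seq_of[[templates[j]]]
      art <- runif(1) < config$artifact_rate
      if (art) {
        nmut <- sample(1:2, 1L)
        pos <- sample.int(nchar(sq), nmut)
        ch <- strsplit(sq, "", fixed = TRUE)[[1]]
        for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        sq <- paste(ch, collapse = "")
      }
      cid <- sprintf("%s|c%03d", ind, j)
      out[[length(out) + 1L]] <- list(cid, ind, sq)
      truth[[length(truth) + 1L]] <- list(cid, ind, templates[j], art)
    }
  }
  clones <- clone_records(
    vapply(out, `[[`, character(1), 1L),
    vapply(out, `[[`, character(1), 2L),
    vapply(out, `[[`, character(1), 3L))
  truth <- data.frame(
    clone_id = vapply(truth, `[[`, character(1), 1L),
    individual_id = vapply(truth, `[[`, character(1), 2L),
    source_allele = vapply(truth, `[[`, character(1), 3L),
    is_artifact = vapply(truth, `[[`, logical(1), 4L),
    stringsAsFactors = FALSE)
  list(clones = clones, truth = truth)
}

#' Simulate pedigree-consistent microsatellite genotypes
#'
#' Independent multinomial genotypes per locus from locus-specific
#' Dirichlet frequencies; pups inherit one maternal allele per locus, the
#' other drawn from the population frequencies, so parent-offspring pairs
#' carry the expected first-degree relatedness signal.
#'
#' @param genotypes Genotype table defining the individuals.
#' @param pedigree Mother-pup pairs to respect.
#' @param config A \code{\link{sim_config}}.
#' @return Long-format microsatellite data frame (see
#'   \code{\link{read_microsats}}).
#' @export
simulate_microsats <- function(genotypes, pedigree, config = sim_config()) {
  set.seed(config$seed + 3L)
  inds <- genotypes$individual_id
  mother_of <- setNames(pedigree$mother_id, pedigree$pup_id)
  res <- vector("list", config$n_microsat_loci)
  for (l in seq_len(config$n_microsat_loci)) {
    k <- sample(config$microsat_alleles_range[1]:config$microsat_alleles_range[2], 1L)
    g <- stats::rgamma(k, 1); p <- g / sum(g)
    labs <- sprintf("L%02d.%d", l, seq_len(k))
    a1 <- setNames(sample(labs, length(inds), TRUE, p), inds)
    a2 <- setNames(sample(labs, length(inds), TRUE, p), inds)
    for (pup in names(mother_of)) {
      m <- mother_of[[pup]]
      if (m %in% inds)
        a1[pup] <- if (runif(1) < 0.5) a1[m] else a2[m]
    }
    res[[l]] <- data.frame(individual_id = inds, locus = sprintf("L%02d", l),
                           allele1 = unname(a1), allele2 = unname(a2),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Simulate a complete synthetic study dataset
#'
#' Convenience wrapper chaining \code{\link{generate_allele_pool}},
#' \code{\link{simulate_population}}, \code{\link{simulate_clone_library}}
#' and \code{\link{simulate_microsats}} under one configuration.
#'
#' @param config A \code{\link{sim_config}}.
#' @param primers Optional primer set forwarded to the clone simulator.
#' @return List with \code{pool}, \code{genotypes}, \code{pedigree},
#'   \code{clones}, \code{truth}, \code{microsats} and the \code{config}.
#' @export
simulate_study <- function(config = sim_config(), primers = NULL) {
  pool <- generate_allele_pool(config)
  popn <- simulate_population(pool, config)
  lib <- simulate_clone_library(popn$genotypes, pool, config, primers)
  ms <- simulate_microsats(popn$genotypes, popn$pedigree, config)
  list(pool = pool, genotypes = popn$genotypes, pedigree = popn$pedigree,
       clones = lib$clones, truth = lib$truth, microsats = ms,
       config = config)
}
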