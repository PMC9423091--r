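# Independent brute-force oracles used to validate the matrix builders and
# selection accounting, plus small simulation helpers shared across tests.

# additive genomic relationship by explicit double loop
brute_G_additive <- function(dosage) {
  p <- colMeans(dosage) / 2
  denom <- 2 * sum(p * (1 - p))
  w <- sweep(dosage, 2, 2 * p, "-")
  n <- nrow(dosage)
  g <- matrix(0, n, n, dimnames = list(rownames(dosage), rownames(dosage)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    g[i, j] <- sum(w[i, ] * w[j, ]) / denom
  }
  g
}

# dominance genomic relationship by explicit double loop
brute_G_dominance <- function(dosage) {
  p <- colMeans(dosage) / 2
  q <- 1 - p
  denom <- sum((2 * p * q)^2)
  n <- nrow(dosage)
  h <- matrix(0, n, ncol(dosage))
  for (m in seq_len(ncol(dosage))) {
    codes <- c(-2 * q[m]^2, 2 * p[m] * q[m], -2 * p[m]^2)
    h[, m] <- codes[dosage[, m] + 1L]
  }
  g <- matrix(0, n, n, dimnames = list(rownames(dosage), rownames(dosage)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    g[i, j] <- sum(h[i, ] * h[j, ]) / denom
  }
  g
}

# gene-dropping Monte Carlo estimates of additive and dominance relationship:
# founders carry unique allele labels; alleles drop through the pedigree at
# n_loci independent loci.  Additive relationship = 2 * kinship; dominance
# relationship = probability both unordered parental allele pairs are IBD.
gene_drop_relationship <- function(ped, n_loci = 1e5L, seed = 1) {
  set.seed(seed)
  ids <- as.character(ped$id)
  mo <- match(as.character(ped$mother), ids)
  fa <- match(as.character(ped$father), ids)
  n <- length(ids)
  al1 <- matrix(0L, n, n_loci)
  al2 <- matrix(0L, n, n_loci)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (is.na(mo[i])) {
      al1[i, ] <- next_allele; al2[i, ] <- next_allele + 1L
      next_allele <- next_allele + 2L
    } else {
      pick <- stats::runif(n_loci) < 0.5
      al1[i, ] <- ifelse(pick, al1[mo[i], ], al2[mo[i], ])
      pick <- stats::runif(n_loci) < 0.5
      al2[i, ] <- ifelse(pick, al1[fa[i], ], al2[fa[i], ])
    }
  }
  kin <- function(i, j) {
    0.25 * (rowMeans(rbind(al1[i, ] == al1[j, ], al1[i, ] == al2[j, ],
                           al2[i, ] == al1[j, ], al2[i, ] == al2[j, ])))
  }
  add <- matrix(0, n, n, dimnames = list(ids, ids))
  dom <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k4 <- (al1[i, ] == al1[j, ]) + (al1[i, ] == al2[j, ]) +
      (al2[i, ] == al1[j, ]) + (al2[i, ] == al2[j, ])
    add[i, j] <- 2 * mean(k4 / 4)
    both <- (al1[i, ] == al1[j, ]) & (al2[i, ] == al2[j, ]) |
      (al1[i, ] == al2[j, ]) & (al2[i, ] == al1[j, ])
    dom[i, j] <- mean(both)
  }
  list(additive = add, dominance = dom, n_loci = n_loci)
}

# group coancestry / status number by explicit double loop over ordered pairs
brute_status_number <- function(A, ids) {
  s <- 0
  for (i in ids) for (j in ids) s <- s + A[i, j] / 2
  theta <- s / length(ids)^2
  1 / (2 * theta)
}

# small clean polycross trial reused by several tests
clean_trial <- function(n_females = 6, n_males = 5, n_snps = 800,
                        offspring_per_family = 30, n_sites = 2, seed = 99,
                        ...) {
  cfg <- sim_config(n_females = n_females, n_males = n_males,
                    n_snps = n_snps,
                    offspring_per_family = offspring_per_family,
                    n_sites = n_sites, maternal_mislabel_rate = 0,
                    dual_genotype_mother_fraction = 0,
                    contamination_rate = 0, selfing_rate = 0, seed = seed,
                    ...)
  founders <- simulate_founders(cfg)
  cross <- simulate_polycross(founders, cfg)
  design <- make_design(rownames(cross$dosage), cfg)
  list(cfg = cfg, founders = founders, cross = cross, design = design)
}
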