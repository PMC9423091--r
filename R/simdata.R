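#' Configuration for a synthetic polycross trial
#'
#' Defines the mating design and error structure of a simulated polycross
#' progeny trial: a set of maternal families each pollinated with a shared
#' pollen mix of known donors contributed in unequal proportions, with the
#' pedigree-corrupting processes observed in operational trials (maternal
#' mislabeling, mothers represented by two distinct genotypes, pollen
#' contamination from outside the mix, and selfing).
#'
#' Defaults mirror the structure of a realistic conifer polycross trial:
#' 26 maternal parents crossed with a 21-donor pollen mix, strongly unequal
#' male contributions (symmetric Dirichlet weights), 12% maternal mislabels,
#' 8/26 dual-genotype mothers, 5% pollen contamination, 1% selfing, and three
#' test sites with single-tree plots in replicates subdivided into sets.
#'
#' @param n_females,n_males numbers of maternal parents and pollen donors.
#' @param n_snps number of unlinked biallelic SNPs.
#' @param maf_range range of per-SNP allele frequencies, drawn uniformly.
#' @param offspring_per_family single count or per-family vector.
#' @param male_weights pollen-mix contribution probabilities (length
#'   `n_males`, summing to 1) or `NULL` to draw from a symmetric Dirichlet.
#' @param dirichlet_alpha concentration for the default Dirichlet weights.
#' @param maternal_mislabel_rate probability an offspring's recorded mother
#'   differs from its true mother.
#' @param dual_genotype_mother_fraction fraction of mothers whose recorded id
#'   covers two distinct genotypes (the second is a hidden founder).
#' @param contamination_rate probability the true father is an unsampled
#'   foreign tree outside the pollen mix.
#' @param selfing_rate probability the mother pollinates herself.
#' @param n_shared_parents number of parents used in both female and male
#'   roles (genotype shared between the two role lists).
#' @param n_sites,reps_per_site,sets_per_rep trial layout.
#' @param site_means fixed site means used by [simulate_phenotypes()].
#' @param seed integer seed controlling all randomness downstream.
#' @return an object of class `px_simconfig` (a validated list).
#' @export
sim_config <- function(n_females = 26L, n_males = 21L, n_snps = 2000L,
                       maf_range = c(0.05, 0.5), offspring_per_family = 58L,
                       male_weights = NULL, dirichlet_alpha = 1,
                       maternal_mislabel_rate = 0.12,
                       dual_genotype_mother_fraction = 8 / 26,
                       contamination_rate = 0.05, selfing_rate = 0.01,
                       n_shared_parents = 0L,
                       n_sites = 3L, reps_per_site = 5L, sets_per_rep = 4L,
                       site_means = NULL, seed = 1L) {
  stopifnot(n_females >= 1, n_males >= 1, n_snps >= 1,
            n_females + n_males >= 2)
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be an increasing pair within (0, 0.5]")
  rates <- c(maternal_mislabel_rate, dual_genotype_mother_fraction,
             contamination_rate, selfing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (!is.null(male_weights)) {
    if (length(male_weights) != n_males)
      stop("male_weights must have length n_males")
    if (abs(sum(male_weights) - 1) > 1e-12 || any(male_weights < 0))
      stop("male_weights must be a probability vector summing to 1")
  }
  if (n_shared_parents > min(n_females, n_males))
    stop("n_shared_parents exceeds parent counts")
  if (is.null(site_means)) site_means <- 100 + 10 * seq_len(n_sites)
  cfg <- list(n_females = as.integer(n_females), n_males = as.integer(n_males),
              n_snps = as.integer(n_snps), maf_range = maf_range,
              offspring_per_family = offspring_per_family,
              male_weights = male_weights, dirichlet_alpha = dirichlet_alpha,
              maternal_mislabel_rate = maternal_mislabel_rate,
              dual_genotype_mother_fraction = dual_genotype_mother_fraction,
              contamination_rate = contamination_rate,
              selfing_rate = selfing_rate,
              n_shared_parents = as.integer(n_shared_parents),
              n_sites = as.integer(n_sites),
              reps_per_site = as.integer(reps_per_site),
              sets_per_rep = as.integer(sets_per_rep),
              site_means = site_means, seed = as.integer(seed))
  class(cfg) <- "px_simconfig"
  cfg
}

#' Trait architecture for the phenotype simulator
#'
#' Variance components follow the individual-tree model used in multi-site
#' progeny-trial analysis: additive, site-by-additive, dominance,
#' site-by-dominance, and heterogeneous residual variances, plus optional
#' replicate/set design variances and fixed covariate regressions. Wood-like
#' traits can be flagged lognormal: they are simulated on the log scale and
#' exponentiated.
#'
#' @param name trait label.
#' @param sigma2_a,sigma2_sa,sigma2_d,sigma2_sd genetic variance components.
#' @param sigma2_e_by_site residual variance, one value per site (recycled).
#' @param sigma2_rep,sigma2_set design-effect variances.
#' @param lognormal flag; simulate on log scale and exponentiate.
#' @param covariate_effects named numeric vector of fixed regression
#'   coefficients on standard-normal covariates (e.g. ring count analogues).
#' @return an object of class `px_traitconfig`.
#' @export
trait_config <- function(name, sigma2_a, sigma2_e_by_site, sigma2_sa = 0,
                         sigma2_d = 0, sigma2_sd = 0, sigma2_rep = 0,
                         sigma2_set = 0, lognormal = FALSE,
                         covariate_effects = NULL) {
  vars <- c(sigma2_a, sigma2_sa, sigma2_d, sigma2_sd, sigma2_e_by_site,
            sigma2_rep, sigma2_set)
  if (any(vars < 0)) stop("variances must be non-negative")
  structure(list(name = name, sigma2_a = sigma2_a, sigma2_sa = sigma2_sa,
                 sigma2_d = sigma2_d, sigma2_sd = sigma2_sd,
                 sigma2_e_by_site = sigma2_e_by_site,
                 sigma2_rep = sigma2_rep, sigma2_set = sigma2_set,
                 lognormal = lognormal, covariate_effects = covariate_effects),
            class = "px_traitconfig")
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

hwe_draw <- function(n, p) {
  stats::rbinom(n, 2L, p)
}

#' Simulate unrelated founder genotypes
#'
#' Draws founder dosages per SNP as Hardy-Weinberg binomial draws at an
#' allele frequency sampled uniformly from the configured range. Founders are
#' unrelated and non-inbred; parents used in both sexual roles share one
#' genotype under both ids' roles.
#'
#' @param config a [sim_config()] object.
#' @return list with `dosage` (founders x SNPs, rownames `F..`/`M..`),
#'   `pedigree` (founder rows with `NA` parents and a `role` column), and
#'   `allele_freq` (the generating frequencies, used for foreign
#'   contaminant genotypes).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "px_simconfig"))
  set.seed(config$seed)
  p <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  fem_ids <- sprintf("F%02d", seq_len(config$n_females))
  mal_ids <- sprintf("M%02d", seq_len(config$n_males))
  n_unique <- config$n_females + config$n_males - config$n_shared_parents
  geno <- matrix(0L, n_unique, config$n_snps)
  for (m in seq_len(config$n_snps)) geno[, m] <- hwe_draw(n_unique, p[m])
  ## shared parents: the last n_shared females double as the first males
  unique_ids <- c(fem_ids,
                  if (config$n_shared_parents < config$n_males)
                    mal_ids[seq.int(config$n_shared_parents + 1L,
                                    config$n_males)])
  rownames(geno) <- unique_ids
  colnames(geno) <- sprintf("snp%05d", seq_len(config$n_snps))
  role <- c(rep("female", config$n_females),
            rep("male", nrow(geno) - config$n_females))
  shared_map <- NULL
  if (config$n_shared_parents > 0) {
    shared_map <- stats::setNames(fem_ids[seq_len(config$n_shared_parents)],
                                  mal_ids[seq_len(config$n_shared_parents)])
  }
  ped <- data.frame(id = unique_ids, mother = NA_character_,
                    father = NA_character_, role = role,
                    stringsAsFactors = FALSE)
  list(dosage = geno, pedigree = ped, allele_freq = p,
       female_ids = fem_ids, male_ids = mal_ids, shared_map = shared_map)
}

mendel_gamete <- function(dosage_row) {
  ## one allele per SNP: deterministic for homozygotes, fair coin for hets
  out <- dosage_row / 2
  het <- dosage_row == 1L
  out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  as.integer(out)
}

#' Simulate a polycross offspring generation with ground truth
#'
#' Each maternal family receives offspring whose true fathers are drawn from
#' the pollen-mix contribution weights, replaced by the mother herself
#' (selfing) or by a freshly simulated unrelated foreign tree (pollen
#' contamination) at the configured rates. Gametes segregate independently
#' per SNP (unlinked loci). The recorded pedigree then corrupts the truth:
#' maternal mislabels swap the recorded mother, and for dual-genotype mothers
#' a hidden second genotype truly mothers a Uniform(0.3, 0.7) fraction of the
#' family while the records keep the original id.
#'
#' @param founders output of [simulate_founders()].
#' @param config the same [sim_config()] object.
#' @return list with `dosage` (offspring x SNPs), `truth` (a list holding
#'   `true_pedigree`, `recorded_pedigree`, `status` per offspring, the
#'   hidden-mother dosages in `extra_founders`, and the realized
#'   `male_weights`).
#' @export
simulate_polycross <- function(founders, config) {
  stopifnot(inherits(config, "px_simconfig"))
  set.seed(config$seed + 1L)
  weights <- config$male_weights
  if (is.null(weights))
    weights <- rdirichlet1(config$n_males, config$dirichlet_alpha)
  fem <- founders$female_ids
  mal <- founders$male_ids
  offn <- config$offspring_per_family
  if (length(offn) == 1L) offn <- rep(offn, config$n_females)
  stopifnot(length(offn) == config$n_females)

  n_dual <- round(config$dual_genotype_mother_fraction * config$n_females)
  dual_mothers <- if (n_dual > 0) sort(sample(fem, n_dual)) else character(0)
  p <- founders$allele_freq
  n_snps <- config$n_snps

  ## hidden second genotypes for dual-genotype mothers
  extra <- list()
  for (dm in dual_mothers) {
    g <- vapply(p, function(pp) hwe_draw(1L, pp), integer(1))
    extra[[paste0(dm, "_B")]] <- g
  }

  geno_of <- function(id) {
    if (id %in% rownames(founders$dosage)) return(founders$dosage[id, ])
    if (!is.null(founders$shared_map) && id %in% names(founders$shared_map))
      return(founders$dosage[founders$shared_map[[id]], ])
    if (id %in% names(extra)) return(extra[[id]])
    stop("unknown parent genotype: ", id)
  }

  total <- sum(offn)
  off_ids <- sprintf("O%04d", seq_len(total))
  dosage <- matrix(0L, total, n_snps,
                   dimnames = list(off_ids, colnames(founders$dosage)))
  true_mother <- true_father <- rec_mother <- character(total)
  status <- character(total)
  k <- 0L
  n_foreign <- 0L
  for (fidx in seq_along(fem)) {
    fam_mother <- fem[fidx]
    fam_size <- offn[fidx]
    ## dual-genotype: which of this family's offspring come from the hidden tree
    hidden_frac <- 0
    if (fam_mother %in% dual_mothers) hidden_frac <- stats::runif(1, 0.3, 0.7)
    hidden_pick <- stats::runif(fam_size) < hidden_frac
    for (o in seq_len(fam_size)) {
      k <- k + 1L
      tm <- if (hidden_pick[o]) paste0(fam_mother, "_B") else fam_mother
      u <- stats::runif(1)
      if (u < config$selfing_rate) {
        tf <- tm
        st <- "self"
      } else if (u < config$selfing_rate + config$contamination_rate) {
        n_foreign <- n_foreign + 1L
        tf <- sprintf("X%03d", n_foreign)
        extra[[tf]] <- vapply(p, function(pp) hwe_draw(1L, pp), integer(1))
        st <- "contaminant"
      } else {
        tf <- sample(mal, 1L, prob = weights)
        st <- "clean"
      }
      dosage[k, ] <- mendel_gamete(geno_of(tm)) + mendel_gamete(geno_of(tf))
      rm_ <- fam_mother
      if (st == "clean" && hidden_pick[o]) st <- "dual_genotype"
      if (stats::runif(1) < config$maternal_mislabel_rate &&
          config$n_females > 1L) {
        rm_ <- sample(setdiff(fem, fam_mother), 1L)
        if (st == "clean") st <- "mislabeled_mother"
      }
      true_mother[k] <- tm; true_father[k] <- tf
      rec_mother[k] <- rm_; status[k] <- st
    }
  }
  true_ped <- data.frame(id = off_ids, mother = true_mother,
                         father = true_father, stringsAsFactors = FALSE)
  rec_ped <- data.frame(id = off_ids, mother = rec_mother,
                        father = NA_character_, stringsAsFactors = FALSE)
  extra_mat <- if (length(extra))
    matrix(unlist(extra), nrow = length(extra), byrow = TRUE,
           dimnames = list(names(extra), colnames(founders$dosage)))
  else NULL
  list(dosage = dosage,
       truth = list(true_pedigree = true_ped, recorded_pedigree = rec_ped,
                    status = stats::setNames(status, off_ids),
                    extra_founders = extra_mat, male_weights = weights,
                    dual_mothers = dual_mothers))
}

#' Assign offspring to a multi-site single-tree-plot layout
#'
#' Randomly allocates individuals to sites, replicates within site, and sets
#' (incomplete blocks) within replicate, as evenly as possible.
#'
#' @param ids individual ids.
#' @param config a [sim_config()] object (layout fields and seed are used).
#' @return data.frame `id`, `site`, `rep`, `set`.
#' @export
make_design <- function(ids, config) {
  set.seed(config$seed + 2L)
  n <- length(ids)
  site <- sample(rep_len(seq_len(config$n_sites), n))
  rep_ <- integer(n); set_ <- integer(n)
  for (s in seq_len(config$n_sites)) {
    idx <- which(site == s)
    rep_[idx] <- sample(rep_len(seq_len(config$reps_per_site), length(idx)))
    for (r in seq_len(config$reps_per_site)) {
      jdx <- idx[rep_[idx] == r]
      set_[jdx] <- sample(rep_len(seq_len(config$sets_per_rep), length(jdx)))
    }
  }
  data.frame(id = ids, site = paste0("S", site),
             rep = paste0("R", rep_), set = paste0("B", set_),
             stringsAsFactors = FALSE)
}

## draw n-vector from N(0, sigma2 * K) via Cholesky with a small jitter
mvn_kernel <- function(kernel, sigma2) {
  if (sigma2 <= 0) return(stats::setNames(numeric(nrow(kernel)), rownames(kernel)))
  L <- chol(unclass(kernel) + diag(1e-8, nrow(kernel)))
  stats::setNames(drop(crossprod(L, stats::rnorm(nrow(kernel)))) * sqrt(sigma2),
                  rownames(kernel))
}

#' Simulate phenotypes under the individual-tree model
#'
#' Generates \eqn{y = site + rep(site) + set(rep) + a + sa + d + sd + e}
#' with the additive and dominance effects drawn from marker-derived kernels
#' of the true genotypes (or user-supplied kernels), the site-by-genetic
#' interactions drawn independently per site from the same kernels, and
#' heterogeneous residuals by site. Lognormal traits are simulated on the log
#' scale around `log(site mean)` and exponentiated.
#'
#' @param dosage offspring dosage matrix (true genotypes).
#' @param design output of [make_design()].
#' @param traits list of [trait_config()] objects.
#' @param config a [sim_config()] object (site means and seed).
#' @param kernel_a,kernel_d optional relationship kernels; defaults are the
#'   marker-derived [G_additive()] / [G_dominance()] of `dosage`.
#' @return list with `phenotypes` (data.frame: id, site, rep, set, covariates,
#'   one column per trait) and `truth` (per-trait list of the generating
#'   additive/dominance values and site-specific genetic values).
#' @export
simulate_phenotypes <- function(dosage, design, traits, config,
                                kernel_a = NULL, kernel_d = NULL) {
  stopifnot(all(design$id %in% rownames(dosage)))
  set.seed(config$seed + 3L)
  ids <- design$id
  n <- length(ids)
  if (is.null(kernel_a)) kernel_a <- G_additive(dosage[ids, , drop = FALSE])
  need_d <- any(vapply(traits, function(t) t$sigma2_d > 0 || t$sigma2_sd > 0,
                       logical(1)))
  if (need_d && is.null(kernel_d))
    kernel_d <- G_dominance(dosage[ids, , drop = FALSE])
  sites <- sort(unique(design$site))
  if (length(config$site_means) < length(sites))
    stop("site_means shorter than number of sites")
  covar_names <- unique(unlist(lapply(traits, function(t)
    names(t$covariate_effects))))
  covars <- NULL
  if (length(covar_names)) {
    covars <- matrix(stats::rnorm(n * length(covar_names)), n,
                     dimnames = list(ids, covar_names))
  }
  pheno <- data.frame(design, stringsAsFactors = FALSE)
  if (!is.null(covars)) pheno <- cbind(pheno, as.data.frame(covars))
  truth <- list()
  for (tc in traits) {
    se_site <- rep_len(tc$sigma2_e_by_site, length(sites))
    site_mu <- config$site_means[seq_along(sites)]
    if (tc$lognormal) site_mu <- log(site_mu)
    mu <- site_mu[match(design$site, sites)]
    rep_f <- interaction(design$site, design$rep, drop = TRUE)
    set_f <- interaction(design$site, design$rep, design$set, drop = TRUE)
    rep_eff <- stats::rnorm(nlevels(rep_f), 0, sqrt(tc$sigma2_rep))[rep_f]
    set_eff <- stats::rnorm(nlevels(set_f), 0, sqrt(tc$sigma2_set))[set_f]
    a <- mvn_kernel(kernel_a, tc$sigma2_a)
    d <- if (tc$sigma2_d > 0) mvn_kernel(kernel_d, tc$sigma2_d) else
      stats::setNames(numeric(n), ids)
    sa <- sd_ <- stats::setNames(numeric(n), ids)
    sval <- matrix(a[ids], n, length(sites), dimnames = list(ids, sites))
    for (si in seq_along(sites)) {
      idx <- design$site == sites[si]
      if (tc$sigma2_sa > 0) {
        sa_s <- mvn_kernel(kernel_a, tc$sigma2_sa)
        sval[, si] <- sval[, si] + sa_s[ids]
        sa[idx] <- sa_s[ids][idx]
      }
      if (tc$sigma2_sd > 0) sd_[idx] <- mvn_kernel(kernel_d, tc$sigma2_sd)[idx]
    }
    e <- stats::rnorm(n, 0, sqrt(se_site[match(design$site, sites)]))
    y <- mu + rep_eff + set_eff + a[ids] + sa[ids] + d[ids] + sd_[ids] + e
    if (!is.null(tc$covariate_effects)) {
      y <- y + drop(covars[, names(tc$covariate_effects), drop = FALSE] %*%
                      tc$covariate_effects)
    }
    if (tc$lognormal) y <- exp(y)
    pheno[[tc$name]] <- y
    truth[[tc$name]] <- list(a = a[ids], d = d[ids], sa_realized = sa[ids],
                             site_values = sval)
  }
  list(phenotypes = pheno, truth = truth)
}
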