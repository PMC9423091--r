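# Balanced designs with closed-form REML solutions anchor the AI-REML
# engine; the remaining tests exercise the genetic-parameter layer.

test_that("balanced half-sib REML matches the closed-form estimator", {
  set.seed(42)
  s <- 20; n <- 15
  sire <- rep(paste0("P", seq_len(s)), each = n)
  ids <- sprintf("o%03d", seq_len(s * n))
  ped <- rbind(data.frame(id = unique(sire), mother = NA, father = NA),
               data.frame(id = ids, mother = NA, father = sire))
  Aoff <- A_additive(ped)[ids, ids]
  a <- drop(crossprod(chol(unclass(Aoff) + diag(1e-8, s * n)),
                      stats::rnorm(s * n))) * sqrt(0.3)
  y <- 10 + a + stats::rnorm(s * n, 0, sqrt(0.7))
  df <- data.frame(id = ids, site = "S1", rep = "R1", set = "B1", y = y)
  fit <- fit_treemodel(df, "y", Aoff, random = "additive")
  aovt <- stats::anova(stats::lm(y ~ factor(sire)))
  msb <- aovt[["Mean Sq"]][1]; msw <- aovt[["Mean Sq"]][2]
  sb <- (msb - msw) / n
  expect_equal(unname(varcomp(fit)["additive"]), 4 * sb, tolerance = 1e-6)
  expect_equal(unname(varcomp(fit)["residual_S1"]), msw - 3 * sb,
               tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("identity kernel with grouped records reproduces one-way REML", {
  # 30 'individuals' each recorded 8 times: the additive term with an
  # identity kernel is then an ordinary random group effect
  set.seed(7)
  g <- 30; r <- 8
  gid <- rep(sprintf("g%02d", seq_len(g)), each = r)
  K <- diag(1, g); dimnames(K) <- list(unique(gid), unique(gid))
  y <- 5 + rep(stats::rnorm(g, 0, sqrt(2)), each = r) +
    stats::rnorm(g * r, 0, 1)
  df <- data.frame(id = gid, site = "S1", rep = "R1", set = "B1", y = y)
  fit <- fit_treemodel(df, "y", K, random = "additive")
  aovt <- stats::anova(stats::lm(y ~ factor(gid)))
  msb <- aovt[["Mean Sq"]][1]; msw <- aovt[["Mean Sq"]][2]
  expect_equal(unname(varcomp(fit)["additive"]), (msb - msw) / r,
               tolerance = 1e-6)
  expect_equal(unname(varcomp(fit)["residual_S1"]), msw, tolerance = 1e-6)
})

test_that("BLUP solutions solve the mixed-model equations", {
  set.seed(11)
  tr <- clean_trial(n_females = 4, n_males = 3, n_snps = 500,
                    offspring_per_family = 25, n_sites = 1, seed = 123)
  ids <- tr$design$id
  G <- G_additive(tr$cross$dosage)
  tc <- trait_config("y", sigma2_a = 1, sigma2_e_by_site = 2)
  ph <- simulate_phenotypes(tr$cross$dosage, tr$design, list(tc), tr$cfg)
  df <- cbind(id = ids, ph$phenotypes[setdiff(names(ph$phenotypes), "id")])
  fit <- fit_treemodel(df, "y", G, random = "additive")
  th <- varcomp(fit)
  # independent route: Henderson's equations at the converged components
  y <- df$y
  X <- matrix(1, length(y), 1)
  Kj <- unclass(G)[ids, ids] + diag(1e-8, length(ids))
  Kinv <- solve(Kj)
  lambda <- th["residual_S1"] / th["additive"]
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(1, length(y)) + lambda * Kinv))
  rhs <- c(crossprod(X, y), y)
  sol <- solve(C, rhs)
  bv <- breeding_values(fit)
  expect_equal(unname(sol[1]), unname(coef(fit)[1]), tolerance = 1e-6)
  expect_equal(unname(sol[-1]), unname(bv$value[match(ids, bv$id)]),
               tolerance = 1e-5)
  # prediction-error variances from the inverse coefficient matrix
  pev <- unname(diag(solve(C))[-1] * th["residual_S1"])
  expect_equal(sqrt(pev), unname(bv$se[match(ids, bv$id)]),
               tolerance = 1e-4)
})

test_that("variance components are recovered across simulated replicates", {
  truth <- c(rep_in_site = 4, set_in_rep = 3, additive = 25,
             site_x_additive = 10, residual_S1 = 60, residual_S2 = 80)
  cover <- c()
  for (r in 1:5) {
    cfg <- sim_config(n_females = 8, n_males = 6, n_snps = 1200,
                      offspring_per_family = 60, n_sites = 2,
                      maternal_mislabel_rate = 0,
                      dual_genotype_mother_fraction = 0,
                      contamination_rate = 0, selfing_rate = 0,
                      seed = 9000 + r)
    f <- simulate_founders(cfg)
    x <- simulate_polycross(f, cfg)
    des <- make_design(rownames(x$dosage), cfg)
    tc <- trait_config("y", sigma2_a = 25, sigma2_sa = 10,
                       sigma2_e_by_site = c(60, 80), sigma2_rep = 4,
                       sigma2_set = 3)
    ph <- simulate_phenotypes(x$dosage, des, list(tc), cfg)
    G <- G_additive(x$dosage)
    fit <- fit_treemodel(cbind(id = des$id,
                               ph$phenotypes[setdiff(names(ph$phenotypes),
                                                     "id")]),
                         "y", G)
    vc <- fit$vc
    est <- stats::setNames(vc$estimate, vc$component)[names(truth)]
    se <- stats::setNames(vc$se, vc$component)[names(truth)]
    cover <- c(cover, abs(est - truth) <= 2 * se)
  }
  expect_gte(mean(cover), 0.85)
})

test_that("likelihood-ratio test behaves at the null and under signal", {
  tr <- clean_trial(n_females = 6, n_males = 5, n_snps = 800,
                    offspring_per_family = 60, n_sites = 3, seed = 77)
  tc <- trait_config("y", sigma2_a = 20, sigma2_sa = 40,
                     sigma2_e_by_site = c(50, 50, 50))
  ph <- simulate_phenotypes(tr$cross$dosage, tr$design, list(tc), tr$cfg)
  df <- cbind(id = tr$design$id,
              ph$phenotypes[setdiff(names(ph$phenotypes), "id")])
  G <- G_additive(tr$cross$dosage)
  full <- fit_treemodel(df, "y", G, random = c("additive", "site_x_additive"))
  red <- fit_treemodel(df, "y", G, random = "additive")
  lr <- lrt_component(full, red)
  expect_equal(lr$term, "site_x_additive")
  expect_equal(lr$p_value,
               stats::pchisq(lr$stat, 1, lower.tail = FALSE))
  expect_equal(lr$p_value_mixture, lr$p_value / 2)
  expect_lt(lr$p_value, 0.05)  # strong simulated interaction
  expect_error(lrt_component(red, full), "nested")
})

test_that("heritability and type-B formulas match the printed-table arithmetic", {
  h <- heritability(list(sigma2_a = 1468, sigma2_sa = 824, sigma2_e = 8753))
  expect_equal(round(h$estimate, 2), 0.13)
  h2 <- heritability(list(sigma2_a = 0.14, sigma2_sa = 0.06, sigma2_e = 0.54))
  expect_equal(round(h2$estimate, 2), 0.19)
  H <- heritability(list(sigma2_a = 1158, sigma2_sa = 694, sigma2_d = 1049,
                         sigma2_sd = 1685, sigma2_e = 6044), mode = "broad")
  expect_equal(round(H$estimate, 2), 0.21)
  # with no interaction or dominance variance, H2 equals h2
  comps <- list(sigma2_a = 2, sigma2_sa = 0, sigma2_d = 0, sigma2_sd = 0,
                sigma2_e = 6)
  expect_equal(heritability(comps, "broad")$estimate,
               heritability(comps, "narrow")$estimate)
  expect_error(heritability(list(sigma2_a = 0, sigma2_e = 0)), "denominator")

  rb <- typeB_correlation(list(sigma2_a = 1468, sigma2_sa = 824))
  expect_equal(round(rb$estimate, 2), 0.64)
  rb2 <- typeB_correlation(list(sigma2_a = 58, sigma2_sa = 56))
  expect_equal(round(rb2$estimate, 2), 0.51)
  expect_equal(typeB_correlation(list(sigma2_a = 5, sigma2_sa = 0))$estimate, 1)
  expect_true(is.na(typeB_correlation(list(sigma2_a = 0,
                                           sigma2_sa = 0))$estimate))
})

test_that("delta-method standard errors propagate the component covariance", {
  tr <- clean_trial(n_females = 6, n_males = 5, n_snps = 800,
                    offspring_per_family = 40, n_sites = 2, seed = 888)
  tc <- trait_config("y", sigma2_a = 20, sigma2_sa = 8,
                     sigma2_e_by_site = c(50, 60))
  ph <- simulate_phenotypes(tr$cross$dosage, tr$design, list(tc), tr$cfg)
  df <- cbind(id = tr$design$id,
              ph$phenotypes[setdiff(names(ph$phenotypes), "id")])
  fit <- fit_treemodel(df, "y", G_additive(tr$cross$dosage),
                       random = c("additive", "site_x_additive"))
  h <- heritability(fit)
  rb <- typeB_correlation(fit)
  expect_true(is.finite(h$se) && h$se > 0 && h$se < 1)
  expect_true(is.finite(rb$se) && rb$se > 0 && rb$se < 1)
})

test_that("theoretical accuracy evaluates the reliability formula", {
  expect_equal(theoretical_accuracy(se = 0, F = 0, sigma2_a = 1), 1)
  expect_equal(theoretical_accuracy(se = 1, F = 0, sigma2_a = 1), 0)
  expect_equal(theoretical_accuracy(se = 0.6, F = 0, sigma2_a = 1), 0.8)
  expect_equal(theoretical_accuracy(se = sqrt(1.5), F = 0.5, sigma2_a = 1), 0)
  # from a fitted model: parents gain accuracy over unphenotyped strangers
  tr <- clean_trial(n_females = 5, n_males = 4, n_snps = 600,
                    offspring_per_family = 30, n_sites = 1, seed = 99)
  tc <- trait_config("y", sigma2_a = 2, sigma2_e_by_site = 2)
  ph <- simulate_phenotypes(tr$cross$dosage, tr$design, list(tc), tr$cfg)
  df <- cbind(id = tr$design$id,
              ph$phenotypes[setdiff(names(ph$phenotypes), "id")])
  G <- G_additive(rbind(tr$founders$dosage, tr$cross$dosage))
  fit <- fit_treemodel(df, "y", G, random = "additive")
  acc <- theoretical_accuracy(fit)
  expect_true(all(acc$accuracy >= 0 & acc$accuracy <= 1))
  expect_gt(mean(acc$accuracy[acc$id %in% tr$design$id]), 0.3)
})

test_that("adjusted phenotypes strip design effects only", {
  tr <- clean_trial(n_females = 4, n_males = 3, n_snps = 300,
                    offspring_per_family = 20, n_sites = 2, seed = 444)
  tc <- trait_config("y", sigma2_a = 10, sigma2_sa = 0,
                     sigma2_e_by_site = c(30, 30), sigma2_rep = 5,
                     sigma2_set = 4)
  ph <- simulate_phenotypes(tr$cross$dosage, tr$design, list(tc), tr$cfg)
  df <- cbind(id = tr$design$id,
              ph$phenotypes[setdiff(names(ph$phenotypes), "id")])
  ystar <- adjusted_phenotypes(df, "y")
  expect_lte(stats::var(ystar), stats::var(df$y))
  # data that are exactly site means adjust to exactly zero
  tc0 <- trait_config("z", sigma2_a = 0, sigma2_e_by_site = 0)
  ph0 <- simulate_phenotypes(tr$cross$dosage, tr$design, list(tc0), tr$cfg)
  df0 <- cbind(id = tr$design$id,
               ph0$phenotypes[setdiff(names(ph0$phenotypes), "id")])
  z <- adjusted_phenotypes(df0, "z")
  mu <- tapply(df0$z, df0$site, mean)
  expect_equal(unname(z), as.vector(df0$z - mu[df0$site]), tolerance = 1e-8)
})

test_that("bivariate genetic correlation recovers extremes and shared signal", {
  tr <- clean_trial(n_females = 6, n_males = 5, n_snps = 800,
                    offspring_per_family = 35, n_sites = 2, seed = 202)
  ids <- tr$design$id
  G <- G_additive(tr$cross$dosage)
  set.seed(5)
  L <- chol(unclass(G)[ids, ids] + diag(1e-8, length(ids)))
  a <- drop(crossprod(L, stats::rnorm(length(ids)))) * sqrt(0.5)
  y1 <- 10 + a + stats::rnorm(length(ids), 0, sqrt(0.5))
  df <- data.frame(id = ids, site = tr$design$site, rep = tr$design$rep,
                   set = tr$design$set, y1 = y1, y2 = -y1,
                   y3 = 10 + a + stats::rnorm(length(ids), 0, sqrt(0.5)))
  # mirrored trait: perfect negative genetic correlation
  gc_neg <- suppressWarnings(genetic_correlation(df, "y1", "y2", G))
  expect_equal(gc_neg$estimate, -1, tolerance = 0.02)
  # shared additive signal: strong positive correlation, flagged significant
  gc_pos <- genetic_correlation(df, "y1", "y3", G)
  expect_true(gc_pos$converged)
  expect_gt(gc_pos$estimate, 1 - 2 * gc_pos$se - 0.05)
  expect_true(gc_pos$significant)
})

test_that("constrained components are held fixed during maximization", {
  tr <- clean_trial(n_females = 5, n_males = 4, n_snps = 600,
                    offspring_per_family = 30, n_sites = 2, seed = 66)
  tc <- trait_config("y", sigma2_a = 15, sigma2_sa = 6,
                     sigma2_e_by_site = c(40, 50))
  ph <- simulate_phenotypes(tr$cross$dosage, tr$design, list(tc), tr$cfg)
  df <- cbind(id = tr$design$id,
              ph$phenotypes[setdiff(names(ph$phenotypes), "id")])
  G <- G_additive(tr$cross$dosage)
  fit <- fit_treemodel(df, "y", G, random = c("additive", "site_x_additive"),
                       constrained_components = c(additive = 15,
                                                  site_x_additive = 6))
  vc <- varcomp(fit)
  expect_equal(unname(vc["additive"]), 15)
  expect_equal(unname(vc["site_x_additive"]), 6)
  expect_true(all(fit$vc$constrained[fit$vc$component %in%
                                       c("additive", "site_x_additive")]))
})
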