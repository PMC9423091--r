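## Genetic-parameter summaries derived from fitted variance components.

vc_pieces <- function(x) {
  if (inherits(x, "px_fit")) {
    th <- varcomp(x)
    get0 <- function(nm) if (nm %in% names(th)) unname(th[nm]) else 0
    list(a = get0("additive"), sa = get0("site_x_additive"),
         d = get0("dominance"), sd = get0("site_x_dominance"),
         e = unname(th[x$res_names]), cov = x$cov_theta,
         names = names(th))
  } else {
    x <- as.list(x)
    g <- function(nm) if (!is.null(x[[nm]])) x[[nm]] else 0
    list(a = g("sigma2_a"), sa = g("sigma2_sa"), d = g("sigma2_d"),
         sd = g("sigma2_sd"), e = g("sigma2_e"), cov = x$cov, names = NULL)
  }
}

delta_se <- function(pieces, grad_fun) {
  if (is.null(pieces$cov) || is.null(pieces$names)) return(NA_real_)
  g <- stats::setNames(numeric(length(pieces$names)), pieces$names)
  gr <- grad_fun(pieces)
  for (nm in names(gr)) if (nm %in% names(g)) g[nm] <- gr[[nm]]
  cv <- pieces$cov
  cv[is.na(cv)] <- 0   # constrained components contribute no sampling variance
  sqrt(max(0, drop(t(g) %*% cv %*% g)))
}

#' Narrow- and broad-sense individual heritability
#'
#' Narrow-sense: \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{sa} +
#' \sigma^2_d + \sigma^2_{sd} + \bar\sigma^2_e)} with \eqn{\bar\sigma^2_e}
#' the unweighted mean of the per-site residual variances (dominance terms
#' appear only when the model includes them). Broad-sense adds
#' \eqn{\sigma^2_d} to the numerator. Standard errors are first-order delta
#' method using the asymptotic covariance of the variance components.
#'
#' @param x a `px_fit`, or a list of components
#'   (`sigma2_a`, `sigma2_sa`, `sigma2_d`, `sigma2_sd`, `sigma2_e` -- the
#'   latter a scalar mean or per-site vector).
#' @param mode `"narrow"` or `"broad"`.
#' @return list with `estimate`, `se`, `mode`.
#' @examples
#' heritability(list(sigma2_a = 1468, sigma2_sa = 824, sigma2_e = 8753))
#' @export
heritability <- function(x, mode = c("narrow", "broad")) {
  mode <- match.arg(mode)
  p <- vc_pieces(x)
  ebar <- mean(p$e)
  denom <- p$a + p$sa + p$d + p$sd + ebar
  if (denom <= 0) stop("zero denominator: heritability undefined")
  num <- if (mode == "narrow") p$a else p$a + p$d
  est <- num / denom
  k <- length(p$e)
  se <- delta_se(p, function(p) {
    base <- -num / denom^2
    gnum <- (denom - num) / denom^2
    gr <- list(additive = gnum,
               site_x_additive = base, site_x_dominance = base,
               dominance = if (mode == "broad") gnum else base)
    if (inherits(x, "px_fit")) for (rn in x$res_names) gr[[rn]] <- base / k
    gr
  })
  list(estimate = est, se = se, mode = mode)
}

#' Type-B additive genetic correlation
#'
#' \eqn{r_B = \sigma^2_a / (\sigma^2_a + \sigma^2_{sa})}: the correlation of
#' additive effects across sites implied by the main-plus-interaction
#' decomposition; values below 1 indicate genotype-by-environment
#' interaction. With no interaction term (or a zero estimate) \eqn{r_B = 1}.
#'
#' @param x a `px_fit` or a list with `sigma2_a`, `sigma2_sa`.
#' @return list with `estimate`, `se`.
#' @examples
#' typeB_correlation(list(sigma2_a = 1468, sigma2_sa = 824))
#' @export
typeB_correlation <- function(x) {
  p <- vc_pieces(x)
  if (p$a + p$sa <= 0)
    return(list(estimate = NA_real_, se = NA_real_))
  est <- p$a / (p$a + p$sa)
  se <- delta_se(p, function(p) {
    s <- p$a + p$sa
    list(additive = p$sa / s^2, site_x_additive = -p$a / s^2)
  })
  list(estimate = est, se = se)
}

#' Likelihood-ratio test for one variance component
#'
#' Compares a full and a reduced REML fit differing by exactly one random
#' term: \eqn{LRT = 2(\ell_{full} - \ell_{reduced})}, floored at zero, tested
#' against \eqn{\chi^2_1}. The boundary-corrected mixture p-value
#' (\eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}) is reported alongside.
#'
#' @param full,reduced `px_fit` objects with identical fixed effects.
#' @return list `stat`, `df`, `p_value`, `p_value_mixture`, `term`.
#' @export
lrt_component <- function(full, reduced) {
  stopifnot(inherits(full, "px_fit"), inherits(reduced, "px_fit"))
  extra <- setdiff(full$random, reduced$random)
  if (length(extra) != 1L || !all(reduced$random %in% full$random))
    stop("models are not nested by exactly one random term")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p_mix <- if (stat == 0) 1 else 0.5 * p
  list(stat = stat, df = 1L, p_value = p, p_value_mixture = p_mix,
       term = extra)
}

#' Theoretical accuracy of predicted breeding values
#'
#' \deqn{\hat r_i = \sqrt{1 - SE_i^2 / ((1 + F_i)\,\hat\sigma^2_a)}}
#' where \eqn{1 + F_i} is the diagonal of the additive relationship matrix.
#' Values are clipped to \eqn{[0, 1]}.
#'
#' @param fit a `px_fit` with an additive term, or `NULL` when supplying
#'   `se`, `F`, `sigma2_a` directly.
#' @param se,F,sigma2_a used when `fit` is `NULL` (vectorized).
#' @param ids optional subset of individuals.
#' @return data.frame `id`, `breeding_value`, `se`, `inbreeding_F`,
#'   `accuracy` (or a numeric vector in direct mode).
#' @examples
#' theoretical_accuracy(se = 0.6, F = 0, sigma2_a = 1)  # 0.8
#' @export
theoretical_accuracy <- function(fit = NULL, se = NULL, F = 0,
                                 sigma2_a = NULL, ids = NULL) {
  if (is.null(fit)) {
    if (is.null(se) || is.null(sigma2_a))
      stop("direct mode needs se and sigma2_a")
    rel <- 1 - se^2 / ((1 + F) * sigma2_a)
    return(sqrt(pmin(pmax(rel, 0), 1)))
  }
  stopifnot(inherits(fit, "px_fit"))
  bv <- breeding_values(fit, "additive")
  if (anyNA(bv$se)) stop("breeding-value standard errors missing")
  if (is.null(sigma2_a)) sigma2_a <- unname(varcomp(fit)["additive"])
  if (!is.null(ids)) bv <- bv[bv$id %in% ids, , drop = FALSE]
  Fi <- fit$kernel_diag[bv$id] - 1
  rel <- 1 - bv$se^2 / ((1 + Fi) * sigma2_a)
  data.frame(id = bv$id, breeding_value = bv$value, se = bv$se,
             inbreeding_F = unname(Fi),
             accuracy = sqrt(pmin(pmax(rel, 0), 1)),
             stringsAsFactors = FALSE)
}

#' Phenotypes adjusted for design and fixed effects
#'
#' Fits the individual-tree model without its genetic terms (site means and
#' covariates fixed; replicate and set random; heterogeneous residuals) and
#' returns the residual, i.e. the phenotype freed of design effects. Used for
#' phenotypic trait-trait correlations.
#'
#' @inheritParams fit_treemodel
#' @return named numeric vector of adjusted phenotypes.
#' @export
adjusted_phenotypes <- function(data, trait, covariates = NULL,
                                lognormal = FALSE) {
  fit <- fit_treemodel(data, trait, random = c("rep_in_site", "set_in_rep"),
                       covariates = covariates, lognormal = lognormal)
  stats::residuals(fit)
}

#' Bivariate additive genetic correlation
#'
#' Fits a two-trait REML model with an unstructured 2x2 additive covariance
#' (proportional to the supplied kernel) and an unstructured residual
#' covariance per site, and reports the additive correlation
#' \eqn{r_g = \sigma_{a_{12}} / \sqrt{\sigma^2_{a_1}\sigma^2_{a_2}}}
#' (constrained to \eqn{[-1, 1]}) with its delta-method standard error.
#' Significance follows the at-least-double-the-SE rule. If the bivariate
#' fit does not converge, the correlation of univariate breeding values is
#' returned with a warning.
#'
#' @param data data.frame with `id`, `site`, `rep`, `set` and both traits.
#' @param trait1,trait2 trait column names.
#' @param kernel_additive additive relationship kernel.
#' @param lognormal length-2 logical: log-transform each trait.
#' @param include_design add trait-specific replicate/set variances.
#' @param max_iter optimizer control.
#' @return list `estimate`, `se`, `significant`, `converged`, `components`.
#' @export
genetic_correlation <- function(data, trait1, trait2, kernel_additive,
                                lognormal = c(FALSE, FALSE),
                                include_design = FALSE, max_iter = 200L) {
  keep <- !is.na(data[[trait1]]) & !is.na(data[[trait2]])
  df <- data[keep, , drop = FALSE]
  ids <- as.character(df$id)
  n <- nrow(df)
  y1 <- df[[trait1]]; y2 <- df[[trait2]]
  if (lognormal[1]) y1 <- log(y1)
  if (lognormal[2]) y2 <- log(y2)
  y <- c(y1, y2)
  site <- factor(df$site)
  X1 <- vapply(levels(site), function(s) as.numeric(site == s), numeric(n))
  zero <- matrix(0, n, ncol(X1))
  X <- rbind(cbind(X1, zero), cbind(zero, X1))

  K <- unclass(kernel_additive)[ids, ids]
  Z0 <- matrix(0, n, n)
  blk <- function(a, b, c_) rbind(cbind(a, b), cbind(t(b), c_))
  vstruct <- list(
    a11 = blk(K, Z0, Z0),
    a22 = blk(Z0, Z0, K),
    a12 = blk(Z0, K, Z0))
  constraint <- c("pos", "pos", "free")
  for (s in levels(site)) {
    D <- diag((site == s) * 1)
    vstruct[[paste0("e11_", s)]] <- blk(D, Z0, Z0)
    vstruct[[paste0("e22_", s)]] <- blk(Z0, Z0, D)
    vstruct[[paste0("e12_", s)]] <- blk(Z0, D, Z0)
    constraint <- c(constraint, "pos", "pos", "free")
  }
  if (include_design) {
    f <- interaction(df$site, df$rep, drop = TRUE)
    Z <- vapply(levels(f), function(l) as.numeric(f == l), numeric(n))
    R <- tcrossprod(Z)
    vstruct$rep1 <- blk(R, Z0, Z0)
    vstruct$rep2 <- blk(Z0, Z0, R)
    constraint <- c(constraint, "pos", "pos")
  }
  v1 <- stats::var(y1); v2 <- stats::var(y2)
  init <- stats::setNames(numeric(length(vstruct)), names(vstruct))
  init["a11"] <- v1 / 2; init["a22"] <- v2 / 2
  for (s in levels(site)) {
    init[paste0("e11_", s)] <- v1 / 2
    init[paste0("e22_", s)] <- v2 / 2
  }
  if (include_design) { init["rep1"] <- v1 / 10; init["rep2"] <- v2 / 10 }

  fit <- tryCatch(
    reml_fit(y, X, vstruct, constraint = constraint, init = init,
             max_iter = max_iter),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    warning("bivariate REML did not converge; falling back to the ",
            "correlation of univariate breeding values", call. = FALSE)
    f1 <- fit_treemodel(df, trait1, kernel_additive,
                        random = c("rep_in_site", "additive"),
                        lognormal = lognormal[1])
    f2 <- fit_treemodel(df, trait2, kernel_additive,
                        random = c("rep_in_site", "additive"),
                        lognormal = lognormal[2])
    b1 <- breeding_values(f1); b2 <- breeding_values(f2)
    r <- stats::cor(b1$value[match(ids, b1$id)], b2$value[match(ids, b2$id)])
    return(list(estimate = r, se = NA_real_, significant = NA,
                converged = FALSE, components = NULL))
  }
  th <- fit$theta
  s12 <- sqrt(th["a11"] * th["a22"])
  r <- unname(th["a12"] / s12)
  r_cl <- min(max(r, -1), 1)
  g <- stats::setNames(numeric(length(th)), names(th))
  g["a11"] <- -r / (2 * th["a11"])
  g["a22"] <- -r / (2 * th["a22"])
  g["a12"] <- 1 / s12
  cv <- fit$cov_theta
  cv[is.na(cv)] <- 0
  se <- sqrt(max(0, drop(t(g) %*% cv %*% g)))
  list(estimate = r_cl, se = se, significant = abs(r_cl) >= 2 * se,
       converged = TRUE, components = th)
}
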