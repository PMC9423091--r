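indicator_matrix <- function(f) {
  Z <- vapply(levels(f), function(l) as.numeric(f == l),
              numeric(length(f)))
  colnames(Z) <- levels(f)
  Z
}

#' Fit an individual-tree mixed model by AI-REML
#'
#' Fits the multi-site individual-tree model
#' \deqn{y = X\beta + Z_1 rs + Z_2 ibr + Z_3 a + Z_4 sa + Z_5 d + Z_6 sd + e}
#' where the fixed part holds site means and optional covariates, `rs` and
#' `ibr` are replicate-within-site and set-within-replicate effects, `a` and
#' `d` are additive and dominance genetic effects with covariance
#' proportional to the supplied relationship kernels, `sa`/`sd` are
#' site-by-genetic interactions modeled as an independent kernel-distributed
#' effect per site (block covariance), and `e` is a heterogeneous residual
#' with one variance per site. Variance components are estimated by
#' average-information REML with step-halving and an EM-style fallback;
#' negative proposals for variance components are clamped at a small positive
#' floor and flagged as boundary estimates.
#'
#' @param data data.frame with columns `id`, `site`, `rep`, `set`, the trait,
#'   and any covariates.
#' @param trait name of the response column.
#' @param kernel_additive additive relationship matrix covering at least all
#'   phenotyped individuals (extra individuals, e.g. parents, receive
#'   breeding values too).
#' @param kernel_dominance optional dominance kernel (required by the
#'   dominance terms).
#' @param random character vector of random terms, an ordered subset of
#'   `rep_in_site`, `set_in_rep`, `additive`, `site_x_additive`,
#'   `dominance`, `site_x_dominance`.
#' @param covariates names of fixed covariate columns (e.g. heartwood width
#'   and ring count for wood traits).
#' @param lognormal if `TRUE` the trait is log-transformed before modeling.
#' @param constrained_components named numeric vector of variance components
#'   held fixed during maximization (e.g. to re-fit a pedigree model at
#'   genomic component values).
#' @param max_iter,tol_loglik,tol_param optimizer controls.
#' @return an object of class `px_fit` with components `vc` (variance
#'   component table), `cov_theta`, `loglik`, `aic`, `beta`, `blups`
#'   (additive, and dominance when fitted: id, value, se), `residuals`,
#'   `converged`, and bookkeeping fields.
#' @seealso [heritability()], [typeB_correlation()], [lrt_component()],
#'   [theoretical_accuracy()]
#' @export
fit_treemodel <- function(data, trait, kernel_additive = NULL,
                          kernel_dominance = NULL,
                          random = c("rep_in_site", "set_in_rep", "additive",
                                     "site_x_additive"),
                          covariates = NULL, lognormal = FALSE,
                          constrained_components = NULL,
                          max_iter = 200L, tol_loglik = 1e-8,
                          tol_param = 1e-6) {
  known <- c("rep_in_site", "set_in_rep", "additive", "site_x_additive",
             "dominance", "site_x_dominance")
  if (!all(random %in% known))
    stop("unknown random term(s): ", paste(setdiff(random, known), collapse = ", "))
  if ("site_x_dominance" %in% random && !("dominance" %in% random))
    stop("site_x_dominance requires the dominance term")
  need_a <- any(c("additive", "site_x_additive") %in% random)
  if (need_a && is.null(kernel_additive))
    stop("additive terms need kernel_additive")
  if (any(c("dominance", "site_x_dominance") %in% random) &&
      is.null(kernel_dominance))
    stop("dominance terms need kernel_dominance")

  keep <- !is.na(data[[trait]])
  if (length(covariates))
    keep <- keep & stats::complete.cases(data[covariates])
  df <- data[keep, , drop = FALSE]
  ids <- as.character(df$id)
  if (need_a && !all(ids %in% rownames(kernel_additive)))
    stop("kernel_additive does not cover all phenotyped individuals")
  y <- df[[trait]]
  if (lognormal) {
    if (any(y <= 0)) stop("lognormal trait has non-positive values")
    y <- log(y)
  }
  n <- length(y)
  site <- factor(df$site)
  ## site cell means (built by hand: a one-level factor trips model.matrix)
  X <- vapply(levels(site), function(s) as.numeric(site == s), numeric(n))
  colnames(X) <- paste0("site", levels(site))
  if (length(covariates))
    X <- cbind(X, as.matrix(df[covariates]))

  same_site <- outer(as.integer(site), as.integer(site), "==") * 1
  vstruct <- list()
  zmats <- list()   # incidence for factor terms (BLUP back-out)
  if (need_a) {
    Ka <- unclass(kernel_additive)[ids, ids]
  }
  for (term in random) {
    V <- switch(term,
      rep_in_site = {
        f <- interaction(df$site, df$rep, drop = TRUE)
        Z <- indicator_matrix(f)
        zmats[[term]] <- list(Z = Z, levels = levels(f))
        tcrossprod(Z)
      },
      set_in_rep = {
        f <- interaction(df$site, df$rep, df$set, drop = TRUE)
        Z <- indicator_matrix(f)
        zmats[[term]] <- list(Z = Z, levels = levels(f))
        tcrossprod(Z)
      },
      additive = Ka,
      site_x_additive = Ka * same_site,
      dominance = unclass(kernel_dominance)[ids, ids],
      site_x_dominance = unclass(kernel_dominance)[ids, ids] * same_site)
    vstruct[[term]] <- V
  }
  for (s in levels(site)) {
    vstruct[[paste0("residual_", s)]] <- diag((site == s) * 1)
  }
  constraint <- rep("pos", length(vstruct))

  fit <- reml_fit(y, X, vstruct, constraint = constraint,
                  fixed = constrained_components,
                  tol_loglik = tol_loglik, tol_param = tol_param,
                  max_iter = max_iter)
  if (!fit$converged)
    warning("REML did not meet the convergence tolerances; partial fit returned",
            call. = FALSE)
  theta <- fit$theta
  res_names <- paste0("residual_", levels(site))

  ## BLUPs of genetic effects over every individual in the kernel
  blups <- list()
  if ("additive" %in% random) {
    all_ids <- rownames(kernel_additive)
    Kfull <- unclass(kernel_additive)[all_ids, ids, drop = FALSE]
    u <- theta["additive"] * drop(Kfull %*% fit$Py)
    KP <- Kfull %*% fit$P                        # N x n
    pev <- theta["additive"] * diag(unclass(kernel_additive))[all_ids] -
      theta["additive"]^2 * rowSums(KP * Kfull)
    blups$additive <- data.frame(id = all_ids, value = u,
                                 se = sqrt(pmax(pev, 0)),
                                 stringsAsFactors = FALSE)
  }
  if ("dominance" %in% random) {
    all_ids <- rownames(kernel_dominance)
    Kfull <- unclass(kernel_dominance)[all_ids, ids, drop = FALSE]
    u <- theta["dominance"] * drop(Kfull %*% fit$Py)
    KP <- Kfull %*% fit$P
    pev <- theta["dominance"] * diag(unclass(kernel_dominance))[all_ids] -
      theta["dominance"]^2 * rowSums(KP * Kfull)
    blups$dominance <- data.frame(id = all_ids, value = u,
                                  se = sqrt(pmax(pev, 0)),
                                  stringsAsFactors = FALSE)
  }
  for (term in names(zmats)) {
    Z <- zmats[[term]]$Z
    u <- theta[term] * drop(crossprod(Z, fit$Py))
    blups[[term]] <- data.frame(level = zmats[[term]]$levels, value = u,
                                stringsAsFactors = FALSE)
  }

  ## conditional residuals: y - X beta - all random-effect predictions
  fitted_r <- numeric(n)
  for (term in random) {
    fitted_r <- fitted_r + theta[term] * drop(vstruct[[term]] %*% fit$Py)
  }
  fitted_fx <- drop(X %*% fit$beta)
  resid <- y - fitted_fx - fitted_r

  vc <- data.frame(component = names(theta), estimate = unname(theta),
                   se = unname(fit$se), boundary = unname(fit$boundary),
                   constrained = names(theta) %in% names(constrained_components),
                   stringsAsFactors = FALSE)
  aic <- -2 * fit$loglik + 2 * fit$n_free

  out <- list(trait = trait, random = random, vc = vc,
              cov_theta = fit$cov_theta, loglik = fit$loglik, aic = aic,
              beta = fit$beta, beta_cov = fit$beta_cov, blups = blups,
              residuals = stats::setNames(resid, ids),
              fitted = stats::setNames(fitted_fx + fitted_r, ids),
              sites = levels(site), res_names = res_names,
              kernel_diag = if (need_a)
                diag(unclass(kernel_additive)) else NULL,
              converged = fit$converged, n_iter = fit$n_iter,
              n = n, n_free = fit$n_free, lognormal = lognormal,
              y = stats::setNames(y, ids), ids = ids)
  class(out) <- "px_fit"
  out
}

#' @export
print.px_fit <- function(x, ...) {
  cat(sprintf("Individual-tree REML fit: %s (n = %d, %s)\n", x$trait, x$n,
              if (x$converged) sprintf("converged in %d iterations", x$n_iter)
              else "NOT converged"))
  cat(sprintf("logLik(REML) = %.3f   AIC = %.1f\n", x$loglik, x$aic))
  vt <- x$vc
  vt$estimate <- signif(vt$estimate, 5)
  vt$se <- signif(vt$se, 3)
  print(vt, row.names = FALSE)
  invisible(x)
}

#' @export
summary.px_fit <- function(object, ...) {
  h2 <- tryCatch(heritability(object, "narrow"), error = function(e) NULL)
  rb <- tryCatch(typeB_correlation(object), error = function(e) NULL)
  structure(list(fit = object, h2 = h2, rB = rb), class = "summary.px_fit")
}

#' @export
print.summary.px_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$h2))
    cat(sprintf("narrow-sense h2 = %.3f (SE %.3f)\n", x$h2$estimate, x$h2$se))
  if (!is.null(x$rB) && !is.na(x$rB$estimate))
    cat(sprintf("type-B genetic correlation rB = %.3f (SE %.3f)\n",
                x$rB$estimate, x$rB$se))
  invisible(x)
}

#' @export
coef.px_fit <- function(object, ...) object$beta

#' @export
logLik.px_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, class = "logLik")
}

#' @export
residuals.px_fit <- function(object, ...) object$residuals

#' @export
fitted.px_fit <- function(object, ...) object$fitted

#' Extract predicted breeding values from a fitted model
#'
#' @param fit a `px_fit` object with an additive term.
#' @param effect `"additive"` (breeding values) or `"dominance"`.
#' @return data.frame `id`, `value`, `se`.
#' @export
breeding_values <- function(fit, effect = c("additive", "dominance")) {
  effect <- match.arg(effect)
  stopifnot(inherits(fit, "px_fit"))
  bv <- fit$blups[[effect]]
  if (is.null(bv)) stop("model has no ", effect, " term")
  bv
}

#' Variance components of a fitted model
#'
#' @param fit a `px_fit` object.
#' @return named numeric vector of the REML estimates.
#' @export
varcomp <- function(fit) {
  stopifnot(inherits(fit, "px_fit"))
  stats::setNames(fit$vc$estimate, fit$vc$component)
}
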