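## Generic REML engine for linear covariance structures
##   V(theta) = sum_m theta_m * V_m
## maximized by average-information (AI) updates with step-halving and an
## EM-style fallback, so the restricted log-likelihood never decreases.
## Positivity-constrained parameters are clamped at a small floor relative to
## the phenotypic variance and flagged as boundary estimates.

reml_loglik <- function(theta, vstruct, X, y) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (m in seq_along(vstruct)) V <- V + theta[m] * vstruct[[m]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(V + diag(1e-8 * mean(diag(V)), n)),
                   error = function(e) NULL)
    if (is.null(ch)) return(NULL)
  }
  Vinv <- chol2inv(ch)
  XtVi <- crossprod(X, Vinv)
  C <- XtVi %*% X
  chC <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(chC)) return(NULL)
  Cinv <- chol2inv(chC)
  P <- Vinv - crossprod(XtVi, Cinv %*% XtVi)
  Py <- drop(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chC))) +
                  sum(y * Py))
  list(ll = ll, P = P, Py = Py, Vinv = Vinv, Cinv = Cinv, XtVi = XtVi)
}

reml_fit <- function(y, X, vstruct, constraint = NULL, init = NULL,
                     fixed = NULL, tol_loglik = 1e-8, tol_param = 1e-6,
                     max_iter = 200L, verbose = FALSE) {
  n <- length(y)
  M <- length(vstruct)
  pnames <- names(vstruct)
  if (is.null(constraint)) constraint <- rep("pos", M)
  vary <- stats::var(y)
  floor_v <- 1e-8 * vary
  theta <- if (is.null(init)) {
    ini <- rep(vary / M, M)
    ini[constraint == "free"] <- 0
    ini
  } else init
  names(theta) <- pnames
  is_fixed <- pnames %in% names(fixed)
  if (any(is_fixed)) theta[is_fixed] <- fixed[pnames[is_fixed]]
  free_idx <- which(!is_fixed)

  state <- reml_loglik(theta, vstruct, X, y)
  if (is.null(state)) stop("initial covariance matrix not positive definite")
  ll <- state$ll
  converged <- FALSE
  used_fallback <- FALSE
  AI_free <- NULL
  for (iter in seq_len(max_iter)) {
    P <- state$P; Py <- state$Py
    tr_PV <- numeric(M); quad <- numeric(M)
    Tm <- vector("list", M)
    for (m in seq_len(M)) {
      tr_PV[m] <- sum(P * vstruct[[m]])
      Tm[[m]] <- drop(vstruct[[m]] %*% Py)
      quad[m] <- sum(Py * Tm[[m]])
    }
    score <- -0.5 * (tr_PV - quad)
    PT <- vector("list", M)
    for (m in seq_len(M)) PT[[m]] <- drop(P %*% Tm[[m]])
    AI <- matrix(0, M, M)
    for (m in seq_len(M)) for (l in m:M) {
      AI[m, l] <- AI[l, m] <- 0.5 * sum(Tm[[m]] * PT[[l]])
    }
    AI_free <- AI[free_idx, free_idx, drop = FALSE]

    ## active set: parameters pinned at the floor with a downhill score are
    ## frozen for this update so they do not distort the Newton step
    pinned <- constraint == "pos" & !is_fixed &
      theta <= floor_v * (1 + 1e-6) & score < 0
    work_idx <- setdiff(free_idx, which(pinned))
    if (length(work_idx) == 0L) {
      converged <- TRUE
      break
    }
    AI_work <- AI[work_idx, work_idx, drop = FALSE]
    ridge <- 1e-8 * mean(diag(AI_work)) + 1e-300
    dtheta_free <- stats::setNames(numeric(length(free_idx)),
                                   pnames[free_idx])
    step_work <- tryCatch(
      solve(AI_work + diag(ridge, length(work_idx)), score[work_idx]),
      error = function(e) score[work_idx] / (diag(AI_work) + ridge))
    dtheta_free[match(work_idx, free_idx)] <- step_work

    accepted <- FALSE
    step <- 1
    for (half in 1:12) {
      cand <- theta
      cand[free_idx] <- theta[free_idx] + step * dtheta_free
      pos <- constraint == "pos" & !is_fixed
      cand[pos] <- pmax(cand[pos], floor_v)
      st <- reml_loglik(cand, vstruct, X, y)
      if (!is.null(st) && st$ll >= ll - 1e-10) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      ## EM-style fallback: scaled gradient step for positive parameters,
      ## guaranteed-uphill direction with its own halving
      used_fallback <- TRUE
      step <- 1
      for (half in 1:12) {
        cand <- theta
        em <- theta[free_idx]^2 * (2 * score[free_idx]) / n
        em[constraint[free_idx] == "free"] <-
          score[free_idx][constraint[free_idx] == "free"] * vary / n
        cand[free_idx] <- theta[free_idx] + step * em
        pos <- constraint == "pos" & !is_fixed
        cand[pos] <- pmax(cand[pos], floor_v)
        st <- reml_loglik(cand, vstruct, X, y)
        if (!is.null(st) && st$ll >= ll - 1e-10) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!accepted) {
      ## no uphill move: if the quadratic model predicts only a negligible
      ## feasible gain (typical at a boundary optimum), declare convergence
      proj <- dtheta_free
      at_floor <- constraint[free_idx] == "pos" &
        theta[free_idx] <= floor_v * (1 + 1e-6)
      proj[at_floor & proj < 0] <- 0
      pred_gain <- 0.5 * abs(sum(score[free_idx] * proj))
      if (pred_gain < 1e-4 * max(1, abs(ll))) converged <- TRUE
      break
    }
    dpar <- max(abs(cand - theta) / pmax(abs(theta), floor_v))
    dll <- abs(st$ll - ll) / max(1, abs(ll))
    theta <- cand; state <- st
    if (verbose) message(sprintf("iter %d  logLik %.6f", iter, st$ll))
    if (st$ll >= ll && dll < tol_loglik && dpar < tol_param) {
      ll <- st$ll
      converged <- TRUE
      break
    }
    ll <- st$ll
  }

  boundary <- constraint == "pos" & !is_fixed & theta <= floor_v * (1 + 1e-6)
  ## asymptotic covariance of the free parameters from the AI matrix
  cov_theta <- matrix(NA_real_, M, M, dimnames = list(pnames, pnames))
  ok <- free_idx
  if (length(ok)) {
    ci <- tryCatch(solve(AI_free), error = function(e)
      matrix(NA_real_, length(ok), length(ok)))
    cov_theta[ok, ok] <- ci
  }
  se <- sqrt(pmax(diag(cov_theta), 0))
  beta_cov <- state$Cinv
  beta <- drop(beta_cov %*% (state$XtVi %*% y))
  names(beta) <- colnames(X)
  list(theta = theta, se = se, cov_theta = cov_theta,
       loglik = ll, beta = beta, beta_cov = beta_cov,
       P = state$P, Py = state$Py,
       converged = converged, boundary = boundary, n_iter = iter,
       used_fallback = used_fallback, floor = floor_v,
       n_free = sum(!is_fixed & !boundary))
}
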