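#' Specify a random effect for the mixed model
#'
#' @param name effect name (unique within a model).
#' @param levels character vector, one entry per observation, giving the
#'   level of this effect for that observation (e.g. the dent parent of each
#'   hybrid).
#' @param kernel a [kernel_matrix()] giving the covariance among levels, or
#'   `NULL` for an identity covariance over the observed levels. The kernel
#'   may contain additional levels (e.g. untested parents); their BLUPs are
#'   obtained for free and drive out-of-sample prediction.
#' @return object of class `random_effect`.
#' @export
random_effect <- function(name, levels, kernel = NULL) {
  levels <- as.character(levels)
  if (anyNA(levels)) stop("effect '", name, "': missing level assignments", call. = FALSE)
  if (!is.null(kernel)) {
    stopifnot(inherits(kernel, "kernel_matrix"))
    missing_lv <- setdiff(unique(levels), rownames(kernel))
    if (length(missing_lv)) {
      stop("effect '", name, "': kernel lacks level(s) ",
           paste(missing_lv, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, levels = levels, kernel = kernel),
            class = "random_effect")
}

# n x q incidence matrix mapping observations to kernel levels
incidence_matrix <- function(levels, level_ids) {
  Z <- matrix(0, length(levels), length(level_ids),
              dimnames = list(NULL, level_ids))
  Z[cbind(seq_along(levels), match(levels, level_ids))] <- 1
  Z
}

# restricted log-likelihood for V (n x n covariance) and fixed design X
reml_loglik_V <- function(y, X, V) {
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(-Inf)
  Vinv <- chol2inv(cV)
  VX <- Vinv %*% X
  XtVX <- crossprod(X, VX)
  cX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cX)) return(-Inf)
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(VX, y)))
  r <- y - X %*% beta
  quad <- sum(r * (Vinv %*% r))
  -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) + quad)
}

#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates the restricted likelihood at a given parameter vector; used by
#' the fitter and available for independent grid-search checks.
#'
#' @param theta variance components, one per effect, residual last.
#' @param y observations.
#' @param effects list of [random_effect()].
#' @param X fixed-effects design matrix (default: intercept).
#' @return restricted log-likelihood (`-Inf` if `V` is not invertible).
#' @export
reml_loglik <- function(theta, y, effects, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  Vlist <- build_vlist(effects, n)
  V <- matrix(0, n, n)
  for (k in seq_along(Vlist)) V <- V + theta[k] * Vlist[[k]]
  reml_loglik_V(y, X, V)
}

# observation-level covariance structures, residual identity last
build_vlist <- function(effects, n) {
  Vlist <- vector("list", length(effects) + 1L)
  for (k in seq_along(effects)) {
    ef <- effects[[k]]
    if (length(ef$levels) != n) {
      stop("effect '", ef$name, "': level vector length != n observations",
           call. = FALSE)
    }
    if (is.null(ef$kernel)) {
      lev <- unique(ef$levels)
      Z <- incidence_matrix(ef$levels, lev)
      Vlist[[k]] <- tcrossprod(Z)
    } else {
      K <- unclass(ef$kernel)
      # only levels carrying observations matter for the n x n structure
      used <- intersect(rownames(K), unique(ef$levels))
      Z <- incidence_matrix(ef$levels, used)
      Vlist[[k]] <- Z %*% K[used, used, drop = FALSE] %*% t(Z)
    }
  }
  Vlist[[length(effects) + 1L]] <- diag(n)
  Vlist
}

#' Fit a multi-kernel linear mixed model by AI-REML
#'
#' Estimates the variance components of
#' `y = X beta + sum_k Z_k u_k + e`, `u_k ~ N(0, C_k sigma2_k)`,
#' `e ~ N(0, I sigma2_e)` by average-information REML with EM fallback
#' steps whenever the AI proposal is inadmissible or decreases the
#' restricted likelihood. Components are floored at
#' `floor_frac * var(y)`. Convergence requires both the restricted
#' log-likelihood change below `tol` and the relative parameter change
#' below `1e-6`.
#'
#' @param y numeric observations (no missing values; drop them upstream).
#' @param effects list of [random_effect()].
#' @param X fixed-effects design matrix; default a column of ones
#'   (intercept-only, as in the hybrid GCA/SCA models).
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param max_iter maximum iterations.
#' @param floor_frac variance floor as a fraction of `var(y)`.
#' @return object of class `fitted_model`: fixed-effect estimates (`beta`,
#'   `mu` when intercept-only), named variance components `sigma2` (residual
#'   included as `"residual"`), per-level BLUPs for every effect (over all
#'   kernel levels), the restricted log-likelihood, and a convergence
#'   record.
#' @export
fit_reml <- function(y, effects, X = NULL, tol = 1e-8, max_iter = 100L,
                     floor_frac = 1e-10) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("missing phenotypes: drop them before fitting", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  p <- ncol(X)
  if (n < p + 2L) stop("need at least ", p + 2L, " observations", call. = FALSE)
  K <- length(effects)
  names_k <- c(vapply(effects, `[[`, character(1), "name"), "residual")
  vy <- stats::var(y)

  # degenerate response: nothing to estimate
  if (!is.finite(vy) || vy < 1e-300) {
    beta <- qr.solve(X, y)
    return(finish_fit(rep(0, K + 1L), names_k, beta, y, X, effects,
                      ll = NA_real_, iter = 0L, converged = TRUE,
                      trace = NULL))
  }

  Vlist <- build_vlist(effects, n)
  floor_v <- floor_frac * vy
  theta <- rep(vy / (K + 1L), K + 1L)
  q_k <- c(vapply(seq_len(K), function(k) {
    ef <- effects[[k]]
    length(unique(ef$levels))
  }, numeric(1)), n - p)

  ll <- -Inf
  trace <- matrix(NA_real_, max_iter, K + 3L,
                  dimnames = list(NULL, c("iter", "logREML", names_k)))
  converged <- FALSE
  flat_count <- 0L

  for (it in seq_len(max_iter)) {
    V <- matrix(0, n, n)
    for (k in seq_len(K + 1L)) V <- V + theta[k] * Vlist[[k]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) stop("singular V; consider jittering the kernels (ensure_psd)",
                          call. = FALSE)
    Vinv <- chol2inv(cV)
    VX <- Vinv %*% X
    XtVX <- crossprod(X, VX)
    cX <- chol(XtVX)
    P <- Vinv - VX %*% chol2inv(cX) %*% t(VX)
    Py <- drop(P %*% y)
    ll_new <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) + sum(y * Py))

    score <- numeric(K + 1L)
    W <- matrix(0, n, K + 1L)
    for (k in seq_len(K + 1L)) {
      Vk <- Vlist[[k]]
      W[, k] <- Vk %*% Py
      score[k] <- -0.5 * (sum(P * Vk) - sum(Py * W[, k]))
    }
    AI <- 0.5 * crossprod(W, P %*% W)

    trace[it, ] <- c(it, ll_new, theta)
    # relative parameter change, ignoring components pinned at the floor
    # (they can dither between the floor and tiny values indefinitely)
    d_theta <- if (it == 1L) Inf else {
      active <- theta > 100 * floor_v | theta_prev > 100 * floor_v
      if (!any(active)) 0 else
        max(abs(theta[active] - theta_prev[active]) /
              pmax(theta_prev[active], floor_v))
    }
    flat_count <- if (it > 1L && abs(ll_new - ll) < tol) flat_count + 1L else 0L
    if (it > 1L && abs(ll_new - ll) < tol && (d_theta < 1e-6 || flat_count >= 3L)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
    theta_prev <- theta

    step_ok <- FALSE
    # active-set AI proposal: components pushed below the floor are pinned
    # there and the AI system is re-solved for the free components, which
    # avoids crawling along the boundary
    free <- rep(TRUE, K + 1L)
    cand_full <- theta
    for (pass in seq_len(K + 2L)) {
      sub <- tryCatch(solve(AI[free, free, drop = FALSE] + diag(1e-10, sum(free)),
                            score[free]),
                      error = function(e) NULL)
      if (is.null(sub)) { cand_full <- NULL; break }
      cand_full <- theta
      cand_full[free] <- theta[free] + sub
      cand_full[!free] <- floor_v
      viol <- cand_full < floor_v & free
      if (!any(viol)) break
      free[viol] <- FALSE
      if (!any(free)) break
    }
    if (!is.null(cand_full)) {
      delta <- pmax(cand_full, floor_v) - theta
      for (half in 0:12) {
        cand <- pmax(theta + delta / 2^half, floor_v)
        ll_cand <- reml_loglik_V2(y, X, Vlist, cand)
        if (is.finite(ll_cand) && ll_cand >= ll - 1e-10) {
          theta <- cand
          step_ok <- TRUE
          break
        }
      }
    }
    if (!step_ok) {
      # EM-style update: slow but safe
      em <- theta + theta^2 * (colSums(Py * W) - vapply(Vlist, function(Vk) sum(P * Vk),
                                                        numeric(1))) / q_k
      cand <- pmax(em, floor_v)
      ll_cand <- reml_loglik_V2(y, X, Vlist, cand)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-8) {
        theta <- cand
      } else if (abs(ll_new - ll) < tol) {
        converged <- TRUE
        break
      } else {
        stop("REML failed to find an admissible ascent step at iteration ", it,
             call. = FALSE)
      }
    }
  }
  if (!converged) {
    # accept a flat likelihood as converged even if parameters still drift
    last2 <- trace[stats::complete.cases(trace), "logREML"]
    if (length(last2) >= 2L &&
        abs(diff(utils::tail(last2, 2L))) < sqrt(tol)) {
      converged <- TRUE
    } else {
      fm_trace <- trace[stats::complete.cases(trace), , drop = FALSE]
      cond <- simpleError(paste0("REML did not converge in ", max_iter, " iterations"))
      cond$trace <- fm_trace
      stop(cond)
    }
  }

  # final quantities at the solution
  V <- matrix(0, n, n)
  for (k in seq_len(K + 1L)) V <- V + theta[k] * Vlist[[k]]
  Vinv <- chol2inv(chol(V))
  VX <- Vinv %*% X
  XtVX <- crossprod(X, VX)
  beta <- drop(solve(XtVX, crossprod(VX, y)))
  finish_fit(theta, names_k, beta, y, X, effects, ll = ll, iter = it,
             converged = converged,
             trace = trace[stats::complete.cases(trace), , drop = FALSE],
             Vinv = Vinv)
}

reml_loglik_V2 <- function(y, X, Vlist, theta) {
  V <- matrix(0, length(y), length(y))
  for (k in seq_along(Vlist)) V <- V + theta[k] * Vlist[[k]]
  reml_loglik_V(y, X, V)
}

finish_fit <- function(theta, names_k, beta, y, X, effects, ll, iter,
                       converged, trace, Vinv = NULL) {
  n <- length(y)
  K <- length(effects)
  resid <- drop(y - X %*% beta)
  blups <- vector("list", K)
  names(blups) <- names_k[seq_len(K)]
  if (is.null(Vinv)) Vinv <- diag(0, n)
  Vr <- drop(Vinv %*% resid)
  for (k in seq_len(K)) {
    ef <- effects[[k]]
    if (is.null(ef$kernel)) {
      lev <- unique(ef$levels)
      Z <- incidence_matrix(ef$levels, lev)
      blups[[k]] <- stats::setNames(theta[k] * drop(crossprod(Z, Vr)), lev)
    } else {
      K_full <- unclass(ef$kernel)
      used <- intersect(rownames(K_full), unique(ef$levels))
      Z <- incidence_matrix(ef$levels, used)
      # u_hat over ALL kernel levels: sigma2_k * C[., used] Z' Vinv r
      blups[[k]] <- stats::setNames(
        theta[k] * drop(K_full[, used, drop = FALSE] %*% crossprod(Z, Vr)),
        rownames(K_full))
    }
  }
  structure(list(
    beta = beta,
    mu = if (ncol(X) == 1L && all(X == 1)) beta[1L] else NA_real_,
    sigma2 = stats::setNames(theta, names_k),
    blups = blups,
    loglik = ll,
    n = n,
    converged = converged,
    iterations = iter,
    trace = trace,
    intercept_only = ncol(X) == 1L && all(X == 1)
  ), class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model> logREML =", format(x$loglik, digits = 8),
      "| iterations:", x$iterations,
      "| converged:", x$converged, "\n")
  print(round(x$sigma2, 6))
  invisible(x)
}

#' Predict hybrid values from a fitted GCA/SCA model
#'
#' For each new observation, sums the fitted intercept and the BLUPs of its
#' levels across all random effects:
#' `pred = mu + sum_k sigma2_k C_k(new, train) Z_k' Vinv (y - mu)`.
#' The per-level BLUPs stored in the fit already cover every kernel level,
#' so prediction is a lookup; levels with zero kernel covariance to the
#' training data get BLUP 0 and are predicted at the intercept.
#'
#' @param fm a [fitted_model][fit_reml()] from an intercept-only fit.
#' @param newlevels data.frame with one column per random effect (named as
#'   the effects), giving each new observation's level id.
#' @return numeric vector of predictions.
#' @export
predict_hybrids <- function(fm, newlevels) {
  stopifnot(inherits(fm, "fitted_model"))
  if (!isTRUE(fm$intercept_only)) {
    stop("prediction is defined for intercept-only models", call. = FALSE)
  }
  newlevels <- as.data.frame(newlevels, stringsAsFactors = FALSE)
  missing_ef <- setdiff(names(fm$blups), names(newlevels))
  if (length(missing_ef)) {
    stop("newlevels lacks column(s) for effect(s): ",
         paste(missing_ef, collapse = ", "), call. = FALSE)
  }
  pred <- rep(fm$mu, nrow(newlevels))
  for (ef in names(fm$blups)) {
    u <- fm$blups[[ef]]
    lv <- as.character(newlevels[[ef]])
    unknown <- setdiff(lv, names(u))
    if (length(unknown)) {
      stop("effect '", ef, "': level(s) absent from its kernel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    pred <- pred + u[lv]
  }
  unname(pred)
}
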