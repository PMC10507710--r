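# REML machinery for kernel-based mixed models
#
#   y = X beta + sum_k u_k + e,   u_k ~ N(0, sigma2_k K_k),  e ~ N(0, sigma2_e I)
#
# One record per genotype, so the random-effect incidence matrices are the
# identity. Single-kernel fits use the spectral shortcut (one symmetric
# eigendecomposition, 1-D optimization of the log variance ratio); multi-kernel
# fits optimize the profiled REML likelihood over log variance ratios with a
# Cholesky factorization per evaluation. Both parameterizations profile out the
# residual variance, which makes the fit exactly scale-equivariant.

.jitter <- function(K) K + diag(1e-8 * mean(diag(K)), nrow(K))

.check_X <- function(X, n) {
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X rows must match y length")
  if (qr(X)$rank < ncol(X)) stop("X is rank deficient")
  X
}

# Profiled REML criterion at gamma = sigma2_k / sigma2_e.
# Returns -0.5*((n-p) log s2e + log|V0| + log|X'V0inv X| + (n-p)) and byproducts.
.reml_profile_chol <- function(y, X, Klist, gamma) {
  n <- length(y); p <- ncol(X)
  V0 <- diag(n)
  for (k in seq_along(Klist)) V0 <- V0 + gamma[k] * Klist[[k]]
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, Vi_X)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  q <- sum(r * Vi_r)
  s2e <- q / (n - p)
  ll <- -0.5 * ((n - p) * log(s2e) + 2 * sum(log(diag(R))) +
                2 * sum(log(diag(cX))) + (n - p))
  list(ll = ll, beta = beta, s2e = s2e, Vinv_resid = Vi_r / s2e)
}

#' REML log-likelihood at a given variance point
#'
#' Evaluates the restricted log-likelihood (up to the usual additive constant)
#' of the kernel mixed model at fixed variance components, with beta profiled
#' out by GLS.
#'
#' @param y trait vector.
#' @param X fixed-effect design (full column rank).
#' @param kernels list of [kernel_matrix()] objects.
#' @param varcomp numeric vector: one variance per kernel followed by the
#'   residual variance.
#' @return scalar log-likelihood.
#' @export
reml_loglik <- function(y, X, kernels, varcomp) {
  if (inherits(kernels, "kernel_matrix")) kernels <- list(kernels)
  stopifnot(length(varcomp) == length(kernels) + 1)
  y <- as.numeric(y)
  n <- length(y)
  X <- .check_X(X, n)
  s2e <- varcomp[length(varcomp)]
  if (s2e <= 0) stop("residual variance must be positive")
  V <- diag(s2e, n)
  for (k in seq_along(kernels)) V <- V + varcomp[k] * .jitter(kernels[[k]]$values)
  R <- tryCatch(chol(V), error = function(e)
    stop("variance point gives a non-PD covariance"))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, Vi_X)
  cX <- chol(XtViX)
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(cX))) + sum(r * Vi_r))
}

#' Fit GBLUP-type kernel mixed models by REML
#'
#' @param y numeric trait vector (complete).
#' @param X fixed-effect design matrix including the intercept.
#' @param kernels a [kernel_matrix()] or list of them (training samples, in
#'   the order of `y`).
#' @param fixed optional numeric vector, one entry per kernel: `NA` to
#'   estimate, `0` to fix that component at zero (model nesting checks).
#' @return object of class `mm_fit` with elements `beta`, `varcomp` (named,
#'   residual last), `blups` (list per kernel), `fitted`, `reml_loglik`,
#'   `Vinv_resid` and `heritability` (phenotypic-scale variance share of the
#'   first kernel, using each kernel's mean diagonal to map variance
#'   components to sample variance).
#' @export
fit_gblup <- function(y, X, kernels, fixed = NULL) {
  if (inherits(kernels, "kernel_matrix")) kernels <- list(kernels)
  y <- as.numeric(y)
  if (anyNA(y)) stop("y must be complete")
  n <- length(y)
  X <- .check_X(X, n)
  for (K in kernels) {
    if (!inherits(K, "kernel_matrix")) stop("kernels must be kernel_matrix objects")
    if (nrow(K$values) != n) stop("kernel dimension must match y")
  }
  active <- seq_along(kernels)
  if (!is.null(fixed)) {
    stopifnot(length(fixed) == length(kernels))
    active <- which(is.na(fixed))
    if (any(!is.na(fixed) & fixed != 0))
      stop("only fixing components to zero is supported")
  }
  Klist <- lapply(kernels[active], function(K) .jitter(K$values))
  if (!length(Klist)) stop("at least one free kernel is required")

  if (length(Klist) == 1L) {
    eg <- eigen(Klist[[1]], symmetric = TRUE)
    d <- pmax(eg$values, 0); U <- eg$vectors
    ys <- crossprod(U, y); Xs <- crossprod(U, X)
    p <- ncol(X)
    prof <- function(lg) {
      g <- exp(lg)
      w <- 1 / (g * d + 1)
      XtWX <- crossprod(Xs, Xs * w)
      cX <- chol(XtWX)
      beta <- backsolve(cX, forwardsolve(t(cX), crossprod(Xs, ys * w)))
      r <- ys - Xs %*% beta
      q <- sum(r^2 * w)
      s2e <- q / (n - p)
      ll <- -0.5 * ((n - p) * log(s2e) + sum(log(g * d + 1)) +
                    2 * sum(log(diag(cX))) + (n - p))
      list(ll = ll, beta = beta, s2e = s2e, w = w, r = r, g = g)
    }
    opt <- optimize(function(lg) -prof(lg)$ll, c(-23, 23), tol = 1e-10)
    fin <- prof(opt$minimum)
    gamma <- fin$g
    s2e <- fin$s2e
    Vinv_resid <- U %*% (fin$w * fin$r) / s2e
    beta <- fin$beta
  } else {
    k <- length(Klist)
    obj <- function(theta) {
      pr <- .reml_profile_chol(y, X, Klist, exp(theta))
      if (is.null(pr)) return(1e10)
      -pr$ll
    }
    opt <- optim(rep(log(1 / k), k), obj, method = "L-BFGS-B",
                 lower = -23, upper = 23,
                 control = list(factr = 1e5, maxit = 500))
    gamma <- exp(opt$par)
    pr <- .reml_profile_chol(y, X, Klist, gamma)
    s2e <- pr$s2e
    Vinv_resid <- pr$Vinv_resid
    beta <- pr$beta
  }

  sigma2 <- rep(0, length(kernels))
  sigma2[active] <- gamma * s2e
  blups <- lapply(seq_along(kernels), function(k)
    as.numeric(sigma2[k] * (kernels[[k]]$values %*% Vinv_resid)))
  fitted <- as.numeric(X %*% beta) + Reduce(`+`, blups)
  varcomp <- c(sigma2, s2e)
  names(varcomp) <- c(vapply(kernels, function(K) K$kind, character(1)), "residual")
  names(varcomp) <- make.unique(names(varcomp))
  ll <- reml_loglik(y, X, kernels, varcomp)
  # phenotypic-scale variance share of the first kernel: sigma2_k maps to
  # sample variance via the kernel's mean diagonal (= 2 for inbred panels)
  mdiag <- vapply(kernels, function(K) mean(diag(K$values)), numeric(1))
  h2 <- unname(sigma2[1] * mdiag[1] / (sum(sigma2 * mdiag) + s2e))
  structure(list(beta = as.numeric(beta), varcomp = varcomp, blups = blups,
                 fitted = fitted, reml_loglik = ll, Vinv_resid = as.numeric(Vinv_resid),
                 heritability = h2,
                 n = n, kernels_kind = names(varcomp)[-length(varcomp)]),
            class = "mm_fit")
}

#' Extended GBLUP with additive x additive epistasis
#'
#' Delegates to [fit_gblup()] with kernels `[G, G # G]` (Hadamard square).
#'
#' @inheritParams fit_gblup
#' @param G additive [kernel_matrix()].
#' @return an `mm_fit` with variance components `additive`, `epistatic`,
#'   `residual`.
#' @export
fit_egblup <- function(y, X, G, fixed = NULL) {
  fit_gblup(y, X, list(G, epistatic_grm(G)), fixed = fixed)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("<mm_fit> REML kernel mixed model\n  variance components:\n")
  for (nm in names(x$varcomp))
    cat(sprintf("    %-10s %.5g\n", nm, x$varcomp[nm]))
  cat(sprintf("  h2 (first kernel / total): %.3f\n", x$heritability))
  invisible(x)
}

#' Predict new samples from a fitted kernel mixed model
#'
#' BLUP extension: `yhat = X_new beta + sum_k sigma2_k K_k(new, train)
#' V^-1 (y - X beta)`.
#'
#' @param object an `mm_fit`.
#' @param kernel_cross list (one per kernel, same order as in the fit) of
#'   new x train kernel blocks from the same kernel construction as training.
#' @param X_new fixed design for the new samples.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.mm_fit <- function(object, kernel_cross, X_new, ...) {
  if (is.matrix(kernel_cross)) kernel_cross <- list(kernel_cross)
  nk <- length(object$varcomp) - 1L
  if (length(kernel_cross) != nk)
    stop("need one cross-kernel block per fitted kernel")
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$beta)) stop("X_new column mismatch")
  for (K in kernel_cross)
    if (ncol(K) != object$n) stop("cross kernel columns must match training samples")
  yhat <- as.numeric(X_new %*% object$beta)
  for (k in seq_len(nk))
    yhat <- yhat + object$varcomp[[k]] * as.numeric(kernel_cross[[k]] %*% object$Vinv_resid)
  yhat
}
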