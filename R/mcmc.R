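# Bayesian samplers: LASSO regression on marker/haplotype dosages and RKHS
# kernel averaging. Chain defaults (6000 / 1000 / 5) are deliberately longer
# than typical package defaults; see the methods vignette.

#' Fit the Bayesian LASSO by Gibbs sampling
#'
#' `y = X beta + M f + e` with flat priors on beta and double-exponential
#' (Laplace) priors on the marker/haplotype effects f, via the
#' exponential-mixture representation. The shrinkage parameter lambda^2
#' carries a weakly informative Gamma hyperprior whose mode sits at the
#' standard heuristic `2 (1 - R2) MSx / R2` (`MSx` = sum of column variances
#' of M, R2 = 0.5).
#'
#' @param y trait vector.
#' @param X fixed design including the intercept.
#' @param M marker/haplotype dosage matrix coded 0/1/2 (complete).
#' @param n_iter,burn_in,thin chain settings (`n_iter > burn_in`).
#' @param seed integer seed; the chain is reproducible given the seed.
#' @param df0,R2 residual-variance prior: scaled-inv-chi2 with `df0` degrees
#'   of freedom and scale from `var(y)` at prior R2.
#' @return object of class `mcmc_fit` with posterior means (`beta`,
#'   `effects`, `genetic_values`, `sigma2_e`, `lambda2`) and chain metadata.
#' @export
fit_bayesian_lasso <- function(y, X, M, n_iter = 6000, burn_in = 1000,
                               thin = 5, seed, df0 = 5, R2 = 0.5) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("y must be complete")
  n <- length(y)
  X <- .check_X(X, n)
  M <- as.matrix(M)
  if (anyNA(M)) stop("M must be complete")
  if (nrow(M) != n) stop("M rows must match y")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  vy <- var(y)
  S0 <- vy * (1 - R2) * (df0 + 2)
  MSx <- sum(apply(M, 2, var))
  if (MSx <= 0) stop("M has no variance")
  lambda2_init <- 2 * (1 - R2) * MSx / R2
  lshape <- 1.1
  lrate <- (lshape - 1) / lambda2_init
  post <- with_seed(seed,
    bl_gibbs_cpp(y, X, M, as.integer(n_iter), as.integer(burn_in),
                 as.integer(thin), df0, S0, lshape, lrate, lambda2_init))
  structure(list(model = "bayesian_lasso",
                 posterior = list(beta = post$beta, effects = post$effects,
                                  genetic_values = post$genetic_values,
                                  sigma2_e = post$sigma2_e,
                                  lambda2 = post$lambda2),
                 chain = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                              n_kept = post$n_kept, seed = seed),
                 n = n),
            class = "mcmc_fit")
}

#' Fit RKHS regression with kernel averaging by Gibbs sampling
#'
#' `y = X beta + sum_l u_l + e` with `u_l ~ N(0, K_l sigma2_ul)`; typically
#' the three Gaussian kernels at bandwidths 0.1, 0.5, 2.5 enter as separate
#' random effects whose variance components weight them. Sampling is done in
#' the eigenbasis of each (jittered) kernel.
#'
#' @param y trait vector.
#' @param X fixed design including the intercept.
#' @param kernels a [kernel_matrix()] or list of them.
#' @param n_iter,burn_in,thin chain settings.
#' @param seed integer seed.
#' @param df0,R2 prior settings as in [fit_bayesian_lasso()]; the genetic
#'   prior variance is split evenly across kernels.
#' @return an `mcmc_fit` with posterior means (`beta`, `u` per kernel,
#'   `genetic_values`, `sigma2_u`, `sigma2_e`) and kernel eigendecompositions
#'   retained for prediction.
#' @export
fit_rkhs <- function(y, X, kernels, n_iter = 6000, burn_in = 1000, thin = 5,
                     seed, df0 = 5, R2 = 0.5) {
  if (inherits(kernels, "kernel_matrix")) kernels <- list(kernels)
  y <- as.numeric(y)
  if (anyNA(y)) stop("y must be complete")
  n <- length(y)
  X <- .check_X(X, n)
  L <- length(kernels)
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  eigs <- lapply(kernels, function(K) {
    if (nrow(K$values) != n) stop("kernel dimension must match y")
    eg <- eigen(.jitter(K$values), symmetric = TRUE)
    keep <- eg$values > 1e-10 * max(eg$values)
    list(U = eg$vectors, d = pmax(eg$values, 0), keep = keep,
         mdiag = mean(diag(K$values)))
  })
  vy <- var(y)
  S0e <- vy * (1 - R2) * (df0 + 2)
  Sl <- vapply(eigs, function(eg) vy * R2 / L * (df0 + 2) / eg$mdiag, numeric(1))
  px <- ncol(X)
  XtX <- colSums(X^2)

  with_seed(seed, {
    beta <- rep(0, px)
    u <- replicate(L, rep(0, n), simplify = FALSE)
    s2u <- rep(vy * R2 / L, L)
    s2e <- vy * (1 - R2)
    e <- y - as.numeric(X %*% beta) - Reduce(`+`, u)
    keep_every <- thin
    acc <- list(beta = rep(0, px), u = replicate(L, rep(0, n), simplify = FALSE),
                g = rep(0, n), s2u = rep(0, L), s2e = 0)
    n_kept <- 0L
    for (it in seq_len(n_iter)) {
      # fixed effects (flat prior, coordinate-wise)
      for (j in seq_len(px)) {
        rhs <- sum(X[, j] * e) + XtX[j] * beta[j]
        mu <- rhs / XtX[j]
        nv <- mu + rnorm(1) * sqrt(s2e / XtX[j])
        e <- e - X[, j] * (nv - beta[j])
        beta[j] <- nv
      }
      # kernel random effects in eigenbasis
      for (l in seq_len(L)) {
        eg <- eigs[[l]]
        r <- e + u[[l]]
        v <- crossprod(eg$U, r)                       # rotated residual
        lam <- s2u[l] * eg$d
        shrink <- lam / (lam + s2e)
        m_coef <- shrink * v
        sd_coef <- sqrt(shrink * s2e)
        cvec <- m_coef + rnorm(n) * sd_coef
        u_new <- as.numeric(eg$U %*% cvec)
        e <- r - u_new
        u[[l]] <- u_new
        quad <- sum((cvec[eg$keep]^2) / eg$d[eg$keep])
        s2u[l] <- (quad + Sl[l]) / rchisq(1, sum(eg$keep) + df0)
      }
      s2e <- (sum(e^2) + S0e) / rchisq(1, n + df0)
      if (!is.finite(s2e) || any(!is.finite(s2u)))
        stop("RKHS chain diverged at iteration ", it)
      if (it > burn_in && (it - burn_in) %% keep_every == 0) {
        n_kept <- n_kept + 1L
        acc$beta <- acc$beta + beta
        for (l in seq_len(L)) acc$u[[l]] <- acc$u[[l]] + u[[l]]
        acc$g <- acc$g + Reduce(`+`, u)
        acc$s2u <- acc$s2u + s2u
        acc$s2e <- acc$s2e + s2e
      }
    }
    structure(list(model = "rkhs",
                   posterior = list(beta = acc$beta / n_kept,
                                    u = lapply(acc$u, `/`, n_kept),
                                    genetic_values = acc$g / n_kept,
                                    sigma2_u = acc$s2u / n_kept,
                                    sigma2_e = acc$s2e / n_kept),
                   chain = list(n_iter = n_iter, burn_in = burn_in,
                                thin = thin, n_kept = n_kept, seed = seed),
                   eigs = eigs, n = n),
              class = "mcmc_fit")
  })
}

#' @export
print.mcmc_fit <- function(x, ...) {
  cat(sprintf("<mcmc_fit> %s: %d iterations (%d kept), seed %s\n",
              x$model, x$chain$n_iter, x$chain$n_kept, x$chain$seed))
  invisible(x)
}

#' Predict new samples from a Bayesian fit
#'
#' Bayesian LASSO: `X_new beta + M_new f` (posterior means). RKHS:
#' `X_new beta + sum_l K_l(new, train) K_l(train, train)^- u_l`.
#'
#' @param object an `mcmc_fit`.
#' @param X_new fixed design for new samples.
#' @param M_new dosage matrix for new samples (Bayesian LASSO).
#' @param kernel_cross list of new x train kernel blocks (RKHS).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.mcmc_fit <- function(object, X_new, M_new = NULL, kernel_cross = NULL, ...) {
  X_new <- as.matrix(X_new)
  yhat <- as.numeric(X_new %*% object$posterior$beta)
  if (object$model == "bayesian_lasso") {
    if (is.null(M_new)) stop("Bayesian LASSO prediction needs M_new")
    yhat + as.numeric(as.matrix(M_new) %*% object$posterior$effects)
  } else {
    if (is.null(kernel_cross)) stop("RKHS prediction needs kernel_cross")
    if (is.matrix(kernel_cross)) kernel_cross <- list(kernel_cross)
    for (l in seq_along(kernel_cross)) {
      eg <- object$eigs[[l]]
      v <- crossprod(eg$U, object$posterior$u[[l]])
      w <- rep(0, length(v))
      w[eg$keep] <- v[eg$keep] / eg$d[eg$keep]
      yhat <- yhat + as.numeric(kernel_cross[[l]] %*% (eg$U %*% w))
    }
    yhat
  }
}
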