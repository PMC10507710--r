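# Cross-validation schemes and the block-method x model sweep.

#' Prediction accuracy
#'
#' Pearson correlation between observed and predicted values.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3), both
#'   non-constant.
#' @return Pearson r.
#' @export
accuracy <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("accuracy undefined for a constant vector")
  cor(observed, predicted)
}

# Fit the requested model on the training split and predict the test split.
# `data` carries whichever inputs the model needs:
#   gblup: kernels (list), egblup: G, blasso: M, rkhs: kernels (list).
fit_predict_split <- function(model, y, X, data, train, test, seed,
                              mcmc = list()) {
  y_tr <- y[train]
  X_tr <- X[train, , drop = FALSE]
  X_te <- X[test, , drop = FALSE]
  # drop non-intercept columns whose variance vanished in the split
  if (ncol(X_tr) > 1) {
    keep <- c(TRUE, vapply(2:ncol(X_tr), function(j) sd(X_tr[, j]) > 0, logical(1)))
    X_tr <- X_tr[, keep, drop = FALSE]
    X_te <- X_te[, keep, drop = FALSE]
  }
  n_iter <- mcmc$n_iter %||% 6000
  burn_in <- mcmc$burn_in %||% 1000
  thin <- mcmc$thin %||% 5
  if (model %in% c("gblup", "rkhs")) {
    kernels <- data$kernels
    if (inherits(kernels, "kernel_matrix")) kernels <- list(kernels)
    Ktr <- lapply(kernels, function(K)
      kernel_matrix(kernel_sub(K, train), K$sample_ids[train], K$kind))
    Kx <- lapply(kernels, function(K) kernel_sub(K, test, train))
    if (model == "gblup") {
      fit <- fit_gblup(y_tr, X_tr, Ktr)
      predict(fit, Kx, X_te)
    } else {
      fit <- fit_rkhs(y_tr, X_tr, Ktr, n_iter = n_iter, burn_in = burn_in,
                      thin = thin, seed = seed)
      predict(fit, X_te, kernel_cross = Kx)
    }
  } else if (model == "egblup") {
    G <- data$G
    Gtr <- kernel_matrix(kernel_sub(G, train), G$sample_ids[train], "additive")
    fit <- fit_egblup(y_tr, X_tr, Gtr)
    Kx <- list(kernel_sub(G, test, train), kernel_sub(G, test, train)^2)
    predict(fit, Kx, X_te)
  } else if (model == "blasso") {
    M <- data$M
    fit <- fit_bayesian_lasso(y_tr, X_tr, M[train, , drop = FALSE],
                              n_iter = n_iter, burn_in = burn_in, thin = thin,
                              seed = seed)
    predict(fit, X_te, M_new = M[test, , drop = FALSE])
  } else stop("unknown model: ", model)
}

.cv_result <- function(scheme, runs, seed, metadata) {
  ok <- runs$ok
  structure(list(scheme = scheme, per_run = runs,
                 mean = mean(runs$accuracy[ok]),
                 sd = sd(runs$accuracy[ok]),
                 n_runs = nrow(runs), n_failed = sum(!ok),
                 seed = seed, metadata = metadata),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s CV: %d runs (%d failed), mean r = %.4f (sd %.4f)\n",
              x$scheme, x$n_runs, x$n_failed, x$mean, x$sd))
  invisible(x)
}

#' Random (Monte Carlo) cross-validation
#'
#' Repeated independent 80/20 splits (not k-fold): each run draws a fresh
#' simple random split without replacement, refits the model on the training
#' fraction and scores Pearson accuracy on the validation fraction. Failed
#' runs are flagged and excluded from the mean. Deterministic given `seed`
#' (per-run seeds are derived from it).
#'
#' @param y trait vector.
#' @param X fixed design including intercept.
#' @param data model inputs: `kernels` (gblup/rkhs), `G` (egblup), `M`
#'   (blasso); full-population objects, subset internally.
#' @param model `"gblup"`, `"egblup"`, `"blasso"` or `"rkhs"`.
#' @param n_runs number of runs (default 100).
#' @param test_frac validation fraction (default 0.2); validation size is
#'   `round(n * test_frac)` with exact ties rounded up.
#' @param seed master seed.
#' @param mcmc optional list of chain settings for Bayesian models.
#' @return object of class `cv_result`.
#' @export
random_cv <- function(y, X, data, model = "gblup", n_runs = 100,
                      test_frac = 0.2, seed, mcmc = list()) {
  n <- length(y)
  n_test <- floor(n * test_frac + 0.5)
  if (n_test < 3) stop("validation set would have fewer than 3 samples")
  runs <- data.frame(run = seq_len(n_runs), accuracy = NA_real_,
                     n_test = n_test, ok = FALSE)
  for (r in seq_len(n_runs)) {
    rs <- derive_seed(seed, "cv", r)
    test <- with_seed(rs, sample.int(n, n_test))
    train <- setdiff(seq_len(n), test)
    acc <- tryCatch({
      pred <- fit_predict_split(model, y, X, data, train, test,
                                seed = derive_seed(rs, "fit"), mcmc = mcmc)
      accuracy(y[test], pred)
    }, error = function(e) NA_real_)
    runs$accuracy[r] <- acc
    runs$ok[r] <- is.finite(acc)
  }
  .cv_result("random", runs, seed,
             list(model = model, test_frac = test_frac))
}

#' Family-wise (leave-one-family-out) cross-validation
#'
#' Each family with at least 3 members serves once as the validation set;
#' smaller families are skipped with a warning. Every retained sample is
#' validated exactly once.
#'
#' @inheritParams random_cv
#' @param family_labels family assignment per sample (>= 2 retained families).
#' @param seed seed for Bayesian model chains (default 1).
#' @return a `cv_result` with one run per retained family.
#' @export
family_cv <- function(y, X, data, model = "gblup", family_labels, seed = 1,
                      mcmc = list()) {
  family_labels <- as.character(family_labels)
  stopifnot(length(family_labels) == length(y))
  fams <- split(seq_along(y), family_labels)
  small <- names(fams)[lengths(fams) < 3]
  if (length(small)) {
    warning("skipping family(ies) of size < 3: ", paste(small, collapse = ", "))
    fams <- fams[lengths(fams) >= 3]
  }
  if (length(fams) < 2) stop("need at least 2 families of size >= 3")
  runs <- data.frame(run = seq_along(fams), family = names(fams),
                     accuracy = NA_real_, n_test = lengths(fams), ok = FALSE)
  for (r in seq_along(fams)) {
    test <- fams[[r]]
    train <- setdiff(seq_along(y), test)
    acc <- tryCatch({
      pred <- fit_predict_split(model, y, X, data, train, test,
                                seed = derive_seed(seed, "famcv", r),
                                mcmc = mcmc)
      accuracy(y[test], pred)
    }, error = function(e) NA_real_)
    runs$accuracy[r] <- acc
    runs$ok[r] <- is.finite(acc)
  }
  .cv_result("family", runs, seed, list(model = model))
}

#' Sweep block methods x parameters x models
#'
#' For every block specification (method + parameter) the chromosome-wise
#' partition, haplotype catalog, design and the kernels/dosages each model
#' needs are built once, then the requested cross-validation is run per
#' model. Individual cell failures are recorded and the sweep continues.
#'
#' @param y,X as in [random_cv()].
#' @param gm complete [genotype_matrix()].
#' @param map paired [marker_map()].
#' @param block_specs list of lists `list(method=, param=)`; method one of
#'   `"snp"`, `"ld"`, `"fixm"`, `"fixbp"`, `"gabriel"`, `"fourgamete"`,
#'   `"spine"`.
#' @param models character vector of model names.
#' @param cv list: `scheme` ("random"/"family"), `n_runs`, `test_frac`,
#'   `seed`, optional `family_labels`, optional `mcmc`.
#' @return data.frame, one row per (block spec, model) cell.
#' @export
sweep_grid <- function(y, X, gm, map, block_specs, models, cv) {
  rows <- list()
  for (bs in block_specs) {
    part <- tryCatch(switch(bs$method,
      snp = blocks_fixed_markers(map, 1L),
      ld = blocks_ld_threshold(gm, map, threshold = bs$param),
      fixm = blocks_fixed_markers(map, bs$param),
      fixbp = blocks_fixed_bp(map, bs$param),
      gabriel = blocks_gabriel(gm, map, seed = cv$seed %||% 1),
      fourgamete = blocks_four_gamete(gm, map),
      spine = blocks_solid_spine(gm, map),
      stop("unknown block method: ", bs$method)),
      error = function(e) e)
    for (model in models) {
      row <- data.frame(block_method = bs$method,
                        param = if (is.null(bs$param)) NA else bs$param,
                        model = model, mean_r = NA_real_, sd_r = NA_real_,
                        n_effective_predictors = NA_integer_,
                        error = NA_character_)
      res <- tryCatch({
        if (inherits(part, "error")) stop(conditionMessage(part))
        cat_ <- enumerate_haplotypes(gm, part)
        des <- build_design(cat_)
        data <- list()
        if (model %in% c("gblup", "egblup")) {
          G <- grm_vanraden(des)
          data <- list(kernels = list(G), G = G)
        } else if (model == "rkhs") {
          data <- list(kernels = gaussian_kernels(des))
        } else if (model == "blasso") {
          data <- list(M = sweep(des$Z, 2, -2 * des$freqs))   # raw 0/1/2 counts
        }
        cvres <- if ((cv$scheme %||% "random") == "family")
          family_cv(y, X, data, model, cv$family_labels, seed = cv$seed %||% 1,
                    mcmc = cv$mcmc %||% list())
        else
          random_cv(y, X, data, model, n_runs = cv$n_runs %||% 100,
                    test_frac = cv$test_frac %||% 0.2, seed = cv$seed %||% 1,
                    mcmc = cv$mcmc %||% list())
        row$mean_r <- cvres$mean; row$sd_r <- cvres$sd
        row$n_effective_predictors <- ncol(des$Z)
        row
      }, error = function(e) { row$error <- conditionMessage(e); row })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}
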