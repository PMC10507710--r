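#' Kernel matrix container
#'
#' @param values symmetric n x n numeric matrix.
#' @param sample_ids sample identifiers (rows/columns).
#' @param kind `"additive"`, `"epistatic"` or `"gaussian"`.
#' @param provenance free-form list describing the source design/parameters.
#' @return object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, sample_ids = rownames(values),
                          kind = c("additive", "epistatic", "gaussian"),
                          provenance = list()) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kernel must be square")
  if (max(abs(values - t(values))) > 1e-8 * (1 + max(abs(values))))
    stop("kernel must be symmetric")
  values <- (values + t(values)) / 2
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 kind = kind, provenance = provenance),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %s, %d x %d, mean diag %.3f\n",
              x$kind, nrow(x$values), ncol(x$values), mean(diag(x$values))))
  invisible(x)
}

# subset a kernel (square or rectangular cross-block)
kernel_sub <- function(K, i, j = i) K$values[i, j, drop = FALSE]

#' VanRaden additive genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_i (1 - p_i)))` over the centered design columns.
#'
#' @param design a [build_design()] / [snp_design()] result.
#' @return additive [kernel_matrix()].
#' @export
grm_vanraden <- function(design) {
  if (design$denominator <= 0)
    stop("zero VanRaden denominator (all blocks monomorphic)")
  G <- tcrossprod(design$Z) / design$denominator
  kernel_matrix(G, rownames(design$Z), "additive",
                provenance = list(denominator = design$denominator,
                                  n_columns = ncol(design$Z)))
}

#' Epistatic (additive x additive) relationship matrix
#'
#' Hadamard square of the additive kernel: `Gaa[i,j] = G[i,j]^2`.
#'
#' @param G an additive [kernel_matrix()].
#' @return epistatic [kernel_matrix()].
#' @export
epistatic_grm <- function(G) {
  stopifnot(inherits(G, "kernel_matrix"))
  if (G$kind != "additive") stop("epistatic_grm expects an additive kernel")
  kernel_matrix(G$values * G$values, G$sample_ids, "epistatic",
                provenance = list(source = "hadamard_square"))
}

#' Gaussian kernels at a set of bandwidths
#'
#' `K_l[i,j] = exp(-h_l * d2_ij / mean(d2))` with `d2` the squared Euclidean
#' distance between genotype profiles and `mean(d2)` the off-diagonal mean,
#' so the bandwidths are scale-free. Diagonal is 1.
#'
#' @param design a [build_design()] result (distances use the centered Z).
#' @param bandwidths positive bandwidth values (default `c(0.1, 0.5, 2.5)`).
#' @return list of gaussian [kernel_matrix()] objects, one per bandwidth.
#' @export
gaussian_kernels <- function(design, bandwidths = c(0.1, 0.5, 2.5)) {
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")
  d2 <- as.matrix(stats::dist(design$Z))^2
  md <- mean(d2[upper.tri(d2)])
  if (!is.finite(md) || md <= 0)
    stop("all samples identical: Gaussian kernel undefined")
  lapply(bandwidths, function(h)
    kernel_matrix(exp(-h * d2 / md), rownames(design$Z), "gaussian",
                  provenance = list(bandwidth = h, mean_d2 = md)))
}

#' Pearson correlation of relationship coefficients
#'
#' Correlation over the strict upper triangle (diagonal excluded) of two
#' kernels on the same samples in the same order.
#'
#' @param G_a,G_b [kernel_matrix()] objects.
#' @return Pearson correlation.
#' @export
relationship_correlation <- function(G_a, G_b) {
  stopifnot(inherits(G_a, "kernel_matrix"), inherits(G_b, "kernel_matrix"))
  if (!identical(G_a$sample_ids, G_b$sample_ids))
    stop("kernels must cover the same samples in the same order")
  ut <- upper.tri(G_a$values)
  a <- G_a$values[ut]; b <- G_b$values[ut]
  if (sd(a) == 0 || sd(b) == 0)
    stop("constant off-diagonal relationship coefficients: correlation undefined")
  cor(a, b)
}

#' Write / read a kernel as a plain square table
#'
#' Tab-delimited square matrix with a header row of sample ids.
#' @param K a [kernel_matrix()].
#' @param path file path.
#' @return `path` (write) or a [kernel_matrix()] (read).
#' @export
write_kernel <- function(K, path) {
  d <- data.frame(sample = K$sample_ids, K$values, check.names = FALSE)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_kernel
#' @param kind kernel kind tag for the read object.
#' @export
read_kernel <- function(path, kind = "additive") {
  d <- data.table::fread(path, data.table = FALSE)
  ids <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  kernel_matrix(m, ids, kind)
}
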