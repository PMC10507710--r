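#' Genotype matrix container
#'
#' Holds a sample x marker dosage matrix coded as minor/alt-allele counts in
#' \{0, 1, 2\} (NA = missing). Two ploidy modes are supported: `"homozygous"`
#' (fully inbred / doubled-haploid material; no dosage of 1 allowed) and
#' `"phased_diploid"` (e.g. in-silico F1 hybrids, where the two parental
#' gametes are stored explicitly as 0/1 haplotype matrices).
#'
#' @param dosages numeric matrix, samples in rows, markers in columns.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(dosages)`.
#' @param ploidy `"homozygous"` or `"phased_diploid"`.
#' @param phase1,phase2 for phased material, 0/1 matrices of the two gametes
#'   per sample; `phase1 + phase2` must equal `dosages`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            ploidy = c("homozygous", "phased_diploid"),
                            phase1 = NULL, phase2 = NULL) {
  ploidy <- match.arg(ploidy)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids length does not match dosage rows")
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("non-missing dosages must be 0, 1 or 2")
  if (ploidy == "homozygous") {
    if (any(vals == 1))
      stop("homozygous material cannot contain dosage 1 (heterozygote)")
    if (!is.null(phase1) || !is.null(phase2))
      stop("phases are only stored for phased_diploid material")
  } else {
    if (is.null(phase1) || is.null(phase2))
      stop("phased_diploid material requires phase1 and phase2")
    phase1 <- as.matrix(phase1); phase2 <- as.matrix(phase2)
    storage.mode(phase1) <- "double"; storage.mode(phase2) <- "double"
    if (!identical(dim(phase1), dim(dosages)) ||
        !identical(dim(phase2), dim(dosages)))
      stop("phase matrices must match dosage dimensions")
    if (!all(phase1 %in% c(0, 1), na.rm = TRUE) ||
        !all(phase2 %in% c(0, 1), na.rm = TRUE))
      stop("phases must be 0/1 haplotypes")
    ok <- is.na(dosages) | (phase1 + phase2 == dosages)
    if (!all(ok)) stop("phase1 + phase2 must equal dosages")
  }
  rownames(dosages) <- sample_ids
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 ploidy = ploidy, phase1 = phase1, phase2 = phase2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d markers (%s)\n",
              nrow(x$dosages), ncol(x$dosages), x$ploidy))
  nm <- sum(is.na(x$dosages))
  if (nm) cat(sprintf("  missing entries: %d (%.2f%%)\n", nm,
                      100 * nm / length(x$dosages)))
  invisible(x)
}

#' Number of samples / markers in a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$dosages)

#' @rdname n_samples
#' @export
n_markers <- function(gm) ncol(gm$dosages)

#' Physical marker map
#'
#' @param marker character vector of unique marker ids.
#' @param chrom chromosome label per marker.
#' @param pos 1-based physical position in bp (positive integers); the pair
#'   (chrom, pos) must be unique per marker, and the map is stored sorted by
#'   chromosome then position.
#' @return a `data.frame` of class `marker_map` with columns
#'   `marker`, `chrom`, `pos`.
#' @export
marker_map <- function(marker, chrom, pos) {
  marker <- as.character(marker); chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (anyDuplicated(marker)) stop("marker ids must be unique")
  if (any(is.na(pos)) || any(pos < 1)) stop("positions must be positive integers")
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicate (chromosome, position) pairs: markers need a unique physical position")
  map <- data.frame(marker = marker, chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  map
}

# reorder genotype columns to match a (sorted) map given current marker ids
align_to_map <- function(gm, map, marker_ids) {
  idx <- match(map$marker, marker_ids)
  if (anyNA(idx)) stop("map and genotype marker ids disagree")
  sub_markers(gm, idx)
}

sub_markers <- function(gm, j) {
  genotype_matrix(gm$dosages[, j, drop = FALSE], gm$sample_ids, gm$ploidy,
                  phase1 = if (!is.null(gm$phase1)) gm$phase1[, j, drop = FALSE],
                  phase2 = if (!is.null(gm$phase2)) gm$phase2[, j, drop = FALSE])
}

sub_samples <- function(gm, i) {
  genotype_matrix(gm$dosages[i, , drop = FALSE], gm$sample_ids[i], gm$ploidy,
                  phase1 = if (!is.null(gm$phase1)) gm$phase1[i, , drop = FALSE],
                  phase2 = if (!is.null(gm$phase2)) gm$phase2[i, , drop = FALSE])
}

# Gamete (haplotype) matrix over the given marker columns: one row per gamete,
# entries 0/1. A homozygous line contributes one gamete, a phased diploid two.
gametes <- function(gm, markers = seq_len(n_markers(gm))) {
  d <- gm$dosages[, markers, drop = FALSE]
  if (anyNA(d)) stop("gametes require complete (imputed) genotypes")
  if (gm$ploidy == "homozygous") {
    g <- d / 2
    rownames(g) <- gm$sample_ids
    g
  } else {
    g <- rbind(gm$phase1[, markers, drop = FALSE],
               gm$phase2[, markers, drop = FALSE])
    rownames(g) <- c(paste0(gm$sample_ids, ".1"), paste0(gm$sample_ids, ".2"))
    g
  }
}

gametes_per_sample <- function(gm) if (gm$ploidy == "homozygous") 1L else 2L

#' Phenotype table
#'
#' @param sample sample identifiers (must be unique).
#' @param trait numeric trait values (adjusted means); no missing values.
#' @param covariates optional data.frame/matrix of fixed-effect covariates
#'   (an intercept is always added by the model code, do not include one).
#' @param family optional family labels (e.g. NAM half-sib families).
#' @return a data.frame of class `phenotype_table`.
#' @export
phenotype_table <- function(sample, trait, covariates = NULL, family = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) stop("phenotype sample ids must be unique")
  trait <- as.numeric(trait)
  if (anyNA(trait)) stop("missing trait values are not allowed")
  out <- data.frame(sample = sample, trait = trait, stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(sample))
    out <- cbind(out, covariates)
    attr(out, "covariate_names") <- colnames(covariates)
  }
  if (!is.null(family)) out$family <- as.character(family)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Fixed-effect design matrix from a phenotype table
#'
#' Intercept plus any covariate columns declared at construction.
#' @param pheno a [phenotype_table()].
#' @return numeric matrix with `nrow(pheno)` rows.
#' @export
fixed_design <- function(pheno) {
  X <- matrix(1, nrow(pheno), 1, dimnames = list(pheno$sample, "intercept"))
  cv <- attr(pheno, "covariate_names")
  if (!is.null(cv)) X <- cbind(X, as.matrix(pheno[, cv, drop = FALSE]))
  X
}

#' Filter markers on minor allele frequency and missingness
#'
#' Retains markers with MAF >= `maf_min` (boundary inclusive) and a missing
#' fraction <= `max_missing`. Frequencies are computed on non-missing calls.
#'
#' @param gm a [genotype_matrix()].
#' @param map the paired [marker_map()].
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`.
#' @param max_missing maximum fraction of missing calls, in `[0, 1]`.
#' @return list with elements `gm`, `map` (filtered) and `report`, a
#'   data.frame of dropped markers with the removal reason.
#' @export
filter_markers <- function(gm, map, maf_min = 0.05, max_missing = 0.10) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(map, "marker_map"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0, 1]")
  if (n_markers(gm) != nrow(map)) stop("genotypes and map differ in marker count")
  d <- gm$dosages
  miss <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0     # fully missing marker
  drop_missing <- miss > max_missing
  drop_maf <- !drop_missing & maf < maf_min
  keep <- !(drop_missing | drop_maf)
  if (!any(keep)) stop("all markers removed by filtering")
  report <- data.frame(
    marker = map$marker[!keep],
    reason = ifelse(drop_missing[!keep], "missingness", "maf"),
    maf = maf[!keep], missing = miss[!keep],
    stringsAsFactors = FALSE)
  out_map <- map[keep, , drop = FALSE]
  rownames(out_map) <- NULL
  class(out_map) <- c("marker_map", "data.frame")
  list(gm = sub_markers(gm, which(keep)), map = out_map, report = report)
}

#' Naive seeded imputation of missing dosages
#'
#' Each missing entry is replaced by a draw from the marker's observed dosage
#' distribution. Deterministic given `seed`; a stand-in for haplotype-aware
#' imputation, which is out of scope.
#'
#' @param gm a [genotype_matrix()] (homozygous).
#' @param seed integer seed.
#' @return a complete [genotype_matrix()].
#' @export
impute_naive <- function(gm, seed) {
  d <- gm$dosages
  if (!anyNA(d)) return(gm)
  if (gm$ploidy != "homozygous")
    stop("impute_naive supports homozygous material only")
  with_seed(seed, {
    for (j in seq_len(ncol(d))) {
      mis <- which(is.na(d[, j]))
      if (!length(mis)) next
      obs <- d[!is.na(d[, j]), j]
      if (!length(obs)) stop(sprintf("marker %d is fully missing", j))
      d[mis, j] <- sample(obs, length(mis), replace = TRUE)
    }
  })
  genotype_matrix(d, gm$sample_ids, gm$ploidy)
}

#' Derive in-silico hybrids from homozygous parents
#'
#' Crosses fully homozygous mother and father lines; the hybrid dosage at each
#' marker is `(mother + father) / 2` and the two parental gametes are recorded
#' as the hybrid's phases, so downstream haplotype coding is exact.
#'
#' @param mothers,fathers homozygous [genotype_matrix()] objects sharing the
#'   same marker map.
#' @param pairings data.frame or 2-column matrix of (mother, father) sample
#'   ids (or integer indices), one row per hybrid.
#' @return a phased-diploid [genotype_matrix()] of the hybrids; sample ids are
#'   `"<mother>x<father>"`.
#' @export
in_silico_cross <- function(mothers, fathers, pairings) {
  stopifnot(inherits(mothers, "genotype_matrix"),
            inherits(fathers, "genotype_matrix"))
  if (mothers$ploidy != "homozygous" || fathers$ploidy != "homozygous")
    stop("parents must be homozygous (phase undefined otherwise)")
  if (anyNA(mothers$dosages) || anyNA(fathers$dosages))
    stop("parents must be complete (imputed)")
  if (n_markers(mothers) != n_markers(fathers))
    stop("parents must share a marker map")
  pairings <- as.data.frame(pairings)
  mi <- pairings[[1]]; fi <- pairings[[2]]
  if (is.character(mi) || is.factor(mi)) mi <- match(as.character(mi), mothers$sample_ids)
  if (is.character(fi) || is.factor(fi)) fi <- match(as.character(fi), fathers$sample_ids)
  if (anyNA(mi) || anyNA(fi)) stop("pairing references unknown parent")
  p1 <- mothers$dosages[mi, , drop = FALSE] / 2
  p2 <- fathers$dosages[fi, , drop = FALSE] / 2
  ids <- paste0(mothers$sample_ids[mi], "x", fathers$sample_ids[fi])
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  rownames(p1) <- rownames(p2) <- ids
  genotype_matrix(p1 + p2, ids, "phased_diploid", phase1 = p1, phase2 = p2)
}
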