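#' Read genotypes and marker map
#'
#' Two formats are supported. `format = "matrix"`: `path` is a file prefix;
#' `<prefix>.geno.tsv` holds the sample x marker dosage matrix (first column
#' `sample`, remaining columns named by marker id) and `<prefix>.map.tsv` the
#' 3-column map (`marker`, `chrom`, `pos`). `format = "vcf"`: `path` is a VCF
#' (v4.x) with GT calls; only biallelic SNP sites are used, others are skipped
#' with a warning (parsing via the VariantAnnotation package).
#'
#' Dosages are re-oriented to count the minor allele, determined from the full
#' sample at read time.
#'
#' @param path file prefix (matrix format) or VCF path.
#' @param format `"matrix"` or `"vcf"`.
#' @return list with elements `gm` ([genotype_matrix()]) and `map`
#'   ([marker_map()]).
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  if (format == "matrix") .read_matrix_format(path) else .read_vcf_format(path)
}

.read_matrix_format <- function(prefix) {
  gf <- paste0(prefix, ".geno.tsv"); mf <- paste0(prefix, ".map.tsv")
  for (f in c(gf, mf)) if (!file.exists(f)) stop("file not found: ", f)
  geno <- data.table::fread(gf, sep = "\t", header = TRUE, data.table = FALSE)
  mapd <- data.table::fread(mf, sep = "\t", header = TRUE, data.table = FALSE)
  if (!identical(colnames(mapd)[1:3], c("marker", "chrom", "pos")))
    stop("malformed map file (expected columns marker, chrom, pos): ", mf)
  if (colnames(geno)[1] != "sample")
    stop("malformed genotype file (first column must be 'sample'): ", gf)
  ids <- as.character(geno[[1]])
  d <- as.matrix(geno[, -1, drop = FALSE])
  if (!is.numeric(d)) stop("non-numeric dosages in ", gf)
  map <- marker_map(mapd$marker, mapd$chrom, mapd$pos)
  het <- any(d == 1, na.rm = TRUE)
  gm <- genotype_matrix(d, ids, ploidy = if (het) stop(
    "matrix format supports homozygous material only (dosage 1 found)") else "homozygous")
  gm <- align_to_map(gm, map, colnames(d))
  gm <- .orient_minor(gm)
  list(gm = gm, map = map)
}

# flip columns so dosages count the minor allele
.orient_minor <- function(gm) {
  p <- colMeans(gm$dosages, na.rm = TRUE) / 2
  flip <- which(!is.na(p) & p > 0.5)
  if (!length(flip)) return(gm)
  d <- gm$dosages
  d[, flip] <- 2 - d[, flip]
  if (gm$ploidy == "phased_diploid") {
    p1 <- gm$phase1; p2 <- gm$phase2
    p1[, flip] <- 1 - p1[, flip]; p2[, flip] <- 1 - p2[, flip]
    genotype_matrix(d, gm$sample_ids, gm$ploidy, phase1 = p1, phase2 = p2)
  } else genotype_matrix(d, gm$sample_ids, gm$ploidy)
}

.read_vcf_format <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  biallelic <- lengths(alt) == 1L
  n_skip <- sum(!biallelic)
  if (n_skip) warning(sprintf("skipped %d non-biallelic site(s)", n_skip))
  if (!any(biallelic)) stop("no biallelic sites in ", path)
  vcf <- vcf[biallelic]
  gt <- VariantAnnotation::geno(vcf)$GT      # markers x samples
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ids <- rownames(gt)
  if (is.null(ids) || anyDuplicated(ids))
    ids <- paste0(chrom, "_", pos)
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicate (chromosome, position) in VCF: ", path)
  parse_gt <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) {
      if (any(x == ".")) return(NA_real_)
      sum(x == "1")
    }, numeric(1))
  }
  d <- t(apply(gt, 1, parse_gt))             # markers x samples
  phased_any <- any(grepl("\\|", gt))
  het <- any(d == 1, na.rm = TRUE)
  dt <- t(d)                                  # samples x markers
  samples <- colnames(gt)
  map <- marker_map(ids, chrom, pos)
  if (het) {
    if (!phased_any || any(grepl("/", gt[!is.na(gt) & gt != "./."])))
      stop("heterozygous unphased GT found; phased input required")
    split1 <- apply(gt, 1, function(g)
      vapply(strsplit(g, "\\|"), function(x) as.numeric(x[1]), numeric(1)))
    split2 <- apply(gt, 1, function(g)
      vapply(strsplit(g, "\\|"), function(x) as.numeric(x[2]), numeric(1)))
    gm <- genotype_matrix(dt, samples, "phased_diploid",
                          phase1 = split1, phase2 = split2)
  } else {
    gm <- genotype_matrix(dt, samples, "homozygous")
  }
  gm <- align_to_map(gm, map, ids)
  gm <- .orient_minor(gm)
  list(gm = gm, map = map)
}

#' Write genotypes in the plain matrix format
#'
#' Emits `<prefix>.geno.tsv` and `<prefix>.map.tsv`; round-trips with
#' [read_genotypes()] for homozygous material.
#'
#' @param gm a [genotype_matrix()].
#' @param map the paired [marker_map()].
#' @param prefix output file prefix.
#' @return `prefix`, invisibly.
#' @export
write_genotypes <- function(gm, map, prefix) {
  stopifnot(n_markers(gm) == nrow(map))
  g <- data.frame(sample = gm$sample_ids, gm$dosages, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(g) <- c("sample", map$marker)
  data.table::fwrite(g, paste0(prefix, ".geno.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(unclass(map)), paste0(prefix, ".map.tsv"),
                     sep = "\t")
  invisible(prefix)
}

#' Write genotypes as a minimal VCF
#'
#' Plain-text VCF v4.2 with GT calls only; homozygous lines are written as
#' `0/0` / `1/1`, phased diploids with `|` separators.
#'
#' @inheritParams write_genotypes
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, map, path) {
  stopifnot(n_markers(gm) == nrow(map))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")), con)
  n <- n_samples(gm)
  for (j in seq_len(nrow(map))) {
    if (gm$ploidy == "homozygous") {
      gt <- c("0/0", "1/1")[gm$dosages[, j] / 2 + 1]
      gt[is.na(gt)] <- "./."
    } else {
      gt <- paste0(gm$phase1[, j], "|", gm$phase2[, j])
      gt[is.na(gm$dosages[, j])] <- ".|."
    }
    writeLines(paste(c(map$chrom[j], map$pos[j], map$marker[j], "A", "T", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype CSV
#'
#' Expected columns: `sample`, `trait` (or a named trait column given by
#' `trait`), optional covariate columns and an optional `family` column.
#'
#' @param path CSV path.
#' @param trait name of the trait column (default `"trait"`).
#' @param covariates character vector of covariate column names.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, trait = "trait", covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- data.table::fread(path, data.table = FALSE)
  if (!"sample" %in% colnames(d)) stop("phenotype file needs a 'sample' column")
  if (!trait %in% colnames(d)) stop("trait column not found: ", trait)
  phenotype_table(d$sample, d[[trait]],
                  covariates = if (!is.null(covariates)) d[, covariates, drop = FALSE],
                  family = if ("family" %in% colnames(d)) d$family)
}
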