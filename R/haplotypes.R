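#' Enumerate haplotype alleles within blocks
#'
#' Per block, the distinct gamete allele strings over the block's markers are
#' the haplotypes; frequencies are gamete counts over total gametes, and each
#' sample carries a haplotype dosage (0/1/2). Haplotypes are ordered by
#' descending frequency, ties broken lexicographically.
#'
#' @param gm a complete, phase-resolved [genotype_matrix()].
#' @param partition a [block_partition()].
#' @return object of class `haplo_catalog`: a list with `blocks` (per block:
#'   `haps`, `freqs`, `dosage` matrix n_samples x k), `sample_ids`,
#'   `n_gametes` and the originating `partition`.
#' @export
enumerate_haplotypes <- function(gm, partition) {
  stopifnot(inherits(partition, "block_partition"))
  if (partition$n_markers != n_markers(gm))
    stop("partition and genotypes disagree in marker count")
  if (anyNA(gm$dosages)) stop("complete (imputed) genotypes required")
  n <- n_samples(gm)
  gps <- gametes_per_sample(gm)
  blocks <- lapply(seq_len(nrow(partition$blocks)), function(b) {
    cols <- partition$blocks$start[b]:(partition$blocks$end[b] - 1L)
    g <- gametes(gm, cols)
    strs <- apply(g, 1, paste, collapse = "")
    tab <- table(strs)
    freqs <- as.numeric(tab) / length(strs)
    haps <- names(tab)
    ord <- order(-freqs, haps)
    haps <- haps[ord]; freqs <- freqs[ord]
    # per-sample dosage of each haplotype
    idx <- match(strs, haps)
    dosage <- matrix(0, n, length(haps))
    if (gps == 1L) {
      dosage[cbind(seq_len(n), idx)] <- 2
    } else {
      for (s in seq_len(n)) {
        dosage[s, idx[s]] <- dosage[s, idx[s]] + 1
        dosage[s, idx[n + s]] <- dosage[s, idx[n + s]] + 1
      }
    }
    list(haps = haps, freqs = freqs, dosage = dosage)
  })
  structure(list(blocks = blocks, sample_ids = gm$sample_ids,
                 n_gametes = n * gps, partition = partition),
            class = "haplo_catalog")
}

#' @export
print.haplo_catalog <- function(x, ...) {
  k <- vapply(x$blocks, function(b) length(b$haps), integer(1))
  cat(sprintf("<haplo_catalog> %d blocks, %d haplotypes total, %d samples\n",
              length(x$blocks), sum(k), length(x$sample_ids)))
  invisible(x)
}

#' Block / haplotype summary counts
#'
#' Reports the number of blocks, unblocked SNPs (size-1 blocks), haplotypes
#' available for prediction (excluding single-SNP blocks) and rare haplotypes
#' at the given inclusive frequency cuts.
#'
#' @param catalog a [enumerate_haplotypes()] result.
#' @param rare_cuts inclusive frequency cuts (default `c(0.05, 0.01)`).
#' @return list with `n_blocks`, `n_unblocked`, `n_haplotypes` and `rare`, a
#'   named vector of rare-haplotype counts per cut.
#' @export
count_summary <- function(catalog, rare_cuts = c(0.05, 0.01)) {
  sizes <- block_sizes(catalog$partition)
  multi <- which(sizes > 1)
  freqs <- unlist(lapply(catalog$blocks[multi], `[[`, "freqs"))
  rare <- vapply(rare_cuts, function(cut) sum(freqs <= cut), numeric(1))
  names(rare) <- paste0("freq<=", rare_cuts)
  list(n_blocks = length(sizes),
       n_unblocked = sum(sizes == 1),
       n_haplotypes = length(freqs),
       rare = rare)
}

#' Centered multi-allelic design matrix
#'
#' Builds the haplotype design Z: blocks with exactly two haplotypes are
#' treated as standard biallelic markers (one column, minor-haplotype dosage);
#' blocks with k > 2 haplotypes contribute one column per haplotype;
#' monomorphic blocks contribute none. Raw 0/1/2 counts are centered by twice
#' the haplotype frequency, and the VanRaden denominator
#' `2 * sum(p_i * (1 - p_i))` is accumulated over all emitted columns.
#'
#' @param catalog a [enumerate_haplotypes()] result.
#' @param min_hap_freq optional minimum haplotype frequency; columns of rarer
#'   haplotypes are dropped (default 0 = keep all, as in the reference
#'   analysis).
#' @return object of class `haplo_design`: list with `Z` (centered matrix),
#'   `freqs`, `column_map` (block, haplotype) and `denominator`.
#' @export
build_design <- function(catalog, min_hap_freq = 0) {
  n <- length(catalog$sample_ids)
  cols <- list(); freqs <- c(); cmap <- list()
  for (b in seq_along(catalog$blocks)) {
    blk <- catalog$blocks[[b]]
    k <- length(blk$haps)
    if (k < 2) next
    if (k == 2) {
      j <- 2L                    # minor = lower frequency (second after sort)
      if (blk$freqs[j] < min_hap_freq) next
      cols[[length(cols) + 1L]] <- blk$dosage[, j]
      freqs <- c(freqs, blk$freqs[j])
      cmap[[length(cmap) + 1L]] <- data.frame(block = b, hap = blk$haps[j])
    } else {
      keep <- which(blk$freqs >= min_hap_freq)
      for (j in keep) {
        cols[[length(cols) + 1L]] <- blk$dosage[, j]
        freqs <- c(freqs, blk$freqs[j])
        cmap[[length(cmap) + 1L]] <- data.frame(block = b, hap = blk$haps[j])
      }
    }
  }
  if (!length(cols)) stop("no polymorphic blocks: design is empty")
  raw <- do.call(cbind, cols)
  Z <- sweep(raw, 2, 2 * freqs)
  rownames(Z) <- catalog$sample_ids
  structure(list(Z = Z, freqs = freqs,
                 column_map = do.call(rbind, cmap),
                 denominator = 2 * sum(freqs * (1 - freqs))),
            class = "haplo_design")
}

#' @export
print.haplo_design <- function(x, ...) {
  cat(sprintf("<haplo_design> %d samples x %d columns, denominator %.4f\n",
              nrow(x$Z), ncol(x$Z), x$denominator))
  invisible(x)
}

#' SNP (single-marker) design matrix
#'
#' The all-singleton special case of [build_design()]: every marker is its own
#' block, so Z reduces to the centered minor-allele dosage matrix.
#'
#' @param gm a complete [genotype_matrix()].
#' @param map the paired [marker_map()].
#' @return a `haplo_design`.
#' @export
snp_design <- function(gm, map) {
  part <- blocks_fixed_markers(map, 1L)
  build_design(enumerate_haplotypes(gm, part))
}

#' Export a haplotype catalog as a long table
#'
#' @param catalog a [enumerate_haplotypes()] result.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  rows <- do.call(rbind, lapply(seq_along(catalog$blocks), function(b) {
    blk <- catalog$blocks[[b]]
    data.frame(block_id = sprintf("blk%04d", b), haplotype = blk$haps,
               frequency = blk$freqs)
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}
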