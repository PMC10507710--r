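#' Block partition container
#'
#' A partition is a data.frame with columns `chrom`, `start`, `end` where
#' `start`/`end` are half-open global marker indices into the (sorted) map.
#' Blocks are non-overlapping and their union covers every marker; size-1
#' blocks are "unblocked SNPs".
#'
#' @param blocks data.frame with columns `chrom`, `start`, `end`.
#' @param map the [marker_map()] the indices refer to.
#' @param method builder tag.
#' @param params named list of builder parameters.
#' @return object of class `block_partition`.
#' @export
block_partition <- function(blocks, map, method, params = list()) {
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  if (any(blocks$end <= blocks$start)) stop("empty block (end <= start)")
  cov <- unlist(mapply(seq, blocks$start, blocks$end - 1L, SIMPLIFY = FALSE))
  if (length(cov) != nrow(map) || anyDuplicated(cov) ||
      !setequal(cov, seq_len(nrow(map))))
    stop("blocks must disjointly cover every marker of the map")
  for (r in seq_len(nrow(blocks))) {
    ch <- map$chrom[blocks$start[r]:(blocks$end[r] - 1L)]
    if (length(unique(ch)) != 1L || ch[1] != blocks$chrom[r])
      stop("block crosses a chromosome boundary")
  }
  structure(list(blocks = blocks, method = method, params = params,
                 n_markers = nrow(map)),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  sz <- x$blocks$end - x$blocks$start
  cat(sprintf("<block_partition> %s: %d blocks over %d markers (%d singletons)\n",
              x$method, nrow(x$blocks), x$n_markers, sum(sz == 1)))
  invisible(x)
}

#' Marker count per block of a partition
#' @param partition a [block_partition()].
#' @return integer vector, one entry per block.
#' @export
block_sizes <- function(partition) partition$blocks$end - partition$blocks$start

# per-chromosome marker index ranges of a sorted map
chrom_index <- function(map) split(seq_len(nrow(map)), map$chrom)

.partition_from_chrom_blocks <- function(per_chrom, map, method, params) {
  rows <- do.call(rbind, lapply(names(per_chrom), function(ch) {
    b <- per_chrom[[ch]]
    if (is.null(b) || !nrow(b)) return(NULL)
    data.frame(chrom = ch, start = b[, 1], end = b[, 2])
  }))
  block_partition(rows, map, method, params)
}

# add singleton runs for members not covered by the (start, end) ranges
.add_singletons <- function(runs, members) {
  covered <- unlist(lapply(runs, function(r) r[1]:r[2]))
  left <- setdiff(members, covered)
  c(runs, lapply(left, function(i) c(i, i)))
}

.runs_to_matrix <- function(runs) {
  if (!length(runs)) return(matrix(numeric(0), 0, 2))
  m <- do.call(rbind, lapply(runs, function(r) c(r[1], r[2] + 1L)))
  m[order(m[, 1]), , drop = FALSE]
}

#' LD-threshold haplotype blocks
#'
#' Per chromosome, blocks are seeded at the unassigned adjacent marker pair
#' with the highest r-squared (ties to the lowest index) provided it meets
#' `threshold`, then extended at both borders while the candidate adjacent
#' marker and the current border marker have r-squared >= `threshold`. Up to
#' `tolerance` consecutive failing markers are absorbed into the block when
#' the marker just beyond them passes against the same border marker.
#' Remaining markers become singleton blocks.
#'
#' @param gm a complete [genotype_matrix()]; all markers polymorphic.
#' @param map the paired [marker_map()].
#' @param threshold r-squared threshold in `(0, 1]`.
#' @param tolerance number of consecutive sub-threshold markers that may be
#'   bridged (default 1).
#' @return a [block_partition()].
#' @export
blocks_ld_threshold <- function(gm, map, threshold, tolerance = 1L) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (tolerance < 0) stop("tolerance must be >= 0")
  d <- gm$dosages
  if (anyNA(d)) stop("complete (imputed) genotypes required")
  per <- lapply(chrom_index(map), function(ii) {
    M <- length(ii)
    if (M == 1) return(matrix(c(ii, ii + 1L), 1, 2))
    r2 <- function(i, j) compute_r2(gm, ii[i], ii[j])
    adj <- vapply(seq_len(M - 1), function(i) r2(i, i + 1), numeric(1))
    assigned <- rep(FALSE, M)
    runs <- list()
    repeat {
      cand <- which(!assigned[-M] & !assigned[-1] & adj >= threshold)
      if (!length(cand)) break
      s <- cand[which.max(adj[cand])]     # which.max takes first on ties
      block <- c(s, s + 1L)
      assigned[block] <- TRUE
      extend <- function(border, step) {
        repeat {
          c0 <- border + step
          absorbed <- integer(0)
          found <- FALSE
          skipped <- 0L
          while (c0 >= 1 && c0 <= M && !assigned[c0]) {
            if (r2(border, c0) >= threshold) { found <- TRUE; break }
            skipped <- skipped + 1L
            if (skipped > tolerance) break
            absorbed <- c(absorbed, c0)
            c0 <- c0 + step
          }
          if (!found) break
          block <<- c(block, absorbed, c0)
          assigned[c(absorbed, c0)] <<- TRUE
          border <- c0
        }
      }
      extend(s + 1L, +1L)
      extend(s, -1L)
      runs[[length(runs) + 1L]] <- range(block)
    }
    runs <- .add_singletons(runs, seq_len(M))
    m <- .runs_to_matrix(runs)
    cbind(ii[m[, 1]], ii[m[, 2] - 1L] + 1L)
  })
  .partition_from_chrom_blocks(per, map, "ld_threshold",
                               list(threshold = threshold, tolerance = tolerance))
}

#' Fixed windows of adjacent markers
#'
#' Per chromosome, consecutive windows of `m` markers starting at the first
#' marker; the final window may be shorter. `m` at or above a chromosome's
#' marker count makes the whole chromosome one block.
#'
#' @param map a [marker_map()].
#' @param m window size in markers (>= 1).
#' @return a [block_partition()].
#' @export
blocks_fixed_markers <- function(map, m) {
  if (m < 1) stop("m must be >= 1")
  per <- lapply(chrom_index(map), function(ii) {
    starts <- seq(1L, length(ii), by = m)
    ends <- pmin(starts + m - 1L, length(ii))
    cbind(ii[starts], ii[ends] + 1L)
  })
  .partition_from_chrom_blocks(per, map, "fixed_markers", list(m = m))
}

#' Fixed windows of adjacent base pairs
#'
#' Per chromosome, bins `[1, w], (w, 2w], ...` anchored at position 1; markers
#' are grouped by bin, empty bins produce no block.
#'
#' @param map a [marker_map()].
#' @param window_bp window size in base pairs (>= 1).
#' @return a [block_partition()].
#' @export
blocks_fixed_bp <- function(map, window_bp) {
  if (window_bp < 1) stop("window_bp must be >= 1")
  per <- lapply(chrom_index(map), function(ii) {
    bin <- (map$pos[ii] - 1L) %/% window_bp
    runs <- lapply(split(seq_along(ii), bin), range)
    m <- .runs_to_matrix(runs)
    cbind(ii[m[, 1]], ii[m[, 2] - 1L] + 1L)
  })
  .partition_from_chrom_blocks(per, map, "fixed_bp", list(window_bp = window_bp))
}

#' D-prime confidence-interval (Gabriel) blocks
#'
#' A marker pair is in "strong LD" when the bootstrap upper confidence bound
#' on D-prime exceeds `ci_upper_min` and the lower bound exceeds
#' `ci_lower_min`. Blocks grow greedily left-to-right: a candidate marker
#' joins the open block iff the pair (block's first marker, candidate) is in
#' strong LD; markers that never pair become singletons.
#'
#' @inheritParams blocks_ld_threshold
#' @param ci_upper_min strong-LD threshold on the upper bound (default 0.98).
#' @param ci_lower_min strong-LD threshold on the lower bound (default 0.70).
#' @param conf bootstrap confidence level (default 0.95).
#' @param n_boot bootstrap replicates per pair.
#' @param seed integer master seed; per-pair seeds are derived so results do
#'   not depend on evaluation order.
#' @return a [block_partition()].
#' @export
blocks_gabriel <- function(gm, map, ci_upper_min = 0.98, ci_lower_min = 0.70,
                           conf = 0.95, n_boot = 200, seed) {
  if (ci_upper_min <= 0 || ci_upper_min > 1 || ci_lower_min < 0 || ci_lower_min > 1)
    stop("confidence-bound thresholds must be in [0, 1]")
  strong <- function(i, j) {
    ci <- dprime_ci(gm, i, j, conf = conf, n_boot = n_boot,
                    seed = derive_seed(seed, i, j))
    ci[2] > ci_upper_min && ci[1] > ci_lower_min
  }
  per <- lapply(chrom_index(map), function(ii) {
    M <- length(ii)
    runs <- list()
    i <- 1L
    while (i <= M) {
      j <- i
      while (j < M && strong(ii[i], ii[j + 1L])) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    }
    m <- .runs_to_matrix(runs)
    cbind(ii[m[, 1]], ii[m[, 2] - 1L] + 1L)
  })
  .partition_from_chrom_blocks(per, map, "gabriel",
                               list(ci_upper_min = ci_upper_min,
                                    ci_lower_min = ci_lower_min,
                                    conf = conf, n_boot = n_boot, seed = seed))
}

#' Four-gamete-rule blocks
#'
#' Scans left to right; a candidate marker joins the open block iff the
#' four-gamete test finds no recombination evidence against every marker
#' already in the block; otherwise a block border is created and a new block
#' starts at the candidate.
#'
#' @inheritParams blocks_ld_threshold
#' @param freq_min minimum gamete frequency counting as evidence (default 0.01).
#' @return a [block_partition()].
#' @export
blocks_four_gamete <- function(gm, map, freq_min = 0.01) {
  per <- lapply(chrom_index(map), function(ii) {
    M <- length(ii)
    g <- gametes(gm, ii)
    runs <- list()
    cur <- 1L
    for (j in seq_len(M)[-1]) {
      evid <- any(vapply(cur:(j - 1L), function(k)
        four_gamete_evidence(counts_from_gametes(g[, k], g[, j]), freq_min),
        logical(1)))
      if (evid) {
        runs[[length(runs) + 1L]] <- c(cur, j - 1L)
        cur <- j
      }
    }
    runs[[length(runs) + 1L]] <- c(cur, M)
    m <- .runs_to_matrix(runs)
    cbind(ii[m[, 1]], ii[m[, 2] - 1L] + 1L)
  })
  .partition_from_chrom_blocks(per, map, "four_gamete", list(freq_min = freq_min))
}

#' Solid-spine-of-LD blocks
#'
#' From each anchor marker i the largest j > i with pairwise D-prime above
#' `dprime_min` is sought; if found, markers i..j form a block (intermediate
#' markers need not be in LD) and scanning resumes after the block, otherwise
#' the anchor is a singleton.
#'
#' @inheritParams blocks_ld_threshold
#' @param dprime_min D-prime threshold (strict; default 0.8).
#' @return a [block_partition()].
#' @export
blocks_solid_spine <- function(gm, map, dprime_min = 0.8) {
  per <- lapply(chrom_index(map), function(ii) {
    M <- length(ii)
    g <- gametes(gm, ii)
    runs <- list()
    i <- 1L
    while (i <= M) {
      j_found <- 0L
      if (i < M) for (j in M:(i + 1L)) {
        if (dprime_from_gametes(g[, i], g[, j]) > dprime_min) { j_found <- j; break }
      }
      if (j_found) {
        runs[[length(runs) + 1L]] <- c(i, j_found)
        i <- j_found + 1L
      } else {
        runs[[length(runs) + 1L]] <- c(i, i)
        i <- i + 1L
      }
    }
    m <- .runs_to_matrix(runs)
    cbind(ii[m[, 1]], ii[m[, 2] - 1L] + 1L)
  })
  .partition_from_chrom_blocks(per, map, "solid_spine", list(dprime_min = dprime_min))
}

#' LD-threshold parameter grid
#'
#' The 100 thresholds 0.01, 0.02, ..., 1.00.
#' @return numeric vector of length 100.
#' @export
ld_threshold_grid <- function() (1:100) / 100

#' Window-size parameter grid
#'
#' `ceiling(2^x)` with x = 1, 1.5, 2, ... for marker windows and
#' x = 10, 10.5, 11, ... for base-pair windows, deduplicated ascending and
#' truncated after the first value at or above `max_extent` so that the
#' whole-chromosome scenario stays representable.
#'
#' @param kind `"markers"` or `"bp"`.
#' @param max_extent chromosome extent (max marker count or bp length).
#' @return integer vector of window sizes.
#' @export
window_size_grid <- function(kind = c("markers", "bp"), max_extent) {
  kind <- match.arg(kind)
  x0 <- if (kind == "markers") 1 else 10
  if (max_extent < ceiling(2^x0)) stop("max_extent below the first grid value")
  out <- c()
  x <- x0
  repeat {
    v <- ceiling(2^x)
    out <- c(out, v)
    if (v >= max_extent) break
    x <- x + 0.5
  }
  unique(out)
}

#' Import an externally computed block partition
#'
#' Reads BED-like intervals (`chrom`, `start_bp` 0-based, `end_bp` exclusive,
#' tab-delimited, header optional) such as those produced by subgroup-aware
#' block software, maps them to marker index ranges, and turns uncovered
#' markers into singletons. Overlapping intervals or unknown chromosomes are
#' errors.
#'
#' @param path interval file path.
#' @param map a [marker_map()].
#' @return a [block_partition()] with method `"imported"`.
#' @export
import_partition <- function(path, map) {
  if (!file.exists(path)) stop("file not found: ", path)
  iv <- data.table::fread(path, data.table = FALSE, header = "auto")
  if (ncol(iv) < 3) stop("interval file needs columns chrom, start_bp, end_bp")
  colnames(iv)[1:3] <- c("chrom", "start_bp", "end_bp")
  iv$chrom <- as.character(iv$chrom)
  unknown <- setdiff(iv$chrom, unique(map$chrom))
  if (length(unknown)) stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  runs <- list()
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start_bp), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start_bp[-1] < sub$end_bp[-nrow(sub)]))
      stop("overlapping intervals on chromosome ", ch)
    ii <- which(map$chrom == ch)
    for (r in seq_len(nrow(sub))) {
      hit <- ii[map$pos[ii] > sub$start_bp[r] & map$pos[ii] <= sub$end_bp[r]]
      if (length(hit))
        runs[[length(runs) + 1L]] <- data.frame(chrom = ch, start = min(hit),
                                                end = max(hit) + 1L)
    }
  }
  covered <- unlist(lapply(runs, function(r) r$start:(r$end - 1L)))
  if (anyDuplicated(covered)) stop("overlapping intervals cover a marker twice")
  single <- setdiff(seq_len(nrow(map)), covered)
  rows <- rbind(do.call(rbind, runs),
                if (length(single)) data.frame(chrom = map$chrom[single],
                                               start = single, end = single + 1L))
  block_partition(rows, map, "imported", list(path = path))
}

#' Export a partition as BED-like intervals
#'
#' Columns: chromosome, 0-based start (first marker position - 1), end (last
#' marker position), block id, marker count, method.
#'
#' @param partition a [block_partition()].
#' @param map the paired [marker_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(partition, map, path) {
  b <- partition$blocks
  out <- data.frame(chrom = b$chrom,
                    start_bp = map$pos[b$start] - 1L,
                    end_bp = map$pos[b$end - 1L],
                    block_id = sprintf("blk%04d", seq_len(nrow(b))),
                    n_markers = b$end - b$start,
                    method = partition$method)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
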