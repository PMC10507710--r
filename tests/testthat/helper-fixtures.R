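# Fixture generators and independent brute-force oracles. The oracles
# re-implement each acceptance rule literally with plain loops and their own
# LD arithmetic; they share nothing with the package code paths they check
# (except, for the Gabriel builder, the bootstrap CI primitive itself, whose
# replicates are verified separately against stored-replicate quantiles).

# ---- tiny deterministic panels -------------------------------------------

# homozygous panel from a 0/1 haplotype matrix (rows = lines)
panel_from_haps <- function(h, chrom = rep("chr1", ncol(h)), pos = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(h)) * 100L
  gm <- genotype_matrix(2 * h, paste0("L", seq_len(nrow(h))), "homozygous")
  map <- marker_map(paste0("m", seq_len(ncol(h))), chrom, pos)
  list(gm = gm, map = map)
}

# random small panel with block-ish LD; all columns polymorphic
random_panel <- function(n_markers = 10, n_lines = 15, seed = 1, n_chrom = 1) {
  set.seed(seed)
  repeat {
    pool_n <- sample(2:4, 1)
    pool <- matrix(rbinom(pool_n * n_markers, 1, 0.5), pool_n, n_markers)
    rows <- pool[sample.int(pool_n, n_lines, replace = TRUE), , drop = FALSE]
    mut <- matrix(rbinom(n_lines * n_markers, 1, 0.08), n_lines) == 1
    rows[mut] <- 1 - rows[mut]
    if (all(apply(rows, 2, function(cc) length(unique(cc)) > 1))) break
  }
  per <- table(sort(rep_len(paste0("chr", seq_len(n_chrom)), n_markers)))
  chrom <- rep(names(per), per)
  pos <- unlist(lapply(per, function(m) sort(sample.int(1e6, m))))
  panel_from_haps(rows, chrom = chrom, pos = pos)
}

# ---- independent LD arithmetic -------------------------------------------

o_pearson_r2 <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  (num / sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
}

o_gametes <- function(gm) {
  if (gm$ploidy == "homozygous") gm$dosages / 2
  else rbind(gm$phase1, gm$phase2)
}

o_counts <- function(a, b) {
  n <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (g in seq_along(a)) {
    key <- paste0(if (a[g] == 1) "A" else "a", if (b[g] == 1) "B" else "b")
    n[key] <- n[key] + 1
  }
  n
}

o_dprime <- function(a, b) {
  n <- o_counts(a, b); nt <- sum(n)
  pAB <- n["AB"] / nt
  pA <- (n["AB"] + n["Ab"]) / nt; pB <- (n["AB"] + n["aB"]) / nt
  D <- pAB - pA * pB
  if (D == 0) return(0)
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  unname(abs(D) / Dmax)
}

o_recomb_evidence <- function(a, b, fmin = 0.01) {
  n <- o_counts(a, b)
  min(n) / sum(n) >= fmin
}

# ---- literal block-rule oracles (per chromosome, local indices) ----------

# inclusive (start, end) rows -> sorted matrix
o_runs <- function(runs, M) {
  left <- setdiff(seq_len(M), unlist(lapply(runs, function(r) r[1]:r[2])))
  runs <- c(runs, lapply(left, function(i) c(i, i)))
  m <- do.call(rbind, runs)
  m[order(m[, 1]), , drop = FALSE]
}

oracle_ld_blocks <- function(d, thr, tol) {
  M <- ncol(d)
  r2m <- matrix(NA_real_, M, M)
  for (i in 1:(M - 1)) for (j in (i + 1):M)
    r2m[i, j] <- r2m[j, i] <- o_pearson_r2(d[, i], d[, j])
  assigned <- rep(FALSE, M)
  runs <- list()
  repeat {
    best <- -1; bi <- 0
    for (i in seq_len(M - 1))
      if (!assigned[i] && !assigned[i + 1] && r2m[i, i + 1] >= thr &&
          r2m[i, i + 1] > best) { best <- r2m[i, i + 1]; bi <- i }
    if (bi == 0) break
    blk <- c(bi, bi + 1); assigned[blk] <- TRUE
    for (step in c(1L, -1L)) {
      border <- if (step == 1L) bi + 1L else bi
      repeat {
        j <- border + step; skip <- 0; absorbed <- c(); found <- FALSE
        while (j >= 1 && j <= M && !assigned[j]) {
          if (r2m[border, j] >= thr) { found <- TRUE; break }
          skip <- skip + 1
          if (skip > tol) break
          absorbed <- c(absorbed, j); j <- j + step
        }
        if (!found) break
        blk <- c(blk, absorbed, j)
        assigned[c(absorbed, j)] <- TRUE
        border <- j
      }
    }
    runs[[length(runs) + 1]] <- range(blk)
  }
  o_runs(runs, M)
}

oracle_fixed_markers <- function(M, m) {
  starts <- seq(1, M, by = m)
  cbind(starts, pmin(starts + m - 1, M))
}

oracle_fixed_bp <- function(pos, w) {
  bins <- (pos - 1) %/% w
  runs <- lapply(unique(bins), function(b) range(which(bins == b)))
  o_runs(runs, length(pos))
}

oracle_gabriel <- function(gm, global_idx, upper_min, lower_min, seed,
                           n_boot = 200) {
  M <- length(global_idx)
  strong <- matrix(FALSE, M, M)
  for (i in seq_len(M - 1)) for (j in (i + 1):M) {
    ci <- dprime_ci(gm, global_idx[i], global_idx[j], n_boot = n_boot,
                    seed = hapblockr:::derive_seed(seed, global_idx[i], global_idx[j]))
    strong[i, j] <- strong[j, i] <- ci[2] > upper_min && ci[1] > lower_min
  }
  runs <- list(); i <- 1
  while (i <= M) {
    j <- i
    while (j < M && strong[i, j + 1]) j <- j + 1
    runs[[length(runs) + 1]] <- c(i, j)
    i <- j + 1
  }
  o_runs(runs, M)
}

oracle_four_gamete <- function(g, fmin = 0.01) {
  M <- ncol(g)
  runs <- list(); cur <- 1
  if (M > 1) for (j in 2:M) {
    evid <- FALSE
    for (k in cur:(j - 1))
      if (o_recomb_evidence(g[, k], g[, j], fmin)) { evid <- TRUE; break }
    if (evid) { runs[[length(runs) + 1]] <- c(cur, j - 1); cur <- j }
  }
  runs[[length(runs) + 1]] <- c(cur, M)
  o_runs(runs, M)
}

oracle_solid_spine <- function(g, dmin = 0.8) {
  M <- ncol(g)
  runs <- list(); i <- 1
  while (i <= M) {
    jf <- 0
    if (i < M) for (j in M:(i + 1))
      if (o_dprime(g[, i], g[, j]) > dmin) { jf <- j; break }
    if (jf) { runs[[length(runs) + 1]] <- c(i, jf); i <- jf + 1 }
    else { runs[[length(runs) + 1]] <- c(i, i); i <- i + 1 }
  }
  o_runs(runs, M)
}

# ---- partition helpers ----------------------------------------------------

# package partition -> per-chromosome inclusive local (start, end) matrix
part_local <- function(partition, map, chrom) {
  b <- partition$blocks[partition$blocks$chrom == chrom, , drop = FALSE]
  off <- min(which(map$chrom == chrom)) - 1L
  m <- cbind(b$start - off, b$end - 1L - off)
  m[order(m[, 1]), , drop = FALSE]
}

expect_valid_partition <- function(partition, map) {
  b <- partition$blocks
  cov <- unlist(mapply(seq, b$start, b$end - 1L, SIMPLIFY = FALSE))
  expect_setequal(cov, seq_len(nrow(map)))
  expect_false(any(duplicated(cov)))
  for (r in seq_len(nrow(b)))
    expect_length(unique(map$chrom[b$start[r]:(b$end[r] - 1L)]), 1)
}

# direct scalar-loop VanRaden oracle from raw haplotype-count columns
oracle_grm <- function(raw_counts, freqs) {
  Z <- sweep(raw_counts, 2, 2 * freqs)
  n <- nrow(Z)
  G <- matrix(0, n, n)
  den <- 2 * sum(freqs * (1 - freqs))
  for (i in 1:n) for (j in 1:n) G[i, j] <- sum(Z[i, ] * Z[j, ]) / den
  G
}

# small simulated dataset wrapper used by several suites
quick_sim <- function(seed, n = 120, m_per = 40, n_chrom = 2, h2 = 0.5,
                      material = "inbred", qtl = 15, epi = 0, ...) {
  cfg <- sim_config(n_samples = n, n_chromosomes = n_chrom,
                    markers_per_chromosome = m_per, h2_target = h2,
                    material = material, n_qtl = qtl, epistatic_pairs = epi,
                    seed = seed, ...)
  pop <- simulate_population(cfg)
  ph <- simulate_phenotypes(pop$gm, pop$map, cfg)
  list(cfg = cfg, gm = pop$gm, map = pop$map, fam = pop$family_labels,
       y = ph$pheno$trait, truth = ph$truth,
       X = matrix(1, n, 1, dimnames = list(pop$gm$sample_ids, "intercept")))
}
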