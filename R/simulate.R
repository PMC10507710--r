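# Forward-in-time founder-recombination simulator. Founders are fully
# homozygous lines with independent allele frequencies ~ U(0.1, 0.9);
# descendants are produced by meioses with Poisson(crossover_rate) crossovers
# at uniform positions, which yields the block-like LD structure of real
# breeding panels while keeping family structure under direct control.

#' Simulation configuration
#'
#' @param n_founders number of founder lines.
#' @param n_samples number of emitted samples.
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_bp map shape.
#' @param crossover_rate expected crossovers per chromosome per meiosis.
#' @param n_generations generations of random mating before fixation.
#' @param material `"inbred"` (DH panel), `"dh_nam"` (half-sib DH families
#'   sharing a common parent) or `"hybrid"` (DH pollinators crossed in silico
#'   to tester lines, phased F1s).
#' @param n_families number of NAM families (dh_nam only).
#' @param n_testers number of tester lines (hybrid only).
#' @param n_qtl number of additive QTL.
#' @param epistatic_pairs number of local epistatic QTL pairs.
#' @param epistasis_window_bp maximum bp separation of an epistatic pair.
#' @param h2_target narrow-ish sense heritability of the emitted phenotype.
#' @param seed master seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 10, n_samples = 200, n_chromosomes = 3,
                       markers_per_chromosome = 60, chromosome_length_bp = 5e7,
                       crossover_rate = 1.5, n_generations = 3,
                       material = c("inbred", "dh_nam", "hybrid"),
                       n_families = 10, n_testers = 2, n_qtl = 20,
                       epistatic_pairs = 5, epistasis_window_bp = 5e6,
                       h2_target = 0.5, seed = 1) {
  material <- match.arg(material)
  cfg <- list(n_founders = n_founders, n_samples = n_samples,
              n_chromosomes = n_chromosomes,
              markers_per_chromosome = markers_per_chromosome,
              chromosome_length_bp = chromosome_length_bp,
              crossover_rate = crossover_rate, n_generations = n_generations,
              material = material, n_families = n_families,
              n_testers = n_testers, n_qtl = n_qtl,
              epistatic_pairs = epistatic_pairs,
              epistasis_window_bp = epistasis_window_bp,
              h2_target = h2_target, seed = seed)
  counts <- cfg[c("n_founders", "n_samples", "n_chromosomes",
                  "markers_per_chromosome", "chromosome_length_bp",
                  "n_generations")]
  if (any(unlist(counts) < 1)) stop("all counts must be positive")
  if (crossover_rate < 0) stop("crossover_rate must be >= 0")
  if (h2_target < 0 || h2_target > 1) stop("h2_target must be in [0, 1]")
  if (epistasis_window_bp > chromosome_length_bp)
    stop("epistasis_window_bp exceeds chromosome length")
  if (material == "dh_nam" && n_families > n_founders - 1)
    stop("dh_nam needs n_families <= n_founders - 1 (one common parent)")
  class(cfg) <- "sim_config"
  cfg
}

# one meiosis of a chromosome: haplotypes h1/h2 (0/1 vectors), marker
# positions pos in [1, L]; Poisson(rate) crossovers at uniform bp positions
meiosis_chrom <- function(h1, h2, pos, L, rate) {
  k <- rpois(1, rate)
  start <- sample.int(2, 1)
  if (k == 0) return(if (start == 1) h1 else h2)
  breaks <- sort(runif(k, 1, L))
  seg <- findInterval(pos, breaks)
  from1 <- (seg + start) %% 2 == 1
  ifelse(from1, h1, h2)
}

# apply meiosis per chromosome over the whole genome
meiosis_genome <- function(h1, h2, chrom_idx, pos, L, rate) {
  out <- numeric(length(pos))
  for (ii in chrom_idx)
    out[ii] <- meiosis_chrom(h1[ii], h2[ii], pos[ii], L, rate)
  out
}

#' Simulate a structured genotype panel
#'
#' Founders carry independent alleles at frequencies ~ U(0.1, 0.9);
#' descendants are recombinant mosaics of founder haplotypes, so LD decays
#' with physical distance. Inbred/DH material is fully homozygous; `dh_nam`
#' produces half-sib DH families from a common parent; `hybrid` crosses a DH
#' panel to tester lines in silico (phased F1s). Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return list with `gm` ([genotype_matrix()]), `map` ([marker_map()]) and
#'   `family_labels` (character or NULL).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    m <- cfg$markers_per_chromosome
    L <- cfg$chromosome_length_bp
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    pos <- unlist(lapply(chroms, function(ch) sort(sample.int(L, m))))
    chrom <- rep(chroms, each = m)
    map <- marker_map(paste0("m", seq_along(pos)), chrom, pos)
    # map is sorted by (chrom, pos); rebuild pos/chrom in map order
    pos <- map$pos; chrom <- map$chrom
    M <- nrow(map)
    cidx <- chrom_index(map)
    freq <- runif(M, 0.1, 0.9)
    founders <- matrix(rbinom(cfg$n_founders * M, 1, rep(freq, each = cfg$n_founders)),
                       nrow = cfg$n_founders)
    rate <- cfg$crossover_rate
    mk_gamete <- function(ind) meiosis_genome(ind[[1]], ind[[2]], cidx, pos, L, rate)

    if (cfg$material %in% c("inbred", "hybrid")) {
      n_lines <- if (cfg$material == "inbred") cfg$n_samples
                 else cfg$n_samples + cfg$n_testers
      # gen 1: F1s of random founder pairs
      pop <- lapply(seq_len(n_lines), function(i) {
        pr <- sample.int(cfg$n_founders, 2, replace = FALSE)
        list(founders[pr[1], ], founders[pr[2], ])
      })
      if (cfg$n_generations > 1) for (g in seq_len(cfg$n_generations - 1)) {
        pop <- lapply(seq_len(n_lines), function(i) {
          pq <- sample.int(n_lines, 2, replace = TRUE)
          list(mk_gamete(pop[[pq[1]]]), mk_gamete(pop[[pq[2]]]))
        })
      }
      haps <- t(vapply(pop, mk_gamete, numeric(M)))       # DH fixation
      dos <- 2 * haps
      if (cfg$material == "inbred") {
        gm <- genotype_matrix(dos, paste0("L", seq_len(n_lines)), "homozygous")
        fam <- NULL
      } else {
        ids <- c(paste0("P", seq_len(cfg$n_samples)),
                 paste0("T", seq_len(cfg$n_testers)))
        lines <- genotype_matrix(dos, ids, "homozygous")
        poll <- sub_samples(lines, seq_len(cfg$n_samples))
        test <- sub_samples(lines, cfg$n_samples + seq_len(cfg$n_testers))
        tester_of <- rep(seq_len(cfg$n_testers), length.out = cfg$n_samples)
        gm <- in_silico_cross(poll, test,
                              data.frame(mother = seq_len(cfg$n_samples),
                                         father = tester_of))
        fam <- paste0("T", tester_of)
      }
    } else {                                              # dh_nam
      per_fam <- ceiling(cfg$n_samples / cfg$n_families)
      common <- founders[1, ]
      haps <- matrix(0, cfg$n_samples, M)
      fam <- character(cfg$n_samples)
      s <- 0L
      for (f in seq_len(cfg$n_families)) {
        other <- founders[1 + f, ]
        take <- min(per_fam, cfg$n_samples - s)
        if (take <= 0) break
        for (i in seq_len(take)) {
          s <- s + 1L
          # F1 meiosis (+ extra generations of selfed recombination)
          gam <- meiosis_genome(common, other, cidx, pos, L, rate)
          if (cfg$n_generations > 1) for (g in seq_len(cfg$n_generations - 1))
            gam <- meiosis_genome(gam,
                                  meiosis_genome(common, other, cidx, pos, L, rate),
                                  cidx, pos, L, rate)
          haps[s, ] <- gam
          fam[s] <- paste0("F", f)
        }
      }
      gm <- genotype_matrix(2 * haps, paste0("D", seq_len(cfg$n_samples)),
                            "homozygous")
    }
    list(gm = gm, map = map, family_labels = fam)
  })
}

#' Simulate phenotypes with additive QTL and local epistasis
#'
#' Picks `n_qtl` polymorphic markers with standard-normal additive effects on
#' standardized dosages, plus `epistatic_pairs` marker pairs within
#' `epistasis_window_bp` on the same chromosome whose centered dosage
#' products carry effects scaled to a 4:1 additive:epistatic variance ratio.
#' The residual is orthogonalized against the genetic values and rescaled so
#' the realized heritability on the emitted sample equals `h2_target`
#' exactly; `h2_target = 0` emits pure noise (truth retained),
#' `h2_target = 1` emits the genetic values themselves.
#'
#' @param gm complete [genotype_matrix()].
#' @param map paired [marker_map()].
#' @param config a [sim_config()] (fields `n_qtl`, `epistatic_pairs`,
#'   `epistasis_window_bp`, `h2_target`, `seed` are used).
#' @return list with `pheno` ([phenotype_table()]) and `truth` (QTL indices,
#'   effects, genetic values, realized h2).
#' @export
simulate_phenotypes <- function(gm, map, config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  d <- gm$dosages
  if (anyNA(d)) stop("complete genotypes required")
  with_seed(derive_seed(cfg$seed, "pheno"), {
    p <- colMeans(d) / 2
    poly <- which(p > 0 & p < 1)
    if (length(poly) < cfg$n_qtl) stop("fewer polymorphic markers than n_qtl")
    qtl <- sort(sample(poly, cfg$n_qtl))
    a <- rnorm(cfg$n_qtl)
    Xs <- scale(d[, qtl, drop = FALSE])
    g_add <- as.numeric(Xs %*% a)
    epi <- NULL; w <- numeric(0); g_epi <- 0
    if (cfg$epistatic_pairs > 0) {
      epi <- matrix(0L, cfg$epistatic_pairs, 2)
      P <- matrix(0, nrow(d), cfg$epistatic_pairs)
      for (k in seq_len(cfg$epistatic_pairs)) {
        for (try in 1:100) {
          i <- sample(poly, 1)
          js <- poly[map$chrom[poly] == map$chrom[i] &
                     abs(map$pos[poly] - map$pos[i]) <= cfg$epistasis_window_bp &
                     poly != i]
          if (length(js)) { j <- if (length(js) == 1) js else sample(js, 1); break }
        }
        if (!length(js)) stop("no epistatic partner found within the window")
        epi[k, ] <- c(i, j)
        pr <- scale(d[, i]) * scale(d[, j])
        P[, k] <- pr - mean(pr)
      }
      w <- rnorm(cfg$epistatic_pairs)
      g_epi <- as.numeric(P %*% w)
      if (sd(g_epi) > 0 && sd(g_add) > 0)
        g_epi <- g_epi * (sd(g_add) / 2) / sd(g_epi)   # 4:1 variance ratio
    }
    g <- g_add + g_epi
    vg <- var(g)
    h2 <- cfg$h2_target
    if (h2 >= 1) {
      y <- g
    } else if (h2 <= 0) {
      y <- rnorm(length(g), 0, sqrt(max(vg, 1)))
    } else {
      e <- rnorm(length(g))
      e <- e - g * (cov(e, g) / vg)          # orthogonalize against g
      e <- e * sqrt(vg * (1 - h2) / h2) / sd(e)
      y <- g + e
    }
    realized <- if (h2 <= 0) 0 else vg / var(y)
    list(pheno = phenotype_table(gm$sample_ids, y),
         truth = list(qtl = qtl, additive_effects = a,
                      epistatic_pairs = epi, epistatic_effects = w,
                      genetic_values = g, realized_h2 = realized))
  })
}
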