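# the six partitioning algorithms vs literal rule oracles, plus the grids
# and the partition-import hook

test_that("ld_threshold_grid and window_size_grid match the stated grids", {
  g <- ld_threshold_grid()
  expect_length(g, 100)
  expect_equal(g[1], 0.01)
  expect_equal(g[100], 1.00)
  expect_true(all(diff(g) > 0))

  wm <- window_size_grid("markers", max_extent = 40)
  expect_equal(head(wm, 7), c(2, 3, 4, 6, 8, 12, 16))   # ceil(2^{1,1.5,...})
  expect_gte(tail(wm, 1), 40)                            # whole chromosome reachable
  wb <- window_size_grid("bp", max_extent = 5000)
  expect_equal(head(wb, 3), c(1024, 1449, 2048))         # ceil(2^{10,10.5,11})
  expect_equal(window_size_grid("markers", max_extent = 2), 2)
})

test_that("blocks_ld_threshold: trivial limits and parameter validation", {
  dup <- panel_from_haps(cbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 0, 1, 1)))
  p <- blocks_ld_threshold(dup$gm, dup$map, threshold = 1.0)
  expect_equal(nrow(p$blocks), 1)
  expect_equal(block_sizes(p), 3)

  ind <- panel_from_haps(cbind(c(0, 0, 1, 1), c(0, 1, 0, 1), c(0, 1, 1, 0)))
  p2 <- blocks_ld_threshold(ind$gm, ind$map, threshold = 0.5)
  expect_equal(block_sizes(p2), c(1, 1, 1))
  expect_error(blocks_ld_threshold(ind$gm, ind$map, threshold = 0), "threshold")
})

test_that("ld tolerance bridges a single outlier marker", {
  # high-LD run with one shuffled marker in the middle
  set.seed(42)
  base <- rep(c(0, 1), each = 6)
  h <- replicate(12, base)                      # 12 identical markers
  h[, 6] <- sample(base)                        # outlier inside the run
  while (o_pearson_r2(h[, 5], h[, 6]) > 0.2 ||
         o_pearson_r2(h[, 6], h[, 7]) > 0.2) h[, 6] <- sample(base)
  pan <- panel_from_haps(h)
  with_tol <- blocks_ld_threshold(pan$gm, pan$map, threshold = 0.9, tolerance = 1)
  expect_equal(nrow(with_tol$blocks), 1)        # outlier absorbed
  no_tol <- blocks_ld_threshold(pan$gm, pan$map, threshold = 0.9, tolerance = 0)
  expect_equal(nrow(no_tol$blocks), 3)          # run split around the outlier
  expect_equal(sort(block_sizes(no_tol)), c(1, 5, 6))
  # both match the literal extension oracle
  for (tol in 0:1)
    expect_equal(unname(part_local(
        blocks_ld_threshold(pan$gm, pan$map, 0.9, tol), pan$map, "chr1")),
      unname(oracle_ld_blocks(pan$gm$dosages, 0.9, tol)))
})

test_that("fixed windows of markers and base pairs bin exactly", {
  pan <- random_panel(n_markers = 10, n_lines = 8, seed = 5)
  p4 <- blocks_fixed_markers(pan$map, 4)
  expect_equal(block_sizes(p4), c(4, 4, 2))
  expect_equal(block_sizes(blocks_fixed_markers(pan$map, 1)), rep(1, 10))
  expect_equal(block_sizes(blocks_fixed_markers(pan$map, 99)), 10)

  map <- marker_map(c("a", "b", "c"), "1", c(100, 900, 1100))
  gmp <- genotype_matrix(matrix(rep(c(0, 2), 3), 2, 3))
  pb <- blocks_fixed_bp(map, 1024)
  expect_equal(block_sizes(pb), c(2, 1))         # {100,900} then {1100}
  expect_equal(block_sizes(blocks_fixed_bp(map, 2000)), 3)
  expect_equal(block_sizes(blocks_fixed_bp(map, 1)), c(1, 1, 1))
})

test_that("gabriel blocks: degenerate cases and oracle equivalence", {
  per <- panel_from_haps(replicate(5, rep(c(0, 1), each = 6)))
  pg <- blocks_gabriel(per$gm, per$map, seed = 1)
  expect_equal(block_sizes(pg), 5)               # all CIs are (1,1)

  # balanced independent markers: no sustained strong LD
  set.seed(8)
  h <- replicate(6, sample(rep(0:1, each = 10)))
  ind2 <- panel_from_haps(h)
  pi <- blocks_gabriel(ind2$gm, ind2$map, seed = 2)
  expect_true(all(block_sizes(pi) <= 2))         # no sustained strong LD

  pan <- random_panel(n_markers = 10, n_lines = 20, seed = 31)
  p <- blocks_gabriel(pan$gm, pan$map, seed = 77)
  expect_equal(unname(part_local(p, pan$map, "chr1")),
               unname(oracle_gabriel(pan$gm, 1:10, 0.98, 0.70, seed = 77)))
  expect_error(blocks_gabriel(pan$gm, pan$map, ci_upper_min = 2, seed = 1),
               "threshold")
})

test_that("four-gamete blocks: degenerate cases and oracle equivalence", {
  two <- panel_from_haps(replicate(6, rep(c(0, 1), each = 4)))
  expect_equal(block_sizes(blocks_four_gamete(two$gm, two$map)), 6)

  # every adjacent pair shows all four gametes at 25%
  h <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1), c(0, 0, 1, 1), c(0, 1, 0, 1))
  allfour <- panel_from_haps(h)
  expect_equal(block_sizes(blocks_four_gamete(allfour$gm, allfour$map)),
               rep(1, 4))

  for (s in 1:3) {
    pan <- random_panel(n_markers = 12, n_lines = 16, seed = 500 + s)
    p <- blocks_four_gamete(pan$gm, pan$map)
    expect_equal(unname(part_local(p, pan$map, "chr1")),
                 unname(oracle_four_gamete(o_gametes(pan$gm))))
  }
})

test_that("solid spine: long-range spine bridges low-LD interior", {
  # markers 1 and 5 co-segregate; 2-4 independent of them
  set.seed(21)
  a <- rep(c(0, 1), each = 8)
  h <- cbind(a, sample(a), sample(a), sample(a), a)
  while (max(o_dprime(h[, 1], h[, 2]), o_dprime(h[, 1], h[, 3]),
             o_dprime(h[, 1], h[, 4])) > 0.8)
    h[, 2:4] <- cbind(sample(a), sample(a), sample(a))
  pan <- panel_from_haps(h)
  p <- blocks_solid_spine(pan$gm, pan$map)
  expect_equal(nrow(p$blocks), 1)
  expect_equal(block_sizes(p), 5)

  for (s in 1:3) {
    pan <- random_panel(n_markers = 12, n_lines = 16, seed = 600 + s)
    p <- blocks_solid_spine(pan$gm, pan$map)
    expect_equal(unname(part_local(p, pan$map, "chr1")),
                 unname(oracle_solid_spine(o_gametes(pan$gm))))
  }
})

test_that("every builder emits a disjoint exhaustive within-chromosome partition", {
  # randomized property sweep; gabriel is run on a subset (bootstrap cost)
  for (s in 1:100) {
    pan <- random_panel(n_markers = sample(4:12, 1), n_lines = sample(8:20, 1),
                        seed = 1000 + s, n_chrom = sample(1:2, 1))
    expect_valid_partition(blocks_ld_threshold(pan$gm, pan$map, 0.4), pan$map)
    expect_valid_partition(blocks_fixed_markers(pan$map, 3), pan$map)
    expect_valid_partition(blocks_fixed_bp(pan$map, 2.5e5), pan$map)
    expect_valid_partition(blocks_four_gamete(pan$gm, pan$map), pan$map)
    expect_valid_partition(blocks_solid_spine(pan$gm, pan$map), pan$map)
    if (s <= 15)
      expect_valid_partition(blocks_gabriel(pan$gm, pan$map, n_boot = 60,
                                            seed = s), pan$map)
  }
  # fixed-marker block count per chromosome = ceil(M_c / m)
  pan <- random_panel(n_markers = 11, n_lines = 8, seed = 4, n_chrom = 2)
  for (m in c(2, 3, 5)) {
    p <- blocks_fixed_markers(pan$map, m)
    cnt <- table(p$blocks$chrom)
    mc <- table(pan$map$chrom)
    expect_equal(as.numeric(cnt), as.numeric(ceiling(mc / m)))
  }
})

test_that("import_partition maps intervals, singles leftovers, rejects overlap", {
  pan <- random_panel(n_markers = 8, n_lines = 8, seed = 9)
  pos <- pan$map$pos
  dir <- withr::local_tempdir()
  f <- file.path(dir, "blocks.bed")
  # two intervals covering all 8 markers
  writeLines(c("chrom\tstart_bp\tend_bp",
               paste("chr1", pos[1] - 1, pos[4], sep = "\t"),
               paste("chr1", pos[4], pos[8], sep = "\t")), f)
  p <- import_partition(f, pan$map)
  expect_equal(nrow(p$blocks), 2)
  expect_equal(sum(block_sizes(p)), 8)

  # half coverage -> blocks + singletons summing to all markers
  writeLines(c("chrom\tstart_bp\tend_bp",
               paste("chr1", pos[1] - 1, pos[4], sep = "\t")), f)
  p2 <- import_partition(f, pan$map)
  expect_equal(sum(block_sizes(p2)), 8)
  expect_equal(sum(block_sizes(p2) == 1), 4)

  writeLines(c("chrom\tstart_bp\tend_bp",
               paste("chr1", pos[1] - 1, pos[5], sep = "\t"),
               paste("chr1", pos[3] - 1, pos[8], sep = "\t")), f)
  expect_error(import_partition(f, pan$map), "verlap")
  writeLines(c("chrom\tstart_bp\tend_bp", "chr9\t1\t100"), f)
  expect_error(import_partition(f, pan$map), "nknown chromosome")
})

test_that("block export writes BED-like half-open intervals", {
  pan <- random_panel(n_markers = 6, n_lines = 8, seed = 2)
  p <- blocks_fixed_markers(pan$map, 3)
  f <- file.path(withr::local_tempdir(), "out.bed")
  write_blocks(p, pan$map, f)
  bed <- read.delim(f)
  expect_equal(nrow(bed), 2)
  expect_equal(bed$start_bp, pan$map$pos[c(1, 4)] - 1)
  expect_equal(bed$end_bp, pan$map$pos[c(3, 6)])
  expect_equal(bed$n_markers, c(3, 3))
})
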