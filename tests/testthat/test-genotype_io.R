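# genotype containers, filtering, imputation, in-silico crossing, file I/O

test_that("genotype_matrix enforces its invariants", {
  expect_error(genotype_matrix(matrix(c(0, 3), 1, 2)), "0, 1 or 2")
  expect_error(genotype_matrix(matrix(c(0, 1), 1, 2), ploidy = "homozygous"),
               "heterozygote")
  expect_error(genotype_matrix(matrix(0, 2, 2), sample_ids = c("a", "a")),
               "unique")
  p1 <- matrix(c(0, 1), 1, 2); p2 <- matrix(c(1, 0), 1, 2)
  gm <- genotype_matrix(p1 + p2, "h1", "phased_diploid", phase1 = p1, phase2 = p2)
  expect_equal(gm$dosages[1, ], c(1, 1))
  expect_error(genotype_matrix(matrix(2, 1, 2), "h1", "phased_diploid",
                               phase1 = p1, phase2 = p2), "equal dosages")
})

test_that("marker_map rejects duplicate physical positions and sorts", {
  expect_error(marker_map(c("a", "b"), c("1", "1"), c(5, 5)), "unique physical")
  map <- marker_map(c("a", "b", "c"), c("2", "1", "1"), c(10, 50, 20))
  expect_equal(map$marker, c("c", "b", "a"))
  expect_equal(map$pos, c(20, 50, 10))
})

test_that("filter_markers applies inclusive MAF and missingness thresholds", {
  # 20 homozygous lines, one carrier: allele frequency exactly 0.05 -> kept
  d <- matrix(0, 20, 3)
  d[1, 1] <- 2                       # MAF 0.05 boundary
  d[1:2, 2] <- 2                     # MAF 0.10
  d[1:2, 3] <- NA; d[3, 3] <- 2      # 10% missing, kept; MAF on observed
  gm <- genotype_matrix(d)
  map <- marker_map(c("a", "b", "c"), "1", c(1, 2, 3))
  out <- filter_markers(gm, map, maf_min = 0.05, max_missing = 0.10)
  expect_equal(out$map$marker, c("a", "b", "c"))
  expect_equal(nrow(out$report), 0)

  # 2/10 missing (0.20 > 0.10) -> dropped for missingness
  d2 <- matrix(rep(c(0, 2), 5), 10, 2)
  d2[1:2, 2] <- NA
  gm2 <- genotype_matrix(d2)
  map2 <- marker_map(c("a", "b"), "1", c(1, 2))
  out2 <- filter_markers(gm2, map2)
  expect_equal(out2$report$marker, "b")
  expect_equal(out2$report$reason, "missingness")

  # identity thresholds keep everything; filtering is idempotent
  out3 <- filter_markers(gm2, map2, maf_min = 0, max_missing = 1)
  expect_equal(out3$gm$dosages, gm2$dosages)
  again <- filter_markers(out2$gm, out2$map)
  expect_equal(again$gm$dosages, out2$gm$dosages)
  expect_equal(nrow(again$report), 0)

  # everything dropped is an explicit error
  mono <- genotype_matrix(matrix(0, 10, 2))
  expect_error(filter_markers(mono, map2), "all markers removed")
})

test_that("impute_naive is seeded, complete and degenerate-safe", {
  d <- matrix(rep(c(0, 2), 10), 10, 2)
  d[3, 1] <- NA
  d[, 2] <- 0; d[5, 2] <- NA
  gm <- genotype_matrix(d)
  a <- impute_naive(gm, seed = 42)
  b <- impute_naive(gm, seed = 42)
  expect_false(anyNA(a$dosages))
  expect_identical(a$dosages, b$dosages)
  expect_equal(unname(a$dosages[5, 2]), 0)   # all-0 marker forces 0
  # no-missing input returns identical dosages
  full <- genotype_matrix(matrix(rep(c(0, 2), 4), 4, 2))
  expect_identical(impute_naive(full, 1)$dosages, full$dosages)
  # fully missing marker errors
  allna <- matrix(c(0, 2, NA, NA), 2, 2)
  expect_error(impute_naive(genotype_matrix(allna), 1), "fully missing")
})

test_that("in_silico_cross derives phased hybrids from homozygous parents", {
  mo <- genotype_matrix(matrix(c(0, 2, 2, 0, 0, 2, 2, 2), 2, 4),
                        c("A", "B"))
  fa <- genotype_matrix(matrix(c(2, 2, 0, 0, 2, 0, 2, 2), 2, 4),
                        c("S1", "S2"))
  hy <- in_silico_cross(mo, fa, data.frame(m = c("A", "B", "A"),
                                           f = c("S1", "S1", "S2")))
  expect_equal(n_samples(hy), 3)
  expect_equal(hy$ploidy, "phased_diploid")
  # mother 0 x father 2 -> 1; 2 x 2 -> 2
  expect_equal(unname(hy$dosages[1, 1]), 1)
  expect_equal(unname(hy$dosages[3, 1]), 1)   # A x S2 at marker 1
  expect_equal(unname(hy$dosages[1, 4]), 2)
  # phases equal parental gametes
  expect_equal(unname(hy$phase1[1, ]), unname(mo$dosages[1, ] / 2))
  expect_equal(unname(hy$phase2[1, ]), unname(fa$dosages[1, ] / 2))
  # selfing a parent reproduces it exactly
  self <- in_silico_cross(mo, mo, data.frame(m = "A", f = "A"))
  expect_equal(unname(self$dosages[1, ]), unname(mo$dosages[1, ]))
  # heterozygous parent is rejected by construction
  expect_error(genotype_matrix(matrix(1, 1, 1), "X"), "heterozygote")
})

test_that("matrix format round-trips dosages, ids and map", {
  pan <- random_panel(n_markers = 8, n_lines = 10, seed = 7, n_chrom = 2)
  pan$gm <- hapblockr:::.orient_minor(pan$gm)   # readers emit minor coding
  prefix <- file.path(withr::local_tempdir(), "panel")
  write_genotypes(pan$gm, pan$map, prefix)
  back <- read_genotypes(prefix, format = "matrix")
  expect_equal(unname(back$gm$dosages), unname(pan$gm$dosages))
  expect_equal(back$gm$sample_ids, pan$gm$sample_ids)
  expect_equal(as.data.frame(unclass(back$map)), as.data.frame(unclass(pan$map)))
})

test_that("VCF reading maps GT to dosages and skips non-biallelic sites", {
  skip_if_not_installed("VariantAnnotation")
  f <- file.path(withr::local_tempdir(), "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=chr1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("chr1", "100", "v1", "A", "T", ".", "PASS", ".", "GT", "0/0", "1/1"),
          collapse = "\t"),
    paste(c("chr1", "200", "v2", "G", "C", ".", "PASS", ".", "GT", "1/1", "1/1"),
          collapse = "\t"),
    paste(c("chr1", "250", "vtri", "G", "C,T", ".", "PASS", ".", "GT", "1/2", "0/0"),
          collapse = "\t"),
    paste(c("chr1", "300", "v3", "T", "A", ".", "PASS", ".", "GT", "0/0", "0/0"),
          collapse = "\t"),
    paste(c("chr1", "400", "v4", "T", "A", ".", "PASS", ".", "GT", "1/1", "0/0"),
          collapse = "\t")), f)
  expect_warning(out <- read_genotypes(f, format = "vcf"), "non-biallelic")
  expect_equal(n_markers(out$gm), 4)
  # minor-allele orientation: v2 (alt freq 1) flips to dosage 0
  expect_equal(unname(out$gm$dosages[, out$map$marker == "v1"]), c(0, 2))
  expect_equal(unname(out$gm$dosages[, out$map$marker == "v2"]), c(0, 0))
  # VCF -> write -> read round-trip on the package's own writer
  pan <- random_panel(n_markers = 6, n_lines = 8, seed = 3)
  pan$gm <- hapblockr:::.orient_minor(pan$gm)
  vf <- file.path(withr::local_tempdir(), "rt.vcf")
  write_vcf(pan$gm, pan$map, vf)
  back <- read_genotypes(vf, format = "vcf")
  expect_equal(unname(back$gm$dosages), unname(pan$gm$dosages))
})

test_that("phenotype CSV reading picks up traits, covariates and families", {
  f <- file.path(withr::local_tempdir(), "ph.csv")
  writeLines(c("sample,trait,nitro,family",
               "s1,1.5,0,F1", "s2,2.5,1,F1", "s3,3.5,1,F2"), f)
  ph <- read_phenotypes(f, covariates = "nitro")
  expect_equal(ph$trait, c(1.5, 2.5, 3.5))
  expect_equal(ph$family, c("F1", "F1", "F2"))
  X <- fixed_design(ph)
  expect_equal(colnames(X), c("intercept", "nitro"))
  expect_equal(unname(X[, 2]), c(0, 1, 1))
})
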