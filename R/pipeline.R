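# Config-driven pipeline: filter -> blocks -> haplotypes -> kernels -> model
# -> cross-validation -> report. Configs are JSON (list in R); all randomness
# flows from one master seed via named substreams.

.required_keys <- c("blocks", "model", "cv", "seed", "out_prefix")

# djb2-style rolling hash kept inside 31 bits (config fingerprinting only)
.fnv1a <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Validate a pipeline configuration
#'
#' Pre-flight schema check: `blocks` (list with `method`, optional `param`),
#' `model`, `cv` (list), `seed`, `out_prefix`, plus either `simulate` (a
#' [sim_config()] argument list) or `input` (paths). Errors list every
#' offending key; nothing is written on failure.
#'
#' @param config list or path to a JSON config.
#' @return the validated config (invisibly normalized).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  bad <- setdiff(.required_keys, names(config))
  if (!("simulate" %in% names(config)) && !("input" %in% names(config)))
    bad <- c(bad, "simulate|input")
  if (length(bad))
    stop("config is missing key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$blocks$method))
    stop("config is missing key(s): blocks$method")
  config
}

#' Run the full prediction pipeline
#'
#' Executes simulate/load -> filter -> impute -> blocks -> haplotypes ->
#' kernels -> model -> cross-validation and writes a results CSV plus the
#' resolved config (with toolkit version, config hash and master seed) next
#' to it.
#'
#' @param config list or JSON path; see [validate_config()].
#' @return list with `results` (the sweep/cv table) and `files` written.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  seed <- config$seed
  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config, c(config$simulate, list(seed = seed)))
    pop <- simulate_population(cfg)
    gm <- pop$gm; map <- pop$map; fam <- pop$family_labels
    ph <- simulate_phenotypes(gm, map, cfg)
    pheno <- ph$pheno
  } else {
    gen <- read_genotypes(config$input$genotypes,
                          format = config$input$format %||% "matrix")
    gm <- gen$gm; map <- gen$map
    pheno <- read_phenotypes(config$input$phenotypes,
                             trait = config$input$trait %||% "trait",
                             covariates = config$input$covariates)
    keep <- match(pheno$sample, gm$sample_ids)
    if (anyNA(keep)) stop("phenotyped samples missing from genotypes")
    gm <- sub_samples(gm, keep)
    fam <- pheno$family
  }
  flt <- config$filter %||% list()
  f <- filter_markers(gm, map, maf_min = flt$maf %||% 0.05,
                      max_missing = flt$max_missing %||% 0.10)
  gm <- impute_naive(f$gm, seed = derive_seed(seed, "impute"))
  map <- f$map
  y <- pheno$trait
  X <- fixed_design(pheno)
  bs <- config$blocks
  specs <- list(list(method = bs$method, param = bs$param))
  cv <- config$cv
  cv$seed <- derive_seed(seed, "cv")
  if ((cv$scheme %||% "random") == "family") cv$family_labels <- fam
  results <- sweep_grid(y, X, gm, map, specs, config$model, cv)
  resolved <- config
  resolved$toolkit_version <- as.character(utils::packageVersion("hapblockr"))
  js <- jsonlite::toJSON(config, auto_unbox = TRUE)
  resolved$config_hash <- .fnv1a(as.character(js))
  resolved$master_seed <- seed
  files <- c(results = paste0(config$out_prefix, "_results.csv"),
             config = paste0(config$out_prefix, "_config.json"))
  data.table::fwrite(results, files["results"])
  jsonlite::write_json(resolved, files["config"], auto_unbox = TRUE, pretty = TRUE)
  list(results = results, files = files)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `filter`, `blocks`, `cv`, `pipeline`. Arguments
#' are `--key value` pairs; see the package README. Installed as the
#' `hapblock` script under `inst/cli`.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
hapblock_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: hapblock <simulate|filter|blocks|cv|pipeline> [--key value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--")) stop("unexpected argument: ", rest[i])
    key <- sub("^--", "", rest[i])
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  switch(cmd,
    simulate = {
      cfg <- sim_config(
        n_samples = num(opts$`n-samples`) %||% 200,
        n_chromosomes = num(opts$`n-chromosomes`) %||% 3,
        markers_per_chromosome = num(opts$markers) %||% 60,
        material = opts$material %||% "inbred",
        h2_target = num(opts$h2) %||% 0.5,
        seed = num(opts$seed) %||% 1)
      pop <- simulate_population(cfg)
      ph <- simulate_phenotypes(pop$gm, pop$map, cfg)
      prefix <- opts$out %||% "simulated"
      write_genotypes(pop$gm, pop$map, prefix)
      write_vcf(pop$gm, pop$map, paste0(prefix, ".vcf"))
      ptab <- data.frame(sample = ph$pheno$sample, trait = ph$pheno$trait)
      if (!is.null(pop$family_labels)) ptab$family <- pop$family_labels
      data.table::fwrite(ptab, paste0(prefix, ".pheno.csv"))
      jsonlite::write_json(ph$truth, paste0(prefix, ".truth.json"),
                           auto_unbox = TRUE, digits = NA)
      message("wrote ", prefix, ".{geno.tsv,map.tsv,vcf,pheno.csv,truth.json}")
    },
    filter = {
      gen <- read_genotypes(opts$`in` %||% opts$vcf,
                            format = if (!is.null(opts$vcf)) "vcf" else "matrix")
      f <- filter_markers(gen$gm, gen$map, maf_min = num(opts$maf) %||% 0.05,
                          max_missing = num(opts$`max-missing`) %||% 0.10)
      gm <- impute_naive(f$gm, seed = num(opts$seed) %||% 1)
      write_genotypes(gm, f$map, opts$out %||% "filtered")
      message(nrow(f$report), " marker(s) dropped; ",
              n_markers(gm), " retained")
    },
    blocks = {
      gen <- read_genotypes(opts$`in`, format = "matrix")
      part <- switch(opts$method,
        ld = blocks_ld_threshold(gen$gm, gen$map, threshold = num(opts$param)),
        fixm = blocks_fixed_markers(gen$map, num(opts$param)),
        fixbp = blocks_fixed_bp(gen$map, num(opts$param)),
        gabriel = blocks_gabriel(gen$gm, gen$map, seed = num(opts$seed) %||% 1),
        fourgamete = blocks_four_gamete(gen$gm, gen$map),
        spine = blocks_solid_spine(gen$gm, gen$map),
        stop("unknown --method: ", opts$method))
      write_blocks(part, gen$map, opts$out %||% "blocks.bed")
      message(nrow(part$blocks), " block(s) written")
    },
    cv = {
      gen <- read_genotypes(opts$`in`, format = "matrix")
      pheno <- read_phenotypes(opts$pheno)
      part <- blocks_fixed_markers(gen$map, num(opts$`block-size`) %||% 1)
      des <- build_design(enumerate_haplotypes(gen$gm, part))
      G <- grm_vanraden(des)
      res <- random_cv(pheno$trait, fixed_design(pheno),
                       list(kernels = list(G), G = G),
                       model = opts$model %||% "gblup",
                       n_runs = num(opts$runs) %||% 100,
                       test_frac = num(opts$`test-frac`) %||% 0.2,
                       seed = num(opts$seed) %||% 1)
      message(sprintf("mean accuracy %.4f (sd %.4f) over %d runs",
                      res$mean, res$sd, res$n_runs))
    },
    pipeline = {
      run_pipeline(opts$config)
      message("pipeline complete")
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
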