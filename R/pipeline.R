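#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters with a master seed. Stage seeds are
#' derived deterministically from the master seed and the stage name, so
#' inserting or removing stages never shifts another stage's random stream.
#'
#' @param calibration a [calibration_spec()].
#' @param design a [simulation_design()].
#' @param admixture an [admixture_config()].
#' @param admixture_preset a [run_preset()] for the admixture sampler.
#' @param category_prior `"jeffreys"` or `"uniform"`.
#' @param category_preset a [run_preset()] for the category sampler.
#' @param diag_params list of diagnostic-rule parameters (see
#'   [diagnostic_allele_set()]).
#' @param grid threshold grid for the scans.
#' @param seed master seed (integer).
#' @param stages character vector of stages to run, a subset of
#'   `c("calibrate", "simulate", "admixture", "categories", "diagnose",
#'   "scan")`; downstream outputs depending on a skipped stage are skipped.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(calibration = calibration_spec(),
                            design = simulation_design(),
                            admixture = admixture_config(),
                            admixture_preset = run_preset("custom",
                                                          total = 2e4,
                                                          burnin = 4e3),
                            category_prior = "uniform",
                            category_preset = run_preset("custom",
                                                         total = 2e4,
                                                         burnin = 4e3),
                            diag_params = list(),
                            grid = threshold_grid(),
                            seed = 1L,
                            stages = c("calibrate", "simulate", "admixture",
                                       "categories", "diagnose", "scan")) {
  structure(list(calibration = calibration, design = design,
                 admixture = admixture,
                 admixture_preset = admixture_preset,
                 category_prior = category_prior,
                 category_preset = category_preset,
                 diag_params = diag_params, grid = grid,
                 seed = as.integer(seed), stages = stages),
            class = "pipeline_config")
}

# deterministic stage seed from (master seed, stage name); < 2^31
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 1009L)
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full simulation study
#'
#' Orchestrates calibrate -> simulate -> estimate (Gibbs and EM admixture,
#' category model) -> diagnose -> threshold scan, writing tidy tab-separated
#' result tables plus a manifest (config hash, stage seeds, package version)
#' to `out_dir`. Fully deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_simulation_study <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  res <- list()
  seeds <- list()
  run_stage <- function(name, fun) {
    seeds[[name]] <<- derive_seed(config$seed, name)
    tryCatch(fun(seeds[[name]]),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  if ("calibrate" %in% stages) {
    res$pools <- run_stage("calibrate", function(s)
      calibrate_pools(config$calibration, seed = s))
    write_tsv(pool_table(res$pools), file.path(out_dir, "pools.tsv"))
  }
  if ("simulate" %in% stages && !is.null(res$pools)) {
    res$test_set <- run_stage("simulate", function(s)
      build_test_set(res$pools, config$design, seed = s))
    write_structure_table(res$test_set,
                          file.path(out_dir, "test_set.structure.tsv"))
    write_truth_table(res$test_set, file.path(out_dir, "truth.tsv"))
  }
  ref_A <- if (!is.null(res$test_set))
    res$test_set$ids[res$test_set$truth == "PURE_A"] else NULL
  if ("admixture" %in% stages && !is.null(res$test_set)) {
    res$q_gibbs <- run_stage("admixture", function(s)
      gibbs_admixture(res$test_set, config$admixture,
                      config$admixture_preset,
                      reference_A = ref_A, seed = s))
    res$q_em <- run_stage("admixture_em", function(s)
      em_admixture(res$test_set, seed = s))
    res$q_em <- align_clusters(list(res$q_em), ref_A)[[1]]
    write_tsv(as.data.frame(res$q_gibbs),
              file.path(out_dir, "q_gibbs.tsv"))
    write_tsv(as.data.frame(res$q_em), file.path(out_dir, "q_em.tsv"))
  }
  if ("categories" %in% stages && !is.null(res$test_set)) {
    res$cat_post <- run_stage("categories", function(s)
      category_posterior_mcmc(res$test_set, prior = config$category_prior,
                              preset = config$category_preset,
                              reference_A = ref_A, seed = s))
    write_tsv(as.data.frame(res$cat_post),
              file.path(out_dir, "category_posteriors.tsv"))
  }
  if ("diagnose" %in% stages && !is.null(res$pools) &&
      !is.null(res$test_set)) {
    res$diag <- do.call(diagnostic_allele_set,
                        c(list(res$pools), config$diag_params))
    res$diag_class <- classify_by_alleles(res$test_set, res$diag)
    write_tsv(res$diag$specific_B,
              file.path(out_dir, "diagnostic_alleles_B.tsv"))
    write_tsv(res$diag_class, file.path(out_dir, "diagnostic_classes.tsv"))
  }
  if ("scan" %in% stages && !is.null(res$test_set)) {
    truth <- res$test_set$truth
    if (!is.null(res$q_gibbs)) {
      res$scan_q <- threshold_scan(truth, res$q_gibbs,
                                   method = "structure_q",
                                   grid = config$grid)
      res$removal <- removal_curve(truth, res$q_gibbs, grid = config$grid)
      write_tsv(res$scan_q$table, file.path(out_dir, "scan_structure_q.tsv"))
      write_tsv(res$removal$overall,
                file.path(out_dir, "removal_overall.tsv"))
      write_tsv(res$removal$per_class,
                file.path(out_dir, "removal_per_class.tsv"))
    }
    if (!is.null(res$cat_post)) {
      res$scan_nh <- threshold_scan(truth, res$cat_post,
                                    method = "newhybrids_three",
                                    grid = config$grid)
      write_tsv(res$scan_nh$table,
                file.path(out_dir, "scan_newhybrids_three.tsv"))
    }
  }

  manifest <- list(config_hash = config_hash(config),
                   master_seed = config$seed,
                   stage_seeds = seeds,
                   stages = stages,
                   package_version =
                     as.character(utils::packageVersion("hybriq")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

# tidy locus/allele/frequency table for a reference pair
pool_table <- function(pools) {
  one <- function(pool, name) {
    do.call(rbind, lapply(seq_along(pool$loci), function(l) {
      f <- pool$freqs[[l]]
      data.frame(pool = name, locus = pool$loci[l],
                 allele = as.integer(names(f)), frequency = unname(f),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(one(pools$pool_A, "A"), one(pools$pool_B, "B"))
}

#' Run the estimation stack on an empirical genotype file
#'
#' Reads a GenePop or STRUCTURE-format file, estimates admixture (Gibbs and
#' EM) using the named reference groups to orient clusters, classifies
#' hybrid categories, and reports per-location composition at the chosen
#' threshold.
#'
#' @param config a [pipeline_config()] (estimation settings and seed are
#'   used; calibration/simulation stages are ignored).
#' @param path genotype file path.
#' @param reference_A,reference_B group labels of the nonadmixed reference
#'   populations for taxa A and B.
#' @param format `"genepop"` or `"structure"`.
#' @param threshold three-way threshold for the per-location report.
#' @param out_dir optional output directory for result tables.
#' @return a list: `dataset`, `q_gibbs`, `q_em`, `cat_post`, `labels`,
#'   `locations` (per-location composition).
#' @export
run_empirical_analysis <- function(config, path, reference_A, reference_B,
                                   format = c("genepop", "structure"),
                                   threshold = 0.90, out_dir = NULL) {
  format <- match.arg(format)
  dataset <- switch(format, genepop = read_genepop(path),
                    structure = read_structure_table(path))
  for (g in c(reference_A, reference_B)) {
    k <- sum(dataset$group == g)
    if (k == 0L) stop("reference group not found: ", g)
    if (k < 2L) stop("reference group '", g, "' has fewer than 2 individuals")
  }
  ref_ids <- dataset$ids[dataset$group %in% reference_A]
  q_gibbs <- gibbs_admixture(dataset, config$admixture,
                             config$admixture_preset,
                             reference_A = ref_ids,
                             seed = derive_seed(config$seed, "admixture"))
  q_em <- em_admixture(dataset, seed = derive_seed(config$seed,
                                                   "admixture_em"))
  q_em <- align_clusters(list(q_em), ref_ids)[[1]]
  cat_post <- category_posterior_mcmc(dataset,
                                      prior = config$category_prior,
                                      preset = config$category_preset,
                                      reference_A = ref_ids,
                                      seed = derive_seed(config$seed,
                                                         "categories"))
  labels <- assign_structure_threshold(q_gibbs$Q, threshold)
  locations <- location_composition(labels, dataset$group)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(as.data.frame(q_gibbs), file.path(out_dir, "q_gibbs.tsv"))
    write_tsv(as.data.frame(q_em), file.path(out_dir, "q_em.tsv"))
    write_tsv(as.data.frame(cat_post),
              file.path(out_dir, "category_posteriors.tsv"))
    write_tsv(locations$table, file.path(out_dir, "locations.tsv"))
  }
  list(dataset = dataset, q_gibbs = q_gibbs, q_em = q_em,
       cat_post = cat_post, labels = labels, locations = locations)
}
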