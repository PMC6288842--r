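#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end pipeline. Defaults are
#' the published study settings: segregation-distortion tolerance 0.001, LOD
#' limit 16, minimum 25 markers per linkage group, 3 ordering runs, 20%
#' maximum missingness, MAPQ > 30 for synteny. The `sim` block configures
#' the synthetic cross used when no input VCF is given; the packaged demo
#' default keeps it small (5 groups x 80 markers) so the full pipeline runs
#' in seconds.
#'
#' @param sim A list of [sim_config()] arguments for the simulated input.
#' @param filter,linkage,synteny Named lists overriding stage parameters.
#' @param seed Master seed for every stochastic stage.
#' @param paths Optional list: `vcf` (input VCF instead of simulation),
#'   `hits` (mapping-record TSV; simulated if absent), `arms` (arm table CSV;
#'   packaged synthetic table if absent).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = list(), filter = list(), linkage = list(),
                            synteny = list(), seed = 1L, paths = list()) {
  cfg <- list(
    sim = modifyList(list(n_groups = 5L, markers_per_group = 80L,
                          mean_spacing_cM = 0.5), sim),
    filter = modifyList(list(tolerance = 0.001, max_missing = 0.20,
                             both_inf_classes = "homozygous"), filter),
    linkage = modifyList(list(lod_limit = 16, min_markers = 25, n_runs = 3L,
                              max_interval_cM = 50,
                              map_function = "haldane",
                              averaged_method = "mean_sex"), linkage),
    synteny = modifyList(list(min_mapq = 30, prop_mapped = 0.3,
                              concordance = 0.9), synteny),
    seed = as.integer(seed),
    paths = paths
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Save / load a pipeline configuration as YAML
#'
#' Round-trip safe: `load_config(save_config(cfg, f))` reproduces `cfg`.
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` invisibly returns `path`; `load_config` returns a
#'   `pipeline_config`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(sim = raw$sim %||% list(),
                  filter = raw$filter %||% list(),
                  linkage = raw$linkage %||% list(),
                  synteny = raw$synteny %||% list(),
                  seed = raw$seed %||% 1L,
                  paths = raw$paths %||% list())
}

#' Run the whole pipeline and write its artifacts
#'
#' simulate (or read) genotypes -> informative-marker filtering -> linkage
#' grouping, ordering and map construction -> map summary statistics ->
#' synteny analysis. Every output is a TSV with a `#schema:` header line
#' (plus a provenance JSON recording package version, configuration and
#' seeds), and the run is fully deterministic given the configuration.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the main in-memory results (`geno`,
#'   `map`, `summary`, `synteny`) and `files` (paths written).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  truth <- NULL
  geno <- stage("genotypes", {
    if (!is.null(cfg$paths$vcf)) {
      read_cross_vcf(cfg$paths$vcf)
    } else {
      sc <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
      cross <- sim_cross(sc)
      truth <- cross$true_map
      p <- file.path(out_dir, "simulated.vcf")
      write_cross_vcf(cross$geno, p)
      files <- c(files, p, write_truth(cross, out_dir))
      cross$geno
    }
  })

  filtered <- stage("filter", filter_genotypes(
    geno, tolerance = cfg$filter$tolerance,
    max_missing = cfg$filter$max_missing,
    both_inf_classes = cfg$filter$both_inf_classes,
    seed = cfg$seed, verbose = verbose))
  flog <- file.path(out_dir, "filter_log.tsv")
  writeLines("#schema: whitemap/filter_log v1", flog)
  readr::write_tsv(filter_log(filtered), flog, append = TRUE, col_names = TRUE)
  files <- c(files, flog)

  map <- stage("map", build_map(
    filtered, lod_limit = cfg$linkage$lod_limit,
    min_markers = cfg$linkage$min_markers, n_runs = cfg$linkage$n_runs,
    seed = cfg$seed, max_interval_cM = cfg$linkage$max_interval_cM,
    map_function = cfg$linkage$map_function,
    averaged_method = cfg$linkage$averaged_method, verbose = verbose))
  if (nrow(map) == 0L) {
    abort("pipeline stage 'map' failed: no linkage groups formed")
  }
  fmap <- file.path(out_dir, "map.tsv")
  write_map(map, fmap)
  files <- c(files, fmap)

  summ <- stage("stats", map_summary(map))
  fsum <- file.path(out_dir, "map_summary_groups.tsv")
  writeLines("#schema: whitemap/map_summary_groups v1", fsum)
  readr::write_tsv(summ$by_group, fsum, append = TRUE, col_names = TRUE)
  fglob <- file.path(out_dir, "map_summary_global.tsv")
  writeLines("#schema: whitemap/map_summary_global v1", fglob)
  readr::write_tsv(summ$global, fglob, append = TRUE, col_names = TRUE)
  files <- c(files, fsum, fglob)

  synt <- stage("synteny", {
    arms <- load_arm_table(cfg$paths$arms)
    hits <- if (!is.null(cfg$paths$hits)) {
      read_mapping_records(cfg$paths$hits)
    } else {
      sim_mapping_records(map, arms, scheme = "by_group",
                          prop_mapped = cfg$synteny$prop_mapped,
                          concordance = cfg$synteny$concordance,
                          seed = cfg$seed + 1000L)
    }
    synteny_analysis(map, hits, arms, min_mapq = cfg$synteny$min_mapq)
  })
  fsynt <- file.path(out_dir, "synteny_groups.tsv")
  writeLines("#schema: whitemap/synteny_groups v1", fsynt)
  readr::write_tsv(synt$assignment$groups %>% select(-dplyr::any_of("run_scores")),
                   fsynt, append = TRUE, col_names = TRUE)
  farm <- file.path(out_dir, "synteny_arm_ratios.tsv")
  writeLines("#schema: whitemap/synteny_arm_ratios v1", farm)
  readr::write_tsv(synt$ratio_test$arms, farm, append = TRUE, col_names = TRUE)
  files <- c(files, fsynt, farm)

  prov <- file.path(out_dir, "provenance.json")
  cfg_plain <- unclass(cfg)
  jsonlite::write_json(list(
    package = "whitemap",
    version = as.character(utils::packageVersion("whitemap")),
    seed = cfg$seed,
    config = cfg_plain,
    config_hash = rlang::hash(cfg_plain),
    outputs = basename(files)
  ), prov, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, prov)

  if (verbose) inform(sprintf("pipeline complete: %d files in %s",
                              length(files), out_dir))
  invisible(list(geno = filtered, map = map, summary = summ, synteny = synt,
                 truth = truth, files = files))
}
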