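#' Configuration for a full ecological-group analysis run
#'
#' Collects every knob of the simulate/ingest -> rarefy -> partition ->
#' beta-null -> statistics pipeline with the conventional defaults
#' (rarefaction to 7000 reads; 1000 quasiswap permutations for the
#' occurrence null; 999 null metacommunities for the beta deviation;
#' 999 permutations for Adonis/ANOSIM/MRPP). A configuration can also be
#' read from YAML via [read_pipeline_config()].
#'
#' @param table_path path to an OTU table TSV, or `NULL` to simulate.
#' @param scenario a [metacommunity_scenario] used when `table_path` is
#'   `NULL`.
#' @param plant named list of arguments for [plant_group_structure()]
#'   applied to a simulated table (`NULL` = no planting).
#' @param metadata_path optional sample metadata TSV.
#' @param depth rarefaction depth (`NULL` skips rarefaction).
#' @param partition_mode dispersion statistic form, `"occurrence"` or
#'   `"classic"`.
#' @param partition_n_null quasiswap tables for the occurrence null.
#' @param core_min_occupancy_frac core occupancy threshold.
#' @param gs_metric occurrence-null metric, see [generalist_specialist()].
#' @param beta_n_null null metacommunities per group.
#' @param stats_tests subset of `c("adonis", "anosim", "mrpp")`.
#' @param stats_n_perm permutations for the group-structure tests.
#' @param group_col metadata column defining the tested grouping.
#' @param seed master seed; stage sub-seeds are derived from it by hashing
#'   the stage name, so adding a stage never perturbs earlier stages.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(table_path = NULL, scenario = NULL,
                            plant = NULL, metadata_path = NULL,
                            depth = 7000,
                            partition_mode = "occurrence",
                            partition_n_null = 1000,
                            core_min_occupancy_frac = 0.5,
                            gs_metric = "occurrence",
                            beta_n_null = 999,
                            stats_tests = c("adonis", "anosim", "mrpp"),
                            stats_n_perm = 999,
                            group_col = "location",
                            seed = 1L, out_dir = "results") {
  if (is.null(table_path) && is.null(scenario))
    stop("config needs either table_path or a simulation scenario")
  for (nm in c("partition_n_null", "beta_n_null", "stats_n_perm"))
    if (get(nm) < 1) stop("config field ", nm, " must be positive")
  structure(list(table_path = table_path, scenario = scenario,
                 plant = plant, metadata_path = metadata_path,
                 depth = depth, partition_mode = partition_mode,
                 partition_n_null = partition_n_null,
                 core_min_occupancy_frac = core_min_occupancy_frac,
                 gs_metric = gs_metric, beta_n_null = beta_n_null,
                 stats_tests = stats_tests, stats_n_perm = stats_n_perm,
                 group_col = group_col, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; a `scenario` mapping
#' is passed to [metacommunity_scenario()] and a `plant` mapping to
#' [plant_group_structure()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario))
    y$scenario <- do.call(metacommunity_scenario, y$scenario)
  do.call(pipeline_config, y)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full ecological-group analysis
#'
#' Executes: input (simulate or read) -> rarefaction -> core/satellite and
#' generalist/specialist partition -> per-group beta-null deviations and
#' pairwise Wilcoxon comparisons -> group-structure permutation tests and
#' abundance-occupancy fit. All result tables are written as TSV under
#' `config$out_dir` together with a JSON manifest recording the
#' configuration, derived stage seeds, row counts, and package version;
#' re-running an identical config reproduces identical files.
#'
#' @param config a [pipeline_config].
#' @return (invisibly) a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(simulate = stage_seed(config$seed, "simulate"),
                plant = stage_seed(config$seed, "plant"),
                rarefy = stage_seed(config$seed, "rarefy"),
                partition = stage_seed(config$seed, "partition"),
                beta_null = stage_seed(config$seed, "beta_null"),
                stats = stage_seed(config$seed, "stats"))
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_tsv_out(df, p)
    files <<- c(files, name)
  }
  truth <- NULL

  tab <- pipeline_stage("input", {
    if (!is.null(config$table_path)) {
      x <- read_otu_table(config$table_path)
      if (!is.null(config$metadata_path)) {
        meta <- read_sample_metadata(config$metadata_path)
        x <- otu_table(x$counts, taxonomy = x$taxonomy, metadata = meta)
      }
      x
    } else {
      sc <- config$scenario
      sc$seed <- seeds$simulate
      sim <- simulate_metacommunity(sc)
      x <- sim$table
      if (!is.null(config$plant)) {
        pl <- do.call(plant_group_structure,
                      c(list(table = x, seed = seeds$plant), config$plant))
        truth <- pl$truth
        x <- pl$table
      }
      x
    }
  })

  if (!is.null(config$depth))
    tab <- pipeline_stage("rarefaction",
                          rarefy_table(tab, config$depth,
                                       seed = seeds$rarefy))

  part <- pipeline_stage("partition", {
    cs <- core_satellite(tab, mode = config$partition_mode,
                         core_min_occupancy_frac =
                           config$core_min_occupancy_frac)
    gs <- generalist_specialist(tab, n_null = config$partition_n_null,
                                metric = config$gs_metric,
                                seed = seeds$partition)
    assignment <- assign_groups(cs, gs)
    emit(cs, "dispersion.tsv")
    emit(gs, "occurrence_null.tsv")
    emit(assignment, "labels.tsv")
    emit(group_summary(tab, assignment), "group_summary.tsv")
    emit(group_overlap(assignment), "overlaps.tsv")
    list(cs = cs, gs = gs, assignment = assignment)
  })

  beta <- pipeline_stage("beta_null", {
    mem <- Filter(length, group_members(part$assignment))
    res <- lapply(names(mem), function(g)
      beta_null_deviation(tab, mem[[g]], n_null = config$beta_n_null,
                          seed = stage_seed(seeds$beta_null, g),
                          group_label = g))
    names(res) <- names(mem)
    dev_df <- do.call(rbind, lapply(res, function(r)
      data.frame(group = r$group_label,
                 pair = names(r$pairwise_deviations),
                 observed = r$observed_pairwise,
                 expected = r$expected_pairwise,
                 deviation = r$pairwise_deviations,
                 row.names = NULL, stringsAsFactors = FALSE)))
    emit(dev_df, "deviations.tsv")
    cmp <- list()
    for (p in list(c("core", "satellite"), c("generalist", "specialist")))
      if (all(p %in% names(res))) {
        if (!setequal(res[[p[1]]]$sample_ids, res[[p[2]]]$sample_ids)) {
          message("skipping ", paste(p, collapse = " vs "),
                  " comparison: groups cover different sample sets")
          next
        }
        cc <- compare_group_deviations(res[[p[1]]], res[[p[2]]])
        cmp[[paste(p, collapse = "_vs_")]] <- cc
      }
    if (length(cmp))
      emit(data.frame(comparison = names(cmp),
                      statistic = vapply(cmp, `[[`, 0, "statistic"),
                      p_value = vapply(cmp, `[[`, 0, "p_value"),
                      median_difference = vapply(cmp, `[[`, 0,
                                                 "median_difference"),
                      row.names = NULL, stringsAsFactors = FALSE),
           "deviation_tests.tsv")
    list(results = res, comparisons = cmp)
  })

  stats_out <- pipeline_stage("stats", {
    rows <- list()
    meta <- tab$metadata
    if (!is.null(meta) && config$group_col %in% names(meta)) {
      grouping <- stats::setNames(meta[[config$group_col]],
                                  rownames(meta))
      mem <- Filter(function(v) length(v) >= 2,
                    group_members(part$assignment))
      for (g in names(mem)) {
        d <- bray_curtis(hellinger_transform(subset_otus(tab, mem[[g]])))
        for (tst in config$stats_tests) {
          fun <- switch(tst, adonis = adonis_test, anosim = anosim_test,
                        mrpp = mrpp_test)
          r <- fun(d, grouping, n_perm = config$stats_n_perm,
                   seed = stage_seed(seeds$stats, paste(g, tst)))
          rows[[paste(g, tst)]] <-
            data.frame(group = g, test = r$test_name,
                       statistic = r$statistic, effect_r2 = r$effect_r2,
                       p_value = r$p_value, stringsAsFactors = FALSE)
        }
      }
    }
    ao <- abundance_occupancy(tab)
    emit(data.frame(slope = ao$slope, intercept = ao$intercept,
                    r_squared = ao$r_squared, p_value = ao$p_value,
                    n_otus = ao$n_otus), "abundance_occupancy.tsv")
    if (length(rows))
      emit(do.call(rbind, c(rows, make.row.names = FALSE)), "stats.tsv")
    list(tests = rows, abundance_occupancy = ao)
  })

  manifest <- list(
    package = "asgroups",
    version = as.character(utils::packageVersion("asgroups")),
    config = {
      cfg <- unclass(config)
      cfg[!vapply(cfg, is.null, TRUE)]
    },
    stage_seeds = seeds,
    files = files,
    n_otus = n_otus(tab), n_samples = n_samples(tab),
    group_counts = vapply(group_members(part$assignment), length, 0L))
  if (!is.null(manifest$config$scenario))
    manifest$config$scenario <- unclass(manifest$config$scenario)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(table = tab, truth = truth, partition = part,
                 beta_null = beta, stats = stats_out,
                 manifest = manifest))
}
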