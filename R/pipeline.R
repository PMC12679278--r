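stop_cfg <- function(...) {
  stop(errorCondition(paste0(...), class = c("metgge_config_error", "error")))
}

#' Run the full MET analysis pipeline
#'
#' Orchestrates: load (or simulate) a balanced trial, append the
#' multi-trait selection index, per-trait ANOVA with percent
#' contribution, variance components and genetic parameters, the GGE
#' biplot suite on the index (both SVP modes, mean-vs-stability,
#' ideal-genotype ranking, environment metrics, which-won-where), Ward
#' clustering, and (optionally) the LOO-CV model-validation harness.
#' All stage outputs are written under `out_dir` as CSV/JSON and listed
#' in a manifest with md5 checksums and the seed; identical config and
#' seed reproduce all outputs bit-identically.
#'
#' Config fields: one of `input` (long CSV path) or `simulation` (named
#' list of [sim_config()] arguments); optional `traits` (default: all),
#' `index` (list with `traits`, `weights`; default unit weights over all
#' traits), `index_name` (default `"BLPSI"`), `k` (selection intensity,
#' default 2.06), `cluster_k` (genotype cluster count, default
#' `min(7, g)`), `ml` (list with `families`, `grids` per family,
#' `trait`, `selection_metric`; omit to skip the ML stage), `out_dir`,
#' `seed`.
#'
#' When the input carries a single replicate the ANOVA/variance stages
#' are skipped (no error stratum); when it carries a single environment
#' the GGE stage is skipped. Both skips are recorded in the manifest.
#'
#' @param config named list, or path to a JSON/YAML config file.
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  out_dir <- config$out_dir %||% "met_output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  skipped <- character()

  # --- data stage -----------------------------------------------------
  if (!is.null(config$input)) {
    if (!file.exists(config$input)) stop_cfg("input not found: ", config$input)
    dataset <- read_met_csv(config$input)
  } else if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    dataset <- simulate_met(do.call(sim_config, sim_args))
  } else {
    stop_cfg("config needs either 'input' or 'simulation'")
  }
  balance <- validate_balance(dataset)
  if (!balance$complete) {
    stop("data stage failed: unbalanced trial (",
         nrow(balance$offending_cells), " offending cells)", call. = FALSE)
  }
  traits <- config$traits %||% attr(dataset, "trait_names")

  # --- selection index stage ------------------------------------------
  index_name <- config$index_name %||% "BLPSI"
  ispec <- if (!is.null(config$index)) {
    index_spec(config$index$traits %||% traits,
               config$index$weights %||% 1)
  } else {
    index_spec(traits, 1)
  }
  dataset <- add_selection_index(dataset, ispec, name = index_name)
  write_met_csv(dataset, file.path(out_dir, "dataset_with_index.csv"))

  # --- variance / genetics stage --------------------------------------
  k <- config$k %||% 2.06
  dims <- met_dims(dataset)
  genetics <- list()
  for (tr in c(traits, index_name)) {
    gm <- rowMeans(to_two_way(dataset, tr))
    entry <- list(trait = tr, descriptives = as.list(descriptive_stats(gm)))
    if (balance$r >= 2) {
      an <- met_anova(dataset, tr)
      vc <- suppressWarnings(variance_components(an))
      h2 <- heritability_anova(vc, dims$e, balance$r)
      entry$anova <- as.data.frame(an)
      entry$percent_contribution <- as.list(percent_contribution(an))
      entry$variance_components <- vc[c("var_g", "var_ge", "var_err")]
      entry$h2_anova <- h2
      entry$lsd_5pct <- lsd_threshold(an)
      if (!is.na(h2) && h2 > 0) {
        entry$genetic_parameters <-
          genetic_parameters(vc$var_g, h2, mean(dataset[[tr]]), k = k)
      }
    }
    genetics[[tr]] <- entry
  }
  if (balance$r < 2) skipped <- c(skipped, "anova (single replicate)")
  jsonlite::write_json(genetics, file.path(out_dir, "genetics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- GGE stage -------------------------------------------------------
  gge <- NULL
  if (dims$e >= 2 && dims$g >= 3) {
    tw <- to_two_way(dataset, index_name)
    gmod <- fit_gge(tw, svp = "genotype")
    emod <- fit_gge(tw, svp = "environment")
    try_stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        skipped <<- c(skipped, paste0(name, ": ", conditionMessage(e)))
        NULL
      })
    }
    frame_g <- try_stage("aec", aec_frame(gmod))
    ranking <- if (!is.null(frame_g)) {
      try_stage("ranking", rank_vs_ideal(mean_stability(gmod, frame_g)))
    }
    env_eval <- try_stage("environment-metrics",
                          environment_metrics(emod, aec_frame(emod)))
    www <- try_stage("which-won-where", which_won_where(gmod))
    feat <- sapply(c(traits, index_name),
                   function(tr) rowMeans(to_two_way(dataset, tr)))
    ck <- config$cluster_k %||% min(7L, dims$g)
    clusters <- ward_cluster(feat, k = ck)
    gge <- list(model = gmod, env_model = emod, aec = frame_g,
                ranking = ranking, environment_metrics = env_eval,
                which_won_where = www, clusters = clusters)
    if (!is.null(ranking)) {
      utils::write.csv(ranking, file.path(out_dir, "genotype_ranking.csv"),
                       row.names = FALSE)
    }
    if (!is.null(env_eval)) {
      utils::write.csv(env_eval, file.path(out_dir, "environment_metrics.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(singular_values = gmod$singular_values,
           var_explained = gmod$var_explained,
           genotype_scores = as.data.frame(gmod$genotype_scores[, 1:gmod$n_axes,
                                                                drop = FALSE]),
           environment_scores = as.data.frame(
             emod$environment_scores[, 1:emod$n_axes, drop = FALSE]),
           aec_abscissa = if (!is.null(frame_g)) frame_g$abscissa,
           mega_environments = if (!is.null(www)) www$mega_environments,
           hull_vertices = if (!is.null(www)) www$hull_vertices,
           clusters = as.list(clusters$cluster)),
      file.path(out_dir, "gge.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  } else {
    skipped <- c(skipped, "gge (needs >= 2 environments and >= 3 genotypes)")
  }

  # --- ML validation stage --------------------------------------------
  ml <- NULL
  if (!is.null(config$ml)) {
    mlc <- config$ml
    tr <- mlc$trait %||% index_name
    fm <- build_feature_matrix(dataset, tr)
    ml <- lapply(mlc$families %||% "random_forest", function(fam) {
      grid <- (mlc$grids %||% list())[[fam]] %||%
        default_grid(fam)
      gs <- grid_search(fam, grid, fm$features, fm$target,
                        selection_metric = mlc$selection_metric %||% "rmse",
                        seed = seed)
      list(family = fam, trait = tr, best_params = gs$best_params,
           metrics = gs$best_metrics[c("r2", "rmse", "mae", "mape",
                                       "msle", "medae")])
    })
    names(ml) <- mlc$families %||% "random_forest"
    jsonlite::write_json(ml, file.path(out_dir, "ml_validation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # --- manifest --------------------------------------------------------
  files <- setdiff(list.files(out_dir), "run_manifest.json")
  manifest <- list(seed = seed,
                   skipped_stages = as.list(skipped),
                   files = lapply(stats::setNames(nm = files), function(f) {
                     list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
                   }))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dataset = dataset, balance = balance, genetics = genetics,
                 gge = gge, ml = ml, manifest = manifest))
}

default_grid <- function(family) {
  switch(family,
         random_forest = list(ntree = c(200, 500), nodesize = c(1, 5)),
         mlp = list(size = c(3, 6), decay = c(0.01, 0.1)),
         linear = data.frame(dummy = 1)[, 0, drop = FALSE],
         mean = data.frame(dummy = 1)[, 0, drop = FALSE],
         stop_cfg("unknown model family: ", family))
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_cfg("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop_cfg("yaml package required for YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop_cfg("config must be a list or a file path")
  config
}
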