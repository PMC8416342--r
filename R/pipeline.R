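#' Configuration of a full pipeline run
#'
#' @param input Path to a cohort CSV, the string \code{"table1"} to run
#'   the comparisons stage on the packaged printed contingency rows, or
#'   \code{NULL} to generate a synthetic cohort from \code{sim}.
#' @param sim A [simulation_config()] used when \code{input} is NULL.
#' @param stages Subset of \code{c("score", "compare", "pca", "dag",
#'   "icn")} to run (\code{"all"} expands to every stage). Hub detection
#'   and centrality associations are produced by the \code{icn} stage.
#' @param B Bootstrap resamples for the DAG stage.
#' @param K Fixed ICN sparsity, or NULL to select over \code{k_grid}.
#' @param k_grid Sparsity grid for selection.
#' @param hub_preset Passed to [hub_criteria()].
#' @param n_null Null graphs per screened network.
#' @param seed_bootstrap,seed_null Stage seeds (the generator seed lives in
#'   \code{sim}).
#' @param out_dir Output directory (created if absent).
#' @return List of class \code{run_config}.
#' @export
run_config <- function(input = NULL, sim = simulation_config(),
                       stages = "all", B = 200L, K = NULL,
                       k_grid = seq(0.05, 0.20, by = 0.01),
                       hub_preset = "results", n_null = 20L,
                       seed_bootstrap = 1L, seed_null = 1L,
                       out_dir = "surveynet-results") {
  all_stages <- c("score", "compare", "pca", "dag", "icn")
  if (identical(stages, "all")) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!is.null(input) && !identical(input, "table1") && !file.exists(input)) {
    stop("input file not found: ", input)
  }
  structure(list(input = input, sim = sim, stages = stages, B = as.integer(B),
                 K = K, k_grid = k_grid, hub_preset = hub_preset,
                 n_null = as.integer(n_null),
                 seed_bootstrap = as.integer(seed_bootstrap),
                 seed_null = as.integer(seed_null), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the arguments of [run_config()]; simulation
#' settings live under a \code{sim:} block (\code{n_per_grade},
#' \code{grade_shift}, \code{noise_sd}, \code{seed}).
#'
#' @param path YAML file path.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  sim <- do.call(simulation_config, sim_args)
  args <- y[setdiff(names(y), "sim")]
  args$sim <- sim
  do.call(run_config, args)
}

write_tidy_csv <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full survey network analysis pipeline
#'
#' Executes the configured stages in order — cohort acquisition and
#' validation, scale scoring, grade comparisons, attitude-item PCA
#' diagnostics, bootstrap-averaged DAG learning, and the ICN / hub /
#' association analysis — writing one tidy CSV per stage plus a JSON
#' manifest of every seed and parameter. Identical configurations produce
#' byte-identical outputs. A failing stage aborts the run with the stage
#' named.
#'
#' @param config A [run_config()] or the path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, the manifest list (also written to
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  manifest <- list(
    package = "surveynet",
    version = as.character(utils::packageVersion("surveynet")),
    stages = config$stages,
    parameters = list(
      B = config$B, K = config$K, k_grid = config$k_grid,
      hub_preset = config$hub_preset, n_null = config$n_null,
      seed_bootstrap = config$seed_bootstrap, seed_null = config$seed_null,
      generator_seed = if (is.null(config$input)) config$sim$seed
    ),
    input = if (is.null(config$input)) "synthetic" else config$input
  )
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  table1_mode <- identical(config$input, "table1")
  cohort <- NULL
  if (!table1_mode) {
    cohort <- run_stage("input", {
      if (is.null(config$input)) {
        generate_cohort(config$sim)
      } else {
        read_cohort(config$input)
      }
    })
    manifest$n_respondents <- nrow(cohort)
    manifest$n_dropped <- attr(cohort, "n_dropped") %||% 0L
    outputs <- c(outputs, write_tidy_csv(cohort, config$out_dir,
                                         "cohort.csv"))
  }

  scores <- NULL
  if ("score" %in% config$stages && !table1_mode) {
    scores <- run_stage("score", score_cohort(cohort))
    outputs <- c(outputs, write_tidy_csv(scores, config$out_dir,
                                         "scores.csv"))
  }

  if ("compare" %in% config$stages) {
    comparisons <- run_stage("compare", {
      if (table1_mode) {
        compare_table1()
      } else {
        compare_cohort(cohort, scores)
      }
    })
    outputs <- c(outputs, write_tidy_csv(comparisons, config$out_dir,
                                         "comparisons.csv"))
  }

  if ("pca" %in% config$stages && !table1_mode) {
    pca_out <- run_stage("pca", {
      att <- as.matrix(cohort[, paste0("att", 1:7)])
      fit <- pca_varimax(att)
      adequacy <- kmo(att)
      bart <- bartlett_sphericity(att, n = nrow(att))
      diag_df <- data.frame(
        measure = c("kmo_overall", "bartlett_chi2", "bartlett_df",
                    "bartlett_p", "retained_components",
                    "cumulative_explained_variance",
                    paste0("kmo_", names(adequacy$kmo_per_item))),
        value = c(adequacy$kmo_overall, bart$bartlett_chi2,
                  bart$bartlett_df, bart$bartlett_p,
                  fit$retained_components,
                  fit$cumulative_explained_variance,
                  unname(adequacy$kmo_per_item)),
        stringsAsFactors = FALSE)
      list(fit = fit, diag = diag_df)
    })
    outputs <- c(outputs,
                 write_tidy_csv(pca_out$diag, config$out_dir,
                                "pca_diagnostics.csv"))
    if (pca_out$fit$retained_components > 0) {
      load_df <- data.frame(item = rownames(pca_out$fit$rotated_loadings),
                            pca_out$fit$rotated_loadings,
                            communality = pca_out$fit$communalities)
      outputs <- c(outputs, write_tidy_csv(load_df, config$out_dir,
                                           "pca_loadings.csv"))
    }
  }

  if ("dag" %in% config$stages && !table1_mode) {
    avg <- run_stage("dag", {
      ds <- discrete_dataset(cohort)
      bootstrap_average(ds, B = config$B, seed = config$seed_bootstrap)
    })
    outputs <- c(outputs, write_dag_csv(avg, file.path(config$out_dir,
                                                       "dag_edges.csv")))
    outputs <- c(outputs, write_dag_dot(avg, file.path(config$out_dir,
                                                       "dag.dot")))
    manifest$dag <- list(B = avg$B, threshold = avg$threshold,
                         n_edges = nrow(avg$edges),
                         n_dropped_cycle_edges = nrow(avg$dropped_edges))
  }

  if ("icn" %in% config$stages && !table1_mode) {
    fit <- run_stage("icn", {
      icn_study(cohort, K = config$K, k_grid = config$k_grid,
                criteria = hub_criteria(config$hub_preset),
                n_null = config$n_null, seed = config$seed_null)
    })
    manifest$icn <- list(K = fit$K,
                         n_hubs = sum(fit$hubs$hub))
    if (!is.null(fit$pass_rates)) {
      outputs <- c(outputs, write_tidy_csv(fit$pass_rates, config$out_dir,
                                           "icn_pass_rates.csv"))
    }
    outputs <- c(outputs, write_tidy_csv(fit$hubs, config$out_dir,
                                         "icn_hubs.csv"))
    outputs <- c(outputs, write_tidy_csv(fit$associations, config$out_dir,
                                         "icn_associations.csv"))
  }

  manifest$outputs <- basename(outputs)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Grade comparisons for every analysis variable of a cohort
#'
#' Chi-square homogeneity for the binary items, Kruskal-Wallis for the
#' ordinal attitude items, and one-way ANOVA for the three scale totals,
#' at the Bonferroni-adjusted main threshold of 0.017.
#'
#' @param cohort Validated cohort data frame.
#' @param scores Optional precomputed [score_cohort()] output.
#' @return Tidy data frame: item, test, statistic, df, p_value,
#'   significant_main.
#' @export
compare_cohort <- function(cohort, scores = NULL) {
  cohort <- validate_cohort(cohort, drop_incomplete = FALSE)
  if (is.null(scores)) scores <- score_cohort(cohort)
  schema <- item_schema()
  rows <- list()
  binary_items <- schema$item[schema$nlevels == 2]
  for (it in binary_items) {
    counts <- t(vapply(1:4, function(g) {
      v <- cohort[[it]][cohort$grade == g]
      c(sum(v == 1), sum(v == 0))
    }, numeric(2)))
    res <- chi_square_homogeneity(contingency_table(counts, item = it))
    rows[[it]] <- data.frame(item = it, test = res$test,
                             statistic = res$statistic,
                             df = paste(res$df, collapse = ";"),
                             p_value = res$p_value,
                             significant_main = res$significant_main,
                             stringsAsFactors = FALSE)
  }
  for (it in paste0("att", 1:7)) {
    res <- kruskal_wallis(cohort[[it]], cohort$grade, item = it)
    rows[[it]] <- data.frame(item = it, test = res$test,
                             statistic = res$statistic,
                             df = paste(res$df, collapse = ";"),
                             p_value = res$p_value,
                             significant_main = res$significant_main,
                             stringsAsFactors = FALSE)
  }
  for (sc in c("pss_total", "gad7_total", "phq9_total")) {
    res <- one_way_anova(scores[[sc]], scores$grade, item = sc)
    rows[[sc]] <- data.frame(item = sc, test = res$test,
                             statistic = res$statistic,
                             df = paste(res$df, collapse = ";"),
                             p_value = res$p_value,
                             significant_main = res$significant_main,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
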