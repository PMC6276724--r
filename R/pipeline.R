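#' Default end-to-end study configuration
#'
#' A desk-scale analogue of the full study design: a four-cell cohort,
#' a linear-additive feature model with a diagnosis effect, repeated
#' cross-validated two- and four-group classification, the a posteriori
#' screen, and MDS export. All sizes are deliberately small so the demo
#' completes in minutes on one CPU; pass the study's own values
#' (`n_per_cell = c(55, 55, 43, 40)`, `n_regions = 165`,
#' `n_repetitions = 500`) to emulate the full design.
#'
#' @param n_per_cell cohort cell counts (ASD-M, ASD-F, TD-M, TD-F).
#' @param n_regions regions in the synthetic feature table.
#' @param n_sites acquisition sites.
#' @param beta_dx,beta_sex,beta_int,beta_age effect sizes in noise-SD units.
#' @param site_offsets per-site shifts in noise-SD units.
#' @param feature_set `"all"`, `"structural"` (area, volume, thickness,
#'   curvature) or `"cd"`.
#' @param ticv_measures TICV normalization scope: `"all"` (literal) or a
#'   measure subset.
#' @param pca_threshold variance-retention threshold.
#' @param n_repetitions,k CV repetitions and folds.
#' @param stratify stratify CV folds by class.
#' @param alpha FDR level for the screen.
#' @param seed master integer seed.
#' @return a `study_config` list.
#' @export
study_config <- function(n_per_cell = c(20, 20, 20, 20),
                         n_regions = 10, n_sites = 4,
                         beta_dx = 1.5, beta_sex = 0.3, beta_int = 0.5,
                         beta_age = 0.05, site_offsets = c(0, 0.25, -0.25, 0.1),
                         feature_set = c("all", "structural", "cd"),
                         ticv_measures = "all",
                         pca_threshold = 0.95,
                         n_repetitions = 50, k = 10,
                         stratify = FALSE, alpha = 0.05, seed = 1) {
  feature_set <- match.arg(feature_set)
  structure(list(n_per_cell = n_per_cell, n_regions = n_regions,
                 n_sites = n_sites, beta_dx = beta_dx, beta_sex = beta_sex,
                 beta_int = beta_int, beta_age = beta_age,
                 site_offsets = site_offsets, feature_set = feature_set,
                 ticv_measures = ticv_measures,
                 pca_threshold = pca_threshold,
                 n_repetitions = n_repetitions, k = k, stratify = stratify,
                 alpha = alpha, seed = seed),
            class = "study_config")
}

# Polynomial rolling hash (mod 2^31 - 1) of the serialized config,
# for output provenance headers.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

write_tsv_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic study
#'
#' Executes simulate -> TICV normalization -> two-group repeated CV ->
#' four-group repeated CV -> most-frequent-scenario confusion summaries ->
#' a posteriori screen -> MDS, writing TSV tables, a JSON summary and a log
#' to `out_dir`. Every output file carries a header comment with the config
#' hash and seed; re-running with an identical config reproduces the bundle.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return invisible list with the in-memory results (`cohort`, `features`,
#'   `cv_two`, `cv_four`, `confusion_two`, `confusion_four`, `screen`,
#'   `mds`, `summary`).
#' @export
run_study <- function(config = study_config(), out_dir = tempfile("study_"),
                      quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- sprintf("# morphoclass study | config %s | seed %d", hash,
                 config$seed)
  log_path <- file.path(out_dir, "study.log")
  log_lines <- character(0)
  say <- function(...) {
    # no timestamps: identical configs must reproduce the bundle byte-for-byte
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed (config %s): %s", name, hash,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("simulate: cohort %s, %d regions", paste(config$n_per_cell, collapse = "/"),
      config$n_regions)
  cohort <- stage("simulate", generate_cohort(
    config$n_per_cell, n_sites = config$n_sites, seed = config$seed))
  spec <- effect_spec(n_regions = config$n_regions,
                      beta_dx = config$beta_dx, beta_sex = config$beta_sex,
                      beta_int = config$beta_int, beta_age = config$beta_age,
                      site_offsets = config$site_offsets)
  features <- stage("simulate", generate_feature_table(
    cohort, spec, seed = config$seed + 1))

  say("preprocess: TICV normalization (%s), feature set %s",
      paste(config$ticv_measures, collapse = ","), config$feature_set)
  features <- stage("preprocess",
                    ticv_normalize(features, cohort, config$ticv_measures))
  meta <- parse_feature_names(colnames(features))
  keep <- switch(config$feature_set,
                 all = rep(TRUE, ncol(features)),
                 structural = meta$measure != "CD",
                 cd = meta$measure == "CD")
  features <- features[, keep, drop = FALSE]

  say("classify: %d x %d-fold CV, two-group", config$n_repetitions, config$k)
  cv_two <- stage("cv_two", run_repeated_cv(
    features, cohort, "two_group", n_repetitions = config$n_repetitions,
    k = config$k, seed = config$seed + 100, stratify = config$stratify,
    pca_threshold = config$pca_threshold))
  say("classify: %d x %d-fold CV, four-group", config$n_repetitions, config$k)
  cv_four <- stage("cv_four", run_repeated_cv(
    features, cohort, "four_group", n_repetitions = config$n_repetitions,
    k = config$k, seed = config$seed + 200, stratify = config$stratify,
    pca_threshold = config$pca_threshold))

  sc_two <- most_frequent_scenario(cv_two)
  sc_four <- most_frequent_scenario(cv_four)
  conf_two <- confusion_summary(cv_two$truth, sc_two$predictions, "two_group")
  conf_four <- confusion_summary(cv_four$truth, sc_four$predictions,
                                 "four_group")

  say("posthoc: Welch + ANOVA screen at alpha %.3g", config$alpha)
  screen <- stage("posthoc", screen_features(features, cohort,
                                             alpha = config$alpha))

  say("mds: classical scaling of standardized features")
  emb <- stage("mds", classical_mds(standardize(features)$x, n_dims = 3))

  # chance level for flagging accuracies consistent with the null; the
  # band is the single-labeling binomial 99% scale (repetitions share one
  # labeling, so averaging over them does not shrink it)
  chance_two <- max(table(cv_two$truth)) / nrow(cohort)
  band_two <- 2.576 * sqrt(chance_two * (1 - chance_two) / nrow(cohort)) +
    0.02
  summary <- list(
    config_hash = hash, seed = config$seed, n = nrow(cohort),
    n_features = ncol(features),
    two_group = list(mean_accuracy = cv_two$mean_accuracy,
                     sd_accuracy = cv_two$sd_accuracy,
                     sensitivity = conf_two$sensitivity,
                     specificity = conf_two$specificity,
                     scenario_count = sc_two$count,
                     chance = chance_two,
                     consistent_with_chance =
                       abs(cv_two$mean_accuracy - chance_two) <= band_two),
    four_group = list(mean_accuracy = cv_four$mean_accuracy,
                      sd_accuracy = cv_four$sd_accuracy,
                      sensitivity = conf_four$sensitivity,
                      specificity = conf_four$specificity,
                      scenario_count = sc_four$count),
    screen = list(n_features = nrow(screen),
                  n_rejected_welch = sum(screen$sig_t),
                  n_rejected_anova = sum(screen$sig_F))
  )

  write_tsv_report(cohort, file.path(out_dir, "cohort.tsv"), hdr)
  write_tsv_report(data.frame(repetition = seq_along(cv_two$accuracies),
                              accuracy_two = cv_two$accuracies,
                              accuracy_four = cv_four$accuracies),
                   file.path(out_dir, "cv_accuracies.tsv"), hdr)
  write_tsv_report(data.frame(metric = names(conf_two$counts),
                              count = as.integer(conf_two$counts),
                              percent = as.numeric(conf_two$percent)),
                   file.path(out_dir, "confusion_two_group.tsv"), hdr)
  write_tsv_report(data.frame(metric = names(conf_four$counts),
                              count = as.integer(conf_four$counts),
                              percent = as.numeric(conf_four$percent)),
                   file.path(out_dir, "confusion_four_group.tsv"), hdr)
  write_tsv_report(screen, file.path(out_dir, "posthoc_screen.tsv"), hdr)
  embdf <- data.frame(subject_id = cohort$subject_id, emb$points[, 1:3],
                      diagnosis = cohort$diagnosis, sex = cohort$sex)
  names(embdf)[2:4] <- c("x", "y", "z")
  write_tsv_report(embdf, file.path(out_dir, "mds_embedding.tsv"), hdr)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(hdr, log_lines), log_path)
  say("done: %s", out_dir)

  invisible(list(cohort = cohort, features = features, cv_two = cv_two,
                 cv_four = cv_four, confusion_two = conf_two,
                 confusion_four = conf_four, screen = screen, mds = emb,
                 summary = summary, out_dir = out_dir))
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's stages. Subcommands: `simulate`,
#' `connectivity`, `preprocess`, `classify`, `posthoc`, `mds` and
#' `run-study`. Flags use `--key value` syntax; `--config file.(json|yaml)`
#' supplies a [study_config()] override block for `run-study`. See
#' `inst/cli/morphoclass.R` for the installed launcher.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return invisibly, the result of the dispatched stage.
#' @export
mclass_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: morphoclass <simulate|connectivity|preprocess|classify|posthoc|mds|run-study> [--key value ...]",
    "  common flags: --seed INT --out DIR/FILE",
    sep = "\n")
  if (length(args) == 0) {
    cat(usage, "\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- parse_cli_flags(args[-1])
  seed <- as.integer(opts$seed %||% 1)
  out <- opts$out %||% "."
  getn <- function(key, default) as.numeric(opts[[key]] %||% default)

  switch(cmd,
    "simulate" = {
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      coh <- generate_cohort(seed = seed)
      spec <- effect_spec(n_regions = getn("n-regions", 165),
                          beta_dx = getn("beta-dx", 0))
      ft <- generate_feature_table(coh, spec, seed = seed + 1)
      write_cohort(coh, file.path(out, "cohort.tsv"))
      write_feature_table(ft, file.path(out, "features.tsv"))
      invisible(list(cohort = coh, features = ft))
    },
    "connectivity" = {
      mesh <- read_mesh_obj(opts$mesh)
      sl <- read_streamlines_tsv(opts$streamlines)
      parc <- if (!is.null(opts$parcellation))
        read_parcellation_tsv(opts$parcellation) else NULL
      res <- connectivity_pipeline(
        mesh, sl, parc,
        max_angle = getn("max-angle", 60),
        snap_radius = getn("snap-radius", 2),
        radius = getn("radius", 5), fwhm = getn("fwhm", 5),
        literal = isTRUE(opts[["literal-angle-rule"]] == "true"))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(
        data.frame(vertex_id = seq_along(res$metrics$cd),
                   cd = res$metrics$cd, cd_smoothed = res$cd_smoothed,
                   mean_fa = res$metrics$mean_fa),
        file.path(out, "vertex_metrics.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      if (!is.null(res$parcel_cd)) {
        utils::write.table(
          data.frame(parcel_id = names(res$parcel_cd),
                     cd = as.numeric(res$parcel_cd)),
          file.path(out, "parcel_cd.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
      }
      invisible(res)
    },
    "preprocess" = {
      ft <- read_feature_table(opts$features)
      coh <- read_cohort(opts$cohort)
      meas <- strsplit(opts[["ticv-measures"]] %||% "all", ",")[[1]]
      if (identical(meas, "all")) meas <- "all"
      ft <- ticv_normalize(ft, coh, meas)
      if (isTRUE(opts$residualize == "true")) {
        ft <- residualize_covariates(ft, coh)
      }
      pm <- fit_pca(ft, getn("pca-threshold", 0.95))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_feature_table(project(pm, ft), file.path(out, "pc_scores.tsv"))
      jsonlite::write_json(
        list(k = pm$k, eigenvalues = pm$eigenvalues,
             fractions = pm$fractions),
        file.path(out, "pca_model.json"), digits = NA, auto_unbox = TRUE)
      invisible(pm)
    },
    "classify" = {
      ft <- read_feature_table(opts$features)
      coh <- read_cohort(opts$cohort)
      mode <- if ((opts$mode %||% "two") == "four") "four_group" else "two_group"
      runs <- run_repeated_cv(ft, coh, mode,
                              n_repetitions = getn("reps", 50),
                              k = getn("folds", 10), seed = seed,
                              stratify = isTRUE(opts$stratify == "true"))
      sc <- most_frequent_scenario(runs)
      conf <- confusion_summary(runs$truth, sc$predictions, mode)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(
        data.frame(repetition = seq_along(runs$accuracies),
                   accuracy = runs$accuracies),
        file.path(out, "cv_accuracies.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(
        data.frame(metric = names(conf$counts),
                   count = as.integer(conf$counts),
                   percent = as.numeric(conf$percent)),
        file.path(out, "confusion.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(
        list(mean_accuracy = runs$mean_accuracy,
             sd_accuracy = runs$sd_accuracy,
             scenario_count = sc$count, scenario_repetition = sc$repetition,
             sensitivity = conf$sensitivity, specificity = conf$specificity),
        file.path(out, "scenario.json"), digits = NA, auto_unbox = TRUE)
      invisible(list(runs = runs, confusion = conf))
    },
    "posthoc" = {
      ft <- read_feature_table(opts$features)
      coh <- read_cohort(opts$cohort)
      res <- screen_features(ft, coh, alpha = getn("alpha", 0.05),
                             anova_method = opts$anova %||% "oneway")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(res, file.path(out, "posthoc_screen.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(res)
    },
    "mds" = {
      ft <- read_feature_table(opts$features)
      coh <- if (!is.null(opts$cohort)) read_cohort(opts$cohort) else NULL
      emb <- classical_mds(if ((opts$input %||% "features") == "distances")
        ft else standardize(ft)$x,
        n_dims = getn("dims", 3),
        input = opts$input %||% "features")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      export_embedding(emb, file.path(out, "mds_embedding.tsv"), coh)
      invisible(emb)
    },
    "run-study" = {
      cfg <- study_config(seed = seed)
      if (!is.null(opts$config)) {
        ov <- read_config_file(opts$config)
        for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
      }
      if (!is.null(opts[["feature-set"]])) {
        cfg$feature_set <- opts[["feature-set"]]
      }
      if (!is.null(opts$reps)) cfg$n_repetitions <- as.integer(opts$reps)
      run_study(cfg, out_dir = out)
    },
    {
      cat(usage, "\n")
      stop("unknown subcommand: ", cmd)
    }
  )
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("expected --flag, got: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- "true"
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

# JSON (always) or YAML (if the yaml package is installed) config blocks.
read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
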