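#' Generate a synthetic case-control cohort
#'
#' Builds a subject covariate table for a four-cell diagnosis-by-sex design
#' (ASD male, ASD female, TD male, TD female). Ages are drawn uniformly on
#' `age_range`, acquisition sites are assigned either uniformly at random or
#' round-robin, and total intracranial volume (TICV) is drawn from a
#' log-normal distribution with the requested mean and standard deviation so
#' that it is strictly positive.
#'
#' @param n_per_cell integer vector of length 4: counts for the ASD-M, ASD-F,
#'   TD-M and TD-F cells (in that order).
#' @param n_sites number of acquisition sites (>= 1).
#' @param age_range numeric length-2 interval in years, both endpoints > 0.
#' @param ticv_mean,ticv_sd mean and SD of TICV in mm^3.
#' @param site_assignment `"random"` (uniform, default) or `"round_robin"`.
#' @param seed integer seed; identical arguments and seed give identical
#'   tables.
#' @return A `cohort_table`: a data.frame with columns `subject_id`,
#'   `diagnosis` (factor ASD/TD), `sex` (factor M/F), `age`, `site` (factor)
#'   and `ticv`.
#' @examples
#' coh <- generate_cohort(c(55, 55, 43, 40), n_sites = 4, seed = 1)
#' table(coh$diagnosis)
#' @export
generate_cohort <- function(n_per_cell = c(55, 55, 43, 40),
                            n_sites = 4,
                            age_range = c(8, 18),
                            ticv_mean = 1.45e6,
                            ticv_sd = 1.4e5,
                            site_assignment = c("random", "round_robin"),
                            seed = 1) {
  site_assignment <- match.arg(site_assignment)
  if (length(n_per_cell) != 4 || any(n_per_cell < 1) ||
      any(n_per_cell != round(n_per_cell))) {
    stop("`n_per_cell` must be four positive integers (ASD-M, ASD-F, TD-M, TD-F)")
  }
  if (n_sites < 1) stop("`n_sites` must be >= 1")
  if (length(age_range) != 2 || diff(age_range) <= 0 || any(age_range <= 0)) {
    stop("`age_range` must be a non-empty positive interval")
  }
  if (ticv_mean <= 0 || ticv_sd <= 0) stop("TICV mean and SD must be positive")

  n <- sum(n_per_cell)
  withr_seed(seed, {
    diagnosis <- factor(rep(c("ASD", "ASD", "TD", "TD"), n_per_cell),
                        levels = c("ASD", "TD"))
    sex <- factor(rep(c("M", "F", "M", "F"), n_per_cell), levels = c("M", "F"))
    age <- stats::runif(n, age_range[1], age_range[2])
    site <- if (site_assignment == "round_robin") {
      factor(rep_len(seq_len(n_sites), n), levels = seq_len(n_sites))
    } else {
      factor(sample.int(n_sites, n, replace = TRUE), levels = seq_len(n_sites))
    }
    # log-normal with moment-matched mean/SD keeps TICV > 0
    cv2 <- (ticv_sd / ticv_mean)^2
    sdlog <- sqrt(log1p(cv2))
    meanlog <- log(ticv_mean) - sdlog^2 / 2
    ticv <- stats::rlnorm(n, meanlog, sdlog)
    out <- data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      diagnosis = diagnosis, sex = sex, age = age, site = site, ticv = ticv,
      stringsAsFactors = FALSE
    )
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Four-group cell labels of a cohort
#'
#' Interaction of diagnosis and sex, with levels ordered
#' ASD_M, ASD_F, TD_M, TD_F.
#' @param cohort a `cohort_table`.
#' @return factor of length `nrow(cohort)`.
#' @export
cohort_groups <- function(cohort) {
  factor(paste(cohort$diagnosis, cohort$sex, sep = "_"),
         levels = c("ASD_M", "ASD_F", "TD_M", "TD_F"))
}

#' Effect specification for synthetic regional feature tables
#'
#' Describes the linear-additive generative model for one feature table:
#' per-measure baseline means and noise standard deviations, plus effect
#' coefficients expressed in units of the per-measure noise SD. Setting all
#' coefficients to zero gives the null configuration.
#'
#' @param n_regions number of brain regions (default 165).
#' @param baseline named numeric: per-measure baseline mean, in the measure's
#'   native unit (mm, mm^2, mm^3, dimensionless, dimensionless).
#' @param noise_sd named numeric: per-measure Gaussian noise SD (> 0).
#' @param beta_dx,beta_sex,beta_int diagnosis (ASD), sex (F) and
#'   diagnosis-by-sex interaction effects, in noise-SD units.
#' @param beta_age age slope in noise-SD units per year.
#' @param site_offsets numeric vector of per-site additive shifts in noise-SD
#'   units (recycled over sites), or a single value applied to all sites.
#' @param affected_fraction fraction of regions carrying the diagnosis, sex
#'   and interaction effects; the first `ceiling(fraction * n_regions)`
#'   regions are affected.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(n_regions = 165,
                        baseline = c(thickness = 2.5, area = 700,
                                     volume = 1800, curvature = 0.12,
                                     CD = 0.5),
                        noise_sd = c(thickness = 0.15, area = 70,
                                     volume = 200, curvature = 0.02,
                                     CD = 0.08),
                        beta_dx = 0, beta_sex = 0, beta_int = 0,
                        beta_age = 0,
                        site_offsets = 0,
                        affected_fraction = 1) {
  measures <- c("thickness", "area", "volume", "curvature", "CD")
  if (n_regions < 1) stop("`n_regions` must be >= 1")
  if (!all(measures %in% names(baseline)) ||
      !all(measures %in% names(noise_sd))) {
    stop("`baseline` and `noise_sd` must name all five measures")
  }
  if (any(noise_sd[measures] <= 0)) stop("noise SDs must be strictly positive")
  if (affected_fraction < 0 || affected_fraction > 1) {
    stop("`affected_fraction` must be in [0, 1]")
  }
  structure(list(
    n_regions = n_regions, measures = measures,
    baseline = baseline[measures], noise_sd = noise_sd[measures],
    beta_dx = beta_dx, beta_sex = beta_sex, beta_int = beta_int,
    beta_age = beta_age, site_offsets = site_offsets,
    affected_fraction = affected_fraction
  ), class = "effect_spec")
}

#' Generate a synthetic regional feature table
#'
#' Draws a subjects x (region, measure) matrix under the linear-additive
#' Gaussian model of an [effect_spec()]: for subject s and feature (r, m)
#'
#' value = baseline_m + sd_m * (b_dx 1\[ASD\] + b_sex 1\[F\] +
#'         b_int 1\[ASD\]1\[F\] + b_age age_s + site shift) + noise,
#'
#' where effects apply only to the affected regions. Area and volume columns
#' are additionally scaled multiplicatively by `ticv / mean(ticv)` so the
#' downstream TICV normalization has something to undo.
#'
#' @param cohort a `cohort_table`.
#' @param spec an `effect_spec`; `spec$n_regions` sets the region count.
#' @param seed integer seed.
#' @return numeric matrix with `nrow(cohort)` rows and `n_regions * 5`
#'   columns named `<region>__<measure>`; rownames are subject ids.
#' @examples
#' coh <- generate_cohort(c(5, 5, 5, 5), n_sites = 2, seed = 1)
#' ft <- generate_feature_table(coh, effect_spec(n_regions = 3), seed = 1)
#' dim(ft)  # 20 x 15
#' @export
generate_feature_table <- function(cohort, spec = effect_spec(), seed = 1) {
  stopifnot(inherits(spec, "effect_spec"))
  n <- nrow(cohort)
  R <- spec$n_regions
  measures <- spec$measures
  n_sites <- nlevels(cohort$site)
  site_shift <- rep_len(spec$site_offsets, n_sites)

  n_affected <- ceiling(spec$affected_fraction * R)
  affected <- seq_len(R) <= n_affected

  is_asd <- as.numeric(cohort$diagnosis == "ASD")
  is_f <- as.numeric(cohort$sex == "F")
  subj_fixed <- spec$beta_age * cohort$age +
    site_shift[as.integer(cohort$site)]
  subj_eff <- spec$beta_dx * is_asd + spec$beta_sex * is_f +
    spec$beta_int * is_asd * is_f
  ticv_scale <- cohort$ticv / mean(cohort$ticv)

  withr_seed(seed, {
    out <- matrix(NA_real_, n, R * length(measures))
    cn <- character(R * length(measures))
    col <- 0L
    for (r in seq_len(R)) {
      for (m in measures) {
        col <- col + 1L
        cn[col] <- sprintf("region_%03d__%s", r, m)
        mu <- spec$baseline[[m]] + spec$noise_sd[[m]] *
          (subj_fixed + if (affected[r]) subj_eff else 0)
        v <- mu + stats::rnorm(n, 0, spec$noise_sd[[m]])
        if (m %in% c("area", "volume")) v <- v * ticv_scale
        out[, col] <- v
      }
    }
    dimnames(out) <- list(cohort$subject_id, cn)
    out
  })
}

#' Parse `<region>__<measure>` column names
#' @param colnames character vector of feature-table column names.
#' @return data.frame with columns `region` and `measure`.
#' @export
parse_feature_names <- function(colnames) {
  parts <- strsplit(colnames, "__", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop("malformed feature names (expected `<region>__<measure>`): ",
         paste(colnames[bad], collapse = ", "))
  }
  data.frame(region = vapply(parts, `[`, "", 1),
             measure = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write cohort and feature tables as TSV
#'
#' Cohort tables are written with a one-line header and tab separators;
#' feature tables carry the subject id in the first column.
#'
#' @param path file path.
#' @param cohort,table objects to write.
#' @name cohort_io
#' @return `read_cohort` returns a `cohort_table`; `read_feature_table`
#'   returns a numeric matrix with subject-id rownames.
#' @export
read_cohort <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  x$diagnosis <- factor(x$diagnosis, levels = c("ASD", "TD"))
  x$sex <- factor(x$sex, levels = c("M", "F"))
  x$site <- factor(x$site)
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' @rdname cohort_io
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(subject_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
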