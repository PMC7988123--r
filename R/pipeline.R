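oft_trait_names <- c("stai_trait", "asi3_physical", "asi3_cognitive",
                     "asi3_social", "acq_physical", "acq_loss_of_control",
                     "mi_accompanied", "mi_alone")
oft_behavior_names <- c("time_outer", "pct_thigmotaxis", "pct_center_entry")

#' Center-avoidance direction of a correlation coefficient
#'
#' A trait-behavior correlation counts toward "more center avoidance with
#' higher anxiety" when its sign is positive for time in the outer region
#' and for the thigmotaxis proportion, and negative for the center-entry
#' proportion. Isolated here so the direction coding is auditable in one
#' place.
#'
#' @param behavior One of `"time_outer"`, `"pct_thigmotaxis"`,
#'   `"pct_center_entry"`.
#' @param r Correlation coefficient.
#'
#' @return Logical: does the coefficient point in the avoidance direction?
#'   Zero coefficients count as not avoidance-direction.
#' @export
is_avoidance_direction <- function(behavior, r) {
  stopifnot(behavior %in% oft_behavior_names)
  if (behavior == "pct_center_entry") r < 0 else r > 0
}

cohort_index_table <- function(cohort) {
  arena <- cohort$config$null_config$arena
  grid <- bin_grid(arena)
  do.call(rbind, lapply(cohort$trajectories, compute_indices,
                        arena = arena, grid = grid))
}

tidy_stat_row <- function(index, st, mu = NA_real_) {
  data.frame(index = index, mu = mu, statistic = st$statistic,
             df = st$df[1], p = st$p, effect_size = st$effect_size,
             ci_lower = st$effect_ci[1], ci_upper = st$effect_ci[2],
             n = st$n, stringsAsFactors = FALSE)
}

#' Analyze one experiment cohort against null-model expectations
#'
#' Runs the full inferential sequence for one experiment: one-sample
#' t-tests of each behavioral index against its null-model expectation
#' (and of time in the outer region against the 450 s equal-occupancy
#' reference), paired t-tests of path length and walking speed in the
#' outer vs inner region, the 8 traits x 3 behaviors correlation table
#' with Bonferroni threshold, the center-avoidance sign count, the
#' position-ratings repeated-measures ANOVAs, and the cohort occupancy
#' heatmap.
#'
#' @param cohort An `oft_cohort` (or any list with `trajectories`,
#'   `traits`, `ratings` and a `config` holding the null config).
#' @param null_mu An [expected_values()] result supplying the per-index
#'   reference means.
#' @param alpha Experiment-wise alpha for the Bonferroni threshold.
#' @param heatmap_resolution Cell side in meters for the occupancy
#'   heatmap.
#'
#' @return An object of class `oft_report`: a list with `indices`,
#'   `one_sample`, `paired`, `correlations`, `bonferroni_alpha`,
#'   `sign_count` (k and m), `ratings_anova`, `heatmap` and `n`.
#' @export
analyze_experiment <- function(cohort, null_mu, alpha = 0.05,
                               heatmap_resolution = 2) {
  stopifnot(inherits(null_mu, "oft_expected"))
  idx <- cohort_index_table(cohort)
  if (nrow(idx) < 3) {
    stop("need at least 3 participants with complete indices", call. = FALSE)
  }

  mu_keys <- c(time_outer = "time_outer",
               mean_wall_distance = "mean_wall_distance",
               pct_thigmotaxis = "pct_thigmotaxis",
               pct_center_entry = "pct_center_entry",
               pct_center_ambulation = "pct_center_ambulation",
               pct_center_leave = "pct_center_leave")
  one_sample <- do.call(rbind, lapply(names(mu_keys), function(key) {
    mu <- null_mu$mean[[mu_keys[[key]]]]
    tidy_stat_row(paste0(key, "_vs_mu"), one_sample_t(idx[[key]], mu), mu)
  }))
  one_sample <- rbind(
    one_sample,
    tidy_stat_row("time_outer_vs_450",
                  one_sample_t(idx$time_outer,
                               cohort$config$null_config$arena$session_duration / 2),
                  cohort$config$null_config$arena$session_duration / 2))

  paired <- rbind(
    tidy_stat_row("path_outer_minus_inner",
                  paired_t(idx$path_outer, idx$path_inner)),
    tidy_stat_row("speed_outer_minus_inner",
                  paired_t(idx$speed_outer, idx$speed_inner)))

  traits <- cohort$traits
  missing_traits <- setdiff(oft_trait_names, names(traits))
  if (length(missing_traits) > 0) {
    stop("missing trait column(s): ",
         paste(missing_traits, collapse = ", "), call. = FALSE)
  }
  merged <- merge(traits, idx, by = "participant_id")
  cor_rows <- list()
  for (trait in oft_trait_names) {
    for (behavior in oft_behavior_names) {
      res <- pearson_r(merged[[trait]], merged[[behavior]])
      cor_rows[[length(cor_rows) + 1]] <- data.frame(
        trait = trait, behavior = behavior, r = res$r, p = res$p,
        n = res$n,
        avoidance_direction = is_avoidance_direction(behavior, res$r),
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cor_rows)

  ratings_anova <- list()
  for (measure in c("anxiety", "arousal")) {
    cols <- paste(measure, rating_positions, sep = "_")
    if (all(cols %in% names(cohort$ratings))) {
      ratings_anova[[measure]] <-
        rm_anova_gg(as.matrix(cohort$ratings[cols]))
    }
  }

  structure(
    list(indices = idx,
         one_sample = one_sample,
         paired = paired,
         correlations = correlations,
         bonferroni_alpha = bonferroni_threshold(alpha, nrow(correlations)),
         sign_count = list(k = sum(correlations$avoidance_direction),
                           m = nrow(correlations)),
         ratings_anova = ratings_anova,
         heatmap = occupancy_heatmap(cohort$trajectories,
                                     cohort$config$null_config$arena,
                                     heatmap_resolution),
         n = nrow(idx)),
    class = "oft_report"
  )
}

#' @export
print.oft_report <- function(x, ...) {
  cat(sprintf("Open-field experiment report (n = %d)\n", x$n))
  cat(sprintf("  %d one-sample tests, %d paired tests, %d correlations (Bonferroni alpha = %.4g)\n",
              nrow(x$one_sample), nrow(x$paired), nrow(x$correlations),
              x$bonferroni_alpha))
  cat(sprintf("  avoidance-direction coefficients: %d of %d\n",
              x$sign_count$k, x$sign_count$m))
  invisible(x)
}

#' Pooled correlation-sign test across experiments
#'
#' Counts avoidance-direction coefficients over the correlation tables of
#' several experiment reports (24 per experiment, 72 over three) and
#' tests the count against an equal split with [sign_count_chisq()].
#'
#' @param reports A list of `oft_report` objects.
#'
#' @return As [sign_count_chisq()].
#' @export
pooled_sign_test <- function(reports) {
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "oft_report")))
  expected_cells <- length(oft_trait_names) * length(oft_behavior_names)
  for (rep in reports) {
    if (nrow(rep$correlations) != expected_cells) {
      stop("incomplete correlation table: expected ", expected_cells,
           " cells, found ", nrow(rep$correlations), call. = FALSE)
    }
  }
  k <- sum(vapply(reports, function(r) r$sign_count$k, numeric(1)))
  m <- sum(vapply(reports, function(r) r$sign_count$m, numeric(1)))
  sign_count_chisq(k, m)
}

#' Full-study run configuration
#'
#' @param experiments Named list, one entry per experiment: either an
#'   [cohort_config()] (a synthetic cohort to generate) or a character
#'   path to a cohort directory in the [write_cohort()] layout.
#' @param null_config An [null_model_config()] for the expected values;
#'   its seed is derived from the master seed.
#' @param alpha Experiment-wise alpha.
#' @param out_dir Output directory.
#' @param seed Master seed; stage seeds are derived as
#'   `seed * 100 + stage` (null model stage 1, experiment cohorts stages
#'   2, 3, ...), so one integer pins the whole run.
#'
#' @return An object of class `oft_run_config`.
#' @export
run_config <- function(experiments, null_config = null_model_config(),
                       alpha = 0.05, out_dir, seed) {
  ok <- vapply(experiments, function(e) {
    inherits(e, "oft_cohort_config") ||
      (is.character(e) && length(e) == 1)
  }, logical(1))
  stopifnot(length(experiments) >= 1, all(ok))
  if (is.null(names(experiments)) || any(names(experiments) == "")) {
    names(experiments) <- sprintf("experiment%d", seq_along(experiments))
  }
  structure(
    list(experiments = experiments, null_config = null_config,
         alpha = alpha, out_dir = out_dir, seed = as.integer(seed)),
    class = "oft_run_config"
  )
}

write_report_tables <- function(report, dir, name) {
  utils::write.csv(report$indices,
                   file.path(dir, paste0(name, "_indices.csv")),
                   row.names = FALSE)
  utils::write.csv(report$one_sample,
                   file.path(dir, paste0(name, "_one_sample.csv")),
                   row.names = FALSE)
  utils::write.csv(report$paired,
                   file.path(dir, paste0(name, "_paired.csv")),
                   row.names = FALSE)
  utils::write.csv(report$correlations,
                   file.path(dir, paste0(name, "_correlations.csv")),
                   row.names = FALSE)
  anova_rows <- do.call(rbind, lapply(names(report$ratings_anova), function(m) {
    st <- report$ratings_anova[[m]]
    data.frame(measure = m, f = st$statistic, df1 = st$df[1],
               df2 = st$df[2], p = st$p, eta2p = st$effect_size,
               ci_lower = st$effect_ci[1], ci_upper = st$effect_ci[2],
               epsilon = st$epsilon, gg_applied = st$gg_applied,
               n = st$n, stringsAsFactors = FALSE)
  }))
  if (!is.null(anova_rows)) {
    utils::write.csv(anova_rows,
                     file.path(dir, paste0(name, "_ratings_anova.csv")),
                     row.names = FALSE)
  }
  utils::write.table(report$heatmap,
                     file.path(dir, paste0(name, "_heatmap.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
}

#' Run the complete analysis pipeline
#'
#' End-to-end orchestration: simulates the null model and writes its
#' expected values, generates (or analyzes) each experiment cohort,
#' writes per-experiment index and result tables, pools the
#' correlation-sign test across experiments, and records a JSON run
#' manifest with every derived seed and a config hash. Deterministic
#' given the master seed: re-running with the same config yields
#' byte-identical outputs.
#'
#' @param cfg An [run_config()].
#'
#' @return The output directory, invisibly; the assembled results (null
#'   expectations, reports, pooled sign test) as attribute `"results"`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "oft_run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  null_cfg <- cfg$null_config
  null_cfg$seed <- cfg$seed * 100 + 1
  mu <- expected_values(null_cfg)
  ev <- data.frame(index = names(mu$mean), mean = unname(mu$mean),
                   se = unname(mu$se), stringsAsFactors = FALSE)
  utils::write.csv(ev, file.path(cfg$out_dir, "expected_values.csv"),
                   row.names = FALSE)

  reports <- list()
  for (i in seq_along(cfg$experiments)) {
    name <- names(cfg$experiments)[i]
    ecfg <- cfg$experiments[[i]]
    if (is.character(ecfg)) {
      cohort <- read_cohort(ecfg, arena = cfg$null_config$arena)
    } else {
      ecfg$seed <- cfg$seed * 100 + 1 + i
      cohort <- generate_cohort(ecfg)
    }
    reports[[name]] <- analyze_experiment(cohort, mu, alpha = cfg$alpha)
    write_report_tables(reports[[name]], cfg$out_dir, name)
  }

  pooled <- pooled_sign_test(reports)
  utils::write.csv(
    data.frame(k = pooled$k, n = pooled$n, chisq = pooled$statistic,
               df = pooled$df, p = pooled$p),
    file.path(cfg$out_dir, "pooled_sign_test.csv"), row.names = FALSE)

  cfg_for_hash <- cfg
  cfg_for_hash$out_dir <- NULL
  cfg_json <- jsonlite::serializeJSON(cfg_for_hash)
  hash_file <- tempfile()
  writeLines(cfg_json, hash_file)
  manifest <- list(
    master_seed = cfg$seed,
    null_seed = null_cfg$seed,
    experiment_seeds = stats::setNames(
      as.list(cfg$seed * 100 + 1 + seq_along(cfg$experiments)),
      names(cfg$experiments)),
    config_md5 = unname(tools::md5sum(hash_file)),
    n_runs = null_cfg$n_runs,
    experiments = names(cfg$experiments)
  )
  unlink(hash_file)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  out <- cfg$out_dir
  attr(out, "results") <- list(expected = mu, reports = reports,
                               pooled_sign = pooled)
  invisible(out)
}
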