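#' One wall-biased teleport step
#'
#' Proposes destinations exactly like [sim_step()] and thins them by a
#' Metropolis-style acceptance probability decreasing in the destination's
#' wall distance: a proposal at normalized wall distance
#' `w = d_wall / (side / 2)` (0 at a wall, 1 at the center) is accepted
#' with probability `exp(-beta * w)` for `beta > 0` and
#' `exp(beta * (1 - w))` for `beta < 0`, so the maximum acceptance
#' probability is always 1 and `beta = 0` accepts every in-arena proposal
#' without consuming an extra random draw — making the unbiased agent
#' byte-identical to [sim_step()] under a shared seed. Positive `beta`
#' attracts the agent to the walls, negative `beta` to the center.
#'
#' @param pose A list with `x`, `y`, `heading`.
#' @param beta Wall-attraction coefficient (finite; dimensionless).
#' @param cfg An [null_model_config()].
#'
#' @return The new pose; raises a simulation error after `max_reject`
#'   consecutive rejections.
#' @export
biased_step <- function(pose, beta, cfg) {
  if (!is.finite(beta)) stop("'beta' must be finite", call. = FALSE)
  if (beta == 0) return(sim_step(pose, cfg))
  side <- cfg$arena$side_length
  sigma_rad <- cfg$heading_sigma * pi / 180
  shift <- max(0, -beta)     # normalizes max acceptance probability to 1
  for (i in seq_len(cfg$max_reject)) {
    heading <- pose$heading + stats::rnorm(1, 0, sigma_rad)
    d <- sample_distance(cfg$distance_sampler, 1)
    x <- pose$x + d * cos(heading)
    y <- pose$y + d * sin(heading)
    if (x >= 0 && x <= side && y >= 0 && y <= side) {
      w <- min(x, side - x, y, side - y) / (side / 2)
      if (stats::runif(1) < exp(-beta * w - shift)) {
        return(list(x = x, y = y, heading = heading))
      }
    }
  }
  stop(sprintf(
    "simulation error: %d consecutive proposals rejected at (%.2f, %.2f)",
    cfg$max_reject, pose$x, pose$y), call. = FALSE)
}

#' Default trait-questionnaire generating spec
#'
#' One row per instrument scale: the latent (pre-clipping) mean and sd on
#' the instrument scale, the loading of the scale on the shared anxiety
#' factor, the legal score range, and the rounding applied (0 digits for
#' integer sum scores, 2 for item-mean scales). Defaults reflect
#' unselected community samples: STAI trait around 37 +/- 9, ASI-3
#' subscales summing to a total near 18, ACQ and MI item means in the
#' lower fifth of their 1-5 range. The STAI trait scale, the core measure
#' of trait anxiety, carries the highest loading on the shared anxiety
#' factor. Clipping to the instrument range
#' shrinks extreme configurations' moments; callers matching target
#' descriptives should verify the realized moments.
#'
#' @return A data.frame with columns `trait`, `mean`, `sd`, `loading`,
#'   `min`, `max`, `digits`.
#' @export
default_trait_spec <- function() {
  data.frame(
    trait = c("stai_trait", "asi3_physical", "asi3_cognitive", "asi3_social",
              "acq_physical", "acq_loss_of_control",
              "mi_alone", "mi_accompanied"),
    mean = c(37, 5.5, 5, 7.5, 1.5, 1.8, 1.5, 1.3),
    sd = c(9, 5.2, 5.0, 5.2, 0.45, 0.55, 0.5, 0.4),
    loading = c(0.85, 0.55, 0.55, 0.55, 0.6, 0.6, 0.5, 0.5),
    min = c(20, 0, 0, 0, 1, 1, 1, 1),
    max = c(80, 24, 24, 24, 5, 5, 5, 5),
    digits = c(0, 0, 0, 0, 2, 2, 2, 2),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-cohort configuration
#'
#' Parameters for [generate_cohort()]: cohort size, the base agent
#' configuration, the distribution of the per-participant wall-attraction
#' coefficient beta, the target correlation between the latent anxiety
#' factor and beta, the trait-score generating spec, and the
#' position-rating model (anxiety/arousal probes at the center, wall and
#' corner of the arena on a 0-100 distress scale).
#'
#' @param n_participants Cohort size (>= 2).
#' @param null_config An [null_model_config()] describing arena and
#'   movement kernel.
#' @param wall_bias_mean,wall_bias_sd Mean and sd of beta across
#'   participants.
#' @param trait_behavior_rho Correlation between the latent anxiety factor
#'   and beta, in `[-1, 1]`.
#' @param trait_spec Trait generating table, see [default_trait_spec()].
#' @param rating_effect Rating-point difference between the center and a
#'   corner (default 0: position has no effect, matching a null outcome;
#'   set positive as an ANOVA positive control).
#' @param rating_base Baseline rating (at a corner) for anxiety and
#'   arousal.
#' @param rating_sd Rating noise sd in points.
#' @param missing_rating_rate Probability that any single rating is
#'   missing.
#' @param seed Integer master seed (required).
#'
#' @return An object of class `oft_cohort_config`.
#' @export
cohort_config <- function(n_participants,
                          null_config = null_model_config(),
                          wall_bias_mean = 1.5, wall_bias_sd = 1.5,
                          trait_behavior_rho = 0,
                          trait_spec = default_trait_spec(),
                          rating_effect = 0,
                          rating_base = c(anxiety = 30, arousal = 40),
                          rating_sd = 15,
                          missing_rating_rate = 0,
                          seed) {
  stopifnot(inherits(null_config, "oft_null_config"))
  if (n_participants < 2) stop("'n_participants' must be >= 2", call. = FALSE)
  if (abs(trait_behavior_rho) > 1) {
    stop("'trait_behavior_rho' must lie in [-1, 1]", call. = FALSE)
  }
  if (missing_rating_rate < 0 || missing_rating_rate >= 1) {
    stop("'missing_rating_rate' must lie in [0, 1)", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("a 'seed' is required for cohort generation", call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         null_config = null_config,
         wall_bias_mean = wall_bias_mean, wall_bias_sd = wall_bias_sd,
         trait_behavior_rho = trait_behavior_rho,
         trait_spec = trait_spec,
         rating_effect = rating_effect, rating_base = rating_base,
         rating_sd = rating_sd,
         missing_rating_rate = missing_rating_rate,
         seed = as.integer(seed)),
    class = "oft_cohort_config"
  )
}

rating_positions <- c("center", "wall", "corner")
# proximity-to-center weight of each rating probe
rating_centrality <- c(center = 1, wall = 0.5, corner = 0)

#' Generate a synthetic participant cohort
#'
#' Produces a full cohort for pipeline testing. Per participant, a latent
#' anxiety factor `z ~ N(0, 1)` drives (a) the wall-attraction coefficient
#' `beta = mean + sd * (rho * z + sqrt(1 - rho^2) * eps)`, (b) every trait
#' score via its loading (`score = mean + sd * (loading * z +
#' sqrt(1 - loading^2) * noise)`, rounded and clipped to the instrument
#' range, with the ASI-3 total formed as the sum of its three subscales),
#' and (c) nothing of the ratings, which are position effects plus noise.
#' Trajectories come from the wall-biased teleport agent ([biased_step()])
#' with start poses cycled across participants.
#'
#' @param cfg An [cohort_config()].
#' @param simulate_trajectories Set `FALSE` to skip trajectory simulation
#'   and generate traits, ratings and ground truth only — useful for
#'   large-sample studies of the trait generator itself.
#'
#' @return An object of class `oft_cohort`: a list with `trajectories`
#'   (list of `oft_trajectory`, empty when skipped), `traits` (data.frame,
#'   one row per participant), `ratings` (wide data.frame: measure x
#'   position columns), `ground_truth` (participant_id, latent `z`, true
#'   `beta`, start label, trajectory seed) and `config`.
#' @export
generate_cohort <- function(cfg, simulate_trajectories = TRUE) {
  stopifnot(inherits(cfg, "oft_cohort_config"))
  n <- cfg$n_participants
  ncfg <- cfg$null_config
  set.seed(cfg$seed)

  z <- stats::rnorm(n)
  eps <- stats::rnorm(n)
  rho <- cfg$trait_behavior_rho
  beta <- cfg$wall_bias_mean +
    cfg$wall_bias_sd * (rho * z + sqrt(1 - rho^2) * eps)

  spec <- cfg$trait_spec
  traits <- data.frame(participant_id = sprintf("p%03d", seq_len(n)),
                       stringsAsFactors = FALSE)
  for (j in seq_len(nrow(spec))) {
    a <- spec$loading[j]
    raw <- spec$mean[j] + spec$sd[j] *
      (a * z + sqrt(1 - a^2) * stats::rnorm(n))
    traits[[spec$trait[j]]] <-
      pmin(pmax(round(raw, spec$digits[j]), spec$min[j]), spec$max[j])
  }
  if (all(c("asi3_physical", "asi3_cognitive", "asi3_social") %in%
          names(traits))) {
    traits$asi3_total <- traits$asi3_physical + traits$asi3_cognitive +
      traits$asi3_social
  }

  ratings <- data.frame(participant_id = traits$participant_id,
                        stringsAsFactors = FALSE)
  for (measure in names(cfg$rating_base)) {
    for (pos in rating_positions) {
      val <- cfg$rating_base[[measure]] +
        cfg$rating_effect * rating_centrality[[pos]] +
        stats::rnorm(n, 0, cfg$rating_sd)
      val <- pmin(pmax(val, 0), 100)
      if (cfg$missing_rating_rate > 0) {
        val[stats::runif(n) < cfg$missing_rating_rate] <- NA_real_
      }
      ratings[[paste(measure, pos, sep = "_")]] <- val
    }
  }

  # per-participant trajectory seeds drawn from the master stream
  traj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  start_labels <- ncfg$start_positions[(seq_len(n) - 1) %%
                                         length(ncfg$start_positions) + 1]
  trajectories <- list()
  if (simulate_trajectories) {
    trajectories <- vector("list", n)
    for (i in seq_len(n)) {
      trajectories[[i]] <- simulate_run(
        ncfg, start_labels[i], seed = traj_seeds[i], wall_bias = beta[i],
        participant_id = traits$participant_id[i],
        experiment_id = "synthetic"
      )
    }
  }

  structure(
    list(trajectories = trajectories, traits = traits, ratings = ratings,
         ground_truth = data.frame(
           participant_id = traits$participant_id, z = z, beta = beta,
           start_label = start_labels, traj_seed = traj_seeds,
           stringsAsFactors = FALSE),
         config = cfg),
    class = "oft_cohort"
  )
}

#' @export
print.oft_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic open-field cohort: %d participants, wall bias %.2f +/- %.2f, rho = %.2f\n",
    x$config$n_participants, x$config$wall_bias_mean,
    x$config$wall_bias_sd, x$config$trait_behavior_rho))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one canonical position log per participant plus a combined
#' traits/ratings CSV and a ground-truth CSV (latent factor and true beta)
#' for parameter-recovery checks.
#'
#' @param cohort An `oft_cohort`.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "oft_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arena <- cohort$config$null_config$arena
  for (traj in cohort$trajectories) {
    write_log(traj, file.path(dir, paste0(traj$participant_id, ".csv")),
              arena = arena)
  }
  utils::write.csv(merge(cohort$traits, cohort$ratings,
                         by = "participant_id"),
                   file.path(dir, "traits_ratings.csv"), row.names = FALSE)
  utils::write.csv(cohort$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Counterpart of [write_cohort()]: reads every participant position log
#' (canonical dialect) in `dir` plus the combined traits/ratings CSV.
#'
#' @param dir Directory written by [write_cohort()] (or hand-assembled in
#'   the same layout).
#' @param arena An [arena_spec()] for validation.
#'
#' @return An `oft_cohort` (without ground truth unless
#'   `ground_truth.csv` is present).
#' @export
read_cohort <- function(dir, arena = arena_spec()) {
  if (!dir.exists(dir)) {
    stop("cohort directory not found: ", dir, call. = FALSE)
  }
  tr_file <- file.path(dir, "traits_ratings.csv")
  if (!file.exists(tr_file)) {
    stop("cohort directory ", dir, " lacks traits_ratings.csv",
         call. = FALSE)
  }
  tab <- utils::read.csv(tr_file, stringsAsFactors = FALSE)
  logs <- setdiff(list.files(dir, pattern = "\\.csv$", full.names = TRUE),
                  c(tr_file, file.path(dir, "ground_truth.csv")))
  trajectories <- lapply(sort(logs), read_log, arena = arena)
  rating_cols <- grep("^(anxiety|arousal)_", names(tab), value = TRUE)
  gt_file <- file.path(dir, "ground_truth.csv")
  structure(
    list(trajectories = trajectories,
         traits = tab[setdiff(names(tab), rating_cols)],
         ratings = tab[c("participant_id", rating_cols)],
         ground_truth = if (file.exists(gt_file))
           utils::read.csv(gt_file, stringsAsFactors = FALSE) else NULL,
         config = list(null_config = null_model_config(arena))),
    class = "oft_cohort"
  )
}
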