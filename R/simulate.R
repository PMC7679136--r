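#' Configuration for the chase simulator
#'
#' Defaults mirror the study design the analysis expects: same-sex
#' groups of four mice, four baseline days plus one post-acute day,
#' and chase rates at which every dyad typically interacts daily.
#'
#' @param n_groups_per_sex Number of groups per sex (default 10 male /
#'   12 female is set at [simulate_chases()] level via this count;
#'   default here 10).
#' @param group_size Animals per group (default 4).
#' @param days Number of baseline days (default 4).
#' @param ability_sd Latent ability SD tau (default 1): spread of the
#'   per-animal dominance abilities.
#' @param discriminability Logistic slope beta (default 3): how
#'   strongly an ability gap decides who chases whom. 0 gives fair
#'   coin dyads; large beta gives near-deterministic hierarchies.
#' @param dyad_rate Expected encounters per unordered dyad per day,
#'   lambda (default 8).
#' @param post_acute_rate_factor Multiplier rho in (0, 1] applied to
#'   the dyad rate on the post-acute day (default 0.5), emulating the
#'   chase-rate drop after an acute stressor.
#' @param seed Integer seed.
#' @return A `chase_sim_config` list.
#' @export
chase_sim_config <- function(n_groups_per_sex = 10, group_size = 4,
                             days = 4, ability_sd = 1,
                             discriminability = 3, dyad_rate = 8,
                             post_acute_rate_factor = 0.5,
                             seed = 1L) {
  stopifnot(group_size >= 2, days >= 1, dyad_rate > 0,
            ability_sd >= 0, discriminability >= 0,
            post_acute_rate_factor > 0, post_acute_rate_factor <= 1)
  structure(list(
    n_groups_per_sex = as.integer(n_groups_per_sex),
    group_size = as.integer(group_size),
    days = as.integer(days),
    ability_sd = ability_sd,
    discriminability = discriminability,
    dyad_rate = dyad_rate,
    post_acute_rate_factor = post_acute_rate_factor,
    seed = as.integer(seed)
  ), class = "chase_sim_config")
}

#' Simulate chase-event logs from a latent-ability hierarchy
#'
#' Bradley-Terry-style generative model: each animal i in a group
#' draws a latent ability `theta_i ~ Normal(0, tau^2)`. On each day,
#' each unordered dyad \{i, j\} meets `K ~ Poisson(lambda)` times and
#' each encounter is attributed as i-chases-j with probability
#' `plogis(beta * (theta_i - theta_j))`. After the baseline days one
#' post-acute day is generated at rate `rho * lambda`. The true
#' abilities are attached for recovery checks.
#'
#' @param config A [chase_sim_config()].
#' @return A `chase_log` tibble; attribute `abilities` holds the
#'   latent `theta` per animal.
#' @export
simulate_chases <- function(config = chase_sim_config()) {
  stopifnot(inherits(config, "chase_sim_config"))
  set.seed(config$seed)
  n <- config$group_size
  dyads <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rows <- list()
  abilities <- list()
  for (sex in c("female", "male")) {
    for (g in seq_len(config$n_groups_per_sex)) {
      gid <- sprintf("%s_G%02d", ifelse(sex == "male", "M", "F"), g)
      ids <- sprintf("%s_m%d", gid, seq_len(n))
      theta <- stats::rnorm(n, 0, config$ability_sd)
      abilities[[gid]] <- tibble::tibble(
        group_id = gid, individual_id = ids, theta = theta
      )
      day_plan <- rbind(
        data.frame(day = seq_len(config$days), phase = "baseline",
                   rate = config$dyad_rate),
        data.frame(day = config$days + 1L, phase = "post_acute",
                   rate = config$dyad_rate *
                     config$post_acute_rate_factor)
      )
      for (r in seq_len(nrow(day_plan))) {
        for (d in seq_len(nrow(dyads))) {
          i <- dyads[d, 1]; j <- dyads[d, 2]
          k <- stats::rpois(1, day_plan$rate[r])
          if (k == 0) next
          p_ij <- stats::plogis(
            config$discriminability * (theta[i] - theta[j])
          )
          wins_i <- stats::rbinom(1, k, p_ij)
          if (wins_i > 0) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              group_id = gid, sex = sex, day = day_plan$day[r],
              phase = day_plan$phase[r], actor_id = ids[i],
              recipient_id = ids[j], count = wins_i
            )
          }
          if (k - wins_i > 0) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              group_id = gid, sex = sex, day = day_plan$day[r],
              phase = day_plan$phase[r], actor_id = ids[j],
              recipient_id = ids[i], count = k - wins_i
            )
          }
        }
      }
    }
  }
  abilities <- dplyr::bind_rows(abilities)
  roster <- dplyr::mutate(
    dplyr::select(abilities, "group_id", "individual_id"),
  )
  log <- as_chase_log(dplyr::bind_rows(rows), roster = roster)
  attr(log, "abilities") <- abilities
  log
}

#' Configuration for the outcome simulator
#'
#' Generates a post-stress outcome table with the structure the
#' analysis pipeline targets: batch offsets, sex and condition main
#' effects, and a dominance-by-sex interaction confined to the
#' stressed condition and loaded onto a shared latent factor carried
#' by a fraction of the variables.
#'
#' @param n_variables Number of readouts (default 20).
#' @param batch_offsets Numeric vector of per-batch additive offsets
#'   (default `c(0, 1)`, i.e. two batches).
#' @param sex_effect Additive effect of being male (default 0.5).
#' @param condition_effect Additive effect of the stressed condition
#'   (default 0.5).
#' @param interaction_loading Gamma: slope of centered dominance on
#'   the shared factor, positive in males and negative in females,
#'   stressed animals only (default 1).
#' @param shared_fraction Fraction of variables loading on the shared
#'   factor (default 0.5).
#' @param noise_sd Residual SD (default 1).
#' @param missing_rate Completely-at-random missingness rate (default
#'   0.02).
#' @param seed Integer seed.
#' @return An `outcome_sim_config` list.
#' @export
outcome_sim_config <- function(n_variables = 20,
                               batch_offsets = c(0, 1),
                               sex_effect = 0.5,
                               condition_effect = 0.5,
                               interaction_loading = 1,
                               shared_fraction = 0.5,
                               noise_sd = 1, missing_rate = 0.02,
                               seed = 1L) {
  stopifnot(n_variables >= 2, noise_sd > 0,
            missing_rate >= 0, missing_rate < 1,
            shared_fraction >= 0, shared_fraction <= 1)
  structure(list(
    n_variables = as.integer(n_variables),
    batch_offsets = batch_offsets,
    sex_effect = sex_effect,
    condition_effect = condition_effect,
    interaction_loading = interaction_loading,
    shared_fraction = shared_fraction,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "outcome_sim_config")
}

#' Simulate a post-stress outcome table
#'
#' Each variable v for animal i is
#' `y_iv = mu_v + batch_offset + sex_effect * 1[male] +
#' condition_effect * 1[stressed] + a_v * gamma * s(sex) *
#' (dominance_i - mean) * 1[stressed] + Normal(0, noise_sd)`,
#' with `s(male) = +1`, `s(female) = -1` and `a_v = 1` for the shared
#' fraction of variables. Missingness is applied completely at random.
#'
#' @param config An [outcome_sim_config()].
#' @param roster Data frame with `individual_id`, `sex`, and
#'   optionally `group_id`; `condition` and `batch` columns are used
#'   if present, otherwise assigned by alternating groups.
#' @param dominance Numeric vector of normalized dominance scores
#'   aligned with `roster` rows.
#' @return An `outcome_table` tibble with metadata columns, a
#'   `dominance` column and readout columns `V1..Vm`; attribute
#'   `shared_vars` marks the factor-loaded variables.
#' @export
simulate_outcomes <- function(config = outcome_sim_config(), roster,
                              dominance) {
  stopifnot(inherits(config, "outcome_sim_config"))
  roster <- tibble::as_tibble(roster)
  if (length(dominance) != nrow(roster)) {
    stop("dominance must align with roster rows", call. = FALSE)
  }
  set.seed(config$seed)
  n <- nrow(roster)
  m <- config$n_variables
  if (!"condition" %in% names(roster)) {
    grp <- if ("group_id" %in% names(roster)) {
      roster$group_id
    } else {
      roster$individual_id
    }
    lv <- unique(grp)
    cond_map <- stats::setNames(
      rep(c("CMS", "control"), length.out = length(lv)), lv
    )
    roster$condition <- unname(cond_map[grp])
  }
  if (!"batch" %in% names(roster)) {
    nb <- length(config$batch_offsets)
    grp <- if ("group_id" %in% names(roster)) {
      roster$group_id
    } else {
      roster$individual_id
    }
    lv <- unique(grp)
    batch_map <- stats::setNames(
      rep(paste0("B", seq_len(nb)), length.out = length(lv)), lv
    )
    roster$batch <- unname(batch_map[grp])
  }
  batch_idx <- match(roster$batch, unique(roster$batch))
  mu <- stats::rnorm(m, 0, 0.25)
  n_shared <- round(config$shared_fraction * m)
  a_v <- c(rep(1, n_shared), rep(0, m - n_shared))
  s_sex <- ifelse(roster$sex == "male", 1, -1)
  stressed <- as.numeric(roster$condition == "CMS")
  dom_c <- dominance - mean(dominance)
  Y <- matrix(NA_real_, n, m)
  for (v in seq_len(m)) {
    Y[, v] <- mu[v] +
      config$batch_offsets[batch_idx] +
      config$sex_effect * (roster$sex == "male") +
      config$condition_effect * stressed +
      a_v[v] * config$interaction_loading * s_sex * dom_c * stressed +
      stats::rnorm(n, 0, config$noise_sd)
  }
  if (config$missing_rate > 0) {
    Y[stats::runif(n * m) < config$missing_rate] <- NA_real_
  }
  colnames(Y) <- paste0("V", seq_len(m))
  out <- dplyr::bind_cols(
    roster[, intersect(c("individual_id", "group_id", "sex",
                         "condition", "batch"), names(roster))],
    tibble::tibble(dominance = dominance),
    tibble::as_tibble(Y)
  )
  structure(out, shared_vars = paste0("V", which(a_v == 1)),
            class = c("outcome_table", class(tibble::tibble())))
}
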