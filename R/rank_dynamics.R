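#' Daily rank trajectories over the baseline window
#'
#' Computes one dominance profile per baseline day (per group) plus the
#' cumulative profile over the whole window, and returns the daily
#' ranks alongside the final (cumulative) rank that each animal is
#' assigned.
#'
#' @param log A `chase_log`.
#' @param groups Group identifiers (default: all groups in the log).
#' @param baseline_days Integer vector of at least two baseline days
#'   (default `1:4`).
#' @param phase Phase label for the baseline window.
#' @inheritParams win_proportions
#' @return A `rank_trajectories` tibble with columns `group_id`, `sex`,
#'   `individual_id`, `day`, `daily_rank`, `daily_norm_ds`,
#'   `final_rank`.
#' @export
daily_trajectories <- function(log, groups = NULL, baseline_days = 1:4,
                               phase = "baseline", corrected = FALSE) {
  if (length(baseline_days) < 2) {
    stop("need at least two baseline days", call. = FALSE)
  }
  if (is.null(groups)) groups <- unique(log$group_id)
  res <- purrr::map_dfr(groups, function(g) {
    cum <- dominance_profile(log, g, baseline_days, phase, corrected)
    final <- stats::setNames(cum$rank, cum$individual_id)
    purrr::map_dfr(baseline_days, function(d) {
      daily <- suppressWarnings(
        dominance_profile(log, g, d, phase, corrected)
      )
      tibble::tibble(
        group_id = g,
        sex = daily$sex,
        individual_id = daily$individual_id,
        day = as.integer(d),
        daily_rank = daily$rank,
        daily_norm_ds = daily$norm_ds,
        final_rank = as.integer(final[daily$individual_id])
      )
    })
  })
  structure(res, baseline_days = baseline_days,
            class = c("rank_trajectories", class(tibble::tibble())))
}

#' Rank-maintenance counts by sex and final rank
#'
#' For every pair of consecutive baseline days, an individual scores a
#' success when its daily rank on day t+1 equals its daily rank on day
#' t (D-1 trials per individual over D days). Trials are aggregated
#' into strata defined by sex and the cumulative final rank, the
#' grouping used when comparing maintenance to the chance level.
#'
#' @param trajectories Output of [daily_trajectories()].
#' @param p0 Chance probability of maintaining a rank (default
#'   `1/N` computed from the ranks present; 0.25 for groups of four).
#' @return A `maintenance_table` tibble: `sex`, `final_rank`, `k`
#'   (successes), `n` (trials), `p0`, `p_value` (one-tailed exact
#'   binomial, upper tail), `odds_ratio_vs_chance`.
#' @export
maintenance_counts <- function(trajectories, p0 = NULL) {
  traj <- dplyr::arrange(tibble::as_tibble(trajectories),
                         .data$group_id, .data$individual_id, .data$day)
  if (is.null(p0)) {
    n_ranks <- length(unique(traj$final_rank))
    p0 <- 1 / n_ranks
  }
  trials <- dplyr::mutate(
    dplyr::group_by(traj, .data$group_id, .data$individual_id),
    success = .data$daily_rank == dplyr::lag(.data$daily_rank),
    .keep = "all"
  )
  trials <- dplyr::ungroup(trials)
  trials <- dplyr::filter(trials, !is.na(.data$success))
  tab <- dplyr::summarise(
    dplyr::group_by(trials, .data$sex, .data$final_rank),
    k = sum(.data$success), n = dplyr::n(), .groups = "drop"
  )
  chance <- p0
  tests <- purrr::map2(tab$k, tab$n, binomial_vs_chance, p0 = chance)
  tab$p0 <- chance
  tab$p_value <- purrr::map_dbl(tests, "p_value")
  tab$odds_ratio_vs_chance <- purrr::map_dbl(tests, "odds_ratio")
  structure(tab, class = c("maintenance_table",
                           class(tibble::tibble())))
}

#' One-tailed exact binomial test against a chance level
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`,
#' testing whether rank maintenance exceeds the chance level (0.25 for
#' four-rank hierarchies). Also reports the odds ratio of the observed
#' maintenance odds against the chance odds; `k = n` and `k = 0` give
#' infinite and zero odds ratios explicitly.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Chance probability, in (0, 1). Default 0.25.
#' @return A list with `p_value` and `odds_ratio`.
#' @export
binomial_vs_chance <- function(k, n, p0 = 0.25) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k < 0 || n < 1 || k > n || k != round(k) || n != round(n)) {
    stop("k and n must be integers with 0 <= k <= n", call. = FALSE)
  }
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  prop <- k / n
  or <- if (k == n) {
    Inf
  } else if (k == 0) {
    0
  } else {
    (prop / (1 - prop)) / (p0 / (1 - p0))
  }
  list(p_value = p, odds_ratio = or)
}

#' Persistence of David's Scores between two windows
#'
#' Pearson correlation between the scores of matched individuals in a
#' baseline profile and a later profile (e.g. the post-acute-restraint
#' day), quantifying how robust the hierarchy is to an acute stressor.
#'
#' @param baseline,later `dominance_profile` tibbles sharing
#'   individuals.
#' @param use Which score column to correlate (`"ds"` or `"norm_ds"`).
#' @return A tibble with `r`, `p_value`, `n` (two-sided p from the t
#'   distribution with n-2 degrees of freedom).
#' @export
ds_persistence <- function(baseline, later, use = c("ds", "norm_ds")) {
  use <- match.arg(use)
  m <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(baseline),
                  "individual_id", "group_id", b = dplyr::all_of(use)),
    dplyr::select(tibble::as_tibble(later),
                  "individual_id", "group_id", a = dplyr::all_of(use)),
    by = c("individual_id", "group_id")
  )
  if (nrow(m) < 3) stop("need at least 3 matched individuals",
                        call. = FALSE)
  ct <- stats::cor.test(m$b, m$a, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(m))
}

#' Repeated-measures ANOVA on log-transformed chase counts
#'
#' Tests whether per-mouse chase numbers change between two stages
#' (e.g. baseline vs post-acute-restraint) and whether the change
#' differs by sex. Counts are `log(x + 1)` transformed so zero counts
#' are admissible, then analysed with a two-way mixed ANOVA: sex as
#' the between-subject factor, stage as the within-subject factor,
#' subject as the error stratum. The stage and sex-by-stage F tests
#' have degrees of freedom (1, n_subjects - 2).
#'
#' @param chases Data frame with columns `individual_id`, `sex`,
#'   `stage` (two levels), `count` (chases initiated at that stage).
#'   Individuals missing either stage are dropped with a message.
#' @return A `chase_anova` tibble: one row per term (`stage`,
#'   `sex:stage`) with `statistic` (F), `df1`, `df2`, `p_value`,
#'   `n_subjects`.
#' @export
chase_change_anova <- function(chases) {
  chases <- tibble::as_tibble(chases)
  needed <- c("individual_id", "sex", "stage", "count")
  miss <- setdiff(needed, names(chases))
  if (length(miss) > 0) {
    stop("chases is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  stages <- unique(chases$stage)
  if (length(stages) != 2) stop("stage must have exactly two levels",
                                call. = FALSE)
  complete <- dplyr::filter(
    dplyr::group_by(chases, .data$individual_id),
    dplyr::n_distinct(.data$stage) == 2
  )
  complete <- dplyr::ungroup(complete)
  dropped <- setdiff(unique(chases$individual_id),
                     unique(complete$individual_id))
  if (length(dropped) > 0) {
    message("excluded ", length(dropped),
            " individual(s) missing a stage: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  df <- dplyr::mutate(
    complete,
    y = log(.data$count + 1),
    individual_id = factor(.data$individual_id),
    sex = factor(.data$sex),
    stage = factor(.data$stage)
  )
  n_sub <- nlevels(df$individual_id)
  fit <- stats::aov(y ~ sex * stage + Error(individual_id), data = df)
  within <- summary(fit)[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  i_stage <- match("stage", rn)
  i_int <- match("sex:stage", rn)
  i_res <- match("Residuals", rn)
  f_vals <- within[c(i_stage, i_int), "F value"]
  p_vals <- within[c(i_stage, i_int), "Pr(>F)"]
  # degenerate case (identical stage values for everyone): the whole
  # within stratum is numerically zero, so report no effect
  ss_terms <- within[c(i_stage, i_int), "Sum Sq"]
  ss_resid <- within[i_res, "Sum Sq"]
  degen <- (ss_terms < 1e-10) & (ss_resid < 1e-10)
  f_vals[degen] <- 0
  p_vals[degen] <- 1
  out <- tibble::tibble(
    term = c("stage", "sex:stage"),
    statistic = f_vals,
    df1 = within[c(i_stage, i_int), "Df"],
    df2 = rep(within[i_res, "Df"], 2),
    p_value = p_vals,
    n_subjects = n_sub
  )
  structure(out, class = c("chase_anova", class(tibble::tibble())))
}
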