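#' Run the full dominance-and-outcomes analysis from one config
#'
#' Executes every stage in order — per-group dominance scoring,
#' hierarchy metrics, rank-stability analysis, chase-rate change
#' ANOVA, and (when an outcome table is supplied) the preprocessing /
#' PCA / interaction-model pipeline — writing per-stage CSVs and a
#' machine-readable JSON report.
#'
#' @param config Either a path to a YAML file or a named list with
#'   elements:
#'   \describe{
#'     \item{events}{path to a chase-event CSV (required)}
#'     \item{roster}{optional roster CSV (group_id, individual_id)}
#'     \item{outcomes}{optional outcome-table CSV}
#'     \item{baseline_days}{integer vector, default 1:4}
#'     \item{post_phase}{default "post_acute"}
#'     \item{corrected}{use chance-corrected win proportions, default FALSE}
#'     \item{dci_method}{"pooled" or "mean"}
#'     \item{adjust}{"BH" or "bonferroni" for the correlation screen}
#'     \item{n_rand}{h' randomizations, default 10000}
#'     \item{seed}{integer seed, default 1}
#'     \item{out_dir}{output directory (required)}
#'   }
#' @return Invisibly, the report as a list (also written to
#'   `out_dir/report.json`).
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(baseline_days = 1:4, post_phase = "post_acute",
                   corrected = FALSE, dci_method = "pooled",
                   adjust = "BH", n_rand = 10000, seed = 1L)
  config <- utils::modifyList(defaults, config)
  for (key in c("events", "out_dir")) {
    if (is.null(config[[key]])) {
      stop("config is missing required field: ", key, call. = FALSE)
    }
  }
  if (!file.exists(config$events)) {
    stop("events file not found: ", config$events, call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  days <- as.integer(unlist(config$baseline_days))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  roster <- NULL
  if (!is.null(config$roster)) {
    roster <- readr::read_csv(config$roster, show_col_types = FALSE,
                              progress = FALSE)
  }
  log <- stage("read_events",
               read_chase_events(config$events, roster = roster))
  groups <- unique(log$group_id)

  profiles <- stage("score", purrr::map_dfr(groups, function(g) {
    tibble::as_tibble(dominance_profile(
      log, g, days, "baseline", corrected = config$corrected
    ))
  }))
  readr::write_csv(profiles, file.path(config$out_dir, "profiles.csv"),
                   progress = FALSE)

  metrics <- stage("metrics", purrr::map_dfr(groups, function(g) {
    hierarchy_metrics(log, g, days, corrected = config$corrected,
                      n_rand = config$n_rand, seed = config$seed,
                      dci_method = config$dci_method)
  }))
  readr::write_csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   progress = FALSE)

  traj <- stage("stability", daily_trajectories(
    log, groups, days, corrected = config$corrected
  ))
  maint <- maintenance_counts(traj)
  readr::write_csv(maint, file.path(config$out_dir, "stability.csv"),
                   progress = FALSE)

  post_days <- unique(log$day[log$phase == config$post_phase])
  persistence <- NULL
  chase_anova <- NULL
  if (length(post_days) > 0) {
    persistence <- stage("persistence", {
      base_all <- profiles
      post_all <- purrr::map_dfr(groups, function(g) {
        tibble::as_tibble(suppressWarnings(dominance_profile(
          log, g, post_days, config$post_phase,
          corrected = config$corrected
        )))
      })
      purrr::map_dfr(unique(base_all$sex), function(s) {
        b <- base_all[base_all$sex == s, ]
        a <- post_all[post_all$sex == s, ]
        cbind(sex = s, ds_persistence(b, a))
      })
    })
    chase_anova <- stage("chase_anova", {
      totals <- dplyr::bind_rows(
        chase_totals(log, days, "baseline", "baseline"),
        chase_totals(log, post_days, config$post_phase, "post_acute")
      )
      chase_change_anova(totals)
    })
    readr::write_csv(chase_anova,
                     file.path(config$out_dir, "chase_anova.csv"),
                     progress = FALSE)
  }

  outcome_report <- NULL
  if (!is.null(config$outcomes)) {
    outcome_report <- stage("outcomes", {
      tab <- readr::read_csv(config$outcomes, show_col_types = FALSE,
                             progress = FALSE)
      if (!"dominance" %in% names(tab)) {
        tab <- dplyr::left_join(
          tab,
          dplyr::select(profiles, "individual_id",
                        dominance = "norm_ds"),
          by = "individual_id"
        )
      }
      adj <- preprocess_outcomes(tab)
      pca <- outcome_pca(adj)
      scores <- tidy(pca, "scores")
      readr::write_csv(
        dplyr::bind_cols(adj$values[, 0], tidy(adj)),
        file.path(config$out_dir, "adjusted_outcomes.csv"),
        progress = FALSE)
      readr::write_csv(scores,
                       file.path(config$out_dir, "pca_scores.csv"),
                       progress = FALSE)
      readr::write_csv(tidy(pca, "loadings"),
                       file.path(config$out_dir, "pca_loadings.csv"),
                       progress = FALSE)
      meta <- adj$values
      pc1 <- scores$PC1[match(meta$individual_id,
                              scores$individual_id)]
      eff <- pc_group_effects(pc1, meta$sex, meta$condition)
      inter <- ds_sex_interaction(
        dplyr::mutate(meta, PC1 = pc1), "PC1"
      )
      screen <- correlation_screen(
        dplyr::mutate(meta, PC1 = pc1), "PC1", adj$readouts,
        adjust = config$adjust
      )
      assoc <- dplyr::bind_rows(
        dplyr::mutate(eff, stage = "pc1_group_effects"),
        dplyr::mutate(inter, stage = "ds_sex_interaction")
      )
      readr::write_csv(assoc,
                       file.path(config$out_dir, "associations.csv"),
                       progress = FALSE)
      readr::write_csv(screen,
                       file.path(config$out_dir, "pc1_screen.csv"),
                       progress = FALSE)
      list(
        n_individuals = nrow(meta),
        pc1_var_explained = pca$var_explained[1],
        pc1_group_effects = as.list(split(eff$p_value, eff$term)),
        ds_sex_interaction = list(
          F = inter$statistic, df1 = inter$df1, df2 = inter$df2,
          p = inter$p_value
        ),
        n_screen_hits = sum(screen$q_value < 0.05)
      )
    })
  }

  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("domstress")),
    config = config[setdiff(names(config), "out_dir")],
    seeds = list(main = config$seed),
    n_groups = length(groups),
    dominance = list(
      n_individuals = nrow(profiles),
      norm_ds_range = range(profiles$norm_ds)
    ),
    metrics = as.list(dplyr::summarise(
      metrics,
      steepness = mean(.data$steepness),
      despotism = mean(.data$despotism),
      dci = mean(.data$dci),
      h_prime = mean(.data$h_prime)
    )),
    stability = purrr::pmap(
      dplyr::select(maint, "sex", "final_rank", "k", "n", "p_value"),
      list
    ),
    persistence = if (!is.null(persistence)) {
      purrr::pmap(persistence, list)
    },
    chase_anova = if (!is.null(chase_anova)) {
      purrr::pmap(chase_anova, list)
    },
    outcomes = outcome_report
  )
  validate_report(report)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Per-mouse chase totals for a day window
#'
#' @param log A `chase_log`.
#' @param days Days to include.
#' @param phase Phase label to filter on.
#' @param stage_label Label written into the `stage` column.
#' @return Tibble `individual_id`, `sex`, `stage`, `count` (animals
#'   with no chases in the window get an explicit zero).
#' @export
chase_totals <- function(log, days, phase, stage_label = phase) {
  roster <- chase_roster(log)
  sex_map <- dplyr::distinct(
    tibble::as_tibble(log)[, c("group_id", "sex")]
  )
  roster <- dplyr::left_join(roster, sex_map, by = "group_id")
  sel <- log$day %in% days & log$phase == phase
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(log)[sel, ], .data$actor_id),
    count = sum(.data$count), .groups = "drop"
  )
  out <- dplyr::left_join(roster, agg,
                          by = c(individual_id = "actor_id"))
  out$count[is.na(out$count)] <- 0L
  tibble::tibble(individual_id = out$individual_id, sex = out$sex,
                 stage = stage_label, count = out$count)
}

validate_report <- function(report) {
  required <- c("schema_version", "package_version", "config", "seeds",
                "n_groups", "dominance", "metrics", "stability")
  miss <- setdiff(required, names(report))
  if (length(miss) > 0) {
    stop("internal: report missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
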