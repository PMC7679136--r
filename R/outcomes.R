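#' Rank-based inverse normal (Blom) transform
#'
#' `z_i = qnorm((r_i - 3/8) / (n + 1/4))`, where `r_i` is the rank of
#' `x_i` among the non-missing values (ties receive average ranks).
#' Missing values pass through as missing; an all-constant vector maps
#' to zeros with a warning.
#'
#' @param x Numeric vector, possibly with ties and `NA`s.
#' @return Numeric vector of normal scores, same length as `x`.
#' @export
blom_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 non-missing values", call. = FALSE)
  out <- rep(NA_real_, length(x))
  xv <- x[ok]
  if (length(unique(xv)) == 1) {
    warning("constant input: Blom transform returns zeros",
            call. = FALSE)
    out[ok] <- 0
    return(out)
  }
  r <- rank(xv, ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Batch adjustment by standardized residuals
#'
#' Per variable, fits a linear model with batch as a factorial
#' predictor and returns the standardized residuals (residuals divided
#' by the residual standard deviation). Batch means of the adjusted
#' values are zero; with a single batch this reduces to z-scoring.
#'
#' @param X Numeric matrix or data frame (individuals x variables),
#'   possibly with `NA`s (rows with `NA` in a variable are skipped for
#'   that variable's fit and stay `NA`).
#' @param batch Factor (or coercible) of batch labels, one per row.
#' @return Numeric matrix of adjusted values with the input dimnames.
#' @export
batch_adjust <- function(X, batch) {
  X <- as.matrix(X)
  batch <- factor(batch)
  if (length(batch) != nrow(X)) {
    stop("batch must have one label per row of X", call. = FALSE)
  }
  counts <- table(batch)
  thin <- names(counts)[counts < 2]
  if (length(thin) > 0) {
    stop("batch level(s) with fewer than 2 observations: ",
         paste(thin, collapse = ", "), call. = FALSE)
  }
  out <- X
  for (j in seq_len(ncol(X))) {
    ok <- !is.na(X[, j])
    b <- batch[ok, drop = TRUE]
    fit <- if (nlevels(b) > 1) {
      stats::lm(X[ok, j] ~ b)
    } else {
      stats::lm(X[ok, j] ~ 1)
    }
    res <- stats::residuals(fit)
    s <- stats::sd(res)
    out[ok, j] <- if (s > 0) res / s else 0
  }
  out
}

#' Preprocess an outcome table for analysis
#'
#' Applies, in order: (1) per-stratum outlier masking — values more
#' than `sd_threshold` standard deviations from their sex-by-condition
#' stratum mean are set to missing and logged; (2) exclusion of
#' individuals with more than `max_missing` missing readouts; (3)
#' median imputation of remaining missing values (per variable, across
#' retained individuals); (4) Blom rank-normalization per variable;
#' (5) batch adjustment by standardized residuals; (6) re-expression
#' relative to the reference stratum mean (female controls by
#' default), so reference animals average zero on every variable.
#'
#' @param outcomes Data frame with columns `individual_id`, `sex`,
#'   `condition`, `batch`, plus the numeric readout columns.
#' @param readouts Character vector naming the readout columns
#'   (default: all numeric columns not in the metadata set).
#' @param sd_threshold Outlier cutoff in stratum SD units (default
#'   3.5).
#' @param max_missing Maximum missing readouts per individual before
#'   exclusion (default 2).
#' @param reference Named list giving the reference stratum for
#'   centering, default `list(sex = "female", condition = "control")`;
#'   `NULL` skips the centering step.
#' @return An `adjusted_outcomes` object: a list with `values` (tibble
#'   of adjusted readouts with metadata columns), `outlier_log`,
#'   `excluded`, `imputation_log`, `reference_offsets`.
#' @export
preprocess_outcomes <- function(outcomes, readouts = NULL,
                                sd_threshold = 3.5, max_missing = 2,
                                reference = list(sex = "female",
                                                 condition = "control")) {
  outcomes <- tibble::as_tibble(outcomes)
  meta_cols <- c("individual_id", "group_id", "sex", "condition",
                 "batch", "dominance")
  miss <- setdiff(c("individual_id", "sex", "condition", "batch"),
                  names(outcomes))
  if (length(miss) > 0) {
    stop("outcomes is missing metadata column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(readouts)) {
    readouts <- setdiff(names(outcomes)[vapply(outcomes, is.numeric,
                                               logical(1))],
                        meta_cols)
  }
  if (length(readouts) < 1) stop("no readout columns", call. = FALSE)
  X <- as.matrix(outcomes[, readouts])
  rownames(X) <- outcomes$individual_id
  stratum <- interaction(outcomes$sex, outcomes$condition, drop = TRUE)
  if (any(table(stratum) < 2)) {
    stop("each sex-by-condition stratum needs at least 2 individuals",
         call. = FALSE)
  }

  # 1. outlier masking within sex x condition stratum
  outlier_log <- list()
  for (j in seq_len(ncol(X))) {
    for (s in levels(stratum)) {
      idx <- which(stratum == s & !is.na(X[, j]))
      if (length(idx) < 3) next
      mu <- mean(X[idx, j]); sdv <- stats::sd(X[idx, j])
      if (is.na(sdv) || sdv == 0) next
      bad <- idx[abs(X[idx, j] - mu) > sd_threshold * sdv]
      if (length(bad) > 0) {
        outlier_log[[length(outlier_log) + 1]] <- tibble::tibble(
          individual_id = rownames(X)[bad], variable = readouts[j],
          value = X[bad, j], stratum = s
        )
        X[bad, j] <- NA_real_
      }
    }
  }
  outlier_log <- if (length(outlier_log) > 0) {
    dplyr::bind_rows(outlier_log)
  } else {
    tibble::tibble(individual_id = character(), variable = character(),
                   value = numeric(), stratum = character())
  }

  # 2. exclusion by missingness
  n_missing <- rowSums(is.na(X))
  excluded <- rownames(X)[n_missing > max_missing]
  keep <- n_missing <= max_missing
  X <- X[keep, , drop = FALSE]
  outcomes_kept <- outcomes[keep, , drop = FALSE]

  # 3. median imputation per variable
  imputation_log <- list()
  for (j in seq_len(ncol(X))) {
    nas <- which(is.na(X[, j]))
    if (length(nas) > 0) {
      med <- stats::median(X[, j], na.rm = TRUE)
      imputation_log[[length(imputation_log) + 1]] <- tibble::tibble(
        individual_id = rownames(X)[nas], variable = readouts[j],
        imputed_value = med
      )
      X[nas, j] <- med
    }
  }
  imputation_log <- if (length(imputation_log) > 0) {
    dplyr::bind_rows(imputation_log)
  } else {
    tibble::tibble(individual_id = character(), variable = character(),
                   imputed_value = numeric())
  }

  # 4. Blom transform, 5. batch adjustment
  Z <- apply(X, 2, blom_transform)
  rownames(Z) <- rownames(X)
  A <- batch_adjust(Z, outcomes_kept$batch)

  # 6. reference centering
  reference_offsets <- NULL
  if (!is.null(reference)) {
    ref_rows <- rep(TRUE, nrow(A))
    for (nm in names(reference)) {
      ref_rows <- ref_rows & outcomes_kept[[nm]] == reference[[nm]]
    }
    if (!any(ref_rows)) stop("reference stratum is empty", call. = FALSE)
    reference_offsets <- colMeans(A[ref_rows, , drop = FALSE])
    A <- sweep(A, 2, reference_offsets)
  }

  values <- dplyr::bind_cols(
    outcomes_kept[, intersect(meta_cols, names(outcomes_kept))],
    tibble::as_tibble(A)
  )
  structure(
    list(values = values, readouts = readouts,
         outlier_log = outlier_log, excluded = excluded,
         imputation_log = imputation_log,
         reference_offsets = reference_offsets),
    class = "adjusted_outcomes"
  )
}

#' @export
print.adjusted_outcomes <- function(x, ...) {
  cat("# adjusted_outcomes:", nrow(x$values), "individuals x",
      length(x$readouts), "readouts |",
      nrow(x$outlier_log), "outliers masked,",
      length(x$excluded), "excluded,",
      nrow(x$imputation_log), "values imputed\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.adjusted_outcomes <- function(x, ...) {
  x$values
}

#' @exportS3Method generics::glance
glance.adjusted_outcomes <- function(x, ...) {
  tibble::tibble(
    n_individuals = nrow(x$values),
    n_readouts = length(x$readouts),
    n_outliers = nrow(x$outlier_log),
    n_excluded = length(x$excluded),
    n_imputed = nrow(x$imputation_log)
  )
}

#' PCA of a complete adjusted outcome matrix
#'
#' Singular value decomposition of the column-centered, unit-variance
#' scaled matrix. Scores are the left singular vectors scaled by the
#' singular values; per-component variance explained is
#' `sigma_k^2 / sum(sigma^2)`. Constant columns are dropped with a
#' warning before decomposition.
#'
#' @param X Complete numeric matrix or data frame (individuals x
#'   variables), or an `adjusted_outcomes` object.
#' @return An `outcome_pca` list: `scores`, `loadings`,
#'   `var_explained`, `sdev`, `variables`.
#' @export
outcome_pca <- function(X) {
  if (inherits(X, "adjusted_outcomes")) {
    ids <- X$values$individual_id
    X <- as.matrix(X$values[, X$readouts])
    rownames(X) <- ids
  }
  X <- as.matrix(X)
  if (anyNA(X)) stop("PCA input must be complete (impute first)",
                     call. = FALSE)
  if (nrow(X) < 2 || ncol(X) < 2) {
    stop("need at least 2 individuals and 2 variables", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "),
            call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = pc$x, loadings = pc$rotation, var_explained = ve,
         sdev = pc$sdev, variables = colnames(X)),
    class = "outcome_pca"
  )
}

#' @export
print.outcome_pca <- function(x, ...) {
  cat("# outcome_pca:", nrow(x$scores), "individuals,",
      length(x$variables), "variables\n")
  cat("  var explained (top 5):",
      paste0(round(100 * utils::head(x$var_explained, 5), 1), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.outcome_pca <- function(x, matrix = c("scores", "loadings",
                                           "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tibble::as_tibble(x$scores, rownames = "individual_id"),
    loadings = tibble::as_tibble(x$loadings, rownames = "variable"),
    eigenvalues = tibble::tibble(
      component = seq_along(x$var_explained),
      sdev = x$sdev,
      var_explained = x$var_explained,
      cumulative = cumsum(x$var_explained)
    )
  )
}

#' @exportS3Method generics::glance
glance.outcome_pca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores), n_variables = length(x$variables),
    pc1_var_explained = x$var_explained[1]
  )
}

#' Sex and condition effects on a principal component
#'
#' Two-way ANOVA of component scores on sex, condition and their
#' interaction (sequential sums of squares, interaction last).
#'
#' @param scores Numeric vector of component scores.
#' @param sex,condition Factors (or coercible), one value per score.
#' @return An `association_result` tibble: one row per term with
#'   `statistic` (F), `df1`, `df2`, `p_value`, `method`.
#' @export
pc_group_effects <- function(scores, sex, condition) {
  sex <- factor(sex); condition <- factor(condition)
  if (any(table(sex, condition) == 0)) {
    stop("empty sex x condition cell", call. = FALSE)
  }
  fit <- stats::lm(scores ~ sex * condition)
  an <- stats::anova(fit)
  terms <- c("sex", "condition", "sex:condition")
  i <- match(terms, rownames(an))
  out <- tibble::tibble(
    term = terms,
    statistic = an[i, "F value"],
    df1 = an[i, "Df"],
    df2 = an["Residuals", "Df"],
    p_value = an[i, "Pr(>F)"],
    method = "two-way ANOVA"
  )
  as_association_result(out)
}

#' Dominance-by-sex interaction on an outcome within one condition
#'
#' Fits `score ~ dominance + sex + dominance:sex` on the subset of
#' individuals in the selected condition and reports the interaction
#' F test with (1, n - 4) degrees of freedom — the test of whether
#' the dominance slope differs between the sexes (e.g. opposite-sign
#' slopes in stressed males and females). Per-sex slopes are attached.
#'
#' @param data Data frame with the score, dominance, sex and condition
#'   columns.
#' @param score,dominance,sex,condition Column names (strings).
#' @param within Condition level to subset to (default `"CMS"`).
#' @return An `association_result` tibble (one row, term
#'   `dominance:sex`) with a `slopes` attribute giving per-sex OLS
#'   slopes.
#' @export
ds_sex_interaction <- function(data, score = "PC1",
                               dominance = "dominance", sex = "sex",
                               condition = "condition",
                               within = "CMS") {
  d <- tibble::as_tibble(data)
  d <- d[d[[condition]] == within, , drop = FALSE]
  y <- d[[score]]; ds <- d[[dominance]]; sx <- factor(d[[sex]])
  if (nlevels(sx) < 2) stop("need both sexes in condition '", within,
                            "'", call. = FALSE)
  if (min(table(sx)) < 3) {
    stop("need at least 3 individuals per sex", call. = FALSE)
  }
  fit <- stats::lm(y ~ ds * sx)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design", call. = FALSE)
  }
  an <- stats::anova(fit)
  i <- match("ds:sx", rownames(an))
  slopes <- purrr::map_dfr(levels(sx), function(s) {
    f <- stats::lm(y[sx == s] ~ ds[sx == s])
    sm <- summary(f)$coefficients
    tibble::tibble(sex = s, slope = sm[2, 1],
                   p_value = sm[2, 4])
  })
  out <- tibble::tibble(
    term = "dominance:sex",
    statistic = an[i, "F value"],
    df1 = an[i, "Df"],
    df2 = an["Residuals", "Df"],
    p_value = an[i, "Pr(>F)"],
    method = paste0("linear model, condition=", within)
  )
  out <- as_association_result(out)
  attr(out, "slopes") <- slopes
  out
}

#' Spearman correlation screen with multiplicity control
#'
#' Correlates a target variable (e.g. dominance score or PC1 score)
#' with every readout, optionally within groups (e.g. per sex), using
#' Spearman's rank correlation. Benjamini-Hochberg adjustment is
#' applied within each group's family; Bonferroni across the readout
#' family. Readouts with fewer than 4 complete pairs in a group are
#' skipped with a warning.
#'
#' @param data Data frame containing the target, readout and grouping
#'   columns.
#' @param target Name of the target column.
#' @param readouts Character vector of readout column names.
#' @param group_by Optional grouping column name (e.g. `"sex"`);
#'   `NULL` screens the whole table as one family.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return An `association_result` tibble: `group`, `variable`, `rho`,
#'   `n`, `p_value`, `q_value`, `method`.
#' @export
correlation_screen <- function(data, target, readouts,
                               group_by = NULL,
                               adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  d <- tibble::as_tibble(data)
  groups <- if (is.null(group_by)) {
    list(all = rep(TRUE, nrow(d)))
  } else {
    lv <- unique(d[[group_by]])
    stats::setNames(lapply(lv, function(g) d[[group_by]] == g), lv)
  }
  res <- purrr::map_dfr(names(groups), function(g) {
    sub <- d[groups[[g]], , drop = FALSE]
    rows <- purrr::map_dfr(readouts, function(v) {
      ok <- !is.na(sub[[target]]) & !is.na(sub[[v]])
      if (sum(ok) < 4) {
        warning("skipping ", v, " in group ", g,
                ": fewer than 4 complete pairs", call. = FALSE)
        return(NULL)
      }
      ct <- suppressWarnings(
        stats::cor.test(sub[[target]][ok], sub[[v]][ok],
                        method = "spearman", exact = FALSE)
      )
      tibble::tibble(group = g, variable = v,
                     rho = unname(ct$estimate), n = sum(ok),
                     p_value = ct$p.value)
    })
    if (nrow(rows) > 0) {
      rows$q_value <- stats::p.adjust(rows$p_value, method = adjust)
    }
    rows
  })
  res$method <- paste0("Spearman + ", adjust)
  as_association_result(res)
}

#' Two-way ANOVA plus within-sex Welch t-tests for one variable
#'
#' The condition screen applied to single outcomes (bodyweight change,
#' coat state, adrenal weight): a two-way ANOVA for sex, condition and
#' their interaction, followed by two-sided Welch (unequal-variance)
#' t-tests of control vs the treated condition within each sex, with
#' Welch-Satterthwaite degrees of freedom. A Kruskal-Wallis test on
#' condition is reported additionally when `kruskal = TRUE` (for
#' ordinal scores).
#'
#' @param data Data frame with the variable plus `sex` and `condition`
#'   columns.
#' @param variable Name of the outcome column.
#' @param control Condition level treated as reference (default
#'   `"control"`).
#' @param kruskal Also report a Kruskal-Wallis test on condition.
#' @return An `association_result` tibble: ANOVA rows (F, df1, df2)
#'   followed by one Welch row per sex (t, df) and optionally a
#'   Kruskal-Wallis row (chi-squared, df).
#' @export
group_effect_tests <- function(data, variable, control = "control",
                               kruskal = FALSE) {
  d <- tibble::as_tibble(data)
  y <- d[[variable]]
  sex <- factor(d$sex); condition <- factor(d$condition)
  ok <- !is.na(y)
  y <- y[ok]; sex <- droplevels(sex[ok])
  condition <- droplevels(condition[ok])
  if (any(table(sex, condition) == 0)) {
    stop("empty sex x condition cell", call. = FALSE)
  }
  an <- stats::anova(stats::lm(y ~ sex * condition))
  terms <- c("sex", "condition", "sex:condition")
  i <- match(terms, rownames(an))
  rows <- tibble::tibble(
    term = paste0("anova:", terms),
    statistic = an[i, "F value"],
    df1 = an[i, "Df"],
    df2 = an["Residuals", "Df"],
    p_value = an[i, "Pr(>F)"],
    method = "two-way ANOVA"
  )
  other <- setdiff(levels(condition), control)
  welch <- purrr::map_dfr(levels(sex), function(s) {
    a <- y[sex == s & condition == control]
    b <- y[sex == s & condition %in% other]
    tt <- stats::t.test(a, b)
    tibble::tibble(
      term = paste0("welch:", s),
      statistic = unname(tt$statistic),
      df1 = 1,
      df2 = unname(tt$parameter),
      p_value = tt$p.value,
      method = "Welch two-sided t-test"
    )
  })
  rows <- dplyr::bind_rows(rows, welch)
  if (kruskal) {
    kw <- stats::kruskal.test(y ~ condition)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      term = "kruskal:condition",
      statistic = unname(kw$statistic),
      df1 = unname(kw$parameter), df2 = NA_real_,
      p_value = kw$p.value,
      method = "Kruskal-Wallis"
    ))
  }
  as_association_result(rows)
}

as_association_result <- function(x) {
  structure(tibble::as_tibble(x),
            class = c("association_result", class(tibble::tibble())))
}

#' @exportS3Method generics::tidy
tidy.association_result <- function(x, ...) {
  tibble::as_tibble(x)
}
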