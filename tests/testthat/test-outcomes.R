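test_that("Blom transform matches the direct formula", {
  # middle of 5 distinct values maps to the exact median normal score
  z5 <- blom_transform(c(10, 20, 30, 40, 50))
  expect_equal(z5[3], 0)
  # smallest of 3: qnorm((1 - 3/8) / 3.25)
  z3 <- blom_transform(c(7, 1, 4))
  expect_equal(z3[2], qnorm(0.625 / 3.25))
  expect_equal(z3[2], -0.8694, tolerance = 1e-4)
  # rank reversal flips signs elementwise for distinct input
  x <- c(2.3, -1, 0.5, 7, 3)
  expect_equal(blom_transform(x), -blom_transform(-x))
  # ties share average ranks
  zt <- blom_transform(c(1, 2, 2, 3))
  expect_equal(zt[2], zt[3])
  # missing values pass through
  zna <- blom_transform(c(1, NA, 3, 2))
  expect_true(is.na(zna[2]))
  expect_equal(sum(is.na(zna)), 1)
  expect_warning(zc <- blom_transform(rep(4, 6)), "constant")
  expect_equal(zc, rep(0, 6))
  expect_error(blom_transform(c(1, NA)), "2 non-missing")
})

test_that("Blom output is near-normal for continuous input", {
  set.seed(14)
  pass <- vapply(1:40, function(i) {
    z <- blom_transform(rexp(100))
    shapiro.test(z)$p.value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("batch adjustment removes offsets and standardizes", {
  set.seed(8)
  base <- rnorm(20)
  X <- cbind(v = c(base, base + 10))
  batch <- rep(c("b1", "b2"), each = 20)
  adj <- batch_adjust(X, batch)
  expect_equal(adj[1:20, 1], adj[21:40, 1], tolerance = 1e-9)
  expect_lt(max(abs(tapply(adj[, 1], batch, mean))), 1e-9)
  # single batch reduces to z-scoring
  z <- batch_adjust(cbind(base), rep("b1", 20))
  expect_equal(z[, 1], as.numeric(scale(base)), tolerance = 1e-9)
  # random data: batch means 0, unit residual SD
  Y <- matrix(rnorm(60), 30, 2)
  b <- rep(c("b1", "b2", "b3"), each = 10)
  A <- batch_adjust(Y, b)
  for (j in 1:2) {
    expect_lt(max(abs(tapply(A[, j], b, mean))), 1e-9)
  }
  expect_error(batch_adjust(Y, c(rep("b1", 29), "b2")),
               "fewer than 2.*b2")
})

test_that("preprocessing applies outlier, exclusion and imputation rules", {
  set.seed(9)
  n <- 80   # 20 per sex-by-condition stratum, so a z of 3.5 is reachable
  tab <- tibble::tibble(
    individual_id = sprintf("m%02d", 1:n),
    sex = rep(c("female", "male"), each = n / 2),
    condition = rep(c("control", "CMS"), n / 2),
    batch = rep(c("B1", "B2"), length.out = n),
    v1 = rnorm(n), v2 = rnorm(n), v3 = rnorm(n), v4 = rnorm(n)
  )
  # plant a gross outlier in one stratum
  tab$v1[1] <- mean(tab$v1[tab$sex == "female" &
                             tab$condition == "control"]) + 50
  # one animal with three missing readouts -> excluded
  tab$v2[5] <- NA; tab$v3[5] <- NA; tab$v4[5] <- NA
  adj <- preprocess_outcomes(tab)
  expect_true("m01" %in% adj$outlier_log$individual_id)
  expect_equal(adj$excluded, "m05")
  expect_false("m05" %in% adj$values$individual_id)
  expect_true(all(c("m01") %in% adj$imputation_log$individual_id))
  # female-control means are zero after reference centering
  vals <- adj$values
  ref <- vals$sex == "female" & vals$condition == "control"
  for (v in adj$readouts) {
    expect_equal(mean(vals[[v]][ref]), 0, tolerance = 1e-9)
  }
  # glance summarises the logs
  g <- glance(adj)
  expect_equal(g$n_excluded, 1)
  expect_gte(g$n_imputed, 1)
})

test_that("an individual within the missingness allowance is retained", {
  set.seed(10)
  tab <- tibble::tibble(
    individual_id = sprintf("m%02d", 1:20),
    sex = rep(c("female", "male"), each = 10),
    condition = rep(c("control", "CMS"), 10),
    batch = "B1",
    v1 = rnorm(20), v2 = rnorm(20), v3 = rnorm(20)
  )
  tab$v1[3] <- NA; tab$v2[3] <- NA   # exactly max_missing = 2
  adj <- preprocess_outcomes(tab)
  expect_true("m03" %in% adj$values$individual_id)
  expect_equal(nrow(adj$imputation_log), 2)
  imput <- adj$imputation_log$imputed_value[1]
  expect_equal(imput, median(tab$v1, na.rm = TRUE))
})

test_that("PCA follows the SVD identities", {
  set.seed(11)
  # two perfectly correlated variables: all variance on PC1
  x <- rnorm(30)
  pca2 <- outcome_pca(cbind(a = x, b = 2 * x + 3))
  expect_equal(pca2$var_explained, c(1, 0), tolerance = 1e-12)
  # reconstruction and orthogonality
  X <- matrix(rnorm(25 * 6), 25, 6)
  p <- outcome_pca(X)
  Z <- scale(X)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(unname(recon), unname(Z), tolerance = 1e-8,
               ignore_attr = TRUE)
  G <- crossprod(p$scores)
  expect_equal(max(abs(G[upper.tri(G)])), 0, tolerance = 1e-8)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  # scaled-data identity: total score variance = number of variables
  expect_equal(sum(apply(p$scores, 2, var)), 6, tolerance = 1e-8)
  # constant columns are dropped with a warning
  expect_warning(pc <- outcome_pca(cbind(X, k = rep(1, 25))),
                 "constant")
  expect_equal(length(pc$variables), 6)
  expect_error(outcome_pca(cbind(x, ifelse(seq_along(x) == 2, NA, x))),
               "complete")
})

test_that("isotropic noise spreads variance evenly across components", {
  set.seed(12)
  p <- outcome_pca(matrix(rnorm(1000 * 4), 1000, 4))
  expect_true(all(abs(p$var_explained - 0.25) < 0.05))
})

test_that("group effects on a component detect planted separation", {
  sex <- rep(c("male", "female"), each = 20)
  condition <- rep(c("CMS", "control"), 20)
  scores <- ifelse(condition == "CMS", 1, -1)
  res <- suppressWarnings(pc_group_effects(scores, sex, condition))
  expect_lt(res$p_value[res$term == "condition"], 1e-10)
  expect_true(is.finite(res$statistic[res$term == "condition"]))
  # empty sex-by-condition cell is rejected
  expect_error(
    pc_group_effects(
      rnorm(20),
      rep(c("male", "female"), each = 10),
      rep(c("CMS", "control"), each = 10)
    ),
    "empty"
  )
})

test_that("the dominance-by-sex interaction model detects opposite slopes", {
  set.seed(13)
  n <- 48
  meta <- tibble::tibble(
    individual_id = sprintf("m%02d", 1:n),
    sex = rep(c("male", "female"), each = n / 2),
    condition = rep(c("CMS", "control"), n / 2),
    dominance = runif(n, 0, 3)
  )
  b <- 3
  meta$PC1 <- ifelse(meta$sex == "male", b, -b) *
    (meta$dominance - 1.5) * (meta$condition == "CMS") +
    rnorm(n, 0, 0.5)
  res <- ds_sex_interaction(meta, "PC1", within = "CMS")
  expect_lt(res$p_value, 0.01)
  slopes <- attr(res, "slopes")
  expect_gt(slopes$slope[slopes$sex == "male"], 0)
  expect_lt(slopes$slope[slopes$sex == "female"], 0)
  expect_equal(res$df2, sum(meta$condition == "CMS") - 4)
  # control subset carries no association
  res_c <- ds_sex_interaction(meta, "PC1", within = "control")
  expect_gt(res_c$p_value, 0.01)
  # single-sex input errors
  ss <- meta[meta$sex == "male", ]
  expect_error(ds_sex_interaction(ss, "PC1", within = "CMS"),
               "both sexes")
})

test_that("the correlation screen honors monotone invariance and adjustment", {
  set.seed(15)
  n <- 30
  d <- tibble::tibble(
    sex = rep(c("male", "female"), each = n / 2),
    target = runif(n),
    mono = NA_real_, noise1 = rnorm(n), noise2 = rnorm(n)
  )
  d$mono <- exp(d$target)   # monotone transform
  res <- correlation_screen(d, "target", c("mono", "noise1", "noise2"),
                            group_by = "sex")
  mono_rows <- res[res$variable == "mono", ]
  expect_equal(mono_rows$rho, c(1, 1))
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  # Bonferroni q = min(1, m * p)
  resb <- correlation_screen(d, "target", c("mono", "noise1", "noise2"),
                             adjust = "bonferroni")
  expect_equal(resb$q_value, pmin(1, 3 * resb$p_value))
  # too-few pairs are skipped with a warning
  d$thin <- c(rnorm(3), rep(NA, n - 3))
  expect_warning(
    correlation_screen(d, "target", "thin"),
    "fewer than 4"
  )
})

test_that("BH keeps the false-discovery proportion near its level", {
  set.seed(16)
  fdp <- vapply(1:50, function(i) {
    d <- tibble::as_tibble(matrix(rnorm(40 * 20), 40, 20),
                           .name_repair = "minimal")
    names(d) <- paste0("r", 1:20)
    d$target <- rnorm(40)
    res <- correlation_screen(d, "target", paste0("r", 1:20))
    mean(res$q_value < 0.05)
  }, numeric(1))
  expect_lte(mean(fdp), 0.05)
})

test_that("group_effect_tests runs ANOVA plus Welch t-tests per sex", {
  set.seed(17)
  n <- 60
  d <- tibble::tibble(
    sex = rep(c("female", "male"), each = n / 2),
    condition = rep(c("control", "CMS"), n / 2)
  )
  shift <- ifelse(d$sex == "female" & d$condition == "CMS", 3, 0)
  d$bw <- rnorm(n) + shift
  res <- group_effect_tests(d, "bw", kruskal = TRUE)
  expect_lt(res$p_value[res$term == "welch:female"], 0.001)
  expect_gt(res$p_value[res$term == "welch:male"], 0.05)
  expect_true("kruskal:condition" %in% res$term)
  # Welch df matches the Satterthwaite formula on a toy pair
  a <- c(1, 2, 3, 4, 9)
  b <- c(2, 2.5, 3.5)
  tt <- t.test(a, b)
  va <- var(a) / 5; vb <- var(b) / 3
  df_hand <- (va + vb)^2 / (va^2 / 4 + vb^2 / 2)
  expect_equal(unname(tt$parameter), df_hand, tolerance = 1e-9)
  d3 <- tibble::tibble(
    sex = rep(c("male", "female"), each = 10),
    condition = rep(c("CMS", "control"), each = 10),
    bw = rnorm(20)
  )
  expect_error(group_effect_tests(d3, "bw"), "empty")
})
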