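test_that("deterministic linear chasing yields constant trajectories", {
  log <- linear_toy_log()
  traj <- daily_trajectories(log, baseline_days = 1:4)
  expect_equal(nrow(traj), 16)
  wide <- tidyr::pivot_wider(traj[, c("individual_id", "day",
                                      "daily_rank")],
                             names_from = "day",
                             values_from = "daily_rank")
  expect_true(all(apply(wide[, -1], 1, function(r) length(unique(r))) == 1))
  expect_equal(traj$daily_rank, traj$final_rank)
})

test_that("a day-2 top-dyad reversal swaps alpha and beta on day 2 only", {
  log <- linear_toy_log(days = c(1, 3, 4), per_dyad = 3L)
  # day 2: b dominates a instead; lower dyads unchanged
  ids <- c("a", "b", "c", "d")
  day2 <- tibble::tibble(
    group_id = "G1", sex = "male", day = 2L, phase = "baseline",
    actor_id = c("b", "a", "a", "b", "b", "c"),
    recipient_id = c("a", "c", "d", "c", "d", "d"),
    count = c(9L, 3L, 3L, 3L, 3L, 3L)
  )
  log2 <- as_chase_log(dplyr::bind_rows(tibble::as_tibble(log), day2))
  traj <- daily_trajectories(log2, baseline_days = 1:4)
  a_ranks <- traj$daily_rank[traj$individual_id == "a"][order(
    traj$day[traj$individual_id == "a"])]
  b_ranks <- traj$daily_rank[traj$individual_id == "b"][order(
    traj$day[traj$individual_id == "b"])]
  expect_equal(a_ranks, c(1L, 2L, 1L, 1L))
  expect_equal(b_ranks, c(2L, 1L, 2L, 2L))
  expect_error(daily_trajectories(log, baseline_days = 1),
               "two baseline days")
})

test_that("maintenance trials count D-1 consecutive-day pairs per animal", {
  # 12 female-like groups, 4 days -> 3 trials per animal, 36 per rank
  log <- simulate_chases(chase_sim_config(
    n_groups_per_sex = 12, discriminability = 3, seed = 21
  ))
  fem <- tibble::as_tibble(log)
  fem <- as_chase_log(fem[fem$sex == "female", ])
  traj <- daily_trajectories(fem, baseline_days = 1:4)
  tab <- maintenance_counts(traj)
  expect_equal(unique(tab$n), 36L)
  expect_equal(sort(unique(tab$final_rank)), 1:4)
  expect_equal(unique(tab$p0), 0.25)
  # 10 groups -> 30 trials per rank stratum
  ten <- simulate_chases(chase_sim_config(n_groups_per_sex = 10,
                                          seed = 22))
  male <- tibble::as_tibble(ten)
  male <- as_chase_log(male[male$sex == "male", ])
  tab10 <- maintenance_counts(daily_trajectories(male,
                                                 baseline_days = 1:4))
  expect_equal(unique(tab10$n), 30L)
})

test_that("a perfectly stable group maintains every rank (k = n)", {
  log <- linear_toy_log()
  tab <- maintenance_counts(daily_trajectories(log, baseline_days = 1:4))
  expect_equal(tab$k, tab$n)
  expect_equal(tab$odds_ratio_vs_chance, rep(Inf, 4))
  expect_equal(tab$p_value, 0.25^tab$n)
})

test_that("the exact binomial test matches closed forms and brute force", {
  expect_equal(binomial_vs_chance(10, 10, 0.25)$p_value, 0.25^10)
  expect_equal(binomial_vs_chance(0, 10, 0.25)$p_value, 1)
  expect_equal(binomial_vs_chance(0, 10, 0.25)$odds_ratio, 0)
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    brute <- sum(dbinom(k:n, n, p0))
    expect_equal(binomial_vs_chance(k, n, p0)$p_value, brute,
                 tolerance = 1e-12)
  }
  expect_error(binomial_vs_chance(5, 4, 0.25), "k and n")
  expect_error(binomial_vs_chance(1, 4, 1.2), "p0")
})

test_that("chance maintenance for 4 ranks is exactly 25% by enumeration", {
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  expect_equal(nrow(perms), 24)
  # probability a uniformly random permutation fixes a given position
  expect_equal(mean(perms[, 1] == 1), 0.25)
  expect_equal(mean(apply(perms, 1, function(p) mean(p == 1:4))), 0.25)
})

test_that("DS persistence correlation hits its boundary cases", {
  log <- linear_toy_log()
  base <- dominance_profile(log, "G1", 1:4)
  expect_equal(ds_persistence(base, base)$r, 1)
  rev <- base
  rev$ds <- -rev$ds
  expect_equal(ds_persistence(base, rev)$r, -1)
  two <- base[1:2, ]
  expect_error(ds_persistence(two, two), "3 matched")
})

test_that("high-discriminability groups keep DS across the acute stage", {
  log <- simulate_chases(chase_sim_config(
    n_groups_per_sex = 25, discriminability = 5, dyad_rate = 15,
    seed = 31
  ))
  groups <- unique(log$group_id)
  rs <- vapply(groups, function(g) {
    b <- dominance_profile(log, g, 1:4)
    a <- suppressWarnings(dominance_profile(log, g, 5, "post_acute"))
    ds_persistence(b, a)$r
  }, numeric(1))
  expect_gt(mean(rs), 0.6)
})

test_that("chase_change_anova is zero when stages are identical", {
  counts <- tibble::tibble(
    individual_id = rep(sprintf("m%02d", 1:12), 2),
    sex = rep(rep(c("male", "female"), each = 6), 2),
    stage = rep(c("baseline", "post"), each = 12),
    count = rep(rpois(12, 20), 2)
  )
  res <- chase_change_anova(counts)
  expect_equal(res$statistic[res$term == "stage"], 0)
  expect_equal(res$df2, rep(10, 2))
})

test_that("mixed-ANOVA F and sums of squares match the difference-score oracle", {
  set.seed(61)
  for (rep in 1:30) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    n <- n1 + n2
    sex <- rep(c("male", "female"), c(n1, n2))
    base <- rpois(n, 25); post <- rpois(n, 18)
    counts <- tibble::tibble(
      individual_id = rep(sprintf("m%02d", 1:n), 2),
      sex = rep(sex, 2),
      stage = rep(c("baseline", "post"), each = n),
      count = c(base, post)
    )
    res <- chase_change_anova(counts)
    d <- log(post + 1) - log(base + 1)
    oracle <- mixed_anova_oracle(d, sex)
    expect_equal(res$statistic[res$term == "stage"], oracle$f_stage,
                 tolerance = 1e-9)
    expect_equal(res$statistic[res$term == "sex:stage"], oracle$f_int,
                 tolerance = 1e-9)
    expect_equal(res$p_value[res$term == "stage"], oracle$p_stage,
                 tolerance = 1e-9)
    expect_equal(res$df2, rep(n - 2, 2))
  }
})

test_that("a sex-specific chase drop loads the interaction term", {
  set.seed(62)
  n <- 40
  sex <- rep(c("male", "female"), each = n / 2)
  base <- rpois(n, 40) + 5
  post_inter <- ifelse(sex == "female", round(base / 2), base)
  post_plain <- round(base / sqrt(2))   # same overall drop, no interaction
  make <- function(post) tibble::tibble(
    individual_id = rep(sprintf("m%02d", 1:n), 2),
    sex = rep(sex, 2),
    stage = rep(c("baseline", "post"), each = n),
    count = c(base, post)
  )
  with_int <- chase_change_anova(make(post_inter))
  without <- chase_change_anova(make(post_plain))
  expect_gt(with_int$statistic[with_int$term == "sex:stage"],
            without$statistic[without$term == "sex:stage"])
  expect_lt(with_int$p_value[with_int$term == "sex:stage"], 0.01)
})

test_that("individuals missing a stage are excluded with a message", {
  counts <- tibble::tibble(
    individual_id = c("a", "a", "b", "c", "c", "d", "d"),
    sex = c("m", "m", "m", "f", "f", "f", "f"),
    stage = c("s1", "s2", "s1", "s1", "s2", "s1", "s2"),
    count = c(5L, 3L, 9L, 4L, 2L, 6L, 5L)
  )
  expect_message(res <- chase_change_anova(counts), "excluded 1")
  expect_equal(res$n_subjects[1], 3L)
})
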