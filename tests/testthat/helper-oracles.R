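# Independent oracles and fixture builders shared across test files.

# Fully one-directional transitive 4-group: animal 1 chases everyone,
# 2 chases 3 and 4, 3 chases 4; chase counts per dominated dyad given
# by `per_dyad`.
transitive_w4 <- function(per_dyad = 5L) {
  m <- matrix(0L, 4, 4)
  m[upper.tri(m)] <- per_dyad
  win_matrix(m, ids = c("a", "b", "c", "d"))
}

# Matrix in which the alpha (row 1) initiates every chase.
alpha_only_w4 <- function(per_dyad = 10L) {
  m <- matrix(0L, 4, 4)
  m[1, 2:4] <- per_dyad
  win_matrix(m, ids = c("a", "b", "c", "d"))
}

random_win_matrix <- function(n, max_count = 20) {
  m <- matrix(sample(0:max_count, n * n, replace = TRUE), n, n)
  diag(m) <- 0L
  win_matrix(m)
}

# Naive double-loop evaluation of the David's Score sums.
ds_oracle <- function(P) {
  n <- nrow(P)
  w <- l <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      w[i] <- w[i] + P[i, j]
      l[i] <- l[i] + P[j, i]
    }
  }
  w2 <- l2 <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      w2[i] <- w2[i] + P[i, j] * w[j]
      l2[i] <- l2[i] + P[j, i] * l[j]
    }
  }
  w + w2 - l - l2
}

# Exact two-level mixed-ANOVA decomposition via difference scores:
# for y measured at two stages per subject, the within-subject stratum
# reduces to d_i = y_i2 - y_i1 with
#   SS_stage = (sum d)^2 / (2 n),
#   SS_interaction = between-group SS of d / 2,
#   SS_error = within-group SS of d / 2 on n - 2 df.
mixed_anova_oracle <- function(d, sex) {
  n <- length(d)
  ss_stage <- sum(d)^2 / (2 * n)
  gm <- mean(d)
  means <- tapply(d, sex, mean)
  counts <- tapply(d, sex, length)
  ssb <- sum(counts * (means - gm)^2)
  ssw <- sum((d - means[sex])^2)
  ss_int <- ssb / 2
  ss_err <- ssw / 2
  df_err <- n - 2
  f_stage <- ss_stage / (ss_err / df_err)
  f_int <- ss_int / (ss_err / df_err)
  list(
    ss_stage = ss_stage, ss_int = ss_int, ss_err = ss_err,
    f_stage = f_stage, f_int = f_int, df_err = df_err,
    p_stage = stats::pf(f_stage, 1, df_err, lower.tail = FALSE),
    p_int = stats::pf(f_int, 1, df_err, lower.tail = FALSE)
  )
}

# Landau's h for an explicit orientation of all dyads of an n-cycle
# matrix; used to brute-force the all-unknown expectation.
landau_h_oracle <- function(V, n) {
  (12 / (n^3 - n)) * sum((V - (n - 1) / 2)^2)
}

# Mean Landau h over all 2^C(n,2) tournaments on n nodes.
mean_h_all_tournaments <- function(n) {
  dyads <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  k <- nrow(dyads)
  hs <- vapply(seq_len(2^k) - 1, function(code) {
    bits <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1)))
    V <- tabulate(c(dyads[bits, 1], dyads[!bits, 2]), nbins = n)
    landau_h_oracle(V, n)
  }, numeric(1))
  mean(hs)
}

# Small deterministic toy log: strictly linear chasing a > b > c > d,
# identical every day.
linear_toy_log <- function(days = 1:4, per_dyad = 3L,
                           group = "G1", sex = "male") {
  ids <- c("a", "b", "c", "d")
  rows <- expand.grid(i = 1:4, j = 1:4, day = days)
  rows <- rows[rows$i < rows$j, ]
  as_chase_log(tibble::tibble(
    group_id = group, sex = sex, day = as.integer(rows$day),
    phase = "baseline",
    actor_id = ids[rows$i], recipient_id = ids[rows$j],
    count = per_dyad
  ))
}

# Random chase log over one group for property tests.
random_log <- function(n = 4, days = 1:2, seed = NULL,
                       group = "G1", sex = "female") {
  if (!is.null(seed)) set.seed(seed)
  ids <- letters[seq_len(n)]
  rows <- list()
  for (d in days) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        k <- stats::rpois(1, 2)
        if (k > 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            group_id = group, sex = sex, day = as.integer(d),
            phase = "baseline", actor_id = ids[i],
            recipient_id = ids[j], count = k
          )
        }
      }
    }
  }
  roster <- tibble::tibble(group_id = group, individual_id = ids)
  as_chase_log(dplyr::bind_rows(rows), roster = roster)
}
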