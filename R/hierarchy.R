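#' Hierarchy steepness
#'
#' Absolute OLS slope of the normalized David's Scores, sorted in
#' descending order, regressed on the rank positions 1..N. Ranges from
#' 0 (flat, egalitarian) to 1 (maximally steep: power falls linearly
#' from N-1 to 0 across ranks).
#'
#' @param norm_ds Numeric vector of normalized David's Scores.
#' @return Steepness in \[0, 1\].
#' @export
steepness <- function(norm_ds) {
  n <- length(norm_ds)
  if (n < 2) stop("steepness needs N >= 2", call. = FALSE)
  y <- sort(norm_ds, decreasing = TRUE)
  x <- seq_len(n)
  sxx <- sum((x - mean(x))^2)
  abs(sum((x - mean(x)) * (y - mean(y))) / sxx)
}

#' Hierarchy despotism
#'
#' The fraction of the group's total chases initiated by the top-ranked
#' (alpha) individual: 1 means the alpha initiates every chase, 1/N is
#' the uniform baseline.
#'
#' @param W A `win_matrix`.
#' @param ranks Integer ranks (1 = alpha) aligned with the matrix rows.
#' @return Despotism in \[0, 1\].
#' @export
despotism <- function(W, ranks) {
  S <- unclass(W)
  total <- sum(S)
  if (total == 0) stop("despotism undefined: no chases in matrix",
                       call. = FALSE)
  sum(S[which.min(ranks), ]) / total
}

#' Directional consistency index
#'
#' For each dyad let H and L be the larger and smaller of the two
#' directed counts. The pooled index is
#' `sum(H - L) / sum(H + L)` over dyads that interacted at least once;
#' `method = "mean"` instead averages the per-dyad `(H - L)/(H + L)`
#' fractions. Both equal 1 when every dyad is strictly one-directional
#' and 0 when every dyad is perfectly reciprocal.
#'
#' @param W A `win_matrix`.
#' @param method `"pooled"` (default) or `"mean"`.
#' @return DCI in \[0, 1\].
#' @export
directional_consistency <- function(W, method = c("pooled", "mean")) {
  method <- match.arg(method)
  S <- unclass(W)
  n <- nrow(S)
  up <- upper.tri(S)
  a <- S[up]
  b <- t(S)[up]
  tot <- a + b
  keep <- tot > 0
  if (!any(keep)) stop("DCI undefined: all dyads empty", call. = FALSE)
  H <- pmax(a, b)[keep]
  L <- pmin(a, b)[keep]
  if (method == "pooled") {
    sum(H - L) / sum(H + L)
  } else {
    mean((H - L) / (H + L))
  }
}

landau_h <- function(V, n) {
  (12 / (n^3 - n)) * sum((V - (n - 1) / 2)^2)
}

#' Linearity: Landau's modified h-prime
#'
#' The binary dominance relation sets i over j when `s_ij > s_ji`.
#' Tied dyads (`s_ij == s_ji > 0`) and unknown dyads (`n_ij == 0`) are
#' oriented uniformly at random in each of `n_rand` replicates; each
#' replicate evaluates Landau's index
#' `h = 12/(N^3 - N) * sum_i (V_i - (N-1)/2)^2`, where `V_i` is the
#' number of individuals i dominates, and h' is the replicate mean. A
#' fully transitive order with no ties gives h' = 1 regardless of the
#' randomization. The right-tail p-value compares the observed h'
#' against `n_rand` fully random tournaments.
#'
#' @param W A `win_matrix` with N >= 3.
#' @param n_rand Number of randomization replicates (default 10000).
#' @param seed Optional integer seed for the randomization, applied
#'   locally so the caller's RNG state is untouched.
#' @return A list with `h_prime`, `p`, `n_rand`, and `n_undecided`
#'   (count of tied + unknown dyads).
#' @export
linearity_h_prime <- function(W, n_rand = 10000, seed = NULL) {
  if (n_rand < 1) stop("n_rand must be >= 1", call. = FALSE)
  S <- unclass(W)
  n <- nrow(S)
  if (n < 3) stop("linearity needs N >= 3", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  up <- which(upper.tri(S), arr.ind = TRUE)
  a <- S[up]
  b <- S[cbind(up[, 2], up[, 1])]
  decided_i_wins <- a > b          # i (row) dominates j
  undecided <- a == b              # ties and unknowns alike
  n_dyads <- nrow(up)

  h_of_orientation <- function(i_wins) {
    V <- numeric(n)
    wi <- up[i_wins, 1, drop = TRUE]
    wj <- up[!i_wins, 2, drop = TRUE]
    tw <- tabulate(c(wi, wj), nbins = n)
    landau_h(tw, n)
  }

  if (!any(undecided)) {
    h_prime <- h_of_orientation(decided_i_wins)
    h_obs_reps <- rep(h_prime, 0)
  } else {
    hs <- vapply(seq_len(n_rand), function(r) {
      ori <- decided_i_wins
      ori[undecided] <- stats::runif(sum(undecided)) < 0.5
      h_of_orientation(ori)
    }, numeric(1))
    h_prime <- mean(hs)
  }
  # null reference: fully random tournaments
  h_null <- vapply(seq_len(n_rand), function(r) {
    h_of_orientation(stats::runif(n_dyads) < 0.5)
  }, numeric(1))
  p <- mean(h_null >= h_prime)
  list(h_prime = h_prime, p = p, n_rand = as.integer(n_rand),
       n_undecided = sum(undecided))
}

#' All four hierarchy metrics for one group
#'
#' Convenience wrapper computing steepness, despotism, directional
#' consistency and Landau's modified h' (with its randomization
#' p-value) from a chase log, one row per group.
#'
#' @inheritParams dominance_profile
#' @param n_rand Randomization replicates for h'.
#' @param seed Seed for the h' randomization.
#' @param dci_method Passed to [directional_consistency()].
#' @return A `hierarchy_metrics` tibble with one row: `group_id`,
#'   `steepness`, `despotism`, `dci`, `h_prime`, `h_prime_p`,
#'   `n_randomizations`, `seed`.
#' @export
hierarchy_metrics <- function(log, group, days, phase = "baseline",
                              corrected = FALSE, n_rand = 10000,
                              seed = NULL,
                              dci_method = c("pooled", "mean")) {
  dci_method <- match.arg(dci_method)
  prof <- dominance_profile(log, group, days, phase, corrected)
  W <- attr(prof, "win_matrix")
  lin <- linearity_h_prime(W, n_rand = n_rand, seed = seed)
  out <- tibble::tibble(
    group_id = group,
    steepness = steepness(prof$norm_ds),
    despotism = despotism(W, prof$rank),
    dci = directional_consistency(W, dci_method),
    h_prime = lin$h_prime,
    h_prime_p = lin$p,
    n_randomizations = lin$n_rand,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  structure(out,
            class = c("hierarchy_metrics", class(tibble::tibble())))
}

#' @exportS3Method generics::glance
glance.hierarchy_metrics <- function(x, ...) {
  tibble::as_tibble(x)
}
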