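#' Dyadic win proportions
#'
#' For each ordered dyad (i, j) with `n_ij = s_ij + s_ji` observed
#' chases, the raw win proportion is `P_ij = s_ij / n_ij`. Dyads that
#' never interacted (`n_ij = 0`) contribute 0 in both directions by
#' default (the conventional treatment), or 0.5 with
#' `zero_dyad = "half"`. With `corrected = TRUE` the chance-corrected
#' dyadic index `D_ij = P_ij - (P_ij - 0.5) / (n_ij + 1)` is returned
#' instead, which shrinks sparse dyads toward 0.5.
#'
#' @param W A `win_matrix`.
#' @param corrected Use the chance-corrected dyadic proportions
#'   (default `FALSE`: raw proportions, under which the normalized
#'   David's Score attains its full 0 to N-1 range).
#' @param zero_dyad Value convention for never-interacting dyads:
#'   `"zero"` (default) or `"half"`.
#'
#' @return An N x N numeric matrix with zero diagonal; for every
#'   interacting dyad the two raw proportions sum to 1.
#' @export
win_proportions <- function(W, corrected = FALSE,
                            zero_dyad = c("zero", "half")) {
  zero_dyad <- match.arg(zero_dyad)
  S <- unclass(W) * 1.0
  N <- S + t(S)
  P <- matrix(if (zero_dyad == "half") 0.5 else 0,
              nrow(S), ncol(S), dimnames = dimnames(S))
  nz <- N > 0
  P[nz] <- S[nz] / N[nz]
  if (corrected) {
    P[nz] <- P[nz] - (P[nz] - 0.5) / (N[nz] + 1)
  }
  diag(P) <- 0
  P
}

#' David's Score from a win-proportion matrix
#'
#' `DS_i = w_i + w2_i - l_i - l2_i`, where `w_i` is i's summed win
#' proportions, `w2_i = sum_j P_ij * w_j` weights wins by the
#' opponents' own success, and `l_i`, `l2_i` are the mirror-image loss
#' terms. Scores always sum to zero over the group.
#'
#' @param P Square win-proportion matrix with zero diagonal (see
#'   [win_proportions()]).
#' @return Named numeric vector of David's Scores.
#' @export
davids_score <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("P must be square", call. = FALSE)
  w  <- rowSums(P)
  l  <- colSums(P)
  w2 <- as.numeric(P %*% w)
  l2 <- as.numeric(t(P) %*% l)
  ds <- w + w2 - l - l2
  names(ds) <- rownames(P)
  ds
}

#' Normalize David's Scores to the 0 .. N-1 range
#'
#' `nDS_i = (DS_i + N(N-1)/2) / N`. For groups of four this yields the
#' continuous 0 (most subordinate) to 3 (most dominant) scale; the sum
#' is always `N(N-1)/2`.
#'
#' @param ds Vector of David's Scores.
#' @param n Group size (defaults to `length(ds)`).
#' @return Numeric vector of normalized scores.
#' @export
normalize_ds <- function(ds, n = length(ds)) {
  if (length(ds) != n) stop("length(ds) must equal n", call. = FALSE)
  (ds + n * (n - 1) / 2) / n
}

#' Ordinal ranks from normalized David's Scores
#'
#' Rank 1 (alpha) is the highest score, rank N (delta, for N = 4) the
#' lowest. Ties are broken by total chases initiated (more chases wins
#' the higher rank), then by roster order; tie-breaks are recorded in
#' the `tie_breaks` attribute so they can be audited.
#'
#' @param norm_ds Numeric vector of normalized scores.
#' @param chases_initiated Optional numeric vector of per-individual
#'   initiated-chase totals used as the first tie-break.
#' @return Integer vector of ranks (a permutation of `1:N`) with a
#'   `tie_breaks` attribute counting tied score pairs.
#' @export
assign_ranks <- function(norm_ds, chases_initiated = NULL) {
  n <- length(norm_ds)
  if (is.null(chases_initiated)) chases_initiated <- rep(0, n)
  ord <- order(-norm_ds, -chases_initiated, seq_len(n))
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  n_ties <- sum(duplicated(norm_ds))
  attr(ranks, "tie_breaks") <- n_ties
  names(ranks) <- names(norm_ds)
  ranks
}

#' Dominance profile for one group and time window
#'
#' Composes [aggregate_wins()], [win_proportions()], [davids_score()],
#' [normalize_ds()] and [assign_ranks()] into a per-individual
#' dominance table. The default (`mode = "pooled"`) pools chase counts
#' across the selected days before scoring — the cumulative score used
#' as the final dominance measure; `mode = "sum_daily"` instead sums
#' the daily David's Scores, provided for sensitivity analysis.
#'
#' @inheritParams aggregate_wins
#' @inheritParams win_proportions
#' @param mode `"pooled"` (default) or `"sum_daily"`.
#'
#' @return A `dominance_profile` tibble with columns `individual_id`,
#'   `ds`, `norm_ds`, `rank`, `chases_initiated`, plus `group_id`,
#'   `phase` and the day window as attributes.
#' @export
dominance_profile <- function(log, group, days, phase = "baseline",
                              corrected = FALSE,
                              zero_dyad = c("zero", "half"),
                              mode = c("pooled", "sum_daily")) {
  mode <- match.arg(mode)
  zero_dyad <- match.arg(zero_dyad)
  W <- aggregate_wins(log, group, days, phase)
  ids <- rownames(W)
  n <- length(ids)
  if (mode == "pooled") {
    ds <- davids_score(win_proportions(W, corrected, zero_dyad))
  } else {
    daily <- lapply(days, function(d) {
      Wd <- suppressWarnings(aggregate_wins(log, group, d, phase))
      davids_score(win_proportions(Wd, corrected, zero_dyad))
    })
    ds <- Reduce(`+`, daily)
  }
  nds <- normalize_ds(ds, n)
  init <- rowSums(unclass(W))
  rk <- assign_ranks(nds, init)
  sex <- unique(log$sex[log$group_id == group])
  out <- tibble::tibble(
    individual_id = ids,
    group_id = group,
    sex = if (length(sex) == 1) sex else NA_character_,
    ds = unname(ds),
    norm_ds = unname(nds),
    rank = as.integer(rk),
    chases_initiated = unname(init)
  )
  structure(out, phase = phase, days = days, win_matrix = W,
            class = c("dominance_profile", class(tibble::tibble())))
}

#' @export
print.dominance_profile <- function(x, ...) {
  cat("# dominance_profile: group", unique(x$group_id),
      "| phase", attr(x, "phase"),
      "| days", paste(attr(x, "days"), collapse = ","), "\n")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.dominance_profile <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.dominance_profile <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    ds_sum = sum(x$ds),
    norm_ds_max = max(x$norm_ds),
    norm_ds_min = min(x$norm_ds),
    total_chases = sum(x$chases_initiated)
  )
}
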