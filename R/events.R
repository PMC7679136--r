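#' Read a chase-event log from a delimited file
#'
#' Chase-event logs are long-format tables with one row per directed
#' chase (or per aggregated actor/recipient/day cell with a `count`
#' column). Required columns: `group_id`, `sex`, `day`, `phase`,
#' `actor_id`, `recipient_id`; `count` is optional and defaults to 1
#' per row, so per-chase single-row files are accepted as-is.
#'
#' @param path Path to a CSV file (comma separated, header row, UTF-8).
#' @param schema Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(actor_id = "chaser", recipient_id = "chased")`. Unmapped
#'   canonical names are looked up directly.
#' @param roster Optional data frame with columns `group_id`,
#'   `individual_id` (and optionally `sex`) declaring the full group
#'   membership, so that animals that never chase nor get chased still
#'   count toward group size.
#'
#' @return A `chase_log` tibble with columns `group_id`, `sex`, `day`,
#'   `phase`, `actor_id`, `recipient_id`, `count`, validated (no
#'   self-chases, positive integer counts) and carrying the roster as
#'   an attribute.
#' @export
read_chase_events <- function(path, schema = NULL, roster = NULL) {
  if (!file.exists(path)) {
    stop("events file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  canonical <- c("group_id", "sex", "day", "phase", "actor_id",
                 "recipient_id", "count")
  lookup <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) lookup[names(schema)] <- unname(schema)
  required <- setdiff(canonical, "count")
  missing_cols <- required[!lookup[required] %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("events file is missing required column(s): ",
         paste(lookup[missing_cols], collapse = ", "),
         " (canonical: ", paste(missing_cols, collapse = ", "), ")",
         call. = FALSE)
  }
  out <- tibble::tibble(
    group_id     = as.character(raw[[lookup["group_id"]]]),
    sex          = as.character(raw[[lookup["sex"]]]),
    day          = as.integer(raw[[lookup["day"]]]),
    phase        = as.character(raw[[lookup["phase"]]]),
    actor_id     = as.character(raw[[lookup["actor_id"]]]),
    recipient_id = as.character(raw[[lookup["recipient_id"]]]),
    count        = if (lookup["count"] %in% names(raw)) {
      as.integer(raw[[lookup["count"]]])
    } else {
      1L
    }
  )
  as_chase_log(out, roster = roster)
}

#' Validate a data frame of chase events
#'
#' @param events Data frame with the canonical chase-log columns (see
#'   [read_chase_events()]).
#' @param roster Optional roster data frame (`group_id`,
#'   `individual_id`); defaults to the union of actors and recipients
#'   observed per group.
#'
#' @return A validated `chase_log` tibble.
#' @export
as_chase_log <- function(events, roster = NULL) {
  events <- tibble::as_tibble(events)
  needed <- c("group_id", "sex", "day", "phase", "actor_id", "recipient_id")
  miss <- setdiff(needed, names(events))
  if (length(miss) > 0) {
    stop("chase log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"count" %in% names(events)) events$count <- 1L
  bad_self <- which(events$actor_id == events$recipient_id)
  if (length(bad_self) > 0) {
    stop("self-chase rows (actor_id == recipient_id) at row(s): ",
         paste(utils::head(bad_self, 10), collapse = ", "), call. = FALSE)
  }
  if (anyNA(events$count) || any(events$count < 1) ||
      any(events$count != round(events$count))) {
    stop("chase counts must be positive integers", call. = FALSE)
  }
  events$count <- as.integer(events$count)
  if (anyNA(events$day) || any(events$day < 1)) {
    stop("days must be integers >= 1", call. = FALSE)
  }
  if (is.null(roster)) {
    roster <- dplyr::bind_rows(
      dplyr::select(events, "group_id", individual_id = "actor_id"),
      dplyr::select(events, "group_id", individual_id = "recipient_id")
    )
    roster <- dplyr::arrange(
      dplyr::distinct(roster), .data$group_id, .data$individual_id
    )
  } else {
    roster <- tibble::as_tibble(roster)
    seen <- unique(c(
      paste(events$group_id, events$actor_id),
      paste(events$group_id, events$recipient_id)
    ))
    declared <- paste(roster$group_id, roster$individual_id)
    orphan <- setdiff(seen, declared)
    if (length(orphan) > 0) {
      stop("individuals appear in events but not in roster: ",
           paste(utils::head(orphan, 5), collapse = "; "), call. = FALSE)
    }
  }
  structure(events, roster = roster,
            class = c("chase_log", class(tibble::tibble())))
}

#' @export
print.chase_log <- function(x, ...) {
  cat("# chase_log:", nrow(x), "rows,",
      length(unique(x$group_id)), "group(s)\n")
  NextMethod()
}

chase_roster <- function(log) {
  attr(log, "roster", exact = TRUE)
}

#' Write a chase-event log to CSV
#'
#' @param log A `chase_log` (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_chase_events <- function(log, path) {
  readr::write_csv(tibble::as_tibble(log), path, progress = FALSE)
  invisible(path)
}

#' Aggregate chase events into a directed win matrix
#'
#' Sums chase counts over the selected group, days and phase into an
#' N x N matrix whose (i, j) entry is the number of chases by `i`
#' directed at `j`. Individuals from the group roster with no events in
#' the window still occupy rows and columns, since group size enters
#' the David's Score normalization.
#'
#' Aggregation is additive over disjoint day sets:
#' `W(days1 U days2) = W(days1) + W(days2)`.
#'
#' @param log A `chase_log`.
#' @param group Group identifier.
#' @param days Integer vector of days to include.
#' @param phase Phase label to include (default `"baseline"`).
#'
#' @return A `win_matrix`: an integer matrix with the roster ids as
#'   dimnames. An empty selection yields a zero matrix with a warning.
#' @export
aggregate_wins <- function(log, group, days, phase = "baseline") {
  roster <- chase_roster(log)
  if (!group %in% log$group_id &&
      (is.null(roster) || !group %in% roster$group_id)) {
    stop("unknown group: ", group, call. = FALSE)
  }
  if (length(days) == 0) stop("days must be nonempty", call. = FALSE)
  ids <- sort(roster$individual_id[roster$group_id == group])
  sel <- log$group_id == group & log$day %in% days & log$phase == phase
  sub <- log[sel, , drop = FALSE]
  W <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(sub) == 0) {
    warning("no events for group ", group, " in the selected window; ",
            "returning a zero matrix", call. = FALSE)
  } else {
    agg <- dplyr::summarise(
      dplyr::group_by(sub, .data$actor_id, .data$recipient_id),
      count = sum(.data$count), .groups = "drop"
    )
    W[cbind(match(agg$actor_id, ids), match(agg$recipient_id, ids))] <-
      as.integer(agg$count)
  }
  win_matrix(W)
}

#' Construct a win matrix
#'
#' @param counts Square nonnegative-integer matrix of directed chase
#'   counts with a zero diagonal; dimnames give the roster.
#' @param ids Optional character roster overriding the dimnames.
#' @return A `win_matrix` object.
#' @export
win_matrix <- function(counts, ids = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("win matrix must be square",
                                         call. = FALSE)
  if (nrow(counts) < 2) stop("win matrix needs N >= 2", call. = FALSE)
  if (!is.null(ids)) dimnames(counts) <- list(ids, ids)
  if (is.null(rownames(counts))) {
    ids <- paste0("id", seq_len(nrow(counts)))
    dimnames(counts) <- list(ids, ids)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("win counts must be nonnegative", call. = FALSE)
  }
  if (any(diag(counts) != 0)) stop("win matrix diagonal must be zero",
                                   call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(counts, class = c("win_matrix", "matrix", "array"))
}

#' @export
print.win_matrix <- function(x, ...) {
  cat("# win_matrix:", nrow(x), "individuals,", sum(x), "chases\n")
  print(unclass(x))
  invisible(x)
}

#' Read / write win matrices as wide CSV
#'
#' The on-disk format is a wide CSV with the roster ids in the first
#' column (`id`) and one column per recipient.
#'
#' @param W A `win_matrix`.
#' @param path CSV path.
#' @return `read_win_matrix` returns a `win_matrix`; `write_win_matrix`
#'   returns `path` invisibly.
#' @export
write_win_matrix <- function(W, path) {
  df <- tibble::as_tibble(unclass(W), rownames = "id")
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_win_matrix
#' @export
read_win_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  win_matrix(m)
}
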