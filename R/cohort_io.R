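# Cohort file IO and cohort construction from raw event tables.
#
# On-disk schema (long format, delimited/CSV): one row per event with the
# recipient's covariates repeated; a recipient with no recorded events is
# kept as a single row with NA event_time_days. Columns:
#   recipient_id, event_time_days, obs_length_days, <covariate columns...>
# No spreadsheet (XLSX) reader is available in this toolchain, so delimited
# text is the supported format.

#' Write a cohort to a delimited file
#'
#' Deterministic output: rows ordered by recipient id (as character) then
#' event time, fixed column order, so two writes of the same cohort are
#' byte-identical.
#'
#' @param cohort a `tpp_cohort`.
#' @param path output file path (CSV).
#' @return invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "tpp_cohort"))
  rows <- lapply(cohort$recipients, function(r) {
    n <- max(length(r$event_times), 1L)
    d <- data.frame(
      recipient_id = rep(r$recipient_id, n),
      event_time_days = if (length(r$event_times)) r$event_times else NA_real_,
      obs_length_days = rep(r$obs_length, n))
    for (k in seq_along(cohort$covariate_names))
      d[[cohort$covariate_names[k]]] <- r$covariates[k]
    d
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$recipient_id, tab$event_time_days), , drop = FALSE]
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a cohort from a delimited file
#'
#' Reads the long-format schema written by [write_cohort()]. Event rows may
#' appear in any order; duplicate `(recipient, time)` rows are collapsed
#' with a warning; events at or beyond a recipient's `obs_length_days` are
#' a validation error naming the recipient.
#'
#' @param path CSV file path.
#' @return a `tpp_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("recipient_id", "event_time_days", "obs_length_days")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "), call. = FALSE)
  cov_names <- setdiff(names(tab), req)
  ids <- unique(as.character(tab$recipient_id))
  bad <- character(0)
  recips <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    d <- tab[as.character(tab$recipient_id) == ids[k], , drop = FALSE]
    Ti <- unique(d$obs_length_days)
    if (length(Ti) != 1L || is.na(Ti))
      stop(sprintf("recipient %s: obs_length_days must be a single value", ids[k]),
           call. = FALSE)
    times <- d$event_time_days[!is.na(d$event_time_days)]
    if (anyDuplicated(times)) {
      warning(sprintf("recipient %s: duplicate event times collapsed", ids[k]),
              call. = FALSE)
      times <- unique(times)
    }
    if (length(times) && any(times >= Ti)) {
      bad <- c(bad, ids[k])
      next
    }
    xv <- if (length(cov_names)) {
      v <- as.numeric(d[1L, cov_names])
      stats::setNames(v, cov_names)
    } else numeric(0)
    recips[[k]] <- recipient_history(ids[k], sort(times), xv, Ti)
  }
  if (length(bad))
    stop("event times at or beyond obs_length for recipient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  new_cohort(recips, covariate_names = cov_names)
}

# internal: dummy-encode a one-row-per-recipient covariate data frame.
# Character/factor columns are encoded against the alphabetically first
# level; numeric columns pass through unchanged.
encode_covariates <- function(df) {
  if (ncol(df) == 0L) return(matrix(0, nrow(df), 0))
  cols <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v) || is.logical(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      lev <- sort(unique(as.character(v)))
      for (l in lev[-1L])
        cols[[paste(nm, l, sep = ".")]] <- as.numeric(as.character(v) == l)
    }
  }
  do.call(cbind, cols)
}

#' Build an analysis cohort from a raw event table
#'
#' Applies the cohort-construction rules to pre-extracted event records:
#' per recipient, the qualifying event is the earliest one preceded by at
#' least `baseline_days` event-free days within the study window (the
#' baseline condition is evaluated on *observed* events only; history
#' before `study_start` is unknowable); the index date is that event plus
#' `index_offset_days`; recipients without an event strictly after the
#' index date, under `min_age` at index, or with missing demographics are
#' excluded, each with a reason in the exclusion log. Event times are
#' converted to days since the index date and the observation window is
#' censored at `study_end`.
#'
#' Same-day repeat diagnoses are collapsed to a single event by default
#' (claims commonly duplicate codes).
#'
#' @param raw data frame with columns `recipient_id`, `event_date`
#'   (`Date` or `"YYYY-MM-DD"` strings), optionally `age` (age at index
#'   date, used for the `min_age` rule), and any further covariate columns
#'   (constant within recipient; character/factor columns are
#'   dummy-encoded against the alphabetically first level).
#' @param study_start,study_end study window dates.
#' @param baseline_days event-free run-in required before the qualifying
#'   event (days).
#' @param index_offset_days days after the qualifying event that define the
#'   index date.
#' @param min_age minimum age at index date.
#' @param collapse_same_day collapse duplicate same-day events.
#' @return list with `cohort` (a `tpp_cohort`, or `NULL` if no recipient
#'   qualifies) and `exclusions` (data frame `recipient_id`, `reason`).
#' @export
build_cohort <- function(raw, study_start, study_end,
                         baseline_days = 90L, index_offset_days = 90L,
                         min_age = 18L, collapse_same_day = TRUE) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (is.na(study_start) || is.na(study_end) || study_end <= study_start)
    stop("study_end must be after study_start", call. = FALSE)
  if (nrow(raw) == 0L)
    return(list(cohort = NULL,
                exclusions = data.frame(recipient_id = character(0),
                                        reason = character(0))))
  if (!all(c("recipient_id", "event_date") %in% names(raw)))
    stop("`raw` needs recipient_id and event_date columns", call. = FALSE)
  dates <- if (inherits(raw$event_date, "Date")) raw$event_date else
    as.Date(as.character(raw$event_date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    n_bad <- sum(is.na(dates))
    stop(sprintf("%d unparseable event_date value(s) (expected YYYY-MM-DD)",
                 n_bad), call. = FALSE)
  }
  raw$event_date <- dates
  in_window <- dates >= study_start & dates <= study_end
  raw <- raw[in_window, , drop = FALSE]

  cov_cols <- setdiff(names(raw), c("recipient_id", "event_date", "age"))
  ids <- unique(as.character(raw$recipient_id))
  excl <- list()
  recips <- list()
  cov_rows <- list()
  for (id in ids) {
    d <- raw[as.character(raw$recipient_id) == id, , drop = FALSE]
    ev <- sort(unique(d$event_date))
    if (!collapse_same_day) ev <- sort(d$event_date)
    # earliest event with an event-free run-in of baseline_days observed days
    gaps_ok <- c(TRUE, diff(ev) >= baseline_days)
    qual <- ev[which(gaps_ok)[1L]]
    index_date <- qual + index_offset_days
    post <- ev[ev > index_date]
    if (length(post) == 0L) {
      excl[[id]] <- "no overdose after index date"
      next
    }
    if (index_date >= study_end) {
      excl[[id]] <- "index date at or after study end"
      next
    }
    if ("age" %in% names(d)) {
      a <- d$age[1L]
      if (is.na(a)) { excl[[id]] <- "missing demographics"; next }
      if (a < min_age) { excl[[id]] <- "under minimum age at index date"; next }
    }
    if (length(cov_cols) && anyNA(d[1L, cov_cols])) {
      excl[[id]] <- "missing demographics"
      next
    }
    times <- as.numeric(post - index_date)
    obs_len <- as.numeric(study_end - index_date)
    # events exactly at study_end would sit on the closed edge; keep within [0, T)
    times <- times[times < obs_len]
    if (length(times) == 0L) {
      excl[[id]] <- "no overdose after index date"
      next
    }
    recips[[id]] <- list(times = times, obs_len = obs_len)
    cov_rows[[id]] <- d[1L, cov_cols, drop = FALSE]
  }
  exclusions <- data.frame(recipient_id = names(excl),
                           reason = unlist(excl, use.names = FALSE),
                           stringsAsFactors = FALSE)
  if (length(recips) == 0L)
    return(list(cohort = NULL, exclusions = exclusions))
  covdf <- do.call(rbind, cov_rows)
  X <- encode_covariates(covdf)
  nm <- colnames(X)
  if (is.null(nm)) nm <- character(0)
  rec_objs <- vector("list", length(recips))
  for (k in seq_along(recips)) {
    id <- names(recips)[k]
    xv <- if (length(nm)) stats::setNames(X[k, ], nm) else numeric(0)
    rec_objs[[k]] <- recipient_history(id, recips[[k]]$times, xv,
                                       recips[[k]]$obs_len)
  }
  list(cohort = new_cohort(rec_objs, covariate_names = nm),
       exclusions = exclusions)
}
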