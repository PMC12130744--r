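#' Read raw capture records
#'
#' Reads the capture-record CSV (one row per capture of an adult bird) with
#' columns `individual_id`, `year`, `sex` (`F`/`M`/empty), `ringed_as_nestling`,
#' `ringing_year`, `brood_id`, `brood_size`, `breeder_with_success`.
#'
#' @param path CSV path (UTF-8, header row).
#' @return Data frame of capture records; unknown sex is `NA`.
#' @export
read_capture_records <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("individual_id", "year", "sex", "ringed_as_nestling",
            "ringing_year", "brood_id", "brood_size", "breeder_with_success")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("capture CSV missing columns: ", paste(miss, collapse = ", "))
  d$individual_id <- as.character(d$individual_id)
  d$year <- as.integer(d$year)
  d$sex <- as.character(d$sex)
  d$sex[!d$sex %in% c("F", "M")] <- NA_character_
  d$ringed_as_nestling <- as.logical(d$ringed_as_nestling)
  d$ringing_year <- as.integer(d$ringing_year)
  d$brood_id <- as.character(d$brood_id)
  d$brood_size <- as.integer(d$brood_size)
  if (any(!is.na(d$brood_size) & d$brood_size < 1L))
    stop("brood_size must be >= 1 when present")
  d$breeder_with_success <- as.logical(d$breeder_with_success)
  d[need]
}

#' Read a nestling morphometrics table
#'
#' @param path CSV with columns `brood_id`, `year`, `mass_g`, `tarsus_mm`
#'   (missing measurements allowed).
#' @return Data frame of nestling records.
#' @export
read_nestlings <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("brood_id", "year", "mass_g", "tarsus_mm")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("nestling CSV missing columns: ", paste(miss, collapse = ", "))
  d$brood_id <- as.character(d$brood_id)
  d$year <- as.integer(d$year)
  d$mass_g <- as.numeric(d$mass_g)
  d$tarsus_mm <- as.numeric(d$tarsus_mm)
  d[need]
}

#' Collapse raw captures to at most one record per individual and year
#'
#' Raw field data may contain several captures of the same bird within a
#' year. A record carrying brood information (a brood size or a brood
#' identifier) is preferred over one without; conflicting non-missing brood
#' sizes within a year resolve to the maximum, with a warning naming the
#' individual. Conflicting sexes (F vs M) for one individual are an error;
#' a known sex fills in unknown-sex records of the same bird.
#'
#' @param records Capture-record data frame (see [read_capture_records()]).
#' @return Collapsed records, one row per individual x year.
#' @export
collapse_to_annual <- function(records) {
  if (nrow(records) == 0L) return(records)
  sex_conflicts <- character()
  out <- list()
  for (id in unique(records$individual_id)) {
    ri <- records[records$individual_id == id, , drop = FALSE]
    sx <- unique(ri$sex[!is.na(ri$sex)])
    if (length(sx) > 1L) { sex_conflicts <- c(sex_conflicts, id); next }
    if (length(sx) == 1L) ri$sex <- sx
    for (yr in unique(ri$year)) {
      ry <- ri[ri$year == yr, , drop = FALSE]
      if (nrow(ry) > 1L) {
        info <- !is.na(ry$brood_size) | !is.na(ry$brood_id)
        if (any(info)) ry <- ry[info, , drop = FALSE]
        sizes <- unique(ry$brood_size[!is.na(ry$brood_size)])
        if (length(sizes) > 1L) {
          warning(sprintf("individual %s has conflicting brood sizes in %d (%s); keeping the maximum",
                          id, yr, paste(sort(sizes), collapse = ", ")))
          ry <- ry[which.max(ry$brood_size), , drop = FALSE]
        } else {
          ry <- ry[1L, , drop = FALSE]
        }
        ry$breeder_with_success <- any(records$breeder_with_success[
          records$individual_id == id & records$year == yr], na.rm = TRUE)
      }
      out[[length(out) + 1L]] <- ry
    }
  }
  if (length(sex_conflicts))
    stop("conflicting sex records for individual(s): ",
         paste(sex_conflicts, collapse = ", "))
  res <- do.call(rbind, out)
  res <- res[order(res$individual_id, res$year), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Apply the study's dataset filters
#'
#' Three filters, in order: (a) keep only years `first_year..last_year`
#' (the first two survey years had almost no adult captures and are dropped);
#' (b) remove entirely any individual whose first retained capture falls in
#' the final year, since it carries no survival information; (c) optionally
#' drop captures of successful breeders whose brood size is missing (the
#' brood-size measure cannot code their state). Per-filter removal counts are
#' reported via `message()` and attached as the `"filter_counts"` attribute.
#'
#' @param records Collapsed capture records.
#' @param first_year,last_year Retained study window (defaults 2008-2021).
#' @param drop_terminal_first_captures Apply filter (b)?
#' @param require_brood_info Apply filter (c)?
#' @param quiet Suppress the count messages.
#' @return Filtered records with attribute `filter_counts`.
#' @export
apply_study_filters <- function(records, first_year = 2008, last_year = 2021,
                                drop_terminal_first_captures = TRUE,
                                require_brood_info = TRUE, quiet = FALSE) {
  n0 <- nrow(records)
  keep <- records$year >= first_year & records$year <= last_year
  r <- records[keep, , drop = FALSE]
  n_year <- n0 - nrow(r)
  n_term <- 0L
  if (drop_terminal_first_captures && nrow(r) > 0L) {
    first_cap <- tapply(r$year, r$individual_id, min)
    drop_ids <- names(first_cap)[first_cap == last_year]
    n_term <- sum(r$individual_id %in% drop_ids)
    r <- r[!r$individual_id %in% drop_ids, , drop = FALSE]
  }
  n_brood <- 0L
  if (require_brood_info && nrow(r) > 0L) {
    bad <- r$breeder_with_success & is.na(r$brood_size)
    n_brood <- sum(bad)
    r <- r[!bad, , drop = FALSE]
  }
  counts <- c(input = n0, outside_years = n_year,
              terminal_first_capture = n_term, missing_brood_size = n_brood,
              retained = nrow(r))
  if (!quiet)
    message(sprintf(paste0("filters: %d records in; %d outside %d-%d; %d from ",
                           "individuals first captured in %d; %d breeder captures ",
                           "without brood size; %d retained"),
                    n0, n_year, first_year, last_year, n_term, last_year,
                    n_brood, nrow(r)))
  attr(r, "filter_counts") <- counts
  rownames(r) <- NULL
  r
}

#' Encode filtered capture records as encounter histories
#'
#' Event codes: 0 = not captured, 1 = captured in state N, 2 = L, 3 = H, and
#' (brood-mass measure only) 4 = captured breeder whose brood mass is
#' unknown. The age class at first capture is `capture_year - ringing_year`
#' for birds ringed as nestlings, binned 1, 2, 3, 4+ ; otherwise unknown.
#'
#' @param records Collapsed, filtered capture records.
#' @param states Data frame `individual_id`, `year`, `state` with state in
#'   `N`/`L`/`H` or `U` (unassigned breeder, mass measure only); see
#'   [build_state_table()]. Every capture must have a state, and every state
#'   must match a capture.
#' @param measure `"size"` or `"mass"`.
#' @param occasion_years Calendar years mapped to occasions 1..T; defaults to
#'   the full range of years present in `records`.
#' @return An [encounter_histories()] set.
#' @export
encode_histories <- function(records, states, measure = c("size", "mass"),
                             occasion_years = NULL) {
  measure <- match.arg(measure)
  key <- function(id, yr) paste(id, yr, sep = "\r")
  rec_keys <- key(records$individual_id, records$year)
  st_keys <- key(states$individual_id, states$year)
  orphan <- setdiff(st_keys, rec_keys)
  if (length(orphan))
    stop("state assigned to individual x year with no capture record: ",
         paste(gsub("\r", "/", orphan[seq_len(min(5, length(orphan)))]),
               collapse = ", "))
  miss <- setdiff(rec_keys, st_keys)
  if (length(miss))
    stop(length(miss), " capture(s) have no assigned state")
  state_of <- setNames(states$state, st_keys)
  occasion_years <- occasion_years %||% seq(min(records$year), max(records$year))
  if (any(diff(occasion_years) != 1L)) stop("occasions must be consecutive years")
  T <- length(occasion_years)
  ids <- sort(unique(records$individual_id))
  events <- matrix(0L, length(ids), T)
  sex <- rep(NA_character_, length(ids))
  age_entry <- rep(NA_integer_, length(ids))
  codes <- c(N = 1L, L = 2L, H = 3L, U = 4L)
  for (k in seq_along(ids)) {
    ri <- records[records$individual_id == ids[k], , drop = FALSE]
    occ <- match(ri$year, occasion_years)
    if (any(is.na(occ))) stop("capture year outside occasion_years for ", ids[k])
    st <- state_of[key(ri$individual_id, ri$year)]
    if (measure == "size" && any(st == "U"))
      stop("unassigned-breeder state 'U' is only valid for measure = 'mass'")
    events[k, occ] <- codes[st]
    sex[k] <- ri$sex[1L]
    first_year <- min(ri$year)
    rn <- ri$ringed_as_nestling[1L] %in% TRUE
    if (rn && !is.na(ri$ringing_year[1L]))
      age_entry[k] <- min(first_year - ri$ringing_year[1L], 4L)
  }
  if (any(!is.na(age_entry) & age_entry < 1L))
    stop("age at first adult capture below 1 year; check ringing_year")
  encounter_histories(events, sex = sex, age_entry = age_entry,
                      measure = measure, occasion_years = occasion_years,
                      ids = ids)
}

#' Write encounter histories as CSV or MARK-style .inp
#'
#' The CSV has one row per individual (`id`, `sex`, `age_class`, and the
#' concatenated event codes per occasion). The `.inp` form writes
#' `/* id */ 02030 1;` lines for interoperability with MARK-family software.
#'
#' @param h An `owlcmr_histories`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_histories_csv <- function(h, path) {
  d <- data.frame(id = h$ids, sex = ifelse(is.na(h$sex), "", h$sex),
                  age_class = h$age_entry,
                  history = apply(h$events, 1L, paste, collapse = ""))
  write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_histories_csv
#' @export
write_inp <- function(h, path) {
  lines <- sprintf("/* %s */ %s 1;", h$ids,
                   apply(h$events, 1L, paste, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}
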