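#' Encounter-history set
#'
#' The central CMR input: one event-code sequence per individual over the
#' study occasions, beginning at first capture, with the individual covariates
#' needed by the stratified model variants.
#'
#' @param events Integer matrix, individuals x occasions, of event codes
#'   (0 = not captured). Entries before the first capture must be 0.
#' @param sex Per-individual sex, `"F"`, `"M"`, or `NA` (unknown).
#' @param age_entry Per-individual age class at first capture, 1..4 (4 = four
#'   and older), or `NA` (unknown age).
#' @param measure `"size"` or `"mass"` (controls the event alphabet).
#' @param occasion_years Calendar years of the occasions (defaults to
#'   `seq_len(ncol(events))`).
#' @param ids Individual identifiers.
#' @return An object of class `owlcmr_histories`.
#' @export
encounter_histories <- function(events, sex = NULL, age_entry = NULL,
                                measure = c("size", "mass"),
                                occasion_years = NULL, ids = NULL) {
  measure <- match.arg(measure)
  events <- as.matrix(events)
  storage.mode(events) <- "integer"
  n <- nrow(events); T <- ncol(events)
  if (T < 1L || n < 1L) stop("empty encounter-history set")
  if (any(is.na(events))) stop("event codes must not be NA")
  if (any(events < 0L) || any(events >= n_events(measure)))
    stop(sprintf("event codes outside the %s alphabet 0..%d",
                 measure, n_events(measure) - 1L))
  first <- apply(events != 0L, 1L, function(z) which(z)[1L])
  if (any(is.na(first))) stop("every history must contain at least one capture")
  sex <- as.character(sex %||% rep(NA_character_, n))
  sex[!sex %in% c("F", "M")] <- NA_character_
  age_entry <- as.integer(age_entry %||% rep(NA_integer_, n))
  if (any(!is.na(age_entry) & (age_entry < 1L | age_entry > 4L)))
    stop("age_entry must be in 1..4")
  h <- structure(list(
    events = events, first_occ = as.integer(first), sex = sex,
    age_entry = age_entry, measure = measure,
    occasion_years = occasion_years %||% seq_len(T),
    ids = as.character(ids %||% paste0("ind", seq_len(n)))
  ), class = "owlcmr_histories")
  validate_histories(h)
  h
}

validate_histories <- function(h) {
  ev <- h$events
  for (i in seq_len(nrow(ev))) {
    f <- h$first_occ[i]
    if (ev[i, f] == 0L) stop("first event must be a capture")
    if (f > 1L && any(ev[i, seq_len(f - 1L)] != 0L))
      stop("events precede recorded first capture")
  }
  invisible(h)
}

#' @export
print.owlcmr_histories <- function(x, ...) {
  cat(sprintf("<owlcmr_histories> %d individuals x %d occasions (%s-%s), measure = %s\n",
              nrow(x$events), ncol(x$events), min(x$occasion_years),
              max(x$occasion_years), x$measure))
  cat(sprintf("  sexed: %d F, %d M, %d unknown; known entry age: %d\n",
              sum(x$sex == "F", na.rm = TRUE), sum(x$sex == "M", na.rm = TRUE),
              sum(is.na(x$sex)), sum(!is.na(x$age_entry))))
  invisible(x)
}

#' Subset an encounter-history set
#'
#' @param h An `owlcmr_histories`.
#' @param idx Logical or integer index over individuals.
#' @return The reduced `owlcmr_histories`.
#' @export
subset_histories <- function(h, idx) {
  stopifnot(inherits(h, "owlcmr_histories"))
  encounter_histories(h$events[idx, , drop = FALSE], sex = h$sex[idx],
                      age_entry = h$age_entry[idx], measure = h$measure,
                      occasion_years = h$occasion_years, ids = h$ids[idx])
}

# Per-occasion stratum index matrix for the forward algorithm. Age classes
# advance deterministically by one per occasion from the entry class, capped
# at class 4 ("age 4 and older").
stratum_matrix <- function(h, spec) {
  n <- nrow(h$events); T <- ncol(h$events)
  if (spec$covariate == "none") return(matrix(1L, n, T))
  if (spec$covariate == "sex") {
    sx <- match(h$sex, spec$strata)
    if (any(is.na(sx)))
      stop("covariate = 'sex' requires every history to be sexed; ",
           sum(is.na(sx)), " unsexed histories present")
    return(matrix(sx, n, T))
  }
  if (any(is.na(h$age_entry)))
    stop("covariate = 'age' requires known entry age for every history; ",
         sum(is.na(h$age_entry)), " unknown-age histories present")
  occ <- matrix(rep(seq_len(T), each = n), n, T)
  cls <- h$age_entry + (occ - h$first_occ)
  cls[cls < 1L] <- 1L   # pre-entry cells, never used
  cls[cls > 4L] <- 4L
  matrix(as.integer(cls), n, T)
}

# Combined per-stratum matrices used by the compiled forward pass.
forward_inputs <- function(h, spec, theta) {
  r <- theta_to_real(spec, theta)
  M <- B <- B0 <- vector("list", length(spec$strata))
  for (k in seq_along(spec$strata)) {
    s <- spec$strata[k]
    tm <- transition_matrices(spec, theta, s)
    M[[k]] <- tm$survival %*% tm$transition
    B[[k]] <- event_matrix(spec, theta, s, first_capture = FALSE)
    B0[[k]] <- event_matrix(spec, theta, s, first_capture = TRUE)
  }
  list(M = M, B = B, B0 = B0, init = c(1 - r$pi, r$pi / 2, r$pi / 2, 0))
}

#' Log-likelihood of an encounter-history set
#'
#' Hidden-Markov forward likelihood over the fate diagram: the initial state
#' distribution `(1 - pi_SB, pi_SB/2, pi_SB/2)` is weighted by the first
#' event's assignment probability (capture at entry is conditioned on, so the
#' detection probability does not enter at the first occasion), then
#' propagated through survival x transition x event-probability products and
#' summed over terminal states. Histories are independent; stratified models
#' route each history through its stratum's parameters.
#'
#' @param h An `owlcmr_histories` compatible with the spec's measure and
#'   covariate.
#' @param spec An `owlcmr_spec`.
#' @param theta Link-scale parameter vector.
#' @param per_history If `TRUE`, return the vector of per-history
#'   log-likelihoods instead of their sum.
#' @param weights Optional per-history multiplicities (for collapsed data).
#' @return Total (or per-history) log-likelihood.
#' @export
total_loglik <- function(h, spec, theta, per_history = FALSE, weights = NULL) {
  stopifnot(inherits(h, "owlcmr_histories"), inherits(spec, "owlcmr_spec"))
  if (h$measure != spec$measure)
    stop(sprintf("histories carry measure '%s' but spec is for '%s'",
                 h$measure, spec$measure))
  fi <- forward_inputs(h, spec, theta)
  strat <- stratum_matrix(h, spec)
  ll <- cmr_forward_loglik(h$events, h$first_occ, strat,
                           fi$M, fi$B, fi$B0, fi$init)
  if (per_history) return(ll)
  if (is.null(weights)) sum(ll) else sum(weights * ll)
}

#' Log-likelihood of a single encounter history
#'
#' @param history Integer vector of event codes over all occasions (0 before
#'   first capture and when not captured).
#' @param spec An `owlcmr_spec`.
#' @param theta Link-scale parameter vector.
#' @param sex,age_entry Covariates of the individual (needed for stratified
#'   specs).
#' @return Log-likelihood (always `<= 0`).
#' @export
history_loglik <- function(history, spec, theta, sex = NA, age_entry = NA) {
  history <- as.integer(history)
  if (length(history) == 0L || all(history == 0L))
    stop("history must contain at least one capture")
  h <- encounter_histories(matrix(history, nrow = 1L), sex = sex,
                           age_entry = age_entry, measure = spec$measure)
  total_loglik(h, spec, theta)
}
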