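#' Standardized major axis (SMA) slope
#'
#' The SMA slope of `log_mass` on `log_length` is `sign(r) * sd(y) / sd(x)`,
#' the symmetric line-fitting estimator used for allometric scaling. The
#' robust variant iteratively downweights SMA residuals with Huber weights
#' (tuning constant 1.345) and recomputes the weighted ratio until the slope
#' changes by less than 1e-8 (at most 50 iterations); it is deterministic.
#'
#' @param log_length,log_mass Numeric vectors (>= 3 complete pairs, nonzero
#'   variance in both).
#' @param robust Use Huber-type iterative downweighting?
#' @return The SMA slope.
#' @export
sma_slope <- function(log_length, log_mass, robust = FALSE) {
  ok <- is.finite(log_length) & is.finite(log_mass)
  x <- log_length[ok]; y <- log_mass[ok]
  if (length(x) < 3L) stop("sma_slope needs at least 3 complete points")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in one axis")
  if (!robust) {
    r <- stats::cor(x, y)
    return(sign(r) * sd(y) / sd(x))
  }
  w <- rep(1, length(x))
  wsd <- function(v, w) {
    m <- sum(w * v) / sum(w)
    sqrt(sum(w * (v - m)^2) / sum(w))
  }
  wcor <- function(x, y, w) {
    mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
    sum(w * (x - mx) * (y - my)) /
      sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  }
  b <- sign(stats::cor(x, y)) * sd(y) / sd(x)
  k <- 1.345
  for (it in seq_len(50L)) {
    a <- sum(w * y) / sum(w) - b * sum(w * x) / sum(w)
    res <- y - (a + b * x)
    s <- stats::mad(res)
    if (s == 0) break
    u <- abs(res / s)
    w <- ifelse(u <= k, 1, k / u)
    b_new <- sign(wcor(x, y, w)) * wsd(y, w) / wsd(x, w)
    if (abs(b_new - b) < 1e-8) { b <- b_new; break }
    b <- b_new
  }
  b
}

#' Scaled-Mass-Index parameters
#'
#' @param reference_length Reference tarsus length in mm (the study adjusts
#'   to the median tarsus, 35.1 mm).
#' @param slope SMA allometric exponent on the log-log scale.
#' @param robust Whether `slope` came from the robust SMA fit.
#' @return An object of class `owlcmr_smi`.
#' @export
smi_params <- function(reference_length = 35.1, slope, robust = FALSE) {
  if (!is.finite(reference_length) || reference_length <= 0)
    stop("reference_length must be positive")
  if (!is.finite(slope)) stop("slope must be finite")
  structure(list(reference_length = reference_length, slope = slope,
                 robust = robust), class = "owlcmr_smi")
}

#' Fit SMI parameters from a pooled nestling table
#'
#' Fits the SMA slope of log mass on log tarsus on the pooled nestling
#' dataset (all years; a single coefficient) and takes the reference length
#' as the median tarsus unless overridden.
#'
#' @param nestlings Data frame with `mass_g` and `tarsus_mm` (incomplete rows
#'   dropped).
#' @param reference_length Override for the reference tarsus (mm); `NULL`
#'   uses the median tarsus of the complete records.
#' @param robust Use the robust SMA estimator?
#' @return An [smi_params()] object.
#' @export
fit_smi_params <- function(nestlings, reference_length = NULL, robust = FALSE) {
  ok <- is.finite(nestlings$mass_g) & is.finite(nestlings$tarsus_mm)
  d <- nestlings[ok, , drop = FALSE]
  b <- sma_slope(log(d$tarsus_mm), log(d$mass_g), robust = robust)
  smi_params(reference_length %||% median(d$tarsus_mm), b, robust = robust)
}

#' Scaled Mass Index of individual nestlings
#'
#' `SMI = mass * (L0 / tarsus)^b`: the mass the nestling would have at the
#' reference tarsus length `L0` under the population's allometric scaling
#' exponent `b`.
#'
#' @param mass Body mass in g (> 0); vectorized.
#' @param tarsus Tarsus length in mm (> 0); vectorized.
#' @param params An [smi_params()] object.
#' @return SMI in g.
#' @export
scaled_mass_index <- function(mass, tarsus, params) {
  stopifnot(inherits(params, "owlcmr_smi"))
  if (any(mass <= 0, na.rm = TRUE) || any(tarsus <= 0, na.rm = TRUE))
    stop("mass and tarsus must be positive")
  mass * (params$reference_length / tarsus)^params$slope
}

#' Brood mass as the sum of nestling SMI
#'
#' Nestlings missing either measurement are excluded (their count is
#' reported via `message()` when positive); if no nestling has complete
#' measurements the brood mass is missing (`NA`), which the brood-mass
#' encounter coding turns into the "unassigned" event.
#'
#' @param nestlings Data frame with `mass_g` and `tarsus_mm` for one brood.
#' @param params An [smi_params()] object.
#' @param quiet Suppress the exclusion message.
#' @return Brood mass in g, or `NA_real_`.
#' @export
brood_mass <- function(nestlings, params, quiet = TRUE) {
  ok <- is.finite(nestlings$mass_g) & is.finite(nestlings$tarsus_mm)
  if (!quiet && any(!ok))
    message(sum(!ok), " nestling(s) excluded for missing measurements")
  if (!any(ok)) return(NA_real_)
  sum(scaled_mass_index(nestlings$mass_g[ok], nestlings$tarsus_mm[ok], params))
}

#' Reproductive-state thresholds
#'
#' @param size_low_max Largest brood size still coded L (the study splits at
#'   the median brood size, 3).
#' @param mass_low_cutoff Brood mass (g) below which a brood codes L
#'   ("lighter than" is strict: a brood exactly at the cutoff codes H; the
#'   study's cutoff is the median brood mass, 424.16 g).
#' @return An object of class `owlcmr_thresholds`.
#' @export
state_thresholds <- function(size_low_max = 3, mass_low_cutoff = 424.16) {
  if (size_low_max < 1) stop("size_low_max must be >= 1")
  if (mass_low_cutoff <= 0) stop("mass_low_cutoff must be positive")
  structure(list(size_low_max = size_low_max, mass_low_cutoff = mass_low_cutoff),
            class = "owlcmr_thresholds")
}

#' Thresholds from the analysed dataset's medians
#'
#' @param brood_sizes Brood sizes of the analysed captures.
#' @param brood_masses Brood masses (g) of the assigned broods.
#' @return An [state_thresholds()] object with median splits.
#' @export
compute_thresholds <- function(brood_sizes = NULL, brood_masses = NULL) {
  state_thresholds(
    size_low_max = if (length(brood_sizes)) median(brood_sizes, na.rm = TRUE) else 3,
    mass_low_cutoff = if (length(brood_masses)) median(brood_masses, na.rm = TRUE) else 424.16)
}

#' Assign a reproductive state from brood size or brood mass
#'
#' No brood (failed breeder or non-breeder, `NA` value) codes N. Otherwise a
#' brood size of at most `size_low_max` (or a brood mass strictly below
#' `mass_low_cutoff`) codes L, and anything larger codes H.
#'
#' @param value Brood size or brood mass (`NA` = no brood); vectorized.
#' @param measure `"size"` or `"mass"`.
#' @param thresholds An [state_thresholds()] object.
#' @return Character vector of states in `N`/`L`/`H`.
#' @export
assign_reproductive_state <- function(value, measure = c("size", "mass"),
                                      thresholds = state_thresholds()) {
  measure <- match.arg(measure)
  stopifnot(inherits(thresholds, "owlcmr_thresholds"))
  if (any(value < 0, na.rm = TRUE)) stop("negative brood value")
  low <- if (measure == "size") value <= thresholds$size_low_max
         else value < thresholds$mass_low_cutoff
  out <- ifelse(is.na(value), "N", ifelse(low, "L", "H"))
  as.character(out)
}

#' Per-brood summary table
#'
#' Computes, for each brood, the number of nestlings, the Scaled-Mass-Index
#' brood mass, and the reproductive state codes under both measures.
#'
#' @param nestlings Nestling table (`brood_id`, `year`, `mass_g`,
#'   `tarsus_mm`).
#' @param params An [smi_params()] object.
#' @param thresholds An [state_thresholds()] object.
#' @return Data frame `brood_id`, `year`, `n_nestlings`, `brood_mass_g`,
#'   `state_size`, `state_mass`.
#' @export
brood_table <- function(nestlings, params, thresholds = state_thresholds()) {
  ids <- unique(nestlings$brood_id)
  rows <- lapply(ids, function(b) {
    nb <- nestlings[nestlings$brood_id == b, , drop = FALSE]
    data.frame(brood_id = b, year = nb$year[1L], n_nestlings = nrow(nb),
               brood_mass_g = brood_mass(nb, params))
  })
  d <- do.call(rbind, rows)
  d$state_size <- assign_reproductive_state(d$n_nestlings, "size", thresholds)
  d$state_mass <- ifelse(is.na(d$brood_mass_g), "U",
                         assign_reproductive_state(d$brood_mass_g, "mass",
                                                   thresholds))
  d
}

#' Reproductive-state table for encounter coding
#'
#' Builds the `individual_id` x `year` state map that [encode_histories()]
#' consumes. Captures without reproductive success code N. Under the
#' brood-size measure the state comes from `brood_size`; under the brood-mass
#' measure it comes from the Scaled-Mass-Index brood mass of the linked
#' brood, with `U` (unassigned) when the brood mass cannot be computed or no
#' brood is linked.
#'
#' @param records Collapsed, filtered capture records.
#' @param measure `"size"` or `"mass"`.
#' @param thresholds An [state_thresholds()] object.
#' @param broods Brood summary from [brood_table()] (required for
#'   `measure = "mass"`).
#' @return Data frame `individual_id`, `year`, `state`.
#' @export
build_state_table <- function(records, measure = c("size", "mass"),
                              thresholds = state_thresholds(), broods = NULL) {
  measure <- match.arg(measure)
  st <- character(nrow(records))
  nb <- !records$breeder_with_success
  st[nb] <- "N"
  if (measure == "size") {
    if (any(!nb & is.na(records$brood_size)))
      stop("breeder capture without brood size; apply the study filters first")
    st[!nb] <- assign_reproductive_state(records$brood_size[!nb], "size",
                                         thresholds)
  } else {
    if (is.null(broods)) stop("measure = 'mass' needs the brood table")
    bm <- setNames(broods$brood_mass_g, broods$brood_id)
    for (k in which(!nb)) {
      b <- records$brood_id[k]
      m <- if (!is.na(b) && b %in% names(bm)) bm[[b]] else NA_real_
      st[k] <- if (is.na(m)) "U" else assign_reproductive_state(m, "mass", thresholds)
    }
  }
  data.frame(individual_id = records$individual_id, year = records$year,
             state = st, stringsAsFactors = FALSE)
}
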