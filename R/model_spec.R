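#' Build a model specification for the twelve-model CMR set
#'
#' The model set crosses three survival structures with four breeding
#' (transition) structures. Survival between occasions may be common to all
#' birds (`phi`), differ between successful breeders and others
#' (`phi_SB`, `phi_N`), or differ among the three departure states
#' (`phi_N`, `phi_L`, `phi_H`). The probability of breeding successfully at
#' the next occasion may be common (`psi`), depend on being a successful
#' breeder (`psi_SB`, `psi_N`), depend on the full departure state
#' (`psi_N`, `psi_L`, `psi_H`), or be a free 3x3 transition structure with
#' six parameters (`psi_NL`, ..., `psi_HH`). Models M1..M12 enumerate the
#' cross in column-major order: M1..M3 vary survival under common breeding,
#' M4..M6 under the successful-breeder split, and so on.
#'
#' Reduced breeding structures split the success probability equally between
#' the low (L) and high (H) arrival states, e.g. under `psi_SB` the four cells
#' `psi_LL = psi_LH = psi_HL = psi_HH = psi_SB / 2`.
#'
#' Every model carries one constant detection probability `p` (one per sex
#' when `covariate = "sex"`), one initial-state parameter `pi_SB` (probability
#' that a first capture is a successful breeder, split equally L/H), and, for
#' the brood-mass measure, one assignment probability `gamma_B` (probability
#' that a captured breeder's brood mass is known).
#'
#' With `covariate = "age"` (four classes, 4+ capped) or `"sex"`, every
#' survival and transition parameter is replicated per stratum (interactive
#' effects). Detection stays shared across age classes but is sex-specific in
#' sex-structured models.
#'
#' @param model_id Model identifier, `1:12` or `"M1"`..`"M12"`.
#' @param covariate Stratification: `"none"`, `"age"` (classes 1,2,3,4+), or
#'   `"sex"` (F, M).
#' @param measure Reproductive-state measure: `"size"` (brood size, events
#'   0..3) or `"mass"` (brood mass, events 0..4 with 4 = unassigned breeder).
#' @return An object of class `owlcmr_spec`: the fully resolved constraint
#'   map, with one row of `$par_info` per free parameter.
#' @examples
#' build_spec("M5")
#' count_parameters(build_spec("M12"))  # 11
#' @export
build_spec <- function(model_id, covariate = c("none", "age", "sex"),
                       measure = c("size", "mass")) {
  covariate <- match.arg(covariate)
  measure <- match.arg(measure)
  if (is.character(model_id)) model_id <- suppressWarnings(as.integer(sub("^[Mm]", "", model_id)))
  if (length(model_id) != 1L || is.na(model_id) || !(model_id %in% 1:12))
    stop("unknown model_id; expected one of M1..M12")
  model_id <- as.integer(model_id)

  n_phi <- ((model_id - 1L) %% 3L) + 1L
  n_psi <- c(1L, 2L, 3L, 6L)[(model_id - 1L) %/% 3L + 1L]
  strata <- switch(covariate, none = "all", age = paste0("age", 1:4), sex = c("F", "M"))
  p_by_stratum <- covariate == "sex"

  phi_base <- switch(n_phi, "phi", c("phi_SB", "phi_N"), c("phi_N", "phi_L", "phi_H"))
  psi_base <- switch(as.character(n_psi),
    "1" = "psi",
    "2" = c("psi_SB", "psi_N"),
    "3" = c("psi_N", "psi_L", "psi_H"),
    "6" = c("psi_NL", "psi_NH", "psi_LL", "psi_LH", "psi_HL", "psi_HH"))

  row <- function(name, block, stratum, link)
    data.frame(name = name, block = block, stratum = stratum, link = link,
               stringsAsFactors = FALSE)
  rows <- list()
  for (s in strata) {
    suff <- if (covariate == "none") "" else paste0("[", s, "]")
    rows[[length(rows) + 1L]] <- row(paste0(phi_base, suff), "phi", s, "logit")
    rows[[length(rows) + 1L]] <- row(paste0(psi_base, suff), "psi", s,
                                     if (n_psi == 6L) "mlogit" else "logit")
  }
  if (p_by_stratum) {
    for (s in strata)
      rows[[length(rows) + 1L]] <- row(paste0("p[", s, "]"), "p", s, "logit")
  } else {
    rows[[length(rows) + 1L]] <- row("p", "p", "(shared)", "logit")
  }
  if (measure == "mass")
    rows[[length(rows) + 1L]] <- row("gamma_B", "gamma", "(shared)", "logit")
  rows[[length(rows) + 1L]] <- row("pi_SB", "pi", "(shared)", "logit")
  par_info <- do.call(rbind, rows)
  rownames(par_info) <- NULL

  structure(list(
    model_id = model_id, label = paste0("M", model_id),
    covariate = covariate, measure = measure,
    n_phi = n_phi, n_psi = n_psi, strata = strata,
    p_by_stratum = p_by_stratum, has_gamma = measure == "mass",
    par_info = par_info, par_names = par_info$name
  ), class = "owlcmr_spec")
}

#' Number of free parameters of a model specification
#'
#' Counts every free parameter: survival and transition parameters (per
#' stratum for interactive models), detection, the brood-mass assignment
#' probability (mass measure only), and the single initial-state parameter.
#'
#' @param spec An `owlcmr_spec`.
#' @return Integer count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "owlcmr_spec"))
  nrow(spec$par_info)
}

#' @export
print.owlcmr_spec <- function(x, ...) {
  cat(sprintf("<owlcmr_spec> %s (%s measure, covariate = %s): %d parameters\n",
              x$label, x$measure, x$covariate, count_parameters(x)))
  cat("  ", paste(x$par_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a model specification
#'
#' @param spec An `owlcmr_spec`.
#' @param theta Optional named parameter vector stored with the spec.
#' @return `spec_to_json()` returns a JSON string; `spec_from_json()` rebuilds
#'   the spec (and returns `theta` as an attribute when present).
#' @export
spec_to_json <- function(spec, theta = NULL) {
  stopifnot(inherits(spec, "owlcmr_spec"))
  doc <- list(model_id = spec$label, covariate = spec$covariate,
              measure = spec$measure, parameters = spec$par_names)
  if (!is.null(theta)) doc$theta <- setNames(as.list(unname(theta)), spec$par_names)
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
}

#' @rdname spec_to_json
#' @param json A JSON string produced by `spec_to_json()`.
#' @export
spec_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  spec <- build_spec(doc$model_id, doc$covariate, doc$measure)
  if (!is.null(doc$theta)) attr(spec, "theta") <- unlist(doc$theta)[spec$par_names]
  spec
}

# Numerically stable two-cell multinomial logit (reference = arrival state N).
.softmax3 <- function(aL, aH) {
  m <- max(0, aL, aH)
  eN <- exp(-m); eL <- exp(aL - m); eH <- exp(aH - m)
  den <- eN + eL + eH
  c(eN, eL, eH) / den
}

#' Map a link-scale parameter vector to probability-scale structures
#'
#' The bijection between the unconstrained optimization scale and the
#' probability scale: logit for survival, detection, assignment, initial
#' state, and two-outcome breeding structures; multinomial logit (reference =
#' staying/N) for the six-parameter transition rows.
#'
#' @param spec An `owlcmr_spec`.
#' @param theta Numeric vector of length `count_parameters(spec)`, in the
#'   order of `spec$par_names`.
#' @return A list with `$strata[[s]]$phi` (named length-3 survival vector),
#'   `$strata[[s]]$psi` (3x3 row-stochastic transition matrix among live
#'   states), `$p` (named per-stratum detection vector), `$gamma`, `$pi`.
#' @export
theta_to_real <- function(spec, theta) {
  stopifnot(inherits(spec, "owlcmr_spec"))
  if (length(theta) != length(spec$par_names))
    stop(sprintf("theta has length %d; spec %s needs %d parameters",
                 length(theta), spec$label, length(spec$par_names)))
  theta <- setNames(as.numeric(theta), spec$par_names)
  g <- function(nm) unname(plogis(theta[[nm]]))
  strata_out <- list()
  for (s in spec$strata) {
    suff <- if (spec$covariate == "none") "" else paste0("[", s, "]")
    phi <- switch(spec$n_phi,
      rep(g(paste0("phi", suff)), 3L),
      { sb <- g(paste0("phi_SB", suff)); c(g(paste0("phi_N", suff)), sb, sb) },
      c(g(paste0("phi_N", suff)), g(paste0("phi_L", suff)), g(paste0("phi_H", suff))))
    names(phi) <- .LIVE
    psi <- matrix(0, 3, 3, dimnames = list(.LIVE, .LIVE))
    if (spec$n_psi == 6L) {
      for (x in .LIVE)
        psi[x, ] <- .softmax3(theta[[paste0("psi_", x, "L", suff)]],
                              theta[[paste0("psi_", x, "H", suff)]])
    } else {
      sb <- switch(as.character(spec$n_psi),
        "1" = rep(g(paste0("psi", suff)), 3L),
        "2" = { v <- g(paste0("psi_SB", suff)); c(g(paste0("psi_N", suff)), v, v) },
        "3" = c(g(paste0("psi_N", suff)), g(paste0("psi_L", suff)),
                g(paste0("psi_H", suff))))
      for (k in 1:3) psi[k, ] <- c(1 - sb[k], sb[k] / 2, sb[k] / 2)
    }
    strata_out[[s]] <- list(phi = phi, psi = psi)
  }
  p <- if (spec$p_by_stratum)
    vapply(spec$strata, function(s) g(paste0("p[", s, "]")), numeric(1))
  else
    setNames(rep(g("p"), length(spec$strata)), spec$strata)
  list(strata = strata_out, p = p,
       gamma = if (spec$has_gamma) g("gamma_B") else 1,
       pi = g("pi_SB"))
}

#' Map probability-scale structures back to the link scale
#'
#' Inverse of [theta_to_real()]. The probability-scale input must respect the
#' spec's equality constraints (e.g. equal L and H survival under the
#' successful-breeder structure); the relevant cells are read off directly.
#'
#' @param spec An `owlcmr_spec`.
#' @param real A list shaped like the return value of [theta_to_real()].
#'   `$p` may be a scalar when detection is shared.
#' @return Named link-scale vector in `spec$par_names` order.
#' @export
real_to_theta <- function(spec, real) {
  stopifnot(inherits(spec, "owlcmr_spec"))
  th <- setNames(numeric(length(spec$par_names)), spec$par_names)
  for (s in spec$strata) {
    suff <- if (spec$covariate == "none") "" else paste0("[", s, "]")
    st <- real$strata[[s]] %||% real$strata[[1L]]
    phi <- st$phi; psi <- st$psi
    if (spec$n_phi == 1L) th[paste0("phi", suff)] <- qlogis(phi[["N"]])
    if (spec$n_phi == 2L) {
      th[paste0("phi_SB", suff)] <- qlogis(phi[["L"]])
      th[paste0("phi_N", suff)] <- qlogis(phi[["N"]])
    }
    if (spec$n_phi == 3L)
      for (x in .LIVE) th[paste0("phi_", x, suff)] <- qlogis(phi[[x]])
    sb_of <- function(x) psi[x, "L"] + psi[x, "H"]
    if (spec$n_psi == 1L) th[paste0("psi", suff)] <- qlogis(sb_of("N"))
    if (spec$n_psi == 2L) {
      th[paste0("psi_SB", suff)] <- qlogis(sb_of("L"))
      th[paste0("psi_N", suff)] <- qlogis(sb_of("N"))
    }
    if (spec$n_psi == 3L)
      for (x in .LIVE) th[paste0("psi_", x, suff)] <- qlogis(sb_of(x))
    if (spec$n_psi == 6L)
      for (x in .LIVE) {
        th[paste0("psi_", x, "L", suff)] <- log(psi[x, "L"] / psi[x, "N"])
        th[paste0("psi_", x, "H", suff)] <- log(psi[x, "H"] / psi[x, "N"])
      }
  }
  pvec <- real$p
  if (spec$p_by_stratum) {
    if (length(pvec) == 1L) pvec <- setNames(rep(pvec, length(spec$strata)), spec$strata)
    for (s in spec$strata) th[paste0("p[", s, "]")] <- qlogis(pvec[[s]])
  } else {
    th["p"] <- qlogis(pvec[[1L]])
  }
  if (spec$has_gamma) th["gamma_B"] <- qlogis(real$gamma)
  th["pi_SB"] <- qlogis(real$pi)
  th
}

#' Survival and state-transition matrices for one stratum
#'
#' The per-interval dynamics decompose into survival followed by a breeding
#' state transition. The survival matrix sends each live state to itself with
#' its survival probability and to the dead state D with the complement; the
#' transition matrix redistributes survivors among the live states by the
#' breeding probabilities and keeps D absorbing. Both are row-stochastic over
#' the ordered state space N, L, H, D.
#'
#' @param spec An `owlcmr_spec`.
#' @param theta Link-scale parameter vector.
#' @param stratum Stratum label (defaults to the first stratum).
#' @return List with 4x4 `$survival` and `$transition` matrices.
#' @export
transition_matrices <- function(spec, theta, stratum = spec$strata[1L]) {
  r <- theta_to_real(spec, theta)
  st <- r$strata[[stratum]]
  if (is.null(st)) stop("unknown stratum: ", stratum)
  if (any(st$phi < 0 | st$phi > 1) || any(st$psi < 0 | st$psi > 1))
    stop("probability outside [0,1] after back-transform")
  surv <- matrix(0, 4, 4, dimnames = list(.STATES, .STATES))
  for (k in 1:3) { surv[k, k] <- st$phi[k]; surv[k, 4] <- 1 - st$phi[k] }
  surv[4, 4] <- 1
  trans <- matrix(0, 4, 4, dimnames = list(.STATES, .STATES))
  trans[1:3, 1:3] <- st$psi
  trans[4, 4] <- 1
  list(survival = surv, transition = trans)
}

#' Event (emission) matrix for one stratum
#'
#' Rows are states N, L, H, D; columns are event codes. For the brood-size
#' measure a live state is either not captured (event 0, probability `1 - p`)
#' or captured and seen in its own state. For the brood-mass measure a
#' captured breeder (L or H) is assigned its state with probability `gamma_B`
#' and otherwise produces the "unassigned" event 4; non-breeders (N) are
#' always assigned. The dead state emits event 0 with probability one.
#'
#' @inheritParams transition_matrices
#' @param first_capture If `TRUE`, return the first-occasion assignment
#'   matrix: the encounter history is conditioned on first capture, so the
#'   capture probability is replaced by one.
#' @return 4 x E row-stochastic matrix (columns named by event code).
#' @export
event_matrix <- function(spec, theta, stratum = spec$strata[1L],
                         first_capture = FALSE) {
  r <- theta_to_real(spec, theta)
  if (!stratum %in% spec$strata) stop("unknown stratum: ", stratum)
  p <- if (first_capture) 1 else r$p[[stratum]]
  E <- n_events(spec$measure)
  B <- matrix(0, 4, E, dimnames = list(.STATES, as.character(0:(E - 1L))))
  B[4, 1] <- 1
  B[1:3, 1] <- 1 - p
  B[1, 2] <- p
  if (spec$measure == "size") {
    B[2, 3] <- p
    B[3, 4] <- p
  } else {
    B[2, 3] <- p * r$gamma
    B[3, 4] <- p * r$gamma
    B[2, 5] <- p * (1 - r$gamma)
    B[3, 5] <- p * (1 - r$gamma)
  }
  B
}
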