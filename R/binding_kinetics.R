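# SPR sensorgram processing and steady-state 1:1 affinity analysis.
#
# Sensorgrams travel as long-format data frames (cycle_id, flow_cell,
# concentration_nM, time_s, response_RU) with a cycle manifest giving phase
# boundaries. The 1:1 Langmuir model: during association
# R(t) = Req (1 - exp(-(ka C + kd) t)) with Req = Rmax C / (KD + C),
# KD = kd / ka; during dissociation R decays as exp(-kd t).

#' Closed-form 1:1 binding response
#'
#' @param t Time in s from the start of the phase.
#' @param conc_nM Analyte concentration in nM.
#' @param ka Association rate, 1/(M s).
#' @param kd Dissociation rate, 1/s.
#' @param rmax Surface capacity, RU.
#' @param r0 Response at the start of dissociation (dissociation phase only).
#' @param phase `"association"` or `"dissociation"`.
#' @return Response in RU.
#' @export
binding_response <- function(t, conc_nM, ka, kd, rmax, r0 = NULL,
                             phase = c("association", "dissociation")) {
  phase <- match.arg(phase)
  stopifnot(ka > 0, kd > 0, rmax > 0)
  if (phase == "association") {
    C <- conc_nM * 1e-9
    req <- rmax * C / (kd / ka + C)
    req * (1 - exp(-(ka * C + kd) * t))
  } else {
    stopifnot(!is.null(r0))
    r0 * exp(-kd * t)
  }
}

#' Read a sensorgram CSV and its cycle manifest
#'
#' CSV columns: `cycle_id, flow_cell, concentration_nM, time_s,
#' response_RU`; manifest TSV columns: `cycle_id, type, assoc_start_s,
#' assoc_end_s, diss_end_s`.
#'
#' @param csv_path Sensorgram CSV path.
#' @param manifest_path Cycle manifest TSV path.
#' @return List with `data` and `manifest` data frames.
#' @export
read_sensorgrams <- function(csv_path, manifest_path) {
  dat <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("cycle_id", "flow_cell", "concentration_nM", "time_s",
            "response_RU")
  if (!all(need %in% names(dat))) {
    stop("sensorgram CSV must have columns: ", paste(need, collapse = ", "))
  }
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  list(data = dat, manifest = man)
}

# Interpolate one cycle/flow-cell trace onto a common time grid.
.trace_on_grid <- function(dat, cycle, cell, grid) {
  tr <- dat[dat$cycle_id == cycle & dat$flow_cell == cell, ]
  if (!nrow(tr)) stop("missing trace: cycle ", cycle, ", flow cell ", cell)
  stats::approx(tr$time_s, tr$response_RU, xout = grid, rule = 2)$y
}

#' Double-reference sensorgram cycles
#'
#' For each analyte cycle: subtract the reference flow cell, then subtract
#' the (reference-subtracted) zero-concentration blank cycle, then subtract
#' the mean pre-injection baseline. Removes bulk-refractive-index jumps and
#' drift common to both flow cells, and systematic injection artefacts
#' carried by the blank. With no blank cycle available the result is
#' single-referenced and flagged.
#'
#' @param sensorgrams A [read_sensorgrams()] list (or equivalent).
#' @param blank_cycle Cycle id of the zero-concentration blank; `NULL` to
#'   auto-select the first cycle with concentration 0 (if any).
#' @param grid_hz Sampling rate of the common time grid (default 1 Hz).
#' @return Long data frame `cycle_id, concentration_nM, time_s, response_RU`
#'   of corrected analyte cycles, with attribute
#'   `double_referenced` (logical).
#' @export
double_reference <- function(sensorgrams, blank_cycle = NULL, grid_hz = 1) {
  dat <- sensorgrams$data
  man <- sensorgrams$manifest
  if (is.null(blank_cycle)) {
    conc <- tapply(dat$concentration_nM, dat$cycle_id, function(x) x[[1]])
    zero <- names(conc)[conc == 0]
    blank_cycle <- if (length(zero)) zero[[1]] else NULL
  }
  grid <- seq(min(dat$time_s), max(dat$time_s), by = 1 / grid_hz)
  blank <- NULL
  if (!is.null(blank_cycle)) {
    blank <- .trace_on_grid(dat, blank_cycle, "active", grid) -
             .trace_on_grid(dat, blank_cycle, "reference", grid)
  }
  cycles <- unique(dat$cycle_id)
  cycles <- setdiff(cycles, blank_cycle)
  out <- lapply(cycles, function(cy) {
    ref_sub <- .trace_on_grid(dat, cy, "active", grid) -
               .trace_on_grid(dat, cy, "reference", grid)
    corrected <- if (is.null(blank)) ref_sub else ref_sub - blank
    a0 <- man$assoc_start_s[match(cy, man$cycle_id)]
    pre <- corrected[grid < a0]
    if (length(pre)) corrected <- corrected - mean(pre)
    data.frame(cycle_id = cy,
               concentration_nM = dat$concentration_nM[
                 match(cy, dat$cycle_id)],
               time_s = grid, response_RU = corrected)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "double_referenced") <- !is.null(blank)
  if (is.null(blank)) {
    warning("no zero-concentration blank cycle: single-referenced output")
  }
  res
}

#' Steady-state response at the end of the association phase
#'
#' Mean corrected response over the final `window_s` seconds of the
#' association phase. If the response is still rising faster than
#' `slope_tol` RU/s within the window, the reading is flagged as not at
#' equilibrium (slow kinetics truncate below the true plateau).
#'
#' @param trace Data frame with `time_s`, `response_RU` for one cycle.
#' @param assoc_start_s,assoc_end_s Association phase boundaries (s).
#' @param window_s Averaging window (default 5 s).
#' @param slope_tol Equilibrium slope tolerance, RU/s (default 0.01).
#' @return List with `req` (RU) and logical `at_equilibrium`.
#' @export
steady_state_response <- function(trace, assoc_start_s, assoc_end_s,
                                  window_s = 5, slope_tol = 0.01) {
  if (window_s > assoc_end_s - assoc_start_s) {
    stop("window longer than association phase")
  }
  sel <- trace$time_s >= assoc_end_s - window_s & trace$time_s <= assoc_end_s
  w <- trace[sel, ]
  if (!nrow(w)) stop("no samples in steady-state window")
  slope <- if (nrow(w) >= 2) {
    unname(stats::coef(stats::lm(response_RU ~ time_s, data = w))[2])
  } else 0
  list(req = mean(w$response_RU), at_equilibrium = abs(slope) <= slope_tol)
}

#' Fit the 1:1 steady-state affinity isotherm
#'
#' Nonlinear least squares of `Req(C) = Rmax C / (KD + C)` using
#' [minpack.lm::nlsLM()]. Initial values: `Rmax0 = 1.1 max(Req)`, `KD0` the
#' concentration nearest half-max response; bounds `KD in (0, 100 Cmax]`,
#' `Rmax in (0, 10 max(Req)]`. Data without curvature (Req proportional to
#' C) return a non-converged fit with the KD flagged as lower-bound
#' censored. A model-free half-max estimate (`kd_half_max`, interpolated C
#' at `Rmax/2`) is reported alongside.
#'
#' @param concentrations_nM Analyte concentrations (>= 3 distinct non-zero).
#' @param req Equilibrium responses, RU.
#' @return List of class `steady_state_fit`: `kd_nM`, `rmax`, `rss`, `req`
#'   (fitted per concentration), `converged`, `kd_censored`, `kd_half_max`.
#' @export
fit_steady_state <- function(concentrations_nM, req) {
  stopifnot(length(concentrations_nM) == length(req))
  keep <- concentrations_nM > 0
  C <- unname(concentrations_nM[keep])
  R <- unname(req[keep])
  if (length(unique(C)) < 3) stop("need >= 3 distinct non-zero concentrations")
  if (all(R <= 0)) {
    return(structure(list(kd_nM = NA_real_, rmax = NA_real_, rss = NA_real_,
                          req = rep(NA_real_, length(C)), converged = FALSE,
                          kd_censored = FALSE, kd_half_max = NA_real_),
                     class = "steady_state_fit"))
  }
  rmax0 <- 1.1 * max(R)
  kd0 <- C[which.min(abs(R - max(R) / 2))]
  upper_kd <- 100 * max(C)
  fit <- try(minpack.lm::nlsLM(
    R ~ rmax * C / (kd + C),
    start = list(rmax = rmax0, kd = kd0),
    lower = c(rmax = 1e-9, kd = 1e-9),
    upper = c(rmax = 10 * max(R), kd = upper_kd),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(kd_nM = NA_real_, rmax = NA_real_, rss = NA_real_,
                          req = rep(NA_real_, length(C)), converged = FALSE,
                          kd_censored = FALSE, kd_half_max = NA_real_),
                     class = "steady_state_fit"))
  }
  est <- stats::coef(fit)
  # a parameter pinned to its upper bound means the isotherm has no usable
  # curvature (Req ~ proportional to C): the KD is lower-bound censored
  censored <- est[["kd"]] >= 0.99 * upper_kd ||
    est[["rmax"]] >= 0.99 * 10 * max(R)
  fitted_req <- est[["rmax"]] * C / (est[["kd"]] + C)
  # model-free half-max reading: interpolate C at Rmax/2 in log-concentration
  half <- est[["rmax"]] / 2
  kd_hm <- NA_real_
  ord <- order(C)
  if (any(R[ord] >= half) && any(R[ord] <= half)) {
    kd_hm <- exp(stats::approx(R[ord], log(C[ord]), xout = half,
                               ties = mean)$y)
  }
  structure(list(kd_nM = unname(est[["kd"]]), rmax = unname(est[["rmax"]]),
                 rss = sum((R - fitted_req)^2), req = fitted_req,
                 converged = !censored, kd_censored = censored,
                 kd_half_max = kd_hm),
            class = "steady_state_fit")
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf(
    "Steady-state 1:1 fit: KD %.4g nM, Rmax %.4g RU (RSS %.4g)%s\n",
    x$kd_nM, x$rmax, x$rss,
    if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Percent inhibition of a binding response
#'
#' `100 (1 - with / alone)`. Negative values (enhancement) are reported as
#' such, not clamped.
#'
#' @param response_alone Binding response without inhibitor, RU (> 0).
#' @param response_with Binding response with inhibitor, RU.
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(response_alone, response_with) {
  if (any(response_alone <= 0)) stop("response_alone must be > 0")
  100 * (1 - response_with / response_alone)
}

#' Serial dilution series
#'
#' @param top Top concentration (> 0, any unit).
#' @param factor Dilution factor (> 1), e.g. 3 for a 1:3 series.
#' @param n_points Number of concentrations (>= 1).
#' @return Descending concentration vector `top, top/factor, ...`.
#' @export
serial_dilution <- function(top, factor, n_points) {
  stopifnot(top > 0, factor > 1, n_points >= 1)
  top / factor^(seq_len(n_points) - 1)
}
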