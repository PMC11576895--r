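# Solver orchestration and derived PK metrics.

#' IV bolus dose schedule
#'
#' @param times_h event times (h), non-negative.
#' @param amounts_nmol amounts (nmol), recycled to the length of `times_h`.
#' @return an object of class `mpbpk_doses` (sorted by time).
#' @export
dose_schedule <- function(times_h, amounts_nmol) {
  if (any(times_h < 0)) stop("dose times must be non-negative", call. = FALSE)
  if (any(amounts_nmol < 0)) stop("dose amounts must be non-negative", call. = FALSE)
  amounts_nmol <- rep_len(amounts_nmol, length(times_h))
  o <- order(times_h)
  structure(data.frame(time_h = times_h[o], amount_nmol = amounts_nmol[o],
                       route = "iv_bolus"),
            class = c("mpbpk_doses", "data.frame"))
}

#' Simulate the mPBPK model
#'
#' Integrates the 39-state system with a stiff implicit solver
#' ([deSolve::lsoda()]; compiled right-hand side by default).  IV bolus
#' events are applied as instantaneous increments of the plasma antibody
#' concentration; the first dose at t = 0 is folded into the initial state.
#'
#' @param params an `mpbpk_params`.
#' @param schedule an [dose_schedule()]; a single number is interpreted as
#'   one bolus (nmol) at t = 0.
#' @param times output time grid (h), covering all dose events.
#' @param rtol,atol solver tolerances (default 1e-8 relative, 1e-10 nM
#'   absolute).
#' @param compiled use the compiled C right-hand side (`TRUE`, default) or
#'   the reference R implementation.
#' @return an object of class `mpbpk_profile`: the time grid, the full
#'   state matrix, and the derived observables `plasma`, `tight_total`,
#'   `leaky_total` (nM, Eqs. of volume-weighted lumping).
#' @export
simulate_pk <- function(params, schedule, times,
                        rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  stopifnot(inherits(params, "mpbpk_params"))
  if (is.numeric(schedule) && length(schedule) == 1L)
    schedule <- dose_schedule(0, schedule)
  stopifnot(inherits(schedule, "mpbpk_doses"))
  times <- sort(unique(c(0, times)))
  if (nrow(schedule) && max(schedule$time_h) > max(times))
    stop("time grid must cover all dose events", call. = FALSE)
  p <- params$pvec
  first <- schedule$time_h == 0
  y0 <- initial_state(params, dose_amount = sum(schedule$amount_nmol[first]))
  ev <- NULL
  later <- schedule[!first, , drop = FALSE]
  if (nrow(later)) {
    ev <- list(data = data.frame(var = "A_p", time = later$time_h,
                                 value = later$amount_nmol / p[["V_p"]],
                                 method = "add"))
    times <- sort(unique(c(times, later$time_h)))
  }
  sol <- if (compiled) {
    deSolve::lsoda(y = y0, times = times, func = "mpbpk_derivs",
                   parms = unname(p), dllname = "mpbpk",
                   initfunc = "mpbpk_initmod", rtol = rtol, atol = atol,
                   events = ev, maxsteps = 50000)
  } else {
    deSolve::lsoda(y = y0, times = times, func = ode_rhs, parms = params,
                   rtol = rtol, atol = atol, events = ev, maxsteps = 50000)
  }
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("ODE solver failed; last accepted time %.4g h",
                 max(sol[, "time"])), call. = FALSE)
  state <- sol[, -1, drop = FALSE]
  colnames(state) <- state_names()
  # solver-tolerance non-negativity check (no clipping)
  minval <- min(state)
  if (minval < -1e4 * atol)
    warning(sprintf("state went negative beyond solver tolerance (min %.3g)", minval),
            call. = FALSE)
  obs <- profile_observables(state, params)
  structure(list(time_h = sol[, "time"], state = state,
                 observables = obs, params = params, schedule = schedule,
                 rtol = rtol, atol = atol),
            class = "mpbpk_profile")
}

#' @export
print.mpbpk_profile <- function(x, ...) {
  cat(sprintf("mPBPK profile: %s / %s, %d time points over %.4g h\n",
              x$params$physiology$species_name, x$params$antibody$name,
              length(x$time_h), max(x$time_h)))
  cat(sprintf("  C_plasma: %.4g -> %.4g nM\n",
              x$observables$plasma[2], utils::tail(x$observables$plasma, 1)))
  invisible(x)
}

#' Tidy data frame of profile observables
#'
#' Long format `time_h, observable, value, unit`; concentrations in nM and,
#' when `ugml = TRUE`, additionally in micrograms/mL via the antibody MW.
#'
#' @param x an `mpbpk_profile`.
#' @param row.names,optional unused (S3 signature).
#' @param ugml also emit microgram/mL rows.
#' @param ... unused.
#' @export
as.data.frame.mpbpk_profile <- function(x, row.names = NULL, optional = FALSE,
                                        ugml = FALSE, ...) {
  obs <- x$observables
  out <- do.call(rbind, lapply(names(obs), function(nm)
    data.frame(time_h = x$time_h, observable = nm, value = obs[[nm]], unit = "nM")))
  if (ugml) {
    mw <- x$params$antibody$MW
    out2 <- out
    out2$value <- nM_to_ugml(out$value, mw)
    out2$unit <- "ug/mL"
    out <- rbind(out, out2)
  }
  rownames(out) <- NULL
  out
}

#' Export a profile as tidy CSV
#'
#' @param profile an `mpbpk_profile`.
#' @param path output path.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Trapezoidal area under the curve
#'
#' @param profile an `mpbpk_profile`.
#' @param observable one of `"plasma"`, `"tight_total"`, `"leaky_total"`.
#' @param t0,t1 integration window (defaults: whole grid).
#' @return AUC in nM h.
#' @export
auc <- function(profile, observable = "plasma", t0 = NULL, t1 = NULL) {
  if (!observable %in% names(profile$observables))
    stop("unknown observable: ", observable, call. = FALSE)
  t <- profile$time_h
  y <- profile$observables[[observable]]
  if (is.null(t0)) t0 <- min(t)
  if (is.null(t1)) t1 <- max(t)
  if (t0 >= t1) stop("'t0' must be less than 't1'", call. = FALSE)
  keep <- t >= t0 & t <= t1
  tt <- t[keep]; yy <- y[keep]
  sum(diff(tt) * (head_(yy) + tail_(yy)) / 2)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' Terminal-slope elimination rate and linear clearance
#'
#' Least-squares slope of `log C_plasma` versus time over a terminal window
#' gives the elimination rate `kel` (1/h); linear clearance is
#' `CL = kel * V_p` and, per kg, `kel * V_p / BW`.
#'
#' @param profile an `mpbpk_profile`.
#' @param terminal_fraction fraction of the simulated span used as the
#'   terminal window (default last 30%).
#' @param observable observable to use (plasma by default).
#' @return list with `kel` (1/h), `CL` (L/h), `CL_per_kg` (L/h/kg),
#'   `window` (h).
#' @export
terminal_clearance <- function(profile, terminal_fraction = 0.3,
                               observable = "plasma") {
  t <- profile$time_h
  y <- profile$observables[[observable]]
  t0 <- max(t) - terminal_fraction * (max(t) - min(t))
  keep <- t >= t0
  if (sum(keep) < 3) stop("terminal window needs at least 3 points", call. = FALSE)
  if (any(y[keep] <= 0))
    stop("non-positive concentrations in terminal window", call. = FALSE)
  fit <- lm(log(y[keep]) ~ t[keep])
  kel <- -unname(coef(fit)[2])
  V_p <- profile$params$pvec[["V_p"]]
  BW <- profile$params$physiology$body_weight_kg
  list(kel = kel, CL = kel * V_p, CL_per_kg = kel * V_p / BW,
       window = c(t0, max(t)))
}
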