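# Local sensitivity analysis and multi-start nonlinear least-squares
# estimation with Latin-hypercube starts and mean-normalized SSE.

# Parameter names settable through rebuild_params(), grouped by where they
# live.
.ARG_PARAMS <- c("k_up", "k_up_p", "sigma_1", "sigma_2", "K_p", "S_pino_1",
                 "S_pino_2", "K_D_NSB", "Rm_total", "k_deg", "cat_rate",
                 "f_rec_v", "f_up_v", "CL_renal")
.PHYS_PARAMS <- c("L_1", "L_2", "Q_1", "Q_2", "sigma_L", "FcRn_total",
                  "V_ep", "GFR", "endosomal_transit_time")
.AB_PARAMS <- c("k1on", "k1off", "kon", "koff", "keon", "keoff", "a_e")
.TGT_PARAMS <- c("k_int", "k_p_Tm", "T_m0", "T_s0")

#' Rebuild a resolved parameter set with named changes
#'
#' Accepts changes to resolved model arguments (`k_up`, `sigma_1`,
#' `K_D_NSB`, `K_p`, ...), physiological fields (`L_2`, `FcRn_total`,
#' `sigma_L`, ...), antibody rate constants and target kinetics; everything
#' downstream (two-pore slots, clearances, synthesis rates) is re-derived.
#' Changes to target parameters when no target is configured are ignored
#' (they touch no active flux).
#'
#' @param params an `mpbpk_params`.
#' @param changes named list of new values.
#' @return a new `mpbpk_params`.
#' @export
rebuild_params <- function(params, changes) {
  stopifnot(inherits(params, "mpbpk_params"))
  phys <- params$physiology; ab <- params$antibody; tgt <- params$target
  args <- params$args
  for (nm in names(changes)) {
    v <- changes[[nm]]
    if (nm %in% .ARG_PARAMS) {
      args[[nm]] <- v
    } else if (nm %in% .PHYS_PARAMS) {
      if (nm %in% c("L_1", "L_2", "Q_1", "Q_2")) {
        lump <- if (grepl("_1$", nm)) "tight" else "leaky"
        field <- sub("_.$", "", nm)
        phys[[lump]][[field]] <- v
        phys <- species_physiology(phys$species_name, phys$body_weight_kg,
                                   phys$V_p, phys$V_lymph, phys$V_ep,
                                   phys$tight, phys$leaky, phys$FcRn_total,
                                   phys$GFR, phys$endosomal_transit_time,
                                   phys$sigma_L)
      } else {
        phys[[nm]] <- v
      }
    } else if (nm %in% .AB_PARAMS) {
      ab[[nm]] <- v
      if (nm == "k1on" && !ab$fcrn_binding) ab$k1on <- 0
    } else if (nm %in% .TGT_PARAMS) {
      if (!is.null(tgt)) tgt[[nm]] <- v
    } else {
      stop("unknown model parameter: ", nm, call. = FALSE)
    }
  }
  do.call(model_params, c(list(physiology = phys, antibody = ab, target = tgt),
                          args))
}

#' @rdname rebuild_params
#' @param name parameter name.
#' @export
get_model_param <- function(params, name) {
  if (name %in% .ARG_PARAMS) {
    v <- params$args[[name]]
    if (!is.null(v)) return(v)
    # derived defaults
    return(switch(name,
                  sigma_1 = unname(params$sigma_eff["tight"]),
                  sigma_2 = unname(params$sigma_eff["leaky"]),
                  K_D_NSB = params$K_D_NSB,
                  cat_rate = 1 / params$physiology$endosomal_transit_time,
                  CL_renal = unname(params$pvec[["CL_renal"]]),
                  stop("no value for ", name, call. = FALSE)))
  }
  if (name %in% c("L_1", "L_2", "Q_1", "Q_2")) {
    lump <- if (grepl("_1$", name)) "tight" else "leaky"
    return(params$physiology[[lump]][[sub("_.$", "", name)]])
  }
  if (name %in% .PHYS_PARAMS) return(params$physiology[[name]])
  if (name %in% .AB_PARAMS) return(params$antibody[[name]])
  if (name %in% .TGT_PARAMS) {
    if (is.null(params$target)) return(NA_real_)
    return(params$target[[name]])
  }
  stop("unknown model parameter: ", name, call. = FALSE)
}

#' Mean-normalized sum of squared errors
#'
#' `sum over observables of [ sum_t (pred - obs)^2 / mean(obs) ]`: the SSE
#' of each observable is normalized by the mean of its observed values and
#' the normalized SSEs are summed across observables.
#'
#' @param predicted,observed either matched numeric vectors, or data frames
#'   with columns `time_h`, `observable`, `value` which are joined on
#'   (`time_h`, `observable`).
#' @return scalar objective value.
#' @export
normalized_sse <- function(predicted, observed) {
  if (is.data.frame(predicted) && is.data.frame(observed)) {
    m <- merge(observed, predicted, by = c("time_h", "observable"),
               suffixes = c("_obs", "_pred"))
    if (!nrow(m)) stop("no matched (time, observable) pairs", call. = FALSE)
    grp <- m$observable; obs <- m$value_obs; pred <- m$value_pred
  } else {
    if (length(predicted) != length(observed) || !length(observed))
      stop("'predicted' and 'observed' must be matched non-empty vectors",
           call. = FALSE)
    grp <- rep("all", length(observed)); obs <- observed; pred <- predicted
  }
  sse <- 0
  for (g in unique(grp)) {
    i <- grp == g
    mu <- mean(obs[i])
    if (mu == 0) stop("observed mean is zero for observable ", g, call. = FALSE)
    sse <- sse + sum((pred[i] - obs[i])^2) / mu
  }
  sse
}

# Model predictions matched to a dataset's (time, observable) records.
predict_dataset <- function(params, schedule, dataset, ...) {
  times <- sort(unique(dataset$time_h))
  prof <- simulate_pk(params, schedule, times = times, ...)
  idx <- match(dataset$time_h, prof$time_h)
  vapply(seq_len(nrow(dataset)), function(r)
    prof$observables[[dataset$observable[r]]][idx[r]], numeric(1))
}

#' Local sensitivity analysis (one-at-a-time +20%)
#'
#' Each parameter is increased by `perturbation` (default +20%) from its
#' current value, one at a time, and the relative percent change in
#' exposure `dAUC% = (AUC_perturbed - AUC_base) / AUC_base * 100` is
#' reported for the plasma, tight-tissue and leaky-tissue AUC.  A perturbed
#' simulation that fails is recorded as `NA`, not an error; parameters
#' absent from all active fluxes give exactly 0.
#'
#' @param scenario an `mpbpk_scenario`.
#' @param parameters character vector of parameter names (see
#'   [rebuild_params()]).
#' @param perturbation fractional increase (0.2 = +20%).  Parameters with a
#'   physical upper limit of 1 (reflection coefficients, fractions, `K_p`)
#'   are clamped at that limit after perturbation.
#' @param n time-grid size for the AUC computation.
#' @param t_end_mult the exposure window is `t_end_mult * t_end` of the
#'   scenario (default 4, so AUC approximates total exposure for
#'   long-half-life antibodies).
#' @return data frame of class `mpbpk_sensitivity` with one row per
#'   parameter x observable and column `dAUC_pct`.
#' @export
local_sensitivity <- function(scenario,
                              parameters = c("k_up", "k_up_p", "sigma_1",
                                             "sigma_2", "sigma_L", "L_1",
                                             "L_2", "Q_1", "Q_2", "k_deg",
                                             "FcRn_total", "k1off",
                                             "endosomal_transit_time",
                                             "f_rec_v", "k_int", "k_p_Tm"),
                              perturbation = 0.2, n = 200, t_end_mult = 4) {
  times <- seq(0, t_end_mult * scenario$t_end, length.out = n)
  base <- simulate_pk(scenario$params, scenario$schedule, times)
  obs_names <- c("plasma", "tight_total", "leaky_total")
  auc_base <- vapply(obs_names, function(o) auc(base, o), numeric(1))
  rows <- list()
  for (pn in parameters) {
    v0 <- get_model_param(scenario$params, pn)
    dauc <- rep(NA_real_, 3)
    if (is.na(v0) || v0 == 0) {
      dauc <- rep(0, 3)  # parameter absent from all active fluxes
    } else {
      v1 <- v0 * (1 + perturbation)
      if (pn %in% c("sigma_1", "sigma_2", "sigma_L", "f_rec_v", "f_up_v", "K_p"))
        v1 <- min(v1, 1)
      if (pn == "sigma_L") v1 <- min(v1, 1 - 1e-9)
      pert <- tryCatch({
        pp <- rebuild_params(scenario$params, setNames(list(v1), pn))
        simulate_pk(pp, scenario$schedule, times)
      }, error = function(e) NULL)
      if (!is.null(pert))
        dauc <- vapply(seq_along(obs_names), function(i)
          (auc(pert, obs_names[i]) - auc_base[i]) / auc_base[i] * 100, numeric(1))
    }
    rows[[pn]] <- data.frame(parameter = pn, observable = obs_names,
                             dAUC_pct = dauc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "perturbation") <- perturbation
  class(out) <- c("mpbpk_sensitivity", "data.frame")
  out
}

#' Screening set of sensitive parameters
#'
#' Parameters whose largest absolute exposure change across the three
#' observables reaches `threshold` percent.
#'
#' @param sens an `mpbpk_sensitivity` result.
#' @param threshold percent change cutoff (default 5).
#' @return character vector of parameter names, most sensitive first.
#' @export
sensitive_set <- function(sens, threshold = 5) {
  mx <- tapply(abs(sens$dAUC_pct), sens$parameter, max, na.rm = TRUE)
  mx <- sort(mx, decreasing = TRUE)
  names(mx)[mx >= threshold]
}

#' Multi-start nonlinear least-squares fit
#'
#' Minimizes the mean-normalized SSE between model predictions and an
#' observed dataset over a set of free parameters, from `n_starts`
#' Latin-hypercube starting points inside the bounds (log-spaced for
#' parameters whose bounds span two or more decades), each refined by
#' bounded Levenberg-Marquardt ([minpack.lm::nls.lm()]).  Deterministic for
#' a given seed.
#'
#' @param scenario an `mpbpk_scenario` providing the parameter template and
#'   dose schedule.
#' @param dataset observed dataset (`time_h`, `observable`, `value`).
#' @param free named list: parameter name -> `c(lower, upper)` bounds.
#' @param n_starts number of Latin-hypercube starts (default 10).
#' @param seed RNG seed for the Latin hypercube.
#' @param maxiter per-start Levenberg-Marquardt iteration cap.
#' @param polish number of Nelder-Mead + Levenberg-Marquardt refinement
#'   cycles applied to the best start (helps along the shallow curved
#'   valleys typical of jointly fitted uptake/reflection parameters).
#' @return an object of class `mpbpk_fit`: `estimates` (named vector),
#'   `sse`, `starts` (per-start table with start values, final values,
#'   objective and convergence info) and `best_start`.
#' @export
multistart_fit <- function(scenario, dataset, free, n_starts = 10, seed = 1L,
                           maxiter = 120, polish = 2) {
  stopifnot(inherits(scenario, "mpbpk_scenario"))
  if (!nrow(dataset)) stop("dataset is empty", call. = FALSE)
  if (!length(free)) stop("no free parameters", call. = FALSE)
  pnames <- names(free)
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper", call. = FALSE)
  use_log <- lower > 0 & upper / lower >= 100
  tr <- function(x) ifelse(use_log, log(x), x)       # to optimizer scale
  itr <- function(x) ifelse(use_log, exp(x), x)      # back to natural scale
  # observable means for the normalization
  mu <- tapply(dataset$value, dataset$observable, mean)
  if (any(mu == 0)) stop("observed mean is zero for an observable", call. = FALSE)
  w <- sqrt(mu[dataset$observable])
  resid_fun <- function(par_t) {
    vals <- itr(par_t)
    pred <- tryCatch({
      pp <- rebuild_params(scenario$params, as.list(setNames(vals, pnames)))
      predict_dataset(pp, scenario$schedule, dataset)
    }, error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(rep(1e6, nrow(dataset)))
    (pred - dataset$value) / w
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  H <- lhs::randomLHS(n_starts, length(pnames))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  starts_t <- sapply(seq_along(pnames), function(j)
    tr(lower)[j] + H[, j] * (tr(upper)[j] - tr(lower)[j]))
  starts_t <- matrix(starts_t, nrow = n_starts)
  rows <- vector("list", n_starts)
  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts_t[s, ], fn = resid_fun,
                         lower = tr(lower), upper = tr(upper),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) {
      rows[[s]] <- data.frame(start = s, converged = FALSE, sse = Inf,
                              t(setNames(itr(starts_t[s, ]), paste0("start_", pnames))),
                              t(setNames(rep(NA_real_, length(pnames)),
                                         paste0("est_", pnames))))
      next
    }
    est <- itr(fit$par)
    rows[[s]] <- data.frame(start = s, converged = fit$info %in% 1:4,
                            sse = fit$deviance,
                            t(setNames(itr(starts_t[s, ]), paste0("start_", pnames))),
                            t(setNames(est, paste0("est_", pnames))))
    fits[[s]] <- fit
  }
  tab <- do.call(rbind, rows)
  ok <- which(is.finite(tab$sse))
  if (!length(ok)) stop("all optimization starts failed", call. = FALSE)
  best <- ok[which.min(tab$sse[ok])]
  best_par <- fits[[best]]$par
  best_sse <- tab$sse[best]
  # refinement cycles on the argmin: a simplex pass to slide along curved
  # valleys, then Levenberg-Marquardt to re-converge
  lo_t <- tr(lower); hi_t <- tr(upper)
  obj <- function(par_t) {
    pen <- sum(pmax(0, par_t - hi_t)^2 + pmax(0, lo_t - par_t)^2)
    r <- resid_fun(pmin(pmax(par_t, lo_t), hi_t))
    sum(r^2) + 1e3 * pen
  }
  for (cyc in seq_len(polish)) {
    nmfit <- if (length(best_par) == 1L) {
      optim(best_par, obj, method = "Brent", lower = lo_t, upper = hi_t,
            control = list(reltol = 1e-14))
    } else {
      optim(best_par, obj, method = "Nelder-Mead",
            control = list(maxit = 500, reltol = 1e-14))
    }
    lmfit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(nmfit$par, lo_t), hi_t),
                         fn = resid_fun, lower = lo_t, upper = hi_t,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(lmfit) && lmfit$deviance < best_sse) {
      best_par <- lmfit$par
      best_sse <- lmfit$deviance
    }
  }
  estimates <- setNames(itr(best_par), pnames)
  structure(list(estimates = estimates, sse = best_sse,
                 best_start = best, starts = tab, free = free,
                 n_starts = n_starts, seed = seed),
            class = "mpbpk_fit")
}

#' @export
print.mpbpk_fit <- function(x, ...) {
  cat(sprintf("mPBPK multi-start fit (%d starts, seed %d)\n", x$n_starts, x$seed))
  cat(sprintf("  best normalized SSE = %.4g (start %d)\n", x$sse, x$best_start))
  for (nm in names(x$estimates))
    cat(sprintf("  %-10s = %.6g  [%.3g, %.3g]\n", nm, x$estimates[[nm]],
                x$free[[nm]][1], x$free[[nm]][2]))
  invisible(x)
}
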