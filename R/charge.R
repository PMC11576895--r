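# Empirical relations between antibody net surface charge and the three
# charge-dependent model parameters: interstitial distribution factor K_p,
# pinocytosis scaling S_pino and non-specific-binding dissociation constant
# K_D,NSB.

CHARGE_RANGE <- c(-10, 10)

# Clamp z to the validity range of the charge relations, with a warning.
clamp_charge <- function(z, range = CHARGE_RANGE) {
  if (any(z < range[1] | z > range[2])) {
    warning(sprintf("net charge outside [%g, %g]; clamped", range[1], range[2]),
            call. = FALSE)
    z <- pmin(pmax(z, range[1]), range[2])
  }
  z
}

#' Fit the charge relations from anchor estimates
#'
#' Builds the three charge-to-parameter maps from per-variant estimates
#' (`z`, `K_p`, `K_D_NSB`, `S_pino`):
#' * `K_p(z)`: the quadratic through the anchors constrained to
#'   `K_p(0) = 1` (exact interpolation when three anchors are given;
#'   constrained least squares otherwise),
#' * `K_D_NSB(z)`: a monotone-decreasing positive logistic
#'   `K_max / (1 + exp(p (z - z0)))` solved through the anchors,
#' * `S_pino(z)` per lumped tissue: 1 in tight tissue for all `z`; in leaky
#'   tissue 1 for `z <= 0` and linear through `(0, 1)` and the positive
#'   anchor for `z > 0`.
#'
#' @param anchors data frame with columns `z`, `K_p`, `K_D_NSB`, `S_pino`
#'   (the leaky-tissue value); needs at least 3 rows including `z = 0`.
#' @return an object of class `mpbpk_charge_relations`.
#' @export
fit_charge_relations <- function(anchors = default_charge_anchors()) {
  need <- c("z", "K_p", "K_D_NSB", "S_pino")
  if (!all(need %in% names(anchors)))
    stop("anchors need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(anchors) < 3) stop("at least 3 anchors are required", call. = FALSE)
  if (!any(anchors$z == 0)) stop("anchors must include z = 0", call. = FALSE)
  anchors <- anchors[order(anchors$z), ]
  # K_p: quadratic a z^2 + b z + 1 (c constrained to the neutral value 1)
  zz <- anchors$z; yy <- anchors$K_p - 1
  X <- cbind(zz^2, zz)
  ab <- qr.solve(crossprod(X), crossprod(X, yy))
  kp_coeffs <- c(a = ab[1], b = ab[2], c = 1)
  # K_D,NSB: logistic through anchors (exact for 3 anchors, least squares
  # otherwise); warn if anchors are not monotone decreasing in z
  kd <- anchors$K_D_NSB
  if (any(diff(kd) >= 0))
    warning("K_D,NSB anchors are not monotone decreasing in z; fitting proceeds",
            call. = FALSE)
  if (any(kd <= 0)) stop("K_D,NSB anchors must be positive", call. = FALSE)
  obj <- function(par) {
    p <- exp(par[1]); z0 <- par[2]; Kmax <- exp(par[3])
    sum((log(Kmax / (1 + exp(p * (zz - z0)))) - log(kd))^2)
  }
  init <- c(log(0.5), 0, log(max(kd) * 1.05))
  opt <- optim(init, obj, method = "BFGS", control = list(maxit = 2000, reltol = 1e-15))
  opt <- optim(opt$par, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  kdnsb_curve <- list(p = exp(opt$par[1]), z0 = opt$par[2], K_max = exp(opt$par[3]))
  # S_pino leaky: slope through (0, 1) and positive anchors
  pos <- anchors$z > 0
  slope <- if (any(pos)) sum((anchors$S_pino[pos] - 1) * anchors$z[pos]) /
    sum(anchors$z[pos]^2) else 0
  structure(list(kp_coeffs = kp_coeffs, kdnsb_curve = kdnsb_curve,
                 spino_slope_leaky = slope, valid_range = CHARGE_RANGE,
                 anchors = anchors),
            class = "mpbpk_charge_relations")
}

#' The packaged charge anchors
#'
#' Estimates for the three 150 kDa IgG charge variants used to calibrate
#' the charge relations: neutral (`z = 0`, `K_p = 1`, `K_D_NSB = 8.35` nM,
#' `S_pino = 1`), positive (`z = +5`, `K_p = 0.8`, `K_D_NSB = 1.21` nM,
#' `S_pino,leaky = 2.99`) and negative (`z = -8`, `K_p = 0.62`,
#' `K_D_NSB = 16.22` nM, `S_pino = 1`).
#'
#' @return data frame of anchors.
#' @export
default_charge_anchors <- function() {
  data.frame(z = c(-8, 0, 5),
             K_p = c(0.62, 1, 0.8),
             K_D_NSB = c(16.22, 8.35, 1.21),
             S_pino = c(1, 1, 2.99))
}

#' @rdname fit_charge_relations
#' @export
default_charge_relations <- function() {
  if (is.null(.mpbpk_cache$charge))
    .mpbpk_cache$charge <- fit_charge_relations(default_charge_anchors())
  .mpbpk_cache$charge
}

#' Interstitial distribution factor from net charge
#'
#' Quadratic `K_p(z) = a z^2 + b z + 1` through the calibration anchors;
#' `K_p(0) = 1` exactly.  Charges outside the valid range are clamped with
#' a warning.
#'
#' @param z net surface charge.
#' @param relations an `mpbpk_charge_relations` object.
#' @return K_p.
#' @export
kp_from_charge <- function(z, relations = default_charge_relations()) {
  z <- clamp_charge(z, relations$valid_range)
  cf <- relations$kp_coeffs
  unname(cf["a"] * z^2 + cf["b"] * z + cf["c"])
}

#' Non-specific-binding dissociation constant from net charge
#'
#' Monotone-decreasing positive logistic `K_D,NSB(z) = K_max / (1 +
#' exp(p (z - z0)))` through the calibration anchors: positively charged
#' antibodies bind negatively charged membrane constituents more tightly
#' (small K_D), negatively charged antibodies plateau at weak binding.
#'
#' @inheritParams kp_from_charge
#' @return K_D,NSB in nM.
#' @export
kdnsb_from_charge <- function(z, relations = default_charge_relations()) {
  z <- clamp_charge(z, relations$valid_range)
  cv <- relations$kdnsb_curve
  cv$K_max / (1 + exp(cv$p * (z - cv$z0)))
}

#' Pinocytosis scaling factor from net charge
#'
#' `S_pino` is 1 in tight tissue for any charge and 1 in leaky tissue for
#' neutral or negative charge; for positive charge the leaky-tissue value
#' increases linearly through `(0, 1)` and the positive calibration anchor.
#' (In the plasma nested endosome `S_pino` is always 1; the model applies
#' no charge scaling there.)
#'
#' @inheritParams kp_from_charge
#' @param tissue `"tight"` or `"leaky"`.
#' @return S_pino `>= 1`.
#' @export
spino_from_charge <- function(z, tissue = c("tight", "leaky"),
                              relations = default_charge_relations()) {
  tissue <- match.arg(tissue)
  z <- clamp_charge(z, relations$valid_range)
  if (tissue == "tight") return(rep(1, length(z)))
  ifelse(z <= 0, 1, 1 + relations$spino_slope_leaky * z)
}

#' @export
print.mpbpk_charge_relations <- function(x, ...) {
  cf <- x$kp_coeffs; cv <- x$kdnsb_curve
  cat("charge relations (valid z in [", x$valid_range[1], ",", x$valid_range[2], "])\n")
  cat(sprintf("  K_p(z)      = %.6g z^2 + %.6g z + %g\n", cf["a"], cf["b"], cf["c"]))
  cat(sprintf("  K_D,NSB(z)  = %.4g / (1 + exp(%.4g (z - %.4g))) nM\n",
              cv$K_max, cv$p, cv$z0))
  cat(sprintf("  S_pino(z)   : tight = 1; leaky = 1 + %.4g z for z > 0, else 1\n",
              x$spino_slope_leaky))
  invisible(x)
}
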