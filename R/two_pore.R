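# Size-dependent transcapillary transport (two-pore formalism) and
# size-based renal clearance.

# Physical constants for pore hydrodynamics at body temperature (310 K).
.kT_J <- 1.380649e-23 * 310          # J
.eta_Pa_s <- 7.0e-4                  # water viscosity at 37 C, Pa s
.eta_mmHg_h <- .eta_Pa_s / 133.322 / 3600

#' Default two-pore geometry
#'
#' Pore radii and fractional hydraulic conductances of the two-pore
#' formalism (small pores 4.44 nm carrying 95.8% of the hydraulic
#' conductance, large pores 22.85 nm carrying 4.2%), the net filtration
#' pressure used to convert lymph flow into a hydraulic conductance, and the
#' isogravimetric circular flow (defaults to 0 so that the fluid flux
#' through each pore class is its conductance fraction of lymph flow).
#'
#' @param r_small,r_large pore radii (nm).
#' @param alpha_large fraction of hydraulic conductance through large pores.
#' @param dP_mmHg net filtration pressure (mmHg) relating lymph flow and
#'   hydraulic conductance, `LpS = L_i / dP`.
#' @param J_iso isogravimetric circular flow (L/h) added to the large-pore
#'   and subtracted from the small-pore fluid flux.
#' @return a list used as the `geometry` argument of [two_pore_params()].
#' @export
two_pore_geometry <- function(r_small = 4.44, r_large = 22.85,
                              alpha_large = 0.042, dP_mmHg = 6, J_iso = 0) {
  stopifnot(r_small > 0, r_large > 0, alpha_large > 0, alpha_large < 1, dP_mmHg > 0)
  list(r_small = r_small, r_large = r_large,
       alpha_small = 1 - alpha_large, alpha_large = alpha_large,
       dP_mmHg = dP_mmHg, J_iso = J_iso)
}

#' Steric partition, diffusive hindrance and pore reflection coefficient
#'
#' Closed-form hindered-transport factors for a spherical solute of Stokes
#' radius `a_e` in a cylindrical pore of radius `r_pore`, as functions of
#' the relative size `lambda = a_e / r_pore`:
#' steric partition coefficient `(1 - lambda)^2`, Renkin diffusive
#' hindrance `(1 - lambda)^2 (1 - 2.104 lambda + 2.09 lambda^3 -
#' 0.95 lambda^5)`, and osmotic reflection coefficient
#' `sigma = (1 - (1 - lambda)^2)^2`.  For `lambda >= 1` the solute is
#' sterically excluded: all transport factors are 0 and `sigma = 1`.
#'
#' @param a_e solute Stokes radius (nm), `>= 0`.
#' @param r_pore pore radius (nm), `> 0`.
#' @return list with `lambda`, `partition`, `diffusive_hindrance`,
#'   `sigma_pore`, all in `[0, 1]`.
#' @export
hindrance_and_reflection <- function(a_e, r_pore) {
  if (any(a_e < 0)) stop("'a_e' must be non-negative", call. = FALSE)
  if (any(r_pore <= 0)) stop("'r_pore' must be positive", call. = FALSE)
  lambda <- a_e / r_pore
  lam <- pmin(lambda, 1)
  phi <- (1 - lam)^2
  renkin <- 1 - 2.104 * lam + 2.09 * lam^3 - 0.95 * lam^5
  H <- pmax(phi * renkin, 0)
  sigma <- (1 - phi)^2
  list(lambda = lambda, partition = phi, diffusive_hindrance = H,
       sigma_pore = pmin(pmax(sigma, 0), 1))
}

# Free diffusivity (dm^2/h) of a solute of Stokes radius a_e (nm),
# Stokes-Einstein at 310 K.
free_diffusivity <- function(a_e_nm) {
  D_m2_s <- .kT_J / (6 * pi * .eta_Pa_s * a_e_nm * 1e-9)
  D_m2_s * 1e2 * 3600
}

#' Two-pore transport parameters for one lumped tissue
#'
#' Derives, for each pore class, the permeability-surface area product
#' `PS_k` (hydraulic conductance split by `alpha_k`, Poiseuille pore area
#' `A0/dx = alpha_k LpS 8 eta / r_k^2`, Stokes-Einstein free diffusivity and
#' Renkin hindrance), the fluid flow `J_k` (`J_small + J_large = L_i`), the
#' Peclet number `Pe_k = J_k (1 - sigma_k) / PS_k` and the effective
#' vascular reflection coefficient
#' `sigma_eff = alpha_small sigma_small + alpha_large sigma_large`.
#'
#' @param a_e solute Stokes radius (nm), `> 0`.
#' @param L_i tissue lymph flow (L/h), `> 0`.
#' @param geometry a [two_pore_geometry()] list.
#' @return an object of class `mpbpk_two_pore` with per-class fields
#'   `r_pore`, `alpha`, `sigma`, `PS`, `J`, `Pe` (named `small`, `large`)
#'   plus `sigma_eff`, `J_iso`, `a_e`, `L_i`.
#' @export
two_pore_params <- function(a_e, L_i, geometry = two_pore_geometry()) {
  if (a_e <= 0) stop("'a_e' must be positive", call. = FALSE)
  if (L_i <= 0) stop("'L_i' must be positive", call. = FALSE)
  LpS <- L_i / geometry$dP_mmHg
  if (!is.finite(LpS) || LpS <= 0)
    stop("degenerate tissue geometry: hydraulic conductance must be positive", call. = FALSE)
  alpha <- c(small = geometry$alpha_small, large = geometry$alpha_large)
  r <- c(small = geometry$r_small, large = geometry$r_large)
  D <- free_diffusivity(a_e)
  sigma <- PS <- J <- Pe <- setNames(numeric(2), names(alpha))
  for (k in names(alpha)) {
    h <- hindrance_and_reflection(a_e, r[[k]])
    sigma[k] <- h$sigma_pore
    A0_dx <- alpha[[k]] * LpS * 8 * .eta_mmHg_h / (r[[k]] * 1e-8)^2  # dm
    PS[k] <- D * h$diffusive_hindrance * A0_dx
  }
  J["small"] <- -geometry$J_iso + alpha[["small"]] * L_i
  J["large"] <- geometry$J_iso + alpha[["large"]] * L_i
  for (k in names(alpha))
    Pe[k] <- if (PS[k] > 0) J[k] * (1 - sigma[k]) / PS[k] else Inf
  structure(list(a_e = a_e, L_i = L_i, r_pore = r, alpha = alpha,
                 sigma = sigma, PS = PS, J = J, Pe = Pe,
                 J_iso = geometry$J_iso,
                 sigma_eff = sum(alpha * sigma)),
            class = "mpbpk_two_pore")
}

#' @export
print.mpbpk_two_pore <- function(x, ...) {
  cat(sprintf("two-pore transport parameters (a_e = %.3g nm, L_i = %.3g L/h)\n",
              x$a_e, x$L_i))
  tab <- data.frame(pore = names(x$alpha), r_nm = x$r_pore, alpha = x$alpha,
                    sigma = signif(x$sigma, 4), PS_L_per_h = signif(x$PS, 4),
                    J_L_per_h = signif(x$J, 4), Pe = signif(x$Pe, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("sigma_eff = %.4g\n", x$sigma_eff))
  invisible(x)
}

#' Net transcapillary solute flux (Patlak convection-diffusion)
#'
#' Per pore class `k`, the net vascular-to-interstitial solute flux is
#' `J_k (1 - sigma_k) (C_v - C_is exp(-Pe_k)) / (1 - exp(-Pe_k))`, summed
#' over the two classes; as `Pe_k -> 0` this reduces analytically to the
#' diffusive limit `PS_k (C_v - C_is)`.
#'
#' @param C_v vascular concentration (nM).
#' @param C_is interstitial concentration (nM).
#' @param p an `mpbpk_two_pore` object.
#' @return net flux in nmol/h (positive into the interstitium).
#' @export
transcapillary_flux <- function(C_v, C_is, p) {
  if (any(C_v < 0) || any(C_is < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  total <- 0
  for (k in names(p$alpha))
    total <- total + patlak_flux(C_v, C_is, p$J[[k]], p$sigma[[k]], p$PS[[k]])
  total
}

# One pore class of the Patlak expression, with analytic Pe -> 0 limit and
# stable evaluation for large |Pe|.
patlak_flux <- function(C_v, C_is, J, sigma, PS) {
  conv <- J * (1 - sigma)
  if (PS <= 0) {
    if (conv == 0) return(0 * C_v)
    return(if (conv > 0) conv * C_v else conv * C_is)
  }
  Pe <- conv / PS
  if (abs(Pe) < 1e-8) return(PS * (C_v - C_is))
  if (Pe > 500) return(conv * C_v)
  if (Pe < -500) return(conv * C_is)
  conv * (C_v - C_is * exp(-Pe)) / (1 - exp(-Pe))
}

#' Fit the glomerular sieving curve theta(a_e)
#'
#' The sieving coefficient is modelled as a logistic function of Stokes
#' radius, `theta(a_e) = 1 / (1 + exp((a_e - a0) / w))`.  Because the logit
#' of `theta` is linear in `a_e`, the fit is an exact least-squares linear
#' regression on the logit scale.
#'
#' @param table data frame with columns `a_e_nm` and `theta` (theta strictly
#'   in (0, 1)); defaults to the packaged synthetic sieving table.
#' @return a list `sieving_curve` with elements `a0` (nm) and `w` (nm).
#' @export
fit_sieving_curve <- function(table = read_sieving_table()) {
  if (!all(c("a_e_nm", "theta") %in% names(table)))
    stop("sieving table needs columns 'a_e_nm' and 'theta'", call. = FALSE)
  th <- table$theta
  if (any(th <= 0 | th >= 1)) stop("theta values must lie strictly in (0, 1)", call. = FALSE)
  fit <- lm(log(1 / th - 1) ~ table$a_e_nm)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope <= 0) stop("sieving table is not size-selective (non-positive slope)", call. = FALSE)
  list(a0 = -intercept / slope, w = 1 / slope)
}

#' @rdname fit_sieving_curve
#' @export
read_sieving_table <- function(path = system.file("extdata", "synthetic_glomerular_sieving.csv",
                                                  package = "mpbpk")) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Cache for the default fitted sieving curve.
.mpbpk_cache <- new.env(parent = emptyenv())

#' @rdname fit_sieving_curve
#' @export
default_sieving_curve <- function() {
  if (is.null(.mpbpk_cache$sieving))
    .mpbpk_cache$sieving <- fit_sieving_curve()
  .mpbpk_cache$sieving
}

#' Glomerular sieving coefficient for a given Stokes radius
#'
#' Evaluates the fitted logistic sieving curve; monotone non-increasing in
#' `a_e`, tends to 1 for point-like solutes and is below 1e-3 for solutes
#' larger than 4 nm (full-length IgG: renal clearance negligible).
#'
#' @param a_e Stokes radius (nm), `> 0`.
#' @param sieving_curve list with `a0` and `w`, e.g. from
#'   [fit_sieving_curve()].
#' @return theta in `[0, 1]`.
#' @export
sieving_coefficient <- function(a_e, sieving_curve = default_sieving_curve()) {
  if (any(a_e <= 0)) stop("'a_e' must be positive", call. = FALSE)
  if (is.null(sieving_curve$a0) || is.null(sieving_curve$w))
    stop("sieving curve parameters 'a0' and 'w' are required", call. = FALSE)
  stats::plogis(-(a_e - sieving_curve$a0) / sieving_curve$w)
}

#' Size-based renal clearance
#'
#' `CL_renal = GFR * theta`: glomerular filtration rate scaled by the
#' sieving coefficient.  Applied in the model to the leaky-tissue vascular
#' space only.
#'
#' @param GFR glomerular filtration rate (L/h), `> 0`.
#' @param theta sieving coefficient in `[0, 1]`.
#' @return clearance in L/h.
#' @export
renal_clearance <- function(GFR, theta) {
  if (GFR <= 0) stop("'GFR' must be positive", call. = FALSE)
  if (any(theta < 0 | theta > 1)) stop("'theta' must lie in [0, 1]", call. = FALSE)
  GFR * theta
}
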