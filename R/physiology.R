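#' @useDynLib mpbpk
#' @importFrom stats setNames approx coef lm median nls optim quantile rnorm runif sd uniroot
#' @importFrom utils read.csv write.csv modifyList
NULL

# Tissues making up the "tight" lump: capillary pore-size upper limit below
# ~5 nm.  Everything else in a per-tissue table is lumped as "leaky".
TIGHT_TISSUES <- c("brain", "muscle", "skin", "adipose")

#' Species physiology for the lumped two-tissue mPBPK geometry
#'
#' Builds a validated `mpbpk_physiology` object holding compartment volumes,
#' plasma/lymph flows, endosomal FcRn concentration and glomerular filtration
#' rate for one species, with tissues lumped into a tight (brain, muscle,
#' skin, adipose) and a leaky (all remaining tissues) compartment.
#'
#' All volumes are litres, flows litres/hour, FcRn nM, transit time hours.
#'
#' @param species_name label, e.g. `"mouse"`.
#' @param body_weight_kg body weight in kg.
#' @param V_p plasma volume (L).
#' @param V_lymph lymph compartment volume (L).
#' @param V_ep plasma nested endosomal volume (L): endosomes of the systemic
#'   vascular endothelium.
#' @param tight,leaky named lists with elements `V_v`, `V_e`, `V_is`
#'   (vascular, endosomal, interstitial volumes, L), `Q` (plasma flow, L/h)
#'   and `L` (lymph flow, L/h).
#' @param FcRn_total endosomal FcRn concentration (nM), assumed equal in all
#'   endosomes of the species.
#' @param GFR glomerular filtration rate (L/h).
#' @param endosomal_transit_time endosomal transit time (h); sets the
#'   recycling clearance of each endosome via [recycling_clearance()].
#' @param sigma_L lymphatic reflection coefficient, in `[0, 1)`.
#' @return an object of class `mpbpk_physiology`.
#' @seealso [lump_tissues()], [mouse_physiology()], [human_physiology()]
#' @export
species_physiology <- function(species_name, body_weight_kg, V_p, V_lymph, V_ep,
                               tight, leaky, FcRn_total, GFR,
                               endosomal_transit_time = 8 / 60,
                               sigma_L = 0.2) {
  chk_pos <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive finite number", what), call. = FALSE)
  }
  chk_pos(body_weight_kg, "body_weight_kg")
  chk_pos(V_p, "V_p"); chk_pos(V_lymph, "V_lymph"); chk_pos(V_ep, "V_ep")
  chk_pos(FcRn_total + 1e-300, "FcRn_total")  # FcRn_total = 0 allowed (knockout)
  if (FcRn_total < 0) stop("'FcRn_total' must be non-negative", call. = FALSE)
  chk_pos(GFR, "GFR"); chk_pos(endosomal_transit_time, "endosomal_transit_time")
  if (sigma_L < 0 || sigma_L >= 1) stop("'sigma_L' must lie in [0, 1)", call. = FALSE)
  for (nm in c("tight", "leaky")) {
    lump <- get(nm)
    need <- c("V_v", "V_e", "V_is", "Q", "L")
    if (!all(need %in% names(lump)))
      stop(sprintf("'%s' must contain fields %s", nm, paste(need, collapse = ", ")), call. = FALSE)
    for (f in need) chk_pos(lump[[f]], paste0(nm, "$", f))
  }
  structure(list(
    species_name = species_name,
    body_weight_kg = body_weight_kg,
    V_p = V_p, V_lymph = V_lymph, V_ep = V_ep,
    tight = tight[c("V_v", "V_e", "V_is", "Q", "L")],
    leaky = leaky[c("V_v", "V_e", "V_is", "Q", "L")],
    L_total = tight$L + leaky$L,
    FcRn_total = FcRn_total,
    GFR = GFR,
    endosomal_transit_time = endosomal_transit_time,
    sigma_L = sigma_L
  ), class = "mpbpk_physiology")
}

#' @export
print.mpbpk_physiology <- function(x, ...) {
  cat(sprintf("mPBPK physiology: %s (%.3g kg)\n", x$species_name, x$body_weight_kg))
  cat(sprintf("  V_p = %.4g L, V_lymph = %.4g L, V_ep = %.4g L\n", x$V_p, x$V_lymph, x$V_ep))
  for (nm in c("tight", "leaky")) {
    l <- x[[nm]]
    cat(sprintf("  %-5s: V_v = %.4g, V_e = %.4g, V_is = %.4g L; Q = %.4g, L = %.4g L/h\n",
                nm, l$V_v, l$V_e, l$V_is, l$Q, l$L))
  }
  cat(sprintf("  L_total = %.4g L/h, FcRn = %.4g nM, GFR = %.4g L/h, tau_endo = %.3g h, sigma_L = %.3g\n",
              x$L_total, x$FcRn_total, x$GFR, x$endosomal_transit_time, x$sigma_L))
  invisible(x)
}

#' Lump a per-tissue physiology table into tight and leaky compartments
#'
#' Sums per-tissue vascular/endosomal/interstitial volumes and plasma/lymph
#' flows into the tight lump (brain, muscle, skin, adipose; case-insensitive)
#' and the leaky lump (all remaining tissues).
#'
#' @param per_tissue_table data frame with columns `tissue`, `V_v_L`, `V_e_L`,
#'   `V_is_L`, `Q_L_per_h`, `L_L_per_h` (the packaged CSV schema).
#' @param ... further arguments passed to [species_physiology()]
#'   (`species_name`, `body_weight_kg`, `V_p`, `V_lymph`, `V_ep`,
#'   `FcRn_total`, `GFR`, ...).
#' @return an `mpbpk_physiology` object.
#' @examples
#' tab <- data.frame(
#'   tissue = c("brain", "muscle", "skin", "adipose", "liver"),
#'   V_v_L = c(1, 2, 3, 4, 5) * 1e-5, V_e_L = c(1, 2, 3, 4, 5) * 1e-6,
#'   V_is_L = c(1, 2, 3, 4, 5) * 1e-4, Q_L_per_h = c(1, 2, 3, 4, 5) * 1e-2,
#'   L_L_per_h = c(1, 2, 3, 4, 5) * 1e-5)
#' phys <- lump_tissues(tab, species_name = "toy", body_weight_kg = 0.028,
#'                      V_p = 9.4e-4, V_lymph = 1e-4, V_ep = 3e-5,
#'                      FcRn_total = 3000, GFR = 0.0167)
#' @export
lump_tissues <- function(per_tissue_table, ...) {
  need <- c("tissue", "V_v_L", "V_e_L", "V_is_L", "Q_L_per_h", "L_L_per_h")
  miss <- setdiff(need, names(per_tissue_table))
  if (length(miss))
    stop("per-tissue table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  tissue <- tolower(trimws(as.character(per_tissue_table$tissue)))
  if (anyDuplicated(tissue))
    stop("duplicate tissue name(s) in table: ",
         paste(unique(tissue[duplicated(tissue)]), collapse = ", "), call. = FALSE)
  missing_tight <- setdiff(TIGHT_TISSUES, tissue)
  if (length(missing_tight))
    stop("tight tissue(s) missing from table: ", paste(missing_tight, collapse = ", "),
         call. = FALSE)
  num <- per_tissue_table[, need[-1]]
  if (any(!vapply(num, is.numeric, logical(1))) || any(as.matrix(num) < 0, na.rm = FALSE) ||
      any(!is.finite(as.matrix(num))))
    stop("all per-tissue volumes and flows must be finite and non-negative", call. = FALSE)
  is_tight <- tissue %in% TIGHT_TISSUES
  sum_lump <- function(idx) list(
    V_v = sum(num$V_v_L[idx]), V_e = sum(num$V_e_L[idx]), V_is = sum(num$V_is_L[idx]),
    Q = sum(num$Q_L_per_h[idx]), L = sum(num$L_L_per_h[idx]))
  species_physiology(tight = sum_lump(is_tight), leaky = sum_lump(!is_tight), ...)
}

#' Endosomal recycling clearance from transit time
#'
#' The recycling clearance of an endosomal pool is its volume divided by the
#' endosomal transit time (default transit time 8 min in the packaged
#' configurations): `CL_rec = V_endosome / transit_time`.
#'
#' @param V_endosome endosomal volume (L).
#' @param transit_time endosomal transit time (h).
#' @return clearance in L/h.
#' @export
recycling_clearance <- function(V_endosome, transit_time) {
  if (!is.numeric(V_endosome) || any(V_endosome <= 0) || any(!is.finite(V_endosome)))
    stop("'V_endosome' must be positive", call. = FALSE)
  if (!is.numeric(transit_time) || any(transit_time <= 0) || any(!is.finite(transit_time)))
    stop("'transit_time' must be positive", call. = FALSE)
  V_endosome / transit_time
}

#' Packaged default mouse physiology (28 g)
#'
#' Lumps the packaged per-tissue table `mouse_tissues.csv` (values compiled
#' from standard PBPK physiology tables; see the file header) and attaches
#' mouse defaults for plasma volume, FcRn concentration and GFR.
#'
#' @param ... overrides forwarded to [species_physiology()] via
#'   [lump_tissues()] (e.g. `FcRn_total = 0` for a knockout).
#' @return an `mpbpk_physiology` object.
#' @export
mouse_physiology <- function(...) {
  tab <- read_tissue_table(system.file("extdata", "mouse_tissues.csv", package = "mpbpk"))
  defaults <- list(species_name = "mouse", body_weight_kg = 0.028,
                   V_p = 9.44e-4, V_lymph = 1.0e-4, V_ep = 1.2e-4,
                   FcRn_total = 3000, GFR = 0.0167)
  args <- modifyList(defaults, list(...))
  do.call(lump_tissues, c(list(per_tissue_table = tab), args))
}

#' Packaged default human physiology (70 kg)
#'
#' @param ... overrides forwarded to [species_physiology()].
#' @return an `mpbpk_physiology` object.
#' @export
human_physiology <- function(...) {
  tab <- read_tissue_table(system.file("extdata", "human_tissues.csv", package = "mpbpk"))
  defaults <- list(species_name = "human", body_weight_kg = 70,
                   V_p = 3.126, V_lymph = 0.274, V_ep = 0.30,
                   FcRn_total = 3000, GFR = 6.6)
  args <- modifyList(defaults, list(...))
  do.call(lump_tissues, c(list(per_tissue_table = tab), args))
}

#' Read a per-tissue physiology table
#'
#' CSV with header `tissue,V_v_L,V_e_L,V_is_L,Q_L_per_h,L_L_per_h`; lines
#' starting with `#` are comments.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tissue_table <- function(path) {
  if (!nzchar(path) || !file.exists(path)) stop("tissue table not found: ", path, call. = FALSE)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Serialize / restore a species physiology configuration
#'
#' Writes an `mpbpk_physiology` to YAML with explicit units in key names
#' (`V_p_L`, `Q_tight_L_per_h`, ...); `read_species_config()` restores it.
#' Numbers are written with 17 significant digits so the round trip is
#' bit-exact.
#'
#' @param phys an `mpbpk_physiology` object.
#' @param path output/input file path.
#' @return `write_species_config()` returns `path` invisibly;
#'   `read_species_config()` an `mpbpk_physiology`.
#' @export
write_species_config <- function(phys, path) {
  stopifnot(inherits(phys, "mpbpk_physiology"))
  cfg <- list(
    species_name = phys$species_name,
    body_weight_kg = phys$body_weight_kg,
    V_p_L = phys$V_p, V_lymph_L = phys$V_lymph, V_ep_L = phys$V_ep,
    FcRn_total_nM = phys$FcRn_total, GFR_L_per_h = phys$GFR,
    endosomal_transit_time_h = phys$endosomal_transit_time,
    sigma_L = phys$sigma_L)
  for (nm in c("tight", "leaky")) {
    l <- phys[[nm]]
    cfg[[paste0("V_v_", nm, "_L")]] <- l$V_v
    cfg[[paste0("V_e_", nm, "_L")]] <- l$V_e
    cfg[[paste0("V_is_", nm, "_L")]] <- l$V_is
    cfg[[paste0("Q_", nm, "_L_per_h")]] <- l$Q
    cfg[[paste0("L_", nm, "_L_per_h")]] <- l$L
  }
  # numbers are emitted with 17 significant digits (full double precision)
  # so the round trip through the text file is bit-exact
  cfg <- lapply(cfg, function(x) if (is.double(x)) sprintf("%.17g", x) else x)
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}

#' @rdname write_species_config
#' @export
read_species_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- lapply(cfg, function(x)
    if (is.character(x) && !is.na(suppressWarnings(as.numeric(x))))
      as.numeric(x) else x)
  lump <- function(nm) list(
    V_v = cfg[[paste0("V_v_", nm, "_L")]], V_e = cfg[[paste0("V_e_", nm, "_L")]],
    V_is = cfg[[paste0("V_is_", nm, "_L")]], Q = cfg[[paste0("Q_", nm, "_L_per_h")]],
    L = cfg[[paste0("L_", nm, "_L_per_h")]])
  species_physiology(
    species_name = cfg$species_name, body_weight_kg = cfg$body_weight_kg,
    V_p = cfg$V_p_L, V_lymph = cfg$V_lymph_L, V_ep = cfg$V_ep_L,
    tight = lump("tight"), leaky = lump("leaky"),
    FcRn_total = cfg$FcRn_total_nM, GFR = cfg$GFR_L_per_h,
    endosomal_transit_time = cfg$endosomal_transit_time_h, sigma_L = cfg$sigma_L)
}
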