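# Physiological parameter tables, derived volumes/flows, tumor geometry,
# and assembly of the complete per-compartment parameterization.

ORGAN_ORDER <- c("liver", "kidneys", "lungs", "spleen", "brain", "heart",
                 "gi", "muscle", "others")

default_params_file <- function() {
  system.file("extdata", "default_params.yaml", package = "nanopbpk",
              mustWork = TRUE)
}

#' Reference parameter tables
#'
#' Reads the versioned YAML parameter file shipped with the package
#' (reference 200 g rat physiology, tumor properties, and reference
#' nanoparticle).
#'
#' @return Nested list mirroring the YAML file.
#' @export
default_params <- function() {
  yaml::read_yaml(default_params_file())
}

#' Reference body specification
#'
#' Whole-body physiology of the reference rat: body weight, cardiac output,
#' excretory flows, hematocrit, blood/capillary/phagocyte properties and the
#' per-organ table (fractional weights, vascular fractions, fractional
#' cardiac output, pore radii, macrophage area fractions).
#'
#' @param ... Named overrides of top-level fields (e.g. `hematocrit = 0.3`).
#'   Organ-table overrides go through [assemble_parameterization()]'s
#'   arguments or by editing the returned object.
#' @return An object of class `body_spec`: scalar fields plus an `organs`
#'   data frame (one row per organ in canonical order).
#' @export
default_body <- function(...) {
  p <- default_params()$body
  org <- p$organs
  organs <- data.frame(
    name = ORGAN_ORDER,
    f_WT = vapply(ORGAN_ORDER, function(o) org[[o]]$f_WT, 0),
    f_v = vapply(ORGAN_ORDER, function(o) org[[o]]$f_v, 0),
    f_CO = vapply(ORGAN_ORDER, function(o) org[[o]]$f_CO, 0),
    r_pore = vapply(ORGAN_ORDER, function(o) org[[o]]$r_pore_nm, 0),
    A_mac = vapply(ORGAN_ORDER, function(o) org[[o]]$A_mac, 0),
    row.names = NULL
  )
  body <- list(
    BW = p$BW_g, CO = p$CO_ml_h, GFR = p$GFR_ml_h, U = p$urine_ml_h,
    B = p$bile_ml_h, H = p$hematocrit, lymph_ratio = p$lymph_ratio,
    lymph_node_wt_frac = p$lymph_node_wt_frac,
    plasma_wt_frac = p$plasma_wt_frac,
    mu = p$blood$mu_cP, beta = p$blood$beta_um,
    cap = capillary(p$capillary$R_um, p$capillary$l_um, p$capillary$l_g_nm,
                    p$capillary$u_um_s, p$capillary$gamma_dot_s,
                    p$capillary$Q_cap_nl_min, p$capillary$f_cap),
    phag = phagocyte(p$phagocyte$p_W, p$phagocyte$gamma_mN_m,
                     p$phagocyte$r_mac_um),
    organs = organs
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(body))
      stop("unknown body field: ", nm, call. = FALSE)
    body[[nm]] <- dots[[nm]]
  }
  if (body$H < 0 || body$H >= 1)
    stop("hematocrit must lie in [0, 1)", call. = FALSE)
  class(body) <- "body_spec"
  body
}

#' Reference tumor specification
#'
#' @param ... Named overrides of tumor fields (`radius_mm`,
#'   `Q_specific_ml_g_min`, `mu_cP`, `f_v`, `r_pore_nm`, `phi`, `l_w_um`).
#' @return An object of class `tumor_spec`.
#' @export
default_tumor <- function(...) {
  t <- default_params()$tumor
  tumor <- list(radius_mm = t$radius_mm, Q_specific = t$Q_specific_ml_g_min,
                mu = t$mu_cP, f_v = t$f_v, r_pore = t$r_pore_nm,
                phi = t$phi, l_w = t$l_w_um)
  dots <- list(...)
  map <- c(radius_mm = "radius_mm", Q_specific_ml_g_min = "Q_specific",
           mu_cP = "mu", f_v = "f_v", r_pore_nm = "r_pore", phi = "phi",
           l_w_um = "l_w")
  for (nm in names(dots)) {
    if (!nm %in% names(map))
      stop("unknown tumor field: ", nm, call. = FALSE)
    tumor[[map[[nm]]]] <- dots[[nm]]
  }
  stopifnot(tumor$radius_mm > 0, tumor$Q_specific > 0, tumor$mu > 0,
            tumor$f_v > 0, tumor$f_v <= 1, tumor$r_pore > 0,
            tumor$phi >= 0, tumor$phi <= 1, tumor$l_w > 0)
  class(tumor) <- "tumor_spec"
  tumor
}

#' Organ volumes
#'
#' Total, vascular and extravascular organ volumes from fractional body
#' weights at unit tissue density.
#'
#' @param body [default_body()] specification.
#' @return Data frame with `name`, `V_total`, `V_v`, `V_e` (ml), plus
#'   attributes `V_plasma` and `V_lymph_node` (ml).
#' @export
organ_volumes <- function(body) {
  org <- body$organs
  V_total <- org$f_WT * body$BW
  V_v <- org$f_v * V_total
  out <- data.frame(name = org$name, V_total = V_total, V_v = V_v,
                    V_e = V_total - V_v)
  attr(out, "V_plasma") <- body$plasma_wt_frac * body$BW
  attr(out, "V_lymph_node") <- body$lymph_node_wt_frac * body$BW
  out
}

#' Organ plasma and lymph flows
#'
#' Arterial inflows from fractional cardiac output; the liver additionally
#' receives the venous outflow of the gut and spleen (portal routing), and
#' the lungs receive the entire cardiac output in series. Lymph flow is
#' `lymph_ratio` (default 1/500) of each organ's total plasma inflow.
#'
#' @param body [default_body()] specification.
#' @return Data frame with `name`, `Q_art` (arterial inflow, ml h^-1),
#'   `Q_in` (total inflow incl. portal, ml h^-1), `L` (lymph, ml h^-1).
#' @export
organ_flows <- function(body) {
  org <- body$organs
  CO <- body$CO
  sys <- org$name != "lungs"
  if (sum(org$f_CO[sys]) > 1)
    stop("systemic fractional cardiac outputs exceed 1", call. = FALSE)
  Q_art <- org$f_CO * CO
  Q_art[org$name == "lungs"] <- CO
  Q_in <- Q_art
  L <- Q_in * body$lymph_ratio
  # portal vein: gi and spleen venous outflow (inflow minus lymph) enters
  # the liver on top of the hepatic artery
  gi <- org$name == "gi"; sp <- org$name == "spleen"; li <- org$name == "liver"
  Q_in[li] <- Q_art[li] + (Q_in[gi] - L[gi]) + (Q_in[sp] - L[sp])
  L[li] <- Q_in[li] * body$lymph_ratio
  data.frame(name = org$name, Q_art = Q_art, Q_in = Q_in, L = L)
}

#' Tumor geometry and microvascular surface area
#'
#' Spherical tumor volume and mass (unit density), vascular volume, surface
#' area of the microvascular exchange wall from the cylinder lateral-area
#' rule `s = 2 f_v / R` (mm^2 per mm^3 tissue), and the capillary count
#' obtained by partitioning the capillary portion of the vascular volume
#' into cylinders of radius `R` and length `l`.
#'
#' @param tumor [default_tumor()] specification.
#' @param cap [capillary()] geometry (radius/length shared with healthy
#'   organs).
#' @return List: `V_T_mm3`, `V_T_ml`, `mass_g`, `V_v_ml`, `s_mm2_mm3`,
#'   `S_mm2`, `N_cap`.
#' @export
tumor_geometry <- function(tumor, cap) {
  V_T_mm3 <- (4 / 3) * pi * tumor$radius_mm^3
  V_T_ml <- V_T_mm3 / 1e3                   # mm^3 -> ml (= cm^3)
  V_v_ml <- tumor$f_v * V_T_ml
  R_mm <- cap$R * 1e-3
  s <- 2 * tumor$f_v / R_mm                 # mm^2 per mm^3
  cap_vol_ml <- pi * (cap$R * 1e-4)^2 * (cap$l * 1e-4)  # um -> cm
  N_cap <- cap$f_cap * V_v_ml / cap_vol_ml
  list(V_T_mm3 = V_T_mm3, V_T_ml = V_T_ml, mass_g = V_T_ml * 1,
       V_v_ml = V_v_ml, s_mm2_mm3 = s, S_mm2 = s * V_T_mm3, N_cap = N_cap)
}

#' Tumor capillary hemodynamics
#'
#' Per-capillary flow from the partition of the total tumor blood flow over
#' the capillary count, the mean velocity from the Poiseuille cross-section,
#' and the mean shear rate `gamma_dot = (8/3) u / R`.
#'
#' @param tumor [default_tumor()] specification.
#' @param geom Output of [tumor_geometry()].
#' @param cap [capillary()] geometry.
#' @return List: `Q_total_ml_h`, `Q_cap_nl_min`, `u_um_s`, `gamma_dot_s`.
#' @export
tumor_hemodynamics <- function(tumor, geom, cap) {
  Q_total_ml_min <- tumor$Q_specific * geom$mass_g
  Q_cap_nl_min <- Q_total_ml_min * 1e6 / geom$N_cap   # ml -> nl
  Q_cap_m3_s <- Q_cap_nl_min * 1e-12 / 60
  u_m_s <- Q_cap_m3_s / (pi * (cap$R * 1e-6)^2)
  u_um_s <- u_m_s * 1e6
  list(Q_total_ml_h = Q_total_ml_min * 60,
       Q_cap_nl_min = Q_cap_nl_min,
       u_um_s = u_um_s,
       gamma_dot_s = (8 / 3) * u_um_s / cap$R)
}

#' Assemble the complete compartment parameterization
#'
#' Binds the physiological tables to the mechanistic transport rates for
#' every compartment, yielding the volumes, flows and rate constants (in
#' ml, ml h^-1 and h^-1) consumed by the ODE core. Healthy organs share the
#' printed capillary hemodynamics; tumor hemodynamics are derived from the
#' tumor blood flow and capillary count. Deterministic: identical inputs
#' give identical output.
#'
#' @param np [nanoparticle()] specification.
#' @param body [default_body()] specification.
#' @param tumor [default_tumor()] specification, or `NULL` to disable the
#'   tumor compartment.
#' @param hindrance Pluggable hindrance-factor function, see
#'   [hindrance_factors()].
#' @return An object of class `pbpk_params`: list with `organs` (data frame
#'   incl. volumes, flows, `sigma`, `k_on`, `k_off`, `k_mac`, `A_mac`, all
#'   rates h^-1), scalars `V_plasma`, `V_lymph_node`, `CO`, `GFR`, `U`,
#'   `B`, `k_deg`, and (when enabled) a `tumor` list with `V_v`, `Q`,
#'   `PS` (ml h^-1), `P_mm_s`, `k_on`, `k_off`, geometry and hemodynamics.
#' @export
assemble_parameterization <- function(np, body = default_body(),
                                      tumor = default_tumor(),
                                      hindrance = hindrance_factors) {
  const <- phys_constants()
  env <- blood_env(mu_cP = body$mu, H = body$H, beta_um = body$beta)
  vols <- organ_volumes(body)
  flows <- organ_flows(body)

  k_on_h <- wall_deposition_rate(np, env, body$cap, const) * 3600
  k_off_h <- wall_dislodging_rate(np, env, body$cap, const) * 3600
  k_mac_h <- phagocytosis_rate(np, body$phag) * 3600
  sigma <- sigma_from_alpha(np$r_nm / body$organs$r_pore, hindrance)

  organs <- data.frame(
    name = body$organs$name,
    V_total = vols$V_total, V_v = vols$V_v, V_e = vols$V_e,
    Q_art = flows$Q_art, Q_in = flows$Q_in, L = flows$L,
    sigma = sigma, k_on = k_on_h, k_off = k_off_h, k_mac = k_mac_h,
    A_mac = body$organs$A_mac
  )

  out <- list(
    organs = organs,
    V_plasma = attr(vols, "V_plasma"),
    V_lymph_node = attr(vols, "V_lymph_node"),
    CO = body$CO, GFR = body$GFR, U = body$U, B = body$B,
    k_deg = np$k_deg, np = np
  )

  if (!is.null(tumor)) {
    geom <- tumor_geometry(tumor, body$cap)
    hemo <- tumor_hemodynamics(tumor, geom, body$cap)
    env_T <- blood_env(mu_cP = tumor$mu, H = body$H, beta_um = body$beta)
    cap_T <- capillary(R_um = body$cap$R, l_um = body$cap$l,
                       l_g_nm = body$cap$l_g, u_um_s = hemo$u_um_s,
                       gamma_dot_s = hemo$gamma_dot_s,
                       Q_cap_nl_min = hemo$Q_cap_nl_min,
                       f_cap = body$cap$f_cap)
    pore_T <- pore_geometry(tumor$r_pore, l_w_um = tumor$l_w,
                            phi = tumor$phi)
    P <- vascular_permeability(np, pore_T, env_T, const, hindrance)
    # P [mm/s] * S [mm^2] = mm^3/s; * 3600 / 1000 -> ml/h
    PS <- P * geom$S_mm2 * 3.6
    out$tumor <- list(
      V_v = geom$V_v_ml, Q = hemo$Q_total_ml_h, PS = PS, P_mm_s = P,
      sigma = sigma_from_alpha(np$r_nm / tumor$r_pore, hindrance),
      k_on = wall_deposition_rate(np, env_T, cap_T, const) * 3600,
      k_off = wall_dislodging_rate(np, env_T, cap_T, const) * 3600,
      geometry = geom, hemodynamics = hemo
    )
  }
  class(out) <- "pbpk_params"
  out
}
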