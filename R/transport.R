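# Mechanistic microvascular transport parameters.
#
# All user-facing inputs are in the mixed units conventional in the PBPK
# literature (nm, um, cP, g/cm^3, mN/m); every function converts to SI
# internally and documents the unit of its return value.

#' Nanoparticle design specification
#'
#' The three tunable nanoparticle (NP) design parameters of the model:
#' hydrodynamic size, mass density, and first-order degradation rate.
#' "Size" in all user-facing interfaces means hydrodynamic *diameter*;
#' the transport equations operate on the radius `r = size / 2`.
#'
#' @param diameter_nm Hydrodynamic diameter (nm). Exactly one of
#'   `diameter_nm` / `radius_nm` must be given.
#' @param radius_nm Hydrodynamic radius (nm).
#' @param density_g_cm3 NP mass density (g cm^-3); default 2 (silica-like).
#' @param k_deg_per_h First-order degradation rate (h^-1) applied to NPs
#'   sequestered in MPS phagocytes and in the tumor interstitium.
#' @return An object of class `np_spec` with fields `r_nm`, `rho_np`,
#'   `k_deg`.
#' @examples
#' nanoparticle(diameter_nm = 100)
#' @export
nanoparticle <- function(diameter_nm = NULL, radius_nm = NULL,
                         density_g_cm3 = 2, k_deg_per_h = 0.01) {
  if (is.null(radius_nm) == is.null(diameter_nm))
    stop("give exactly one of `diameter_nm` or `radius_nm`", call. = FALSE)
  r <- if (is.null(radius_nm)) diameter_nm / 2 else radius_nm
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("NP radius must be a single positive number", call. = FALSE)
  if (density_g_cm3 <= 0) stop("NP density must be positive", call. = FALSE)
  if (k_deg_per_h < 0) stop("k_deg must be non-negative", call. = FALSE)
  structure(list(r_nm = r, rho_np = density_g_cm3, k_deg = k_deg_per_h),
            class = "np_spec")
}

#' Physical constants
#'
#' Boltzmann constant, body temperature, gravitational acceleration and
#' plasma density used throughout the transport calculations.
#'
#' @return List with `k_B` (J K^-1), `T_K` (K), `g` (m s^-2),
#'   `rho_p` (g cm^-3).
#' @export
phys_constants <- function() {
  list(k_B = 1.38e-23, T_K = 310, g = 9.8, rho_p = 1)
}

#' Blood environment
#'
#' Rheological state of the blood in a compartment's microvasculature.
#'
#' @param mu_cP Dynamic blood viscosity (cP); 4 in healthy organs, 7.42 in
#'   the tumor.
#' @param H Hematocrit (volume fraction of erythrocytes), in `[0, 1)`.
#' @param beta_um Erythrocyte radius (um).
#' @return An object of class `blood_env`.
#' @export
blood_env <- function(mu_cP = 4, H = 0.45, beta_um = 3.6) {
  if (mu_cP <= 0) stop("blood viscosity must be positive", call. = FALSE)
  if (H < 0 || H >= 1) stop("hematocrit must lie in [0, 1)", call. = FALSE)
  if (beta_um <= 0) stop("erythrocyte radius must be positive", call. = FALSE)
  structure(list(mu = mu_cP, H = H, beta = beta_um), class = "blood_env")
}

#' Capillary geometry and hemodynamics
#'
#' @param R_um Capillary radius (um).
#' @param l_um Capillary length (um).
#' @param l_g_nm Glycocalyx thickness (nm) — the dislodging diffusion length.
#' @param u_um_s Mean blood flow velocity in a capillary (um s^-1).
#' @param gamma_dot_s Capillary shear rate (s^-1).
#' @param Q_cap_nl_min Single-capillary volumetric flow (nl min^-1).
#' @param f_cap Capillary fraction of the vascular volume.
#' @return An object of class `capillary`.
#' @export
capillary <- function(R_um = 5, l_um = 1000, l_g_nm = 100, u_um_s = 553,
                      gamma_dot_s = 116, Q_cap_nl_min = 2.58, f_cap = 0.55) {
  vals <- c(R_um, l_um, l_g_nm, u_um_s, gamma_dot_s, Q_cap_nl_min, f_cap)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all capillary parameters must be positive", call. = FALSE)
  structure(list(R = R_um, l = l_um, l_g = l_g_nm, u = u_um_s,
                 gamma_dot = gamma_dot_s, Q_cap = Q_cap_nl_min,
                 f_cap = f_cap), class = "capillary")
}

#' Vessel-wall pore geometry
#'
#' @param r_pore_nm Fenestration (pore) radius (nm).
#' @param l_w_um Vessel-wall thickness (um); needed only for the tumor
#'   permeability calculation.
#' @param phi Vascular porosity (pore area per unit vessel-wall area);
#'   needed only for the tumor permeability calculation.
#' @return An object of class `pore_geometry`.
#' @export
pore_geometry <- function(r_pore_nm, l_w_um = NULL, phi = NULL) {
  if (r_pore_nm <= 0) stop("pore radius must be positive", call. = FALSE)
  if (!is.null(phi) && (phi < 0 || phi > 1))
    stop("porosity must lie in [0, 1]", call. = FALSE)
  if (!is.null(l_w_um) && l_w_um <= 0)
    stop("wall thickness must be positive", call. = FALSE)
  structure(list(r_pore = r_pore_nm, l_w = l_w_um, phi = phi),
            class = "pore_geometry")
}

#' Phagocyte (macrophage) specification
#'
#' @param p_W Power of the motor proteins driving membrane wrapping (W).
#' @param gamma_mN_m Membrane surface tension (mN m^-1).
#' @param r_mac_um Macrophage radius (um); metadata only — the accessible
#'   area fractions `A_mac` are direct inputs of the organ table.
#' @param k_mac_cap_s Ceiling on the phagocytosis rate (s^-1). The wrapping
#'   time model diverges as r -> 0; the cap never binds for r >= 1 nm at
#'   default power/tension but protects sensitivity scans.
#' @return An object of class `phagocyte`.
#' @export
phagocyte <- function(p_W = 1e-17, gamma_mN_m = 0.06, r_mac_um = 15,
                      k_mac_cap_s = 1e4) {
  if (p_W <= 0 || gamma_mN_m <= 0)
    stop("motor power and membrane tension must be positive", call. = FALSE)
  structure(list(p = p_W, gamma_m = gamma_mN_m, r_mac = r_mac_um,
                 k_mac_cap = k_mac_cap_s), class = "phagocyte")
}

#' Terminal sedimentation velocity of a nanoparticle
#'
#' Stokes-law terminal velocity of a sphere settling in plasma under
#' gravity and buoyancy: `v = (2/9) ((rho_np - rho_p) / mu) g r^2`.
#' Negative for buoyant particles (`rho_np < rho_p`).
#'
#' @param np [nanoparticle()] spec.
#' @param env [blood_env()] of the compartment.
#' @param const [phys_constants()].
#' @return Velocity (m s^-1), signed.
#' @export
sedimentation_velocity <- function(np, env, const = phys_constants()) {
  r <- np$r_nm * 1e-9                       # nm -> m
  mu <- env$mu * 1e-3                       # cP -> Pa s
  drho <- (np$rho_np - const$rho_p) * 1e3   # g/cm^3 -> kg/m^3
  (2 / 9) * (drho / mu) * const$g * r^2
}

#' Brownian diffusivity (Stokes-Einstein)
#'
#' `D_B = k_B T / (6 pi mu r)`.
#'
#' @inheritParams sedimentation_velocity
#' @return Diffusivity (m^2 s^-1).
#' @export
brownian_diffusivity <- function(np, env, const = phys_constants()) {
  r <- np$r_nm * 1e-9
  mu <- env$mu * 1e-3
  const$k_B * const$T_K / (6 * pi * mu * r)
}

#' Shear-induced diffusivity
#'
#' Erythrocyte-collision-enhanced dispersion in laminar capillary flow:
#' `D_S = 0.3 beta^2 gamma_dot H^2`.
#'
#' @param env [blood_env()].
#' @param cap [capillary()] supplying the shear rate.
#' @return Diffusivity (m^2 s^-1).
#' @export
shear_induced_diffusivity <- function(env, cap) {
  beta <- env$beta * 1e-6                   # um -> m
  0.3 * beta^2 * cap$gamma_dot * env$H^2
}

#' Effective nanoparticle diffusivity
#'
#' Sum of the Brownian and shear-induced contributions.
#'
#' @inheritParams sedimentation_velocity
#' @param cap [capillary()].
#' @return Diffusivity (m^2 s^-1).
#' @export
effective_diffusivity <- function(np, env, cap, const = phys_constants()) {
  brownian_diffusivity(np, env, const) + shear_induced_diffusivity(env, cap)
}

#' Vessel-wall deposition rate constant
#'
#' The sedimentation velocity corrected for advection and diffusion by the
#' capillary Peclet number `u R^2 / (D l)` and divided by the radial
#' sedimentation length `R`:
#' `k_on = v D l / (u R^3)`.
#' Buoyant particles (negative `v`) deposit at rate 0: gravitational
#' margination is one-sided.
#'
#' @inheritParams effective_diffusivity
#' @return Rate (s^-1), non-negative.
#' @export
wall_deposition_rate <- function(np, env, cap, const = phys_constants()) {
  if (cap$u <= 0)
    stop("advective velocity u must be positive for the Peclet correction",
         call. = FALSE)
  v <- sedimentation_velocity(np, env, const)
  D <- effective_diffusivity(np, env, cap, const)
  u <- cap$u * 1e-6                         # um/s -> m/s
  R <- cap$R * 1e-6
  l <- cap$l * 1e-6
  max(0, v * D * l / (u * R^3))
}

#' Vessel-wall dislodging rate constant
#'
#' Brownian escape across the glycocalyx: `k_off = D_B / l_g^2`.
#'
#' @inheritParams effective_diffusivity
#' @return Rate (s^-1).
#' @export
wall_dislodging_rate <- function(np, env, cap, const = phys_constants()) {
  l_g <- cap$l_g * 1e-9                     # nm -> m
  brownian_diffusivity(np, env, const) / l_g^2
}

#' Phagocytosis rate constant
#'
#' Inverse membrane-wrapping time of a macrophage engulfing the particle:
#' `k_mac = p / (4 pi r^2 gamma)`, capped at `phag$k_mac_cap`.
#'
#' @param np [nanoparticle()].
#' @param phag [phagocyte()].
#' @return Rate (s^-1).
#' @export
phagocytosis_rate <- function(np, phag = phagocyte()) {
  r <- np$r_nm * 1e-9
  gamma_m <- phag$gamma_m * 1e-3            # mN/m -> N/m
  min(phag$p / (4 * pi * r^2 * gamma_m), phag$k_mac_cap)
}

#' Pore hindrance factors
#'
#' Centerline hydrodynamic hindrance factors for a sphere of radius `r` in a
#' cylindrical pore of radius `r_pore`, as functions of `alpha = r/r_pore`:
#' the Renkin diffusive factor
#' `F = (1-a)^2 (1 - 2.104 a + 2.09 a^3 - 0.95 a^5)`
#' and the Haberman-Sayre convective drag factor
#' `G = (1 - (2/3) a^2 - 0.20217 a^5) / (1 - 0.75857 a^5)`.
#' Both are clamped to `[0, 1]` and set to 0 for `alpha >= 1` (particle
#' larger than the pore). Vectorised over `alpha`.
#'
#' @param alpha Non-negative particle-to-pore size ratio(s).
#' @return List with numeric vectors `F` and `G`.
#' @export
hindrance_factors <- function(alpha) {
  if (any(alpha < 0)) stop("alpha must be non-negative", call. = FALSE)
  a <- alpha
  Fd <- (1 - a)^2 * (1 - 2.104 * a + 2.09 * a^3 - 0.95 * a^5)
  Gc <- (1 - (2 / 3) * a^2 - 0.20217 * a^5) / (1 - 0.75857 * a^5)
  Fd <- pmin(pmax(Fd, 0), 1)
  Gc <- pmin(pmax(Gc, 0), 1)
  Fd[a >= 1] <- 0
  Gc[a >= 1] <- 0
  list(F = Fd, G = Gc)
}

#' Reflection coefficient as a function of the size ratio
#'
#' Vectorised form of [reflection_coefficient()] in terms of
#' `alpha = r / r_pore` alone; convenient for size scans.
#'
#' @param alpha Non-negative particle-to-pore size ratio(s).
#' @param hindrance Pluggable hindrance-factor function returning
#'   `list(F =, G =)`.
#' @return Sigma value(s) in `[0, 1]`.
#' @export
sigma_from_alpha <- function(alpha, hindrance = hindrance_factors) {
  h <- hindrance(alpha)
  a <- alpha
  s <- 1 - ((1 - (1 - (1 - a)^2)^2) * h$G +
              (16 / 9) * a^2 * (1 - a)^2 * h$F)
  s[a >= 1] <- 1
  pmin(pmax(s, 0), 1)
}

#' Vascular-wall reflection coefficient
#'
#' Fraction of lymph-convected particles rejected at the fenestrated vessel
#' wall:
#' `sigma = 1 - ( [1 - (1 - (1-a)^2)^2] G + (16/9) a^2 (1-a)^2 F )`,
#' with `a = r / r_pore`. Equals 1 (complete exclusion) whenever the
#' particle is at least as large as the pore.
#'
#' @param np [nanoparticle()].
#' @param pore [pore_geometry()].
#' @param hindrance Pluggable hindrance-factor function of `alpha`
#'   returning `list(F =, G =)`; default [hindrance_factors()].
#' @return Dimensionless sigma in `[0, 1]`.
#' @export
reflection_coefficient <- function(np, pore, hindrance = hindrance_factors) {
  sigma_from_alpha(np$r_nm / pore$r_pore, hindrance)
}

#' Tumor vascular permeability
#'
#' Diffusive permeability of the leaky tumor vessel wall:
#' `P = phi (1 - a) F(a) D_B / l_w`, `a = r / r_pore`. The Brownian
#' diffusivity is evaluated with the *tumor* blood viscosity. Zero when the
#' particle exceeds the pore.
#'
#' @param np [nanoparticle()].
#' @param pore [pore_geometry()] with `phi` and `l_w_um` set.
#' @param env [blood_env()] with the tumor viscosity.
#' @param const [phys_constants()].
#' @param hindrance Pluggable hindrance-factor function.
#' @return Permeability (mm s^-1).
#' @export
vascular_permeability <- function(np, pore, env, const = phys_constants(),
                                  hindrance = hindrance_factors) {
  if (is.null(pore$phi) || is.null(pore$l_w))
    stop("tumor pore geometry requires `phi` and `l_w_um`", call. = FALSE)
  a <- np$r_nm / pore$r_pore
  if (a >= 1) return(0)
  D_B <- brownian_diffusivity(np, env, const)
  l_w <- pore$l_w * 1e-6                    # um -> m
  P_m_s <- pore$phi * (1 - a) * hindrance(a)$F * D_B / l_w
  P_m_s * 1e3                               # m/s -> mm/s
}

#' Full transport-rate set for one compartment
#'
#' Convenience wrapper evaluating all mechanistic rates for a compartment's
#' blood environment, capillary, pore geometry and (optionally) phagocytes.
#'
#' @inheritParams vascular_permeability
#' @param cap [capillary()].
#' @param phag [phagocyte()] or `NULL` for non-MPS compartments.
#' @return List with `k_on`, `k_off`, `k_mac` (s^-1), `sigma`
#'   (dimensionless) and, when the pore geometry carries `phi`/`l_w`,
#'   `P` (mm s^-1).
#' @export
transport_rates <- function(np, env, cap, pore, phag = NULL,
                            const = phys_constants(),
                            hindrance = hindrance_factors) {
  out <- list(
    k_on = wall_deposition_rate(np, env, cap, const),
    k_off = wall_dislodging_rate(np, env, cap, const),
    k_mac = if (is.null(phag)) 0 else phagocytosis_rate(np, phag),
    sigma = reflection_coefficient(np, pore, hindrance)
  )
  if (!is.null(pore$phi) && !is.null(pore$l_w))
    out$P <- vascular_permeability(np, pore, env, const, hindrance)
  out
}
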