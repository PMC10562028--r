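# Photon interaction data for the four phantom materials.
#
# Tables are generated semi-analytically at first use and cached:
#   - incoherent (Compton) scattering from the exact Klein-Nishina total
#     cross section per electron times electrons-per-gram (Z/A * N_A);
#   - photoelectric absorption from the standard Z_eff^3.8 / E^3.2 fit,
#     normalized so water reproduces ~4.94 cm2/g at 10 keV;
#   - pair production from a logarithmic threshold fit normalized so water
#     reproduces ~4.3e-3 cm2/g at 10 MeV.
# Energy-transfer fractions: photoelectric 1; Compton 1 - <E'>/E with <E'>
# from numerical integration of the Klein-Nishina differential cross
# section; pair (E - 1.022)/E. Coherent scattering and binding effects are
# neglected (kerma-approximation engine; documented limitation).

MEC2 <- 0.51099895   # electron rest energy, MeV
RE_CM <- 2.8179403262e-13  # classical electron radius, cm
NAVO <- 6.02214076e23

# electrons per gram = N_A * Z/A, and effective Z per material
material_composition <- function() {
  data.frame(
    material = c("Air", "Lung", "Tissue", "Bone"),
    z_over_a = c(0.4992, 0.5505, 0.5551, 0.5148),
    z_eff    = c(7.64, 7.42, 7.42, 12.3),
    stringsAsFactors = FALSE
  )
}

#' Klein-Nishina total cross section per electron
#' @param e_mev photon energy, MeV.
#' @return cross section, cm2/electron.
#' @export
kn_total_cross_section <- function(e_mev) {
  a <- e_mev / MEC2
  2 * pi * RE_CM^2 * (
    (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a) +
      log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
  )
}

#' Klein-Nishina mean scattered-photon energy fraction
#'
#' `<E'>/E` computed by numerical integration of the differential cross
#' section over the scattering angle (Simpson's rule). Serves both the
#' engine's energy-transfer coefficient and as an independent oracle for the
#' sampled Compton kinematics.
#'
#' @param e_mev photon energy, MeV.
#' @param n integration points (odd).
#' @return mean of E'/E under Klein-Nishina.
#' @export
kn_mean_scatter_fraction <- function(e_mev, n = 4001L) {
  a <- e_mev / MEC2
  mu <- seq(-1, 1, length.out = n)
  eps <- 1 / (1 + a * (1 - mu))
  w <- eps^2 * (eps + 1 / eps - (1 - mu^2))  # ~ dsigma/dOmega (unnorm.)
  simp <- c(1, rep(c(4, 2), length.out = n - 2), 1)
  sum(simp * w * eps) / sum(simp * w)
}

xs_photoelectric <- function(e_mev, z_eff) {
  # normalized to water (z_eff 7.42): tau/rho(10 keV) = 4.94 cm2/g
  c0 <- 4.94 / (7.42^3.8 * 0.01^-3.2)
  c0 * z_eff^3.8 * e_mev^-3.2
}

xs_pair <- function(e_mev, z_eff) {
  # normalized to water: kappa/rho(10 MeV) = 4.3e-3 cm2/g
  thr <- 2 * MEC2
  c0 <- 4.3e-3 / (7.42 * log(10 / thr))
  ifelse(e_mev > thr, c0 * z_eff * log(e_mev / thr), 0)
}

#' Cross-section table for one material
#'
#' @param material one of `"Air"`, `"Lung"`, `"Tissue"`, `"Bone"` (water uses
#'   `"Tissue"`).
#' @param n_energies grid size, log-spaced over 0.01-12 MeV.
#' @return list with `energy` (MeV), `mu_rho` total (cm2/g), per-process
#'   `pe`, `compton`, `pair`, energy-transfer `mu_tr_rho` (cm2/g) and the
#'   Compton mean scatter fraction `f_scatter`.
#' @export
cross_section_table <- function(material = c("Air", "Lung", "Tissue", "Bone"),
                                n_energies = 64L) {
  material <- match.arg(material)
  key <- paste0(material, "_", n_energies)
  cached <- .xs_cache[[key]]
  if (!is.null(cached)) return(cached)
  comp <- material_composition()
  row <- comp[comp$material == material, ]
  e <- exp(seq(log(0.01), log(12), length.out = n_energies))
  compton <- NAVO * row$z_over_a * kn_total_cross_section(e)
  pe <- xs_photoelectric(e, row$z_eff)
  pair <- xs_pair(e, row$z_eff)
  f_sc <- vapply(e, kn_mean_scatter_fraction, numeric(1), n = 801L)
  mu_tr <- pe + compton * (1 - f_sc) + pair * (e - 2 * MEC2) / e
  out <- list(material = material, energy = e,
              mu_rho = pe + compton + pair,
              pe = pe, compton = compton, pair = pair,
              mu_tr_rho = mu_tr, f_scatter = f_sc)
  .xs_cache[[key]] <- out
  out
}

.xs_cache <- new.env(parent = emptyenv())

#' Look up a mass attenuation coefficient (log-log interpolation)
#'
#' @param xs a [cross_section_table()].
#' @param e_mev energies, MeV (clamped to the table range).
#' @param what one of `"mu_rho"`, `"mu_tr_rho"`, `"pe"`, `"compton"`, `"pair"`.
#' @return coefficients, cm2/g.
#' @export
xs_lookup <- function(xs, e_mev, what = "mu_rho") {
  v <- xs[[what]]
  e <- pmin(pmax(e_mev, xs$energy[1]), xs$energy[length(xs$energy)])
  pos <- v > 0
  if (all(pos)) {
    exp(stats::approx(log(xs$energy), log(v), xout = log(e))$y)
  } else {
    pmax(0, stats::approx(log(xs$energy), v, xout = log(e))$y)
  }
}

# Pack tables for the C++ engine: one list per material index 1..4.
xs_engine_pack <- function(n_energies = 64L) {
  mats <- material_composition()$material
  lapply(mats, function(m) {
    xs <- cross_section_table(m, n_energies)
    tot <- xs$mu_rho
    list(log_e = log(xs$energy),
         log_mu = log(tot),
         p_pe = xs$pe / tot,
         p_pair = xs$pair / tot)
  })
}
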