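#' Target-volume (compressibility) energy of one cell
#'
#' Volume constraint normalized by the target volume,
#' \eqn{H_v = \lambda_v / V^T (V - V^T)^2}. Dividing the incompressibility
#' by the target volume makes freshly divided daughters stiffer than their
#' mother, which prevents division waves in a compressed monolayer. For a
#' homogeneous population with common target volume c it equals the classic
#' unnormalized CPM volume term divided by c.
#'
#' @param v Current volume (sites).
#' @param v_t Target volume (sites); must be positive for a live cell.
#' @param lambda_v Incompressibility coefficient.
#' @return Energy (vectorized over inputs).
#' @examples
#' volume_energy(45, 50, 25) # 12.5
#' @export
volume_energy <- function(v, v_t, lambda_v) {
  if (any(v_t <= 0)) {
    stop("volume_energy(): target volume must be positive for a live cell")
  }
  lambda_v / v_t * (v - v_t)^2
}

#' Describe a lattice region for adhesion computations
#'
#' @param type One of \code{"c"} (tissue cell), \code{"EC"} (vessel cell),
#'   \code{"m"} (medium).
#' @param rho_cam,rho_mam Adhesion-molecule densities (used for type
#'   \code{"c"}; vessel and medium densities are fixed by
#'   \code{\link{cpm_params}}).
#' @return List of class \code{cpm_region}.
#' @export
cpm_region <- function(type = c("c", "EC", "m"), rho_cam = NA_real_,
                       rho_mam = NA_real_) {
  type <- match.arg(type)
  structure(list(type = type, rho_cam = rho_cam, rho_mam = rho_mam),
            class = "cpm_region")
}

#' Effective adhesion energy between two regions in contact
#'
#' Surface tension minus adhesion-molecule matching:
#' \eqn{J^{eff} = J(\tau,\tau') - \sum_{a,b} k_{a,b} \min[\rho_a, \rho_b]}
#' with cell-adhesion-molecule (CAM) matching on cell-cell and cell-vessel
#' contacts and matrix-adhesion (MAM against medium MAS) matching on
#' cell-medium contacts (all coupling constants k = 1). Vessel cells carry a
#' fixed CAM density of \code{j_max} and the medium a fixed MAS density of
#' \code{j_max/2}, so the effective adhesion ranges over \code{[0, j_max]}
#' for cell-cell/cell-vessel and \code{[0, j_max/2]} for cell-medium.
#'
#' @param region_i,region_j \code{\link{cpm_region}} objects (distinct
#'   regions).
#' @param params A \code{\link{cpm_params}}.
#' @return Effective contact energy (scalar). Unknown type pairings return 0
#'   with a warning.
#' @examples
#' p <- cpm_params()
#' effective_adhesion(cpm_region("c", rho_cam = 99),
#'                    cpm_region("c", rho_cam = 99), p) # 1
#' @export
effective_adhesion <- function(region_i, region_j, params = cpm_params()) {
  ti <- region_i$type; tj <- region_j$type
  pair <- paste(sort(c(ti, tj)), collapse = "-")
  if (pair == "c-c") {
    params$j_cc - min(region_i$rho_cam, region_j$rho_cam)
  } else if (pair == "EC-c") {
    rc <- if (ti == "c") region_i$rho_cam else region_j$rho_cam
    params$j_cec - min(rc, params$rho_cam_ec)
  } else if (pair == "c-m") {
    rm_ <- if (ti == "c") region_i$rho_mam else region_j$rho_mam
    params$j_cm - min(rm_, params$rho_mas_m)
  } else if (pair == "EC-m") {
    params$j_ecm
  } else if (pair == "EC-EC") {
    params$j_ecec
  } else if (pair == "m-m") {
    0
  } else {
    warning("effective_adhesion(): unknown type pair '", pair,
            "', returning 0")
    0
  }
}

#' Chemotactic contribution to the Hamiltonian change of a copy attempt
#'
#' For a cell extending from \code{source} into \code{target},
#' \eqn{\Delta H_\chi = -\sum_s \chi_s (s(x') - s(x))} over the three
#' species, so a positive coefficient biases motion up-gradient
#' (chemoattraction) and a negative one down-gradient (chemorepulsion, as
#' evolved against lactate). The sign is chosen so that the published
#' description of attraction/repulsion holds (the printed formula has the
#' opposite, repulsive, orientation).
#'
#' @param source_conc,target_conc Named numeric vectors (or 3-vectors in
#'   g/o2/l order) of concentrations at the source and target site.
#' @param phenotype Named phenotype vector carrying \code{chi_g},
#'   \code{chi_o2}, \code{chi_l}.
#' @return Energy change contribution (negative favors the extension).
#' @examples
#' ph <- initial_phenotype(); ph["chi_g"] <- 1
#' chemotaxis_delta(c(g = 0.5, o2 = 0, l = 0), c(g = 0.7, o2 = 0, l = 0), ph)
#' @export
chemotaxis_delta <- function(source_conc, target_conc, phenotype) {
  chi <- unname(phenotype[c("chi_g", "chi_o2", "chi_l")])
  -sum(chi * (unname(target_conc[1:3]) - unname(source_conc[1:3])))
}

#' Metropolis acceptance probability
#'
#' Probability 1 for energy-decreasing copies, Boltzmann factor
#' \eqn{\exp(-\Delta H / T)} otherwise (standard Metropolis sign; the
#' printed rule would exceed 1 for energy-increasing moves).
#'
#' @param delta_h Hamiltonian change of the attempted copy.
#' @param temperature Metropolis noise amplitude (> 0).
#' @return Probability in (0, 1] (vectorized over \code{delta_h}).
#' @examples
#' acceptance_probability(-5, 10) # 1
#' acceptance_probability(10, 10) # exp(-1)
#' @export
acceptance_probability <- function(delta_h, temperature) {
  if (temperature <= 0) stop("acceptance_probability(): temperature must be > 0")
  ifelse(delta_h < 0, 1, exp(-delta_h / temperature))
}
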