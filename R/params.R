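#' Names of the ten mutable phenotype parameters
#'
#' Column/entry order used throughout the package for phenotype vectors and
#' matrices: incompressibility, division volume, cell-adhesion-molecule
#' density, matrix-adhesion-molecule density, the three chemotaxis
#' coefficients (glucose, oxygen, lactate), the intracellular growth signal,
#' and the two Hill thresholds of the hypoxia switch.
#'
#' @return Character vector of length 10.
#' @export
phenotype_names <- function() {
  c("lambda_v", "V_D", "rho_cam", "rho_mam",
    "chi_g", "chi_o2", "chi_l", "N0", "kappa_h", "kappa_z")
}

#' Mutation specification for the ten phenotype parameters
#'
#' Per-parameter initial value, Gaussian step size, and reflective bounds,
#' plus a global per-parameter mutation rate. Defaults are the published
#' parameter table of the model. The printed table lists an initial
#' incompressibility of 25 with a maximum of 20; the maximum is raised to 25
#' here so that the initial value is admissible (flagged as a printed
#' inconsistency).
#'
#' @param rate Global per-parameter mutation probability \eqn{\mu_p} applied
#'   independently to each parameter at each mutation pass. The published
#'   sweeps use a single global rate between 0.001 and 0.9.
#' @param table Optional replacement data frame with columns
#'   \code{name, init, step, min, max} (rows in \code{phenotype_names()}
#'   order). Leave \code{NULL} for the default table.
#' @return An object of class \code{mutation_spec}: a data frame with one row
#'   per parameter and attribute \code{rate}.
#' @examples
#' spec <- mutation_spec(rate = 0.1)
#' spec$step
#' @export
mutation_spec <- function(rate = 0.1, table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      name = phenotype_names(),
      init = c(25, 50, 99, 49.5, 0, 0, 0, 250, 0.1, 0.5),
      step = c(0.2, 1, 0.1, 0.1, 0.1, 0.1, 0.1, 25, 1e-3, 0.01),
      min  = c(0, 10, 0, 0, -20, -20, -20, 0, 1e-4, 1e-4),
      max  = c(25, 200, 100, 50, 20, 20, 20, 2500, 10, 100),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(
    identical(table$name, phenotype_names()),
    all(table$step > 0),
    all(table$min <= table$init), all(table$init <= table$max),
    rate >= 0, rate <= 1
  )
  attr(table, "rate") <- rate
  class(table) <- c("mutation_spec", class(table))
  table
}

#' Initial phenotype vector
#'
#' @param spec A \code{\link{mutation_spec}}.
#' @return Named numeric vector of the 10 initial parameter values.
#' @export
initial_phenotype <- function(spec = mutation_spec()) {
  stats::setNames(spec$init, spec$name)
}

#' Lattice/Hamiltonian parameters of the cellular Potts engine
#'
#' @param temperature Metropolis noise amplitude (the model's \eqn{\mu} in
#'   the acceptance rule). Not printed in the source text; default 50, the
#'   same scale as the cell-medium surface tension.
#' @param j_max Adhesion scale. With the published adhesion-molecule ranges
#'   (cell-adhesion density up to 100, matrix-adhesion density up to 50) a
#'   value of 100 makes effective adhesion span exactly \code{[0, j_max]} for
#'   cell-cell/cell-vessel contacts and \code{[0, j_max/2]} for cell-medium.
#' @param j_cc,j_cec,j_cm Surface-tension coefficients for cell-cell,
#'   cell-vessel and cell-medium contacts. Defaults
#'   \code{j_cc = j_cec = j_max} and \code{j_cm = j_max/2}.
#' @param j_ecm,j_ecec Vessel-medium and vessel-vessel coefficients (not
#'   printed; vessels never move so these only shift contact energies by a
#'   near-constant). Default 0.
#' @param rho_cam_ec Fixed cell-adhesion-molecule density on vessel cells;
#'   \code{j_max} by construction so cell-vessel adhesion spans the full
#'   range.
#' @param rho_mas_m Fixed matrix-adhesion-site density of the medium;
#'   \code{j_max/2} by construction.
#' @param neighborhood Neighborhood order for both contact-energy pairs and
#'   copy candidates; \code{"moore"} (8 neighbors, default) or
#'   \code{"von_neumann"} (4).
#' @return List of class \code{cpm_params}.
#' @export
cpm_params <- function(temperature = 50, j_max = 100,
                       j_cc = j_max, j_cec = j_max, j_cm = j_max / 2,
                       j_ecm = 0, j_ecec = 0,
                       rho_cam_ec = j_max, rho_mas_m = j_max / 2,
                       neighborhood = c("moore", "von_neumann")) {
  neighborhood <- match.arg(neighborhood)
  stopifnot(temperature > 0, j_max > 0)
  structure(list(
    temperature = temperature, j_max = j_max,
    j_cc = j_cc, j_cec = j_cec, j_cm = j_cm,
    j_ecm = j_ecm, j_ecec = j_ecec,
    rho_cam_ec = rho_cam_ec, rho_mas_m = rho_mas_m,
    neighborhood = neighborhood
  ), class = "cpm_params")
}

#' Metabolic parameters
#'
#' Published constants: 38 ATP per glucose through respiration, ROS decay
#' 0.1 per MCS, 2 lactate + 2 ATP per fermented glucose, 6 oxygen per
#' respired glucose. The transporter kinetics (\code{v_m}, \code{k_m}), basal
#' cost \code{e_m} and Hill exponents live in the authors' unpublished
#' configuration; defaults here are package calibrations chosen so that an
#' unmutated resting cell is mildly ROS-loaded (well below its switching
#' threshold), nearly fully respiratory, and close to energy balance.
#'
#' @param alpha_r ATP yield per respired glucose (> 2).
#' @param v_m Maximum transport rate per glucose transporter per MCS
#'   (site-concentration units).
#' @param k_m Michaelis constant of glucose uptake (site-concentration
#'   units, vessel level = 1).
#' @param e_m Basal metabolic cost per MCS (ATP units).
#' @param n_h,n_z Hill exponents of the oxygen and ROS arms of the hypoxia
#'   switch.
#' @param omega_z ROS decay constant per MCS.
#' @param n0_cap Hard cap on the growth signal (maximum transporter surface
#'   density).
#' @return List of class \code{metabolic_params}.
#' @export
metabolic_params <- function(alpha_r = 38, v_m = 1e-4, k_m = 0.5,
                             e_m = 0.3, n_h = 4, n_z = 4,
                             omega_z = 0.1, n0_cap = 2500) {
  stopifnot(alpha_r > 2, v_m >= 0, k_m > 0, e_m >= 0,
            omega_z >= 0, omega_z <= 1)
  structure(list(alpha_r = alpha_r, v_m = v_m, k_m = k_m, e_m = e_m,
                 n_h = n_h, n_z = n_z, omega_z = omega_z, n0_cap = n0_cap),
            class = "metabolic_params")
}

#' Growth, division and death parameters
#'
#' The division-window fraction (5 percent of division volume) and the
#' random-apoptosis probability (0.1 percent per cell per MCS) are published
#' values. The anabolism rate \code{alpha}, pressure-relaxation coefficient
#' \code{beta}, ROS-toxicity shrink rate \code{gamma} and ROS tolerance
#' \code{theta_r} are package calibrations fixed so that a non-mutating
#' population under stable vessels is homeostatic (constant cell number,
#' coverage near 1).
#'
#' @param alpha Biomass (target-volume sites) produced per unit net energy
#'   per MCS.
#' @param beta Relaxation coefficient of the density-fluctuation
#'   (pressure) term.
#' @param gamma Target-volume shrink rate (sites/MCS) while ROS exceeds
#'   \code{theta_r}.
#' @param theta_r ROS tolerance threshold.
#' @param w_frac Division-window fraction of division volume.
#' @param p_apoptosis Random apoptosis probability per cell per MCS.
#' @param apoptotic_shrink Target-volume decrease per MCS of an apoptotic
#'   cell (sites).
#' @return List of class \code{growth_params}.
#' @export
growth_params <- function(alpha = 0.5, beta = 0.01, gamma = 0.05,
                          theta_r = 1, w_frac = 0.05,
                          p_apoptosis = 0.001, apoptotic_shrink = 1) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, theta_r >= 0,
            w_frac > 0, p_apoptosis >= 0, p_apoptosis <= 1,
            apoptotic_shrink > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 theta_r = theta_r, w_frac = w_frac,
                 p_apoptosis = p_apoptosis,
                 apoptotic_shrink = apoptotic_shrink),
            class = "growth_params")
}

#' Reaction-diffusion field parameters
#'
#' Physical diffusion coefficients follow the source model
#' (glucose \eqn{10^{-9}} m\eqn{^2}/s, oxygen and lactate \eqn{10^{-11}}
#' m\eqn{^2}/s); decay is zero for all three species. The explicit
#' finite-difference scheme substeps each MCS with diffusion number
#' \code{mu}; the number of substeps is capped at \code{nsub_cap}. At the
#' default cap the in-lattice effective diffusivity is
#' \code{mu * nsub_cap} = 150 site^2/MCS for every species: exact for oxygen
#' and lactate, deliberately below the physical value for glucose (see the
#' methods vignette; a quasi-steady relaxation solver for glucose is
#' available via \code{glucose_solver = "relax"}).
#'
#' @param d_g,d_o2,d_l Diffusion coefficients (m^2/s).
#' @param dx Lattice spacing (m); one site is 2 micrometers.
#' @param dt_mcs Real time per MCS (s); one MCS is one minute.
#' @param mu Diffusion number \code{D dt_sub / dx^2} per substep
#'   (stability requires <= 0.25 for the 5-point stencil).
#' @param nsub_cap Maximum substeps per species per MCS.
#' @param glucose_solver \code{"explicit"} (substep-capped, default) or
#'   \code{"relax"} (iterate the stencil to quasi-steady state each MCS).
#' @param relax_tol,relax_maxiter Convergence tolerance (max absolute change
#'   per sweep) and iteration cap of the relaxation solver.
#' @param inactive_vessel Policy at blocked vessels: \code{"inert"} (sites
#'   evolve freely by diffusion, default) or \code{"zero"} (clamped to zero).
#' @return List of class \code{field_params}.
#' @export
field_params <- function(d_g = 1e-9, d_o2 = 1e-11, d_l = 1e-11,
                         dx = 2e-6, dt_mcs = 60, mu = 0.25,
                         nsub_cap = 600,
                         glucose_solver = c("explicit", "relax"),
                         relax_tol = 1e-6, relax_maxiter = 2000,
                         inactive_vessel = c("inert", "zero")) {
  glucose_solver <- match.arg(glucose_solver)
  inactive_vessel <- match.arg(inactive_vessel)
  stopifnot(mu > 0, mu <= 0.25, dx > 0, dt_mcs > 0, nsub_cap >= 1)
  nsub <- function(d) min(ceiling(d * dt_mcs / dx^2 / mu), nsub_cap)
  structure(list(
    d_g = d_g, d_o2 = d_o2, d_l = d_l, dx = dx, dt_mcs = dt_mcs, mu = mu,
    nsub_cap = nsub_cap,
    nsub_g = nsub(d_g), nsub_o2 = nsub(d_o2), nsub_l = nsub(d_l),
    glucose_solver = glucose_solver,
    relax_tol = relax_tol, relax_maxiter = relax_maxiter,
    inactive_vessel = inactive_vessel
  ), class = "field_params")
}
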