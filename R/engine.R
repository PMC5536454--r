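# Per-MCS engine orchestration. Hook order within one MCS:
#   copy attempts -> vessel state update + field stepping -> metabolism ->
#   hypoxia/ROS update -> growth -> division (+ mutation) -> death.
# The published workflow fixes metabolism -> division -> mutation; the rest
# is a package choice, documented in the methods vignette.

nb_count <- function(cpm) if (cpm$neighborhood == "moore") 8L else 4L

#' Attempt a single identifier copy between two adjacent sites
#'
#' Computes the Hamiltonian change (volume + adhesion + chemotaxis) for
#' copying the identifier at \code{site} into \code{neighbor_site},
#' accepts it with the Metropolis probability, and (when accepted and
#' \code{execute = TRUE}) updates the lattice and the two affected volumes.
#' Identity copies are skipped as no-ops; copies from or into vessel sites
#' are rejected unconditionally.
#'
#' @param state A \code{cpm_state}.
#' @param site,neighbor_site Length-2 integer vectors (1-based x, y);
#'   must be neighbors under the configured copy neighborhood.
#' @param execute Apply the update on acceptance (default TRUE); with
#'   FALSE only the decision and energy change are computed.
#' @return List with \code{accepted}, \code{skipped}, and \code{delta_h}
#'   (NA for skipped/vessel-rejected attempts).
#' @export
attempt_copy <- function(state, site, neighbor_site, execute = TRUE) {
  cpm <- state$params$cpm
  dx <- abs(site[1] - neighbor_site[1]); dx <- min(dx, state$width - dx)
  dy <- abs(site[2] - neighbor_site[2]); dy <- min(dy, state$height - dy)
  if (max(dx, dy) > 1 || (cpm$neighborhood == "von_neumann" && dx + dy != 1)) {
    stop("attempt_copy(): sites are not neighbors under the copy neighborhood")
  }
  cpp_attempt_at(state$grid, state$cell_type, state$V, state$VT, state$pheno,
                 state$g, state$o2, state$lac,
                 cpm$temperature, cpm$j_cc, cpm$j_cec, cpm$j_cm,
                 cpm$j_ecm, cpm$j_ecec, cpm$rho_cam_ec, cpm$rho_mas_m,
                 nb_count(cpm),
                 site[1] - 1L, site[2] - 1L,
                 neighbor_site[1] - 1L, neighbor_site[2] - 1L, execute)
}

# Dirichlet clamp index/value sets for the three species under the current
# vessel states and inactive-vessel policy.
vessel_clamps <- function(state) {
  act <- unlist(state$vessel_sites[state$vessel_active])
  if (is.null(act)) act <- integer(0)
  pol <- state$params$fields$inactive_vessel
  ina <- if (pol == "zero") {
    x <- unlist(state$vessel_sites[!state$vessel_active])
    if (is.null(x)) integer(0) else x
  } else integer(0)
  list(
    g = list(idx = c(act, ina), val = c(rep(1, length(act)), rep(0, length(ina)))),
    o2 = list(idx = c(act, ina), val = c(rep(1, length(act)), rep(0, length(ina)))),
    l = list(idx = c(act, ina), val = rep(0, length(act) + length(ina)))
  )
}

#' Apply vessel boundary values to the nutrient fields
#'
#' Active-vessel sites are clamped to glucose 1, oxygen 1, lactate 0.
#' Blocked vessels follow the configured policy: \code{"inert"} (default;
#' their sites evolve freely by diffusion) or \code{"zero"} (clamped to 0).
#'
#' @param state A \code{cpm_state} (fields modified in place).
#' @return The state, invisibly.
#' @export
apply_vessel_boundary <- function(state) {
  cl <- vessel_clamps(state)
  state$g[cl$g$idx + 1L] <- cl$g$val
  state$o2[cl$o2$idx + 1L] <- cl$o2$val
  state$lac[cl$l$idx + 1L] <- cl$l$val
  invisible(state)
}

#' Advance the three nutrient fields by one MCS
#'
#' Explicit 5-point finite-difference substeps on the periodic lattice with
#' vessel clamps re-applied after every substep; glucose optionally uses the
#' quasi-steady relaxation solver (see \code{\link{field_params}}). Uptake
#' and secretion are applied separately by the metabolism step.
#'
#' @param state A \code{cpm_state} (fields modified in place).
#' @return The state, invisibly.
#' @export
step_fields <- function(state) {
  fp <- state$params$fields
  cl <- vessel_clamps(state)
  relax_g <- fp$glucose_solver == "relax"
  cpp_diffuse(state$g, fp$mu, fp$nsub_g, cl$g$idx, cl$g$val,
              relax_g, fp$relax_tol, fp$relax_maxiter)
  cpp_diffuse(state$o2, fp$mu, fp$nsub_o2, cl$o2$idx, cl$o2$val,
              FALSE, fp$relax_tol, fp$relax_maxiter)
  cpp_diffuse(state$lac, fp$mu, fp$nsub_l, cl$l$idx, cl$l$val,
              FALSE, fp$relax_tol, fp$relax_maxiter)
  invisible(state)
}

#' Run the metabolic trafficking step for all cells
#'
#' Each live cell takes up glucose on its surface sites with
#' Michaelis-Menten kinetics scaled by its (hypoxia-compensated) transporter
#' count, consumes 6 oxygen per respired glucose (oxygen-limited), secretes
#' 2 lactate per fermented glucose, and earns 2 ATP per fermented plus
#' \code{alpha_r} per respired glucose. Fields are modified in place; the
#' per-cell readouts (uptakes, energy) are stored on the state.
#'
#' @param state A \code{cpm_state}.
#' @return Invisibly, the per-cell metabolism matrix (rows = cell ids).
#' @export
cell_metabolic_step <- function(state) {
  met <- state$params$met
  hv <- if (state$frozen) rep(0, length(state$h)) else state$h
  m <- cpp_metabolize(state$grid, state$cell_type, state$pheno, hv,
                      state$g, state$o2, state$lac,
                      met$v_m, met$k_m, met$alpha_r, met$n0_cap)
  state$u_g <- m[, "u_g"]
  state$u_o2 <- m[, "u_o2"]
  state$e_net <- m[, "e_prod"] - met$e_m
  state$last_metabolism <- m
  invisible(m)
}

#' Divide a cell in two
#'
#' The cell's sites are bisected by a line through its (periodic) centroid
#' oriented along the axis of least extent: sites are ranked by their
#' projection on the principal (longest) axis and the lower half seeds the
#' new daughter, so both daughters get \code{floor(V/2)}/\code{ceiling(V/2)}
#' sites. The parent's target volume is shared exactly in half, generation
#' counters increment, and both daughters independently undergo a mutation
#' pass.
#'
#' @param state A \code{cpm_state}.
#' @param id Id of the dividing cell (must occupy >= 2 sites).
#' @param mutate Run the mutation pass on the daughters (default TRUE).
#' @param sites Optional precomputed 2-column coordinate matrix of the
#'   cell's sites (engine fast path); found from the grid when NULL.
#' @return Invisibly, the two daughter ids \code{c(id, new_id)}.
#' @export
divide_cell <- function(state, id, mutate = TRUE, sites = NULL) {
  if (is.null(sites)) sites <- which(state$grid == id, arr.ind = TRUE)
  if (nrow(sites) < 2) stop("divide_cell(): cell must occupy >= 2 sites")
  # unwrap periodic coordinates relative to the first site
  w <- state$width; hgt <- state$height
  rel <- cbind(
    ((sites[, 1] - sites[1, 1] + w %/% 2) %% w) - w %/% 2,
    ((sites[, 2] - sites[1, 2] + hgt %/% 2) %% hgt) - hgt %/% 2
  )
  rel <- sweep(rel, 2, colMeans(rel))
  cv <- crossprod(rel) / nrow(rel)
  ev <- eigen(cv, symmetric = TRUE)
  major <- ev$vectors[, 1]           # axis of greatest extent
  proj <- rel %*% major
  ord <- order(proj, rel[, 1], rel[, 2])
  take <- ord[seq_len(nrow(sites) %/% 2)]

  vt_half <- state$VT[id] / 2
  new_id <- add_cell_record(state, 1L, state$pheno[id, ],
                            v_t = vt_half,
                            generation = state$generation[id] + 1L,
                            mutable = state$mutable[id])
  state$VT[id] <- vt_half
  state$generation[id] <- state$generation[id] + 1L
  state$h[new_id] <- state$h[id]
  state$zeta[new_id] <- state$zeta[id]
  state$grid[sites[take, , drop = FALSE]] <- new_id
  state$V[new_id] <- length(take)
  state$V[id] <- state$V[id] - length(take)
  if (mutate && state$mutable[id]) {
    state$pheno[id, ] <- mutate_phenotype(state$pheno[id, ], state$params$mut)
    state$pheno[new_id, ] <- mutate_phenotype(state$pheno[new_id, ],
                                              state$params$mut)
  }
  ln <- state$lineage_n + 1L
  if (ln > nrow(state$lineage_mat)) {
    state$lineage_mat <- rbind(state$lineage_mat,
                               matrix(0L, max(64L, nrow(state$lineage_mat)), 3))
  }
  state$lineage_mat[ln, ] <- c(state$t, id, new_id)
  state$lineage_n <- ln
  invisible(c(id, new_id))
}

# Growth + division probe for all live cells (internal; part of run_mcs).
growth_and_division_step <- function(state) {
  ids <- live_cells(state)
  ids <- ids[!state$apoptotic[ids]]
  if (length(ids)) {
    up <- update_target_volume(state$V[ids], state$VT[ids],
                               e_prod = state$e_net[ids] + state$params$met$e_m,
                               zeta = state$zeta[ids],
                               growth = state$params$growth,
                               e_m = state$params$met$e_m)
    state$VT[ids] <- up$v_t
    # division probe (once per cell per MCS); dead-flagged cells are
    # removed by the death step below and cannot divide
    cand <- ids[!up$dead & state$V[ids] >= 2]
    if (length(cand)) {
      p <- division_probability(state$V[cand], state$pheno[cand, "V_D"],
                                state$params$growth$w_frac)
      div <- cand[runif(length(cand)) < p]
      if (length(div)) {
        # one grid pass for all dividers instead of one per division
        idx <- which(state$grid %in% div)
        coords <- arrayInd(idx, dim(state$grid))
        byid <- split(seq_along(idx), state$grid[idx])
        for (id in div) {
          divide_cell(state, id,
                      sites = coords[byid[[as.character(id)]], ,
                                     drop = FALSE])
        }
      }
    }
  }
  invisible(state)
}

#' Apoptosis and cell removal step
#'
#' Marks live cells apoptotic with the configured probability, shrinks
#' apoptotic cells' target volume at the constant rate, and removes cells
#' whose target volume has reached zero (mass exhausted or apoptosis
#' complete) or whose lattice volume is zero, converting their sites into
#' extracellular space.
#'
#' @param state A \code{cpm_state}.
#' @return Invisibly, the ids removed this step.
#' @export
death_step <- function(state) {
  gw <- state$params$growth
  ids <- live_cells(state)
  if (length(ids) == 0) return(invisible(integer(0)))
  fresh <- ids[!state$apoptotic[ids]]
  if (gw$p_apoptosis > 0 && length(fresh)) {
    mark <- fresh[runif(length(fresh)) < gw$p_apoptosis]
    state$apoptotic[mark] <- TRUE
  }
  apo <- ids[state$apoptotic[ids]]
  if (length(apo)) state$VT[apo] <- pmax(state$VT[apo] - gw$apoptotic_shrink, 0)
  dead <- ids[state$VT[ids] <= 0 | state$V[ids] <= 0]
  if (length(dead)) {
    state$grid[state$grid %in% dead] <- 0L
    state$cell_type[dead] <- 0L
    state$V[dead] <- 0L
    state$VT[dead] <- 0
    state$apoptotic[dead] <- FALSE
    state$free_ids <- c(state$free_ids, dead)
  }
  invisible(dead)
}

#' Advance the simulation by one Monte Carlo step
#'
#' Performs N copy attempts (N = lattice sites) at random sites, then the
#' per-MCS hooks: vessel state update and field stepping, metabolism,
#' hypoxia/ROS update (one-step delay), target-volume growth, division
#' probe with mutation, and the death step. Advances the clock by 1 MCS
#' (one simulated minute). In the frozen (initial-regime) mode only fields
#' and metabolism run, with hypoxia pinned to zero.
#'
#' @param state A \code{cpm_state}.
#' @param steps Number of MCS to run (default 1).
#' @return The state, invisibly.
#' @export
run_mcs <- function(state, steps = 1) {
  cpm <- state$params$cpm
  met <- state$params$met
  nsites <- state$width * state$height
  for (s in seq_len(steps)) {
    if (!state$frozen && state$n_ids > 0L) {
      cpp_copy_attempts(state$grid, state$cell_type, state$V, state$VT,
                        state$pheno, state$g, state$o2, state$lac,
                        cpm$temperature, cpm$j_cc, cpm$j_cec, cpm$j_cm,
                        cpm$j_ecm, cpm$j_ecec, cpm$rho_cam_ec, cpm$rho_mas_m,
                        nsites, nb_count(cpm))
    }
    if (!state$frozen && length(state$vessel_ids)) {
      p <- blocking_probability(state$schedule, t = state$t,
                                coverage = if (state$schedule$mode ==
                                               "density_feedback")
                                  coverage(state) else NA_real_)
      state$vessel_active <- update_vessel_states(state$vessel_active, p)
    }
    step_fields(state)
    m <- cell_metabolic_step(state)
    ids <- live_cells(state)
    if (length(ids) && !state$frozen) {
      # one-step delay: h from this MCS's oxygen and *previous* ROS;
      # ROS from previous ROS, previous h, and this MCS's respired glucose
      h_new <- update_hypoxia(m[ids, "mean_o2"], state$zeta[ids],
                              state$pheno[ids, "kappa_h"],
                              state$pheno[ids, "kappa_z"],
                              met$n_h, met$n_z)
      z_new <- update_ros(state$zeta[ids], state$h[ids], m[ids, "g_resp"],
                          met$omega_z)
      state$h[ids] <- h_new
      state$zeta[ids] <- z_new
    } else if (length(ids) && state$frozen) {
      # fields equilibrate against fully respiratory cells; ROS settles to
      # its fixed point so released cells start from a consistent state
      state$zeta[ids] <- update_ros(state$zeta[ids], 0, m[ids, "g_resp"],
                                    met$omega_z)
    }
    if (!state$frozen) {
      growth_and_division_step(state)
      death_step(state)
    }
    state$t <- state$t + 1L
  }
  invisible(state)
}

#' Equilibrate the nutrient fields (initial regime)
#'
#' Runs the simulation with cells metabolizing but not moving, growing,
#' dividing, dying, or mutating, and all vessels held active, until the
#' summed-field relative change over 100 MCS is below 5 percent for glucose
#' and oxygen. All cells are fully respiratory during the regime, so no
#' lactate is produced; hypoxia is recomputed once on release.
#'
#' @param state A \code{cpm_state}.
#' @param max_mcs Abort with an error if not converged within this horizon.
#' @param window,tol Convergence window (MCS) and relative tolerance.
#' @return The state, invisibly, with \code{t} reset to 0 for the
#'   production run.
#' @export
equilibrate_initial_regime <- function(state, max_mcs = 20000,
                                       window = 100, tol = 0.05) {
  state$frozen <- TRUE
  saved_active <- state$vessel_active
  state$vessel_active <- rep(TRUE, length(state$vessel_ids))
  prev_g <- state$g; prev_o2 <- state$o2
  elapsed <- 0
  converged <- FALSE
  while (elapsed < max_mcs) {
    run_mcs(state, window)
    elapsed <- elapsed + window
    ok_g <- sum(abs(state$g - prev_g)) < tol * sum(prev_g)
    ok_o2 <- sum(abs(state$o2 - prev_o2)) < tol * sum(prev_o2)
    if (ok_g && ok_o2) { converged <- TRUE; break }
    prev_g <- state$g; prev_o2 <- state$o2
  }
  if (!converged) {
    stop("equilibrate_initial_regime(): no convergence within ", max_mcs,
         " MCS (relative change g = ",
         signif(sum(abs(state$g - prev_g)) / max(sum(prev_g), 1e-12), 3),
         ", o2 = ",
         signif(sum(abs(state$o2 - prev_o2)) / max(sum(prev_o2), 1e-12), 3),
         ")")
  }
  state$frozen <- FALSE
  state$vessel_active <- saved_active
  ids <- live_cells(state)
  if (length(ids)) {
    m <- state$last_metabolism
    state$h[ids] <- update_hypoxia(m[ids, "mean_o2"], state$zeta[ids],
                                   state$pheno[ids, "kappa_h"],
                                   state$pheno[ids, "kappa_z"],
                                   state$params$met$n_h, state$params$met$n_z)
  }
  state$t <- 0L
  invisible(state)
}
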