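#' Experiment configuration
#'
#' Validated bundle of everything a run needs: lattice dimensions, horizon,
#' seed, mutation rate, vessel schedule and layout, snapshot interval, and
#' the per-module parameter blocks. The full-scale published setup is a
#' 200 x 200 lattice (40 x 40 cells of 25 sites) with four vessels in square
#' formation run for 1e5 MCS; the default here is the scaled-down test
#' profile (100 x 100), with the full profile available via
#' \code{width = height = 200}.
#'
#' @param width,height Lattice dimensions (sites).
#' @param mcs Simulation horizon (MCS).
#' @param seed Integer RNG seed recorded in run metadata.
#' @param mutation_rate Global per-parameter mutation probability.
#' @param schedule A \code{\link{vessel_schedule}}.
#' @param vessel_layout \code{"square"} (four vessels at the lattice
#'   quarter-points) or \code{"random"} (\code{n_vessels} non-overlapping
#'   random placements).
#' @param n_vessels Number of vessels for the random layout.
#' @param vessel_radius Vessel disc radius (sites).
#' @param cell_size Initial cell edge (sites); cells start as
#'   \code{cell_size x cell_size} blocks with volume and target volume
#'   \code{cell_size^2}.
#' @param snapshot_interval Record a population snapshot every this many
#'   MCS (0 = none).
#' @param cpm,met,growth,fields Parameter blocks (see
#'   \code{\link{cpm_params}}, \code{\link{metabolic_params}},
#'   \code{\link{growth_params}}, \code{\link{field_params}}).
#' @param equilibrate Run the initial regime before the production run?
#' @param equilibrate_max_mcs Cap for the initial regime.
#' @param preset Optional preset tag (metadata only).
#' @return List of class \code{experiment_config}.
#' @export
experiment_config <- function(width = 100, height = 100, mcs = 1000,
                              seed = 1L, mutation_rate = 0.1,
                              schedule = vessel_schedule("constant", p0 = 0.5),
                              vessel_layout = c("square", "random"),
                              n_vessels = 4, vessel_radius = 3,
                              cell_size = 5, snapshot_interval = 100,
                              cpm = cpm_params(), met = metabolic_params(),
                              growth = growth_params(),
                              fields = field_params(),
                              equilibrate = TRUE,
                              equilibrate_max_mcs = 20000,
                              preset = "custom") {
  vessel_layout <- match.arg(vessel_layout)
  stopifnot(width >= 4 * cell_size, height >= 4 * cell_size,
            mcs >= 0, n_vessels >= 1, vessel_radius >= 1, cell_size >= 2,
            mutation_rate >= 0, mutation_rate <= 1)
  if (width * height < 4 * cell_size^2) {
    stop("experiment_config(): lattice too small for the requested cells")
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    mcs = as.integer(mcs), seed = as.integer(seed),
    mutation_rate = mutation_rate, schedule = schedule,
    vessel_layout = vessel_layout, n_vessels = as.integer(n_vessels),
    vessel_radius = vessel_radius, cell_size = as.integer(cell_size),
    snapshot_interval = as.integer(snapshot_interval),
    cpm = cpm, met = met, growth = growth, fields = fields,
    equilibrate = equilibrate,
    equilibrate_max_mcs = equilibrate_max_mcs,
    preset = preset
  ), class = "experiment_config")
}

#' Experiment presets mirroring the published scenarios
#'
#' \describe{
#'   \item{homeostasis}{No mutation, stable vessels (P = 0.5): the healthy
#'     reference tissue.}
#'   \item{mutating}{All cells mutate (rate settable, default 0.1) with
#'     stable vessels: the staged tumor progression scenario.}
#'   \item{single_mutant}{As homeostasis, but one cell (near or far from a
#'     vessel, see \code{position}) is allowed to mutate.}
#'   \item{tortuosity}{Constant low blocking probability (set \code{p}).}
#'   \item{progressive}{Geometric in-time schedule P(t) = 0.5 *
#'     0.999876^t floored at 0.001.}
#'   \item{feedback}{Density feedback P(rho) = 0.499 rho + 0.001.}
#'   \item{random_vessels}{As mutating, with randomly scattered vessels.}
#' }
#'
#' @param name Preset name.
#' @param mutation_rate,p Overridable knobs for the relevant presets.
#' @param position For \code{single_mutant}: \code{"near"} or \code{"far"}.
#' @param ... Passed on to \code{\link{experiment_config}}.
#' @return An \code{experiment_config}.
#' @export
preset_config <- function(name = c("homeostasis", "mutating",
                                   "single_mutant", "tortuosity",
                                   "progressive", "feedback",
                                   "random_vessels"),
                          mutation_rate = 0.1, p = 0.5,
                          position = c("near", "far"), ...) {
  name <- match.arg(name)
  position <- match.arg(position)
  base <- switch(name,
    homeostasis = list(mutation_rate = 0,
                       schedule = vessel_schedule("constant", p0 = 0.5)),
    mutating = list(mutation_rate = mutation_rate,
                    schedule = vessel_schedule("constant", p0 = 0.5)),
    single_mutant = list(mutation_rate = mutation_rate,
                         schedule = vessel_schedule("constant", p0 = 0.5)),
    tortuosity = list(mutation_rate = mutation_rate,
                      schedule = vessel_schedule("constant", p0 = p)),
    progressive = list(mutation_rate = mutation_rate,
                       schedule = vessel_schedule("geometric", p0 = 0.5,
                                                  r = 0.999876,
                                                  p_floor = 0.001)),
    feedback = list(mutation_rate = mutation_rate,
                    schedule = vessel_schedule("density_feedback")),
    random_vessels = list(mutation_rate = mutation_rate,
                          schedule = vessel_schedule("constant", p0 = 0.5),
                          vessel_layout = "random")
  )
  cfg <- do.call(experiment_config, modifyList(base, list(...)))
  cfg$preset <- name
  cfg$single_mutant_position <- if (name == "single_mutant") position else NA
  cfg
}

# Disc of sites (2-col matrix) around a center, periodic.
disc_sites <- function(cx, cy, r, w, h) {
  xs <- (cx - r):(cx + r); ys <- (cy - r):(cy + r)
  gridc <- expand.grid(x = xs, y = ys)
  keep <- (gridc$x - cx)^2 + (gridc$y - cy)^2 <= r^2
  cbind(((gridc$x[keep] - 1) %% w) + 1L, ((gridc$y[keep] - 1) %% h) + 1L)
}

#' Build the initial simulation state
#'
#' Tiles the lattice with \code{cell_size}-square cells (volume = target
#' volume = \code{cell_size^2} sites), carves out the vessel discs (four in
#' square formation at the lattice quarter-points, or random placements),
#' assigns every cell the common initial phenotype, applies one mutation
#' pass per cell to seed heterogeneity, and (by default) runs the
#' initial-regime field equilibration.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param initial_fields Optional list with matrices \code{g, o2, l} to seed
#'   the fields before the initial regime. The default (\code{"warm"})
#'   seeds glucose and oxygen at vessel level (1) and lactate at 0 — a
#'   synthetic stand-in for the pre-generated near-equilibrium
#'   distributions used to expedite equilibration; pass
#'   \code{list(g = 0, o2 = 0, l = 0)} to equilibrate from empty fields.
#' @param set_seed Seed the RNG from \code{config$seed} (default TRUE).
#' @return A \code{cpm_state} ready for \code{\link{run_mcs}}.
#' @export
build_initial_state <- function(config, initial_fields = "warm",
                                set_seed = TRUE) {
  if (set_seed) set.seed(config$seed)
  mut <- mutation_spec(rate = config$mutation_rate)
  st <- new_cpm_state(config$width, config$height,
                      cpm = config$cpm, met = config$met,
                      growth = config$growth, fields = config$fields,
                      mut = mut, schedule = config$schedule)
  w <- config$width; h <- config$height; cs <- config$cell_size

  # vessel discs first (their sites are never overwritten)
  centers <- if (config$vessel_layout == "square") {
    rw <- round(w / 4); rh <- round(h / 4)
    cbind(c(rw, 3 * rw, rw, 3 * rw), c(rh, rh, 3 * rh, 3 * rh))
  } else {
    n <- config$n_vessels
    found <- matrix(numeric(0), ncol = 2)
    guard <- 0
    while (nrow(found) < n && guard < 1000) {
      cand <- c(sample.int(w, 1), sample.int(h, 1))
      dmin <- if (nrow(found)) {
        dx <- pmin(abs(found[, 1] - cand[1]), w - abs(found[, 1] - cand[1]))
        dy <- pmin(abs(found[, 2] - cand[2]), h - abs(found[, 2] - cand[2]))
        min(sqrt(dx^2 + dy^2))
      } else Inf
      if (dmin > 2.5 * config$vessel_radius) found <- rbind(found, cand)
      guard <- guard + 1
    }
    if (nrow(found) < n) stop("build_initial_state(): could not place vessels")
    found
  }
  ph0 <- initial_phenotype(mut)
  for (k in seq_len(nrow(centers))) {
    sites <- disc_sites(centers[k, 1], centers[k, 2], config$vessel_radius,
                        w, h)
    id <- add_cell_record(st, 2L, ph0, v_t = nrow(sites))
    paint_sites(st, id, sites)
    st$vessel_ids <- c(st$vessel_ids, id)
    st$vessel_sites[[length(st$vessel_sites) + 1L]] <-
      (sites[, 1] - 1L) + w * (sites[, 2] - 1L)
  }
  st$n_ec_sites <- sum(st$V[st$vessel_ids])
  st$vessel_active <- rep(TRUE, length(st$vessel_ids))

  # confluent monolayer of cs x cs cells on the remaining sites
  nx <- w %/% cs; ny <- h %/% cs
  for (by in seq_len(ny)) {
    for (bx in seq_len(nx)) {
      xs <- ((bx - 1) * cs + 1):(bx * cs)
      ys <- ((by - 1) * cs + 1):(by * cs)
      blk <- as.matrix(expand.grid(x = xs, y = ys))
      blk <- blk[st$grid[blk] == 0L, , drop = FALSE]
      if (nrow(blk) == 0) next
      id <- add_cell_record(st, 1L, ph0, v_t = cs^2)
      paint_sites(st, id, blk)
    }
  }

  # initial heterogeneity: one mutation pass for every cell
  cells <- live_cells(st)
  if (config$mutation_rate > 0 && length(cells)) {
    if (identical(config$preset, "single_mutant")) {
      cent <- cpp_centroids(st$grid, length(st$cell_type))
      vx <- centers[1, 1]; vy <- centers[1, 2]
      dx <- pmin(abs(cent[cells, 1] - vx), w - abs(cent[cells, 1] - vx))
      dy <- pmin(abs(cent[cells, 2] - vy), h - abs(cent[cells, 2] - vy))
      d <- sqrt(dx^2 + dy^2)
      eligible <- cells[d > config$vessel_radius + cs]
      pick <- if (identical(config$single_mutant_position, "far")) {
        eligible[which.max(d[match(eligible, cells)])]
      } else {
        eligible[which.min(d[match(eligible, cells)])]
      }
      # only the marked lineage can mutate; the flag is heritable
      st$mutable[cells] <- FALSE
      st$mutable[pick] <- TRUE
      st$pheno[pick, ] <- mutate_phenotype(st$pheno[pick, ], st$params$mut)
      st$mutant_id <- pick
    } else {
      st$pheno[cells, ] <- mutate_phenotype_matrix(
        st$pheno[cells, , drop = FALSE], st$params$mut)
    }
  }

  if (identical(initial_fields, "warm")) {
    st$g[] <- 1; st$o2[] <- 1; st$lac[] <- 0
  } else if (!is.null(initial_fields)) {
    st$g[] <- initial_fields$g
    st$o2[] <- initial_fields$o2
    st$lac[] <- initial_fields$l
  }
  apply_vessel_boundary(st)
  if (config$equilibrate) {
    equilibrate_initial_regime(st, max_mcs = config$equilibrate_max_mcs)
  }
  st
}

#' Run a configured experiment
#'
#' Builds the initial state (including the initial-regime equilibration),
#' runs the MCS loop to the horizon while recording the time series of
#' observables every MCS-decade-friendly interval and population snapshots
#' at the configured interval, and returns the output bundle.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param observable_interval Record observables every this many MCS.
#' @param verbose Print a progress line every 1000 MCS.
#' @param state Optional pre-built state (skips initialization; the seed is
#'   not reset).
#' @return List of class \code{experiment_result}: \code{config},
#'   \code{observables} (data frame), \code{snapshots} (list of data
#'   frames), \code{lineage} (data frame), \code{final_state}, and
#'   \code{metadata}.
#' @export
run_experiment <- function(config, observable_interval = 10,
                           verbose = FALSE, state = NULL) {
  if (is.null(state)) state <- build_initial_state(config)
  obs <- list(compute_observables(state))
  snaps <- list()
  if (config$snapshot_interval > 0) snaps[["0"]] <- population_snapshot(state)
  for (tt in seq_len(config$mcs)) {
    run_mcs(state)
    if (tt %% observable_interval == 0 || tt == config$mcs) {
      obs[[length(obs) + 1L]] <- compute_observables(state)
    }
    if (config$snapshot_interval > 0 && tt %% config$snapshot_interval == 0) {
      snaps[[as.character(tt)]] <- population_snapshot(state)
    }
    if (verbose && tt %% 1000 == 0) {
      o <- obs[[length(obs)]]
      message(sprintf("MCS %d: %d cells, coverage %.2f, g %.0f o2 %.0f l %.0f",
                      tt, o$n_cells, o$coverage, o$total_g, o$total_o2,
                      o$total_l))
    }
    if (n_cells(state) == 0) break   # extinction
  }
  lineage <- lineage_log(state)
  structure(list(
    config = config,
    observables = do.call(rbind, obs),
    snapshots = snaps,
    lineage = lineage,
    final_state = state,
    metadata = list(seed = config$seed, preset = config$preset,
                    package_version = as.character(utils::packageVersion("pottsevo")),
                    finished_t = state$t)
  ), class = "experiment_result")
}

#' Write an experiment result bundle as plain-text files
#'
#' Tidy CSVs: \code{observables.csv}, \code{snapshot_<t>.csv},
#' \code{lineage.csv}, final field grids, final cell configuration
#' (PIF-like), and \code{metadata.txt}.
#'
#' @param result An \code{experiment_result}.
#' @param outdir Output directory (created if missing).
#' @return \code{outdir}, invisibly.
#' @export
write_experiment <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$observables, file.path(outdir, "observables.csv"),
            row.names = FALSE)
  for (nm in names(result$snapshots)) {
    write.csv(result$snapshots[[nm]],
              file.path(outdir, paste0("snapshot_", nm, ".csv")),
              row.names = FALSE)
  }
  write.csv(result$lineage, file.path(outdir, "lineage.csv"),
            row.names = FALSE)
  st <- result$final_state
  write_grid_csv(st$g, file.path(outdir, "field_glucose.csv"))
  write_grid_csv(st$o2, file.path(outdir, "field_oxygen.csv"))
  write_grid_csv(st$lac, file.path(outdir, "field_lactate.csv"))
  write_pif(st, file.path(outdir, "cells.pif"))
  md <- result$metadata
  writeLines(c(paste0("seed: ", md$seed), paste0("preset: ", md$preset),
               paste0("package_version: ", md$package_version),
               paste0("finished_t: ", md$finished_t)),
             file.path(outdir, "metadata.txt"))
  invisible(outdir)
}
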