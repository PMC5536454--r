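# Simulation state: an environment holding the cell lattice, per-cell
# records, nutrient fields and vessel bookkeeping. Matrices handed to the
# C++ engine are modified in place; treat a cpm_state as a mutable handle.

new_cpm_state <- function(width, height,
                          cpm = cpm_params(), met = metabolic_params(),
                          growth = growth_params(), fields = field_params(),
                          mut = mutation_spec(),
                          schedule = vessel_schedule("constant", p0 = 0.5)) {
  st <- new.env(parent = emptyenv())
  st$width <- as.integer(width)
  st$height <- as.integer(height)
  st$grid <- matrix(0L, nrow = width, ncol = height)
  st$cell_type <- integer(0)       # 0 none, 1 cell, 2 vessel
  st$V <- integer(0)
  st$VT <- numeric(0)
  st$h <- numeric(0)
  st$zeta <- numeric(0)
  st$u_g <- numeric(0)
  st$u_o2 <- numeric(0)
  st$e_net <- numeric(0)
  st$generation <- integer(0)
  st$apoptotic <- logical(0)
  st$mutable <- logical(0)
  st$pheno <- matrix(numeric(0), ncol = 10,
                     dimnames = list(NULL, phenotype_names()))
  st$g <- matrix(0, width, height)
  st$o2 <- matrix(0, width, height)
  st$lac <- matrix(0, width, height)
  st$n_ids <- 0L                   # high-water mark of allocated records
  st$free_ids <- integer(0)        # cleared slots available for reuse
  st$lineage_mat <- matrix(0L, 0, 3,
                           dimnames = list(NULL, c("t", "parent", "daughter")))
  st$lineage_n <- 0L
  st$vessel_ids <- integer(0)
  st$vessel_active <- logical(0)
  st$vessel_sites <- list()        # per vessel: 0-based linear site indices
  st$schedule <- schedule
  st$params <- list(cpm = cpm, met = met, growth = growth, fields = fields,
                    mut = mut)
  st$t <- 0L
  st$frozen <- FALSE               # initial-regime mode: fields+metabolism only
  st$n_ec_sites <- 0L
  class(st) <- "cpm_state"
  st
}

# Grow the per-cell arrays geometrically so appends stay amortized O(1).
ensure_capacity <- function(state, n) {
  cap <- length(state$cell_type)
  if (n <= cap) return(invisible(state))
  newcap <- max(64L, 2L * cap, n)
  pad_i <- rep(0L, newcap - cap)
  pad_d <- rep(0, newcap - cap)
  state$cell_type <- c(state$cell_type, pad_i)
  state$mutable <- c(state$mutable, rep(FALSE, newcap - cap))
  state$V <- c(state$V, pad_i)
  state$VT <- c(state$VT, pad_d)
  state$h <- c(state$h, pad_d)
  state$zeta <- c(state$zeta, pad_d)
  state$u_g <- c(state$u_g, pad_d)
  state$u_o2 <- c(state$u_o2, pad_d)
  state$e_net <- c(state$e_net, pad_d)
  state$generation <- c(state$generation, pad_i)
  state$apoptotic <- c(state$apoptotic, rep(FALSE, newcap - cap))
  ph <- matrix(0, newcap, 10, dimnames = list(NULL, phenotype_names()))
  if (cap) ph[seq_len(cap), ] <- state$pheno
  state$pheno <- ph
  invisible(state)
}

# Append one cell record (reusing a cleared slot when available);
# returns its id.
add_cell_record <- function(state, type, phenotype, v_t = 25,
                            generation = 0L, mutable = TRUE) {
  nf <- length(state$free_ids)
  if (nf > 0L) {
    id <- state$free_ids[nf]
    state$free_ids <- state$free_ids[-nf]
  } else {
    id <- state$n_ids + 1L
    ensure_capacity(state, id)
    state$n_ids <- id
  }
  state$cell_type[id] <- as.integer(type)
  state$mutable[id] <- mutable
  state$V[id] <- 0L
  state$VT[id] <- v_t
  state$h[id] <- 0
  state$zeta[id] <- 0
  state$u_g[id] <- 0
  state$u_o2[id] <- 0
  state$e_net[id] <- 0
  state$generation[id] <- as.integer(generation)
  state$apoptotic[id] <- FALSE
  state$pheno[id, ] <- phenotype
  id
}

#' Division (lineage) log of a state
#'
#' @param state A \code{cpm_state}.
#' @return Data frame with one row per division: \code{t}, \code{parent},
#'   \code{daughter}.
#' @export
lineage_log <- function(state) {
  as.data.frame(state$lineage_mat[seq_len(state$lineage_n), , drop = FALSE])
}

# Paint sites (2-column 1-based coordinate matrix) with a cell id.
paint_sites <- function(state, id, sites) {
  state$grid[sites] <- id
  state$V[id] <- state$V[id] + nrow(sites)
  invisible(id)
}

live_cells <- function(state) which(state$cell_type == 1L)

#' Number of live tissue cells
#' @param state A \code{cpm_state}.
#' @return Integer count.
#' @export
n_cells <- function(state) sum(state$cell_type == 1L)

#' Tissue coverage
#'
#' Fraction of non-vessel lattice occupied by live tissue cells, in [0, 1].
#' The denominator excludes the immobile vessel scaffold.
#'
#' @param state A \code{cpm_state}.
#' @return Numeric scalar.
#' @export
coverage <- function(state) {
  denom <- state$width * state$height - state$n_ec_sites
  if (denom <= 0) return(0)
  sum(state$V[state$cell_type == 1L]) / denom
}

#' @export
print.cpm_state <- function(x, ...) {
  cat("<cpm_state> ", x$width, "x", x$height, " lattice, t = ", x$t,
      " MCS\n  live cells: ", n_cells(x), ", vessels: ",
      length(x$vessel_ids), " (", sum(x$vessel_active), " active)",
      "\n  coverage: ", round(coverage(x), 3), "\n", sep = "")
  invisible(x)
}

#' Per-cell snapshot table
#'
#' One row per live tissue cell: id, type, volume, target volume, the ten
#' phenotype parameters, hypoxia, ROS, uptakes, generation, and periodic
#' centroid coordinates. This is the input to the phenotype-space analysis.
#'
#' @param state A \code{cpm_state}.
#' @return Data frame.
#' @export
population_snapshot <- function(state) {
  ids <- live_cells(state)
  cent <- if (length(state$cell_type)) {
    cpp_centroids(state$grid, length(state$cell_type))
  } else matrix(numeric(0), ncol = 2)
  ph <- state$pheno[ids, , drop = FALSE]
  colnames(ph) <- phenotype_names()
  cbind(
    data.frame(id = ids, type = "c",
               t = rep(state$t, length(ids)),
               volume = state$V[ids], target_volume = state$VT[ids]),
    as.data.frame(ph),
    data.frame(h = state$h[ids], zeta = state$zeta[ids],
               u_g = state$u_g[ids], u_o2 = state$u_o2[ids],
               generation = state$generation[ids],
               centroid_x = cent[ids, 1], centroid_y = cent[ids, 2])
  )
}

#' Summary observables of the current state
#'
#' Cell count, mean intracellular pressure (target volume minus volume),
#' tissue coverage, field totals, and population means of the metabolic
#' readouts and the combined chemotaxis parameter.
#'
#' @param state A \code{cpm_state}.
#' @return One-row data frame.
#' @export
compute_observables <- function(state) {
  ids <- live_cells(state)
  ph <- state$pheno
  data.frame(
    t = state$t,
    n_cells = length(ids),
    mean_pressure = if (length(ids)) mean(state$VT[ids] - state$V[ids]) else NA_real_,
    coverage = coverage(state),
    total_g = sum(state$g), total_o2 = sum(state$o2), total_l = sum(state$lac),
    mean_h = if (length(ids)) mean(state$h[ids]) else NA_real_,
    mean_zeta = if (length(ids)) mean(state$zeta[ids]) else NA_real_,
    mean_u_g = if (length(ids)) mean(state$u_g[ids]) else NA_real_,
    mean_u_o2 = if (length(ids)) mean(state$u_o2[ids]) else NA_real_,
    mean_n0 = if (length(ids)) mean(ph[ids, "N0"]) else NA_real_,
    mean_chi_combined = if (length(ids)) {
      mean(combined_chemotaxis(ph[ids, "chi_g"], ph[ids, "chi_o2"],
                               ph[ids, "chi_l"]))
    } else NA_real_,
    vessels_active = sum(state$vessel_active)
  )
}

# ---- plain-text interchange formats ----------------------------------------

#' Write/read a cell configuration in a PIF-like text format
#'
#' One line per horizontal run of sites: \code{cell_id type x1 x2 y y}
#' (1-based inclusive ranges), whitespace-separated — the usual plain-text
#' pixel-initialization format of lattice-based cell models.
#'
#' @param state A \code{cpm_state} (for writing).
#' @param path File path.
#' @return \code{write_pif}: the path, invisibly. \code{read_pif}: a data
#'   frame with columns \code{cell_id, type, x1, x2, y1, y2}.
#' @export
write_pif <- function(state, path) {
  rows <- list()
  tn <- c("c", "EC")
  for (y in seq_len(state$height)) {
    col <- state$grid[, y]
    r <- rle(col)
    x2 <- cumsum(r$lengths)
    x1 <- x2 - r$lengths + 1L
    keep <- r$values != 0L
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = r$values[keep],
        type = tn[state$cell_type[r$values[keep]]],
        x1 = x1[keep], x2 = x2[keep], y1 = y, y2 = y)
    }
  }
  out <- do.call(rbind, rows)
  write.table(out, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pif
#' @export
read_pif <- function(path) {
  read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Write/read a labeled grid or concentration field as CSV
#'
#' Plain 2D array serialization (no headers): rows are x, columns y.
#'
#' @param m Matrix to write.
#' @param path File path.
#' @param integer Read back as integer (for label grids)?
#' @return \code{write_grid_csv}: the path, invisibly;
#'   \code{read_grid_csv}: the matrix.
#' @export
write_grid_csv <- function(m, path) {
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path, integer = FALSE) {
  m <- as.matrix(read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  if (integer) storage.mode(m) <- "integer"
  m
}

#' Checkpoint a simulation state to disk and restore it
#'
#' Serializes the full mutable state (lattice, cell records, fields, vessel
#' states, clock) together with the current RNG state, so a restored run
#' reproduces the uninterrupted trajectory exactly.
#'
#' @param state A \code{cpm_state}.
#' @param path File path.
#' @return \code{save_state}: path, invisibly; \code{load_state}: a
#'   \code{cpm_state}.
#' @export
save_state <- function(state, path) {
  if (!exists(".Random.seed", globalenv())) runif(1)
  payload <- as.list.environment(state, all.names = TRUE)
  payload$.rng <- get(".Random.seed", globalenv())
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  payload <- readRDS(path)
  rng <- payload$.rng
  payload$.rng <- NULL
  st <- list2env(payload, new.env(parent = emptyenv()))
  class(st) <- "cpm_state"
  assign(".Random.seed", rng, globalenv())
  st
}
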