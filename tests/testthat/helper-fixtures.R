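# Fixture builders and independent oracles used across the suite.

# Bare state on a small lattice with no vessels and uniform fields.
make_bare_state <- function(width = 12, height = 12, g = 1, o2 = 1, l = 0,
                            cpm = cpm_params(), met = metabolic_params(),
                            growth = growth_params(),
                            fields = field_params(),
                            mut = mutation_spec(rate = 0)) {
  st <- pottsevo:::new_cpm_state(width, height, cpm = cpm, met = met,
                                 growth = growth, fields = fields, mut = mut)
  st$g[] <- g; st$o2[] <- o2; st$lac[] <- l
  st
}

# Add a rectangular cell; returns its id.
add_block_cell <- function(st, x1, x2, y1, y2, v_t = 25,
                           phenotype = initial_phenotype(), type = 1L) {
  id <- pottsevo:::add_cell_record(st, type, phenotype, v_t = v_t)
  sites <- as.matrix(expand.grid(x = x1:x2, y = y1:y2))
  pottsevo:::paint_sites(st, id, sites)
  id
}

# Random fragmented configuration: each site drawn from {0, 1..k} ids.
# Occasionally includes a vessel cell. Returns the state.
random_state <- function(width, height, k = 4, with_ec = FALSE,
                         common_vt = NULL) {
  st <- make_bare_state(width, height,
                        g = matrix(runif(width * height), width),
                        o2 = matrix(runif(width * height), width),
                        l = matrix(runif(width * height), width))
  spec <- mutation_spec()
  for (i in seq_len(k)) {
    ph <- stats::setNames(runif(10, spec$min, spec$max), spec$name)
    pottsevo:::add_cell_record(st, 1L, ph,
                               v_t = if (is.null(common_vt)) {
                                 runif(1, 5, 60)
                               } else common_vt)
  }
  st$grid[] <- sample(0:k, width * height, replace = TRUE)
  if (with_ec) {
    ec <- pottsevo:::add_cell_record(st, 2L, initial_phenotype(), v_t = 4)
    sites <- as.matrix(expand.grid(x = 1:2, y = 1:2))
    st$grid[sites] <- ec
    st$vessel_ids <- ec
    st$vessel_active <- TRUE
    st$vessel_sites <- list((sites[, 1] - 1L) + width * (sites[, 2] - 1L))
    st$n_ec_sites <- 4L
  }
  st$V <- tabulate(st$grid[st$grid > 0], nbins = length(st$cell_type))
  st
}

# ---- independent brute-force Hamiltonian oracle ---------------------------
# Plain-R re-derivation of the goal function (volume + adhesion terms) from
# its definition; deliberately independent of the engine's incremental path.

oracle_jeff <- function(a, b, ctype, pheno, p) {
  ta <- if (a == 0) "m" else c("c", "EC")[ctype[a]]
  tb <- if (b == 0) "m" else c("c", "EC")[ctype[b]]
  key <- paste(sort(c(ta, tb)), collapse = "-")
  if (key == "c-c") {
    p$j_cc - min(pheno[a, "rho_cam"], pheno[b, "rho_cam"])
  } else if (key == "EC-c") {
    rc <- if (ta == "c") pheno[a, "rho_cam"] else pheno[b, "rho_cam"]
    p$j_cec - min(rc, p$rho_cam_ec)
  } else if (key == "c-m") {
    rm_ <- if (ta == "c") pheno[a, "rho_mam"] else pheno[b, "rho_mam"]
    p$j_cm - min(rm_, p$rho_mas_m)
  } else if (key == "EC-m") p$j_ecm
  else if (key == "EC-EC") p$j_ecec
  else 0
}

oracle_hamiltonian <- function(st) {
  grid <- st$grid; ctype <- st$cell_type; pheno <- st$pheno
  colnames(pheno) <- phenotype_names()
  p <- st$params$cpm
  W <- nrow(grid); H <- ncol(grid)
  ids <- which(ctype == 1L)
  V <- tabulate(grid[grid > 0], nbins = length(ctype))
  hv <- sum(pheno[ids, "lambda_v"] / st$VT[ids] * (V[ids] - st$VT[ids])^2)
  # unordered neighbor pairs: half the Moore offsets cover each pair once
  offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  if (p$neighborhood == "von_neumann") offs <- offs[1:2, , drop = FALSE]
  ha <- 0
  for (k in seq_len(nrow(offs))) {
    sx <- ((seq_len(W) - 1 + offs[k, 1]) %% W) + 1
    sy <- ((seq_len(H) - 1 + offs[k, 2]) %% H) + 1
    shifted <- grid[sx, sy]
    for (idx in which(grid != shifted)) {
      ha <- ha + oracle_jeff(grid[idx], shifted[idx], ctype, pheno, p)
    }
  }
  hv + ha
}
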