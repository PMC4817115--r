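#' Specification for a synthetic two-protomer dimer trajectory
#'
#' The generator emulates the statistical structure of an MD trajectory of a
#' homodimeric chaperone: two chains (protomers A and B), each built from
#' rigid domain blocks (by default NTD, MD, CTD stacked along the protomer
#' long axis), with controllable per-atom thermal jitter, controllable
#' inter-domain distance fluctuation for chosen domain pairs, an imposed
#' bending distortion of protomer B's N+M region, and an imposed NTD-NTD
#' separation shift. Every imposed quantity is returned as ground truth so
#' downstream estimators can be validated against construction.
#'
#' @param atoms_per_domain Atoms per rigid domain block; a multiple of 4
#'   (each group of 4 is one synthetic residue named N/CA/C/O so backbone and
#'   c-alpha filters work unmodified). Default 8 (2 residues per domain).
#' @param domains_per_protomer Rigid blocks per chain; default 3 (NTD, MD,
#'   CTD). Other counts get domains named `D1`, `D2`, ...
#' @param n_frames Number of frames; default 200.
#' @param positional_noise_sigma Isotropic per-atom Gaussian jitter, nm.
#'   Default 0.02 nm (about the thermal positional spread of a backbone atom
#'   in a folded protein).
#' @param interdomain_sigma `NULL`, or a data frame with columns `chain_a`,
#'   `domain_a`, `chain_b`, `domain_b`, `sigma` (nm): each row adds a scalar
#'   Gaussian fluctuation of that pair's centre-centre distance with the
#'   stated standard deviation (applied to the second block along the fixed
#'   pair axis, so the centre-distance variance equals `sigma^2` exactly).
#'   Pairs should not share a block, otherwise contributions mix.
#' @param protomer_b_twist Distortion angle (degrees) reached by protomer B's
#'   N+M blocks at the final frame, growing linearly from 0. Implemented as a
#'   hinge rotation about an axis orthogonal to the N+M principal axis,
#'   anchored between the MD and CTD blocks, so the angle between the frame's
#'   N+M axis and the reference axis equals the schedule exactly in the
#'   noiseless limit. The CTD is untouched.
#' @param ntd_separation_drift Extra NTD-NTD distance (nm) imposed on the
#'   second half of the trajectory (a step at the midpoint, modelling two
#'   condition ensembles in one run; the distance-histogram peaks of the two
#'   halves are then separated by exactly this amount).
#' @param dt Frame spacing in ns (default 0.1).
#' @param seed Integer RNG seed; identical spec + seed gives identical output.
#'
#' @return A `dimer_sim_spec` list.
#' @export
dimer_sim_spec <- function(atoms_per_domain = 8, domains_per_protomer = 3,
                           n_frames = 200, positional_noise_sigma = 0.02,
                           interdomain_sigma = NULL, protomer_b_twist = 0,
                           ntd_separation_drift = 0, dt = 0.1, seed = 1) {
  assert_scalar_number(atoms_per_domain, "atoms_per_domain", lower = 4)
  if (atoms_per_domain %% 4 != 0) {
    stop_allodyn("`atoms_per_domain` must be a multiple of 4 (4 atoms per synthetic residue)",
                 class = "allodyn_spec_error")
  }
  assert_scalar_number(domains_per_protomer, "domains_per_protomer", lower = 1)
  assert_scalar_number(n_frames, "n_frames", lower = 2)
  assert_scalar_number(positional_noise_sigma, "positional_noise_sigma", lower = 0)
  assert_scalar_number(protomer_b_twist, "protomer_b_twist")
  assert_scalar_number(ntd_separation_drift, "ntd_separation_drift")
  assert_scalar_number(seed, "seed")
  if (!is.null(interdomain_sigma)) {
    interdomain_sigma <- as_tibble(interdomain_sigma)
    req <- c("chain_a", "domain_a", "chain_b", "domain_b", "sigma")
    if (!all(req %in% names(interdomain_sigma)) || any(interdomain_sigma$sigma < 0)) {
      stop_allodyn("`interdomain_sigma` needs columns chain_a, domain_a, chain_b, domain_b, sigma >= 0",
                   class = "allodyn_spec_error")
    }
  }
  structure(list(
    atoms_per_domain = as.integer(atoms_per_domain),
    domains_per_protomer = as.integer(domains_per_protomer),
    n_frames = as.integer(n_frames),
    positional_noise_sigma = positional_noise_sigma,
    interdomain_sigma = interdomain_sigma,
    protomer_b_twist = protomer_b_twist,
    ntd_separation_drift = ntd_separation_drift,
    dt = dt, seed = as.integer(seed)
  ), class = "dimer_sim_spec")
}

domain_names <- function(k) {
  if (k == 3L) c("NTD", "MD", "CTD") else paste0("D", seq_len(k))
}

# deterministic prolate template: atoms on a loose helix along z so every
# block (and any stack of blocks) has a well-separated largest gyration axis
domain_template <- function(n_atoms) {
  k <- seq_len(n_atoms) - 1
  cbind(0.12 * cos(1.7 * k), 0.12 * sin(1.7 * k), 0.18 * k)
}

rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
  diag(3) * cos(th) + sin(th) * ux + (1 - cos(th)) * tcrossprod(u)
}

#' Generate a synthetic dimer trajectory with known ground truth
#'
#' @param spec A [dimer_sim_spec()].
#' @param replica_id Replica label for the returned ensemble.
#' @return A list with elements
#'   * `ensemble`: a [trajectory_ensemble()] (chains A and B),
#'   * `reference`: the noiseless, undistorted single-frame ensemble,
#'   * `truth`: ground-truth record (domain map, per-chain-domain residue
#'     selections, expected centre- and CA-pair distance variances for each
#'     configured pair, the twist schedule in degrees, the separation-shift
#'     schedule in nm).
#' @export
generate_dimer_trajectory <- function(spec, replica_id = "rep1") {
  stopifnot(inherits(spec, "dimer_sim_spec"))
  nd <- spec$domains_per_protomer
  apd <- spec$atoms_per_domain
  n_res_dom <- apd %/% 4L
  dnames <- domain_names(nd)
  # NTD on top, CTD at the bottom; protomers offset along x
  z_centers <- rev(seq_len(nd) - 1) * 3.0
  x_chain <- c(A = -2.0, B = 2.0)
  template <- domain_template(apd)
  template <- sweep(template, 2, colMeans(template))  # centre the block

  atom_names <- rep(c("N", "CA", "C", "O"), n_res_dom)
  elements <- rep(c("N", "C", "C", "O"), n_res_dom)

  top <- list(); base_centers <- list(); res_map <- list()
  res_counter <- 0L
  for (ch in c("A", "B")) {
    res_counter <- 0L
    for (d in seq_len(nd)) {
      resids <- res_counter + rep(seq_len(n_res_dom), each = 4L)
      top[[paste(ch, d)]] <- tibble(
        chain_id = ch, residue_id = resids, residue_name = "GLY",
        atom_name = atom_names, element = elements
      )
      base_centers[[paste(ch, d)]] <- c(x_chain[[ch]], 0, z_centers[d])
      res_map[[paste(ch, d)]] <- tibble(
        chain_id = ch, domain = dnames[d], residue_id = unique(resids)
      )
      res_counter <- res_counter + n_res_dom
    }
  }
  topology <- dplyr::bind_rows(top)
  domain_map <- dplyr::bind_rows(res_map)
  block_rows <- lapply(seq_along(top), function(i) ((i - 1) * apd + 1):(i * apd))
  names(block_rows) <- names(top)

  frac <- if (spec$n_frames > 1) (seq_len(spec$n_frames) - 1) / (spec$n_frames - 1) else 0
  twist_schedule <- spec$protomer_b_twist * frac
  drift_schedule <- spec$ntd_separation_drift * as.numeric(frac >= 0.5)

  # hinge axis: component of x orthogonal to the CA-based N+M principal axis
  # of protomer B, so the imposed rotation tilts that axis by exactly the
  # scheduled angle (a rotation about an axis with a component along the axis
  # itself would tilt it by less)
  nm_rows <- unlist(block_rows[seq_len(max(nd - 1L, 1L))], use.names = FALSE) +
    nd * apd  # protomer B blocks come after protomer A's nd blocks
  hinge_axis <- local({
    ca_rows <- nm_rows[atom_names[(nm_rows - 1L) %% apd + 1L] == "CA"]
    base <- matrix(0, nrow(topology), 3)
    for (i in seq_along(block_rows)) {
      base[block_rows[[i]], ] <- sweep(template, 2, base_centers[[i]], `+`)
    }
    x <- base[ca_rows, , drop = FALSE]
    x <- sweep(x, 2, colMeans(x))
    v <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)$vectors[, 1]
    u <- c(1, 0, 0) - sum(c(1, 0, 0) * v) * v
    if (sqrt(sum(u^2)) < 1e-8) u <- c(0, 1, 0) - sum(c(0, 1, 0) * v) * v
    u / sqrt(sum(u^2))
  })

  build_frame <- function(centers, twist_deg, drift, noise) {
    xyz <- matrix(0, nrow(topology), 3)
    # hinge pivot: between the two lowest blocks of protomer B (MD/CTD junction)
    pivot <- c(x_chain[["B"]], 0, if (nd > 1) mean(z_centers[(nd - 1):nd]) else 0)
    rot <- rotation_about(hinge_axis, twist_deg)
    for (key in names(block_rows)) {
      ch <- substr(key, 1, 1)
      d <- as.integer(substr(key, 3, 10))
      ctr <- centers[[key]]
      block <- sweep(template, 2, ctr, `+`)
      if (ch == "B" && d < nd && twist_deg != 0) {
        block <- sweep(sweep(block, 2, pivot) %*% t(rot), 2, pivot, `+`)
      }
      if (ch == "B" && d == 1L && drift != 0) {
        block[, 1] <- block[, 1] + drift
      }
      xyz[block_rows[[key]], ] <- block
    }
    if (noise > 0) xyz <- xyz + rnorm(length(xyz), sd = noise)
    xyz
  }

  pair_sigma <- spec$interdomain_sigma
  coords <- withr::with_seed(spec$seed, {
    arr <- array(0, dim = c(nrow(topology), 3, spec$n_frames))
    for (f in seq_len(spec$n_frames)) {
      centers <- base_centers
      if (!is.null(pair_sigma)) {
        for (r in seq_len(nrow(pair_sigma))) {
          ka <- paste(pair_sigma$chain_a[r], match(pair_sigma$domain_a[r], dnames))
          kb <- paste(pair_sigma$chain_b[r], match(pair_sigma$domain_b[r], dnames))
          u <- base_centers[[kb]] - base_centers[[ka]]
          u <- u / sqrt(sum(u^2))
          centers[[kb]] <- centers[[kb]] + rnorm(1, sd = pair_sigma$sigma[r]) * u
        }
      }
      arr[, , f] <- build_frame(centers, twist_schedule[f], drift_schedule[f],
                                spec$positional_noise_sigma)
    }
    arr
  })

  reference <- trajectory_ensemble(
    topology,
    array(build_frame(base_centers, 0, 0, 0), dim = c(nrow(topology), 3, 1)),
    times = 0, replica_id = "reference"
  )

  selections <- lapply(split(domain_map, paste(domain_map$chain_id, domain_map$domain)),
                       function(df) residue_selection(df[, c("chain_id", "residue_id")],
                                                      atom_filter = "c_alpha"))
  truth <- list(
    spec = spec,
    domain_map = domain_map,
    selections = selections,
    twist_schedule = tibble(frame = seq_len(spec$n_frames),
                            angle_deg = twist_schedule),
    drift_schedule = tibble(frame = seq_len(spec$n_frames),
                            extra_separation_nm = drift_schedule),
    pair_variance = if (is.null(pair_sigma)) NULL else
      dplyr::mutate(pair_sigma,
                    center_distance_variance = .data$sigma^2,
                    ca_pair_variance = .data$sigma^2 + 2 * spec$positional_noise_sigma^2)
  )

  list(
    ensemble = trajectory_ensemble(topology, coords,
                                   times = (seq_len(spec$n_frames) - 1) * spec$dt,
                                   replica_id = replica_id),
    reference = reference,
    truth = truth
  )
}

#' Specification for synthetic docking-score and activity tables
#'
#' Emulates the structure of an ensemble-docking experiment: per-compound
#' activities (ATP turnover rates) and per-compound, per-receptor best-pose
#' docking scores constructed so that the Pearson correlation between the
#' true per-compound mean ligand efficiency and activity equals
#' `target_correlation` exactly before noise; receptor-level score noise is
#' then added on top.
#'
#' @param n_compounds Number of compounds (>= 3).
#' @param n_receptors Number of receptor structures (default 10, the size of
#'   the DMRS ensemble).
#' @param target_correlation Desired Pearson correlation between true mean LE
#'   and activity, in \[-1, 1\].
#' @param score_noise_sigma SD of Gaussian noise added to each individual
#'   receptor score (kcal/mol), default 0.1.
#' @param heavy_atom_range Integer (min, max) heavy-atom counts; default
#'   c(20, 35), typical of fragment-grown allosteric ligands.
#' @param le_mean,le_sd Location/scale of the true mean-LE distribution
#'   (kcal/mol per heavy atom); defaults -0.26 and 0.03 match the observed
#'   spread of benzofuran-series ligand efficiencies.
#' @param activity_range Uniform range for activities (ATP turnover min^-1);
#'   default c(1, 4.2).
#' @param mode_label Ensemble mode tag stored on the score table.
#' @param seed Integer RNG seed.
#' @return A `score_sim_spec` list.
#' @export
score_sim_spec <- function(n_compounds = 6, n_receptors = 10,
                           target_correlation = -0.9, score_noise_sigma = 0.1,
                           heavy_atom_range = c(20, 35),
                           le_mean = -0.26, le_sd = 0.03,
                           activity_range = c(1, 4.2),
                           mode_label = "dmrs_atp_only", seed = 1) {
  assert_scalar_number(n_compounds, "n_compounds", lower = 1)
  if (n_compounds < 3) {
    stop_allodyn("need at least 3 compounds to impose a target correlation",
                 class = "allodyn_spec_error")
  }
  assert_scalar_number(n_receptors, "n_receptors", lower = 1)
  assert_scalar_number(target_correlation, "target_correlation", lower = -1, upper = 1)
  assert_scalar_number(score_noise_sigma, "score_noise_sigma", lower = 0)
  if (length(heavy_atom_range) != 2L || heavy_atom_range[1] < 1) {
    stop_allodyn("`heavy_atom_range` must be (min >= 1, max)", class = "allodyn_spec_error")
  }
  structure(list(
    n_compounds = as.integer(n_compounds), n_receptors = as.integer(n_receptors),
    target_correlation = target_correlation, score_noise_sigma = score_noise_sigma,
    heavy_atom_range = as.integer(heavy_atom_range),
    le_mean = le_mean, le_sd = le_sd, activity_range = activity_range,
    mode_label = mode_label, seed = as.integer(seed)
  ), class = "score_sim_spec")
}

#' Generate synthetic docking-score and activity tables
#'
#' @param spec A [score_sim_spec()].
#' @return A list with
#'   * `scores`: a dock-score table (see [dock_score_table()]),
#'   * `ligands`: tibble of `compound_id`, `heavy_atom_count`,
#'   * `activities`: tibble of `compound_id`, `atpase_rate`,
#'   * `truth`: the true per-compound mean LEs and the imposed correlation.
#' @export
generate_score_table <- function(spec) {
  stopifnot(inherits(spec, "score_sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_compounds
    id <- sprintf("C%02d", seq_len(n))
    act <- sort(runif(n, spec$activity_range[1], spec$activity_range[2]))
    heavy <- sample(seq(spec$heavy_atom_range[1], spec$heavy_atom_range[2]),
                    n, replace = TRUE)
    # exact-correlation construction: component along the standardized
    # activity plus an orthogonalized residual, mixed by the target r
    a_std <- as.vector(scale(act))
    z <- rnorm(n)
    z_res <- stats::residuals(stats::lm(z ~ a_std))
    z_std <- as.vector(scale(z_res))
    r <- spec$target_correlation
    le_true <- spec$le_mean + spec$le_sd * (r * a_std + sqrt(1 - r^2) * z_std)

    scores <- matrix(
      rep(le_true * heavy, spec$n_receptors) +
        rnorm(n * spec$n_receptors, sd = spec$score_noise_sigma),
      nrow = n
    )
    colnames(scores) <- sprintf("R%02d", seq_len(spec$n_receptors))
    score_tbl <- dock_score_table(
      dplyr::bind_cols(tibble(compound_id = id), as_tibble(scores)),
      mode_label = spec$mode_label
    )
    list(
      scores = score_tbl,
      ligands = tibble(compound_id = id, heavy_atom_count = heavy),
      activities = tibble(compound_id = id, atpase_rate = act),
      truth = list(true_mean_le = setNames(le_true, id),
                   target_correlation = r, spec = spec)
    )
  })
}

#' Write a synthetic simulation to disk
#'
#' Writes the trajectory as a multi-model PDB, the reference structure as a
#' single-model PDB, and the ground-truth record as a JSON sidecar.
#'
#' @param sim Result of [generate_dimer_trajectory()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dimer_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory(sim$ensemble, file.path(dir, "trajectory.pdb"))
  write_trajectory(sim$reference, file.path(dir, "reference.pdb"))
  truth <- sim$truth
  truth$selections <- NULL  # not JSON-serializable; reconstructable from domain_map
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
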