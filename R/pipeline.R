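#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end synthetic workflow, with defaults
#' matching the conventional analysis parameters: 0.25 equilibration
#' fraction, 0.6 nm contact cutoff, 0.2 nm cluster cutoff, 0.5 ns sampling
#' stride, 0.05 nm histogram bin width.
#'
#' @param out_dir Output directory for stage results and the manifest.
#' @param stages Stages to run, a subset of
#'   `c("simulate", "cp", "geometry", "clustering", "sdar")`, executed in
#'   dependency order.
#' @param dimer_spec A [dimer_sim_spec()] (its seed is re-derived from
#'   `seed` at run time).
#' @param score_spec A [score_sim_spec()] (ditto).
#' @param equilibration_fraction,contact_cutoff,cluster_cutoff,stride_ns,bin_width
#'   Analysis parameters (see the stage functions).
#' @param n_perm Permutations for SDAR p-values (default 1000).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "cp", "geometry", "clustering", "sdar"),
                       dimer_spec = dimer_sim_spec(),
                       score_spec = score_sim_spec(),
                       equilibration_fraction = 0.25,
                       contact_cutoff = 0.6, cluster_cutoff = 0.2,
                       stride_ns = 0.5, bin_width = 0.05,
                       n_perm = 1000, seed = 1) {
  known <- c("simulate", "cp", "geometry", "clustering", "sdar")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) {
    stop_allodyn(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
                 class = "allodyn_spec_error")
  }
  structure(list(
    out_dir = out_dir, stages = known[known %in% stages],
    dimer_spec = dimer_spec, score_spec = score_spec,
    equilibration_fraction = equilibration_fraction,
    contact_cutoff = contact_cutoff, cluster_cutoff = cluster_cutoff,
    stride_ns = stride_ns, bin_width = bin_width,
    n_perm = n_perm, seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar analysis parameters and the synthetic-spec fields are read from a
#' YAML file; omitted fields keep their defaults.
#'
#' @param path YAML file path.
#' @param out_dir Output directory (overrides any `out_dir` in the file).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  dimer <- do.call(dimer_sim_spec, y$dimer_spec %||% list())
  score <- do.call(score_sim_spec, y$score_spec %||% list())
  args <- y[setdiff(names(y), c("dimer_spec", "score_spec", "out_dir"))]
  args$dimer_spec <- dimer
  args$score_spec <- score
  args$out_dir <- out_dir %||% y$out_dir
  do.call(run_config, args)
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Generates a synthetic dimer trajectory, then runs the requested analysis
#' stages in dependency order, writing one CSV per result plus a JSON
#' manifest (package version, seed, configuration echo, per-file MD5
#' checksums). Re-running with an identical configuration and seed
#' reproduces byte-identical numeric outputs.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (a list; also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stages_run <- character(0)

  dimer_spec <- config$dimer_spec
  dimer_spec$seed <- config$seed
  score_spec <- config$score_spec
  score_spec$seed <- config$seed + 1L

  sim <- NULL
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop_allodyn(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   class = "allodyn_stage_failure", parent = e)
    })
  }

  if ("simulate" %in% config$stages || length(intersect(
    c("cp", "geometry", "clustering"), config$stages)) > 0L) {
    sim <- run_stage("simulate", function() generate_dimer_trajectory(dimer_spec))
    if ("simulate" %in% config$stages) {
      files <- c(files, write_stage_csv(sim$truth$domain_map, config$out_dir,
                                        "domain_map.csv"))
      stages_run <- c(stages_run, "simulate")
    }
  }

  stride_frames <- max(1L, round(config$stride_ns / dimer_spec$dt))

  if ("cp" %in% config$stages) {
    run_stage("cp", function() {
      all_res <- residue_selection(unique(sim$ensemble$topology[, c("chain_id", "residue_id")]),
                                   atom_filter = "c_alpha")
      cp <- compute_cp(sim$ensemble, all_res,
                       equilibration_fraction = config$equilibration_fraction)
      files <<- c(files, write_stage_csv(tidy(cp), config$out_dir, "cp_long.csv"),
                  write_stage_csv(glance(cp), config$out_dir, "cp_chain_blocks.csv"))
      stages_run <<- c(stages_run, "cp")
    })
  }

  if ("geometry" %in% config$stages) {
    run_stage("geometry", function() {
      sel <- sim$truth$selections
      dist <- com_distance(sim$ensemble, sel[["A NTD"]] %||% sel[[1]],
                           sel[["B NTD"]] %||% sel[[length(sel)]],
                           bin_width = config$bin_width)
      contacts <- interprotomer_contacts(sim$ensemble, cutoff = config$contact_cutoff)
      nd <- dimer_spec$domains_per_protomer
      dn <- domain_names(nd)
      nm_res <- sim$truth$domain_map[sim$truth$domain_map$domain %in% dn[-nd], ]
      ctd_res <- sim$truth$domain_map[sim$truth$domain_map$domain == dn[nd], ]
      mk <- function(df, ch, filt) residue_selection(
        df[df$chain_id == ch, c("chain_id", "residue_id")], atom_filter = filt)
      angles <- protomer_angles(
        sim$ensemble, sim$reference,
        ctd_selections = list(A = mk(ctd_res, "A", "backbone"),
                              B = mk(ctd_res, "B", "backbone")),
        nm_selections = list(A = mk(nm_res, "A", "c_alpha"),
                             B = mk(nm_res, "B", "c_alpha")),
        stride = stride_frames
      )
      files <<- c(files,
                  write_stage_csv(dist, config$out_dir, "com_distance.csv"),
                  write_stage_csv(contacts, config$out_dir, "contacts.csv"),
                  write_stage_csv(angles, config$out_dir, "angles.csv"),
                  write_stage_csv(angle_asymmetry(angles), config$out_dir,
                                  "angle_asymmetry.csv"))
      stages_run <<- c(stages_run, "geometry")
    })
  }

  if ("clustering" %in% config$stages) {
    run_stage("clustering", function() {
      nd <- dimer_spec$domains_per_protomer
      dn <- domain_names(nd)
      ctd_res <- sim$truth$domain_map[sim$truth$domain_map$domain == dn[nd], ]
      fit_sel <- residue_selection(ctd_res[, c("chain_id", "residue_id")],
                                   atom_filter = "backbone")
      sampled <- subset_frames(sim$ensemble,
                               seq.int(floor(n_frames(sim$ensemble) / 2) + 1L,
                                       n_frames(sim$ensemble), by = stride_frames))
      rm <- pairwise_rmsd_matrix(sampled, fit_sel)
      cl <- daura_cluster(rm, cutoff = config$cluster_cutoff)
      reps <- select_representatives(cl)
      files <<- c(files,
                  write_stage_csv(tidy(cl), config$out_dir, "cluster_assignments.csv"),
                  write_stage_csv(tibble(rank = seq_along(cl$populations),
                                         population = cl$populations,
                                         representative_frame = cl$representatives,
                                         cumulative_coverage = cl$cumulative_coverage),
                                  config$out_dir, "cluster_table.csv"))
      stages_run <<- c(stages_run, "clustering")
    })
  }

  if ("sdar" %in% config$stages) {
    run_stage("sdar", function() {
      tabs <- generate_score_table(score_spec)
      res <- withr::with_seed(config$seed + 2L,
        sdar_correlate(tabs$scores, tabs$ligands, tabs$activities,
                       n_perm = config$n_perm))
      files <<- c(files,
                  write_stage_csv(res$per_compound, config$out_dir, "sdar_per_compound.csv"),
                  write_stage_csv(res$correlations, config$out_dir, "sdar_correlations.csv"))
      stages_run <<- c(stages_run, "sdar")
    })
  }

  config_echo <- unclass(config)
  config_echo$dimer_spec <- unclass(dimer_spec)
  config_echo$score_spec <- unclass(score_spec)
  yaml::write_yaml(config_echo, file.path(config$out_dir, "config.yaml"))

  manifest <- list(
    package = "allodyn",
    version = as.character(utils::packageVersion("allodyn")),
    seed = config$seed,
    stages = stages_run,
    config = config_echo,
    checksums = setNames(as.list(unname(tools::md5sum(sort(files)))),
                         basename(sort(files)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
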