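#' Docking-score tables
#'
#' A dock-score table holds best-pose docking scores (kcal/mol, more
#' negative = better) for each compound (rows) against each receptor
#' structure of an ensemble (columns), tagged with the ensemble mode it came
#' from. Missing cells are `NA`, never silently zero.
#'
#' @param x A data frame whose first column is `compound_id` and remaining
#'   columns are numeric per-receptor scores.
#' @param mode_label Ensemble mode, one of `"dmrs_atp_only"` (representatives
#'   of the ligand-free ATP-state clusters), `"complex_clusters"`
#'   (representatives of each complex's own clusters), `"complex_snapshots"`
#'   (snapshots from the complex trajectories), or any other label.
#' @return A `dock_score_table` tibble.
#' @export
dock_score_table <- function(x, mode_label = "dmrs_atp_only") {
  x <- as_tibble(x)
  if (!"compound_id" %in% names(x) || ncol(x) < 2L) {
    stop_allodyn("a score table needs a `compound_id` column plus >= 1 receptor column",
                 class = "allodyn_format_error")
  }
  x$compound_id <- as.character(x$compound_id)
  rec_cols <- setdiff(names(x), "compound_id")
  all_missing <- apply(is.na(x[rec_cols]), 1, all)
  if (any(all_missing)) {
    stop_allodyn(
      sprintf("compound(s) with no finite score: %s",
              paste(x$compound_id[all_missing], collapse = ", ")),
      class = "allodyn_missing_data"
    )
  }
  attr(x, "mode_label") <- mode_label
  class(x) <- c("dock_score_table", class(x))
  x
}

#' Read a dock-score table from CSV/TSV
#'
#' Header row holds receptor ids; first column must be `compound_id`.
#'
#' @param path CSV or TSV file path.
#' @inheritParams dock_score_table
#' @return A `dock_score_table`.
#' @export
read_score_table <- function(path, mode_label = "dmrs_atp_only") {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  dock_score_table(utils::read.csv(path, sep = sep, check.names = FALSE),
                   mode_label = mode_label)
}

#' Ligand efficiency
#'
#' Binding (docking) score per heavy atom: `LE = score / heavy_atom_count`,
#' the size-normalised affinity measure that lets differently sized ligands
#' be compared against one target.
#'
#' @param score Docking score(s), kcal/mol (finite).
#' @param heavy_atom_count Number of non-hydrogen atoms (>= 1); recycled
#'   against `score`.
#' @return LE in kcal/mol per heavy atom; `NA` scores propagate.
#' @examples
#' ligand_efficiency(-7.5, 30)  # -0.25
#' @export
ligand_efficiency <- function(score, heavy_atom_count) {
  if (any(heavy_atom_count < 1 | heavy_atom_count != round(heavy_atom_count))) {
    stop_allodyn("`heavy_atom_count` must be a positive integer",
                 class = "allodyn_domain_error")
  }
  if (any(is.infinite(score))) {
    stop_allodyn("scores must be finite (use NA for missing cells)",
                 class = "allodyn_domain_error")
  }
  score / heavy_atom_count
}

#' Average ligand efficiency over a receptor ensemble
#'
#' Per-compound mean and sample standard deviation of the per-receptor
#' ligand efficiencies, over the non-missing cells of a dock-score table.
#'
#' @param table A [dock_score_table()].
#' @param ligands Data frame with `compound_id` and `heavy_atom_count`
#'   covering every compound in `table`.
#' @return A tibble with `compound_id`, `n_receptors`, `mean_le`, `sd_le`
#'   (0 with `single_observation = TRUE` when only one receptor contributes),
#'   and a 2-decimal `display` string in the conventional "mean (sd)" form.
#' @export
average_le <- function(table, ligands) {
  ligands <- as_tibble(ligands)
  missing_lig <- setdiff(table$compound_id, ligands$compound_id)
  if (length(missing_lig) > 0L) {
    stop_allodyn(sprintf("no heavy-atom count for compound(s): %s",
                         paste(missing_lig, collapse = ", ")),
                 class = "allodyn_missing_data")
  }
  rec_cols <- setdiff(names(table), "compound_id")
  heavy <- ligands$heavy_atom_count[match(table$compound_id, ligands$compound_id)]
  le <- as.matrix(table[rec_cols]) / heavy
  n_obs <- rowSums(!is.na(le))
  mean_le <- rowMeans(le, na.rm = TRUE)
  sd_le <- apply(le, 1, sd, na.rm = TRUE)
  single <- n_obs == 1L
  sd_le[single] <- 0
  tibble(
    compound_id = table$compound_id,
    n_receptors = as.integer(n_obs),
    mean_le = mean_le,
    sd_le = sd_le,
    single_observation = single,
    display = sprintf("%.2f (%.2f)", mean_le, sd_le)
  )
}

#' Pearson product-moment correlation
#'
#' Thin validation layer over the standard Pearson coefficient, with an
#' optional seeded permutation p-value (fraction of label shuffles giving
#' |r| at least as large as observed).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @param n_perm Number of permutations for the p-value; 0 (default) skips it.
#' @return The correlation (with attribute `p_perm` when `n_perm > 0`).
#' @export
pearson_r <- function(x, y, n_perm = 0) {
  if (length(x) != length(y)) {
    stop_allodyn("`x` and `y` must have equal length", class = "allodyn_domain_error")
  }
  if (length(x) < 3L) {
    stop_allodyn("need at least 3 observations for a correlation",
                 class = "allodyn_insufficient_data")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_allodyn("zero variance in input; correlation undefined",
                 class = "allodyn_degenerate_input")
  }
  r <- cor(x, y)
  if (n_perm > 0) {
    perm <- vapply(seq_len(n_perm), function(i) abs(cor(x, sample(y))), numeric(1))
    attr(r, "p_perm") <- (sum(perm >= abs(r)) + 1) / (n_perm + 1)
  }
  r
}

#' Structure-dynamics-activity correlation across ensemble modes
#'
#' For each dock-score table (one per ensemble mode): average the ligand
#' efficiencies over the receptor ensemble, then correlate the per-compound
#' mean LE with each experimental activity column. Compounds are matched by
#' id; a mismatch is reported and the analysis proceeds on the intersection
#' when at least 3 compounds remain. Modes are ranked by |r| against the
#' first activity column (most predictive first).
#'
#' @param tables A single [dock_score_table()] or a list of them (one per
#'   mode; names default to each table's `mode_label`).
#' @param ligands Data frame with `compound_id`, `heavy_atom_count`.
#' @param activities Data frame with `compound_id` plus one numeric column
#'   per activity readout (e.g. `atpase_rate` in ATP turnover min^-1, and
#'   optionally a FRET `closure_rate`).
#' @param n_perm Permutations for the p-value on each correlation (seeded by
#'   the caller's RNG state; default 10000). This p-value is a package
#'   extra, not part of the original correlation model.
#' @return An `sdar_result`: list with `per_compound` (tibble of mean LE per
#'   mode), `correlations` (tibble: `mode`, `activity`, `r`, `n`, `p_perm`),
#'   and `ranking` (modes by decreasing |r| vs the first activity column).
#' @export
sdar_correlate <- function(tables, ligands, activities, n_perm = 10000) {
  if (inherits(tables, "dock_score_table")) tables <- list(tables)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- vapply(tables, function(t) attr(t, "mode_label") %||% "mode",
                            character(1))
  }
  activities <- as_tibble(activities)
  act_cols <- setdiff(names(activities), "compound_id")
  if (length(act_cols) == 0L) {
    stop_allodyn("`activities` needs at least one numeric activity column",
                 class = "allodyn_format_error")
  }

  shared <- Reduce(intersect, c(lapply(tables, function(t) t$compound_id),
                                list(activities$compound_id)))
  all_ids <- unique(c(unlist(lapply(tables, function(t) t$compound_id)),
                      activities$compound_id))
  mismatch <- setdiff(all_ids, shared)
  if (length(mismatch) > 0L) {
    if (length(shared) < 3L) {
      stop_allodyn(
        sprintf("fewer than 3 compounds shared across tables and activities (unmatched: %s)",
                paste(mismatch, collapse = ", ")),
        class = "allodyn_insufficient_data"
      )
    }
    warn(sprintf("proceeding on %d shared compounds; unmatched: %s",
                 length(shared), paste(mismatch, collapse = ", ")))
  }

  per_compound <- list(); cors <- list()
  for (mode in names(tables)) {
    tab <- tables[[mode]]
    avg <- average_le(tab[match(shared, tab$compound_id), ], ligands)
    per_compound[[mode]] <- dplyr::mutate(avg, mode = mode, .before = 1)
    act <- activities[match(shared, activities$compound_id), ]
    for (ac in act_cols) {
      y <- act[[ac]]
      ok <- is.finite(y)
      r <- pearson_r(avg$mean_le[ok], y[ok], n_perm = n_perm)
      p_val <- attr(r, "p_perm") %||% NA_real_
      cors[[paste(mode, ac)]] <- tibble(
        mode = mode, activity = ac, r = as.numeric(r), n = sum(ok),
        p_perm = p_val
      )
    }
  }
  correlations <- dplyr::bind_rows(cors)
  first_act <- correlations[correlations$activity == act_cols[1], ]
  ranking <- first_act$mode[order(-abs(first_act$r))]

  structure(list(
    per_compound = dplyr::bind_rows(per_compound),
    correlations = correlations,
    ranking = ranking
  ), class = "sdar_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sdar_result <- function(x, ...) {
  cat("<sdar_result>\n")
  print(x$correlations)
  cat("ranking by |r|:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Tidy an SDAR result
#' @param x An `sdar_result`.
#' @param ... Unused.
#' @return The correlations tibble (`mode`, `activity`, `r`, `n`, `p_perm`).
#' @method tidy sdar_result
#' @export
tidy.sdar_result <- function(x, ...) x$correlations

#' One-row SDAR summary
#' @param x An `sdar_result`.
#' @param ... Unused.
#' @return Tibble with `best_mode`, `best_r`, `n_modes`, `n_compounds`.
#' @method glance sdar_result
#' @export
glance.sdar_result <- function(x, ...) {
  best <- x$correlations[x$correlations$mode == x$ranking[1] &
                           x$correlations$activity == x$correlations$activity[1], ]
  tibble(best_mode = x$ranking[1], best_r = best$r[1],
         n_modes = length(unique(x$correlations$mode)),
         n_compounds = max(x$correlations$n))
}

#' LE-vs-activity scatter per ensemble mode
#' @param object An `sdar_result`.
#' @param activities The activity table passed to [sdar_correlate()].
#' @param activity Activity column to plot (default the first one used).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sdar_result
#' @export
autoplot.sdar_result <- function(object, activities, activity = NULL, ...) {
  activity <- activity %||% object$correlations$activity[1]
  df <- dplyr::left_join(object$per_compound,
                         as_tibble(activities), by = "compound_id")
  ggplot2::ggplot(df, ggplot2::aes(.data[[activity]], .data$mean_le)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = activity, y = "mean ligand efficiency (kcal/mol/atom)") +
    ggplot2::theme_minimal()
}

#' Published ligand-efficiency / ATPase table for the benzofuran series
#'
#' The per-compound average ligand efficiencies (three ensemble-averaging
#' modes, each with its printed standard deviation) and measured ATPase
#' turnover rates for six benzofuran-scaffold allosteric activators of the
#' yeast Hsp90 dimer, as published (2 d.p. precision). Shipped as a plain
#' CSV under `inst/extdata/`.
#'
#' @return A tibble with columns `compound_id`, `le_dmrs_atp_only`,
#'   `sd_dmrs_atp_only`, `le_complex_clusters`, `sd_complex_clusters`,
#'   `le_complex_snapshots`, `sd_complex_snapshots`, `atpase_rate`.
#' @export
benzofuran_activity_table <- function() {
  path <- system.file("extdata", "benzofuran_le_atpase.csv", package = "allodyn",
                      mustWork = TRUE)
  as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Correlate published mean-LE columns with activity
#'
#' Runs the correlation arm of the SDAR model directly on per-compound mean
#' ligand efficiencies (e.g. the published table, where only the ensemble
#' averages are available, not the underlying per-receptor scores).
#'
#' @param le_table Data frame with `compound_id` and one `le_*` column per
#'   ensemble mode.
#' @param activities Data frame with `compound_id` plus activity column(s).
#' @param n_perm Permutations for the p-value (default 0: off).
#' @return A tibble with `mode`, `activity`, `r`, `n`.
#' @export
correlate_le <- function(le_table, activities, n_perm = 0) {
  le_table <- as_tibble(le_table)
  activities <- as_tibble(activities)
  le_cols <- grep("^le_", names(le_table), value = TRUE)
  if (length(le_cols) == 0L) {
    stop_allodyn("`le_table` needs at least one `le_*` column",
                 class = "allodyn_format_error")
  }
  act <- activities[match(le_table$compound_id, activities$compound_id), ]
  act_cols <- setdiff(names(act), "compound_id")
  rows <- list()
  for (lc in le_cols) {
    for (ac in act_cols) {
      r <- pearson_r(le_table[[lc]], act[[ac]], n_perm = n_perm)
      p_val <- attr(r, "p_perm") %||% NA_real_
      rows[[paste(lc, ac)]] <- tibble(
        mode = sub("^le_", "", lc), activity = ac,
        r = as.numeric(r), n = length(le_table[[lc]]),
        p_perm = p_val
      )
    }
  }
  dplyr::bind_rows(rows)
}
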