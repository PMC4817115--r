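#' Distance-fluctuation (coordination propensity) matrices
#'
#' The coordination propensity (CP) of a residue pair (i, j) is the time
#' variance of the Euclidean distance between their C-alpha atoms,
#' `CP_ij = <(d_ij - <d_ij>)^2>` in nm^2, computed over the post-equilibration
#' part of a trajectory. Low CP marks pairs moving as part of the same
#' quasi-rigid unit; high CP marks flexible, poorly coordinated pairs. The
#' statistic depends only on internal distances, so it is invariant under
#' rigid motions of each frame and needs no structural alignment or
#' reference frame.
#'
#' The population (divide-by-N) variance convention is used; this is recorded
#' in the object metadata.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param selection A [residue_selection()]; the `c_alpha` filter is applied
#'   regardless of the selection's own filter (one atom per residue).
#' @param equilibration_fraction Fraction of initial frames discarded before
#'   computing variances (default 0.25, i.e. the first quarter of the run is
#'   treated as equilibration).
#'
#' @return A `cp_matrix`: symmetric non-negative matrix (nm^2, zero
#'   diagonal) with row/column labels `chain:residue`, plus metadata
#'   (`frames_used`, `replicas_averaged`, `equilibration_discarded`,
#'   `selection`, `convention`).
#' @export
compute_cp <- function(ensemble, selection, equilibration_fraction = 0.25) {
  if (!is.numeric(equilibration_fraction) || equilibration_fraction < 0 ||
      equilibration_fraction >= 1) {
    stop_allodyn("`equilibration_fraction` must be in [0, 1)",
                 class = "allodyn_domain_error")
  }
  ca_sel <- residue_selection(selection$members, atom_filter = "c_alpha")
  idx <- resolve_selection(ca_sel, ensemble)
  if (length(idx) < 2L) {
    stop_allodyn("selection must resolve to at least 2 C-alpha atoms",
                 class = "allodyn_selection_error")
  }
  nf <- n_frames(ensemble)
  first <- floor(equilibration_fraction * nf) + 1L
  frames <- seq.int(first, nf)
  if (length(frames) < 2L) {
    stop_allodyn(
      sprintf("only %d frame(s) left after discarding %.0f%% for equilibration; need >= 2",
              length(frames), 100 * equilibration_fraction),
      class = "allodyn_insufficient_data"
    )
  }

  # single-pass streaming mean/M2 (Welford) over frames: memory is bounded by
  # two n_res x n_res accumulators however long the trajectory is
  n <- length(idx)
  mean_d <- matrix(0, n, n)
  m2 <- matrix(0, n, n)
  k <- 0L
  for (f in frames) {
    d <- as.matrix(stats::dist(ensemble$coords[idx, , f]))
    k <- k + 1L
    delta <- d - mean_d
    mean_d <- mean_d + delta / k
    m2 <- m2 + delta * (d - mean_d)
  }
  values <- m2 / k
  values <- (values + t(values)) / 2   # exact symmetry against rounding
  diag(values) <- 0
  values[values < 0] <- 0

  top <- ensemble$topology
  labels <- paste0(top$chain_id[idx], ":", top$residue_id[idx])
  dimnames(values) <- list(labels, labels)

  structure(list(
    values = values, selection = ca_sel, frames_used = length(frames),
    replicas_averaged = 1L, equilibration_discarded = equilibration_fraction,
    convention = "population variance of C-alpha pair distance, nm^2"
  ), class = "cp_matrix")
}

#' @export
print.cp_matrix <- function(x, ...) {
  cat(sprintf(
    "<cp_matrix> %d residues, %d frames (%d replica(s) averaged), mean off-diagonal CP = %.4g nm^2\n",
    nrow(x$values), x$frames_used, x$replicas_averaged,
    mean(x$values[upper.tri(x$values)])
  ))
  invisible(x)
}

#' Average CP matrices over replicas
#'
#' Element-wise arithmetic mean of replicate CP matrices sharing one
#' selection (three independent trajectories per system is the usual design).
#'
#' @param matrices A list of `cp_matrix` objects over the same selection.
#' @return A `cp_matrix` with `replicas_averaged` summed over inputs.
#' @export
average_cp <- function(matrices) {
  if (inherits(matrices, "cp_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!selections_compatible(ref$selection, m$selection)) {
      stop_allodyn("CP matrices to average must share the same residue selection",
                   class = "allodyn_incompatible")
    }
  }
  out <- ref
  out$values <- Reduce(`+`, lapply(matrices, `[[`, "values")) / length(matrices)
  out$frames_used <- sum(vapply(matrices, `[[`, 1L, "frames_used"))
  out$replicas_averaged <- sum(vapply(matrices, `[[`, 1L, "replicas_averaged"))
  out
}

#' Difference distance-fluctuation matrix
#'
#' `reference CP - complex CP`, the map used to localise ligand-induced
#' rigidity and flexibility changes. Positive entries mean the pair
#' fluctuates more in the reference (ligand-free) state; negative entries
#' mean more flexibility in the complex.
#'
#' @param reference,complex_ `cp_matrix` objects over the same selection
#'   (e.g. the ATP-only average and a ligand-complex average).
#' @return A `cp_difference` object (values in nm^2).
#' @export
difference_cp <- function(reference, complex_) {
  if (!selections_compatible(reference$selection, complex_$selection)) {
    stop_allodyn("CP matrices to subtract must share the same residue selection",
                 class = "allodyn_incompatible")
  }
  structure(list(
    values = reference$values - complex_$values,
    selection = reference$selection,
    reference_label = "reference", complex_label = "complex"
  ), class = "cp_difference")
}

#' @export
print.cp_difference <- function(x, ...) {
  cat(sprintf("<cp_difference> %d residues, range [%.4g, %.4g] nm^2\n",
              nrow(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Tidy a CP or difference matrix into long form
#'
#' @param x A `cp_matrix` or `cp_difference`.
#' @param ... Unused.
#' @return A tibble with columns `residue_i`, `residue_j`, `value` (nm^2).
#' @method tidy cp_matrix
#' @export
tidy.cp_matrix <- function(x, ...) {
  m <- x$values
  tibble(
    residue_i = rep(rownames(m), times = ncol(m)),
    residue_j = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
}

#' @rdname tidy.cp_matrix
#' @method tidy cp_difference
#' @export
tidy.cp_difference <- tidy.cp_matrix

#' Summarise CP by chain-pair block
#'
#' Mean CP over residue pairs, grouped by the chains of the two residues —
#' the compact within- vs between-protomer coordination summary.
#'
#' @param x A `cp_matrix` or `cp_difference`.
#' @param ... Unused.
#' @return A tibble with `chain_i`, `chain_j`, `mean_value`, `n_pairs`.
#' @method glance cp_matrix
#' @export
glance.cp_matrix <- function(x, ...) {
  long <- tidy(x)
  long <- long[long$residue_i != long$residue_j, ]
  long$chain_i <- sub(":.*", "", long$residue_i)
  long$chain_j <- sub(":.*", "", long$residue_j)
  dplyr::summarise(
    dplyr::group_by(long, .data$chain_i, .data$chain_j),
    mean_value = mean(.data$value), n_pairs = dplyr::n(), .groups = "drop"
  )
}

#' @rdname glance.cp_matrix
#' @method glance cp_difference
#' @export
glance.cp_difference <- glance.cp_matrix

#' Plot a difference distance-fluctuation matrix
#'
#' Diverging blue-white-black map: blue marks pairs more flexible in the
#' complex, black pairs more flexible in the reference state.
#'
#' @param object A `cp_difference` (or `cp_matrix`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cp_difference
#' @export
autoplot.cp_difference <- function(object, ...) {
  long <- tidy(object)
  long$residue_i <- factor(long$residue_i, levels = rownames(object$values))
  long$residue_j <- factor(long$residue_j, levels = colnames(object$values))
  lim <- max(abs(long$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$residue_i, .data$residue_j,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "black",
                                  limits = c(-lim, lim),
                                  name = expression(Delta * CP ~ (nm^2))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname autoplot.cp_difference
#' @method autoplot cp_matrix
#' @export
autoplot.cp_matrix <- function(object, ...) {
  long <- tidy(object)
  long$residue_i <- factor(long$residue_i, levels = rownames(object$values))
  long$residue_j <- factor(long$residue_j, levels = colnames(object$values))
  ggplot2::ggplot(long, ggplot2::aes(.data$residue_i, .data$residue_j,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(CP ~ (nm^2))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Export a CP or difference matrix as dense CSV
#'
#' @param x A `cp_matrix` or `cp_difference`.
#' @param path Output CSV path (row/column labels preserved).
#' @return `path`, invisibly.
#' @export
write_cp_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x$values), path)
  invisible(path)
}
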