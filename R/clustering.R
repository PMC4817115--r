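#' Pairwise RMSD matrix over trajectory frames
#'
#' Entry (i, j) is the RMSD between frames i and j after optimal Kabsch
#' superposition over the fit selection (typically the backbone atoms of the
#' C-terminal domain, the anchor of the dimer). Full O(n^2) computation;
#' clustering inputs are sampled trajectories of a few hundred frames.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param fit_selection A [residue_selection()]; its own atom filter is used
#'   (use `backbone` for the conventional backbone RMSD).
#' @return Symmetric `n_frames x n_frames` matrix of RMSDs (nm), zero
#'   diagonal.
#' @export
pairwise_rmsd_matrix <- function(ensemble, fit_selection) {
  idx <- resolve_selection(fit_selection, ensemble)
  if (length(idx) < 3L) {
    stop_allodyn("fit selection must resolve to at least 3 atoms",
                 class = "allodyn_selection_error")
  }
  nf <- n_frames(ensemble)
  if (nf < 2L) {
    stop_allodyn("need at least 2 frames for a pairwise RMSD matrix",
                 class = "allodyn_insufficient_data")
  }
  coords <- lapply(seq_len(nf), function(f) matrix(ensemble$coords[idx, , f], ncol = 3))
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      m[i, j] <- m[j, i] <- kabsch_superpose(coords[[j]], coords[[i]])$rmsd
    }
  }
  m
}

#' Daura (GROMOS) leader clustering of trajectory frames
#'
#' Greedy neighbour clustering: repeatedly find the remaining frame with the
#' most neighbours (other remaining frames at RMSD strictly below the
#' cutoff), make it a cluster centre, assign it and its neighbours to that
#' cluster and remove them from the pool; repeat until the pool is empty.
#' Singleton clusters are allowed. Ties on neighbour count go to the lowest
#' original frame index, making the result deterministic.
#'
#' @param rmsd_matrix Square symmetric non-negative matrix (nm), e.g. from
#'   [pairwise_rmsd_matrix()].
#' @param cutoff Neighbour cutoff in nm (default 0.2, strict inequality).
#' @param frame_labels Optional stable labels used only for tie-breaking
#'   (default the row indices); supplying the original frame numbers makes
#'   the partition invariant to the order frames are presented in.
#' @return A `cluster_result`: list with `assignments` (frame -> cluster id,
#'   ids ranked by population), `representatives` (per-cluster centre frame
#'   index), `populations` (non-increasing), `cumulative_coverage`, `cutoff`.
#' @export
daura_cluster <- function(rmsd_matrix, cutoff = 0.2,
                          frame_labels = seq_len(nrow(as.matrix(rmsd_matrix)))) {
  m <- as.matrix(rmsd_matrix)
  if (length(m) == 0L) {
    stop_allodyn("empty RMSD matrix", class = "allodyn_empty_input")
  }
  if (nrow(m) != ncol(m) || any(m < 0) || max(abs(m - t(m))) > 1e-9) {
    stop_allodyn("RMSD matrix must be square, symmetric and non-negative",
                 class = "allodyn_format_error")
  }
  n <- nrow(m)
  remaining <- rep(TRUE, n)
  assignments <- integer(n)
  centers <- integer(0)
  cluster <- 0L
  adj <- m < cutoff
  diag(adj) <- FALSE
  while (any(remaining)) {
    pool <- which(remaining)
    counts <- colSums(adj[pool, pool, drop = FALSE])
    best <- pool[counts == max(counts)]
    center <- best[which.min(frame_labels[best])]  # lowest stable label on ties
    members <- unique(c(center, pool[adj[pool, center]]))
    cluster <- cluster + 1L
    assignments[members] <- cluster
    centers[cluster] <- center
    remaining[members] <- FALSE
  }
  pops <- tabulate(assignments, nbins = cluster)
  # rank clusters by population (extraction order breaks ties: Daura centres
  # are found largest-first, so extraction order is already non-increasing)
  ord <- order(-pops, seq_len(cluster))
  relabel <- match(seq_len(cluster), ord)
  structure(list(
    assignments = relabel[assignments],
    representatives = centers[ord],
    populations = pops[ord],
    cumulative_coverage = cumsum(pops[ord]) / n,
    cutoff = cutoff
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d frames in %d clusters (cutoff %.3g nm); top populations: %s\n",
              length(x$assignments), length(x$populations), x$cutoff,
              paste(head(x$populations, 5), collapse = ", ")))
  invisible(x)
}

#' Tidy cluster assignments
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble with `frame`, `cluster`, `is_representative`.
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble(
    frame = seq_along(x$assignments),
    cluster = x$assignments,
    is_representative = seq_along(x$assignments) %in% x$representatives
  )
}

#' One-row cluster summary
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble with `n_frames`, `n_clusters`, `top_population`,
#'   `coverage_top10`.
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  k <- min(10L, length(x$populations))
  tibble(
    n_frames = length(x$assignments),
    n_clusters = length(x$populations),
    top_population = x$populations[1],
    coverage_top10 = x$cumulative_coverage[k]
  )
}

#' Representative frames for ensemble docking
#'
#' Keeps the representatives of the top-k most populated clusters, where k is
#' the smaller of `max_k` and the smallest rank reaching `min_coverage`
#' cumulative population (the "first ten structures covering more than 95%
#' of the sampled variability" rule).
#'
#' @param result A `cluster_result`.
#' @param min_coverage Required cumulative population fraction (default 0.95).
#' @param max_k Upper bound on the number of representatives (default 10).
#' @return A list with `frames` (representative frame indices), `k`, and
#'   `coverage` (achieved cumulative fraction).
#' @export
select_representatives <- function(result, min_coverage = 0.95, max_k = 10) {
  cov <- result$cumulative_coverage
  reach <- which(cov >= min_coverage)
  k_needed <- if (length(reach) > 0L) reach[1] else length(cov)
  k <- min(max_k, k_needed)
  list(frames = result$representatives[seq_len(k)], k = k, coverage = cov[k])
}

#' Bar plot of cluster populations
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble(rank = seq_along(object$populations),
               population = object$populations,
               coverage = object$cumulative_coverage)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$population)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$coverage * max(.data$population)),
                       colour = "black") +
    ggplot2::labs(x = "cluster rank", y = "population (frames)") +
    ggplot2::theme_minimal()
}
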