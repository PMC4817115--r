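#' Inter-domain centre-of-mass distance series
#'
#' Per-frame Euclidean distance between the unweighted centroids of two
#' backbone-atom selections — typically the NTDs of the two protomers, whose
#' separation distinguishes the closed (dimerised) from the open state.
#' Mass weighting over N/CA/C/O backbone atoms changes the centroid by well
#' under 0.1% and is omitted; this is recorded in the attributes.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param sel_a,sel_b [residue_selection()]s; the `backbone` atom filter is
#'   applied to both.
#' @param bin_width Histogram bin width in nm (default 0.05).
#' @return A `distance_series` tibble with columns `frame`, `time`,
#'   `distance` (nm); the normalised histogram (`bin_mid`, `frequency`) is in
#'   `attr(x, "histogram")`.
#' @export
com_distance <- function(ensemble, sel_a, sel_b, bin_width = 0.05) {
  sa <- residue_selection(sel_a$members, atom_filter = "backbone")
  sb <- residue_selection(sel_b$members, atom_filter = "backbone")
  ia <- resolve_selection(sa, ensemble)
  ib <- resolve_selection(sb, ensemble)
  nf <- n_frames(ensemble)
  d <- vapply(seq_len(nf), function(f) {
    ca <- colMeans(matrix(ensemble$coords[ia, , f], ncol = 3))
    cb <- colMeans(matrix(ensemble$coords[ib, , f], ncol = 3))
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  out <- tibble(frame = seq_len(nf), time = ensemble$times, distance = d)
  attr(out, "histogram") <- distance_histogram(d, bin_width)
  attr(out, "centroid") <- "unweighted backbone-atom centroid"
  class(out) <- c("distance_series", class(out))
  out
}

distance_histogram <- function(d, bin_width) {
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = edges, plot = FALSE)
  tibble(bin_mid = h$mids, frequency = h$counts / length(d))
}

#' Histogram peak of a distance series
#'
#' Mode of the binned distribution (midpoint of the most populated bin),
#' optionally on a subset of frames — used to quantify peak shifts between
#' conditions or trajectory halves.
#'
#' @param series A `distance_series` from [com_distance()], or a numeric
#'   vector of distances.
#' @param frames Optional frame indices to restrict to.
#' @param bin_width Histogram bin width in nm (default 0.05).
#' @return Peak position in nm.
#' @export
distance_peak <- function(series, frames = NULL, bin_width = 0.05) {
  d <- if (is.numeric(series)) series else series$distance
  if (!is.null(frames)) d <- d[frames]
  h <- distance_histogram(d, bin_width)
  h$bin_mid[which.max(h$frequency)]
}

#' Count inter-protomer residue contacts per frame
#'
#' A contact exists between a residue of chain `chain_a` and a residue of
#' `chain_b` when the distance between any pair of their atoms is strictly
#' below `cutoff` (default 0.6 nm, i.e. 6 Angstrom). Each residue pair is
#' counted once however many atom pairs qualify.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param chain_a,chain_b Chain labels of the two protomers.
#' @param cutoff Contact cutoff in nm (strict inequality).
#' @return A `contact_series` tibble with `frame`, `time`, `n_contacts`.
#' @export
interprotomer_contacts <- function(ensemble, chain_a = "A", chain_b = "B",
                                   cutoff = 0.6) {
  top <- ensemble$topology
  ia <- which(top$chain_id == chain_a)
  ib <- which(top$chain_id == chain_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop_allodyn(sprintf("chain '%s' not present in topology",
                         if (length(ia) == 0L) chain_a else chain_b),
                 class = "allodyn_selection_error")
  }
  res_a <- factor(top$residue_id[ia])
  res_b <- factor(top$residue_id[ib])
  nf <- n_frames(ensemble)
  counts <- vapply(seq_len(nf), function(f) {
    xa <- matrix(ensemble$coords[ia, , f], ncol = 3)
    xb <- matrix(ensemble$coords[ib, , f], ncol = 3)
    # squared cross-distance matrix in one shot, then an any-atom reduction
    # per residue pair (rowsum by residue of A, then by residue of B)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
    hit <- d2 < cutoff^2
    pair_hit <- rowsum(t(rowsum(hit + 0, res_a)), res_b)
    sum(pair_hit > 0)
  }, numeric(1))
  out <- tibble(frame = seq_len(nf), time = ensemble$times,
                n_contacts = as.integer(counts))
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_series", class(out))
  out
}

#' Principal (inertia) axis of a point set
#'
#' Unit eigenvector of the gyration tensor (covariance of the unweighted
#' points) with the largest eigenvalue — the long axis of an elongated
#' domain. The sign ambiguity (+v / -v are both eigenvectors) is resolved by
#' requiring a positive dot product with `hint`.
#'
#' @param coords `n x 3` matrix (n >= 3, not all collinear... collinear sets
#'   are fine for the largest axis, but a spherically symmetric set is not).
#' @param hint Orientation hint vector; the returned axis satisfies
#'   `sum(axis * hint) >= 0`.
#' @param gap_tolerance Minimum relative gap between the two largest
#'   gyration eigenvalues below which the axis is reported as degenerate.
#' @return Unit length-3 vector.
#' @export
principal_axis <- function(coords, hint = c(0, 0, 1), gap_tolerance = 1e-8) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) {
    stop_allodyn("need at least 3 points for a principal axis",
                 class = "allodyn_degenerate_axis")
  }
  centred <- sweep(coords, 2, colMeans(coords))
  gyr <- crossprod(centred) / nrow(coords)
  e <- eigen(gyr, symmetric = TRUE)
  gap <- (e$values[1] - e$values[2]) / max(e$values[1], .Machine$double.eps)
  if (!is.finite(gap) || gap < gap_tolerance) {
    stop_allodyn(
      sprintf("degenerate principal axis: relative eigenvalue gap %.3g between top eigenvalues (%.3g, %.3g)",
              gap, e$values[1], e$values[2]),
      class = "allodyn_degenerate_axis"
    )
  }
  v <- e$vectors[, 1]
  if (sum(v * hint) < 0) v <- -v
  v / sqrt(sum(v^2))
}

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Protomer axis angles versus a reference structure
#'
#' For each retained frame and each protomer: superpose the protomer's CTD
#' onto the reference structure's CTD (Kabsch fit over the CTD selection),
#' apply the transform to the whole chain, and measure the angle between the
#' principal axis of the N+M region and the same axis in the reference.
#' The per-frame difference between the two protomers' angles (B - A) is the
#' asymmetry readout; the angle between each protomer's whole-chain axis and
#' its N+M axis is returned as the internal-deformation readout.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param reference A single-frame [trajectory_ensemble()] containing both
#'   chains (e.g. the crystal structure the trajectory started from).
#' @param ctd_selections,nm_selections Named lists of [residue_selection()]s,
#'   one per chain (names are the chain labels, e.g. `list(A = ..., B = ...)`).
#' @param start_fraction Fraction of the trajectory skipped before sampling
#'   (default 0.5: the second half of the run).
#' @param stride Keep every `stride`-th frame after the start (default 1;
#'   with 0.1 ns frames, `stride = 5` reproduces 0.5 ns sampling).
#' @return An `angle_series` tibble with columns `frame`, `time`, `chain`,
#'   `angle_nm_vs_ref` (degrees), `angle_protomer_vs_nm` (degrees).
#'   Use [angle_asymmetry()] for the per-frame B - A series.
#' @export
protomer_angles <- function(ensemble, reference, ctd_selections, nm_selections,
                            start_fraction = 0.5, stride = 1) {
  chains <- names(nm_selections)
  stopifnot(length(chains) >= 1, identical(sort(chains), sort(names(ctd_selections))))
  nf <- n_frames(ensemble)
  frames <- seq.int(floor(start_fraction * nf) + 1L, nf, by = stride)

  ref_xyz <- frame_coords(reference, 1)
  prep <- lapply(chains, function(ch) {
    ctd_idx <- resolve_selection(ctd_selections[[ch]], ensemble)
    nm_sel_ca <- residue_selection(nm_selections[[ch]]$members, atom_filter = "c_alpha")
    nm_idx <- resolve_selection(nm_sel_ca, ensemble)
    chain_idx <- which(ensemble$topology$chain_id == ch &
                         ensemble$topology$atom_name == "CA")
    ref_ctd_idx <- resolve_selection(ctd_selections[[ch]], reference)
    ref_nm_idx <- resolve_selection(nm_sel_ca, reference)
    ref_axis <- principal_axis(ref_xyz[ref_nm_idx, , drop = FALSE])
    list(ctd_idx = ctd_idx, nm_idx = nm_idx, chain_idx = chain_idx,
         ref_ctd = ref_xyz[ref_ctd_idx, , drop = FALSE], ref_axis = ref_axis)
  })
  names(prep) <- chains

  rows <- list()
  for (f in frames) {
    xyz <- frame_coords(ensemble, f)
    for (ch in chains) {
      p <- prep[[ch]]
      tf <- tryCatch(
        kabsch_superpose(xyz[p$ctd_idx, , drop = FALSE], p$ref_ctd),
        error = function(e) {
          stop_allodyn(sprintf("frame %d, chain %s: %s", f, ch, conditionMessage(e)),
                       class = "allodyn_degenerate_fit", parent = e)
        }
      )
      nm_axis <- principal_axis(apply_transform(xyz[p$nm_idx, , drop = FALSE], tf),
                                hint = p$ref_axis)
      chain_xyz <- apply_transform(xyz[p$chain_idx, , drop = FALSE], tf)
      chain_axis <- principal_axis(chain_xyz, hint = nm_axis)
      rows[[length(rows) + 1L]] <- tibble(
        frame = f, time = ensemble$times[f], chain = ch,
        angle_nm_vs_ref = angle_deg(nm_axis, p$ref_axis),
        angle_protomer_vs_nm = angle_deg(chain_axis, nm_axis)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("angle_series", class(out))
  out
}

#' Per-frame protomer asymmetry (B - A angle difference)
#'
#' @param series An `angle_series` from [protomer_angles()].
#' @param chain_a,chain_b Labels of the two protomers (difference is
#'   `chain_b - chain_a`).
#' @return A tibble with `frame`, `time`, `b_minus_a` (degrees).
#' @export
angle_asymmetry <- function(series, chain_a = "A", chain_b = "B") {
  wide <- tidyr::pivot_wider(
    series[, c("frame", "time", "chain", "angle_nm_vs_ref")],
    names_from = "chain", values_from = "angle_nm_vs_ref"
  )
  tibble(frame = wide$frame, time = wide$time,
         b_minus_a = wide[[chain_b]] - wide[[chain_a]])
}

#' Plot helpers for geometry series
#'
#' @param object A `distance_series`, `contact_series` or `angle_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_series
#' @export
autoplot.distance_series <- function(object, ...) {
  h <- attr(object, "histogram")
  ggplot2::ggplot(h, ggplot2::aes(.data$bin_mid, .data$frequency)) +
    ggplot2::geom_col(width = diff(h$bin_mid[1:2]) * 0.95, fill = "steelblue") +
    ggplot2::labs(x = "centre-of-mass distance (nm)", y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.distance_series
#' @method autoplot contact_series
#' @export
autoplot.contact_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$n_contacts)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (ns)", y = "inter-protomer residue contacts") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.distance_series
#' @method autoplot angle_series
#' @export
autoplot.angle_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$angle_nm_vs_ref,
                                       colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "N+M axis angle vs reference (deg)") +
    ggplot2::theme_minimal()
}
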