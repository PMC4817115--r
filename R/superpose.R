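#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mobile` and `reference` over a set of fit atoms (the Kabsch/SVD
#' solution). Used for CTD-anchored protomer alignment and for the pairwise
#' RMSD matrix behind frame clustering.
#'
#' @param mobile,reference `n x 3` coordinate matrices (nm).
#' @param fit_indices Atom indices (rows) used for the fit; default all rows.
#'   At least 3 non-collinear atoms are required.
#' @return A `rigid_transform`: list with `rotation` (3x3 proper rotation),
#'   `translation` (length-3, nm) and `rmsd` (nm) over the fit atoms. Apply
#'   it with [apply_transform()]: `x %*% t(R) + t`.
#' @export
kabsch_superpose <- function(mobile, reference, fit_indices = seq_len(nrow(mobile))) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (max(fit_indices) > nrow(mobile) || max(fit_indices) > nrow(reference)) {
    stop_allodyn("fit_indices out of range for the coordinate arrays",
                 class = "allodyn_selection_error")
  }
  xm <- mobile[fit_indices, , drop = FALSE]
  xr <- reference[fit_indices, , drop = FALSE]
  if (nrow(xm) < 3L) {
    stop_allodyn("need at least 3 fit atoms for a rigid superposition",
                 class = "allodyn_degenerate_fit"
    )
  }
  cm <- colMeans(xm); cr <- colMeans(xr)
  a <- sweep(xm, 2, cm); b <- sweep(xr, 2, cr)
  # collinear fit set leaves the rotation about the line undetermined
  if (qr(a)$rank < 2L) {
    stop_allodyn("fit atoms are collinear; superposition is underdetermined",
                 class = "allodyn_degenerate_fit")
  }
  h <- crossprod(a, b)                 # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rmsd = %.4g nm\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param coords An `n x 3` matrix (nm).
#' @param transform A `rigid_transform` from [kabsch_superpose()].
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2, -transform$translation)
}

#' RMSD after optimal superposition
#' @inheritParams kabsch_superpose
#' @return RMSD in nm.
#' @export
fit_rmsd <- function(mobile, reference, fit_indices = seq_len(nrow(mobile))) {
  kabsch_superpose(mobile, reference, fit_indices)$rmsd
}

random_rotation <- function() {
  # QR of a Gaussian matrix with sign correction gives a Haar-uniform rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
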