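# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately written in a different style (plain loops,
# textbook formulas) from the package implementations they check.

# minimal topology: one 4-atom backbone residue per (chain, residue id)
toy_topology <- function(chains, residues_per_chain) {
  rows <- list()
  for (ch in chains) {
    for (r in seq_len(residues_per_chain)) {
      rows[[paste(ch, r)]] <- tibble::tibble(
        chain_id = ch, residue_id = r, residue_name = "GLY",
        atom_name = c("N", "CA", "C", "O"),
        element = c("N", "C", "C", "O")
      )
    }
  }
  dplyr::bind_rows(rows)
}

# ensemble with explicit coordinates: coords_list is a list of (atoms x 3)
toy_ensemble <- function(topology, coords_list) {
  arr <- array(0, dim = c(nrow(topology), 3, length(coords_list)))
  for (i in seq_along(coords_list)) arr[, , i] <- coords_list[[i]]
  trajectory_ensemble(topology, arr)
}

# random structured frame: residues spread out so distances are O(1) nm
random_frame <- function(n_atoms, scale = 1) {
  matrix(stats::rnorm(n_atoms * 3, sd = scale), ncol = 3)
}

# --- independent oracles -------------------------------------------------

# textbook two-pass Pearson correlation
pearson_two_pass <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force residue contact count: nested loops over residues and atoms
brute_contacts <- function(ensemble, frame, chain_a = "A", chain_b = "B",
                           cutoff = 0.6) {
  top <- ensemble$topology
  xyz <- frame_coords(ensemble, frame)
  res_a <- unique(top$residue_id[top$chain_id == chain_a])
  res_b <- unique(top$residue_id[top$chain_id == chain_b])
  count <- 0L
  for (ra in res_a) {
    ia <- which(top$chain_id == chain_a & top$residue_id == ra)
    for (rb in res_b) {
      ib <- which(top$chain_id == chain_b & top$residue_id == rb)
      found <- FALSE
      for (i in ia) {
        for (j in ib) {
          if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff) found <- TRUE
        }
      }
      if (found) count <- count + 1L
    }
  }
  count
}

# naive re-implementation of the Daura leader algorithm, list-based
brute_daura <- function(m, cutoff = 0.2) {
  pool <- seq_len(nrow(m))
  clusters <- list(); centers <- integer(0)
  while (length(pool) > 0) {
    best_center <- NA_integer_; best_n <- -1L
    for (i in pool) {
      nb <- 0L
      for (j in pool) if (j != i && m[i, j] < cutoff) nb <- nb + 1L
      if (nb > best_n) { best_n <- nb; best_center <- i }
    }
    members <- best_center
    for (j in pool) {
      if (j != best_center && m[best_center, j] < cutoff) members <- c(members, j)
    }
    clusters[[length(clusters) + 1L]] <- sort(members)
    centers <- c(centers, best_center)
    pool <- setdiff(pool, members)
  }
  list(clusters = clusters, centers = centers)
}

# power iteration on the gyration tensor: independent largest-eigenvector
# solver for the principal-axis cross-check
power_axis <- function(coords, iters = 500) {
  x <- sweep(coords, 2, colMeans(coords))
  g <- t(x) %*% x / nrow(x)
  v <- c(1, 1, 1) / sqrt(3)
  for (i in seq_len(iters)) {
    v <- g %*% v
    v <- v / sqrt(sum(v^2))
  }
  as.vector(v)
}

# standard CTD/NM selections for a generated dimer simulation
sim_selections <- function(sim) {
  dm <- sim$truth$domain_map
  nd <- length(unique(dm$domain))
  dn <- unique(dm$domain)
  mk <- function(ch, doms, filt) residue_selection(
    dm[dm$chain_id == ch & dm$domain %in% doms, c("chain_id", "residue_id")],
    atom_filter = filt
  )
  list(
    ctd = list(A = mk("A", dn[nd], "backbone"), B = mk("B", dn[nd], "backbone")),
    nm = list(A = mk("A", dn[-nd], "c_alpha"), B = mk("B", dn[-nd], "c_alpha")),
    ntd = list(A = mk("A", dn[1], "backbone"), B = mk("B", dn[1], "backbone"))
  )
}

# Haar-ish random proper rotation for invariance tests
random_rotation_test <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
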