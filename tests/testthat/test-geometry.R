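test_that("centre-of-mass distances follow plain geometry", {
  top <- toy_topology(c("A", "B"), 1)
  xyz <- matrix(0, 8, 3)
  xyz[5:8, 1] <- 3; xyz[5:8, 2] <- 4   # chain B residue at (3, 4, 0)
  ens <- toy_ensemble(top, list(xyz))

  sa <- residue_selection("A:1"); sb <- residue_selection("B:1")
  d <- com_distance(ens, sa, sb)
  expect_equal(d$distance, 5)                       # 3-4-5 triangle
  expect_equal(com_distance(ens, sa, sa)$distance, 0)

  h <- attr(d, "histogram")
  expect_equal(sum(h$frequency), 1)
})

test_that("histogram frequencies always sum to one", {
  set.seed(41)
  for (bw in c(0.01, 0.05, 0.3)) {
    h <- allodyn:::distance_histogram(runif(200, 2, 6), bw)
    expect_equal(sum(h$frequency), 1)
  }
})

test_that("an imposed separation step shifts the distance-histogram peak by that amount", {
  sim <- generate_dimer_trajectory(
    dimer_sim_spec(n_frames = 400, ntd_separation_drift = 0.5, seed = 13)
  )
  sel <- sim_selections(sim)
  d <- com_distance(sim$ensemble, sel$ntd$A, sel$ntd$B)
  n <- nrow(d)
  early <- distance_peak(d, frames = 1:(n / 2))
  late <- distance_peak(d, frames = (n / 2 + 1):n)
  # peak positions are quantised to the 0.05 nm bin grid
  expect_lte(abs((late - early) - 0.5), 0.05 + 1e-9)
})

test_that("contact counting respects the strict 0.6 nm boundary", {
  top <- toy_topology(c("A", "B"), 1)
  place <- function(gap) {
    xyz <- matrix(0, 8, 3)
    xyz[1:4, 1] <- c(0, -0.1, -0.2, -0.3)      # closest A atom at x = 0
    xyz[5:8, 1] <- gap + c(0, 0.1, 0.2, 0.3)   # closest B atom at x = gap
    xyz[, 2] <- rep(c(0, 0, 0.1, 0.1), 2)
    xyz[1:4, 2] <- 0; xyz[5:8, 2] <- 0
    xyz
  }
  just_inside <- toy_ensemble(top, list(place(0.59)))
  at_cutoff <- toy_ensemble(top, list(place(0.60)))
  expect_equal(interprotomer_contacts(just_inside)$n_contacts, 1L)
  expect_equal(interprotomer_contacts(at_cutoff)$n_contacts, 0L)
  expect_error(interprotomer_contacts(just_inside, chain_b = "C"),
               class = "allodyn_selection_error")
})

test_that("vectorised contact counts equal the brute-force double loop", {
  set.seed(42)
  top <- toy_topology(c("A", "B"), 20)
  for (rep in 1:3) {
    # residues scattered so that some pairs straddle the cutoff
    frames <- list(random_frame(nrow(top), scale = 0.8))
    ens <- toy_ensemble(top, frames)
    fast <- interprotomer_contacts(ens)$n_contacts
    expect_identical(fast, brute_contacts(ens, 1))
    # monotone in the cutoff
    looser <- interprotomer_contacts(ens, cutoff = 0.9)$n_contacts
    expect_gte(looser, fast)
  }
})

test_that("principal axes match construction and an independent eigensolver", {
  line <- cbind(seq(0, 5, length.out = 10), 0, 0)
  ax <- principal_axis(line, hint = c(1, 0, 0))
  expect_equal(ax, c(1, 0, 0), tolerance = 1e-10)
  expect_equal(principal_axis(line, hint = c(-1, 0, 0)), c(-1, 0, 0),
               tolerance = 1e-10)

  # symmetric 10:1 slab in the xy-plane: covariances vanish by construction
  slab <- cbind(rep(seq(-5, 5, length.out = 10), 2),
                rep(c(-0.5, 0.5), each = 10), 0)
  expect_lt(acos(abs(principal_axis(slab)[1])), 1e-6)

  for (i in 1:5) {
    cloud <- matrix(rnorm(60), ncol = 3) %*% diag(c(3, 1.5, 0.5))
    v <- principal_axis(cloud, hint = c(1, 1, 1))
    w <- power_axis(cloud)
    expect_equal(abs(sum(v * w)), 1, tolerance = 1e-8)
  }

  sphere_like <- rbind(diag(3), -diag(3)) * 2
  expect_error(principal_axis(sphere_like), class = "allodyn_degenerate_axis")
  expect_error(principal_axis(matrix(rnorm(6), 2)), class = "allodyn_degenerate_axis")
})

test_that("protomer angles are zero against an identical reference", {
  sim <- generate_dimer_trajectory(
    dimer_sim_spec(n_frames = 10, positional_noise_sigma = 0, seed = 1)
  )
  sel <- sim_selections(sim)
  ang <- protomer_angles(sim$ensemble, sim$reference,
                         ctd_selections = sel$ctd, nm_selections = sel$nm,
                         start_fraction = 0)
  expect_true(all(abs(ang$angle_nm_vs_ref) < 1e-8))
  asym <- angle_asymmetry(ang)
  expect_true(all(abs(asym$b_minus_a) < 1e-8))
})

test_that("a rigid 20-degree rotation of protomer B is read back exactly", {
  sim <- generate_dimer_trajectory(
    dimer_sim_spec(n_frames = 2, positional_noise_sigma = 0, seed = 1)
  )
  sel <- sim_selections(sim)
  ens <- sim$ensemble
  # rotate all of chain B rigidly about an axis orthogonal to its NM axis;
  # the CTD anchor moves with it, so CTD superposition undoes nothing global
  top <- ens$topology
  ib <- which(top$chain_id == "B")
  nm_idx <- resolve_selection(sel$nm$B, ens)
  v <- principal_axis(frame_coords(ens, 1)[nm_idx, ])
  u <- c(1, 0, 0) - sum(c(1, 0, 0) * v) * v; u <- u / sqrt(sum(u^2))
  rot <- allodyn:::rotation_about(u, 20)
  for (f in 1:2) {
    xb <- ens$coords[ib, , f]
    ctr <- colMeans(xb)
    ens$coords[ib, , f] <- sweep(sweep(xb, 2, ctr) %*% t(rot), 2, ctr, `+`)
  }
  ang <- protomer_angles(ens, sim$reference,
                         ctd_selections = sel$ctd, nm_selections = sel$nm,
                         start_fraction = 0)
  a <- ang[ang$chain == "A", ]$angle_nm_vs_ref
  b <- ang[ang$chain == "B", ]$angle_nm_vs_ref
  expect_true(all(abs(a) < 1e-6))
  expect_true(all(abs(b) < 1e-6))  # CTD-anchored fit removes the rigid motion
})

test_that("angles are invariant under global rigid motion of each frame", {
  sim <- generate_dimer_trajectory(
    dimer_sim_spec(n_frames = 20, protomer_b_twist = 15, seed = 6)
  )
  sel <- sim_selections(sim)
  base <- protomer_angles(sim$ensemble, sim$reference,
                          ctd_selections = sel$ctd, nm_selections = sel$nm)
  moved <- sim$ensemble
  set.seed(44)
  for (f in seq_len(n_frames(moved))) {
    q <- random_rotation_test()
    moved$coords[, , f] <- sweep(moved$coords[, , f] %*% t(q), 2, -rnorm(3, sd = 3))
  }
  shifted <- protomer_angles(moved, sim$reference,
                             ctd_selections = sel$ctd, nm_selections = sel$nm)
  expect_equal(shifted$angle_nm_vs_ref, base$angle_nm_vs_ref, tolerance = 1e-6)
})

test_that("the linear twist schedule appears in the B - A asymmetry series", {
  sim <- generate_dimer_trajectory(
    dimer_sim_spec(n_frames = 60, positional_noise_sigma = 0,
                   protomer_b_twist = 30, seed = 2)
  )
  sel <- sim_selections(sim)
  ang <- protomer_angles(sim$ensemble, sim$reference,
                         ctd_selections = sel$ctd, nm_selections = sel$nm,
                         start_fraction = 0)
  asym <- angle_asymmetry(ang)
  sched <- sim$truth$twist_schedule$angle_deg[asym$frame]
  expect_equal(asym$b_minus_a, sched, tolerance = 1e-6)
})
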