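make_two_residue_ensemble <- function(distances) {
  # two CA-bearing residues on the x axis at the given separations
  top <- toy_topology("A", 2)
  frames <- lapply(distances, function(d) {
    xyz <- matrix(0, 8, 3)
    xyz[5:8, 1] <- d  # residue 2 shifted along x
    xyz + cbind(0, rep(c(0, 0.01, 0.02, 0.03), 2), 0)  # break exact overlap
  })
  toy_ensemble(top, frames)
}

test_that("CP is zero on a frozen trajectory and matches hand variance", {
  frozen <- make_two_residue_ensemble(rep(1.5, 4))
  sel <- residue_selection("A:1-2")
  cp <- compute_cp(frozen, sel, equilibration_fraction = 0)
  expect_true(all(cp$values == 0))

  # distances {1, 1, 2, 2}: population variance 0.25 nm^2
  ens <- make_two_residue_ensemble(c(1, 1, 2, 2))
  cp <- compute_cp(ens, sel, equilibration_fraction = 0)
  expect_equal(cp$values[1, 2], 0.25, tolerance = 1e-12)
  expect_equal(cp$values[2, 1], 0.25, tolerance = 1e-12)
  expect_equal(diag(cp$values), c("A:1" = 0, "A:2" = 0))
  expect_equal(cp$frames_used, 4L)
})

test_that("the equilibration discard drops leading frames", {
  ens <- make_two_residue_ensemble(c(99, 1, 1, 2, 2))  # first frame is junk
  sel <- residue_selection("A:1-2")
  cp <- compute_cp(ens, sel, equilibration_fraction = 0.2)
  expect_equal(cp$values[1, 2], 0.25, tolerance = 1e-12)
  expect_equal(cp$equilibration_discarded, 0.2)
  expect_error(compute_cp(ens, sel, equilibration_fraction = 0.9),
               class = "allodyn_insufficient_data")
  expect_error(compute_cp(ens, sel, equilibration_fraction = 1),
               class = "allodyn_domain_error")
})

test_that("CP is invariant under per-frame rigid motions and needs no alignment", {
  set.seed(31)
  sim <- generate_dimer_trajectory(dimer_sim_spec(n_frames = 60, seed = 2))
  sel <- residue_selection(unique(sim$ensemble$topology[, c("chain_id", "residue_id")]))
  cp0 <- compute_cp(sim$ensemble, sel)

  moved <- sim$ensemble
  for (f in seq_len(n_frames(moved))) {
    q <- random_rotation_test()
    shift <- rnorm(3, sd = 5)
    moved$coords[, , f] <- sweep(moved$coords[, , f] %*% t(q), 2, -shift)
  }
  cp1 <- compute_cp(moved, sel)
  expect_lt(max(abs(cp1$values - cp0$values)), 1e-12)
})

test_that("CP matrices are symmetric, non-negative, zero on the diagonal", {
  sim <- generate_dimer_trajectory(dimer_sim_spec(n_frames = 40, seed = 9))
  sel <- residue_selection(unique(sim$ensemble$topology[, c("chain_id", "residue_id")]))
  cp <- compute_cp(sim$ensemble, sel)
  expect_identical(cp$values, t(cp$values))
  expect_true(all(cp$values >= 0))
  expect_true(all(diag(cp$values) == 0))
})

test_that("within-block CP is below cross-block CP when a pair fluctuates", {
  spec <- dimer_sim_spec(
    n_frames = 1500, positional_noise_sigma = 0.01,
    interdomain_sigma = data.frame(chain_a = "A", domain_a = "NTD",
                                   chain_b = "B", domain_b = "CTD",
                                   sigma = 0.08),
    seed = 3
  )
  sim <- generate_dimer_trajectory(spec)
  sel <- residue_selection(unique(sim$ensemble$topology[, c("chain_id", "residue_id")]))
  cp <- compute_cp(sim$ensemble, sel)

  dm <- sim$truth$domain_map
  lab <- function(ch, dom) paste0(ch, ":", dm$residue_id[dm$chain_id == ch & dm$domain == dom])
  within_a <- cp$values[lab("A", "NTD"), lab("A", "NTD")]
  cross <- cp$values[lab("A", "NTD"), lab("B", "CTD")]
  expect_lt(mean(within_a[upper.tri(within_a)]), mean(cross))
  # and the cross block mean recovers sigma^2 + 2 sigma_pos^2
  expect_equal(mean(cross), 0.08^2 + 2 * 0.01^2, tolerance = 0.2)
})

test_that("replica averaging is the element-wise mean and pools provenance", {
  ens1 <- make_two_residue_ensemble(c(1, 1, 2, 2))   # CP12 = 0.25
  ens2 <- make_two_residue_ensemble(c(1.5, 1.5, 1.5, 1.5))  # CP12 = 0
  sel <- residue_selection("A:1-2")
  cp1 <- compute_cp(ens1, sel, equilibration_fraction = 0)
  cp2 <- compute_cp(ens2, sel, equilibration_fraction = 0)

  expect_equal(average_cp(list(cp1))$values, cp1$values)
  avg <- average_cp(list(cp1, cp2))
  expect_equal(avg$values[1, 2], 0.125)
  expect_equal(avg$replicas_averaged, 2L)

  other_top <- toy_topology("B", 2)
  other_ens <- toy_ensemble(other_top, list(random_frame(8), random_frame(8)))
  cp_other <- compute_cp(other_ens, residue_selection("B:1-2"),
                         equilibration_fraction = 0)
  expect_error(average_cp(list(cp1, cp_other)), class = "allodyn_incompatible")
  expect_error(difference_cp(cp1, cp_other), class = "allodyn_incompatible")
})

test_that("averaging replicas moves CP toward ground truth", {
  truth <- 0.06^2 + 2 * 0.01^2
  spec_for <- function(s) dimer_sim_spec(
    n_frames = 300, positional_noise_sigma = 0.01,
    interdomain_sigma = data.frame(chain_a = "A", domain_a = "NTD",
                                   chain_b = "B", domain_b = "CTD", sigma = 0.06),
    seed = s
  )
  sel_of <- function(sim) residue_selection(
    unique(sim$ensemble$topology[, c("chain_id", "residue_id")]))
  wins <- 0L; total <- 0L
  for (trip in 1:6) {
    cps <- lapply(3 * (trip - 1) + 1:3, function(s) {
      sim <- generate_dimer_trajectory(spec_for(s))
      compute_cp(sim$ensemble, sel_of(sim))
    })
    avg <- average_cp(cps)
    dm <- generate_dimer_trajectory(spec_for(1))$truth$domain_map
    lab <- function(ch, dom) paste0(ch, ":", dm$residue_id[dm$chain_id == ch & dm$domain == dom])
    ii <- lab("A", "NTD"); jj <- lab("B", "CTD")
    err_avg <- abs(avg$values[ii, jj] - truth)
    err_single <- abs(cps[[1]]$values[ii, jj] - truth)
    wins <- wins + sum(err_avg <= err_single)
    total <- total + length(err_avg)
  }
  expect_gte(wins / total, 0.6)
})

test_that("difference matrices are antisymmetric in their arguments", {
  ens1 <- make_two_residue_ensemble(c(1, 1, 2, 2))
  ens2 <- make_two_residue_ensemble(c(1, 1.2, 1.4, 1.6))
  sel <- residue_selection("A:1-2")
  cp1 <- compute_cp(ens1, sel, equilibration_fraction = 0)
  cp2 <- compute_cp(ens2, sel, equilibration_fraction = 0)

  expect_true(all(difference_cp(cp1, cp1)$values == 0))
  d12 <- difference_cp(cp1, cp2)
  d21 <- difference_cp(cp2, cp1)
  expect_equal(d12$values, -d21$values)
})

test_that("extra cross-protomer fluctuation in the complex shows as a negative block", {
  base_spec <- function(sig, seed) dimer_sim_spec(
    n_frames = 800, positional_noise_sigma = 0.01,
    interdomain_sigma = data.frame(chain_a = "A", domain_a = "NTD",
                                   chain_b = "B", domain_b = "CTD", sigma = sig),
    seed = seed
  )
  ref_sim <- generate_dimer_trajectory(base_spec(0.02, 11))
  cplx_sim <- generate_dimer_trajectory(base_spec(0.10, 12))
  sel <- residue_selection(unique(ref_sim$ensemble$topology[, c("chain_id", "residue_id")]))
  dmat <- difference_cp(compute_cp(ref_sim$ensemble, sel),
                        compute_cp(cplx_sim$ensemble, sel))
  dm <- ref_sim$truth$domain_map
  lab <- function(ch, dom) paste0(ch, ":", dm$residue_id[dm$chain_id == ch & dm$domain == dom])
  block <- dmat$values[lab("A", "NTD"), lab("B", "CTD")]
  expect_true(all(block < 0))
})

test_that("tidy and glance summarise CP by pair and chain block", {
  sim <- generate_dimer_trajectory(dimer_sim_spec(n_frames = 30, seed = 4))
  sel <- residue_selection(unique(sim$ensemble$topology[, c("chain_id", "residue_id")]))
  cp <- compute_cp(sim$ensemble, sel)
  long <- tidy(cp)
  expect_equal(nrow(long), nrow(cp$values)^2)
  gl <- glance(cp)
  expect_setequal(paste(gl$chain_i, gl$chain_j),
                  c("A A", "A B", "B A", "B B"))
  p <- autoplot(difference_cp(cp, cp))
  expect_s3_class(p, "ggplot")
})
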