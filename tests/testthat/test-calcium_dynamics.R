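test_that("receptor balance matches closed-form values", {
  # direct substitution at full receptor occupancy
  expect_equal(receptor_rhs(1, 0, k_r = 0.5, k_d = 0.34), -0.34)
  # hormone-free steady state r* = k_r / (k_r + k_d)
  r_star <- 0.5 / 0.84
  expect_equal(receptor_rhs(r_star, 0, k_r = 0.5, k_d = 0.34), 0)
  expect_equal(r_star, 0.5952, tolerance = 1e-4)
  # empty-receptor limit: binding terms vanish
  expect_equal(receptor_rhs(0, 100, k_r = 0.5), 0.5)
  expect_error(receptor_rhs(1.2, 0, 0.5), "\\[0, 1\\]")
  expect_error(receptor_rhs(0.5, -1, 0.5), "negative")
})

test_that("IP3 balance gates on calcium and couples symmetrically", {
  # calcium feedback gate closed
  expect_equal(ip3_rhs(0.2, 0.5, 0, 5, neighbors = c(0.1, 0.3),
                       k_IP3 = 0.55, G_ij = 5),
               -0.8 * 0.2 - 5 * ((0.2 - 0.1) + (0.2 - 0.3)))
  # uncoupled case: no junction term
  expect_equal(ip3_rhs(0.2, 0.5, 0.5, 0, neighbors = c(1, 9),
                       k_IP3 = 0.55, G_ij = 0),
               -0.8 * 0.2)
  # equilibrated junctions: coupling vanishes at any strength
  a <- ip3_rhs(0.2, 0.5, 0.5, 3, neighbors = c(0.2, 0.2), k_IP3 = 0.55,
               G_ij = 0)
  b <- ip3_rhs(0.2, 0.5, 0.5, 3, neighbors = c(0.2, 0.2), k_IP3 = 0.55,
               G_ij = 50)
  expect_equal(a, b)
})

test_that("gap-junction exchange conserves IP3 pairwise", {
  # the flux i -> j equals minus the flux j -> i for random pairs
  set.seed(42)
  for (k in 1:25) {
    gi <- runif(1, 0, 5)
    ip_i <- runif(1, 0, 2); ip_j <- runif(1, 0, 2)
    flux_ij <- -gi * (ip_i - ip_j)   # into cell i from j
    flux_ji <- -gi * (ip_j - ip_i)
    expect_equal(flux_ij + flux_ji, 0)
  }
})

test_that("calcium balance matches hand evaluation and limits", {
  # bound-receptor limit g = 1: only the pump remains
  expect_equal(calcium_rhs(0.3, 500.2, g = 1, IP3 = 0.5),
               -0.082 * 0.09 / (0.15^2 + 0.09))
  # empty-store limit: release and leak vanish, rate is non-positive
  expect_lte(calcium_rhs(500.2, 500.2, g = 0, IP3 = 2), 0)
  # hand evaluation with nominal constants at CaI = k2
  v <- calcium_rhs(0.15, 500.2, g = 0, IP3 = 0)
  expect_equal(v, 0.00015 * (500.2 - 0.15) - 0.082 / 2)
  expect_equal(v, 0.0340, tolerance = 2e-3)
  expect_error(calcium_rhs(600, 500.2, 0.5, 0.1), "state violation")
})

test_that("IP3R balance has the stated fixed points", {
  expect_equal(ip3r_rhs(1, 5), -0.01)
  expect_equal(ip3r_rhs(0.3, 0), -0.01)
  # steady state at CaI = 1: g* = 1 - F / (E CaI^4)
  expect_equal(ip3r_rhs(0.99, 1), 0)
})

test_that("module rate functions agree with a straight-line oracle", {
  # independent re-implementation of the four rate laws, written out
  # term by term, compared on random states to near machine precision
  set.seed(7)
  for (k in 1:100) {
    r <- runif(1); g <- runif(1); H <- runif(1, 0, 20)
    ip <- runif(1, 0, 3); ca <- runif(1, 0, 2)
    kr <- runif(1, 0.5, 1); kip <- runif(1, 0.5, 0.6)
    nb <- runif(2, 0, 3); gij <- runif(1, 0, 5)
    o_r <- kr * (1 - r) - 0.34 * r - 1 * H * r
    o_ip <- kip * H * r / (0.45 + r) * ca / (ca + 1) - 0.8 * ip -
      gij * ((ip - nb[1]) + (ip - nb[2]))
    o_ca <- (1 - g) * (0.20 * ip^4 / (1 + ip)^4 + 0.00015) * (500.2 - ca) -
      0.082 * ca^2 / (0.15^2 + ca^2)
    o_g <- 1 * ca^4 * (1 - g) - 0.01
    expect_equal(receptor_rhs(r, H, kr), o_r, tolerance = 1e-12)
    expect_equal(ip3_rhs(ip, r, ca, H, nb, kip, gij), o_ip,
                 tolerance = 1e-12)
    expect_equal(calcium_rhs(ca, 500.2, g, ip), o_ca, tolerance = 1e-12)
    expect_equal(ip3r_rhs(g, ca), o_g, tolerance = 1e-12)
  }
})

test_that("an unstimulated cell relaxes without spiking", {
  tr <- single_cell_trajectory(H = 0, t_end = 2000)
  sp <- detect_spikes(tr[, c("time", "CaI")])
  expect_length(sp$times, 0)
  # trajectory settles: last 100 s nearly constant
  tail_ca <- tr$CaI[tr$time > 1900]
  expect_lt(diff(range(tail_ca)), 1e-3)
})

test_that("stimulated cells oscillate and identical cells stay identical", {
  tr <- single_cell_trajectory(H = 4, t_end = 1500)
  sp <- detect_spikes(tr[, c("time", "CaI")])
  expect_gt(length(sp$times), 5)
  # symmetry: same parameters and stimulus give the same trace
  tr2 <- single_cell_trajectory(H = 4, t_end = 1500)
  expect_identical(tr$CaI, tr2$CaI)
})
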