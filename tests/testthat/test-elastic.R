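pair_network <- function(d0 = 10, gamma = 2) {
  net <- list(beads = tibble::tibble(bead = 1:2, residue = 1:2,
                                     role = "ca", x = c(0, d0), y = 0,
                                     z = 0),
              springs = tibble::tibble(from = 1L, to = 2L, rest = d0),
              gamma = gamma, cutoff = d0 + 2, id = "pair")
  class(net) <- "ln_network"
  net
}

test_that("network construction places springs strictly inside the cutoff", {
  s <- as_structure(rbind(c(0, 0, 0), c(5, 0, 0)))
  net <- build_network(s, cutoff = 9, representation = "ca_only")
  expect_equal(nrow(net$springs), 1)
  expect_equal(net$springs$rest, 5)
  s2 <- as_structure(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(nrow(build_network(s2, 9, representation = "ca_only")$springs), 0)
  # brute-force spring count on a toy globule
  g <- make_globule(25, seed = 1)
  net_g <- build_network(g, cutoff = 9, representation = "ca_only")
  D <- as.matrix(dist(cbind(g$x, g$y, g$z)))
  expect_equal(nrow(net_g$springs), sum(D[upper.tri(D)] < 9))
})

test_that("side-chain beads follow the residue size rules", {
  atoms <- dplyr::bind_rows(
    tibble::tibble(model = 1L, residue = 1L, resname = "GLY",
                   atom = c("N", "CA", "C", "O"),
                   x = c(-1, 0, 1, 2), y = 0, z = 0),
    tibble::tibble(model = 1L, residue = 2L, resname = "ALA",
                   atom = c("N", "CA", "C", "O", "CB"),
                   x = 3 + c(-1, 0, 1, 2, 0), y = c(0, 0, 0, 0, 1.5),
                   z = 0),
    tibble::tibble(model = 1L, residue = 3L, resname = "LEU",
                   atom = c("N", "CA", "C", "O", "CB", "CG", "CD1",
                            "CD2"),
                   x = 7 + c(-1, 0, 1, 2, 0, 0.5, 1, 0),
                   y = c(0, 0, 0, 0, 1.5, 2.8, 3.9, 4.1), z = 0),
    tibble::tibble(model = 1L, residue = 4L, resname = "TRP",
                   atom = c("N", "CA", "C", "O", "CB", "CG", "CD1",
                            "CD2", "NE1", "CE2", "CE3", "CZ2"),
                   x = 11 + c(-1, 0, 1, 2, 0, 0.4, 1, 0.2, 1.3, 0.9,
                              0.1, 1),
                   y = c(0, 0, 0, 0, 1.5, 2.8, 3.7, 3.9, 4.9, 5.0, 5.1,
                         6.1), z = 0))
  net <- build_network(loopnlock:::new_structure(atoms, "toy"))
  counts <- table(net$beads$residue)
  expect_equal(as.integer(counts), c(1, 1, 2, 3))  # GLY/ALA/LEU/TRP
})

test_that("the BD integrator matches equipartition for an isolated pair", {
  traj <- brownian_dynamics(pair_network(), n_steps = 400000, dt = 0.01,
                            temperature = 300, friction = 1, seed = 1,
                            save_every = 5)
  d <- sqrt(rowSums((traj$frames[, 1:3] - traj$frames[, 4:6])^2))
  kT <- 0.0019872041 * 300
  expect_equal(var(d), kT / 2, tolerance = 0.05)  # gamma = 2
})

test_that("BD is exact at zero temperature and reproducible under a seed", {
  net <- pair_network()
  cold <- brownian_dynamics(net, n_steps = 2000, temperature = 0,
                            seed = 1)
  expect_equal(max(abs(cold$frames[, 1])), 0)
  expect_equal(max(abs(cold$frames[, 4] - 10)), 0)
  a <- brownian_dynamics(net, n_steps = 5000, seed = 42)
  b <- brownian_dynamics(net, n_steps = 5000, seed = 42)
  expect_identical(a$frames, b$frames)
  expect_error(brownian_dynamics(net, n_steps = 5000, dt = 10, seed = 1),
               "diverged")
})

test_that("force constants rank buried residues above chain ends", {
  ranks_ok <- 0
  for (seed in 1:3) {
    g <- make_globule(20, seed = seed)
    prof <- rigidity_profile(g, representation = "ca_only",
                             n_steps = 30000, seed = seed + 10)
    # the most buried residue (smallest mean distance to the others)
    xyz <- cbind(g$x, g$y, g$z)
    burial <- rowMeans(as.matrix(dist(xyz)))
    buried <- which.min(burial)
    terminal <- if (burial[1] > burial[20]) 1 else 20
    ranks_ok <- ranks_ok + (prof$k[buried] > prof$k[terminal])
  }
  expect_gte(ranks_ok, 2)
})

test_that("doubling gamma approximately doubles the force constants", {
  g <- make_globule(15, seed = 4)
  k1 <- rigidity_profile(g, gamma = 0.6, representation = "ca_only",
                         n_steps = 40000, seed = 5)$k
  k2 <- rigidity_profile(g, gamma = 1.2, representation = "ca_only",
                         n_steps = 40000, seed = 5)$k
  expect_equal(median(k2 / k1), 2, tolerance = 0.15)
})

test_that("Z-scored profiles have mean zero, unit sd and zero-clipped k'", {
  prof <- rigidity_zscores(tibble::tibble(residue = 1:50,
                                          k = rexp(50) + 0.1))
  expect_equal(mean(prof$k_z), 0, tolerance = 1e-12)
  expect_equal(sd(prof$k_z), 1, tolerance = 1e-12)
  expect_true(all(prof$k_prime >= 0))
  expect_equal(prof$k_prime[prof$k_z > 0], prof$k_z[prof$k_z > 0])
})

test_that("frozen trajectories are rejected", {
  net <- pair_network()
  traj <- brownian_dynamics(net, n_steps = 1000, temperature = 0,
                            seed = 1)
  expect_error(force_constants(traj), "frozen|variance")
})
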