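test_that("planted loops produce the promised contacts and packing", {
  s <- make_loop_protein(50, loops = data.frame(start = 10, end = 35,
                                                gap = 5.0), seed = 1)
  cm <- compute_contacts(s)
  expect_true(any(cm$i == 10 & cm$j == 35))
  expect_equal(35 - 10 + 1, 26)
  d <- loopnlock:::residue_pair_dists(s, 10, 35)[1, 1]
  expect_lt(abs(d - 5.0), 0.5)
  # default gap: lock residues get >= 4 neighbours within 6 A
  s2 <- make_loop_protein(50, loops = data.frame(start = 10, end = 35),
                          seed = 2)
  conn <- residue_connectivity(s2)
  expect_true(all(conn$connectivity[c(10, 35)] >= 4))
  # no loops: extended chain, empty metric contact map
  s0 <- make_loop_protein(30, seed = 3)
  expect_equal(nrow(compute_contacts(s0)), 0)
  # determinism
  expect_identical(make_loop_protein(40, data.frame(start = 5, end = 30),
                                     seed = 9),
                   make_loop_protein(40, data.frame(start = 5, end = 30),
                                     seed = 9))
  # infeasible geometry errors out
  expect_error(make_loop_protein(40, data.frame(start = 5, end = 30,
                                                gap = 1)), "gap")
})

test_that("chains are self-avoiding with near-ideal virtual bonds", {
  for (seed in 1:3) {
    s <- make_loop_protein(100, loops = data.frame(start = c(10, 60),
                                                   end = c(40, 90)),
                           seed = seed)
    xyz <- as.matrix(s[s$model == 1, c("x", "y", "z")])
    expect_gte(loopnlock:::min_nonbonded_dist(xyz), 3.0)
    bonds <- sqrt(rowSums(diff(xyz)^2))
    expect_gt(mean(abs(bonds - 3.8) < 0.7), 0.9)
  }
})

test_that("ensembles realise the planted persistence exactly", {
  s <- make_loop_protein(50, loops = data.frame(start = 8, end = 33),
                         seed = 4)
  for (p in c(0.5, 0.7, 1.0)) {
    ens <- make_ensemble(s, 10, jitter = 0.05, seed = 5,
                         persistence = data.frame(i = 8, j = 33,
                                                  persistence = p))
    frac <- mean(vapply(1:10, function(m)
      loopnlock:::residue_pair_dists(ens, 8, 33, model = m)[1, 1] <= 6,
      logical(1)))
    expect_equal(frac, p)
  }
  # zero jitter: models identical apart from planted breaks
  ens0 <- make_ensemble(s, 4, jitter = 0, seed = 6)
  m1 <- ens0[ens0$model == 1, c("x", "y", "z")]
  m4 <- ens0[ens0$model == 4, c("x", "y", "z")]
  expect_equal(as.data.frame(m1), as.data.frame(m4))
  expect_error(make_ensemble(s, 5, persistence = data.frame(
    i = 8, j = 33, persistence = 1.2)), "persistence")
  expect_error(make_ensemble(s, 1), "n_models")
})

test_that("rate tables follow the planted linear model", {
  coh <- synth_folding_cohort(10, seed = 7)
  vals <- vapply(seq_len(nrow(coh)), function(p)
    total_contact_distance(coh$core[[p]]$contacts, coh$L[p]), numeric(1))
  # zero noise: exact line, r^2 = 1
  r0 <- make_rate_table(coh, noise_sd = 0, seed = 8)
  expect_equal(r0$ln_kf, -100 * vals + 10)
  expect_equal(cor(vals, r0$ln_kf)^2, 1)
  # seed stability
  expect_identical(make_rate_table(coh, seed = 9),
                   make_rate_table(coh, seed = 9))
  # closed-form expected r^2 at n = 200 synthetic metric values
  withr::local_seed(10)
  x <- runif(200, 0.02, 0.12)
  fake <- tibble::tibble(protein_id = as.character(1:200), L = 50L,
                         contacts = list(NULL))
  rt <- make_rate_table(fake, metric = x, noise_sd = 2, seed = 11)
  expected <- var(-100 * x) / (var(-100 * x) + 4)
  expect_equal(cor(x, rt$ln_kf)^2, expected, tolerance = 0.05 / expected)
})

test_that("rigidity profile generation is seeded, clipped and periodic", {
  prof <- make_rigidity_profiles(10, 150, period = 24, seed = 12)
  expect_true(all(prof$k_prime >= 0))
  expect_identical(prof, make_rigidity_profiles(10, 150, period = 24,
                                                seed = 12))
  flat <- make_rigidity_profiles(10, 150, amplitude = 0, noise_sd = 0.5,
                                 seed = 13)
  rt <- randomization_test(flat, n_shuffles = 499, seed = 14)
  expect_equal(rt$ratio, 1, tolerance = 0.2)
})

test_that("the folding cohort carries consistent ground truth", {
  coh <- synth_folding_cohort(6, seed = 15)
  expect_equal(nrow(coh), 6)
  for (p in seq_len(nrow(coh))) {
    planted <- coh$planted[[p]]
    locks <- planted[planted$lock, , drop = FALSE]
    cm <- coh$contacts[[p]]
    # every planted lock loop's end pair is a metric contact
    for (k in seq_len(nrow(locks))) {
      expect_true(any(cm$i == locks$start[k] & cm$j == locks$end[k]))
    }
    # the stored core matches rebuilding it from the planted pairs
    rebuilt <- build_core(c(locks$start, locks$end), cm)
    expect_identical(coh$core[[p]]$contacts, rebuilt$contacts)
    expect_true(all(coh$core[[p]]$contacts$sep >= 3))
  }
})

test_that("elimination cohorts decouple hydrophobicity from connectivity", {
  coh <- synth_elimination_cohort(8, 50, seed = 16)
  cors <- vapply(coh$properties, function(pr)
    cor(pr$hydrophobicity, pr$connectivity), numeric(1))
  expect_lt(abs(mean(cors)), 0.2)
  expect_true(all(coh$tcd_hydcore > 0))
})
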