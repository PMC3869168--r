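test_that("loop enumeration filters contacts by inclusive length", {
  cm <- tibble::tibble(i = c(10, 5), j = c(35, 9))
  cands <- enumerate_closed_loops(cm)
  expect_equal(nrow(cands), 1)                 # (5,9) has length 5
  expect_equal(cands$length, 26)
  # brute-force filter equality on a synthetic multi-loop structure
  s <- make_loop_protein(120, loops = data.frame(start = c(10, 60),
                                                 end = c(35, 95)),
                         seed = 1)
  cm6 <- compute_contacts(s, 6, min_separation = 1)
  cands2 <- enumerate_closed_loops(cm6, 12, 50)
  len <- cm6$j - cm6$i + 1
  expect_equal(nrow(cands2), sum(len >= 12 & len <= 50))
})

test_that("lock scoring multiplies window-averaged scaled properties", {
  props <- tibble::tibble(residue = 1:40, resname = "GLY",
                          hydrophobicity = 1, hydrophobicity_scaled = 1,
                          connectivity = c(5:1, rep(1, 30), 1:5),
                          connectivity_scaled =
                            c(5:1, rep(1, 30), 1:5) / 5,
                          conservation = 1)
  loops <- tibble::tibble(start = c(1, 3), end = c(40, 38),
                          length = c(40, 36))
  scored <- score_lock_region(loops, props, window = 1)
  # uniform hydrophobicity + conservation: ranking by connectivity alone
  expect_equal(scored$score,
               c(mean(c(5, 5)) / 5, mean(c(3, 3)) / 5))
  # window 1 equals the product of each end's own scaled values
  expect_equal(scored$score[1],
               mean(props$connectivity_scaled[c(1, 40)] *
                      props$hydrophobicity_scaled[c(1, 40)] *
                      props$conservation[c(1, 40)]))
  s3 <- score_lock_region(loops, props, window = 3)
  expect_equal(s3$score[2],
               mean(c(mean(props$connectivity_scaled[2:4]),
                      mean(props$connectivity_scaled[37:39]))))
  expect_error(score_lock_region(loops, props, window = 4), "window")
})

test_that("greedy selection respects overlap, shared locks and tie-breaks", {
  one <- tibble::tibble(start = 10, end = 35, length = 26, score = 1)
  expect_equal(nrow(select_loops(one)), 1)
  # two candidates sharing 20 interior residues: higher score wins
  two <- tibble::tibble(start = c(10, 12), end = c(35, 37),
                        length = c(26, 26), score = c(2, 1))
  sel <- select_loops(two)
  expect_equal(sel$start, 10)
  # loops sharing only the lock residue 35 are both kept
  shared <- tibble::tibble(start = c(10, 35), end = c(35, 60),
                           length = c(26, 26), score = c(2, 1))
  expect_equal(nrow(select_loops(shared)), 2)
  # equal scores: shorter loop first, then smaller start
  ties <- tibble::tibble(start = c(50, 2, 2), end = c(70, 30, 25),
                         length = c(21, 29, 24), score = 1)
  sel2 <- select_loops(ties)
  expect_equal(sel2$start[1], 50)   # shortest of the tied candidates
  # zero-score candidates are never selected
  expect_equal(nrow(select_loops(tibble::tibble(
    start = 1, end = 30, length = 30, score = 0))), 0)
})

test_that("NMR refinement keeps persistent lock residues only", {
  s <- make_loop_protein(60, loops = data.frame(start = 10, end = 35),
                         seed = 2)
  loops <- lock_regions(enumerate_closed_loops(
    compute_contacts(s, 6, 9))[1, ], s)
  # all models keep the contact: everything retained
  ens_all <- make_ensemble(s, 10, jitter = 0.05, seed = 3)
  ref <- refine_locks_nmr(loops, ens_all, persistence_threshold = 0.5)
  expect_identical(ref$lock_start_refined[[1]], ref$lock_start[[1]])
  expect_false(ref$lock_flagged[1])
  # planted persistence 0.7 on an isolated residue pair: retained at
  # threshold 0.5, eliminated (and flagged) at 0.8
  ens_p <- make_ensemble(s, 10, jitter = 0.05, seed = 4,
                         persistence = data.frame(i = 10, j = 35,
                                                  persistence = 0.7))
  pair_loop <- tibble::tibble(start = 10, end = 35, length = 26,
                              lock_start = list(10L),
                              lock_end = list(35L))
  ref5 <- refine_locks_nmr(pair_loop, ens_p, persistence_threshold = 0.5)
  ref8 <- refine_locks_nmr(pair_loop, ens_p, persistence_threshold = 0.8)
  expect_equal(ref5$persistence_start[[1]], 0.7)
  expect_true(10 %in% ref5$lock_start_refined[[1]])
  expect_false(10 %in% ref8$lock_start_refined[[1]])
  expect_true(ref8$lock_flagged[1])
  expect_error(refine_locks_nmr(loops, s), "single model|>= 2 models")
})

test_that("minimal pairs maximise connectivity with deterministic ties", {
  # 2x2 candidates: pair (2, 10) has connectivity sum 14, others lower
  pos <- rbind(c(0, 0, 0), c(0, 0, 3.8),
               cbind(30 + 3.8 * (0:3), 0, 0),
               c(0, 4.5, 0), c(0, 4.5, 3.8))
  s <- as_structure(pos[c(1, 2, 3:6, 7, 8), ])
  loops <- tibble::tibble(start = 1, end = 8, length = 8,
                          lock_start = list(c(1L, 2L)),
                          lock_end = list(c(7L, 8L)))
  conn <- c(4, 10, 1, 1, 1, 1, 3, 4)
  got <- minimal_lock_pair(loops, s, conn)
  expect_equal(c(got$pair_start, got$pair_end), c(2, 8))  # sum 14
  # no cross-end contact: error
  far <- tibble::tibble(start = 3, end = 6, length = 4,
                        lock_start = list(3L), lock_end = list(6L))
  expect_error(minimal_lock_pair(far, s, conn), "lock invalid")
})

test_that("the core is the minimal pairs plus everything touching them", {
  cm <- tibble::tibble(i = c(1, 1, 1, 2, 3),
                       j = c(2, 3, 4, 3, 4))
  cm$sep <- cm$j - cm$i
  core <- build_core(c(1, 2), cm)
  expect_setequal(core$residues, 1:4)
  expect_equal(nrow(core$contacts), 4)   # (3,4) untouched by {1,2}
  expect_false(any(core$contacts$i == 3 & core$contacts$j == 4))
  # contacts disjoint from the pairs never enter the core
  core2 <- build_core(5, cm)
  expect_equal(nrow(core2$contacts), 0)
  # monotone growth
  core3 <- build_core(c(1, 2, 3), cm)
  expect_gte(length(core3$residues), length(core$residues))
  expect_gte(nrow(core3$contacts), nrow(core$contacts))
  gl <- glance(core)
  expect_equal(gl$n_core_contacts, 4)
})

test_that("planted loops are recovered end to end", {
  hits <- 0
  for (seed in 1:5) {
    len <- c(18, 30)[seed %% 2 + 1]
    s <- make_loop_protein(70, loops = data.frame(start = 8,
                                                  end = 7 + len),
                           seed = seed)
    fl <- find_loops(s)
    hits <- hits + (nrow(fl) >= 1 && abs(fl$start[1] - 8) <= 1 &&
                      abs(fl$end[1] - (7 + len)) <= 1)
  }
  expect_gte(hits, 4)
})
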