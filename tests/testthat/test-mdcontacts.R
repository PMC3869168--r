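test_that("contact fractions count frames exactly", {
  s <- bead_chain(60)
  tr <- make_trajectory(s, data.frame(i = 10, j = 25, fraction = 0.5),
                        n_frames = 40, seed = 1)
  cf <- contact_fractions(tr)
  expect_equal(cf$fraction[cf$i == 10 & cf$j == 25], 0.5)
  # a pair never in contact is absent from the output
  expect_false(any(cf$i == 2 & cf$j == 40))
  expect_true(all(cf$fraction > 0 & cf$fraction <= 1))
  expect_error(contact_fractions(make_trajectory(
    s, data.frame(i = 10, j = 25, fraction = 0.5), n_frames = 10,
    seed = 1)), "20 frames")
  expect_error(make_trajectory(s, data.frame(i = 10, j = 25,
                                             fraction = 0.5), 0),
               "frame")
})

test_that("separation baselines average over all pairs at a separation", {
  # all pairs at separation 5 with fraction 0.5
  L <- 20
  fr <- tibble::tibble(i = 1:(L - 5), j = 6:L, sep = 5, fraction = 0.5)
  attr(fr, "L") <- L
  bl <- separation_baseline(fr)
  expect_equal(bl$baseline[bl$sep == 5], 0.5)
  # a single observed pair at separation L-1 is its own baseline
  fr2 <- tibble::tibble(i = 1, j = L, sep = L - 1, fraction = 0.8)
  attr(fr2, "L") <- L
  expect_equal(separation_baseline(fr2)$baseline, 0.8)
  # zero-fraction pairs dilute the mean
  fr3 <- tibble::tibble(i = 1, j = 11, sep = 10, fraction = 1)
  attr(fr3, "L") <- L
  expect_equal(separation_baseline(fr3)$baseline, 1 / (L - 10))
  # group-by oracle on a synthetic trajectory
  tr <- make_trajectory(bead_chain(50),
                        data.frame(i = 8, j = 30, fraction = 0.4),
                        n_frames = 60, seed = 2)
  cf <- contact_fractions(tr)
  bl2 <- separation_baseline(cf)
  by_hand <- tapply(cf$fraction, cf$sep, sum)
  expect_equal(bl2$baseline,
               as.numeric(by_hand / (50 - as.integer(names(by_hand)))))
})

test_that("log ratios flag enrichment under either sign convention", {
  fr <- tibble::tibble(i = c(1, 2), j = c(11, 12), sep = 10,
                       fraction = c(1.0, 0.5))
  bl <- tibble::tibble(sep = 10, baseline = 0.5, n_pairs = 10)
  lr <- contact_log_ratio(fr, bl, flag_threshold = 0.3)
  expect_equal(lr$log_ratio, c(log(2), 0))
  expect_equal(lr$flagged, c(TRUE, FALSE))
  lr2 <- contact_log_ratio(fr, bl, convention = "depletion_sign")
  expect_equal(lr2$flagged, c(FALSE, FALSE))
  expect_error(contact_log_ratio(fr, tibble::tibble(sep = 10,
                                                    baseline = 0,
                                                    n_pairs = 10)),
               "zero")
})

test_that("planted enriched pairs are recovered exactly at 500 frames", {
  s <- bead_chain(80)
  planted <- data.frame(i = c(10, 30, 55), j = c(22, 45, 70),
                        fraction = c(0.6, 0.45, 0.3))
  tr <- make_trajectory(s, planted, n_frames = 500, seed = 3)
  cf <- contact_fractions(tr)
  lr <- contact_log_ratio(cf, separation_baseline(cf))
  flagged <- lr[lr$flagged, c("i", "j")]
  expect_equal(nrow(flagged), 3)
  expect_setequal(paste(flagged$i, flagged$j),
                  paste(planted$i, planted$j))
  got <- cf$fraction[match(paste(planted$i, planted$j),
                           paste(cf$i, cf$j))]
  expect_true(all(abs(got - planted$fraction) <= 0.05))
})

test_that("hypergeometric overlap p agrees with exhaustive enumeration", {
  # universe of 12 contacts, 5 in the core, 4 flagged, 3 overlapping
  uni <- tibble::tibble(i = 1:12, j = 21:32)
  core <- uni[1:5, ]
  flagged <- uni[c(1, 2, 3, 9), ]
  got <- core_overlap_significance(flagged, core, uni)
  expect_equal(got$overlap, 3 / 4)
  # enumerate all C(12, 4) draws and count overlap >= 3
  combos <- utils::combn(12, 4)
  hits <- sum(apply(combos, 2, function(cc) sum(cc <= 5) >= 3))
  expect_equal(got$p, hits / ncol(combos), tolerance = 1e-12)
  # flagged subset of the core: full overlap
  all_in <- core_overlap_significance(core[1:2, ], core, uni)
  expect_equal(all_in$overlap, 1)
  expect_error(core_overlap_significance(uni[0, ], core, uni), "empty")
})

test_that("uniformly drawn flagged sets give calibrated overlap", {
  withr::local_seed(4)
  uni <- tibble::tibble(i = rep(1:25, each = 2), j = rep(31:55, 2) +
                          rep(c(0, 1), 25))
  uni <- dplyr::distinct(uni)
  core <- uni[1:15, ]
  ps <- replicate(200, {
    flagged <- uni[sample(nrow(uni), 10), ]
    core_overlap_significance(flagged, core, uni)$p
  })
  # p-values under the null should not pile up below 0.05
  expect_lt(mean(ps < 0.05), 0.12)
})
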