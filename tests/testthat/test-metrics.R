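test_that("CO and TCD match their closed forms on tiny examples", {
  expect_equal(contact_order(data.frame(i = 1, j = 8), L = 10), 0.7)
  expect_equal(contact_order(data.frame(i = c(1, 1), j = c(4, 9)),
                             L = 10), 0.55)
  expect_equal(total_contact_distance(data.frame(i = 1, j = 8), L = 10),
               0.07)
  # identity TCD = CO * N / L
  p <- data.frame(i = c(1, 1), j = c(4, 9))
  expect_equal(total_contact_distance(p, 10),
               contact_order(p, 10) * 2 / 10)
  expect_error(contact_order(data.frame(i = integer(), j = integer()),
                             L = 10), "empty")
})

test_that("metric identities and invariances hold on random subsets", {
  withr::local_seed(1)
  for (rep in 1:20) {
    L <- sample(20:120, 1)
    p <- random_pairs(L, sample(5:60, 1))
    m <- contact_metrics(p, L)
    v <- setNames(m$value, m$metric)
    expect_equal(v[["ACO"]], v[["CO"]] * L)
    expect_equal(v[["ATCD"]], v[["TCD"]] * L)
    # order and duplication invariance
    p_shuf <- p[sample(nrow(p)), ]
    p_dup <- rbind(p, p[1, ])
    expect_equal(contact_order(p_shuf, L), v[["CO"]])
    expect_equal(total_contact_distance(p_dup, L), v[["TCD"]])
  }
})

test_that("TCD is additive over disjoint contact subsets", {
  withr::local_seed(2)
  L <- 80
  all_pairs <- unique(random_pairs(L, 60))
  split <- sample(c(TRUE, FALSE), nrow(all_pairs), replace = TRUE)
  a <- all_pairs[split, , drop = FALSE]
  b <- all_pairs[!split, , drop = FALSE]
  if (nrow(a) > 0 && nrow(b) > 0) {
    expect_equal(total_contact_distance(all_pairs, L),
                 total_contact_distance(a, L) +
                   total_contact_distance(b, L))
  }
})

test_that("TCD is less sensitive than CO to dropping near neighbours", {
  g <- make_globule(50, seed = 3)
  co <- sapply(c(1, 3), function(ms)
    contact_order(compute_contacts(g, min_separation = ms)))
  tcd <- sapply(c(1, 3), function(ms)
    total_contact_distance(compute_contacts(g, min_separation = ms)))
  rel <- function(x) abs(diff(x)) / x[1]
  expect_lt(rel(tcd), rel(co))
})

test_that("correlation with ln k_f recovers exact and noisy linear maps", {
  withr::local_seed(4)
  tcd <- runif(50, 0.05, 0.3)
  rates <- tibble::tibble(protein_id = as.character(1:50),
                          ln_kf = -50 * tcd + 10)
  fit <- correlate_lnkf(tibble::tibble(protein_id = as.character(1:50),
                                       value = tcd), rates)
  expect_equal(fit$r2, 1)
  expect_equal(fit$slope, -50)
  expect_equal(fit$intercept, 10)
  # closed-form expectation at n = 200
  x <- runif(200, 0.05, 0.3)
  a <- -100; sigma <- 3
  y <- a * x + 5 + rnorm(200, 0, sigma)
  expected_r2 <- var(a * x) / (var(a * x) + sigma^2)
  fit2 <- correlate_lnkf(
    tibble::tibble(protein_id = as.character(1:200), value = x),
    tibble::tibble(protein_id = as.character(1:200), ln_kf = y))
  expect_equal(fit2$r2, expected_r2, tolerance = 0.05 / expected_r2)
  # degenerate inputs
  expect_error(correlate_lnkf(
    tibble::tibble(protein_id = as.character(1:5), value = rep(1, 5)),
    tibble::tibble(protein_id = as.character(1:5), ln_kf = rnorm(5))),
    "constant")
  expect_error(correlate_lnkf(
    tibble::tibble(protein_id = "a", value = 1),
    tibble::tibble(protein_id = "a", ln_kf = 1)), "3")
})

test_that("tidy and glance summarise a correlation fit", {
  withr::local_seed(5)
  x <- runif(30); y <- 2 * x + rnorm(30, 0, 0.1)
  fit <- correlate_lnkf(
    tibble::tibble(protein_id = as.character(1:30), value = x),
    tibble::tibble(protein_id = as.character(1:30), ln_kf = y))
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r2)
  expect_true(is.na(gl$empirical.p))
})

test_that("the random-contact control is seeded, bounded and add-one smoothed", {
  coh <- synth_folding_cohort(8, seed = 6)
  rates <- make_rate_table(coh, seed = 7)
  k <- vapply(coh$core, function(co) nrow(co$contacts), integer(1))
  names(k) <- coh$protein_id
  ctrl1 <- random_contact_control(coh, rates, k, n_reps = 100, seed = 8,
                                  observed_r2 = 2)  # above any r^2
  expect_equal(ctrl1$empirical_p, 1 / 101)
  ctrl2 <- random_contact_control(coh, rates, k, n_reps = 100, seed = 8)
  expect_identical(ctrl1$null_r2, ctrl2$null_r2)
  expect_true(all(ctrl1$null_r2 >= 0 & ctrl1$null_r2 <= 1))
  bad_k <- k; bad_k[1] <- nrow(coh$contacts[[1]]) + 1L
  expect_error(random_contact_control(coh, rates, bad_k, n_reps = 100,
                                      seed = 9), "exceeds")
})

test_that("separation scans reproduce the base correlation and detect bands", {
  # contact sets whose short-range (3-24) and banded (25-40) content are
  # drawn independently, with rates generated from the band only
  withr::local_seed(10)
  L <- 100
  coh <- purrr::map_dfr(1:30, function(p) {
    n_short <- sample(10:40, 1)
    n_band <- sample(5:30, 1)
    sep <- c(sample(3:24, n_short, replace = TRUE),
             sample(25:40, n_band, replace = TRUE))
    i <- vapply(sep, function(s) sample.int(L - s, 1), integer(1))
    cm <- dplyr::distinct(tibble::tibble(i = i, j = i + sep,
                                         sep = sep))
    tibble::tibble(protein_id = sprintf("sc%02d", p), L = L,
                   contacts = list(cm))
  })
  band_tcd <- vapply(coh$contacts, function(cm)
    sum(cm$sep[cm$sep >= 25]) / L^2, numeric(1))
  rates <- tibble::tibble(protein_id = coh$protein_id,
                          ln_kf = -100 * band_tcd + 10 +
                            rnorm(30, 0, 0.05))
  base <- correlate_lnkf(
    tibble::tibble(protein_id = coh$protein_id,
                   value = vapply(coh$contacts, total_contact_distance,
                                  L, FUN.VALUE = numeric(1))), rates)
  sc <- separation_scan(coh, rates, min_sep_grid = 3)
  expect_equal(sc$r2, base$r2, tolerance = 1e-12)
  # one value per grid point (high-separation windows may legitimately
  # drop proteins, with a warning)
  sc53 <- suppressWarnings(separation_scan(coh, rates,
                                           min_sep_grid = 2:54))
  expect_equal(nrow(sc53), 53)
  # the in-band restriction keeps the signal, excluding the band loses it
  sc_in <- separation_scan(coh, rates, min_sep_grid = 25, max_sep = 40)
  sc_out <- suppressWarnings(
    separation_scan(coh, rates, min_sep_grid = 3, max_sep = 24))
  expect_gt(sc_in$r2, 0.9)
  expect_lt(sc_out$r2, 0.1)
})
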