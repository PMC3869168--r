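# Normalise rigidity-profile input to a bare list of k' vectors.
as_profile_list <- function(profiles) {
  if (is.data.frame(profiles)) {
    stop_unless(all(c("protein_id", "k_prime") %in% names(profiles)),
                "profile tibble needs protein_id and k_prime columns")
    return(unname(purrr::map(
      split(profiles, profiles$protein_id),
      function(d) d$k_prime[order(d$residue %||% seq_len(nrow(d)))])))
  }
  if (is.numeric(profiles)) return(list(profiles))
  stop_unless(is.list(profiles) && all(purrr::map_lgl(profiles, is.numeric)),
              "profiles must be a tibble, numeric vector or list of numeric vectors")
  profiles
}

#' Sequence autocorrelation of reduced force constants
#'
#' Pooled over proteins:
#' `C(L) = sum_p sum_i k'_i k'_(i+L) / sum_p (count of index pairs at
#' distance L)`, i.e. the products are summed across all proteins and
#' normalized by the total number of residue pairs at each separation.
#' A peak near L = 24-26 signals the ~25-residue spacing of rigid (high
#' k') residues expected under the closed-loop picture. Set
#' `pool = FALSE` to average per-protein autocorrelations instead.
#'
#' @param profiles Tibble with `protein_id`, `residue`, `k_prime` columns,
#'   a numeric k' vector, or a list of such vectors.
#' @param L_range Integer lags to evaluate (default 1:60).
#' @param pool Pool pairs across proteins (default `TRUE`).
#' @return Tibble of class `ln_autocorr` with columns `L`, `C`, `n_pairs`.
#' @export
rigidity_autocorrelation <- function(profiles, L_range = 1:60,
                                     pool = TRUE) {
  ks <- as_profile_list(profiles)
  lens <- purrr::map_int(ks, length)
  L_range <- as.integer(L_range)
  stop_unless(any(L_range < max(lens)),
              "every lag exceeds every profile length")
  if (pool) {
    acc <- rigidity_autocorr_cpp(ks, L_range)
    C <- ifelse(acc$den > 0, acc$num / acc$den, NA_real_)
    n_pairs <- acc$den
  } else {
    per <- purrr::map(ks, function(k) rigidity_autocorr_cpp(list(k), L_range))
    Cm <- purrr::map(per, function(a)
      ifelse(a$den > 0, a$num / a$den, NA_real_))
    C <- rowMeans(do.call(cbind, Cm), na.rm = TRUE)
    n_pairs <- Reduce(`+`, purrr::map(per, "den"))
  }
  out <- tibble::tibble(L = L_range, C = C, n_pairs = n_pairs)
  class(out) <- c("ln_autocorr", class(out))
  out
}

#' Randomization test for the autocorrelation peak
#'
#' The statistic is the mean of C(L) over the peak range divided by its
#' mean over the two flanking ranges. The null permutes the reduced force
#' constants independently within each protein `n_shuffles` times;
#' `p = (1 + #\{null ratio >= observed\}) / (n_shuffles + 1)`. The default
#' shuffle count is kept at 9999 for routine use; increase to 99999 for a
#' final analysis.
#'
#' @inheritParams rigidity_autocorrelation
#' @param n_shuffles Number of within-protein permutations (default 9999).
#' @param peak Peak lag range (default 22:27).
#' @param flanks Flanking lag ranges (default 15:20 and 30:35 combined).
#' @param seed RNG seed (default 1).
#' @return List with `ratio` (observed), `p`, `null_ratios`.
#' @export
randomization_test <- function(profiles, n_shuffles = 9999, peak = 22:27,
                               flanks = c(15:20, 30:35), seed = 1) {
  ks <- as_profile_list(profiles)
  lens <- purrr::map_int(ks, length)
  stop_unless(max(c(peak, flanks)) < max(lens),
              "peak/flank ranges exceed the computed lag range")
  C_of <- function(lags) {
    acc <- rigidity_autocorr_cpp(ks, as.integer(lags))
    mean(ifelse(acc$den > 0, acc$num / acc$den, 0))
  }
  flank_mean <- C_of(flanks)
  stop_unless(flank_mean > 0, "flank autocorrelation mean is zero")
  ratio <- C_of(peak) / flank_mean
  null_ratios <- with_seed_if(seed, rigidity_null_ratios_cpp(
    ks, as.integer(peak), as.integer(flanks), as.integer(n_shuffles)))
  list(ratio = ratio,
       p = (1 + sum(null_ratios >= ratio)) / (n_shuffles + 1),
       null_ratios = null_ratios)
}
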