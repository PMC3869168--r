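#' @title Synthetic structures and datasets with known ground truth
#' @description Generators for every input the pipeline consumes:
#' bead-chain proteins with planted closed loops and lock clusters,
#' NMR-like ensembles with controlled contact persistence, folding-rate
#' tables generated from a chosen metric plus Gaussian noise, snapshot
#' trajectories with planted persistent contacts, and rigidity profiles
#' with planted sequence periodicity. All generators are deterministic
#' under a fixed seed and emit objects (or PDB files) readable by the
#' corresponding analysis functions.
#' @name synthetic_data
NULL

.bond <- 3.8  # virtual C-alpha bond length, Angstrom

# --- geometry helpers ------------------------------------------------------

# Sample `n` points at equal arclength spacing along a polyline (matrix of
# waypoints), starting at arclength `step`; beyond the last waypoint the
# final direction is extrapolated.
sample_polyline <- function(pts, n, step = .bond, spacing = NULL) {
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  spacing <- spacing %||% step
  s_vals <- spacing * seq_len(n)
  t(vapply(s_vals, function(s) {
    if (s >= total) {
      d <- seg[nrow(seg), ] / seg_len[length(seg_len)]
      pts[nrow(pts), ] + (s - total) * d
    } else {
      k <- findInterval(s, cum, rightmost.closed = TRUE)
      frac <- (s - cum[k]) / seg_len[k]
      pts[k, ] + frac * seg[k, ]
    }
  }, numeric(3)))
}

# Local coordinates of a lock cluster: two 3.8-side squares of four
# residues each (chain order s..s+3 around the top square, e-3..e around
# the bottom), twisted 45 degrees and separated so that |s - e| = gap.
# Also returns the entry/exit hub positions (residues s-1 / e+1).
lock_cluster <- function(gap) {
  r <- .bond / sqrt(2)
  planar45 <- 2 * r * sin(pi / 8)
  stop_unless(gap > planar45 + 0.2 && gap < 6,
              "lock gap must be in (%.1f, 6) Angstrom", planar45 + 0.2)
  h <- sqrt(gap^2 - planar45^2)
  ang_top <- (45 + 90 * 0:3) * pi / 180      # residues s .. s+3
  ang_bot <- (90 + 90 * 0:3) * pi / 180      # residues e-3 .. e
  top <- cbind(r * cos(ang_top), r * sin(ang_top), 0)
  bot <- cbind(r * cos(ang_bot), r * sin(ang_bot), -h)
  list(top = top, bot = bot, h = h,
       hub_in = c(0, 0, 2.7), hub_out = c(0, 0, -h - 2.7))
}

# Circular-arc coordinates for the m interior beads of a loop connecting
# anchor A (after s+3) to anchor B (before e-3) with m+1 chords of 3.8 A.
# `tilt` rotates the arc plane's bulge direction within the y-z plane.
loop_arc <- function(A, B, m, tilt = 0) {
  c_len <- sqrt(sum((B - A)^2))
  nb <- m + 1
  f <- function(R) 2 * R * sin(nb * asin(.bond / 2 / R)) - c_len
  R_min <- (.bond / 2) / sin(pi / nb) + 1e-9
  R <- stats::uniroot(f, c(R_min, 1e4), tol = 1e-10)$root
  theta <- nb * 2 * asin(.bond / 2 / R)
  u <- (B - A) / c_len
  p <- c(0, cos(tilt), sin(tilt))
  w <- p - sum(p * u) * u
  # the long way around the circle bulges toward -w, so point w away
  # from +y to keep arcs on the opposite side of the routing corridors
  w <- -w / sqrt(sum(w^2))
  d <- sqrt(max(R^2 - (c_len / 2)^2, 0))
  ctr <- (A + B) / 2 - d * w
  basis <- cbind(u, w)
  ang_of <- function(pt) atan2(sum((pt - ctr) * basis[, 2]),
                               sum((pt - ctr) * basis[, 1]))
  thA <- ang_of(A); thB <- ang_of(B)
  wrap <- function(x) (x + pi) %% (2 * pi) - pi
  dir <- if (abs(wrap(thA + theta - thB)) < 1e-6) 1 else -1
  ang <- thA + dir * theta / (m + 1) * seq_len(m)
  pts <- t(vapply(ang, function(a)
    ctr + R * (cos(a) * basis[, 1] + sin(a) * basis[, 2]), numeric(3)))
  list(pts = pts, R = R)
}

# Corridor polyline between two x positions at depth y = yc, with a
# triangular serpentine in z sized to add `extra` arclength.
corridor_wave <- function(xA, xB, yc, zc, extra) {
  if (extra <= 0.5) {
    return(rbind(c(xA, yc, zc), c(xB, yc, zc)))
  }
  span <- abs(xB - xA)
  n <- max(1L, floor(span / 7))
  w <- span / n
  a <- sqrt((extra / (2 * n) + w / 2)^2 - (w / 2)^2)
  xs <- seq(xA, xB, length.out = 2 * n + 1)
  zs <- rep(c(zc, zc - a), length.out = 2 * n + 1)
  cbind(xs, yc, zs)
}

min_nonbonded_dist <- function(coords) {
  D <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  min(D[sep >= 2])
}

# --- planted-loop protein --------------------------------------------------

normalize_loops <- function(loops, n) {
  if (is.null(loops) || (is.data.frame(loops) && nrow(loops) == 0))
    return(NULL)
  loops <- tibble::as_tibble(loops)
  if (!"gap" %in% names(loops)) loops$gap <- 3.9
  if (!"lock" %in% names(loops)) loops$lock <- TRUE
  loops <- dplyr::arrange(loops, .data$start)
  stop_unless(all(loops$start >= 1 & loops$end <= n),
              "loop ends outside the chain")
  stop_unless(all(loops$end - loops$start + 1 >= 10),
              "planted loops need length >= 10")
  stop_unless(all(loops$gap < 6), "lock gap must be < 6 Angstrom")
  if (nrow(loops) > 1) {
    stop_unless(all(loops$start[-1] - loops$end[-nrow(loops)] >= 8),
                "planted loops need >= 8 residues between them")
  }
  loops
}

build_loop_chain <- function(n, loops, tilts) {
  pos <- matrix(NA_real_, n, 3)
  nl <- nrow(loops)
  arcs <- purrr::map(seq_len(nl), function(k) {
    cl <- lock_cluster(loops$gap[k])
    m <- loops$end[k] - loops$start[k] + 1 - 8
    arc <- loop_arc(cl$top[4, ], cl$bot[1, ], m, tilt = tilts[k])
    list(cl = cl, arc = arc)
  })
  R <- purrr::map_dbl(arcs, function(a) a$arc$R)
  X <- cumsum(c(0, 0.45 * (head(R, -1) + tail(R, -1)) + 14))
  for (k in seq_len(nl)) {
    s <- loops$start[k]; e <- loops$end[k]
    off <- c(X[k], 0, 0)
    cl <- arcs[[k]]$cl
    pos[s:(s + 3), ] <- sweep(cl$top, 2, off, "+")
    pos[(e - 3):e, ] <- sweep(cl$bot, 2, off, "+")
    arc_pts <- sweep(arcs[[k]]$arc$pts, 2, off, "+")
    if (nrow(arc_pts) > 0) pos[(s + 4):(e - 4), ] <- arc_pts
    if (s >= 2) pos[s - 1, ] <- cl$hub_in + off
    if (e < n) pos[e + 1, ] <- cl$hub_out + off
  }
  # Routing: each routed segment gets its own corridor depth y so
  # segments never share a lane; vertical legs are offset 3.5 A in x from
  # the cluster axes to clear the squares and hubs.
  zc <- -9.5
  # clearance stubs: exits from a bottom hub leave below and outside the
  # bottom square; entries to a top hub arrive from above and outside
  exit_stub <- function(k) {
    hub <- c(X[k], 0, -lock_cluster(loops$gap[k])$h - 2.7)
    c(X[k] + 2.5, -5.5, hub[3] - 2.2)
  }
  entry_stub <- function(k) c(X[k] - 2.5, -5.5, 5.2)
  # leading tail: residues 1 .. start_1 - 2, routed backwards from the
  # entry hub on a high shelf off to -x
  s1 <- loops$start[1]
  if (s1 >= 3) {
    hub <- pos[s1 - 1, ]
    wp <- rbind(hub, entry_stub(1), c(X[1] - 2.5, -8, 5.2),
                c(X[1] - 1e4, -8, 5.2))
    pos[(s1 - 2):1, ] <- sample_polyline(wp, s1 - 2)
  }
  # trailing tail: residues end_last + 2 .. n, low corridor off to +x
  el <- loops$end[nl]
  if (el <= n - 2) {
    hub <- pos[el + 1, ]
    Yt <- 10 + 5 * nl
    es <- exit_stub(nl)
    wp <- rbind(hub, es, c(es[1], -Yt, zc), c(X[nl] + 1e4, -Yt, zc))
    pos[(el + 2):n, ] <- sample_polyline(wp, n - el - 1)
  }
  # connectors between consecutive loops: a low corridor with a
  # length-absorbing serpentine when there are many beads to place, or a
  # direct path bowed into -y when there are few
  for (k in seq_len(nl - 1)) {
    eA <- loops$end[k]; sB <- loops$start[k + 1]
    nb <- sB - eA - 3          # beads e+2 .. s'-2
    hubA <- pos[eA + 1, ]; hubB <- pos[sB - 1, ]
    S1 <- exit_stub(k); T1 <- entry_stub(k + 1)
    Y <- 10 + 5 * k
    need <- 3.7 * (nb + 1)
    straight <- sum(sqrt(rowSums(diff(rbind(hubA, S1, T1, hubB))^2)))
    stop_unless(need >= straight,
                "connector between loops %d and %d too short (%d beads for %.0f A)",
                k, k + 1, nb, straight)
    pre <- rbind(hubA, S1, c(S1[1], -Y, zc))
    post <- rbind(c(T1[1], -Y, zc), T1, hubB)
    corridor_direct <- sum(sqrt(rowSums(diff(rbind(pre, post))^2)))
    if (need >= corridor_direct) {
      wave <- corridor_wave(S1[1], T1[1], -Y, zc, need - corridor_direct)
      wp <- rbind(pre, wave[-1, , drop = FALSE],
                  post[-1, , drop = FALSE])
    } else {
      bow_len <- function(d) {
        m1 <- S1 + 0.35 * (T1 - S1); m1[2] <- -(5.5 + d)
        m2 <- S1 + 0.65 * (T1 - S1); m2[2] <- -(5.5 + d)
        wp <- rbind(hubA, S1, m1, m2, T1, hubB)
        list(len = sum(sqrt(rowSums(diff(wp)^2))), wp = wp)
      }
      d <- stats::uniroot(function(d) bow_len(d)$len - need,
                          c(0, 80), tol = 1e-8)$root
      wp <- bow_len(d)$wp
    }
    total <- sum(sqrt(rowSums(diff(wp)^2)))
    pos[(eA + 2):(sB - 2), ] <- sample_polyline(wp, nb,
                                                spacing = total / (nb + 1))
  }
  pos
}

#' Generate a bead-chain protein with planted closed loops
#'
#' Builds a self-avoiding chain of one bead per residue (3.8 Angstrom
#' virtual bonds). Each planted loop places its two ends in a compact
#' two-square lock cluster (residues `start..start+3` and `end-3..end`)
#' whose end pair sits `gap` Angstrom apart; at the default gap the lock
#' residues have at least four neighbours within 6 Angstrom. The loop
#' interior runs around a circular arc and the remaining chain is routed
#' as an extended path clear of the clusters. Lock loops are made
#' recognisable to property scoring by residue naming: planted loop ends
#' are TRP (the octanol-scale maximum) while the background default, ARG,
#' sits at the scale minimum and scores exactly zero — so planted locks
#' carry the full hydrophobicity signal and loops planted with
#' `lock = FALSE` are hydrophobically silent decoys that contribute
#' contacts but never win selection.
#'
#' @param n_residues Chain length (>= 10).
#' @param loops `NULL` for an extended chain, or a data frame with columns
#'   `start`, `end`, optional `gap` (Angstrom, default 3.9, must be < 6)
#'   and optional logical `lock` (default `TRUE`). Loops must be at least
#'   10 residues long and at least 8 residues apart.
#' @param seed RNG seed (jitter and retries are deterministic given it).
#' @param background Background residue name (default `"ARG"`).
#' @param jitter Coordinate jitter s.d. in Angstrom (default 0.1).
#' @param max_tries Rebuild attempts before giving up (default 20).
#' @param backbone Add N and C backbone atoms around each bead so the
#'   written PDB looks like a (crude) three-atom backbone (default FALSE).
#' @param id Structure id.
#' @return Structure tibble; attribute `planted` holds the loop table.
#' @export
make_loop_protein <- function(n_residues, loops = NULL, seed = NULL,
                              background = "ARG", jitter = 0.1,
                              max_tries = 20, backbone = FALSE,
                              id = "synthetic") {
  stop_unless(n_residues >= 10, "need at least 10 residues")
  loops <- normalize_loops(loops, n_residues)
  resnames <- rep(background, n_residues)
  if (!is.null(loops)) {
    for (k in seq_len(nrow(loops))) {
      if (loops$lock[k]) {
        resnames[c(loops$start[k], loops$end[k])] <- "TRP"
      }
    }
  }
  build_once <- function(try) {
    with_seed_if(if (is.null(seed)) NULL else derive_seed(seed, try), {
      if (is.null(loops)) {
        pos <- cbind(.bond * (seq_len(n_residues) - 1), 0, 0)
      } else {
        tilts <- runif(nrow(loops), -0.4, 0.4)
        pos <- build_loop_chain(n_residues, loops, tilts)
      }
      pos + matrix(rnorm(3 * n_residues, 0, jitter), ncol = 3)
    })
  }
  ok <- function(pos) {
    if (anyNA(pos) || !all(is.finite(pos))) return(FALSE)
    if (min_nonbonded_dist(pos) < 3.0) return(FALSE)
    if (!is.null(loops)) {
      d_end <- sqrt(rowSums((pos[loops$start, , drop = FALSE] -
                               pos[loops$end, , drop = FALSE])^2))
      if (any(d_end > 5.99)) return(FALSE)
    }
    TRUE
  }
  pos <- NULL
  for (try in seq_len(max_tries)) {
    cand <- build_once(try)
    if (ok(cand)) { pos <- cand; break }
  }
  stop_unless(!is.null(pos),
              "could not realise the requested loop geometry in %d tries",
              max_tries)
  st <- if (backbone) {
    dirs <- rbind(pos[2, ] - pos[1, ], pos[-1, , drop = FALSE] -
                    pos[-nrow(pos), , drop = FALSE])
    dirs <- dirs / sqrt(rowSums(dirs^2))
    atoms <- purrr::map_dfr(seq_len(n_residues), function(r)
      tibble::tibble(model = 1L, residue = r, resname = resnames[r],
                     atom = c("N", "CA", "C"),
                     x = pos[r, 1] + c(-1.2, 0, 1.2) * dirs[r, 1],
                     y = pos[r, 2] + c(-1.2, 0, 1.2) * dirs[r, 2],
                     z = pos[r, 3] + c(-1.2, 0, 1.2) * dirs[r, 3]))
    new_structure(atoms, id = id)
  } else as_structure(pos, id = id, resnames = resnames)
  attr(st, "planted") <- loops
  st
}

# --- ensembles -------------------------------------------------------------

#' Generate an NMR-like ensemble with controlled contact persistence
#'
#' Each model perturbs the input coordinates with Gaussian jitter. For
#' every row of `persistence` (columns `i`, `j`, `persistence`), the
#' contact is broken in exactly `ceiling((1 - persistence) * n_models)`
#' models (chosen at random) by displacing residue `j` to 9 Angstrom from
#' residue `i` along their axis, so the measured persistence equals the
#' planted value.
#'
#' @param structure Single-model structure tibble.
#' @param n_models Number of models (>= 2).
#' @param jitter Coordinate jitter s.d., Angstrom (default 0.25; 0 gives
#'   identical models apart from planted breaks).
#' @param persistence Optional data frame `i`, `j`, `persistence` in
#'   \[0, 1\].
#' @param seed RNG seed.
#' @return Multi-model structure tibble.
#' @export
make_ensemble <- function(structure, n_models, jitter = 0.25,
                          persistence = NULL, seed = NULL) {
  stop_unless(n_models >= 2, "need n_models >= 2")
  base <- model_atoms(structure, min(structure$model))
  pos <- as.matrix(base[, c("x", "y", "z")])
  if (!is.null(persistence)) {
    stop_unless(all(persistence$persistence >= 0 &
                      persistence$persistence <= 1),
                "persistence must lie in [0, 1]")
  }
  with_seed_if(seed, {
    broken <- if (is.null(persistence)) list() else
      purrr::map(seq_len(nrow(persistence)), function(k) {
        nb <- ceiling(round((1 - persistence$persistence[k]) * n_models,
                            9))
        sample.int(n_models, nb)
      })
    models <- purrr::map(seq_len(n_models), function(m) {
      p <- pos + matrix(rnorm(length(pos), 0, jitter), ncol = 3)
      if (!is.null(persistence)) {
        for (k in seq_len(nrow(persistence))) {
          if (m %in% broken[[k]]) {
            ri <- base$residue == persistence$i[k]
            rj <- base$residue == persistence$j[k]
            ci <- colMeans(p[ri, , drop = FALSE])
            cj <- colMeans(p[rj, , drop = FALSE])
            dir <- (cj - ci) / sqrt(sum((cj - ci)^2))
            shift <- ci + 9 * dir - cj
            p[rj, ] <- sweep(p[rj, , drop = FALSE], 2, shift, "+")
          }
        }
      }
      p
    })
    st <- as_structure(models, id = structure_id(structure),
                       resnames = structure_resnames(structure))
    attr(st, "planted_persistence") <- persistence
    st
  })
}

# --- rate tables -----------------------------------------------------------

#' Generate log folding rates from a structural metric
#'
#' `ln_kf = slope * metric + intercept + N(0, noise_sd^2)`, one value per
#' cohort protein. The default slope/intercept/noise were fixed once so
#' that, on the reference synthetic cohort (seed 1), the all-contacts TCD
#' correlation lands near r^2 = 0.6 while the core-restricted correlation
#' stays higher — mirroring the contrast the analysis is designed to
#' detect.
#'
#' @param cohort Cohort tibble (needs `protein_id`, `L`, `contacts`; the
#'   `"tcd_core"` metric additionally needs a `core` list-column, as
#'   produced by [synth_folding_cohort()]).
#' @param slope,intercept Linear map from metric to `ln_kf` (defaults
#'   -100 and 10).
#' @param noise_sd Gaussian noise s.d. (default 0.5).
#' @param metric `"tcd"` (full contact map), `"tcd_core"` (ground-truth
#'   core contacts), or a numeric vector of per-protein metric values.
#' @param seed RNG seed.
#' @return Tibble `protein_id`, `L`, `ln_kf`; attribute `metric_values`.
#' @export
make_rate_table <- function(cohort, slope = -100, intercept = 10,
                            noise_sd = 0.5, metric = "tcd_core",
                            seed = NULL) {
  vals <- if (is.numeric(metric)) {
    stop_unless(length(metric) == nrow(cohort),
                "metric vector must match the cohort size")
    metric
  } else if (identical(metric, "tcd")) {
    purrr::map_dbl(cohort$contacts, total_contact_distance)
  } else if (identical(metric, "tcd_core")) {
    stop_unless(!is.null(cohort$core), "cohort lacks a core list-column")
    purrr::map_dbl(seq_len(nrow(cohort)), function(p)
      total_contact_distance(cohort$core[[p]]$contacts, cohort$L[p]))
  } else abort("metric must be 'tcd', 'tcd_core' or a numeric vector")
  ln_kf <- with_seed_if(seed,
    slope * vals + intercept + rnorm(nrow(cohort), 0, noise_sd))
  out <- tibble::tibble(protein_id = cohort$protein_id, L = cohort$L,
                        ln_kf = ln_kf)
  attr(out, "metric_values") <- vals
  out
}

# --- trajectories ----------------------------------------------------------

#' Generate snapshot trajectories with planted persistent contacts
#'
#' Frames alternate between two conformers of the chain: an extended chain
#' (no contacts at separation >= 3) and a helical chain in which every
#' (i, i+3) pair is in contact — the helix frames supply a uniform
#' separation-dependent contact baseline. Each planted pair (columns `i`,
#' `j`, `fraction`; separations >= 6, disjoint residues) is put in contact
#' in exactly `round(fraction * n_frames)` extended frames by moving
#' residue `j` next to residue `i`, so measured fractions match the
#' planted ones exactly and the planted pairs are the only
#' separation-enriched contacts.
#'
#' @param structure Structure tibble (supplies L and id; the conformers
#'   are generated, not taken from it).
#' @param persistent_pairs Data frame `i`, `j`, `fraction`.
#' @param n_frames Number of frames (>= 20).
#' @param p_background Fraction of helix (background) frames, default
#'   0.35.
#' @param jitter Coordinate jitter s.d., Angstrom (default 0.05).
#' @param seed RNG seed.
#' @return Multi-model structure tibble (one model per frame); attribute
#'   `planted_pairs`.
#' @export
make_trajectory <- function(structure, persistent_pairs, n_frames,
                            p_background = 0.35, jitter = 0.05,
                            seed = NULL) {
  stop_unless(n_frames >= 1, "need at least one frame")
  L <- structure_length(structure)
  pp <- tibble::as_tibble(persistent_pairs)
  stop_unless(all(pp$j - pp$i >= 6),
              "planted pairs need separation >= 6")
  ids <- c(pp$i, pp$j)
  stop_unless(!any(duplicated(ids)),
              "planted pairs must use disjoint residues")
  stop_unless(all(pp$fraction >= 0 & pp$fraction + p_background <= 0.95),
              "fraction + p_background must stay below 0.95")
  extended <- cbind(.bond * (seq_len(L) - 1), 0, 0)
  rho <- 2.3; rise <- 1.6; phi <- 100 * pi / 180
  helix <- cbind(rho * cos(phi * seq_len(L)), rho * sin(phi * seq_len(L)),
                 rise * seq_len(L))
  with_seed_if(seed, {
    n_helix <- round(p_background * n_frames)
    helix_frames <- sort(sample.int(n_frames, n_helix))
    ext_frames <- setdiff(seq_len(n_frames), helix_frames)
    active <- purrr::map(seq_len(nrow(pp)), function(k)
      sample(ext_frames, round(pp$fraction[k] * n_frames)))
    models <- purrr::map(seq_len(n_frames), function(f) {
      pos <- if (f %in% helix_frames) helix else extended
      if (!(f %in% helix_frames)) {
        for (k in seq_len(nrow(pp))) {
          if (f %in% active[[k]]) {
            pos[pp$j[k], ] <- pos[pp$i[k], ] + c(0, 0, 5.2)
          }
        }
      }
      pos + matrix(rnorm(3 * L, 0, jitter), ncol = 3)
    })
    st <- as_structure(models, id = structure_id(structure),
                       resnames = structure_resnames(structure))
    attr(st, "planted_pairs") <- pp
    st
  })
}

# --- rigidity profiles -----------------------------------------------------

#' Generate reduced-force-constant profiles with planted periodicity
#'
#' Profiles are non-negative: triangular peaks of height `amplitude`
#' (half-height shoulders at +/- 1 residue) every `period` residues at a
#' random per-protein phase, plus Gaussian noise, clipped below at zero.
#' `amplitude = 0` gives pure clipped noise (a null profile set).
#'
#' @param n_proteins Number of profiles (default 50).
#' @param length Profile length in residues (default 150).
#' @param period Peak spacing in residues (default 24).
#' @param amplitude Peak height (default 3).
#' @param noise_sd Noise s.d. (default 0.3).
#' @param seed RNG seed.
#' @return Tibble `protein_id`, `residue`, `k_prime`.
#' @export
make_rigidity_profiles <- function(n_proteins = 50, length = 150,
                                   period = 24, amplitude = 3,
                                   noise_sd = 0.3, seed = NULL) {
  with_seed_if(seed, purrr::map_dfr(seq_len(n_proteins), function(p) {
    phase <- sample.int(period, 1)
    base <- numeric(length)
    centers <- seq(phase, length, by = period)
    for (ctr in centers) {
      idx <- intersect(ctr + (-1:1), seq_len(length))
      base[idx] <- pmax(base[idx],
                        amplitude * c(0.5, 1, 0.5)[idx - ctr + 2])
    }
    tibble::tibble(protein_id = sprintf("synth%03d", p),
                   residue = seq_len(length),
                   k_prime = pmax(0, base + rnorm(length, 0, noise_sd)))
  }))
}

# --- full synthetic cohorts ------------------------------------------------

#' Generate a synthetic folding cohort with planted cores
#'
#' Builds `n_proteins` bead-chain proteins, each with 1-3 planted lock
#' loops (lengths 15-40) and 0-2 hydrophobically silent decoy loops, and
#' records per protein the metric contact map and the ground-truth
#' locks-plus-neighbours core derived from the planted loop-end pairs.
#' Decoy loops contribute long-range contacts to the full map but not to
#' the core, which is what lets a core-restricted correlation beat the
#' all-contacts one when rates are generated from the core.
#'
#' @param n_proteins Cohort size (default 43).
#' @param seed RNG seed.
#' @param n_residues Range of chain lengths to draw from (default
#'   60:130).
#' @param loop_lengths Range of planted loop lengths (default 15:40).
#' @return Cohort tibble with columns `protein_id`, `L`, `structure`,
#'   `contacts`, `properties`, `planted` (loop tables) and `core`
#'   (`ln_core` ground truth).
#' @export
synth_folding_cohort <- function(n_proteins = 43, seed = 1,
                                 n_residues = 60:130,
                                 loop_lengths = 15:40) {
  rows <- purrr::map(seq_len(n_proteins), function(p) {
    sp <- derive_seed(seed, p)
    plan <- with_seed_if(sp, {
      n <- sample(n_residues, 1)
      n_lock <- sample(1:3, 1)
      n_decoy <- sample(0:2, 1)
      kinds <- sample(c(rep(TRUE, n_lock), rep(FALSE, n_decoy)))
      pos <- sample(3:6, 1)
      loops <- NULL
      for (lk in kinds) {
        len <- sample(loop_lengths, 1)
        if (pos + len - 1 > n - 2) break
        loops <- dplyr::bind_rows(loops, tibble::tibble(
          start = pos, end = pos + len - 1, gap = 3.9, lock = lk))
        pos <- pos + len - 1 + sample(15:22, 1)
      }
      if (is.null(loops) || !any(loops$lock)) {
        len <- min(26, n - 6)
        loops <- tibble::tibble(start = 3, end = 3 + len - 1, gap = 3.9,
                                lock = TRUE)
      }
      list(n = n, loops = loops)
    })
    st <- make_loop_protein(plan$n, plan$loops, seed = derive_seed(sp, 7),
                            id = sprintf("synth%03d", p))
    cm <- compute_contacts(st, 6, 3)
    locks <- plan$loops[plan$loops$lock, , drop = FALSE]
    core <- build_core(c(locks$start, locks$end), cm)
    tibble::tibble(protein_id = structure_id(st), L = plan$n,
                   structure = list(st), contacts = list(cm),
                   properties = list(residue_properties(st)),
                   planted = list(plan$loops), core = list(core))
  })
  dplyr::bind_rows(rows)
}

#' Generate a compact self-avoiding globule
#'
#' Random self-avoiding chain growth (3.8 Angstrom bonds, 3.4 Angstrom
#' exclusion) biased toward a target radius so the chain collapses into a
#' compact, contact-rich ball. Used where a generic dense structure is
#' needed (elimination cohorts, brute-force contact oracles).
#'
#' @param n_residues Chain length.
#' @param seed RNG seed.
#' @param resnames Residue names, recycled (default `"GLY"`).
#' @param id Structure id.
#' @return Single-model structure tibble.
#' @export
make_globule <- function(n_residues, seed = NULL, resnames = "GLY",
                         id = "globule") {
  r_target <- 2.6 * n_residues^(1 / 3)
  grow <- function() {
    pos <- matrix(0, n_residues, 3)
    for (k in 2:n_residues) {
      placed <- FALSE
      for (try in 1:300) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        rad <- sqrt(sum(pos[k - 1, ]^2))
        if (rad > 1e-6) {
          pull <- 0.8 * min(rad / r_target, 1.5)
          u <- u - pull * pos[k - 1, ] / rad
          u <- u / sqrt(sum(u^2))
        }
        cand <- pos[k - 1, ] + .bond * u
        prev <- pos[seq_len(max(1, k - 2)), , drop = FALSE]
        if (k == 2 || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= 3.4) {
          pos[k, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) return(NULL)
    }
    pos
  }
  pos <- with_seed_if(seed, {
    out <- NULL
    for (restart in 1:50) {
      out <- grow()
      if (!is.null(out)) break
    }
    out
  })
  stop_unless(!is.null(pos), "could not grow a self-avoiding globule")
  as_structure(pos, id = id, resnames = resnames)
}

#' Generate a hydrophobic-core elimination cohort
#'
#' Compact self-avoiding globules with residue identities drawn uniformly
#' at random (independent of geometry, so hydrophobicity and connectivity
#' are uncorrelated by construction). The cohort's signal metric is the
#' TCD over "hydrophobic-core" contacts — contacts whose two endpoints
#' both lie in the most hydrophobic `top_frac` of each protein's
#' residues. Rates generated from that metric remain predictable as long
#' as hydrophobicity-ranked removal has not eaten into the top fraction,
#' which is what the elimination analysis is designed to expose.
#'
#' @param n_proteins Cohort size (default 30).
#' @param n_residues Residues per globule (default 60).
#' @param top_frac Hydrophobic-core fraction (default 0.4).
#' @param seed RNG seed.
#' @return Cohort tibble from [build_cohort()] with an extra numeric
#'   column `tcd_hydcore` (the signal metric, one value per protein).
#' @export
synth_elimination_cohort <- function(n_proteins = 30, n_residues = 60,
                                     top_frac = 0.4, seed = 1) {
  globules <- purrr::map(seq_len(n_proteins), function(i) {
    sd_i <- derive_seed(seed, i)
    nm <- with_seed_if(sd_i, sample(names(hydrophobicity_scale()),
                                    n_residues, replace = TRUE))
    make_globule(n_residues, seed = sd_i + 1, resnames = nm,
                 id = sprintf("elim%03d", i))
  })
  names(globules) <- purrr::map_chr(globules, structure_id)
  cohort <- build_cohort(globules)
  cohort$tcd_hydcore <- purrr::map_dbl(seq_len(nrow(cohort)),
                                       function(p) {
    pr <- cohort$properties[[p]]
    cm <- cohort$contacts[[p]]
    n_top <- ceiling(top_frac * cohort$L[p])
    top <- pr$residue[rank(-pr$hydrophobicity,
                           ties.method = "min") <= n_top]
    keep <- cm$i %in% top & cm$j %in% top
    sum(cm$sep[keep]) / cohort$L[p]^2
  })
  cohort
}
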