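#' @title Coarse-grain elastic networks and rigidity profiles
#' @description A structure is reduced to one to three pseudo-atoms per
#' residue (the C-alpha plus up to two side-chain centroids); all bead
#' pairs closer than 9 Angstrom are joined by identical harmonic springs
#' (gamma = 0.6 kcal mol^-1 A^-2, rest length = build-time distance).
#' Overdamped Brownian dynamics samples equilibrium fluctuations, and each
#' residue's force constant k_i = 3 k_B T / Var(d_i) is derived from the
#' variance of its mean distance d_i to all other residues — a rigid,
#' buried residue fluctuates little and gets a large k. Per-protein
#' Z-scoring and clipping at zero yield the reduced force constants k'
#' whose sequence autocorrelation is examined for ~25-residue periodicity.
#' @name elastic_network
NULL

# Atom names treated as backbone when splitting off side chains.
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")
# Residues granted a second (distal) side-chain bead.
.large_sidechain <- c("TRP", "TYR", "PHE", "ARG")

#' Build a coarse-grain elastic network
#'
#' @param structure Structure tibble (single model used; model 1).
#' @param cutoff Spring cutoff in Angstrom (default 9; springs connect
#'   bead pairs strictly closer than this).
#' @param gamma Uniform spring constant, kcal mol^-1 A^-2 (default 0.6).
#' @param representation `"ca_plus_sidechain"` places a C-alpha bead plus
#'   a side-chain centroid for residues with more than one side-chain
#'   heavy atom (two centroids, proximal and distal halves, for
#'   large-side-chain residues); `"ca_only"` places one bead per residue.
#' @return List of class `ln_network`: `beads` tibble (`bead`, `residue`,
#'   `role`, `x`, `y`, `z`), `springs` tibble (`from`, `to`, `rest`),
#'   `gamma`, `cutoff`.
#' @export
build_network <- function(structure, cutoff = 9, gamma = 0.6,
                          representation = c("ca_plus_sidechain",
                                             "ca_only")) {
  representation <- match.arg(representation)
  a <- model_atoms(structure, min(structure$model))
  beads <- purrr::map_dfr(split(a, a$residue), function(res) {
    r <- res$residue[1]
    ca <- res[res$atom == "CA", , drop = FALSE]
    if (nrow(ca) == 0) ca <- res[1, , drop = FALSE]  # bead-chain input
    out <- tibble::tibble(residue = r, role = "ca",
                          x = ca$x[1], y = ca$y[1], z = ca$z[1])
    if (representation == "ca_plus_sidechain") {
      side <- res[!res$atom %in% .backbone_atoms, , drop = FALSE]
      if (nrow(side) > 1) {
        if (res$resname[1] %in% .large_sidechain && nrow(side) >= 4) {
          d_ca <- sqrt((side$x - out$x)^2 + (side$y - out$y)^2 +
                         (side$z - out$z)^2)
          prox <- d_ca <= stats::median(d_ca)
          out <- dplyr::bind_rows(out,
            tibble::tibble(residue = r, role = "side1",
                           x = mean(side$x[prox]), y = mean(side$y[prox]),
                           z = mean(side$z[prox])),
            tibble::tibble(residue = r, role = "side2",
                           x = mean(side$x[!prox]),
                           y = mean(side$y[!prox]),
                           z = mean(side$z[!prox])))
        } else {
          out <- dplyr::bind_rows(out,
            tibble::tibble(residue = r, role = "side1",
                           x = mean(side$x), y = mean(side$y),
                           z = mean(side$z)))
        }
      }
    }
    out
  })
  beads$bead <- seq_len(nrow(beads))
  beads <- dplyr::relocate(beads, "bead")
  D <- as.matrix(stats::dist(cbind(beads$x, beads$y, beads$z)))
  idx <- which(upper.tri(D) & D < cutoff, arr.ind = TRUE)
  springs <- tibble::tibble(from = idx[, 1], to = idx[, 2],
                            rest = D[idx])
  structure(list(beads = beads, springs = springs, gamma = gamma,
                 cutoff = cutoff, id = structure_id(structure)),
            class = "ln_network")
}

#' @export
print.ln_network <- function(x, ...) {
  cat(sprintf("<elastic network> %s: %d beads (%d residues), %d springs, gamma = %g kcal/mol/A^2, cutoff = %g A\n",
              x$id, nrow(x$beads), length(unique(x$beads$residue)),
              nrow(x$springs), x$gamma, x$cutoff))
  invisible(x)
}

#' Brownian dynamics of an elastic network
#'
#' Overdamped Langevin integration
#' `x <- x - (dt/zeta) grad U + sqrt(2 kT dt / zeta) eta` starting from
#' the build-time (equilibrium) coordinates. Units: Angstrom, kcal/mol,
#' with friction zeta in kcal mol^-1 A^-2 per unit time, so time is in
#' arbitrary reduced units. The integrator is only stable for
#' `dt < 2 zeta / k_max` where `k_max` is the largest effective stiffness
#' acting on a bead (roughly gamma times its spring count); divergence
#' aborts with a diagnostic. At zero temperature coordinates stay exactly
#' at equilibrium. Fixed seeds give bitwise-identical trajectories.
#'
#' @param network `ln_network` from [build_network()].
#' @param n_steps Production steps.
#' @param dt Time step (reduced units; default 0.01).
#' @param temperature Kelvin (default 300).
#' @param friction Friction coefficient zeta (default 1).
#' @param seed Optional RNG seed.
#' @param save_every Frame-saving stride (default 10).
#' @param n_equil Equilibration steps discarded before saving (default
#'   `n_steps %/% 10`).
#' @return List of class `ln_traj`: `frames` (matrix, rows = saved frames,
#'   columns = flattened bead coordinates), `network`, `temperature`,
#'   `dt`, `save_every`.
#' @export
brownian_dynamics <- function(network, n_steps = 20000, dt = 0.01,
                              temperature = 300, friction = 1,
                              seed = NULL, save_every = 10,
                              n_equil = n_steps %/% 10) {
  kT <- .kB * temperature
  frames <- with_seed_if(seed, bd_integrate(
    as.matrix(network$beads[, c("x", "y", "z")]),
    as.integer(network$springs$from), as.integer(network$springs$to),
    network$springs$rest, network$gamma, kT, friction, dt,
    as.integer(n_steps), as.integer(n_equil), as.integer(save_every)))
  structure(list(frames = frames, network = network,
                 temperature = temperature, dt = dt,
                 save_every = save_every), class = "ln_traj")
}

#' Per-residue force constants from a fluctuation trajectory
#'
#' For residue i, `d_i(frame)` is the mean distance from its C-alpha bead
#' to the C-alpha beads of all other residues; the force constant is
#' `k_i = 3 k_B T / Var(d_i)` (kcal mol^-1 A^-2). Z-scores are taken per
#' protein and clipped below zero to give the reduced force constants
#' `k_prime`.
#'
#' @param traj `ln_traj` from [brownian_dynamics()] (>= 100 saved frames).
#' @return Tibble of class `ln_rigidity` with columns `residue`, `k`,
#'   `k_z`, `k_prime`; attribute `id`.
#' @export
force_constants <- function(traj) {
  frames <- traj$frames
  stop_unless(nrow(frames) >= 100,
              "need >= 100 saved frames, got %d", nrow(frames))
  beads <- traj$network$beads
  ca <- beads[beads$role == "ca", , drop = FALSE]
  dmat <- mean_bead_distances(frames, as.integer(ca$bead))
  v <- apply(dmat, 2, var)
  stop_unless(all(v > 0),
    "zero fluctuation variance for residue(s) %s: trajectory frozen or rigid-body only",
    paste(ca$residue[v <= 0], collapse = ", "))
  k <- 3 * .kB * traj$temperature / v
  out <- rigidity_zscores(tibble::tibble(residue = ca$residue, k = k))
  attr(out, "id") <- traj$network$id
  class(out) <- c("ln_rigidity", class(tibble::tibble()))
  out
}

#' Z-score and clip a force-constant profile
#'
#' @param profile Tibble with columns `residue`, `k`.
#' @return The profile with `k_z` (per-protein Z-score, mean 0 / sd 1)
#'   and `k_prime` (`k_z` clipped below at 0) added.
#' @export
rigidity_zscores <- function(profile) {
  kz <- (profile$k - mean(profile$k)) / sd(profile$k)
  dplyr::mutate(profile, k_z = kz, k_prime = pmax(kz, 0))
}

#' Rigidity profile of a structure, end to end
#'
#' Convenience wrapper: [build_network()], [brownian_dynamics()],
#' [force_constants()].
#'
#' @inheritParams build_network
#' @inheritParams brownian_dynamics
#' @param ... Passed to [brownian_dynamics()].
#' @return `ln_rigidity` tibble (see [force_constants()]).
#' @export
rigidity_profile <- function(structure, cutoff = 9, gamma = 0.6,
                             representation = "ca_plus_sidechain",
                             seed = NULL, ...) {
  net <- build_network(structure, cutoff, gamma, representation)
  force_constants(brownian_dynamics(net, seed = seed, ...))
}
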