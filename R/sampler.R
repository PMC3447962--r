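#' Langevin sampler parameters
#'
#' Reduced-unit protocol for conformational sampling: the production
#' protocol integrates 20,000 reduced time units at a timestep of 0.0005
#' with one snapshot every 0.5 time units (40,000 candidate conformations).
#' Scaled-down runs shorten `total_time`, never the snapshot interval.
#' Temperature and friction are not part of the published protocol; the
#' defaults (1.0 each, reduced units) target near-native-basin sampling and
#' can be overridden.
#'
#' @param timestep integration step, reduced time units (default 0.0005).
#' @param total_time total simulated time, reduced units (default 20000).
#' @param snapshot_interval time between saved frames (default 0.5).
#' @param temperature reduced temperature (default 1); 0 gives damped
#'   descent.
#' @param friction Langevin friction, inverse reduced time (default 1);
#'   0 gives NVE velocity-Verlet integration.
#' @param seed integer RNG seed (default 1).
#' @param energy_bound abort threshold on |V| (default 1e8).
#' @param equilibration burn-in time (reduced units, default 0) discarded
#'   before the first snapshot; use a short burn-in when starting from
#'   constructed (e.g. hinge-rotated) coordinates that may carry clashes.
#' @return a list of class `sampler_params`.
#' @export
sampler_params <- function(timestep = 0.0005, total_time = 20000,
                           snapshot_interval = 0.5, temperature = 1,
                           friction = 1, seed = 1L, energy_bound = 1e8,
                           equilibration = 0) {
  stopifnot(timestep > 0, snapshot_interval >= timestep, temperature >= 0,
            friction >= 0, total_time > 0, equilibration >= 0)
  structure(list(timestep = timestep, total_time = total_time,
                 snapshot_interval = snapshot_interval,
                 temperature = temperature, friction = friction,
                 seed = as.integer(seed), energy_bound = energy_bound,
                 equilibration = equilibration),
            class = "sampler_params")
}

.topo_mats <- function(t) {
  list(bonds = t$bonds, angles = t$angles, impropers = t$impropers,
       dihedrals = t$dihedrals, contacts = t$contacts,
       exclusions = t$exclusions,
       params = unclass(t$params))
}

#' Structure-based model potential energy
#'
#' Evaluates the SBM potential at the given coordinates: harmonic bonds
#' eps_r (r - r0)^2, angles eps_theta (theta - theta0)^2, impropers
#' eps_xi (xi - xi0)^2, proper dihedrals w F(phi) with
#' F(phi) = \[1 - cos(phi - phi0)\] + 1/2 \[1 - cos 3(phi - phi0)\],
#' Lennard-Jones 12-6 native contacts with minimum at the native distance,
#' and a purely repulsive excluded volume eps_nc (sigma_nc / r)^12 over
#' non-excluded pairs.
#'
#' @param topo an `sbm_topology`.
#' @param coords n x 3 coordinate matrix (A), or an [sbm_structure].
#' @return named numeric vector of class `energy_breakdown`: bond, angle,
#'   improper, dihedral, contact, excluded_volume, total.
#' @export
potential_energy <- function(topo, coords) {
  xyz <- if (inherits(coords, "sbm_structure")) coords$xyz else
    as.matrix(coords)
  if (nrow(xyz) != topo$n_atoms)
    stop("coordinate count does not match topology")
  if (!all(is.finite(xyz))) stop("non-finite coordinate")
  m <- .topo_mats(topo)
  out <- .cpp_energy_forces(xyz, m$bonds, m$angles, m$impropers,
                            m$dihedrals, m$contacts, m$exclusions,
                            m$params, FALSE)
  e <- out$energy
  structure(c(e, total = sum(e)), class = "energy_breakdown")
}

#' Analytic forces of the SBM potential
#'
#' @inheritParams potential_energy
#' @return n x 3 matrix of forces, -dV/dr (reduced energy / A).
#' @export
forces <- function(topo, coords) {
  xyz <- if (inherits(coords, "sbm_structure")) coords$xyz else
    as.matrix(coords)
  if (nrow(xyz) != topo$n_atoms)
    stop("coordinate count does not match topology")
  if (!all(is.finite(xyz))) stop("non-finite coordinate")
  m <- .topo_mats(topo)
  .cpp_energy_forces(xyz, m$bonds, m$angles, m$impropers, m$dihedrals,
                     m$contacts, m$exclusions, m$params, TRUE)$forces
}

#' Sample candidate conformations by Langevin dynamics
#'
#' Integrates the SBM potential with a BAOAB Langevin scheme (velocity
#' Verlet when `friction = 0`) at unit atom masses, saving a snapshot every
#' `snapshot_interval` reduced time units; the run is deterministic given
#' `p$seed`. Initial velocities are drawn from the Maxwell-Boltzmann
#' distribution at the target temperature (zero at temperature 0).
#'
#' @param topo an `sbm_topology`.
#' @param start an [sbm_structure] (or coordinate matrix) consistent with
#'   the topology.
#' @param p a [sampler_params].
#' @param return_energies logical; attach per-frame potential/kinetic
#'   energy as attribute "energies" (default TRUE).
#' @return a [conformation_set] of the saved snapshots.
#' @export
run_sampling <- function(topo, start, p = sampler_params(),
                         return_energies = TRUE) {
  s <- if (inherits(start, "sbm_structure")) start else NULL
  xyz <- if (is.null(s)) as.matrix(start) else s$xyz
  if (nrow(xyz) != topo$n_atoms)
    stop("start coordinates do not match topology")
  nsteps <- round(p$total_time / p$timestep)
  save_every <- max(1L, round(p$snapshot_interval / p$timestep))
  m <- .topo_mats(topo)
  set.seed(p$seed)
  v0 <- if (p$temperature > 0)
    stats::rnorm(3 * nrow(xyz), sd = sqrt(p$temperature))
  else rep(0, 3 * nrow(xyz))
  res <- .cpp_langevin(xyz, m$bonds, m$angles, m$impropers, m$dihedrals,
                       m$contacts, m$exclusions, m$params, p$timestep,
                       as.integer(nsteps), as.integer(save_every),
                       p$temperature, p$friction, v0, p$energy_bound,
                       as.integer(round(p$equilibration / p$timestep)))
  nf <- nrow(res$frames)
  frames <- lapply(seq_len(nf), function(k)
    matrix(res$frames[k, ], ncol = 3, byrow = TRUE))
  template <- if (is.null(s)) {
    sbm_structure(element = topo$element, resid = topo$resid,
                  chain = topo$chain, xyz = xyz, domain = topo$domain)
  } else s
  cs <- conformation_set(template, frames)
  if (return_energies)
    attr(cs, "energies") <- data.frame(potential = res$potential,
                                       kinetic = res$kinetic)
  cs
}
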