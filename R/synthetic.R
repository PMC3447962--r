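#' Noise model for mock experimental curves
#'
#' Multiplicative Gaussian noise with linear inflation toward high q:
#' sigma(q) = relative_noise * I(q) * (1 + q_growth * q / q_max). The
#' defaults (1% relative noise, 3-fold inflation across the range) emulate
#' the error growth of a typical solution-scattering acquisition without
#' modelling detector specifics.
#'
#' @param relative_noise fractional noise level (> 0), default 0.01.
#' @param q_growth high-q error inflation multiplier, default 3.
#' @param seed RNG seed for the noise realization, default 1.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(relative_noise = 0.01, q_growth = 3, seed = 1L) {
  if (relative_noise <= 0) stop("relative_noise must be > 0")
  structure(list(relative_noise = relative_noise, q_growth = q_growth,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# place `n` atoms as a compact self-avoiding cluster: atom 1 at `start`,
# growth biased toward `center`; sequential 1.5 A bonds, non-bonded pairs
# kept >= `min_sep` from every atom placed so far (incl. `context` atoms)
.grow_cluster <- function(n, start, center = start, context = NULL,
                          bond = 1.5, min_sep = 2.2, max_try = 400) {
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- start
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (t in seq_len(max_try)) {
      # extend from the previous atom; if that region is saturated,
      # branch from a random earlier atom (still a connected cluster)
      anchor <- if (t <= max_try / 2) i - 1L
                else sample.int(i - 1L, 1L)
      dir <- stats::rnorm(3)
      # bias toward the cluster centre to stay globular
      pull <- center - xyz[anchor, ]
      npull <- sqrt(sum(pull^2))
      if (npull > 1e-9)
        dir <- dir + 0.8 * pull / npull * stats::runif(1, 0, 2)
      dir <- dir / sqrt(sum(dir^2))
      cand <- xyz[anchor, ] + bond * dir
      prev <- rbind(context,
                    xyz[setdiff(seq_len(i - 1L), anchor), , drop = FALSE])
      if (is.null(prev) || nrow(prev) == 0L ||
          min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not grow a self-avoiding cluster (steric impossibility);",
           " reduce atoms_per_domain")
  }
  xyz
}

#' Generate a toy multi-domain structure
#'
#' Builds a miniature analog of a multi-domain kinase architecture:
#' `n_domains` compact random self-avoiding globular clusters (1.5 A
#' bonds, non-bonded separations >= 2.2 A) joined by extended linkers,
#' with domain labels D1, D2, ... and "linker". Atoms get a C/N/O element
#' mix and serial residue indices (3 atoms per residue), making the result
#' a valid input for [build_topology()].
#'
#' @param n_domains number of domains (>= 1).
#' @param atoms_per_domain atoms in each domain (default 60).
#' @param linker_length atoms per inter-domain linker (default 8).
#' @param seed RNG seed.
#' @param atoms_per_residue residue granularity (default 3).
#' @return an [sbm_structure].
#' @export
toy_multidomain <- function(n_domains, atoms_per_domain = 60,
                            linker_length = 8, seed = 1L,
                            atoms_per_residue = 3L) {
  if (n_domains < 1) stop("n_domains must be >= 1")
  set.seed(seed)
  # approximate cluster radius, used to aim the growth centres
  rad <- 1.1 * (3 * atoms_per_domain)^(1 / 3)
  bond <- 1.5
  xhat <- c(1, 0, 0)
  xyz_list <- list()
  labels <- character(0)
  placed <- NULL
  for (d in seq_len(n_domains)) {
    if (d == 1L) {
      start <- c(0, 0, 0)
      dom <- .grow_cluster(atoms_per_domain, start, start)
    } else {
      # extended linker: ~1.5 A steps marching outward (away from the
      # previous domain's centroid) with small jitter, then the next
      # domain grows onward from the linker end
      prev_dom <- xyz_list[[length(xyz_list)]]
      # extended architecture: domains strung out along +x; the linker
      # attaches at the +x-most atom of the previous domain and marches
      # onward, so hinge motions swing whole domains
      a <- prev_dom[which.max(prev_dom[, 1]), ]
      out <- xhat
      lk <- matrix(NA_real_, linker_length, 3)
      pos <- a
      for (k in seq_len(linker_length)) {
        best <- NULL
        best_d <- -Inf
        for (t in 1:200) {
          step <- out + stats::rnorm(3, 0, 0.12)
          cand <- pos + bond * step / sqrt(sum(step^2))
          ctx <- rbind(placed, lk[seq_len(k - 1L), , drop = FALSE])
          ctx <- ctx[rowSums(sweep(ctx, 2, pos)^2) > 1e-12, , drop = FALSE]
          dmin <- min(sqrt(rowSums(sweep(ctx, 2, cand)^2)))
          if (dmin > best_d) {
            best <- cand
            best_d <- dmin
          }
          if (dmin >= 2.2) break
        }
        pos <- best
        lk[k, ] <- pos
      }
      xyz_list[[length(xyz_list) + 1L]] <- lk
      labels <- c(labels, rep("linker", linker_length))
      placed <- rbind(placed, lk)
      start <- pos + bond * out
      dom <- .grow_cluster(atoms_per_domain, start,
                           center = start + 0.9 * rad * out,
                           context = placed)
    }
    xyz_list[[length(xyz_list) + 1L]] <- dom
    labels <- c(labels, rep(paste0("D", d), atoms_per_domain))
    placed <- rbind(placed, dom)
  }
  xyz <- do.call(rbind, xyz_list)
  n <- nrow(xyz)
  elem <- rep(c("C", "C", "N", "C", "O"), length.out = n)
  resid <- rep(seq_len(ceiling(n / atoms_per_residue)),
               each = atoms_per_residue)[seq_len(n)]
  sbm_structure(element = elem, resid = resid,
                chain = rep("A", n), xyz = xyz, domain = labels)
}

# rotate points about an axis through `origin` (Rodrigues)
.rotate_about <- function(pts, origin, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  P <- sweep(pts, 2, origin)
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) * ca + sa * K + (1 - ca) * tcrossprod(axis)
  sweep(P %*% t(R), 2, origin, "+")
}

#' Generate a conformer family from a base structure
#'
#' Hinge mode rigidly rotates whole domains (and everything downstream)
#' about pivots at the linker midpoints, spanning compact to extended
#' shapes while preserving all intra-domain distances exactly; the
#' returned series is ordered by strictly increasing Rg. Sampled mode
#' delegates to [run_sampling()] on the structure-based model topology.
#'
#' @param base an [sbm_structure]; hinge mode needs >= 2 domains.
#' @param n number of conformers (>= 1).
#' @param mode "hinge" or "sampled".
#' @param seed RNG seed.
#' @param max_angle largest hinge opening in radians (default pi * 0.6).
#' @param hinge_scale optional per-hinge angle multipliers (length =
#'   number of hinges); unequal values produce mixed hinge states
#'   (L-shapes) instead of uniform folding.
#' @param sampler_params a [sampler_params] for sampled mode.
#' @return a [conformation_set].
#' @export
conformer_family <- function(base, n, mode = c("hinge", "sampled"),
                             seed = 1L, max_angle = pi * 0.6,
                             hinge_scale = NULL, sampler_params = NULL) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be >= 1")
  if (mode == "sampled") {
    topo <- build_topology(base)
    p <- if (is.null(sampler_params))
      sampler_params(total_time = n * 0.5, seed = seed)
    else sampler_params
    return(run_sampling(topo, base, p))
  }
  doms <- setdiff(unique(base$domain), "linker")
  if (length(doms) < 2L) stop("hinge mode needs at least 2 domains")
  set.seed(seed)
  # pivot for domain d: first atom of the linker block preceding it
  idx_of <- lapply(doms, function(d) which(base$domain == d))
  frames <- vector("list", n)
  angles <- seq(0, max_angle, length.out = n) +
    stats::runif(n, 0, 1e-3) # break exact ties
  # rotation axes perpendicular to each downstream block's direction, so
  # the hinge motion actually swings the domain (compaction/extension)
  axes <- lapply(seq_along(doms)[-1], function(k) {
    first_atom <- min(idx_of[[k]])
    pivot <- base$xyz[max(1L, first_atom - 1L), ]
    dir <- colMeans(base$xyz[first_atom:nrow(base$xyz), , drop = FALSE]) -
      pivot
    v <- c(dir[2] * 1 - dir[3] * 0.3,
           dir[3] * 0.7 - dir[1] * 1,
           dir[1] * 0.3 - dir[2] * 0.7) # cross(dir, fixed oblique vector)
    jit <- stats::rnorm(3, 0, 0.2)
    v <- v + jit - dir * sum(jit * dir) / sum(dir^2)
    v / sqrt(sum(v^2))
  })
  if (is.null(hinge_scale)) hinge_scale <- rep(1, length(doms) - 1L)
  if (length(hinge_scale) != length(doms) - 1L)
    stop("hinge_scale must have one entry per hinge")
  for (f in seq_len(n)) {
    xyz <- base$xyz
    for (k in seq_along(doms)[-1]) {
      first_atom <- min(idx_of[[k]])
      pivot <- xyz[max(1L, first_atom - 1L), ]
      moving <- first_atom:nrow(xyz)
      xyz[moving, ] <- .rotate_about(xyz[moving, , drop = FALSE], pivot,
                                     axes[[k - 1L]],
                                     angles[f] * hinge_scale[k - 1L])
    }
    frames[[f]] <- xyz
  }
  cs <- conformation_set(base, frames)
  ord <- order(cs$rg)
  cs <- subset_conformations(cs, ord)
  cs$frame_index <- seq_len(length(cs)) # a fresh ordered series
  cs
}

#' Synthesize a mock experimental scattering curve
#'
#' Forms the noiseless mixture I(q) = sum_i w_i I_i(q) from the member
#' profiles, attaches the q-dependent error
#' sigma(q) = relative_noise * I(q) * (1 + q_growth * q / q_max), adds one
#' Gaussian noise realization epsilon(q) ~ N(0, sigma(q)), and records the
#' ground truth (members, weights, seed) so recovery can be checked.
#'
#' @param members a [conformation_set] of the generating conformers, or a
#'   list of member [saxs_curve]s already on `qgrid`.
#' @param weights numeric mixture weights summing to 1.
#' @param qgrid q values (1/A); default [default_qgrid()].
#' @param noise a [noise_model].
#' @param mode form-factor mode for the member profiles.
#' @return list with elements `curve` (a [saxs_curve] with sigma) and
#'   `ground_truth` (member ids, weights, seed).
#' @export
mock_experiment <- function(members, weights, qgrid = default_qgrid(),
                            noise = noise_model(), mode = "vacuum") {
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1")
  curves <- if (inherits(members, "conformation_set"))
    profile_set(members, qgrid, mode)
  else members
  if (length(curves) != length(weights))
    stop("one weight per member required")
  M <- vapply(curves, `[[`, numeric(length(qgrid)), "I")
  I0 <- as.numeric(matrix(M, ncol = length(curves)) %*% weights)
  sg <- noise$relative_noise * I0 *
    (1 + noise$q_growth * qgrid / max(qgrid))
  set.seed(noise$seed)
  I <- I0 + stats::rnorm(length(I0), 0, sg)
  list(curve = saxs_curve(qgrid, I, sigma = sg),
       ground_truth = list(
         member_ids = if (inherits(members, "conformation_set"))
           members$frame_index else seq_along(curves),
         weights = weights, seed = noise$seed,
         noiseless = saxs_curve(qgrid, I0)))
}
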