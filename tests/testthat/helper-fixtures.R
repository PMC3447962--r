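# shared fixtures and independent oracles used across test files

# hand-assembled topology for term-level checks
make_topo <- function(n, bonds = NULL, angles = NULL, impropers = NULL,
                      dihedrals = NULL, contacts = NULL,
                      exclude_all = TRUE, params = ff_params()) {
  em <- function(m, nc) if (is.null(m)) matrix(numeric(0), 0, nc)
                        else matrix(m, ncol = nc, byrow = TRUE)
  excl <- if (exclude_all && n >= 2) t(utils::combn(n, 2))
          else matrix(numeric(0), 0, 2)
  structure(list(n_atoms = n, element = rep("C", n),
                 domain = rep("D1", n), resid = seq_len(n),
                 chain = rep("A", n),
                 bonds = em(bonds, 3), angles = em(angles, 4),
                 impropers = em(impropers, 5),
                 dihedrals = em(dihedrals, 7), contacts = em(contacts, 4),
                 exclusions = excl, params = params),
            class = "sbm_topology")
}

# central-difference gradient of the total potential (independent oracle)
numeric_forces <- function(topo, x, h = 1e-5, atoms = seq_len(nrow(x))) {
  num <- matrix(0, nrow(x), 3)
  for (i in atoms) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    num[i, d] <- -(potential_energy(topo, xp)[["total"]] -
                   potential_energy(topo, xm)[["total"]]) / (2 * h)
  }
  num
}

# literal O(N^3) Shadow oracle: apply rules (a)-(c) pair by pair
brute_shadow <- function(s, params = ff_params()) {
  xyz <- s$xyz
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d >= params$contact_cutoff) next
    sep_ok <- s$chain[i] != s$chain[j] ||
      abs(s$resid[i] - s$resid[j]) >= params$min_seq_sep
    if (!sep_ok) next
    blocked <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      dik <- sqrt(sum((xyz[k, ] - xyz[i, ])^2))
      djk <- sqrt(sum((xyz[k, ] - xyz[j, ])^2))
      if (dik >= params$contact_cutoff || djk >= params$contact_cutoff)
        next
      ab <- xyz[j, ] - xyz[i, ]
      t <- sum((xyz[k, ] - xyz[i, ]) * ab) / sum(ab^2)
      if (t <= 0 || t >= 1) next
      perp <- xyz[k, ] - (xyz[i, ] + t * ab)
      if (sum(perp^2) < params$shadow_radius^2) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) out[[length(out) + 1]] <- c(i, j)
  }
  if (!length(out)) return(matrix(numeric(0), 0, 2))
  do.call(rbind, out)
}

# naive double-loop Debye oracle
naive_debye <- function(xyz, elements, q, mode = "vacuum") {
  G <- if (identical(elements[1], "POINT"))
    matrix(1, length(q), nrow(xyz))
  else form_factors(elements, q, mode)
  I <- numeric(length(q))
  for (i in seq_len(nrow(xyz))) for (j in seq_len(nrow(xyz))) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    x <- q * r
    sinc <- ifelse(x < 1e-12, 1, sin(x) / x)
    I <- I + G[, i] * G[, j] * sinc
  }
  I
}

# random rigid motion of a coordinate matrix
random_rigid <- function(xyz) {
  A <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(xyz %*% R, 2, stats::rnorm(3, 0, 20), "+")
}

# small structure with arbitrary coordinates/resids for shadow rule tests
place_atoms <- function(xyz, resid, chain = NULL, domain = NULL) {
  n <- nrow(xyz)
  sbm_structure(element = rep("C", n), resid = resid,
                chain = if (is.null(chain)) rep("A", n) else chain,
                xyz = xyz,
                domain = if (is.null(domain)) rep("D1", n) else domain)
}

# shared expensive fixture: multi-start sampled candidate pool of the
# 2-domain toy, with profiles and three shape-distinct generator picks.
# built once per test run.
.pool_cache <- new.env(parent = emptyenv())
shared_pool_fixture <- function() {
  if (!is.null(.pool_cache$fix)) return(.pool_cache$fix)
  toy <- toy_multidomain(2, atoms_per_domain = 40, linker_length = 8,
                         seed = 101)
  topo <- build_topology(toy)
  starts <- conformer_family(toy, 3, mode = "hinge", seed = 101)
  pool <- bind_conformations(lapply(1:3, function(i)
    run_sampling(topo, starts$frames[[i]],
                 sampler_params(total_time = 400,
                                snapshot_interval = 0.5,
                                equilibration = 10,
                                seed = 41L + i))))
  curves <- profile_set(pool)
  picks <- pick_distinct(pool, curves, 3)
  .pool_cache$fix <- list(toy = toy, topo = topo, pool = pool,
                          curves = curves, picks = picks,
                          gen_curves = curves[picks])
  .pool_cache$fix
}

# greedy max-min selection of k shape-distinct conformers (scale-free
# profile distance); seeds with the most compact and most extended frames
pick_distinct <- function(pool, curves, k) {
  M <- vapply(curves, `[[`, numeric(length(curves[[1]]$q)), "I")
  sdist <- function(a, b) {
    cc <- sum(M[, a] * M[, b]) / sum(M[, b]^2)
    sqrt(mean((M[, a] - cc * M[, b])^2 / M[, a]^2))
  }
  picks <- c(which.min(pool$rg), which.max(pool$rg))
  while (length(picks) < k) {
    cand <- setdiff(seq_len(ncol(M)), picks)
    d <- vapply(cand, function(j)
      min(vapply(picks, function(a) sdist(a, j), numeric(1))), numeric(1))
    picks <- c(picks, cand[which.max(d)])
  }
  picks[order(pool$rg[picks])]
}
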