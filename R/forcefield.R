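#' Structure-based model forcefield parameters
#'
#' Parameter set for the all-atom structure-based (Go-type) forcefield:
#' harmonic bond/angle/improper stiffnesses, excluded-volume term, native
#' contact definition and Shadow screening radius. Energies are in reduced
#' units; lengths in Angstrom.
#'
#' @param eps_r bond stiffness (reduced energy / A^2), default 100.
#' @param eps_theta angle stiffness (reduced energy / rad^2), default 20.
#' @param eps_xi improper/planarity stiffness (reduced energy / rad^2),
#'   default 10.
#' @param eps_nc excluded-volume strength (reduced energy), default 0.01.
#' @param sigma_nc excluded-volume diameter (A), default 2.5.
#' @param contact_cutoff native contact distance cutoff (A), default 6.
#' @param min_seq_sep minimum residue separation for a contact, default 4.
#' @param shadow_radius screening radius of the Shadow algorithm (A),
#'   default 1.
#' @param eps_rigid stiffness of orbital-hybridization-rigid (peptide
#'   omega, ring, sp2 planarity) proper dihedrals, default 10.
#' @param contact_dihedral_ratio ratio of total stabilizing contact energy
#'   to total stabilizing dihedral energy, default 2.
#' @param eps_unit stabilizing energy per atom used by the normalization,
#'   default 1.
#' @return a list of class `ff_params`.
#' @export
ff_params <- function(eps_r = 100, eps_theta = 20, eps_xi = 10,
                      eps_nc = 0.01, sigma_nc = 2.5,
                      contact_cutoff = 6, min_seq_sep = 4,
                      shadow_radius = 1, eps_rigid = 10,
                      contact_dihedral_ratio = 2, eps_unit = 1) {
  p <- list(eps_r = eps_r, eps_theta = eps_theta, eps_xi = eps_xi,
            eps_nc = eps_nc, sigma_nc = sigma_nc,
            contact_cutoff = contact_cutoff, min_seq_sep = min_seq_sep,
            shadow_radius = shadow_radius, eps_rigid = eps_rigid,
            contact_dihedral_ratio = contact_dihedral_ratio,
            eps_unit = eps_unit)
  if (any(unlist(p) <= 0))
    stop("all forcefield parameters must be strictly positive")
  if (contact_cutoff <= sigma_nc)
    stop("contact_cutoff must exceed sigma_nc")
  class(p) <- "ff_params"
  p
}

# covalent radii (A) for distance-based bond perception
.COV_RADIUS <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                 P = 1.07, SE = 1.20, FE = 1.32, ZN = 1.22, MG = 1.41,
                 CA = 1.76, MN = 1.39)

# all covalent bonds: pairs with d < r_i + r_j + 0.4 A (covers the
# disulfide rule: S-S perceived out to 2.5 A)
.perceive_bonds <- function(s) {
  xyz <- s$xyz
  n <- nrow(xyz)
  if (n < 2L) return(matrix(numeric(0), 0, 3))
  rc <- .COV_RADIUS[s$element]
  if (anyNA(rc))
    stop("no covalent radius for element(s): ",
         paste(unique(s$element[is.na(rc)]), collapse = ", "),
         " (unknown residue chemistry)")
  D <- as.matrix(stats::dist(xyz))
  cut <- outer(rc, rc, "+") + 0.4
  hit <- which(D < cut & upper.tri(D), arr.ind = TRUE)
  if (nrow(hit) == 0L) return(matrix(numeric(0), 0, 3))
  cbind(i = hit[, 1], j = hit[, 2], r0 = D[hit])
}

# adjacency list from a bond matrix
.neighbors <- function(bonds, n) {
  nb <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, sort)
}

# interior angle at j (rad) for rows of (i, j, k)
.angle_values <- function(xyz, ijk) {
  u <- xyz[ijk[, 1], , drop = FALSE] - xyz[ijk[, 2], , drop = FALSE]
  v <- xyz[ijk[, 3], , drop = FALSE] - xyz[ijk[, 2], , drop = FALSE]
  cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
  acos(pmin(1, pmax(-1, cosang)))
}

# signed dihedral (rad) for rows of (i, j, k, l)
.dihedral_values <- function(xyz, ijkl) {
  b1 <- xyz[ijkl[, 2], , drop = FALSE] - xyz[ijkl[, 1], , drop = FALSE]
  b2 <- xyz[ijkl[, 3], , drop = FALSE] - xyz[ijkl[, 2], , drop = FALSE]
  b3 <- xyz[ijkl[, 4], , drop = FALSE] - xyz[ijkl[, 3], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

#' Shadow contact map
#'
#' A native contact is an atom pair that (a) lies closer than
#' `contact_cutoff`, (b) is separated by at least `min_seq_sep` residues in
#' sequence (pairs on different chains always qualify), and (c) has an
#' unoccluded line of sight: no third atom within `contact_cutoff` of both
#' partners comes closer than `shadow_radius` to the open segment joining
#' them (the Shadow algorithm).
#'
#' @param s an [sbm_structure] with at least 2 residues.
#' @param params an [ff_params].
#' @return matrix with columns i, j (i < j) and r0, the native distance.
#' @export
shadow_contacts <- function(s, params = ff_params()) {
  xyz <- s$xyz
  n <- nrow(xyz)
  if (length(unique(paste(s$chain, s$resid))) < 2L)
    stop("structure must contain at least 2 residues")
  D <- as.matrix(stats::dist(xyz))
  sep_ok <- outer(s$resid, s$resid, function(a, b) abs(a - b)) >=
    params$min_seq_sep
  sep_ok <- sep_ok | outer(s$chain, s$chain, "!=")
  cand <- which(D < params$contact_cutoff & sep_ok & upper.tri(D),
                arr.ind = TRUE)
  if (nrow(cand) == 0L) return(cbind(i = numeric(0), j = numeric(0),
                                     r0 = numeric(0)))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    ks <- which(D[i, ] < params$contact_cutoff &
                D[j, ] < params$contact_cutoff)
    ks <- ks[ks != i & ks != j]
    keep[r] <- !.any_shadowed(xyz[i, ], xyz[j, ],
                              xyz[ks, , drop = FALSE],
                              params$shadow_radius)
  }
  kept <- cand[keep, , drop = FALSE]
  cbind(i = kept[, 1], j = kept[, 2], r0 = D[kept])
}

# TRUE if any row of K occludes segment a-b: perpendicular distance to the
# open segment (projection strictly interior) below `radius`
.any_shadowed <- function(a, b, K, radius) {
  if (nrow(K) == 0L) return(FALSE)
  ab <- b - a
  L2 <- sum(ab^2)
  t <- (sweep(K, 2, a) %*% ab) / L2
  interior <- t > 0 & t < 1
  if (!any(interior)) return(FALSE)
  P <- outer(t[interior], ab) + rep(a, each = sum(interior))
  d2 <- rowSums((K[interior, , drop = FALSE] - P)^2)
  any(d2 < radius^2)
}

#' Build a structure-based model topology from a native structure
#'
#' Enumerates bonded terms from covalent connectivity (perceived from
#' covalent radii), takes native reference values for every term, computes
#' the Shadow contact map and removes every contact whose two atoms carry
#' different domain labels (the linker counts as its own label), so that
#' only steric interactions act between domains. One proper dihedral is
#' assigned per rotatable central bond; dihedrals at sp2-like planar
#' centres are flagged rigid and keep a fixed stiffness, and non-rigid
#' dihedrals whose four atoms do not share one domain label carry weight 0
#' (free linker dihedrals). Planar 3-coordinate centres get harmonic
#' improper terms. Stabilizing weights are then normalized with
#' [assign_energy_weights()].
#'
#' @param s an [sbm_structure] with domain labels.
#' @param params an [ff_params].
#' @param contacts optional user-supplied contact list (matrix i, j or
#'   i, j, r0) overriding the Shadow map.
#' @param normalize logical, run [assign_energy_weights()] (default TRUE).
#' @return an object of class `sbm_topology`.
#' @export
build_topology <- function(s, params = ff_params(), contacts = NULL,
                           normalize = TRUE) {
  xyz <- s$xyz
  n <- nrow(xyz)
  bonds <- .perceive_bonds(s)
  nb <- .neighbors(bonds, n)

  # angles: every pair of neighbours about each centre
  ang <- list()
  for (j in seq_len(n)) {
    nbj <- nb[[j]]
    if (length(nbj) >= 2L) {
      pr <- utils::combn(nbj, 2)
      ang[[length(ang) + 1L]] <- cbind(pr[1, ], j, pr[2, ])
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else
    matrix(numeric(0), 0, 3)
  if (nrow(angles))
    angles <- cbind(angles, theta0 = .angle_values(xyz, angles))
  else angles <- cbind(angles, theta0 = numeric(0))
  colnames(angles) <- c("i", "j", "k", "theta0")

  # planar sp2-like centres: 3 neighbours, improper within 10 deg of flat
  planar <- logical(n)
  imp <- list()
  for (j in seq_len(n)) {
    nbj <- nb[[j]]
    if (length(nbj) == 3L) {
      q <- matrix(c(nbj[1], j, nbj[2], nbj[3]), 1, 4)
      xi <- .dihedral_values(xyz, q)
      dev <- min(abs(xi), abs(abs(xi) - pi))
      if (dev < 10 * pi / 180) {
        planar[j] <- TRUE
        imp[[length(imp) + 1L]] <- cbind(q, xi0 = xi)
      }
    }
  }
  impropers <- if (length(imp)) do.call(rbind, imp) else
    matrix(numeric(0), 0, 5)
  colnames(impropers) <- c("i", "j", "k", "l", "xi0")

  # one proper dihedral per central bond with flanking atoms
  dih <- list()
  for (r in seq_len(nrow(bonds))) {
    j <- bonds[r, 1]; k <- bonds[r, 2]
    is <- setdiff(nb[[j]], k); ls <- setdiff(nb[[k]], j)
    if (length(is) && length(ls))
      dih[[length(dih) + 1L]] <- c(min(is), j, k, min(ls))
  }
  dihedrals <- if (length(dih)) do.call(rbind, dih) else
    matrix(numeric(0), 0, 4)
  if (nrow(dihedrals)) {
    phi0 <- .dihedral_values(xyz, dihedrals)
    rigid <- planar[dihedrals[, 2]] | planar[dihedrals[, 3]]
    same_dom <- s$domain[dihedrals[, 1]] == s$domain[dihedrals[, 2]] &
      s$domain[dihedrals[, 2]] == s$domain[dihedrals[, 3]] &
      s$domain[dihedrals[, 3]] == s$domain[dihedrals[, 4]]
    weight <- ifelse(rigid, params$eps_rigid,
                     ifelse(same_dom, 1, 0)) # 1 = placeholder, normalized
    dihedrals <- cbind(dihedrals, phi0 = phi0, weight = weight,
                       rigid = as.numeric(rigid))
  } else {
    dihedrals <- cbind(dihedrals, phi0 = numeric(0), weight = numeric(0),
                       rigid = numeric(0))
  }
  colnames(dihedrals)[1:4] <- c("i", "j", "k", "l")

  # contacts: shadow map (or override) minus inter-label pairs
  cm <- if (is.null(contacts)) shadow_contacts(s, params) else {
    contacts <- as.matrix(contacts)
    if (ncol(contacts) == 2L) {
      d <- sqrt(rowSums((xyz[contacts[, 1], , drop = FALSE] -
                         xyz[contacts[, 2], , drop = FALSE])^2))
      contacts <- cbind(contacts, d)
    }
    ii <- pmin(contacts[, 1], contacts[, 2])
    jj <- pmax(contacts[, 1], contacts[, 2])
    cbind(i = ii, j = jj, r0 = contacts[, 3])
  }
  if (nrow(cm)) {
    intra <- s$domain[cm[, 1]] == s$domain[cm[, 2]]
    cm <- cm[intra, , drop = FALSE]
  }
  contacts_m <- cbind(cm, eps = rep(1, nrow(cm)))

  # non-bonded exclusions: 1-2, 1-3, 1-4 and native-contact pairs
  excl <- rbind(bonds[, 1:2, drop = FALSE],
                if (nrow(angles)) angles[, c(1, 3), drop = FALSE],
                if (nrow(dihedrals)) dihedrals[, c(1, 4), drop = FALSE],
                if (nrow(contacts_m)) contacts_m[, 1:2, drop = FALSE])
  if (is.null(excl)) excl <- matrix(numeric(0), 0, 2)
  if (nrow(excl)) {
    excl <- cbind(pmin(excl[, 1], excl[, 2]), pmax(excl[, 1], excl[, 2]))
    excl <- unique(excl)
    excl <- excl[excl[, 1] != excl[, 2], , drop = FALSE]
  }
  colnames(excl) <- c("i", "j")

  topo <- structure(
    list(n_atoms = n, element = s$element, domain = s$domain,
         resid = s$resid, chain = s$chain,
         bonds = bonds, angles = angles, impropers = impropers,
         dihedrals = dihedrals, contacts = contacts_m,
         exclusions = excl, params = params),
    class = "sbm_topology")
  if (normalize) topo <- assign_energy_weights(topo)
  topo
}

#' @export
print.sbm_topology <- function(x, ...) {
  cat("sbm_topology:", x$n_atoms, "atoms |",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$impropers), "impropers,", nrow(x$dihedrals), "dihedrals,",
      nrow(x$contacts), "contacts\n")
  invisible(x)
}

#' Normalize stabilizing contact and dihedral weights
#'
#' Distributes the total stabilizing energy N_atoms * eps_unit over native
#' contacts and non-rigid intra-domain dihedrals at the fixed ratio
#' `contact_dihedral_ratio` (default 2:1), with every contact receiving the
#' same epsilon and every weighted dihedral the same weight. Rigid
#' dihedrals and zero-weight (linker) dihedrals are untouched. If one class
#' is empty its share moves to the other.
#'
#' @param topo an `sbm_topology`.
#' @return the topology with contact `eps` and dihedral `weight` columns
#'   normalized.
#' @export
assign_energy_weights <- function(topo) {
  p <- topo$params
  total <- topo$n_atoms * p$eps_unit
  r <- p$contact_dihedral_ratio
  n_c <- nrow(topo$contacts)
  eligible <- topo$dihedrals[, "rigid"] == 0 & topo$dihedrals[, "weight"] > 0
  n_d <- sum(eligible)
  e_c <- total * r / (r + 1)
  e_d <- total / (r + 1)
  if (n_c == 0L) { e_d <- e_d + e_c; e_c <- 0 }
  if (n_d == 0L) { e_c <- e_c + e_d; e_d <- 0 }
  if (n_c > 0L) topo$contacts[, "eps"] <- e_c / n_c
  if (n_d > 0L) topo$dihedrals[eligible, "weight"] <- e_d / n_d
  topo
}

#' Serialize a topology to a plain-text term-list file
#'
#' Sections (atoms, bonds, angles, impropers, dihedrals, contacts,
#' exclusions, params) written as whitespace-delimited tables with
#' `[section]` headers; readable back with [read_topology()].
#'
#' @param topo an `sbm_topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  emit <- function(name, m) {
    writeLines(paste0("[", name, "]"), con)
    if (is.matrix(m) && nrow(m)) {
      writeLines(paste(colnames(m), collapse = " "), con)
      utils::write.table(format(m, digits = 17, trim = TRUE), con,
                         row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    } else if (is.matrix(m)) {
      writeLines(paste(colnames(m), collapse = " "), con)
    }
  }
  writeLines("[params]", con)
  pu <- unclass(topo$params)
  writeLines(paste(names(pu), unlist(pu)), con)
  writeLines("[atoms]", con)
  writeLines("element domain resid chain", con)
  writeLines(paste(topo$element, topo$domain, topo$resid, topo$chain), con)
  emit("bonds", topo$bonds)
  emit("angles", topo$angles)
  emit("impropers", topo$impropers)
  emit("dihedrals", topo$dihedrals)
  emit("contacts", topo$contacts)
  emit("exclusions", topo$exclusions)
  invisible(path)
}

#' Read a topology written by [write_topology()]
#'
#' @param path input path.
#' @return an `sbm_topology`.
#' @export
read_topology <- function(path) {
  ln <- readLines(path)
  sec_at <- grep("^\\[", ln)
  names(sec_at) <- gsub("\\[|\\]", "", ln[sec_at])
  block <- function(name) {
    k <- which(names(sec_at) == name)
    if (!length(k)) return(character(0))
    from <- sec_at[k] + 1L
    to <- if (k == length(sec_at)) length(ln) else sec_at[k + 1L] - 1L
    out <- ln[seq(from, length.out = max(0L, to - from + 1L))]
    out[nzchar(trimws(out))]
  }
  parse_mat <- function(lines) {
    if (length(lines) <= 1L) {
      hdr <- if (length(lines)) strsplit(lines[1], " +")[[1]] else character(0)
      m <- matrix(numeric(0), 0, length(hdr))
      colnames(m) <- hdr
      return(m)
    }
    hdr <- strsplit(lines[1], " +")[[1]]
    vals <- do.call(rbind, lapply(strsplit(trimws(lines[-1]), " +"),
                                  as.numeric))
    colnames(vals) <- hdr
    vals
  }
  pl <- strsplit(block("params"), " +")
  pv <- as.numeric(vapply(pl, `[`, character(1), 2))
  names(pv) <- vapply(pl, `[`, character(1), 1)
  params <- do.call(ff_params, as.list(pv))
  al <- strsplit(block("atoms")[-1], " +")
  topo <- structure(
    list(n_atoms = length(al),
         element = vapply(al, `[`, character(1), 1),
         domain = vapply(al, `[`, character(1), 2),
         resid = as.integer(vapply(al, `[`, character(1), 3)),
         chain = vapply(al, `[`, character(1), 4),
         bonds = parse_mat(block("bonds")),
         angles = parse_mat(block("angles")),
         impropers = parse_mat(block("impropers")),
         dihedrals = parse_mat(block("dihedrals")),
         contacts = parse_mat(block("contacts")),
         exclusions = parse_mat(block("exclusions")),
         params = params),
    class = "sbm_topology")
  topo
}
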