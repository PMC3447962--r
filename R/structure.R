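#' Atomic structure objects
#'
#' An `sbm_structure` is a heavy-atom model of a (possibly multi-domain)
#' protein or toy molecule: element symbols, serial residue indices, chain
#' identifiers, Cartesian coordinates in Angstrom, and a domain label per
#' atom. It is the conformational state unit used throughout the package.
#'
#' @param element character vector of element symbols (e.g. "C", "N").
#' @param resid integer vector of residue indices, non-decreasing per chain.
#' @param chain character vector of chain identifiers.
#' @param xyz numeric matrix with one row per atom and columns x, y, z (A).
#' @param domain character vector of domain labels, one per atom.
#' @param atom_name optional character vector of atom names.
#' @param res_name optional character vector of residue names.
#'
#' @return An object of class `sbm_structure`.
#' @export
sbm_structure <- function(element, resid, chain, xyz, domain,
                          atom_name = NULL, res_name = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L)
    stop("xyz must have three columns")
  n <- nrow(xyz)
  if (n < 1L)
    stop("structure must contain at least one atom")
  if (length(element) != n || length(resid) != n ||
      length(chain) != n || length(domain) != n)
    stop("element, resid, chain and domain must each have one entry per atom")
  if (!all(is.finite(xyz)))
    stop("all coordinates must be finite")
  for (ch in unique(chain)) {
    r <- resid[chain == ch]
    if (is.unsorted(r))
      stop("residue indices must be non-decreasing within chain ", ch)
  }
  structure(
    list(element = toupper(as.character(element)),
         resid = as.integer(resid),
         chain = as.character(chain),
         domain = as.character(domain),
         xyz = unname(xyz),
         atom_name = if (is.null(atom_name)) toupper(as.character(element))
                     else as.character(atom_name),
         res_name = if (is.null(res_name)) rep("UNK", n)
                    else as.character(res_name)),
    class = "sbm_structure")
}

#' @export
print.sbm_structure <- function(x, ...) {
  cat("sbm_structure:", n_atoms(x), "atoms,",
      length(unique(paste(x$chain, x$resid))), "residues\n")
  tab <- table(x$domain)
  cat("domains:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s an `sbm_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$xyz)

# standard atomic masses (u), heavy atoms + H for completeness
.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, SE = 78.971, FE = 55.845,
                  ZN = 65.38, MG = 24.305, CA = 40.078, MN = 54.938)

#' Standard atomic masses
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in unified atomic mass units.
#' @export
atomic_mass <- function(element) {
  m <- .ATOMIC_MASS[toupper(element)]
  if (anyNA(m))
    stop("no mass tabulated for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Read a heavy-atom structure from a PDB file
#'
#' Parses ATOM records (via bio3d), keeping the first alternate location
#' (blank or "A"), dropping hydrogens and all non-protein (HETATM) content,
#' and assigning each residue a domain label from `domain_map`. Residues not
#' covered by any named domain receive `linker_label`; pass
#' `linker_label = NULL` to make uncovered residues an error.
#'
#' @param path path to a PDB file.
#' @param domain_map named list; each entry is `c(first, last)` residue
#'   numbers (inclusive) for that domain, or an integer vector of residues.
#' @param linker_label label for residues outside every named domain
#'   (default "linker"), or NULL to forbid uncovered residues.
#' @return an [sbm_structure].
#' @export
read_pdb <- function(path, domain_map, linker_label = "linker") {
  if (!file.exists(path))
    stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no ATOM records found (HETATM-only or empty file)")
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported; renumber residues serially")
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]
  ele <- toupper(at$elesy)
  blank <- is.na(ele) | !nzchar(ele)
  if (any(blank)) # fall back to first letter of the atom name
    ele[blank] <- substr(gsub("[^A-Za-z].*$", "",
                              gsub("^[0-9]+", "", at$elety[blank])), 1, 1)
  heavy <- ele != "H" & ele != "D"
  at <- at[heavy, , drop = FALSE]
  ele <- ele[heavy]
  if (nrow(at) == 0L)
    stop("no heavy atoms left after filtering")
  dom <- .map_domains(at$resno, domain_map, linker_label)
  sbm_structure(element = ele, resid = at$resno, chain = at$chain,
                xyz = cbind(at$x, at$y, at$z), domain = dom,
                atom_name = at$elety, res_name = at$resid)
}

.map_domains <- function(resno, domain_map, linker_label) {
  if (is.null(domain_map) || length(domain_map) == 0L)
    stop("domain_map must name at least one domain")
  if (is.null(names(domain_map)) || any(!nzchar(names(domain_map))))
    stop("domain_map entries must be named")
  dom <- rep(NA_character_, length(resno))
  for (lab in names(domain_map)) {
    rr <- unlist(domain_map[[lab]])
    covered <- if (length(rr) == 2L) resno >= rr[1] & resno <= rr[2]
               else resno %in% rr
    dom[covered] <- lab
  }
  if (anyNA(dom)) {
    if (is.null(linker_label))
      stop("residue(s) not covered by domain_map: ",
           paste(utils::head(unique(resno[is.na(dom)]), 5), collapse = ", "))
    dom[is.na(dom)] <- linker_label
  }
  dom
}

#' Mass-weighted radius of gyration
#'
#' Rg = sqrt( sum_i m_i |r_i - r_cm|^2 / sum_i m_i ) with standard atomic
#' masses and the mass-weighted centroid r_cm (the convention used by
#' Gromacs' g_gyrate).
#'
#' @param s an [sbm_structure], or a numeric n x 3 coordinate matrix
#'   (unit masses assumed for a bare matrix unless `masses` is given).
#' @param masses optional numeric vector of per-atom masses.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(s, masses = NULL) {
  if (inherits(s, "sbm_structure")) {
    xyz <- s$xyz
    if (is.null(masses)) masses <- atomic_mass(s$element)
  } else {
    xyz <- as.matrix(s)
    if (is.null(masses)) masses <- rep(1, nrow(xyz))
  }
  if (nrow(xyz) < 1L) stop("empty structure")
  w <- masses / sum(masses)
  cm <- colSums(xyz * w)
  d2 <- rowSums(sweep(xyz, 2, cm)^2)
  sqrt(sum(w * d2))
}

# Kabsch optimal rotation aligning moving B onto fixed A (both centred)
.kabsch <- function(A, B) {
  H <- crossprod(B, A) # maximize tr(R' H) over rotations R (B %*% R ~ A)
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Minimum RMSD after optimal rigid-body superposition
#'
#' Centres both coordinate sets, finds the optimal rotation (Kabsch/SVD)
#' and returns the root-mean-square atomic deviation of the superposed
#' pair. Atoms are paired by index.
#'
#' @param a,b [sbm_structure] objects or n x 3 coordinate matrices with the
#'   same atom count and ordering.
#' @return RMSD in Angstrom.
#' @export
rmsd_superposed <- function(a, b) {
  A <- if (inherits(a, "sbm_structure")) a$xyz else as.matrix(a)
  B <- if (inherits(b, "sbm_structure")) b$xyz else as.matrix(b)
  if (nrow(A) != nrow(B))
    stop("structures must have the same atom count and ordering")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  R <- .kabsch(A, B)
  sqrt(mean(rowSums((B %*% R - A)^2)))
}

#' Conformation sets
#'
#' A `conformation_set` holds an ordered list of conformations sharing one
#' topology: a template [sbm_structure] plus a list of coordinate frames
#' with identical atom count and ordering, annotated with the frame index
#' and mass-weighted Rg of each frame.
#'
#' @param template an [sbm_structure] providing elements/residues/domains.
#' @param frames list of n x 3 coordinate matrices.
#' @param frame_index optional integer vector of frame labels.
#' @return an object of class `conformation_set`.
#' @export
conformation_set <- function(template, frames, frame_index = NULL) {
  stopifnot(inherits(template, "sbm_structure"))
  n <- n_atoms(template)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != n || ncol(f) != 3L)
      stop("every frame must be an n x 3 matrix matching the template")
    unname(f)
  })
  if (is.null(frame_index)) frame_index <- seq_along(frames)
  m <- atomic_mass(template$element)
  rg <- vapply(frames, radius_of_gyration, numeric(1), masses = m)
  structure(list(template = template, frames = frames,
                 frame_index = as.integer(frame_index), rg = rg),
            class = "conformation_set")
}

#' @export
print.conformation_set <- function(x, ...) {
  cat("conformation_set:", length(x$frames), "frames,",
      n_atoms(x$template), "atoms\n")
  if (length(x$rg))
    cat(sprintf("Rg range: %.2f - %.2f A\n", min(x$rg), max(x$rg)))
  invisible(x)
}

#' @export
length.conformation_set <- function(x) length(x$frames)

#' Extract one frame of a conformation set as a structure
#' @param cs a [conformation_set].
#' @param i frame position.
#' @return an [sbm_structure].
#' @export
get_frame <- function(cs, i) {
  s <- cs$template
  s$xyz <- cs$frames[[i]]
  s
}

#' Concatenate conformation sets sharing one template
#'
#' Frames are renumbered sequentially; all sets must have identical atom
#' counts. Used to pool several sampling runs (e.g. launched from
#' different starting conformations) into one candidate pool.
#'
#' @param sets list of [conformation_set] objects.
#' @return a single [conformation_set].
#' @export
bind_conformations <- function(sets) {
  stopifnot(length(sets) >= 1L)
  n <- n_atoms(sets[[1]]$template)
  for (s in sets)
    if (n_atoms(s$template) != n)
      stop("all sets must share one template")
  frames <- do.call(c, lapply(sets, `[[`, "frames"))
  conformation_set(sets[[1]]$template, frames)
}

#' Subset a conformation set
#' @param cs a [conformation_set].
#' @param idx positions to keep.
#' @return a [conformation_set].
#' @export
subset_conformations <- function(cs, idx) {
  structure(list(template = cs$template, frames = cs$frames[idx],
                 frame_index = cs$frame_index[idx], rg = cs$rg[idx]),
            class = "conformation_set")
}

# fixed-width PDB ATOM line
.pdb_atom_line <- function(i, name, resname, chain, resno, xyz, element) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000L, substr(name, 1, 4), substr(resname, 1, 3),
          substr(chain, 1, 1), resno %% 10000L,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Write structures to a (multi-model) PDB file
#'
#' A single [sbm_structure] is written as plain ATOM records; a
#' [conformation_set] is written with MODEL/ENDMDL wrappers, one model per
#' frame.
#'
#' @param x an [sbm_structure] or [conformation_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fmt_one <- function(s) {
    vapply(seq_len(n_atoms(s)), function(i)
      .pdb_atom_line(i, s$atom_name[i], s$res_name[i], s$chain[i],
                     s$resid[i], s$xyz[i, ], s$element[i]),
      character(1))
  }
  if (inherits(x, "sbm_structure")) {
    writeLines(c(fmt_one(x), "END"), path)
  } else if (inherits(x, "conformation_set")) {
    con <- file(path, "w")
    on.exit(close(con))
    s <- x$template
    for (k in seq_along(x$frames)) {
      s$xyz <- x$frames[[k]]
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(fmt_one(s), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else stop("x must be an sbm_structure or conformation_set")
  invisible(path)
}

#' Read a multi-model PDB trajectory into a conformation set
#'
#' @param path path to a multi-model PDB written by [write_pdb()].
#' @param domain_map,linker_label as in [read_pdb()].
#' @return a [conformation_set].
#' @export
read_models <- function(path, domain_map, linker_label = "linker") {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records found")
  template <- read_pdb(path, domain_map, linker_label)
  nm <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nm), function(k)
    matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE))
  conformation_set(template, frames)
}
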