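# Cromer-Mann vacuum form factor coefficients (international tables),
# f(q) = sum_k a_k exp(-b_k (q/4pi)^2) + c; f(0) = Z to < 1e-3.
.CROMER_MANN <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
           b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900))

# displaced solvent volumes (A^3) for the Gaussian dummy-atom subtraction
.SOLVENT_VOLUME <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13,
                     P = 5.73, S = 19.86)

.WATER_EDENS <- 0.334 # bulk water electron density, e / A^3

#' Atomic X-ray form factors
#'
#' Vacuum form factors from the tabulated Cromer-Mann Gaussian
#' parameterization (f(0) equals the electron count); in solvent-corrected
#' mode a Gaussian dummy-atom term rho_s V exp(-q^2 V^(2/3) / 4 pi) with
#' bulk water density rho_s = 0.334 e/A^3 is subtracted, the standard
#' displaced-solvent treatment.
#'
#' @param element character vector of element symbols.
#' @param q numeric vector of momentum transfer values (1/A).
#' @param mode "vacuum" or "solvent".
#' @return matrix of form factors, `length(q)` rows x `length(element)`
#'   columns.
#' @export
form_factors <- function(element, q, mode = c("vacuum", "solvent")) {
  mode <- match.arg(mode)
  element <- toupper(element)
  unknown <- setdiff(unique(element), names(.CROMER_MANN))
  if (length(unknown))
    stop("no form factor tabulated for element(s): ",
         paste(unknown, collapse = ", "))
  s2 <- (q / (4 * pi))^2
  per_elem <- lapply(unique(element), function(e) {
    cm <- .CROMER_MANN[[e]]
    f <- rep(cm$c, length(q))
    for (k in 1:4) f <- f + cm$a[k] * exp(-cm$b[k] * s2)
    if (mode == "solvent") {
      V <- .SOLVENT_VOLUME[[e]]
      f <- f - .WATER_EDENS * V * exp(-q^2 * V^(2 / 3) / (4 * pi))
    }
    f
  })
  names(per_elem) <- unique(element)
  out <- vapply(element, function(e) per_elem[[e]], numeric(length(q)))
  matrix(out, nrow = length(q), ncol = length(element))
}

#' Default momentum-transfer grid
#'
#' 100 points spanning q = 0.01 to 0.18 1/A, mirroring the standard
#' small-angle acquisition range for this problem class.
#'
#' @param n number of points (default 100).
#' @param qmin,qmax grid limits (1/A).
#' @return numeric vector.
#' @export
default_qgrid <- function(n = 100, qmin = 0.01, qmax = 0.18) {
  seq(qmin, qmax, length.out = n)
}

#' Theoretical scattering profile by the Debye equation
#'
#' I(q) = sum_i sum_j g_i(q) g_j(q) sin(q r_ij) / (q r_ij), evaluated
#' exactly over all atom pairs with tabulated atomic form factors
#' (optionally solvent-corrected); the q -> 0 limit sinc(0) = 1 is handled
#' analytically. Rotation- and translation-invariant by construction.
#'
#' @param s an [sbm_structure] (or coordinate matrix with `elements`).
#' @param qgrid numeric vector of non-negative q values (1/A); default
#'   [default_qgrid()].
#' @param mode "vacuum" (default) or "solvent" (dummy-atom corrected).
#' @param elements element symbols when `s` is a bare matrix; a unit point
#'   scatterer (g = 1) is used when `elements = "POINT"`.
#' @return a [saxs_curve] (no error column).
#' @export
debye_profile <- function(s, qgrid = default_qgrid(),
                          mode = c("vacuum", "solvent"), elements = NULL) {
  mode <- match.arg(mode)
  if (inherits(s, "sbm_structure")) {
    xyz <- s$xyz
    elements <- s$element
  } else {
    xyz <- as.matrix(s)
    if (is.null(elements)) elements <- rep("C", nrow(xyz))
    if (length(elements) == 1L) elements <- rep(elements, nrow(xyz))
  }
  if (nrow(xyz) < 1L) stop("structure must contain at least one atom")
  qgrid <- as.numeric(qgrid)
  if (any(qgrid < 0)) stop("negative q is not allowed")
  G <- if (identical(unique(elements), "POINT"))
    matrix(1, nrow = length(qgrid), ncol = nrow(xyz))
  else form_factors(elements, qgrid, mode)
  I <- .cpp_debye(xyz, G, qgrid)
  if (is.unsorted(qgrid, strictly = TRUE))
    stop("qgrid must be strictly increasing")
  saxs_curve(qgrid, I)
}

#' Profiles for every frame of a conformation set
#'
#' @param cs a [conformation_set].
#' @param qgrid q values (1/A).
#' @param mode "vacuum" or "solvent".
#' @return list of [saxs_curve] objects, one per frame.
#' @export
profile_set <- function(cs, qgrid = default_qgrid(),
                        mode = c("vacuum", "solvent")) {
  mode <- match.arg(mode)
  G <- form_factors(cs$template$element, qgrid, mode)
  lapply(cs$frames, function(f)
    saxs_curve(qgrid, .cpp_debye(f, G, qgrid)))
}

#' Guinier analysis
#'
#' Iteratively fits ln I = ln I0 - q^2 Rg^2 / 3 by (error-weighted) linear
#' least squares over the self-consistent window q Rg <= `qmax_rule`,
#' starting from the first `min_points` points and shrinking/growing the
#' window until the fitted Rg is stable.
#'
#' @param curve a [saxs_curve].
#' @param qmax_rule dimensionless window rule (default 1.3).
#' @param min_points minimum points in the window (default 5).
#' @param max_iter window iteration cap (default 50).
#' @return list with elements `rg` (A), `i0`, `window` (indices used).
#' @export
guinier_rg <- function(curve, qmax_rule = 1.3, min_points = 5,
                       max_iter = 50) {
  q <- curve$q
  I <- curve$I
  pos <- I > 0
  if (sum(pos) < min_points) stop("too few positive intensities")
  w_all <- if (is.null(curve$sigma)) rep(1, length(q))
           else (I / curve$sigma)^2 # delta(ln I) = sigma / I
  fit_window <- function(idx) {
    x <- q[idx]^2
    y <- log(I[idx])
    fit <- stats::lm.wfit(cbind(1, x), y, w_all[idx])
    fit$coefficients
  }
  idx <- which(pos)[seq_len(min_points)]
  rg_prev <- -Inf
  for (it in seq_len(max_iter)) {
    cf <- fit_window(idx)
    slope <- cf[2]
    if (!is.finite(slope) || slope >= 0)
      stop("no Guinier regime: non-negative low-q slope")
    rg <- sqrt(-3 * slope)
    qmax <- qmax_rule / rg
    idx_new <- which(pos & q <= qmax)
    if (length(idx_new) < min_points)
      stop("Guinier window under-populated (fewer than ", min_points,
           " points below q = ", signif(qmax, 3), ")")
    if (abs(rg - rg_prev) < 1e-9 || identical(idx_new, idx)) {
      idx <- idx_new
      break
    }
    rg_prev <- rg
    idx <- idx_new
  }
  cf <- fit_window(idx)
  if (cf[2] >= 0) stop("no Guinier regime: non-negative low-q slope")
  list(rg = unname(sqrt(-3 * cf[2])), i0 = unname(exp(cf[1])),
       window = idx)
}

#' Kratky transform
#'
#' Pointwise I(q) q^2 versus q; bell-shaped for globular particles,
#' plateauing or rising for extended/disordered ones.
#'
#' @param curve a [saxs_curve].
#' @return a data.frame with columns `q` and `Iq2`.
#' @export
kratky <- function(curve) {
  stopifnot(inherits(curve, "saxs_curve"))
  data.frame(q = curve$q, Iq2 = curve$I * curve$q^2)
}
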