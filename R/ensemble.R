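#' Reduced chi-square between an experimental and a theoretical curve
#'
#' chi2 = (1/N_q) sum_q \[ (c I_theo(q) - I_exp(q)) / sigma(q) \]^2.
#' With `fit_scale = TRUE` the multiplicative scale c is the closed-form
#' weighted least-squares optimum
#' c = sum(I_exp I_theo / sigma^2) / sum(I_theo^2 / sigma^2); otherwise
#' c = 1. Simulated intensities are on an arbitrary scale, so ensemble
#' scoring always fits c.
#'
#' @param exp_curve a [saxs_curve] with errors.
#' @param theo_curve a [saxs_curve] on the identical q grid.
#' @param fit_scale logical (default TRUE).
#' @return list with elements `chi2` and `scale`.
#' @export
chi_square <- function(exp_curve, theo_curve, fit_scale = TRUE) {
  if (is.null(exp_curve$sigma))
    stop("experimental curve must carry errors (sigma)")
  if (length(exp_curve$q) != length(theo_curve$q) ||
      max(abs(exp_curve$q - theo_curve$q)) > 1e-9)
    stop("q grids do not match")
  Ie <- exp_curve$I; It <- theo_curve$I; s2 <- exp_curve$sigma^2
  c_ <- if (fit_scale) sum(Ie * It / s2) / sum(It^2 / s2) else 1
  chi2 <- mean((c_ * It - Ie)^2 / s2)
  list(chi2 = chi2, scale = c_)
}

#' Score a conformer pool against an experimental curve
#'
#' Computes a theoretical profile for every frame (Debye equation on the
#' experimental q grid) and its scale-fitted chi-square against the
#' experimental curve, returning a `candidate_set`.
#'
#' @param cs a [conformation_set].
#' @param exp_curve experimental [saxs_curve] with errors.
#' @param mode form-factor mode passed to [profile_set()].
#' @param curves optional precomputed list of per-frame curves on the
#'   experimental grid (skips the Debye computation).
#' @return an object of class `candidate_set`: the conformations, their
#'   curves, per-frame Rg, chi2 and fitted scale.
#' @export
score_candidates <- function(cs, exp_curve, mode = "vacuum",
                             curves = NULL) {
  if (is.null(curves))
    curves <- profile_set(cs, qgrid = exp_curve$q, mode = mode)
  sc <- lapply(curves, chi_square, exp_curve = exp_curve, fit_scale = TRUE)
  structure(list(conformations = cs, curves = curves,
                 rg = cs$rg, frame_index = cs$frame_index,
                 chi2 = vapply(sc, `[[`, numeric(1), "chi2"),
                 scale = vapply(sc, `[[`, numeric(1), "scale"),
                 exp_curve = exp_curve),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d conformers, chi2 in [%.3g, %.3g], Rg in [%.2f, %.2f] A\n",
              length(x$chi2), min(x$chi2), max(x$chi2), min(x$rg),
              max(x$rg)))
  invisible(x)
}

#' @export
length.candidate_set <- function(x) length(x$chi2)

.subset_candidates <- function(x, idx) {
  structure(list(conformations = subset_conformations(x$conformations, idx),
                 curves = x$curves[idx], rg = x$rg[idx],
                 frame_index = x$frame_index[idx], chi2 = x$chi2[idx],
                 scale = x$scale[idx], exp_curve = x$exp_curve),
            class = "candidate_set")
}

#' Keep the lowest-chi-square fraction of a candidate set
#'
#' Retains the floor(fraction * N) conformations with the smallest chi2;
#' boundary ties are broken by frame index (earlier frames kept). The 5%
#' filter is the production default, with 2.5% and 7.5% used as a
#' robustness check.
#'
#' @param cset a `candidate_set`.
#' @param fraction fraction in (0, 1), default 0.05.
#' @return the filtered `candidate_set`.
#' @export
filter_lowest <- function(cset, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_keep <- floor(fraction * length(cset$chi2))
  if (n_keep < 1L)
    stop("fraction ", fraction, " keeps zero of ", length(cset$chi2),
         " conformations")
  ord <- order(cset$chi2, cset$frame_index)
  idx <- sort(ord[seq_len(n_keep)])
  .subset_candidates(cset, idx)
}

#' Radius-of-gyration population histogram P(Rg)
#'
#' Normalized histogram of the member Rg values on a fixed-width grid,
#' with peak detection: local maxima whose topographic prominence exceeds
#' `prominence_frac` of the tallest bin. Peaks are reported sorted by
#' decreasing prominence.
#'
#' @param x a `candidate_set`, `conformation_set`, or numeric Rg vector.
#' @param bin_width bin width in A (default 0.25).
#' @param prominence_frac prominence threshold as a fraction of the
#'   maximum bin mass (default 0.05).
#' @return object of class `rg_histogram`: `breaks`, `mids`, `prob`
#'   (summing to 1) and `peaks` (data.frame: bin, location, height,
#'   prominence).
#' @export
prg_histogram <- function(x, bin_width = 0.25, prominence_frac = 0.05) {
  rg <- if (inherits(x, "candidate_set")) x$rg
        else if (inherits(x, "conformation_set")) x$rg
        else as.numeric(x)
  if (length(rg) < 1L) stop("empty conformation set")
  lo <- floor(min(rg) / bin_width) * bin_width
  hi <- ceiling(max(rg) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (max(rg) >= breaks[length(breaks)])
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  h <- graphics::hist(rg, breaks = breaks, plot = FALSE, right = FALSE)
  prob <- h$counts / sum(h$counts)
  pk <- .find_peaks(prob)
  keep <- pk$prominence >= prominence_frac * max(prob)
  pk <- pk[keep, , drop = FALSE]
  pk$location <- h$mids[pk$bin]
  pk <- pk[order(-pk$prominence, pk$bin), , drop = FALSE]
  rownames(pk) <- NULL
  structure(list(breaks = h$breaks, mids = h$mids, prob = prob,
                 peaks = pk[, c("bin", "location", "height", "prominence")],
                 bin_width = bin_width),
            class = "rg_histogram")
}

# local maxima + topographic prominence of a non-negative series
.find_peaks <- function(p) {
  n <- length(p)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1) p[i - 1] else -Inf
    right <- if (i < n) p[i + 1] else -Inf
    if (p[i] > 0 && p[i] >= left && p[i] >= right &&
        (p[i] > left || p[i] > right))
      is_max[i] <- TRUE
  }
  # deduplicate plateaus: keep first bin of equal-height runs
  for (i in which(is_max))
    if (i > 1 && is_max[i - 1] && p[i] == p[i - 1]) is_max[i] <- FALSE
  idx <- which(is_max)
  prom <- vapply(idx, function(i) {
    # walk each side to the nearest strictly higher bin (or the edge);
    # the side base is the minimum seen, or 0 when the peak sits at the
    # edge itself (the series is bounded by empty bins)
    side_base <- function(step) {
      j <- i
      minv <- Inf
      repeat {
        j <- j + step
        if (j < 1 || j > length(p)) return(if (is.finite(minv)) minv else 0)
        minv <- min(minv, p[j])
        if (p[j] > p[i]) return(minv)
      }
    }
    p[i] - max(side_base(-1L), side_base(1L))
  }, numeric(1))
  data.frame(bin = idx, height = p[idx], prominence = prom)
}

#' @export
print.rg_histogram <- function(x, ...) {
  cat(sprintf("P(Rg): %d bins of %.3g A, %d peak(s)\n",
              length(x$prob), x$bin_width, nrow(x$peaks)))
  if (nrow(x$peaks)) print(x$peaks, digits = 3)
  invisible(x)
}

#' @export
plot.rg_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$prob, type = "h", lwd = 3,
                 xlab = "Rg (A)", ylab = "P(Rg)", ...)
  if (nrow(x$peaks))
    graphics::points(x$peaks$location, x$peaks$height, pch = 2,
                     col = "red3")
  invisible(x)
}

#' Select representative conformations from P(Rg) peaks
#'
#' For each of the `n_peaks` most prominent peaks, takes the
#' `k_per_peak` lowest-chi2 conformations inside the peak window (the
#' contiguous bins at or above half the peak height) that are mutually
#' distinct: greedy admission in chi2 order, skipping any conformer within
#' `min_rmsd` (superposed RMSD) of one already chosen for that peak. A
#' warning is issued when a peak yields fewer than `k_per_peak`.
#'
#' @param cset a `candidate_set` (typically after [filter_lowest()]).
#' @param hist an `rg_histogram` of `cset`, or NULL to compute one.
#' @param n_peaks number of peaks to use (default 3).
#' @param k_per_peak representatives per peak (default 4).
#' @param min_rmsd distinctness threshold in A (default 2).
#' @param bin_width,prominence_frac passed to [prg_histogram()] when
#'   `hist` is NULL.
#' @return list of class `representative_set`: `groups` (per-peak integer
#'   indices into `cset`), `peaks` (the peak table used), `cset`.
#' @export
select_representatives <- function(cset, hist = NULL, n_peaks = 3,
                                   k_per_peak = 4, min_rmsd = 2,
                                   bin_width = 0.25,
                                   prominence_frac = 0.05) {
  if (is.null(hist))
    hist <- prg_histogram(cset, bin_width, prominence_frac)
  if (nrow(hist$peaks) == 0L) stop("no peaks detected in P(Rg)")
  use <- utils::head(hist$peaks, n_peaks)
  groups <- vector("list", nrow(use))
  for (g in seq_len(nrow(use))) {
    b <- use$bin[g]
    half <- use$height[g] / 2
    lo_b <- b
    while (lo_b > 1 && hist$prob[lo_b - 1] >= half) lo_b <- lo_b - 1
    hi_b <- b
    while (hi_b < length(hist$prob) && hist$prob[hi_b + 1] >= half)
      hi_b <- hi_b + 1
    lo <- hist$breaks[lo_b]
    hi <- hist$breaks[hi_b + 1]
    members <- which(cset$rg >= lo & cset$rg < hi)
    members <- members[order(cset$chi2[members], cset$frame_index[members])]
    chosen <- integer(0)
    for (m in members) {
      if (length(chosen) >= k_per_peak) break
      ok <- all(vapply(chosen, function(cc)
        rmsd_superposed(cset$conformations$frames[[m]],
                        cset$conformations$frames[[cc]]) > min_rmsd,
        logical(1)))
      if (ok) chosen <- c(chosen, m)
    }
    if (length(chosen) < k_per_peak)
      warning("peak ", g, ": only ", length(chosen),
              " admissible conformations (requested ", k_per_peak, ")")
    groups[[g]] <- chosen
  }
  structure(list(groups = groups, peaks = use, cset = cset),
            class = "representative_set")
}

#' Enumerate grid-quantized weight vectors
#'
#' All vectors of `k` non-negative multiples of `step` summing exactly to
#' one (zeros allowed), generated from integer compositions of
#' `round(1/step)` so the sum is exact by construction, in lexicographic
#' order.
#'
#' @param k number of ensemble members (>= 1).
#' @param step weight grid spacing; 1/step must be an integer (default
#'   0.1).
#' @return numeric matrix, one weight vector per row, with the integer
#'   composition matrix in attribute `counts` and the denominator in
#'   attribute `denominator`.
#' @export
enumerate_weights <- function(k, step = 0.1) {
  if (k < 1) stop("k must be >= 1")
  m <- round(1 / step)
  if (abs(m * step - 1) > 1e-9) stop("1/step must be an integer")
  rec <- function(k, m) {
    if (k == 1L) return(matrix(m, 1, 1))
    out <- vector("list", m + 1L)
    for (first in 0:m) {
      rest <- rec(k - 1L, m - first)
      out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  counts <- rec(as.integer(k), as.integer(m))
  w <- counts / m
  attr(w, "counts") <- counts
  attr(w, "denominator") <- m
  w
}

#' Fit a weighted conformer ensemble to an experimental curve
#'
#' Evaluates the combined intensity I_combined(q) = sum_i w_i I_i(q) for
#' every enumerated weight vector on the step-`step` grid, scores each with
#' the scale-fitted reduced chi-square against the experimental curve, and
#' returns the global minimum; ties are broken toward the
#' lexicographically smallest weight vector.
#'
#' @param exp_curve experimental [saxs_curve] with errors.
#' @param member_curves list of theoretical [saxs_curve]s on the same grid.
#' @param step weight grid spacing (default 0.1).
#' @param member_ids optional identifiers for the members.
#' @return object of class `saxs_ensemble_fit`.
#' @export
fit_ensemble <- function(exp_curve, member_curves, step = 0.1,
                         member_ids = NULL) {
  k <- length(member_curves)
  if (k < 1) stop("at least one member curve required")
  if (is.null(exp_curve$sigma)) stop("experimental curve must carry sigma")
  for (mc in member_curves)
    if (length(mc$q) != length(exp_curve$q) ||
        max(abs(mc$q - exp_curve$q)) > 1e-9)
      stop("member curve q grid does not match the experimental grid")
  if (is.null(member_ids)) member_ids <- seq_len(k)
  W <- enumerate_weights(k, step)
  M <- vapply(member_curves, `[[`, numeric(length(exp_curve$q)), "I")
  M <- matrix(M, ncol = k)
  Ie <- exp_curve$I
  s2 <- exp_curve$sigma^2
  nq <- length(Ie)
  best <- list(chi2 = Inf, row = NA_integer_, scale = NA_real_)
  chunk <- 20000L
  for (start in seq(1L, nrow(W), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(W))
    C <- M %*% t(W[rows, , drop = FALSE])        # nq x nrows combined
    num <- colSums(C * (Ie / s2))
    den <- colSums(C^2 / s2)
    cc <- num / den
    resid2 <- (C * rep(cc, each = nq) - Ie)^2 / s2
    chi2 <- colMeans(resid2)
    jb <- which.min(chi2)                        # first = lex smallest
    if (chi2[jb] < best$chi2) {
      best <- list(chi2 = chi2[jb], row = rows[jb], scale = cc[jb])
    }
  }
  w <- W[best$row, ]
  combined <- saxs_curve(exp_curve$q, as.numeric(M %*% w))
  structure(list(weights = w,
                 counts = attr(W, "counts")[best$row, ],
                 denominator = attr(W, "denominator"),
                 member_ids = member_ids,
                 member_curves = member_curves,
                 exp_curve = exp_curve,
                 combined = combined,
                 scale = best$scale,
                 chi2 = best$chi2,
                 n_evaluated = nrow(W),
                 step = step),
            class = "saxs_ensemble_fit")
}

#' Search candidate ensembles built from per-peak representatives
#'
#' Forms every cross-product combination taking one conformer from each
#' peak group (4 x 4 x 4 = 64 candidate ensembles with the defaults), runs
#' [fit_ensemble()] on each, and returns the overall best fit.
#'
#' @param exp_curve experimental [saxs_curve] with errors.
#' @param reps a `representative_set` from [select_representatives()], or
#'   a plain list of per-group index vectors (then `cset` is required).
#' @param cset the `candidate_set` the indices refer to (taken from
#'   `reps` when it is a `representative_set`).
#' @param step weight grid spacing (default 0.1).
#' @return the best `saxs_ensemble_fit`; attribute `n_combinations` holds
#'   the number of candidate ensembles evaluated.
#' @export
combination_search <- function(exp_curve, reps, cset = NULL, step = 0.1) {
  if (inherits(reps, "representative_set")) {
    groups <- reps$groups
    cset <- reps$cset
  } else groups <- reps
  if (is.null(cset)) stop("cset required when reps is a plain list")
  if (any(lengths(groups) == 0L)) stop("empty representative group")
  grid <- expand.grid(groups, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    ids <- as.integer(grid[r, ])
    fit <- fit_ensemble(exp_curve, cset$curves[ids], step = step,
                        member_ids = cset$frame_index[ids])
    if (is.null(best) || fit$chi2 < best$chi2) best <- fit
  }
  attr(best, "n_combinations") <- nrow(grid)
  best
}

#' Cross-condition fit table
#'
#' Entry (i, j) is the scale-fitted reduced chi-square of fit i's combined
#' curve against experimental curve j; the diagonal reproduces each fit's
#' own chi2. When each condition's own ensemble describes its data best,
#' every diagonal entry is its row minimum.
#'
#' @param fits list of `saxs_ensemble_fit` objects (one per condition).
#' @param exp_curves list of experimental [saxs_curve]s, same order.
#' @return numeric matrix, `length(fits)` x `length(exp_curves)`.
#' @export
cross_table <- function(fits, exp_curves) {
  out <- matrix(NA_real_, length(fits), length(exp_curves))
  for (i in seq_along(fits))
    for (j in seq_along(exp_curves))
      out[i, j] <- chi_square(exp_curves[[j]], fits[[i]]$combined,
                              fit_scale = TRUE)$chi2
  rownames(out) <- names(fits)
  colnames(out) <- names(exp_curves)
  out
}
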