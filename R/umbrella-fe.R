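# Umbrella-sampling free-energy core: bias potential, window grid, WHAM
# reconstruction with bootstrap errors, the consecutive-window consistency
# diagnostic, and macroscopic binding free energies from the profile.

#' Umbrella bias potential on a contact pair list
#'
#' The restraint used during domain unbinding: when the minimal pair distance
#' is below the window center, every pair closer than the center is biased,
#' `U = sum k (d_ij - d_c)^2` over those pairs; once the minimal distance
#' reaches the center, only the minimal pair is biased,
#' `U = k (d_min - d_c)^2`. This lets pairs beyond the restraint separate
#' freely (progressive, hierarchical unbinding) while forbidding any pair
#' from coming closer than the current minimal distance.
#'
#' @param d_ij Non-negative pair distances, A (at least one).
#' @param d_c Window center, A.
#' @param k Force constant, kcal/mol/A^2.
#' @return Bias energy, kcal/mol.
#' @export
bias_energy <- function(d_ij, d_c, k) {
  if (length(d_ij) == 0L) stop("empty pair list")
  if (any(d_ij < 0)) stop("pair distances must be >= 0")
  d_min <- min(d_ij)
  if (d_min < d_c) {
    sel <- d_ij[d_ij < d_c]
    sum(k * (sel - d_c)^2)
  } else {
    k * (d_min - d_c)^2
  }
}

#' Umbrella window grid
#'
#' Inclusive arithmetic grid of window centers. The default reproduces the
#' unbinding protocol: 60 windows every 0.05 A covering minimal distances
#' from 2.55 to 5.5 A.
#'
#' @param start,stop First and last center, A.
#' @param spacing Center spacing, A.
#' @return Numeric vector of centers.
#' @examples
#' length(window_grid())  # 60
#' @export
window_grid <- function(start = 2.55, stop = 5.5, spacing = 0.05) {
  stopifnot(stop >= start, spacing > 0)
  n <- round((stop - start) / spacing) + 1L
  start + (seq_len(n) - 1L) * spacing
}

# dimensionless bias energies u[b, i] = k_i (x_b - c_i)^2 / kT
bias_matrix <- function(bins, windows, kT) {
  outer(bins, seq_len(nrow(windows)),
        function(x, i) windows$k[i] * (x - windows$center[i])^2 / kT)
}

#' WHAM reconstruction of the free-energy profile
#'
#' Self-consistent weighted-histogram solution for the unbiased profile
#' `G(d_min)` from harmonic-bias windows. The bias is modeled as
#' `k (x - d_c)^2` in the scalar coordinate. Iteration stops when the
#' largest change in any window free energy falls below `tol` (in units of
#' `k_B T`). The profile is anchored at `min G = 0`; unsampled bins are `NA`.
#' A warning is issued when consecutive windows have no overlapping sampled
#' bins (the profile may then contain disjoint, mutually unanchored
#' segments).
#'
#' @param dataset An [umbrella_dataset()].
#' @param bin_width Histogram bin width, A (default 0.01).
#' @param tol Convergence tolerance on window free energies, k_B T units
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 1e5).
#' @param f_init Optional warm-start window free energies (kT units).
#' @return An `fe_profile`: list with `profile` (tibble: `d`, `G`, `error`),
#'   `f` (window free energies, kcal/mol), `thermo`, `bin_width`,
#'   `iterations`, `converged`.
#' @export
wham <- function(dataset, bin_width = 0.01, tol = 1e-6, max_iter = 1e5,
                 f_init = NULL) {
  w <- dataset$windows
  kT <- dataset$thermo$kT
  rng <- range(unlist(w$samples))
  edges <- seq(floor(rng[1] / bin_width) * bin_width,
               rng[2] + bin_width, by = bin_width)
  bins <- head(edges, -1) + bin_width / 2
  nb <- length(bins); nw <- nrow(w)
  counts <- vapply(w$samples, function(s)
    tabulate(pmin(pmax(floor((s - edges[1]) / bin_width) + 1L, 1L), nb),
             nbins = nb), numeric(nb))
  counts <- matrix(counts, nrow = nb)
  N <- colSums(counts)
  ctot <- rowSums(counts)

  # overlap diagnostic between consecutive windows
  occ <- counts > 0
  for (i in seq_len(nw - 1)) {
    if (!any(occ[, i] & occ[, i + 1])) {
      warning("windows ", i, " and ", i + 1,
              " share no sampled bins; profile may be disjoint")
      break
    }
  }

  u <- bias_matrix(bins, w, kT)
  E <- exp(-u)                      # nb x nw, underflows to 0 harmlessly
  f <- f_init %||% rep(0, nw)       # dimensionless window free energies
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- as.numeric(E %*% (N * exp(f)))
    rho <- ifelse(denom > 0, ctot / denom, 0)
    zi <- as.numeric(crossprod(E, rho))
    fnew <- -log(zi)
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; converged <- TRUE; break }
    f <- fnew
  }
  denom <- as.numeric(E %*% (N * exp(f)))
  rho <- ifelse(denom > 0 & ctot > 0, ctot / denom, NA_real_)
  G <- -kT * log(rho)
  G <- G - min(G, na.rm = TRUE)
  structure(list(
    profile = tibble::tibble(d = bins, G = G, error = NA_real_),
    f = f * kT, thermo = dataset$thermo, bin_width = bin_width,
    iterations = iter, converged = converged),
    class = "fe_profile")
}

#' @export
print.fe_profile <- function(x, ...) {
  ok <- sum(is.finite(x$profile$G))
  cat("<fe_profile> ", ok, " sampled bins of width ", x$bin_width,
      " A; WHAM ", if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

# integrated autocorrelation -> statistical inefficiency g = 1 + 2 tau
statistical_inefficiency <- function(x, c_max = 0.05) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(1)
  ac <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE,
                   demean = TRUE)$acf[-1]
  cut <- which(ac < c_max)[1]
  if (is.na(cut)) cut <- length(ac)
  max(1, 1 + 2 * sum(ac[seq_len(cut)]))
}

#' Bootstrap errors on the WHAM profile
#'
#' Bayesian bootstrap over decorrelated samples: each window's series is
#' subsampled at its statistical-inefficiency stride, each replicate
#' re-weights those samples with Dirichlet weights and re-solves WHAM
#' (warm-started from the base solution), and the per-bin standard deviation
#' across replicates is reported. Replicates are aligned on the
#' well-sampled region (count-weighted mean of G over bins holding at least
#' 10 samples in the full dataset), so the reported error reflects profile
#' shape uncertainty rather than the shot noise of a single anchor bin.
#'
#' @param dataset An [umbrella_dataset()].
#' @param n_boot Number of replicates (>= 20; default 32).
#' @param seed RNG seed.
#' @param bin_width,tol,max_iter Passed to [wham()].
#' @param keep_replicates Keep the aligned replicate profiles (bins x
#'   n_boot matrix, element `replicates`); these preserve the bin-to-bin
#'   error correlations that independent per-bin propagation discards, and
#'   are the right input for replicate-based errors on derived quantities
#'   such as the macroscopic binding free energy.
#' @return An `fe_profile` whose `profile$error` column is filled.
#' @export
wham_error <- function(dataset, n_boot = 32L, seed = 1L, bin_width = 0.01,
                       tol = 1e-6, max_iter = 1e5,
                       keep_replicates = FALSE) {
  if (n_boot < 20L) stop("n_boot must be >= 20")
  base <- wham(dataset, bin_width = bin_width, tol = tol,
               max_iter = max_iter)
  kT <- dataset$thermo$kT
  w <- dataset$windows
  set.seed(seed)
  dec <- purrr::map(w$samples, function(s) {
    g <- statistical_inefficiency(s)
    s[seq(1, length(s), by = max(1L, round(g)))]
  })
  bins <- base$profile$d
  edges0 <- bins[1] - bin_width / 2
  nb <- length(bins)
  u <- bias_matrix(bins, w, kT)
  E <- exp(-u)
  base_counts <- rowSums(matrix(vapply(w$samples, function(s)
    tabulate(pmin(pmax(floor((s - edges0) / bin_width) + 1L, 1L), nb),
             nbins = nb), numeric(nb)), nrow = nb))
  ref <- which(base_counts >= 10)
  if (length(ref) == 0L) ref <- which.max(base_counts)
  align <- function(G) {
    ok <- ref[is.finite(G[ref])]
    G - stats::weighted.mean(G[ok], base_counts[ok])
  }
  f0 <- base$f / kT
  reps <- matrix(NA_real_, nb, n_boot)
  for (b in seq_len(n_boot)) {
    counts <- vapply(dec, function(s) {
      wt <- stats::rexp(length(s))
      wt <- wt / sum(wt) * length(s)
      bi <- pmin(pmax(floor((s - edges0) / bin_width) + 1L, 1L), nb)
      out <- numeric(nb)
      rs <- rowsum(wt, bi)
      out[as.integer(rownames(rs))] <- rs[, 1]
      out
    }, numeric(nb))
    counts <- matrix(counts, nrow = nb)
    N <- colSums(counts); ctot <- rowSums(counts)
    f <- f0
    for (it in seq_len(max_iter)) {
      denom <- as.numeric(E %*% (N * exp(f)))
      rho <- ifelse(denom > 0, ctot / denom, 0)
      fnew <- -log(as.numeric(crossprod(E, rho)))
      fnew <- fnew - fnew[1]
      if (max(abs(fnew - f)) < tol) { f <- fnew; break }
      f <- fnew
    }
    denom <- as.numeric(E %*% (N * exp(f)))
    rho <- ifelse(denom > 0 & ctot > 0, ctot / denom, NA_real_)
    reps[, b] <- align(-kT * log(rho))
  }
  err <- apply(reps, 1, function(x) stats::sd(x, na.rm = TRUE))
  out <- base
  out$profile$error <- err
  if (keep_replicates) out$replicates <- reps
  out
}

#' Sampling-consistency diagnostic between consecutive windows
#'
#' For each pair of consecutive windows, both windows' histograms are
#' unbiased into local density-of-states estimates (counts times
#' `exp(+U_bias/kT)`), normalized over the bins sampled by both windows, and
#' compared by L1 distance: theta is ~0 when the two windows see the same
#' underlying density and grows toward the maximum of 2 as they disagree;
#' disjoint sampling gives exactly 2 (flagged). Only bins with at least
#' `min_count` samples in both windows enter the comparison: the exponential
#' unbiasing factor otherwise amplifies shot noise from single-count tail
#' bins into the diagnostic.
#'
#' @param dataset An [umbrella_dataset()].
#' @param bin_width Histogram bin width, A (default 0.02).
#' @param min_count Minimum per-bin count in both windows for a bin to count
#'   as shared support (default 10).
#' @return A tibble with `pair` ("i:i+1"), `center_lo`, `center_hi`,
#'   `theta`, `shared_bins`, `disjoint`.
#' @export
theta_consistency <- function(dataset, bin_width = 0.02, min_count = 10L) {
  w <- dataset$windows
  kT <- dataset$thermo$kT
  res <- purrr::map(seq_len(nrow(w) - 1), function(i) {
    s1 <- w$samples[[i]]; s2 <- w$samples[[i + 1]]
    lo <- min(s1, s2); hi <- max(s1, s2)
    edges <- seq(floor(lo / bin_width) * bin_width, hi + bin_width,
                 by = bin_width)
    bins <- head(edges, -1) + bin_width / 2
    h1 <- tabulate(findInterval(s1, edges), nbins = length(bins))
    h2 <- tabulate(findInterval(s2, edges), nbins = length(bins))
    shared <- which(h1 >= min_count & h2 >= min_count)
    if (length(shared) == 0L)
      return(tibble::tibble(pair = paste0(i, ":", i + 1),
                            center_lo = w$center[i],
                            center_hi = w$center[i + 1],
                            theta = 2, shared_bins = 0L, disjoint = TRUE))
    dos <- function(h, k, c0) {
      v <- h[shared] * exp(k * (bins[shared] - c0)^2 / kT)
      v / sum(v)
    }
    r1 <- dos(h1, w$k[i], w$center[i])
    r2 <- dos(h2, w$k[i + 1], w$center[i + 1])
    tibble::tibble(pair = paste0(i, ":", i + 1),
                   center_lo = w$center[i], center_hi = w$center[i + 1],
                   theta = sum(abs(r1 - r2)),
                   shared_bins = length(shared), disjoint = FALSE)
  })
  dplyr::bind_rows(res)
}

# ---------------------------------------------------------------------------
# Macroscopic binding free energy

fe_profile_table <- function(profile) {
  if (inherits(profile, "fe_profile")) profile$profile else
    tibble::as_tibble(profile)
}

#' Macroscopic binding free energy from a profile
#'
#' Boltzmann-integrates the profile into bound and unbound state
#' probabilities and reports
#' `dG = -kT ln( int_lower^threshold rho dx / int_threshold^upper rho dx )`
#' with `rho(x) = exp(-G(x)/kT)` (note the negative sign: the bound well at
#' low G must dominate the bound integral). Trapezoidal integration on the
#' profile grid; `threshold` and `upper` are snapped to the nearest grid
#' point; the lower limit is the lowest sampled bin.
#'
#' @param profile An `fe_profile` or a tibble with columns `d`, `G` (and
#'   optionally `error`).
#' @param thermo A [thermo()]; defaults to the profile's own.
#' @param threshold Bound/unbound boundary, A.
#' @param upper Upper integration limit, A (default 5.5).
#' @return An `affinity_estimate` tibble row: `threshold`, `dG`, `error`
#'   (`NA` without per-bin errors), `lower`, `upper` (kcal/mol, A).
#' @export
pmf_to_dG <- function(profile, thermo = NULL, threshold, upper = 5.5) {
  thermo <- thermo %||% (if (inherits(profile, "fe_profile"))
    profile$thermo else dnacoop::thermo())
  tab <- fe_profile_table(profile)
  tab <- tab[is.finite(tab$G), ]
  d <- tab$d; G <- tab$G
  if (threshold <= min(d) || threshold >= max(d))
    stop("threshold ", threshold, " A outside the profile support [",
         min(d), ", ", max(d), "] A")
  iu <- which.min(abs(d - upper))
  it <- which.min(abs(d - threshold))
  if (d[iu] < threshold) stop("upper limit below threshold")
  kT <- thermo$kT
  rho <- exp(-(G - min(G)) / kT)
  trap <- function(i1, i2) {
    dd <- d[i1:i2]; rr <- rho[i1:i2]
    sum(diff(dd) * (head(rr, -1) + tail(rr, -1)) / 2)
  }
  Ib <- trap(1L, it); Iu <- trap(it, iu)
  dG <- -kT * log(Ib / Iu)
  err <- NA_real_
  if (!is.null(tab[["error"]]) && all(is.finite(tab[["error"]][1:iu])))
    err <- dG_error(tab[1:iu, ], thermo = thermo, threshold = d[it],
                    upper = d[iu])
  structure(tibble::tibble(threshold = d[it], dG = dG, error = err,
                           lower = d[1], upper = d[iu]),
            class = c("affinity_estimate", "tbl_df", "tbl", "data.frame"))
}

#' Error on the macroscopic binding free energy
#'
#' Propagates per-bin profile errors into the binding free energy, either by
#' first-order (linear) propagation through the log-ratio of the trapezoidal
#' sums (per-bin errors treated as independent), or by Monte Carlo
#' resampling of the per-bin values from independent normals.
#'
#' @param profile An `fe_profile` (or tibble `d`, `G`, `error`) with finite
#'   per-bin errors.
#' @param thermo A [thermo()].
#' @param threshold Bound/unbound boundary, A (snapped to the grid).
#' @param upper Upper integration limit, A.
#' @param method `"linear"` (default) or `"monte-carlo"`.
#' @param n_mc Monte Carlo replicates (default 200).
#' @param seed RNG seed for the Monte Carlo method.
#' @return Standard error of `dG`, kcal/mol.
#' @export
dG_error <- function(profile, thermo = NULL, threshold, upper = 5.5,
                     method = c("linear", "monte-carlo"), n_mc = 200L,
                     seed = 1L) {
  method <- match.arg(method)
  thermo <- thermo %||% (if (inherits(profile, "fe_profile"))
    profile$thermo else dnacoop::thermo())
  tab <- fe_profile_table(profile)
  tab <- tab[is.finite(tab$G), ]
  if (is.null(tab[["error"]]) || !all(is.finite(tab[["error"]])))
    stop("profile lacks finite per-bin errors")
  kT <- thermo$kT
  d <- tab$d; G <- tab$G; sig <- tab[["error"]]
  iu <- which.min(abs(d - upper)); it <- which.min(abs(d - threshold))
  d <- d[1:iu]; G <- G[1:iu]; sig <- sig[1:iu]
  rho <- exp(-(G - min(G)) / kT)
  tw <- function(i1, i2) {         # trapezoid weights on bins i1..i2
    w <- numeric(length(d))
    dd <- diff(d[i1:i2])
    w[i1:i2] <- c(dd / 2, 0) + c(0, dd / 2)
    w
  }
  wb <- tw(1L, it); wu <- tw(it, length(d))
  Ib <- sum(wb * rho); Iu <- sum(wu * rho)
  if (method == "linear") {
    grad <- wb * rho / Ib - wu * rho / Iu   # d(dG)/dG_k
    sqrt(sum((grad * sig)^2))
  } else {
    set.seed(seed)
    reps <- vapply(seq_len(n_mc), function(r) {
      Gr <- G + rnorm(length(G), sd = sig)
      rr <- exp(-(Gr - min(Gr)) / kT)
      -kT * log(sum(wb * rr) / sum(wu * rr))
    }, numeric(1))
    stats::sd(reps)
  }
}

#' Binding free energy across bound/unbound thresholds
#'
#' One affinity estimate per threshold (default 3.1 to 4.3 A in 0.2 A steps,
#' the thresholds tested when the profiles lack a clear transition state),
#' with a monotonicity report of `dG` versus threshold.
#'
#' @param profile An `fe_profile` or tibble (`d`, `G`, optional `error`).
#' @param thermo A [thermo()].
#' @param thresholds Thresholds, A.
#' @param upper Upper integration limit, A (default 5.5).
#' @return A tibble with one row per threshold (`threshold`, `dG`, `error`,
#'   `lower`, `upper`) and attribute `monotone` (`TRUE` when `dG` is
#'   non-increasing with threshold).
#' @export
threshold_sweep <- function(profile, thermo = NULL,
                            thresholds = seq(3.1, 4.3, by = 0.2),
                            upper = 5.5) {
  out <- dplyr::bind_rows(purrr::map(thresholds, function(th)
    pmf_to_dG(profile, thermo = thermo, threshold = th, upper = upper)))
  attr(out, "monotone") <- !is.unsorted(-out$dG)
  out
}
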