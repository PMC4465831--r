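# Synthetic generators: idealized B-DNA, toy protein-DNA complexes with
# controlled contact persistence and correlated displacements, and Brownian
# umbrella sampling on a reference 1D free-energy profile. These emulate the
# statistical structure of the molecular-dynamics ensembles the analytics
# consume, so every downstream stage is testable without trajectories.

# ---------------------------------------------------------------------------
# Reference PMF

#' Reference free-energy profile
#'
#' A piecewise-linear reference potential of mean force \eqn{G_{ref}(x)} on a
#' strictly increasing grid. Used as ground truth for the Brownian umbrella
#' generator and for closed-form binding free-energy oracles.
#'
#' @param x Strictly increasing grid positions (Angstrom).
#' @param G Finite values (kcal/mol).
#' @return Object of class `reference_pmf`.
#' @export
reference_pmf <- function(x, G) {
  stopifnot(length(x) == length(G), length(x) >= 2L,
            all(is.finite(x)), all(is.finite(G)), all(diff(x) > 0))
  structure(list(x = as.numeric(x), G = as.numeric(G)),
            class = "reference_pmf")
}

#' Evaluate a reference PMF by linear interpolation
#' @param pmf A [reference_pmf()].
#' @param x Positions inside the grid.
#' @return G(x) in kcal/mol.
#' @export
pmf_eval <- function(pmf, x) {
  stats::approx(pmf$x, pmf$G, xout = x, rule = 2)$y
}

#' Canonical double-well reference profile
#'
#' A smooth double well on the minimal-distance range typical of protein-DNA
#' unbinding: a deep bound well near 3.05 A, a barrier (default 4 kcal/mol)
#' near 3.85 A, and a shallower unbound basin around 4.7 A, sampled at
#' 0.005 A resolution between 2.5 and 5.5 A.
#'
#' @param barrier Barrier height above the bound well, kcal/mol (default 4).
#' @return A [reference_pmf()].
#' @export
pmf_double_well <- function(barrier = 4) {
  cx <- c(2.50, 2.75, 3.05, 3.45, 3.85, 4.30, 4.70, 5.10, 5.50)
  cg <- c(9.00, 2.20, 0.00, 2.60, 4.00, 2.90, 1.60, 1.90, 2.30) *
    (barrier / 4)
  s <- stats::spline(cx, cg, xout = seq(2.5, 5.5, by = 0.005),
                     method = "natural")
  reference_pmf(s$x, s$y)
}

# ---------------------------------------------------------------------------
# Brownian dynamics umbrella sampling

#' Brownian-dynamics parameters
#'
#' Parameters of the overdamped Langevin (Euler-Maruyama) integrator used to
#' sample umbrella windows on a reference profile. Defaults (D = 0.1 A^2/ps,
#' dt = 0.01 ps) resolve harmonic wells with force constants up to several
#' hundred kcal/mol/A^2 with a comfortable stability margin.
#'
#' @param temperature Kelvin.
#' @param D Diffusion coefficient, A^2/ps.
#' @param dt Timestep, ps.
#' @param n_steps Integration steps per window.
#' @param save_stride Keep every `save_stride`-th position.
#' @param seed RNG seed used by [gen_bd_umbrella()].
#' @return A list of class `bd_params`.
#' @export
bd_params <- function(temperature = 300, D = 0.1, dt = 0.01,
                      n_steps = 1e5, save_stride = 10L, seed = 1L) {
  stopifnot(temperature > 0, D > 0, dt > 0, n_steps >= 1, save_stride >= 1)
  structure(list(temperature = temperature, D = D, dt = dt,
                 n_steps = n_steps, save_stride = as.integer(save_stride),
                 seed = as.integer(seed)),
            class = "bd_params")
}

# drift stability: (i) the reference-profile drift per step must stay well
# below the thermal scale on the grid, and (ii) the harmonic bias must be
# resolved, i.e. the discrete relaxation factor 2 k D dt / kT must be small
# (the discrete stationary variance is inflated by ~ 1/(1 - theta/2))
bd_stability_check <- function(pmf, windows, bd) {
  kT <- KB_KCAL * bd$temperature
  slope <- diff(pmf$G) / diff(pmf$x)
  crit_pmf <- max(abs(slope)) * bd$dt * bd$D / kT
  if (crit_pmf >= 0.1)
    stop("Brownian integrator unstable on the reference profile ",
         "(max |dG/dx| * dt * D / kT = ", signif(crit_pmf, 3),
         " >= 0.1); reduce dt")
  theta <- 2 * max(windows$k) * bd$D * bd$dt / kT
  if (theta >= 0.1)
    stop("harmonic bias under-resolved (2 k D dt / kT = ",
         signif(theta, 3), " >= 0.1); reduce dt")
  invisible(max(crit_pmf, theta))
}

#' Umbrella-sampling dataset
#'
#' An ordered set of umbrella windows, each a harmonic bias
#' \eqn{k (x - d_c)^2} on the scalar reaction coordinate together with the
#' sampled coordinate series, plus the thermodynamic state.
#'
#' @param windows Tibble with columns `center` (A, distinct; rows are sorted
#'   by center so the stored centers are strictly increasing),
#'   `k` (kcal/mol/A^2, > 0) and `samples` (list column of numeric series).
#' @param thermo A [thermo()].
#' @param sample_period Time between kept samples, ps (bookkeeping only).
#' @return Object of class `umbrella_dataset`.
#' @export
umbrella_dataset <- function(windows, thermo = dnacoop::thermo(),
                             sample_period = NA_real_) {
  windows <- tibble::as_tibble(windows)
  stopifnot(all(c("center", "k", "samples") %in% names(windows)))
  if (anyDuplicated(windows$center))
    stop("window centers must be distinct")
  windows <- windows[order(windows$center), ]
  if (any(windows$k <= 0)) stop("force constants must be > 0")
  if (!all(vapply(windows$samples, function(s) all(is.finite(s)), logical(1))))
    stop("window samples must be finite")
  windows$n <- vapply(windows$samples, length, integer(1))
  structure(list(windows = windows, thermo = thermo,
                 sample_period = sample_period),
            class = "umbrella_dataset")
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  cat("<umbrella_dataset> ", nrow(x$windows), " windows, centers ",
      min(x$windows$center), "-", max(x$windows$center), " A, T = ",
      x$thermo$temperature, " K\n", sep = "")
  invisible(x)
}

#' Generate umbrella-sampling data by biased Brownian dynamics
#'
#' Runs overdamped Langevin dynamics on `G_ref(x) + k (x - d_c)^2` for each
#' window, mirroring the biased molecular simulations the free-energy analysis
#' consumes. The first `equilibration` fraction of each window's samples is
#' discarded, mirroring the discarded equilibration segment of biased
#' simulations. Positions reflect at the reference-grid edges; the analysis
#' range should exclude those boundaries. Seeded and reproducible.
#'
#' @param pmf A [reference_pmf()]; window centers must lie inside its grid.
#' @param windows Tibble (or data frame) with columns `center` and `k`, or a
#'   numeric vector of centers combined with `k`.
#' @param bd A [bd_params()].
#' @param k Force constant used when `windows` is a bare vector of centers.
#' @param equilibration Fraction of each window discarded (default 6/22.5,
#'   the discarded share of a 22.5 ns window after 6 ns equilibration).
#' @return An [umbrella_dataset()].
#' @export
gen_bd_umbrella <- function(pmf, windows, bd = bd_params(), k = 300,
                            equilibration = 6 / 22.5) {
  if (is.numeric(windows)) windows <- tibble::tibble(center = windows, k = k)
  windows <- tibble::as_tibble(windows)
  stopifnot(all(c("center", "k") %in% names(windows)),
            equilibration >= 0, equilibration < 1)
  if (any(windows$center < min(pmf$x) | windows$center > max(pmf$x)))
    stop("window centers must lie inside the reference grid")
  bd_stability_check(pmf, windows, bd)
  kT <- KB_KCAL * bd$temperature
  set.seed(bd$seed)
  samples <- purrr::map(seq_len(nrow(windows)), function(w) {
    x <- bd_trajectory(pmf$x, pmf$G, windows$center[w], windows$k[w],
                       windows$center[w], bd$n_steps, bd$save_stride,
                       bd$D, bd$dt, kT)
    ndrop <- floor(equilibration * length(x))
    if (ndrop > 0) x <- x[-seq_len(ndrop)]
    x
  })
  windows$samples <- samples
  umbrella_dataset(windows[order(windows$center), ],
                   thermo = thermo(bd$temperature),
                   sample_period = bd$dt * bd$save_stride)
}

#' Write / read an umbrella dataset as plain-text files
#'
#' `write_umbrella_text()` writes a `manifest.tsv` (window, center, k,
#' temperature, sample_period, file) plus one two-column (time, x) file per
#' window; `read_umbrella_text()` reads the directory back.
#'
#' @param dataset An [umbrella_dataset()].
#' @param dir Directory (created if missing).
#' @return `dir` (write) or an [umbrella_dataset()] (read).
#' @export
write_umbrella_text <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- dataset$windows
  per <- dataset$sample_period
  if (is.na(per)) per <- 1
  files <- sprintf("window_%03d.tsv", seq_len(nrow(w)))
  for (i in seq_len(nrow(w))) {
    s <- w$samples[[i]]
    utils::write.table(
      data.frame(time = seq_along(s) * per, x = s),
      file.path(dir, files[i]), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  man <- data.frame(window = seq_len(nrow(w)), center = w$center, k = w$k,
                    temperature = dataset$thermo$temperature,
                    sample_period = per, file = files)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_umbrella_text
#' @export
read_umbrella_text <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                           sep = "\t")
  samples <- purrr::map(man$file, function(f) {
    utils::read.table(file.path(dir, f), header = TRUE, sep = "\t")$x
  })
  umbrella_dataset(tibble::tibble(center = man$center, k = man$k,
                                  samples = samples),
                   thermo = thermo(man$temperature[1]),
                   sample_period = man$sample_period[1])
}

# ---------------------------------------------------------------------------
# Idealized B-DNA duplex

# Cylindrical coordinates (radius A, azimuth deg, rise-offset A) of the
# reduced nucleotide representation, dyad-symmetric about the base-pair x
# axis. The phosphate azimuth is set so cross-strand P-P register minima
# reproduce canonical B-DNA groove widths (minor ~5.4 A, major ~11 A after
# the 5.8 A phosphate-radius correction); base proxies straddle the helix
# axis at hydrogen-bond distance (~3 A), standing in for the H-bond edge.
BDNA_GEOM <- data.frame(
  atom = c("P", "C3'", "C1'", "BASE"),
  r    = c(8.91, 7.40, 5.75, 1.50),
  phi  = c(92, 80, 69, 85),
  zoff = c(2.08, 1.00, 0.00, 0.00)
)

PURINES <- c("DA", "DG", "A", "G")

#' Generate an idealized B-form DNA duplex
#'
#' Places a reduced heavy-atom representation (P, C3', C1' and a base proxy:
#' N3 for purines, C4 for pyrimidines) of both antiparallel strands on a
#' regular right-handed helix. Deterministic. Strand 1 is chain `A`
#' (residues 1..n, 5'->3'); strand 2 is chain `B` (residues n+1..2n, 5'->3',
#' so pair level i couples residue i with residue 2n+1-i).
#'
#' @param n_basepairs Number of base pairs (>= 4).
#' @param rise Helical rise per base pair, A (default 3.38).
#' @param twist Helical twist per base pair, degrees (default 36).
#' @param sequence Strand-1 base letters (e.g. `"ACGTAC"`); recycled `ACGT`
#'   by default. Strand 2 is the complement.
#' @return A single-frame [ensemble()].
#' @export
gen_ideal_bdna <- function(n_basepairs, rise = 3.38, twist = 36,
                           sequence = NULL) {
  if (n_basepairs < 4) stop("n_basepairs must be >= 4")
  n <- as.integer(n_basepairs)
  if (is.null(sequence))
    sequence <- paste(rep(c("A", "C", "G", "T"), length.out = n),
                      collapse = "")
  bases1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases1) != n) stop("sequence length must equal n_basepairs")
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  bases2 <- unname(comp[bases1])

  place <- function(level, strand) {
    th <- (level - 1) * twist
    sgn <- if (strand == 1) 1 else -1
    ang <- (th + sgn * BDNA_GEOM$phi) * pi / 180
    cbind(BDNA_GEOM$r * cos(ang), BDNA_GEOM$r * sin(ang),
          (level - 1) * rise + sgn * BDNA_GEOM$zoff)
  }
  rows <- list(); xyz <- list(); k <- 1L
  for (level in seq_len(n)) {      # strand 1, 5'->3'
    b <- bases1[level]
    rows[[k]] <- tibble::tibble(
      atom_name = c("P", "C3'", "C1'", if (b %in% c("A", "G")) "N3" else "C4"),
      residue_index = level, residue_name = paste0("D", b), chain_id = "A")
    xyz[[k]] <- place(level, 1); k <- k + 1L
  }
  for (j in seq_len(n)) {          # strand 2, 5'->3' runs level n -> 1
    level <- n - j + 1L
    b <- bases2[level]
    rows[[k]] <- tibble::tibble(
      atom_name = c("P", "C3'", "C1'", if (b %in% c("A", "G")) "N3" else "C4"),
      residue_index = n + j, residue_name = paste0("D", b), chain_id = "B")
    xyz[[k]] <- place(level, 2); k <- k + 1L
  }
  ensemble(dplyr::bind_rows(rows), do.call(rbind, xyz))
}

# ---------------------------------------------------------------------------
# Toy protein-DNA complex ensembles

#' Specification of a toy protein-DNA complex
#'
#' Describes a coarse pseudo-atom complex: an idealized duplex, a set of
#' protein pseudo-residues (CA + CB + one "contact" atom per designated
#' protein-DNA contact), Bernoulli persistence probabilities for the
#' designated contacts, and a covariance matrix driving correlated Gaussian
#' displacements of the moving units (each protein residue and each base-pair
#' level moves rigidly). Displacement coordinates are i.i.d. across x, y, z
#' with the given covariance, so positional cross-correlations between node
#' anchors recover the designed correlations.
#'
#' @param n_basepairs Duplex length (default 12).
#' @param n_protein_res Number of protein pseudo-residues (default 4).
#' @param contacts Tibble with columns `protein_res`, `dna_level`,
#'   `dna_part` (`"base"` or `"backbone"`), `persistence` (in `[0, 1]`).
#' @param node_cov Covariance (A^2 per coordinate) over the displacement
#'   units, ordered `p1..pN, bp1..bpM`; default `0.04 * I`. Must be symmetric
#'   positive semi-definite.
#' @param noise_sigma Extra i.i.d. per-atom jitter, A (default 0).
#' @param rise,twist Duplex geometry.
#' @param seed RNG seed.
#' @return Object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_basepairs = 12, n_protein_res = 4,
                             contacts = NULL, node_cov = NULL,
                             noise_sigma = 0, rise = 3.38, twist = 36,
                             seed = 1L) {
  if (is.null(contacts))
    contacts <- tibble::tibble(protein_res = integer(), dna_level = integer(),
                               dna_part = character(),
                               persistence = numeric())
  contacts <- tibble::as_tibble(contacts)
  if (nrow(contacts) > 0) {
    stopifnot(all(contacts$dna_part %in% c("base", "backbone")),
              all(contacts$protein_res >= 1 &
                    contacts$protein_res <= n_protein_res),
              all(contacts$dna_level >= 1 &
                    contacts$dna_level <= n_basepairs))
    if (any(contacts$persistence < 0 | contacts$persistence > 1))
      stop("persistence probabilities must be in [0, 1]")
  }
  n_units <- n_protein_res + n_basepairs
  if (is.null(node_cov)) node_cov <- diag(0.04, n_units)
  node_cov <- as.matrix(node_cov)
  if (nrow(node_cov) != n_units || ncol(node_cov) != n_units)
    stop("node_cov must be ", n_units, " x ", n_units,
         " (protein residues then base-pair levels)")
  if (max(abs(node_cov - t(node_cov))) > 1e-10)
    stop("node_cov must be symmetric")
  ev <- eigen(node_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("node_cov must be positive semi-definite")
  structure(list(n_basepairs = as.integer(n_basepairs),
                 n_protein_res = as.integer(n_protein_res),
                 contacts = contacts, node_cov = node_cov,
                 noise_sigma = noise_sigma, rise = rise, twist = twist,
                 seed = as.integer(seed)),
            class = "toy_complex_spec")
}

# lab-frame unit direction along which a contact atom approaches its target
# DNA atom: radially outward for backbone (P) targets; tilted groove
# direction for base-proxy targets (clearance-optimal for the idealized
# geometry: azimuth +59 deg from the proxy azimuth, elevation -12 deg)
contact_direction <- function(part, level, twist) {
  th <- (level - 1) * twist
  if (part == "backbone") {
    a <- (th + 92) * pi / 180
    c(cos(a), sin(a), 0)
  } else {
    a <- (th + 85 + 59) * pi / 180
    el <- -12 * pi / 180
    c(cos(el) * cos(a), cos(el) * sin(a), sin(el))
  }
}

toy_target_atom <- function(ens, level, part) {
  top <- ens$topology
  nm <- if (part == "backbone") "P" else c("N3", "C4")
  i <- which(top$chain_id == "A" & top$residue_index == level &
               top$atom_name %in% nm)
  i[1]
}

# deterministic single-frame builder: duplex + protein skeleton, designated
# contacts in the given state, unit displacements added per moving unit
build_toy_frame <- function(spec, state = NULL, displ = NULL) {
  dna <- gen_ideal_bdna(spec$n_basepairs, spec$rise, spec$twist)
  nb <- spec$n_basepairs; np <- spec$n_protein_res
  cts <- spec$contacts
  state <- state %||% rep(TRUE, nrow(cts))
  # protein residue -> duplex level it sits against
  lvl <- vapply(seq_len(np), function(r) {
    m <- cts$dna_level[cts$protein_res == r]
    if (length(m)) m[1] else round(1 + (r - 1) * (nb - 1) / max(np - 1, 1))
  }, numeric(1))
  prows <- list(); pxyz <- list()
  for (r in seq_len(np)) {
    th <- (lvl[r] - 1) * spec$twist * pi / 180
    z <- (lvl[r] - 1) * spec$rise
    at <- c("CA", "CB")
    xy <- rbind(c(14.0 * cos(th), 14.0 * sin(th), z),
                c(15.5 * cos(th), 15.5 * sin(th), z + 1.0))
    own <- which(cts$protein_res == r)
    for (ci in seq_along(own)) {
      at <- c(at, paste0("CG", ci))
      xy <- rbind(xy, c(0, 0, 0))  # placed below from the DNA target
    }
    prows[[r]] <- tibble::tibble(atom_name = at, residue_index = r,
                                 residue_name = "LYS", chain_id = "P")
    pxyz[[r]] <- xy
  }
  top <- dplyr::bind_rows(dna$topology, dplyr::bind_rows(prows))
  xyz <- rbind(frame_coords(dna), do.call(rbind, pxyz))

  # apply rigid displacements of the moving units (protein residues, levels)
  if (!is.null(displ)) {
    for (r in seq_len(np)) {
      i <- which(top$chain_id == "P" & top$residue_index == r)
      xyz[i, ] <- sweep(xyz[i, , drop = FALSE], 2, -displ[r, ])
    }
    for (l in seq_len(nb)) {
      i <- which(top$chain_id %in% c("A", "B") &
                   top$residue_index %in% c(l, 2 * nb + 1 - l))
      xyz[i, ] <- sweep(xyz[i, , drop = FALSE], 2, -displ[np + l, ])
    }
  }
  # place contact atoms relative to the (displaced) DNA target atoms
  if (nrow(cts) > 0) {
    for (ci in seq_len(nrow(cts))) {
      r <- cts$protein_res[ci]
      own <- which(cts$protein_res == r)
      aname <- paste0("CG", match(ci, own))
      ai <- which(top$chain_id == "P" & top$residue_index == r &
                    top$atom_name == aname)
      ti <- toy_target_atom(list(topology = top), cts$dna_level[ci],
                            cts$dna_part[ci])
      u <- contact_direction(cts$dna_part[ci], cts$dna_level[ci], spec$twist)
      d <- if (state[ci]) 3.0 else 6.5
      xyz[ai, ] <- xyz[ti, ] + d * u
    }
  }
  ensemble(top, xyz)
}

#' Reference (all-contacts-formed) frame of a toy complex
#'
#' The deterministic geometry with every designated contact in its bound
#' state and no displacements; the construction oracle for contact and
#' network tests.
#'
#' @param spec A [toy_complex_spec()].
#' @return A single-frame [ensemble()].
#' @export
toy_complex_reference <- function(spec) build_toy_frame(spec)

#' Generate a toy protein-DNA complex ensemble
#'
#' Frames combine (i) the idealized geometry, (ii) correlated Gaussian rigid
#' displacements of each protein residue and base-pair level drawn from the
#' spec's covariance (independently per coordinate), and (iii) designated
#' contact atoms toggled between their bound (3.0 A) and unbound (6.5 A)
#' distances by independent Bernoulli draws with the designed persistence.
#' Contact atoms track their (displaced) DNA target, so designated pair
#' distances are exact in both states. Seeded and reproducible.
#'
#' @param spec A [toy_complex_spec()].
#' @param n_frames Number of frames.
#' @return An [ensemble()] with a `toy_spec` attribute.
#' @export
gen_toy_complex_ensemble <- function(spec, n_frames) {
  stopifnot(inherits(spec, "toy_complex_spec"), n_frames >= 1)
  set.seed(spec$seed)
  base <- build_toy_frame(spec)
  top <- base$topology
  xyz0 <- frame_coords(base)
  nb <- spec$n_basepairs; np <- spec$n_protein_res
  n_units <- np + nb
  # atom indices of each rigidly moving unit (protein residues, bp levels)
  unit_idx <- c(
    lapply(seq_len(np), function(r)
      which(top$chain_id == "P" & top$residue_index == r)),
    lapply(seq_len(nb), function(l)
      which(top$chain_id %in% c("A", "B") &
              top$residue_index %in% c(l, 2 * nb + 1 - l))))
  cts <- spec$contacts
  ct_atom <- ct_target <- integer(nrow(cts))
  ct_dir <- matrix(0, nrow(cts), 3)
  if (nrow(cts) > 0) for (ci in seq_len(nrow(cts))) {
    r <- cts$protein_res[ci]
    own <- which(cts$protein_res == r)
    ct_atom[ci] <- which(top$chain_id == "P" & top$residue_index == r &
                           top$atom_name == paste0("CG", match(ci, own)))
    ct_target[ci] <- toy_target_atom(list(topology = top),
                                     cts$dna_level[ci], cts$dna_part[ci])
    ct_dir[ci, ] <- contact_direction(cts$dna_part[ci], cts$dna_level[ci],
                                      spec$twist)
  }
  L <- chol_psd(spec$node_cov)
  coords <- array(0, dim = c(nrow(top), 3L, n_frames))
  for (f in seq_len(n_frames)) {
    displ <- L %*% matrix(rnorm(n_units * 3), n_units, 3)
    xyz <- xyz0
    for (uu in seq_len(n_units))
      xyz[unit_idx[[uu]], ] <- sweep(xyz[unit_idx[[uu]], , drop = FALSE],
                                     2, -displ[uu, ])
    if (nrow(cts) > 0) {
      state <- runif(nrow(cts)) < cts$persistence
      d <- ifelse(state, 3.0, 6.5)
      xyz[ct_atom, ] <- xyz[ct_target, , drop = FALSE] + d * ct_dir
    }
    if (spec$noise_sigma > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), sd = spec$noise_sigma),
                          nrow(xyz))
    coords[, , f] <- xyz
  }
  ens <- ensemble(top, coords)
  attr(ens, "toy_spec") <- spec
  ens
}

# Cholesky-like factor for a PSD (possibly singular) matrix via eigen
chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), length(v))
}

#' Generate an unbinding schedule of labeled ensembles
#'
#' Emulates the umbrella windows of an unbinding simulation at the contact
#' level: at each minimal-distance label, the designated contacts listed as
#' broken are placed in their unbound state, and contacts may only break
#' (never re-form) as the separation grows.
#'
#' @param spec A [toy_complex_spec()].
#' @param schedule Tibble with columns `d_min` (increasing labels, A) and
#'   `broken` (list column of designated-contact row indices broken at and
#'   beyond that label; cumulative supersets).
#' @param n_frames Frames per labeled window (default 5).
#' @return A tibble with columns `d_min` and `ens` (list of [ensemble()]s).
#' @export
gen_unbinding_schedule <- function(spec, schedule, n_frames = 5L) {
  schedule <- tibble::as_tibble(schedule)
  stopifnot(all(c("d_min", "broken") %in% names(schedule)))
  if (is.unsorted(schedule$d_min, strictly = TRUE))
    stop("schedule d_min labels must be strictly increasing")
  prev <- integer()
  for (i in seq_len(nrow(schedule))) {
    cur <- sort(unique(as.integer(schedule$broken[[i]])))
    if (!all(prev %in% cur))
      stop("schedule must be monotone: contacts broken at a smaller d_min ",
           "cannot re-form at ", schedule$d_min[i], " A")
    prev <- cur
  }
  out <- purrr::map(seq_len(nrow(schedule)), function(i) {
    state <- rep(TRUE, nrow(spec$contacts))
    state[as.integer(schedule$broken[[i]])] <- FALSE
    fr <- build_toy_frame(spec, state = state)
    ensemble(fr$topology,
             array(rep(frame_coords(fr), n_frames),
                   dim = c(n_atoms(fr), 3L, n_frames)))
  })
  tibble::tibble(d_min = schedule$d_min, ens = out)
}
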