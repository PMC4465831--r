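# DNA-based coordinate frame and Rock/Tumble docking-helix orientation.

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# split a duplex selection into base-pair levels: chain of the first selected
# residue is strand 1 read 5'->3'; strand 2 residues are paired in reverse
# order (level i couples strand-1 residue i with strand-2 residue n-i+1)
duplex_levels <- function(ens, site) {
  idx <- resolve_region(ens, site)
  top <- ens$topology[idx, ]
  chains <- unique(top$chain_id)
  if (length(chains) != 2L)
    stop("duplex selection must span exactly 2 chains, got ",
         length(chains))
  r1 <- sort(unique(top$residue_index[top$chain_id == chains[1]]))
  r2 <- sort(unique(top$residue_index[top$chain_id == chains[2]]))
  if (length(r1) != length(r2))
    stop("strands have unequal residue counts (", length(r1), " vs ",
         length(r2), ")")
  tibble::tibble(level = seq_along(r1),
                 res1 = r1, res2 = rev(r2),
                 chain1 = chains[1], chain2 = chains[2])
}

level_atoms <- function(ens, lv, row, strand = c(1, 2), atom_names = NULL) {
  top <- ens$topology
  keep <- rep(FALSE, nrow(top))
  if (1 %in% strand)
    keep <- keep | (top$chain_id == row$chain1 &
                      top$residue_index == row$res1)
  if (2 %in% strand)
    keep <- keep | (top$chain_id == row$chain2 &
                      top$residue_index == row$res2)
  if (!is.null(atom_names)) keep <- keep & top$atom_name %in% atom_names
  which(keep & top$is_heavy)
}

#' DNA-based orthogonal coordinate frame
#'
#' Builds the frame the Rock/Tumble angles are measured in: `v_x` is the
#' vector from the center of mass of the first base pair of the site to that
#' of the last; `v_t` is the vector between the two strands' backbone
#' reference atoms (P, falling back to C3') of the first base pair;
#' `v_z = v_x x v_t` and `v_y = v_x x v_z`, all normalized. `v_y` and `v_z`
#' are orthogonal to `v_x` by construction.
#'
#' @param ens An [ensemble()].
#' @param site [region()] selecting the binding-site duplex (two chains,
#'   >= 2 base pairs with backbone atoms).
#' @param frame Frame index (default 1).
#' @return A list of class `dna_frame` with unit vectors `v_x`, `v_t`,
#'   `v_y`, `v_z`.
#' @export
dna_frame <- function(ens, site, frame = 1L) {
  lv <- duplex_levels(ens, site)
  if (nrow(lv) < 2L) stop("site must contain at least 2 base pairs")
  xyz <- frame_coords(ens, frame)
  first <- lv[1, ]; last <- lv[nrow(lv), ]
  com <- function(row) colMeans(xyz[level_atoms(ens, lv, row), , drop = FALSE])
  v_x <- com(last) - com(first)
  bb <- function(row, strand) {
    i <- level_atoms(ens, lv, row, strand = strand, atom_names = "P")
    if (length(i) == 0L)
      i <- level_atoms(ens, lv, row, strand = strand, atom_names = "C3'")
    if (length(i) == 0L)
      stop("first base pair lacks backbone reference atoms (P or C3')")
    xyz[i[1], ]
  }
  v_t <- bb(first, 2) - bb(first, 1)
  vx <- normalize3(v_x)
  cz <- cross3(vx, normalize3(v_t))
  if (sqrt(sum(cz^2)) < 1e-8)
    stop("degenerate frame: v_x and v_t are parallel")
  v_z <- normalize3(cz)
  v_y <- normalize3(cross3(vx, v_z))
  structure(list(v_x = vx, v_t = normalize3(v_t), v_y = v_y, v_z = v_z),
            class = "dna_frame")
}

#' Axis of a docking helix
#'
#' The principal axis (largest-variance direction) of the helix backbone
#' positions (CA atoms for proteins), signed to point from the first to the
#' last residue (N- to C-terminal).
#'
#' @param ens An [ensemble()].
#' @param helix [region()] selecting the helix; >= 4 backbone positions.
#' @param frame Frame index (default 1).
#' @param atom_names Backbone atom names to use (default `"CA"`).
#' @return A unit 3-vector.
#' @export
helix_axis <- function(ens, helix, frame = 1L, atom_names = "CA") {
  idx <- resolve_region(ens, helix)
  top <- ens$topology[idx, ]
  keep <- top$atom_name %in% atom_names
  idx <- idx[keep][order(top$residue_index[keep])]
  if (length(idx) < 4L) stop("helix axis needs >= 4 backbone positions")
  xyz <- frame_coords(ens, frame)[idx, , drop = FALSE]
  cen <- sweep(xyz, 2, colMeans(xyz))
  ax <- svd(cen)$v[, 1]
  if (sum(ax * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) ax <- -ax
  normalize3(ax)
}

#' Rock and Tumble angles of a docking helix
#'
#' Per frame, the helix axis is projected onto the stated planes of the
#' DNA-based frame: Rock is the signed angle between the axis projected on
#' the `v_y`/`v_z` plane and `v_y` (rotation around the helical axis of the
#' DNA); Tumble is the signed angle between the axis projected on the
#' `v_x`/`v_z` plane and `v_x` (motion inside the binding groove). Angles in
#' degrees, `(-180, 180]`, computed with `atan2` on the plane coordinates.
#' Frames where a projection nearly vanishes are flagged undefined (`NA`)
#' with a warning and excluded from summaries.
#'
#' @param ens An [ensemble()].
#' @param site DNA binding-site [region()] (passed to [dna_frame()]).
#' @param helix Docking-helix [region()] (passed to [helix_axis()]).
#' @param frames Frames to evaluate (default all).
#' @return A tibble of class `orientation_samples` with columns `frame`,
#'   `rock`, `tumble` (degrees).
#' @export
rock_tumble <- function(ens, site, helix, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(ens))
  eps <- 1e-10
  res <- purrr::map(frames, function(f) {
    fr <- dna_frame(ens, site, frame = f)
    a <- helix_axis(ens, helix, frame = f)
    py <- sum(a * fr$v_y); pz <- sum(a * fr$v_z); px <- sum(a * fr$v_x)
    rock <- if (abs(py) < eps && abs(pz) < eps) NA_real_ else
      atan2(pz, py) * 180 / pi
    tumble <- if (abs(px) < eps && abs(pz) < eps) NA_real_ else
      atan2(pz, px) * 180 / pi
    tibble::tibble(frame = f, rock = rock, tumble = tumble)
  })
  out <- dplyr::bind_rows(res)
  if (anyNA(out$rock) || anyNA(out$tumble))
    warning("some frames have an undefined Rock or Tumble angle ",
            "(helix axis parallel to the plane normal); flagged NA")
  structure(out, class = c("orientation_samples", class(out)))
}

#' Ratio of conformational areas of two orientation sample sets
#'
#' The conformational area sampled in the 2D Rock/Tumble subspace is
#' proportional to the product of the square roots of the covariance-matrix
#' eigenvalues (the confidence-ellipse area at any fixed confidence level,
#' which cancels in the ratio). Returns area(A) / area(B).
#'
#' @param samplesA,samplesB Tibbles with `rock` and `tumble` columns, at
#'   least 50 samples each.
#' @return A single numeric ratio.
#' @export
ellipse_area_ratio <- function(samplesA, samplesB) {
  area <- function(s) {
    s <- s[stats::complete.cases(s[, c("rock", "tumble")]), ]
    if (nrow(s) < 50L) stop("need >= 50 orientation samples")
    ev <- eigen(stats::cov(cbind(s$rock, s$tumble)), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev))
      stop("rank-deficient orientation covariance")
    sqrt(prod(ev))
  }
  area(samplesA) / area(samplesB)
}

#' 2D histogram of Rock/Tumble samples
#'
#' @param samples An `orientation_samples` tibble.
#' @param bin Bin width in degrees (default 2).
#' @return A tibble with `rock_bin`, `tumble_bin` (bin centers) and `n`.
#' @export
orientation_histogram <- function(samples, bin = 2) {
  s <- samples[stats::complete.cases(samples[, c("rock", "tumble")]), ]
  tibble::as_tibble(s) |>
    dplyr::mutate(rock_bin = (floor(.data$rock / bin) + 0.5) * bin,
                  tumble_bin = (floor(.data$tumble / bin) + 0.5) * bin) |>
    dplyr::count(.data$rock_bin, .data$tumble_bin, name = "n")
}
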