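# Simplified DNA structural descriptors: groove widths from cross-strand
# phosphate registers, local axis bending from base-pair-center chords,
# inter-base-pair property correlations, and block-averaged standard errors.

# register windows (in base-pair levels along strand 1, 5'->3') over which
# the cross-strand P-P minimum is taken for each groove
GROOVE_REGISTER <- list(minor = 2:5, major = -(2:5))
PHOSPHATE_RADIUS_CORRECTION <- 5.8  # A, subtracted from P-P distances

#' Groove widths along a duplex
#'
#' Minor and major groove widths per base-pair level: the minimal
#' cross-strand phosphate-phosphate distance over a fixed register window
#' (minor: strand-2 partners offset +2..+5 levels; major: -5..-2), minus
#' 5.8 A for the phosphate van der Waals radii. This "pp-register" convention
#' reproduces the canonical ideal-B-DNA scale (minor ~5.4 A) but is not a
#' curvilinear-axis groove definition; values carry the convention tag.
#' Levels whose register window leaves the duplex (and the 2 terminal levels)
#' are flagged undefined (`NA`).
#'
#' @param ens An [ensemble()].
#' @param duplex [region()] selecting the duplex (two chains with phosphate
#'   atoms).
#' @return A list of class `groove_profile`: `per_frame` (tibble: frame,
#'   level, minor, major), `summary` (tibble: level, minor, minor_se, major,
#'   major_se via [block_se()] over frames), `convention`.
#' @export
groove_widths <- function(ens, duplex) {
  lv <- duplex_levels(ens, duplex)
  n <- nrow(lv)
  p1 <- vapply(seq_len(n), function(i)
    level_atoms(ens, lv, lv[i, ], strand = 1, atom_names = "P")[1],
    numeric(1))
  p2 <- vapply(seq_len(n), function(i)
    level_atoms(ens, lv, lv[i, ], strand = 2, atom_names = "P")[1],
    numeric(1))
  if (anyNA(p1) || anyNA(p2))
    stop("duplex lacks phosphate atoms on one or both strands")
  nf <- n_frames(ens)
  per <- purrr::map(seq_len(nf), function(f) {
    xyz <- frame_coords(ens, f)
    width <- function(i, offsets) {
      j <- i + offsets
      if (any(j < 1 | j > n)) return(NA_real_)  # incomplete register window
      min(sqrt(colSums((t(xyz[p2[j], , drop = FALSE]) - xyz[p1[i], ])^2))) -
        PHOSPHATE_RADIUS_CORRECTION
    }
    minor <- vapply(seq_len(n), width, numeric(1),
                    offsets = GROOVE_REGISTER$minor)
    major <- vapply(seq_len(n), width, numeric(1),
                    offsets = GROOVE_REGISTER$major)
    end <- c(1, 2, n - 1, n)
    minor[end] <- NA_real_; major[end] <- NA_real_
    tibble::tibble(frame = f, level = seq_len(n), minor = minor,
                   major = major)
  })
  per <- dplyr::bind_rows(per)
  summarise_level <- function(v) {
    if (all(is.na(v))) return(c(NA_real_, NA_real_))
    c(mean(v), if (length(v) >= 16) block_se(v) else
      stats::sd(v) / sqrt(length(v)))
  }
  summ <- per |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      minor_se = summarise_level(.data$minor)[2],
      minor = summarise_level(.data$minor)[1],
      major_se = summarise_level(.data$major)[2],
      major = summarise_level(.data$major)[1],
      .groups = "drop") |>
    dplyr::select("level", "minor", "minor_se", "major", "major_se")
  structure(list(per_frame = per, summary = summ,
                 convention = "pp-register (minor +2..+5, major -5..-2, -5.8 A)"),
            class = "groove_profile")
}

#' Local DNA axis bending profile
#'
#' The bend at level i is the angle between the two base-pair-center chords
#' `c(i) - c(i-2)` and `c(i+2) - c(i)`, where `c(i)` is the midpoint of the
#' paired base atoms of level i. Per-base-pair resolution; the first/last two
#' levels are undefined.
#'
#' @param ens An [ensemble()].
#' @param duplex Duplex [region()] (>= 5 base pairs).
#' @return A list of class `bend_profile`: `per_frame` (frame, level,
#'   bend in degrees) and `summary` (level, bend, bend_se).
#' @export
bend_profile <- function(ens, duplex) {
  lv <- duplex_levels(ens, duplex)
  n <- nrow(lv)
  if (n < 5L) stop("bend profile needs >= 5 base-pair levels")
  top <- ens$topology
  base_atoms <- purrr::map(seq_len(n), function(i) {
    a <- level_atoms(ens, lv, lv[i, ])
    a[dna_atom_class(top$atom_name[a]) == "base"]
  })
  nf <- n_frames(ens)
  per <- purrr::map(seq_len(nf), function(f) {
    xyz <- frame_coords(ens, f)
    cen <- t(vapply(base_atoms, function(a)
      colMeans(xyz[a, , drop = FALSE]), numeric(3)))
    bend <- rep(NA_real_, n)
    for (i in 3:(n - 2)) {
      u <- cen[i, ] - cen[i - 2, ]
      v <- cen[i + 2, ] - cen[i, ]
      ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      bend[i] <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
    }
    tibble::tibble(frame = f, level = seq_len(n), bend = bend)
  })
  per <- dplyr::bind_rows(per)
  summ <- per |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      bend_se = if (all(is.na(.data$bend))) NA_real_
        else if (dplyr::n() >= 16) block_se(.data$bend)
        else stats::sd(.data$bend) / sqrt(dplyr::n()),
      bend = mean(.data$bend), .groups = "drop") |>
    dplyr::select("level", "bend", "bend_se")
  structure(list(per_frame = per, summary = summ), class = "bend_profile")
}

#' Inter-base-pair correlation of a scalar property
#'
#' Pearson correlation across frames between every pair of base-pair levels
#' of a per-frame property (groove width, bend angle, ...). Zero-variance
#' levels get 1 on the diagonal and `NA` off-diagonal.
#'
#' @param property A frames x levels numeric matrix, or a long tibble with
#'   columns `frame`, `level` and the property as the remaining column.
#' @param min_frames Minimum number of frames (default 10).
#' @return A symmetric correlation matrix (levels x levels).
#' @export
property_correlation <- function(property, min_frames = 10L) {
  if (!is.matrix(property)) {
    tb <- tibble::as_tibble(property)
    val <- setdiff(names(tb), c("frame", "level"))[1]
    property <- tb |>
      dplyr::select(dplyr::all_of(c("frame", "level", val))) |>
      tidyr::pivot_wider(names_from = "level", values_from = dplyr::all_of(val)) |>
      dplyr::select(-"frame") |>
      as.matrix()
  }
  if (nrow(property) < min_frames)
    stop("property correlation needs >= ", min_frames, " frames")
  v <- apply(property, 2, stats::var)
  C <- suppressWarnings(stats::cor(property))
  zero <- which(v < 1e-14 | is.na(v))
  if (length(zero)) {
    C[zero, ] <- NA_real_; C[, zero] <- NA_real_
    diag(C)[zero] <- 1
  }
  diag(C) <- 1
  C
}

#' Block-averaged standard error of the mean
#'
#' Standard error of the mean of a (possibly autocorrelated) scalar series by
#' block averaging: the series is cut into non-overlapping blocks of doubling
#' size, and the SE of the block means is tracked as the block size grows.
#' The reported SE is the value at the largest block size that still leaves
#' at least 8 blocks, where the block-size curve has plateaued for series
#' whose correlation time is resolved.
#'
#' @param series Numeric vector, length >= 16.
#' @param min_blocks Minimum number of blocks retained (default 8).
#' @param full If `TRUE` return the whole block-size curve as a tibble.
#' @return The SE (numeric), or a tibble (`block_size`, `n_blocks`, `se`)
#'   when `full = TRUE`.
#' @export
block_se <- function(series, min_blocks = 8L, full = FALSE) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 16L) stop("block_se needs a series of length >= 16")
  sizes <- 2^(0:floor(log2(n / min_blocks)))
  curve <- purrr::map(sizes, function(b) {
    m <- floor(n / b)
    bm <- colMeans(matrix(series[seq_len(m * b)], nrow = b))
    tibble::tibble(block_size = b, n_blocks = m,
                   se = stats::sd(bm) / sqrt(m))
  })
  curve <- dplyr::bind_rows(curve)
  if (full) curve else curve$se[nrow(curve)]
}
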