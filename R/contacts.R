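# Contact maps, recurrence classification, per-residue profiles, and
# unbinding contact-fraction profiles.

# classify a DNA heavy atom as base or sugar-phosphate backbone by name:
# primed atoms and the phosphate group are backbone, ring/exocyclic atoms
# without primes are base
dna_atom_class <- function(atom_name) {
  backbone <- grepl("'", atom_name) |
    atom_name %in% c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P")
  ifelse(backbone, "backbone", "base")
}

#' Protein-DNA contact map with per-frame occupancies
#'
#' A contact is an atom pair (one atom per selection, heavy atoms) within the
#' cutoff; the boundary is included (`d <= cutoff`). Occupancy is the
#' fraction of frames in which the pair is in contact.
#'
#' @param ens An [ensemble()] with at least one frame.
#' @param selA Protein-side [region()] or atom indices.
#' @param selB DNA-side [region()] or atom indices (disjoint from `selA`).
#' @param cutoff Distance threshold, A (default 4.5).
#' @param threshold Recurrence threshold passed to [classify_recurrence()]
#'   (default 0.5).
#' @return A `contact_table`: a tibble with one row per observed pair and
#'   columns `atom_i`, `atom_j`, `residue_i`, `residue_j`, `atom_name_i`,
#'   `atom_name_j`, `dna_class` (base/backbone of the `selB` atom),
#'   `occupancy`, `n_frames`, `label`; attributes `cutoff` and `threshold`.
#' @export
contact_map <- function(ens, selA, selB, cutoff = 4.5, threshold = 0.5) {
  if (n_frames(ens) < 1L) stop("empty ensemble")
  ia <- resolve_region(ens, selA, heavy_only = TRUE)
  ib <- resolve_region(ens, selB, heavy_only = TRUE)
  if (length(intersect(ia, ib)) > 0L) stop("selections must be disjoint")
  nf <- n_frames(ens)
  counts <- matrix(0L, length(ia), length(ib))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    counts <- counts + (d2 <= cutoff^2)
  }
  hit <- which(counts > 0L, arr.ind = TRUE)
  top <- ens$topology
  tab <- tibble::tibble(
    atom_i = ia[hit[, 1]], atom_j = ib[hit[, 2]],
    residue_i = top$residue_index[ia[hit[, 1]]],
    residue_j = top$residue_index[ib[hit[, 2]]],
    atom_name_i = top$atom_name[ia[hit[, 1]]],
    atom_name_j = top$atom_name[ib[hit[, 2]]],
    chain_j = top$chain_id[ib[hit[, 2]]],
    dna_class = dna_atom_class(top$atom_name[ib[hit[, 2]]]),
    occupancy = counts[hit] / nf,
    n_frames = nf
  )
  tab <- dplyr::arrange(tab, .data$atom_i, .data$atom_j)
  out <- structure(tab, class = c("contact_table", class(tab)),
                   cutoff = cutoff, threshold = threshold,
                   selA = ia, selB = ib)
  classify_recurrence(out, threshold)
}

#' Label contacts as recurrent or non-stable
#'
#' Recurrent contacts are those formed in more than `threshold` (strictly)
#' of the frames; all other observed contacts are non-stable. The two labels
#' partition the table.
#'
#' @param table A `contact_table` from [contact_map()].
#' @param threshold Occupancy threshold (default 0.5, i.e. more than 50\% of
#'   the simulation time).
#' @return The table with a `label` column (`"recurrent"`/`"non-stable"`).
#' @export
classify_recurrence <- function(table, threshold = 0.5) {
  table$label <- ifelse(table$occupancy > threshold, "recurrent",
                        "non-stable")
  attr(table, "threshold") <- threshold
  table
}

#' Per-residue contact counts
#'
#' Counts contact pairs per protein residue, optionally restricted to
#' recurrent contacts and/or split by DNA base vs backbone partner atoms.
#' Pairs are counted at the atom-pair level (a residue contacting one DNA
#' atom through two of its atoms counts 2).
#'
#' @param table A labeled `contact_table`.
#' @param which `"recurrent"` (default), `"non-stable"` or `"all"`.
#' @param split If `TRUE` (default) report separate base/backbone counts.
#' @return A tibble with `residue`, `dna_class` (if split) and `n_contacts`.
#' @export
per_residue_profile <- function(table, which = c("recurrent", "non-stable",
                                                 "all"),
                                split = TRUE) {
  which <- match.arg(which)
  tab <- if (which == "all") table else
    dplyr::filter(table, .data$label == which)
  grp <- if (split) c("residue_i", "dna_class") else "residue_i"
  out <- dplyr::count(tibble::as_tibble(tab),
                      dplyr::across(dplyr::all_of(grp)), name = "n_contacts")
  dplyr::rename(out, residue = "residue_i")
}

#' Contact-breaking profile along an unbinding coordinate
#'
#' For a sequence of ensembles labeled by the minimal-distance collective
#' variable, reports per label (i) the fraction of the reference recurrent
#' contacts still formed, using the unbiased-ensemble recurrent set as
#' reference, and (ii) the number of non-stable contacts present.
#'
#' @param windows Tibble with columns `d_min` (labels, A) and `ens` (list of
#'   [ensemble()]s), e.g. from [gen_unbinding_schedule()].
#' @param reference A labeled `contact_table` from the unbiased ensemble;
#'   must contain at least one recurrent pair.
#' @param cutoff Contact cutoff, A (default: the reference table's cutoff).
#' @param occupancy_min A reference pair counts as "still formed" in a window
#'   when its in-window occupancy exceeds this (default 0.5).
#' @return A tibble with columns `d_min`, `fraction_recurrent`,
#'   `n_non_stable`.
#' @export
unbinding_profile <- function(windows, reference, cutoff = NULL,
                              occupancy_min = 0.5) {
  cutoff <- cutoff %||% attr(reference, "cutoff") %||% 4.5
  rec <- dplyr::filter(reference, .data$label == "recurrent")
  if (nrow(rec) == 0L) stop("reference has no recurrent contacts")
  if (is.unsorted(windows$d_min)) windows <- dplyr::arrange(windows, .data$d_min)
  res <- purrr::map(seq_len(nrow(windows)), function(w) {
    ens <- windows$ens[[w]]
    nf <- n_frames(ens)
    occ <- vapply(seq_len(nrow(rec)), function(p) {
      d <- vapply(seq_len(nf), function(f) {
        xyz <- frame_coords(ens, f)
        sqrt(sum((xyz[rec$atom_i[p], ] - xyz[rec$atom_j[p], ])^2))
      }, numeric(1))
      mean(d <= cutoff)
    }, numeric(1))
    # non-stable contacts observed in this window (pairs below cutoff that
    # are not part of the recurrent reference set)
    ia <- attr(reference, "selA") %||% unique(reference$atom_i)
    ib <- attr(reference, "selB") %||% unique(reference$atom_j)
    counts <- matrix(0L, length(ia), length(ib))
    for (f in seq_len(nf)) {
      xyz <- frame_coords(ens, f)
      counts <- counts +
        (cross_dist2(xyz[ia, , drop = FALSE],
                     xyz[ib, , drop = FALSE]) <= cutoff^2)
    }
    hit <- which(counts > 0L, arr.ind = TRUE)
    pairs <- paste(ia[hit[, 1]], ib[hit[, 2]])
    recur <- paste(rec$atom_i, rec$atom_j)
    tibble::tibble(
      d_min = windows$d_min[w],
      fraction_recurrent = mean(occ > occupancy_min),
      n_non_stable = sum(!pairs %in% recur)
    )
  })
  dplyr::bind_rows(res)
}
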