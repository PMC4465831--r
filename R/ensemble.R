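#' Molecular ensemble container
#'
#' An `ensemble` couples a topology (one row per atom) with an ordered set of
#' coordinate frames. It is the substrate of all trajectory analytics in the
#' package: contact maps, orientation angles, groove geometry, correlation
#' networks and the minimal-distance collective variable.
#'
#' @param topology A data frame with one row per atom and columns
#'   `atom_name`, `residue_index`, `residue_name`, `chain_id`. Columns
#'   `element` and `is_heavy` are derived from `atom_name` when absent.
#' @param coords Coordinates in Angstrom: an `n_atoms x 3` matrix (single
#'   frame), or an `n_atoms x 3 x n_frames` array, or a list of
#'   `n_atoms x 3` matrices.
#' @param frame_period Time between saved frames in ps (default 3 ps).
#' @return An object of class `ensemble` with elements `topology` (tibble),
#'   `coords` (`n_atoms x 3 x n_frames` array) and `frame_period`.
#' @examples
#' top <- data.frame(atom_name = c("CA", "CB"), residue_index = 1,
#'                   residue_name = "ALA", chain_id = "A")
#' ens <- ensemble(top, matrix(rnorm(6), 2, 3))
#' n_frames(ens)
#' @export
ensemble <- function(topology, coords, frame_period = 3) {
  topology <- tibble::as_tibble(topology)
  need <- c("atom_name", "residue_index", "residue_name", "chain_id")
  miss <- setdiff(need, names(topology))
  if (length(miss) > 0)
    stop("topology is missing column(s): ", paste(miss, collapse = ", "))
  if (!"element" %in% names(topology))
    topology$element <- NA_character_
  na_el <- is.na(topology$element)
  topology$element[na_el] <- guess_element(topology$atom_name[na_el])
  if (!"is_heavy" %in% names(topology))
    topology$is_heavy <- NA
  na_h <- is.na(topology$is_heavy)
  topology$is_heavy[na_h] <- topology$element[na_h] != "H"

  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords), dim = c(dim(coords[[1]]), length(coords)))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be n_atoms x 3 (x n_frames)")
  if (dim(coords)[1] != nrow(topology))
    stop("coords has ", dim(coords)[1], " atoms but topology has ",
         nrow(topology))
  if (!is.numeric(frame_period) || frame_period <= 0)
    stop("frame_period must be > 0")
  structure(list(topology = topology, coords = coords,
                 frame_period = frame_period),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", dim(x$coords)[1], " atoms, ", dim(x$coords)[3],
      " frame(s), ", length(unique(x$topology$chain_id)), " chain(s)\n",
      sep = "")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ens An [ensemble()].
#' @return Integer count.
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(ens) dim(ens$coords)[1]

#' Extract one frame as a coordinate matrix
#' @param ens An [ensemble()].
#' @param frame Frame index (1-based).
#' @return An `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(ens, frame = 1L) {
  stopifnot(frame >= 1L, frame <= n_frames(ens))
  m <- ens$coords[, , frame]
  if (!is.matrix(m)) m <- matrix(m, ncol = 3L)
  m
}

#' Subset an ensemble to selected frames
#' @param ens An [ensemble()].
#' @param frames Integer frame indices, kept in the given order.
#' @return An [ensemble()].
#' @export
subset_frames <- function(ens, frames) {
  ensemble(ens$topology, ens$coords[, , frames, drop = FALSE],
           ens$frame_period)
}

# Derive the element symbol from a PDB-style atom name: leading digits are
# dropped ("1H5'"), primes/digits stripped, first letter taken. Two-letter
# elements do not occur among the protein/DNA heavy atoms handled here.
guess_element <- function(atom_name) {
  x <- gsub("^[0-9]+", "", trimws(atom_name))
  toupper(substr(x, 1L, 1L))
}

# ---------------------------------------------------------------------------
# Region selection

#' Define a region of a structure
#'
#' Regions name the structural units the analyses operate on: protein domains
#' (inclusive residue ranges, 1-based), DNA binding sites, docking helices, or
#' explicit atom sets.
#'
#' @param name Label for the region.
#' @param residues Integer vector of residue indices (inclusive ranges are
#'   spelled out, e.g. `95:152`).
#' @param chains Optional chain identifiers to restrict to.
#' @param atom_names Optional atom names to restrict to.
#' @param atoms Optional explicit atom indices (overrides the other filters).
#' @param heavy_only Drop hydrogens when resolving (default TRUE; contacts and
#'   the minimal-distance collective variable are defined on heavy atoms).
#' @return An object of class `region`.
#' @seealso [resolve_region()], [region_presets()]
#' @export
region <- function(name, residues = NULL, chains = NULL, atom_names = NULL,
                   atoms = NULL, heavy_only = TRUE) {
  structure(list(name = name, residues = residues, chains = chains,
                 atom_names = atom_names, atoms = atoms,
                 heavy_only = heavy_only),
            class = "region")
}

#' Named preset regions for POU-family transcription factors
#'
#' The POU DNA-binding region comprises the POU-specific domain (residues
#' 1-88, which includes the helical part of the linker) and the POU
#' homeodomain (residues 95-152) whose N-terminal tail (95-106) docks into
#' the minor groove while the globular part (107-152) binds the major groove.
#'
#' @param chain Chain identifier the protein lives on (default `"P"`).
#' @return A named list of [region()] objects.
#' @export
region_presets <- function(chain = "P") {
  list(
    pou_s           = region("POU_S", residues = 1:88, chains = chain),
    pou_hd          = region("POU_HD", residues = 95:152, chains = chain),
    pou_hd_tail     = region("POU_HD_tail", residues = 95:106, chains = chain),
    pou_hd_globular = region("POU_HD_globular", residues = 107:152,
                             chains = chain),
    pou_s_docking_helix  = region("POU_S_docking_helix", residues = 43:56,
                                  chains = chain),
    pou_hd_docking_helix = region("POU_HD_docking_helix", residues = 139:152,
                                  chains = chain)
  )
}

#' Resolve a region against an ensemble topology
#'
#' @param ens An [ensemble()].
#' @param sel A [region()], an integer vector of atom indices, or a list with
#'   any of `residues`, `chains`, `atom_names`.
#' @param heavy_only Override the region's hydrogen handling.
#' @return Integer atom indices (1-based, in topology order).
#' @export
resolve_region <- function(ens, sel, heavy_only = NULL) {
  top <- ens$topology
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L | idx > nrow(top))) stop("atom index out of range")
    return(idx)
  }
  if (!inherits(sel, "region") && is.list(sel))
    sel <- region(sel$name %||% "ad-hoc", residues = sel$residues,
                  chains = sel$chains, atom_names = sel$atom_names,
                  atoms = sel$atoms, heavy_only = sel$heavy_only %||% TRUE)
  if (!inherits(sel, "region")) stop("cannot interpret selection")
  if (!is.null(sel$atoms)) return(as.integer(sel$atoms))
  keep <- rep(TRUE, nrow(top))
  if (!is.null(sel$residues)) keep <- keep & top$residue_index %in% sel$residues
  if (!is.null(sel$chains)) keep <- keep & top$chain_id %in% sel$chains
  if (!is.null(sel$atom_names)) keep <- keep & top$atom_name %in% sel$atom_names
  ho <- heavy_only %||% sel$heavy_only
  if (isTRUE(ho)) keep <- keep & top$is_heavy
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("region '", sel$name, "' resolves to no atoms")
  idx
}

# ---------------------------------------------------------------------------
# Structure / trajectory I/O

validate_pdb_lines <- function(lines, path) {
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (length(rec) == 0L)
    stop("no ATOM/HETATM records in '", path, "'")
  for (i in rec) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, " of '", path,
           "': record shorter than coordinate fields")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed PDB record at line ", i, " of '", path,
           "': non-numeric coordinates")
  }
  invisible(TRUE)
}

pdb_to_topology <- function(pdb) {
  at <- pdb$atom
  tibble::tibble(
    atom_name     = trimws(at$elety),
    residue_index = as.integer(at$resno),
    residue_name  = trimws(at$resid),
    chain_id      = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  )
}

#' Read a structure from a PDB file
#'
#' Reads a single-model PDB file into a one-frame [ensemble()]. Atom order,
#' chain identifiers and residue numbering are preserved; `is_heavy` is
#' derived from the atom names.
#'
#' @param path Path to the file.
#' @param format Only `"pdb"` is supported.
#' @return A single-frame [ensemble()].
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)
  validate_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  coords <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  ensemble(pdb_to_topology(pdb), coords)
}

#' Read a trajectory into an ensemble
#'
#' Supported trajectory formats: multi-model PDB (`"pdb"`), CHARMM/NAMD DCD
#' (`"dcd"`, requires a PDB topology), and plain CSV frame tables (`"csv"`,
#' columns `frame, atom, x, y, z`). XTC is not supported by the available
#' readers; convert to DCD or multi-model PDB upstream.
#'
#' @param topology_path PDB file providing the topology.
#' @param traj_path Trajectory file; may equal `topology_path` for
#'   multi-model PDB.
#' @param format One of `"pdb"`, `"dcd"`, `"csv"`.
#' @param stride Keep every `stride`-th frame, starting at the first
#'   (default 1).
#' @param frame_period Time per saved frame in ps, after striding is applied
#'   to the raw period (default 3 ps per raw frame).
#' @return An [ensemble()].
#' @export
read_ensemble <- function(topology_path, traj_path = topology_path,
                          format = c("pdb", "dcd", "csv", "xtc"),
                          stride = 1L, frame_period = 3) {
  format <- match.arg(format)
  if (format == "xtc")
    stop("XTC reading is not supported; convert to DCD or multi-model PDB")
  stopifnot(stride >= 1L)
  lines <- readLines(topology_path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", topology_path)
  validate_pdb_lines(lines, topology_path)
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)
  top <- pdb_to_topology(pdb)
  na_top <- nrow(top)

  xyz <- switch(format,
    pdb = {
      p2 <- if (identical(traj_path, topology_path)) pdb else
        bio3d::read.pdb(traj_path, multi = TRUE, verbose = FALSE)
      if (ncol(p2$xyz) / 3 != na_top)
        stop("atom count mismatch: topology has ", na_top,
             " atoms but trajectory frames have ", ncol(p2$xyz) / 3)
      unclass(p2$xyz)
    },
    dcd = {
      x <- bio3d::read.dcd(traj_path, verbose = FALSE)
      if (ncol(x) / 3 != na_top)
        stop("atom count mismatch: topology has ", na_top,
             " atoms but trajectory frames have ", ncol(x) / 3)
      unclass(x)
    },
    csv = {
      tab <- utils::read.csv(traj_path)
      need <- c("frame", "atom", "x", "y", "z")
      if (!all(need %in% names(tab)))
        stop("csv frame table needs columns: ", paste(need, collapse = ", "))
      fr <- sort(unique(tab$frame))
      per <- table(tab$frame)
      if (any(per != na_top))
        stop("atom count mismatch: topology has ", na_top,
             " atoms but trajectory frames have ", per[which(per != na_top)[1]])
      tab <- tab[order(tab$frame, tab$atom), ]
      t(matrix(rbind(tab$x, tab$y, tab$z), nrow = 3 * na_top))
    })

  xyz <- matrix(xyz, ncol = 3 * na_top)
  keep <- seq(1L, nrow(xyz), by = stride)
  coords <- array(0, dim = c(na_top, 3L, length(keep)))
  for (i in seq_along(keep))
    coords[, , i] <- matrix(xyz[keep[i], ], ncol = 3, byrow = TRUE)
  ensemble(top, coords, frame_period = frame_period * stride)
}

#' Write an ensemble as a (multi-model) PDB file
#'
#' One MODEL record per frame; coordinates at the format's 0.001 A precision.
#'
#' @param ens An [ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(ens, path) {
  top <- ens$topology
  nf <- n_frames(ens)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nf > 1L
  for (f in seq_len(nf)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(ens, f)
    nm <- top$atom_name
    # PDB column-13 alignment: names of <4 chars starting with the element
    # are written from column 14
    fmt_nm <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
    lines <- sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(top)) %% 100000L, fmt_nm,
      substr(top$residue_name, 1, 3), substr(top$chain_id, 1, 1),
      top$residue_index %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3],
      1.0, 0.0, top$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Superposition (Kabsch least-squares fit)

kabsch_transform <- function(mobile, ref) {
  # returns list(R, t) minimising ||mobile %*% R + t - ref||^2
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm)
  B <- sweep(ref, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = t(R), t = cr - cm %*% t(R))
}

#' Superpose an ensemble onto a reference
#'
#' Least-squares rigid-body fit (Kabsch) of every frame onto the reference
#' over the fit selection; the resulting rotation + translation is applied to
#' all atoms of the frame. The RMSD over the fit selection is minimised.
#'
#' @param ens An [ensemble()].
#' @param fit_selection A [region()] (or atom indices) with at least 3
#'   non-collinear atoms.
#' @param reference Frame index into `ens` (default 1) or a single-frame
#'   [ensemble()] with the same fit atoms.
#' @return The superposed [ensemble()].
#' @export
superpose <- function(ens, fit_selection, reference = 1L) {
  idx <- resolve_region(ens, fit_selection)
  if (length(idx) < 3L) stop("fit selection needs at least 3 atoms")
  ref_xyz <- if (inherits(reference, "ensemble"))
    frame_coords(reference, 1L)[resolve_region(reference, fit_selection), ,
                                drop = FALSE]
  else frame_coords(ens, reference)[idx, , drop = FALSE]
  s <- svd(sweep(ref_xyz, 2, colMeans(ref_xyz)))$d
  if (s[2] < 1e-8 * max(s[1], 1))
    stop("fit selection atoms are collinear")
  out <- ens$coords
  for (f in seq_len(n_frames(ens))) {
    fx <- frame_coords(ens, f)
    tr <- kabsch_transform(fx[idx, , drop = FALSE], ref_xyz)
    out[, , f] <- sweep(fx %*% tr$R, 2, -as.numeric(tr$t))
  }
  ensemble(ens$topology, out, ens$frame_period)
}

#' Root-mean-square deviation over a selection
#' @param ens An [ensemble()].
#' @param sel A [region()] or atom indices.
#' @param reference Frame index or single-frame [ensemble()].
#' @return A tibble with columns `frame` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(ens, sel, reference = 1L) {
  idx <- resolve_region(ens, sel)
  ref <- if (inherits(reference, "ensemble"))
    frame_coords(reference, 1L)[resolve_region(reference, sel), , drop = FALSE]
  else frame_coords(ens, reference)[idx, , drop = FALSE]
  r <- vapply(seq_len(n_frames(ens)), function(f) {
    d <- frame_coords(ens, f)[idx, , drop = FALSE] - ref
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  tibble::tibble(frame = seq_len(n_frames(ens)), rmsd = r)
}

# ---------------------------------------------------------------------------
# Minimal-distance collective variable

#' Minimal interatomic distance between two regions
#'
#' The unbinding collective variable: the minimal (heavy-atom) interatomic
#' distance between a pulled protein domain and the DNA, evaluated per frame
#' together with the arg-min atom pair.
#'
#' @param ens An [ensemble()].
#' @param selA,selB Disjoint [region()]s or atom index vectors.
#' @param frames Frames to evaluate (default all).
#' @param heavy_only Restrict to heavy atoms (default TRUE).
#' @return A tibble with columns `frame`, `d_min` (Angstrom), `atom_i`,
#'   `atom_j` (topology indices of the arg-min pair).
#' @export
min_distance <- function(ens, selA, selB, frames = NULL, heavy_only = TRUE) {
  ia <- resolve_region(ens, selA, heavy_only = heavy_only)
  ib <- resolve_region(ens, selB, heavy_only = heavy_only)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty selection")
  if (length(intersect(ia, ib)) > 0L) stop("selections must be disjoint")
  frames <- frames %||% seq_len(n_frames(ens))
  res <- purrr::map(frames, function(f) {
    xyz <- frame_coords(ens, f)
    d2 <- cross_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    k <- arrayInd(which.min(d2), dim(d2))
    tibble::tibble(frame = f, d_min = sqrt(d2[k]),
                   atom_i = ia[k[1]], atom_j = ib[k[2]])
  })
  dplyr::bind_rows(res)
}

# squared cross-distance matrix between coordinate blocks (rows = atoms)
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
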