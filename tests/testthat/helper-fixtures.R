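# Shared fixture builders (all generated in code; no stored data).

dna_region <- function() region("dna", chains = c("A", "B"))
prot_region <- function() region("protein", chains = "P")

# standard small toy complex used across contact/network tests
std_toy_spec <- function(seed = 1L, node_cov = NULL,
                         persistence = c(0.9, 1.0, 0.8)) {
  toy_complex_spec(
    n_basepairs = 12, n_protein_res = 3,
    contacts = tibble::tibble(protein_res = c(1, 2, 3),
                              dna_level = c(3, 6, 9),
                              dna_part = c("base", "backbone", "base"),
                              persistence = persistence),
    node_cov = node_cov, seed = seed)
}

# hand-written minimal PDB content (three heavy atoms, one hydrogen variant)
three_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       3.000   3.500   4.250  1.00  0.00           C",
    "END"), path)
  path
}

# build a dynamic_network object directly from an edge list (unit tests of
# the graph algorithms independent of ensemble machinery)
mknet <- function(edges, ids = NULL) {
  ids <- ids %||% sort(unique(c(edges$from, edges$to)))
  nodes <- tibble::tibble(id = ids, chain_id = "X",
                          residue_index = seq_along(ids),
                          residue_name = "LYS", kind = "ca",
                          anchor = seq_along(ids),
                          atoms = as.list(seq_along(ids)))
  structure(list(nodes = structure(nodes,
                                   class = c("node_set", class(nodes))),
                 edges = tibble::as_tibble(edges),
                 persistence = 0.75, cutoff = 4.5),
            class = "dynamic_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ensemble with explicitly provided frames (topology from a one-frame ens)
with_frames <- function(ens, frames) {
  ensemble(ens$topology,
           array(unlist(frames), dim = c(n_atoms(ens), 3, length(frames))))
}

# rigid transform applied to every frame of an ensemble
transform_ensemble <- function(ens, R = diag(3), t = c(0, 0, 0)) {
  out <- ens$coords
  for (f in seq_len(n_frames(ens)))
    out[, , f] <- sweep(frame_coords(ens, f) %*% t(R), 2, -t)
  ensemble(ens$topology, out, ens$frame_period)
}
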