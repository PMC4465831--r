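# Node coarse-graining, cross-correlation, network construction, paths,
# communities.

test_that("node rules follow the coarse-graining conventions", {
  top <- dplyr::bind_rows(
    tibble::tibble(atom_name = c("N", "CA", "C", "O", "CB", "CG"),
                   residue_index = 1, residue_name = "LYS", chain_id = "P"),
    tibble::tibble(atom_name = c("N", "CA", "C", "O"),
                   residue_index = 2, residue_name = "GLY", chain_id = "P"),
    tibble::tibble(atom_name = c("N", "CA", "C", "O", "CB"),
                   residue_index = 3, residue_name = "ALA", chain_id = "P"),
    tibble::tibble(atom_name = c("N", "CA", "C", "O", "CB", "CG"),
                   residue_index = 4, residue_name = "PRO", chain_id = "P"),
    tibble::tibble(atom_name = c("P", "C5'", "C3'", "C1'", "N3", "C2"),
                   residue_index = 5, residue_name = "DA", chain_id = "A"),
    tibble::tibble(atom_name = c("P", "C3'", "C1'", "C4", "O2"),
                   residue_index = 6, residue_name = "DT", chain_id = "A"))
  ens <- ensemble(top, matrix(rnorm(nrow(top) * 3), nrow(top)))
  nodes <- network_nodes(ens)
  # LYS: ca + cb; GLY/ALA/PRO: single ca; nucleotides: backbone + base
  expect_equal(sum(nodes$kind == "ca"), 4L)
  expect_equal(sum(nodes$kind == "cb"), 1L)
  expect_equal(nodes$kind[nodes$residue_index == 3], "ca")
  expect_equal(nodes$kind[nodes$residue_index == 4], "ca")
  expect_equal(sort(nodes$kind[nodes$residue_index == 5]),
               c("dna_backbone", "dna_base"))
  # anchors: purine base node on N3, pyrimidine on C4, backbone on C3'
  a5 <- nodes[nodes$residue_index == 5 & nodes$kind == "dna_base", ]
  expect_equal(ens$topology$atom_name[a5$anchor], "N3")
  a6 <- nodes[nodes$residue_index == 6 & nodes$kind == "dna_base", ]
  expect_equal(ens$topology$atom_name[a6$anchor], "C4")
  bb <- nodes[nodes$residue_index == 5 & nodes$kind == "dna_backbone", ]
  expect_equal(ens$topology$atom_name[bb$anchor], "C3'")
  # represented sets partition each nucleotide into base vs backbone
  expect_setequal(ens$topology$atom_name[a5$atoms[[1]]], c("N3", "C2"))
  expect_setequal(ens$topology$atom_name[bb$atoms[[1]]],
                  c("P", "C5'", "C3'", "C1'"))
  # PRO single node represents the whole residue
  p4 <- nodes[nodes$residue_index == 4, ]
  expect_equal(length(p4$atoms[[1]]), 6L)
})

test_that("cross-correlation is the normalized displacement covariance", {
  top <- tibble::tibble(atom_name = "CA", residue_index = 1:3,
                        residue_name = "LYS", chain_id = "P")
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  # node 2 moves with node 1; node 3 moves exactly opposite
  d <- c(0.3, -0.2, 0.5, -0.4)
  frames <- lapply(d, function(dd)
    base + rbind(c(dd, 0, 0), c(dd, 0, 0), c(-dd, 0, 0)))
  ens <- with_frames(ensemble(top, base), frames)
  nodes <- network_nodes(ens)
  C <- cross_correlation(ens, nodes)
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  # zero-variance node is reported by name
  frames0 <- lapply(d, function(dd)
    base + rbind(c(dd, 0, 0), c(0, 0, 0), c(dd, dd, 0)))
  ens0 <- with_frames(ensemble(top, base), frames0)
  expect_error(cross_correlation(ens0, nodes), "zero-variance.*P2")
})

test_that("network edges follow persistence, exclusions and -log|C| weights", {
  # displacement noise well below every contact margin, so the edge set is
  # fully determined by the construction + designed persistence
  V <- diag(1e-4, 15)
  spec <- std_toy_spec(seed = 5, node_cov = V,
                       persistence = c(0.9, 1.0, 0.6))
  ens <- gen_toy_complex_ensemble(spec, 800)
  nodes <- network_nodes(ens)
  corr <- cross_correlation(ens, nodes)
  net <- build_network(ens, nodes, corr)
  expect_equal(net$edges$weight, -log(abs(net$edges$correlation)))
  expect_true(all(net$edges$weight >= 0))
  # construction oracle: expected node pairs from a brute-force scan of the
  # bound-state reference geometry, gated by the designed persistence
  ref <- toy_complex_reference(spec)
  xyz <- frame_coords(ref)
  atom_node <- integer(n_atoms(ref))
  for (i in seq_len(nrow(nodes))) atom_node[nodes$atoms[[i]]] <- i
  cts <- spec$contacts
  cg <- which(grepl("CG", ref$topology$atom_name))
  gate <- setNames(cts$persistence[match(
    ref$topology$residue_index[cg], cts$protein_res)], cg)
  want <- character()
  used <- which(atom_node > 0)
  prs <- oracle_contact_pairs(xyz, used, used, 4.5)
  for (r in seq_len(nrow(prs))) {
    i <- prs[r, 1]; j <- prs[r, 2]
    m <- atom_node[i]; n2 <- atom_node[j]
    if (m == n2 || i >= j) next
    p_eff <- 1
    if (i %in% cg) p_eff <- p_eff * gate[as.character(i)]
    if (j %in% cg) p_eff <- p_eff * gate[as.character(j)]
    if (p_eff <= 0.75) next
    a <- nodes[m, ]; b <- nodes[n2, ]
    if (a$kind %in% c("ca", "cb") && b$kind %in% c("ca", "cb") &&
        a$residue_index == b$residue_index) next
    if (a$kind == "dna_backbone" && b$kind == "dna_backbone" &&
        a$chain_id == b$chain_id &&
        abs(a$residue_index - b$residue_index) == 1) next
    if (a$kind == "ca" && b$kind == "ca" &&
        a$chain_id == b$chain_id &&
        abs(a$residue_index - b$residue_index) == 1) next
    key <- paste(sort(c(nodes$id[m], nodes$id[n2])), collapse = "|")
    want <- c(want, key)
  }
  got <- paste(pmin(net$edges$from, net$edges$to),
               pmax(net$edges$from, net$edges$to), sep = "|")
  expect_setequal(got, unique(want))
  # the persistence-0.6 designated contact must not create an edge
  expect_false(any(grepl("P3:cb", got) & grepl("A9", got)))
  # edge set invariant under frame-order permutation
  set.seed(1)
  perm <- sample(n_frames(ens))
  net_p <- build_network(subset_frames(ens, perm), nodes, corr)
  got_p <- paste(pmin(net_p$edges$from, net_p$edges$to),
                 pmax(net_p$edges$from, net_p$edges$to), sep = "|")
  expect_setequal(got_p, got)
})

test_that("shortest paths match exhaustive enumeration with tie-breaks", {
  edges <- tibble::tibble(
    from = c("a", "a", "b", "b", "c", "d", "a"),
    to   = c("b", "c", "c", "d", "e", "e", "e"),
    weight = c(1, 2.5, 1, 2, 1.2, 0.4, 4.2))
  net <- mknet(edges)
  sp <- shortest_path(net, "a", "e")
  paths <- oracle_all_paths(edges, "a", "e")
  lens <- vapply(paths, `[[`, 0, "length")
  expect_equal(sp$length, min(lens))
  expect_equal(sp$path, paths[[which.min(lens)]]$path)
  # igraph cross-check of the distance
  g <- as_igraph(net)
  expect_equal(sp$length,
               as.numeric(igraph::distances(g, "a", "e")))
  # single-edge graph
  net1 <- mknet(tibble::tibble(from = "x", to = "y", weight = 0.7))
  expect_equal(shortest_path(net1, "x", "y")$path, c("x", "y"))
  # all-zero weights: length 0, lexicographic-first path returned
  netz <- mknet(tibble::tibble(from = c("a", "a", "b", "c"),
                               to = c("b", "c", "d", "d"),
                               weight = 0))
  spz <- shortest_path(netz, "a", "d")
  expect_equal(spz$length, 0)
  expect_equal(spz$path, c("a", "b", "d"))
  # disconnected: explicit no-path result
  net2 <- mknet(tibble::tibble(from = "x", to = "y", weight = 1),
                ids = c("x", "y", "z"))
  res <- shortest_path(net2, "x", "z")
  expect_false(res$found)
  expect_equal(res$length, Inf)
  # path length additivity
  wsum <- sum(edges$weight[match(
    paste(head(sp$path, -1), tail(sp$path, -1)),
    paste(edges$from, edges$to))], na.rm = TRUE)
  expect_equal(sp$length, wsum, tolerance = 1e-12)
})

test_that("suboptimal paths match exhaustive enumeration", {
  set.seed(42)
  ids <- letters[1:6]
  full <- expand.grid(i = 1:6, j = 1:6)
  full <- full[full$i < full$j, ]
  keep <- full[runif(nrow(full)) < 0.7, ]
  edges <- tibble::tibble(from = ids[keep$i], to = ids[keep$j],
                          weight = round(runif(nrow(keep), 0.2, 2), 3))
  net <- mknet(edges, ids)
  opt <- shortest_path(net, "a", "f")$length
  for (off in c(0, 1.5)) {
    sub <- suboptimal_paths(net, "a", "f", offset = off)
    paths <- oracle_all_paths(edges, "a", "f")
    lens <- vapply(paths, `[[`, 0, "length")
    want <- paths[lens <= opt + off + 1e-12]
    expect_equal(nrow(sub$paths), length(want))
    expect_setequal(
      vapply(sub$paths$path, paste, "", collapse = ">"),
      vapply(want, function(p) paste(p$path, collapse = ">"), ""))
    expect_true(all(sub$paths$length <= opt + off + 1e-12))
    expect_gte(min(sub$paths$length), opt)
  }
  # per-edge traversal counts total the per-path edge counts
  sub <- suboptimal_paths(net, "a", "f", offset = 1.5)
  expect_equal(sum(sub$edge_counts$n_paths),
               sum(lengths(sub$paths$path) - 1))
  # chain graph: exactly one path at any offset
  chain <- mknet(tibble::tibble(from = c("a", "b", "c"),
                                to = c("b", "c", "d"), weight = 1))
  expect_equal(nrow(suboptimal_paths(chain, "a", "d", offset = 50)$paths),
               1L)
  # explosion guard on a dense graph with many near-optimal paths
  dense <- mknet(tibble::tibble(from = ids[full$i], to = ids[full$j],
                                weight = 1))
  expect_error(suboptimal_paths(dense, "a", "f", offset = 10,
                                max_paths = 2L),
               "reduce the offset")
})

test_that("communities split cliques at maximal modularity", {
  clique_edges <- function(ids) {
    eg <- expand.grid(i = seq_along(ids), j = seq_along(ids))
    eg <- eg[eg$i < eg$j, ]
    tibble::tibble(from = ids[eg$i], to = ids[eg$j], weight = 1)
  }
  c1 <- letters[1:5]; c2 <- letters[6:10]
  edges <- dplyr::bind_rows(clique_edges(c1), clique_edges(c2),
                            tibble::tibble(from = "e", to = "f",
                                           weight = 1))
  net <- mknet(edges)
  com <- communities(net)
  expect_equal(com$n_communities, 2L)
  expect_equal(length(unique(com$membership[c1])), 1L)
  expect_equal(length(unique(com$membership[c2])), 1L)
  expect_true(com$membership["a"] != com$membership["j"])
  # modularity matches the brute-force best 2-partition
  orc <- oracle_best_2partition(edges, c(c1, c2))
  expect_equal(com$modularity, orc$modularity, tolerance = 1e-12)
  # returned partition beats the all-in-one partition
  expect_gte(com$modularity, 0)
  # disconnected components end up in different communities
  net2 <- mknet(dplyr::bind_rows(clique_edges(c("p", "q", "r")),
                                 clique_edges(c("x", "y", "z"))))
  com2 <- communities(net2)
  expect_true(com2$membership["p"] != com2$membership["x"])
})

test_that("a designed high-correlation chain carries the optimal path", {
  # protein 1 and 3 bind duplex levels 3 and 9; the intervening levels are
  # strongly co-displaced with them, so the cheap -log|C| route runs along
  # the DNA between the two binding sites
  nu <- 3 + 12
  V <- diag(0.0025, nu)
  chain <- c(1, 3, 3 + (3:9))   # p1, p3, bp3..bp9
  for (i in chain) for (j in chain)
    if (i != j) V[i, j] <- 0.9 * 0.0025
  spec <- std_toy_spec(seed = 19, node_cov = V,
                       persistence = c(1, 1, 1))
  ens <- gen_toy_complex_ensemble(spec, 1500)
  nodes <- network_nodes(ens)
  corr <- cross_correlation(ens, nodes)
  net <- build_network(ens, nodes, corr)
  sp <- shortest_path(net, "P1:cb", "P3:cb")
  expect_true(sp$found)
  # every intermediate node is DNA, and the chain levels 3..9 are crossed
  mid <- sp$path[-c(1, length(sp$path))]
  expect_true(all(grepl("^[AB]", mid)))
  res <- as.integer(sub("^[AB]([0-9]+):.*$", "\\1", mid))
  lvl <- ifelse(res <= 12, res, 25 - res)
  expect_true(all(4:8 %in% lvl | rev(4:8) %in% lvl))
  expect_true(all(lvl >= 3 & lvl <= 9))
})
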