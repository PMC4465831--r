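# Dynamic-network analysis: coarse-grained nodes, positional
# cross-correlation, persistence-filtered contact edges weighted
# -log|C|, shortest/suboptimal communication paths, communities.

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL", "HSD", "HSE", "HSP")
SINGLE_NODE_RES <- c("GLY", "ALA", "PRO")
PROT_BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Coarse-grained network nodes of a protein-DNA complex
#'
#' Protein residues contribute a CA node (anchored on CA, representing the
#' backbone atoms) and a CB node (anchor CB, representing the side chain)
#' except glycine, alanine and proline, which contribute a single CA node
#' representing the whole residue. Each nucleotide contributes a backbone
#' node (anchor C3', representing the sugar-phosphate atoms) and a base node
#' (anchor N3 for purines, C4 for pyrimidines, representing the base atoms).
#'
#' @param ens An [ensemble()].
#' @param sel Optional [region()] restricting the atoms considered.
#' @return A `node_set` tibble: `id`, `chain_id`, `residue_index`,
#'   `residue_name`, `kind` (`ca`, `cb`, `dna_backbone`, `dna_base`),
#'   `anchor` (atom index), `atoms` (list of atom indices).
#' @export
network_nodes <- function(ens, sel = NULL) {
  top <- ens$topology
  idx <- if (is.null(sel)) seq_len(nrow(top)) else resolve_region(ens, sel)
  idx <- idx[top$is_heavy[idx]]
  sub <- top[idx, ]
  key <- paste(sub$chain_id, sub$residue_index)
  rows <- list()
  for (kk in unique(key)) {
    a <- idx[key == kk]
    rn <- top$residue_name[a[1]]
    ch <- top$chain_id[a[1]]; ri <- top$residue_index[a[1]]
    nm <- top$atom_name[a]
    is_nt <- "C3'" %in% nm
    if (is_nt) {
      cls <- dna_atom_class(nm)
      bb <- a[cls == "backbone"]; bs <- a[cls == "base"]
      anchor_bb <- bb[match("C3'", nm[cls == "backbone"])]
      anchor_bs <- bs[which(nm[cls == "base"] %in% c("N3", "C4"))[1]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = paste0(ch, ri, ":bb"), chain_id = ch, residue_index = ri,
        residue_name = rn, kind = "dna_backbone", anchor = anchor_bb,
        atoms = list(bb))
      if (length(bs) > 0 && !is.na(anchor_bs))
        rows[[length(rows) + 1]] <- tibble::tibble(
          id = paste0(ch, ri, ":base"), chain_id = ch, residue_index = ri,
          residue_name = rn, kind = "dna_base", anchor = anchor_bs,
          atoms = list(bs))
    } else if ("CA" %in% nm) {
      anchor_ca <- a[match("CA", nm)]
      if (rn %in% SINGLE_NODE_RES || !"CB" %in% nm) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          id = paste0(ch, ri, ":ca"), chain_id = ch, residue_index = ri,
          residue_name = rn, kind = "ca", anchor = anchor_ca,
          atoms = list(a))
      } else {
        bbm <- nm %in% PROT_BACKBONE
        rows[[length(rows) + 1]] <- tibble::tibble(
          id = paste0(ch, ri, ":ca"), chain_id = ch, residue_index = ri,
          residue_name = rn, kind = "ca", anchor = anchor_ca,
          atoms = list(a[bbm]))
        rows[[length(rows) + 1]] <- tibble::tibble(
          id = paste0(ch, ri, ":cb"), chain_id = ch, residue_index = ri,
          residue_name = rn, kind = "cb", anchor = a[match("CB", nm)],
          atoms = list(a[!bbm]))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("node_set", class(out)))
}

#' Positional cross-correlation matrix between node anchors
#'
#' \eqn{C_{mn} = <\Delta r_m . \Delta r_n> / \sqrt{<\Delta r_m^2><\Delta r_n^2>}}
#' where \eqn{\Delta r} is the anchor-atom displacement from its ensemble
#' mean. The ensemble must already be superposed on the caller's chosen fit
#' selection; correlations are frame-order free.
#'
#' @param ens A superposed [ensemble()] (>= 2 frames).
#' @param nodes A `node_set` from [network_nodes()].
#' @return A symmetric node x node correlation matrix (unit diagonal),
#'   dimnames = node ids.
#' @export
cross_correlation <- function(ens, nodes) {
  nf <- n_frames(ens)
  if (nf < 2L) stop("cross-correlation needs >= 2 frames")
  anchors <- nodes$anchor
  nn <- length(anchors)
  # anchor displacement components, frames x (3 * nodes)
  X <- ens$coords[anchors, , , drop = FALSE]        # nodes x 3 x frames
  mu <- apply(X, c(1, 2), mean)
  D <- sweep(X, c(1, 2), mu)
  flat <- matrix(aperm(D, c(3, 1, 2)), nrow = nf)   # frames x (nodes*3)
  dot <- matrix(0, nn, nn)
  for (c3 in 1:3) {
    block <- flat[, (c3 - 1) * nn + seq_len(nn), drop = FALSE]
    dot <- dot + crossprod(block) / nf
  }
  msd <- diag(dot)
  if (any(msd < 1e-14)) {
    bad <- nodes$id[which(msd < 1e-14)]
    stop("zero-variance node(s): ", paste(bad, collapse = ", "))
  }
  C <- dot / sqrt(outer(msd, msd))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- list(nodes$id, nodes$id)
  C
}

#' Build the dynamic network
#'
#' Nodes are connected when at least one atom-atom contact between their
#' represented atom sets (pair distance <= `cutoff`) is present in more than
#' `persistence` of the frames. Excluded edges: within the same protein
#' residue (CA-CB), between sequence-adjacent protein CA nodes of the same
#' chain, and between sequence-adjacent DNA backbone nodes of the same
#' strand. Edge weights are \eqn{d_{mn} = -log|C_{mn}|}; edges whose
#' correlation is exactly 0 are dropped with a message.
#'
#' @param ens An [ensemble()].
#' @param nodes A `node_set`.
#' @param corr Correlation matrix from [cross_correlation()] (dimnames must
#'   match the node ids).
#' @param persistence Contact persistence threshold, strict (default 0.75).
#' @param cutoff Contact distance cutoff, A (default 4.5).
#' @return A `dynamic_network`: list with `nodes` and an `edges` tibble
#'   (`from`, `to`, `weight`, `correlation`, `occupancy`).
#' @export
build_network <- function(ens, nodes, corr, persistence = 0.75,
                          cutoff = 4.5) {
  if (!all(nodes$id %in% rownames(corr)))
    stop("correlation matrix does not cover all node ids")
  atom_node <- integer(n_atoms(ens))
  for (i in seq_len(nrow(nodes))) atom_node[nodes$atoms[[i]]] <- i
  used <- which(atom_node > 0L)
  nf <- n_frames(ens)
  counts <- matrix(0L, length(used), length(used))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)[used, , drop = FALSE]
    counts <- counts + (cross_dist2(xyz, xyz) <= cutoff^2)
  }
  occ <- counts / nf
  keep <- which(occ > persistence, arr.ind = TRUE)
  keep <- keep[keep[, 1] < keep[, 2], , drop = FALSE]
  m <- atom_node[used[keep[, 1]]]
  n2 <- atom_node[used[keep[, 2]]]
  pocc <- occ[keep]
  diff_node <- m != n2
  lo <- pmin(m, n2)[diff_node]
  hi <- pmax(m, n2)[diff_node]
  df <- tibble::tibble(m = lo, n = hi, occupancy = pocc[diff_node]) |>
    dplyr::group_by(.data$m, .data$n) |>
    dplyr::summarise(occupancy = max(.data$occupancy), .groups = "drop")
  if (nrow(df) > 0) {
    ex <- vapply(seq_len(nrow(df)), function(i) {
      a <- nodes[df$m[i], ]; b <- nodes[df$n[i], ]
      same_prot_res <- a$kind %in% c("ca", "cb") &&
        b$kind %in% c("ca", "cb") &&
        a$chain_id == b$chain_id && a$residue_index == b$residue_index
      adj_ca <- a$kind == "ca" && b$kind == "ca" &&
        a$chain_id == b$chain_id &&
        abs(a$residue_index - b$residue_index) == 1
      adj_bb <- a$kind == "dna_backbone" && b$kind == "dna_backbone" &&
        a$chain_id == b$chain_id &&
        abs(a$residue_index - b$residue_index) == 1
      same_prot_res || adj_ca || adj_bb
    }, logical(1))
    df <- df[!ex, , drop = FALSE]
  }
  cvals <- corr[cbind(nodes$id[df$m], nodes$id[df$n])]
  drop0 <- abs(cvals) < 1e-300
  if (any(drop0))
    message(sum(drop0), " edge(s) dropped: |C| = 0 gives infinite distance")
  edges <- tibble::tibble(from = nodes$id[df$m], to = nodes$id[df$n],
                          correlation = cvals,
                          weight = -log(pmin(abs(cvals), 1)),
                          occupancy = df$occupancy)[!drop0, ]
  structure(list(nodes = nodes, edges = edges,
                 persistence = persistence, cutoff = cutoff),
            class = "dynamic_network")
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat("<dynamic_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (contact persistence > ", x$persistence, ", cutoff ",
      x$cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Convert a dynamic network to an igraph graph
#' @param net A `dynamic_network`.
#' @return An igraph object with edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges[, c("from", "to", "weight")]),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id, kind = net$nodes$kind))
}

# adjacency list representation: for each node, tibble of (neighbor, weight)
edge_adjacency <- function(net) {
  ids <- sort(net$nodes$id)
  adj <- setNames(vector("list", length(ids)), ids)
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- rbind(adj[[e$from[i]]],
                              data.frame(to = e$to[i], w = e$weight[i]))
    adj[[e$to[i]]] <- rbind(adj[[e$to[i]]],
                            data.frame(to = e$from[i], w = e$weight[i]))
  }
  adj
}

# single-source shortest distances (Dijkstra; small graphs, plain R)
dijkstra_dist <- function(net, source) {
  ids <- sort(net$nodes$id)
  adj <- edge_adjacency(net)
  dist <- setNames(rep(Inf, length(ids)), ids)
  done <- setNames(rep(FALSE, length(ids)), ids)
  dist[source] <- 0
  repeat {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0L) break
    u <- names(open)[order(dist[open], names(open))][1]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) for (r in seq_len(nrow(nb))) {
      v <- nb$to[r]; nd <- dist[u] + nb$w[r]
      if (nd < dist[v]) dist[v] <- nd
    }
  }
  dist
}

# lexicographically-first simple path of total weight <= limit, found by
# depth-first search with the remaining-distance lower bound as pruning
lex_first_path <- function(adj, source, target, to_target, limit) {
  found <- NULL
  dfs <- function(node, acc, len, visited) {
    if (!is.null(found)) return(invisible())
    if (node == target) { found <<- acc; return(invisible()) }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    nb <- nb[order(nb$to), , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      v <- nb$to[r]
      if (v %in% visited) next
      nl <- len + nb$w[r]
      if (nl + to_target[v] > limit) next
      dfs(v, c(acc, v), nl, c(visited, v))
      if (!is.null(found)) return(invisible())
    }
  }
  dfs(source, source, 0, source)
  found
}

#' Shortest communication path
#'
#' Minimal total -log|C| weight path between two nodes; ties are broken
#' deterministically toward the lexicographically smallest node sequence.
#'
#' @param net A `dynamic_network`.
#' @param source,target Node ids.
#' @return A list with `path` (character vector of node ids, `NULL` when
#'   disconnected), `length` (total weight, `Inf` when disconnected) and
#'   `found`.
#' @export
shortest_path <- function(net, source, target) {
  stopifnot(source %in% net$nodes$id, target %in% net$nodes$id)
  to_target <- dijkstra_dist(net, target)
  opt <- to_target[source]
  if (is.infinite(opt))
    return(list(path = NULL, length = Inf, found = FALSE))
  path <- lex_first_path(edge_adjacency(net), source, target, to_target,
                         opt + 1e-12)
  list(path = unname(path), length = unname(opt), found = TRUE)
}

#' Suboptimal communication paths
#'
#' All simple paths whose total weight is within `offset` of the optimum,
#' enumerated by depth-first search with admissible pruning (remaining
#' single-source shortest distances to the target as lower bound). Also
#' reports per-edge traversal counts (how many of the returned paths cross
#' each edge).
#'
#' @param net A `dynamic_network`.
#' @param source,target Node ids (a shortest path must exist).
#' @param offset Allowed excess over the optimal length (default 5, in the
#'   dimensionless -log|C| units).
#' @param max_paths Explosion guard (default 10000).
#' @return A list with `paths` (tibble: `path` list column, `length`),
#'   `optimal` (the optimum length) and `edge_counts` (tibble `from`, `to`,
#'   `n_paths`).
#' @export
suboptimal_paths <- function(net, source, target, offset = 5,
                             max_paths = 10000L) {
  sp <- shortest_path(net, source, target)
  if (!sp$found) stop("no path between ", source, " and ", target)
  limit <- sp$length + offset + 1e-12
  to_target <- dijkstra_dist(net, target)
  adj <- edge_adjacency(net)
  paths <- list(); lens <- numeric()
  dfs <- function(node, acc, visited) {
    if (length(paths) >= max_paths)
      stop("more than ", max_paths,
           " suboptimal paths; reduce the offset or raise max_paths")
    if (node == target) {
      paths[[length(paths) + 1]] <<- acc
      lens[length(lens) + 1] <<- attr(acc, "len")
      return(invisible())
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    nb <- nb[order(nb$to), , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      v <- nb$to[r]
      if (v %in% visited) next
      nl <- attr(acc, "len") + nb$w[r]
      if (nl + to_target[v] > limit) next
      nacc <- c(acc, v); attr(nacc, "len") <- nl
      dfs(v, nacc, c(visited, v))
    }
  }
  acc0 <- source; attr(acc0, "len") <- 0
  dfs(source, acc0, source)
  ord <- order(lens)
  paths <- paths[ord]; lens <- lens[ord]
  ec <- list()
  for (p in paths) for (i in seq_len(length(p) - 1)) {
    a <- min(p[i], p[i + 1]); b <- max(p[i], p[i + 1])
    k <- paste(a, b, sep = "\r")
    ec[[k]] <- (ec[[k]] %||% 0L) + 1L
  }
  ekeys <- names(ec)
  edge_counts <- tibble::tibble(
    from = vapply(strsplit(ekeys, "\r"), `[`, "", 1),
    to = vapply(strsplit(ekeys, "\r"), `[`, "", 2),
    n_paths = unlist(ec, use.names = FALSE))
  list(paths = tibble::tibble(path = purrr::map(paths, as.character),
                              length = lens),
       optimal = sp$length, edge_counts = edge_counts)
}

#' Network communities by Girvan-Newman edge betweenness
#'
#' Hierarchical edge-betweenness decomposition (edge weights treated as
#' distances) cut at the partition maximising Newman-Girvan modularity
#' (computed on the unweighted contact topology, so that small -log|C|
#' distances do not count as weak ties). Connected components are handled
#' independently by the decomposition.
#'
#' @param net A `dynamic_network`.
#' @return A list with `membership` (named integer vector),
#'   `modularity` (of the returned partition) and `n_communities`.
#' @export
communities <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0L) {
    mem <- seq_len(igraph::vcount(g))
    names(mem) <- igraph::V(g)$name
    return(list(membership = mem, modularity = 0,
                n_communities = length(mem)))
  }
  eb <- suppressWarnings(igraph::cluster_edge_betweenness(
    g, weights = igraph::E(g)$weight, modularity = FALSE,
    membership = FALSE, directed = FALSE))
  best <- NULL; best_q <- -Inf
  for (k in seq_len(igraph::vcount(g))) {
    memk <- tryCatch(suppressWarnings(igraph::cut_at(eb, no = k)),
                     error = function(e) NULL)
    if (is.null(memk) || anyNA(memk)) next
    q <- igraph::modularity(g, memk)
    if (q > best_q + 1e-12) { best_q <- q; best <- memk }
  }
  mem <- setNames(as.integer(best), igraph::V(g)$name)
  list(membership = mem, modularity = best_q,
       n_communities = length(unique(mem)))
}
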