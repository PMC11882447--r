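# Build a toy interaction graph directly from node/edge tables (bypassing
# structure/hbond machinery) for unit tests of the counting rules.
toy_graph <- function(nodes, edges) {
  nodes$helix <- if (is.null(nodes$helix)) NA_integer_ else nodes$helix
  nodes$class <- if (is.null(nodes$class)) "none" else nodes$class
  nodes$bw <- if (is.null(nodes$bw)) NA_character_ else nodes$bw
  if (nrow(edges)) {
    ka <- nodes$kind[match(edges$from, nodes$name)]
    kb <- nodes$kind[match(edges$to, nodes$name)]
    edges$type <- ifelse(ka == "water" & kb == "water", "water-water",
                         ifelse(ka == "water" | kb == "water",
                                "res-water", "res-res"))
    edges$multiplicity <- 1L
  } else {
    edges <- data.frame(from = character(), to = character(),
                        type = character(), multiplicity = integer())
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

# Independent brute-force reference for the static-switchable edge count:
# exhaustive enumeration of static -> water (<= 2) -> switchable paths over
# the adjacency matrix, collecting every edge on any such path.
oracle_static_switchable <- function(g) {
  vn <- igraph::V(g)$name
  kind <- igraph::V(g)$kind
  cls <- igraph::V(g)$class
  n <- length(vn)
  if (n == 0L) return(0L)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  ek <- function(i, j) paste(sort(c(vn[i], vn[j])), collapse = "~")
  edges <- character()
  statics <- which(kind == "residue" & cls == "static")
  switchs <- which(kind == "residue" & cls == "switchable")
  waters <- which(kind == "water")
  for (s in statics) for (t in switchs) for (w in waters) {
    if (adj[s, w] && adj[w, t])
      edges <- c(edges, ek(s, w), ek(w, t))
    for (w2 in waters) {
      if (w2 == w) next
      if (adj[s, w] && adj[w, w2] && adj[w2, t])
        edges <- c(edges, ek(s, w), ek(w, w2), ek(w2, t))
    }
  }
  length(unique(edges))
}

# Random small graph over residues (random classes) and waters.
random_toy_graph <- function(seed, n_res = 6L, n_wat = 4L, p_edge = 0.3) {
  set.seed(seed)
  nodes <- data.frame(
    name = c(paste0("R", seq_len(n_res)), paste0("W", seq_len(n_wat))),
    kind = c(rep("residue", n_res), rep("water", n_wat)),
    class = c(sample(c("static", "switchable", "none"), n_res, TRUE),
              rep("none", n_wat)),
    helix = c(sample(1:7, n_res, TRUE), rep(NA_integer_, n_wat)),
    stringsAsFactors = FALSE)
  pairs <- t(utils::combn(nodes$name, 2))
  sel <- stats::runif(nrow(pairs)) < p_edge
  toy_graph(nodes, data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
                              stringsAsFactors = FALSE))
}
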