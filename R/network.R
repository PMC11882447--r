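#' Cluster ensemble water positions into consensus solvent nodes
#'
#' Pools the water oxygen positions of all models in an ensemble and applies
#' complete-linkage agglomerative clustering, cutting the tree at `radius`.
#' Clusters supported by fewer than `min_support` distinct models are
#' discarded. Cluster centroids define the consensus solvent nodes used for
#' network analysis of a model ensemble.
#'
#' @param ens an `ensemble` whose models contain waters.
#' @param radius clustering cut height in Angstrom (default 1.0).
#' @param min_support minimum number of distinct contributing models
#'   (default 2).
#' @return data.frame of consensus waters: centroid `x`,`y`,`z`, `support`
#'   (fraction of models contributing), `n_members`, and a list-column
#'   `members` of `(model_id, water residue key)` pairs.
#' @export
cluster_waters <- function(ens, radius = 1.0, min_support = 2L) {
  if (!inherits(ens, "ensemble")) stop("expected an ensemble")
  if (radius <= 0) stop("radius must be positive")
  rows <- list()
  for (m in ens$models) {
    a <- m$atoms
    w <- a[a$kind == "water" & a$element == "O", , drop = FALSE]
    if (!nrow(w)) next
    rows[[length(rows) + 1L]] <- data.frame(
      model_id = m$model_id,
      wkey = paste(w$chain, w$resnum, w$icode, sep = "|"),
      x = w$x, y = w$y, z = w$z, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("ensemble contains no waters")
  all <- do.call(rbind, rows)
  n_models <- length(ens$models)
  if (nrow(all) == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(all[, c("x", "y", "z")]), method = "complete")
    cl <- stats::cutree(hc, h = radius)
  }
  out <- lapply(sort(unique(cl)), function(k) {
    mem <- all[cl == k, , drop = FALSE]
    nsup <- length(unique(mem$model_id))
    if (nsup < min_support) return(NULL)
    data.frame(x = mean(mem$x), y = mean(mem$y), z = mean(mem$z),
               support = nsup / n_models, n_members = nrow(mem),
               members = I(list(mem[, c("model_id", "wkey")])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out))
    out <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      support = numeric(), n_members = integer(),
                      members = I(list()))
  rownames(out) <- NULL
  out
}

#' Replace a model's waters with consensus solvent nodes
#'
#' Builds the input model for ensemble-level network analysis: the protein
#' of `model` plus one `HOH` oxygen per consensus water.
#'
#' @param model a [structure_model] (typically the lowest-energy model).
#' @param consensus consensus waters from [cluster_waters].
#' @return A [structure_model].
#' @export
consensus_model <- function(model, consensus) {
  a <- model$atoms[model$atoms$kind != "water", , drop = FALSE]
  if (nrow(consensus)) {
    maxser <- if (nrow(a)) max(a$serial) else 0L
    w <- data.frame(
      serial = maxser + seq_len(nrow(consensus)),
      name = "O", altloc = "", resname = "HOH", chain = "W",
      resnum = seq_len(nrow(consensus)), icode = "",
      x = consensus$x, y = consensus$y, z = consensus$z,
      occ = 1, bfac = 0, element = "O", record = "HETATM",
      kind = "water", stringsAsFactors = FALSE)
    a <- rbind(a, w[, names(a)])
  }
  structure_model(a, model_id = paste0(model$model_id, "+consensus"),
                  energy = model$energy, source = model$source)
}

#' Build the residue/water interaction graph
#'
#' Converts atom-level hydrogen bonds into a node-level graph: one node per
#' residue owning at least one bonded polar atom and one node per water.
#' Multiple atom-pair bonds between the same two nodes collapse to one edge
#' with a `multiplicity` attribute. Residue nodes carry `helix` and `class`
#' (static/switchable/none) from the annotation.
#'
#' @param model the [structure_model] the bonds were computed on.
#' @param hbonds bond table from [find_hbonds].
#' @param annotation a `bw_annotation` (may be `NULL`; nodes then carry no
#'   helix/class labels).
#' @return An [igraph::igraph] with vertex attributes `kind`
#'   (`residue`/`water`), `helix`, `class`, `bw`, and edge attributes `type`
#'   (`res-res`/`res-water`/`water-water`) and `multiplicity`.
#' @export
build_graph <- function(model, hbonds, annotation = NULL) {
  node_id <- function(kind, rkey) ifelse(kind == "water",
                                         paste0("W:", rkey), paste0("R:", rkey))
  if (nrow(hbonds)) {
    va <- node_id(hbonds$kind_a, hbonds$rkey_a)
    vb <- node_id(hbonds$kind_b, hbonds$rkey_b)
    etype <- ifelse(hbonds$kind_a == "water" & hbonds$kind_b == "water",
                    "water-water",
                    ifelse(hbonds$kind_a == "water" | hbonds$kind_b == "water",
                           "res-water", "res-res"))
    ekey <- ifelse(va < vb, paste(va, vb), paste(vb, va))
    agg <- stats::aggregate(list(multiplicity = ekey), by = list(ekey = ekey),
                            FUN = length)
    first <- !duplicated(ekey)
    edf <- data.frame(ekey = ekey[first], va = va[first], vb = vb[first],
                      type = etype[first], stringsAsFactors = FALSE)
    edf$multiplicity <- agg$multiplicity[match(edf$ekey, agg$ekey)]
    verts <- unique(c(edf$va, edf$vb))
  } else {
    edf <- data.frame(va = character(), vb = character(), type = character(),
                      multiplicity = integer())
    verts <- character()
  }
  vdf <- data.frame(name = verts, stringsAsFactors = FALSE)
  vdf$kind <- ifelse(startsWith(vdf$name, "W:"), "water", "residue")
  vdf$helix <- rep(NA_integer_, nrow(vdf))
  vdf$class <- rep("none", nrow(vdf))
  vdf$bw <- rep(NA_character_, nrow(vdf))
  if (!is.null(annotation) && nrow(vdf)) {
    parts <- strsplit(sub("^[RW]:", "", vdf$name), "\\|")
    for (i in seq_len(nrow(vdf))) {
      if (vdf$kind[i] != "residue") next
      hit <- bw_lookup(annotation, parts[[i]][1], as.integer(parts[[i]][2]))
      if (!is.null(hit)) {
        vdf$helix[i] <- hit$helix
        vdf$class[i] <- hit$class
        vdf$bw[i] <- hit$bw
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    d = edf[, c("va", "vb", "type", "multiplicity"), drop = FALSE],
    directed = FALSE, vertices = vdf)
  g
}

# edge endpoint names as a 2-column character matrix
.edge_ends <- function(g) {
  if (igraph::ecount(g) == 0L)
    return(matrix(character(), ncol = 2))
  igraph::as_edgelist(g, names = TRUE)
}

#' Count all water-mediated hydrogen bonds
#'
#' The total number of graph edges with at least one water endpoint
#' (residue-water plus water-water edges).
#'
#' @param g graph from [build_graph].
#' @return Integer count.
#' @export
count_water_mediated_total <- function(g) {
  if (igraph::ecount(g) == 0L) return(0L)
  sum(igraph::E(g)$type %in% c("res-water", "water-water"))
}

# For each water vertex: names of adjacent static / switchable residue nodes.
.water_adjacency <- function(g) {
  vn <- igraph::V(g)$name
  kind <- igraph::V(g)$kind
  cls <- igraph::V(g)$class
  ends <- .edge_ends(g)
  waters <- vn[kind == "water"]
  adj <- setNames(vector("list", length(waters)), waters)
  for (w in waters) adj[[w]] <- list(static = character(),
                                     switchable = character(),
                                     water = character())
  if (!nrow(ends)) return(adj)
  cls_of <- setNames(cls, vn)
  kind_of <- setNames(kind, vn)
  for (k in seq_len(nrow(ends))) {
    a <- ends[k, 1]; b <- ends[k, 2]
    for (pair in list(c(a, b), c(b, a))) {
      w <- pair[1]; o <- pair[2]
      if (kind_of[[w]] != "water") next
      if (kind_of[[o]] == "water") {
        adj[[w]]$water <- c(adj[[w]]$water, o)
      } else if (cls_of[[o]] == "static") {
        adj[[w]]$static <- c(adj[[w]]$static, o)
      } else if (cls_of[[o]] == "switchable") {
        adj[[w]]$switchable <- c(adj[[w]]$switchable, o)
      }
    }
  }
  adj
}

.ekey <- function(a, b) ifelse(a < b, paste(a, b, sep = "~"), paste(b, a, sep = "~"))

#' Count static-switchable water-mediated interactions
#'
#' A water mediates a static-switchable interaction when it bonds a residue
#' on a static helix and a residue on a switchable helix, either directly
#' (one water) or through a single water-water hop (two waters). Every
#' residue-water and water-water edge lying on at least one such mediating
#' path is counted once. One planted single-water bridge therefore
#' contributes 2 and one two-water chain contributes 3.
#'
#' @param g graph from [build_graph] with residue classes assigned.
#' @return Integer count of distinct mediating edges.
#' @export
count_static_switchable <- function(g) {
  adj <- .water_adjacency(g)
  if (!length(adj)) return(0L)
  med <- character()
  for (w in names(adj)) {
    s <- adj[[w]]$static; t <- adj[[w]]$switchable
    if (length(s) && length(t))
      med <- c(med, .ekey(s, w), .ekey(w, t))
    for (w2 in adj[[w]]$water) {
      t2 <- adj[[w2]]$switchable
      if (length(s) && length(t2))
        med <- c(med, .ekey(s, w), .ekey(w, w2), .ekey(w2, t2))
      s2 <- adj[[w2]]$static
      if (length(t) && length(s2))
        med <- c(med, .ekey(s2, w2), .ekey(w2, w), .ekey(w, t))
    }
  }
  length(unique(med))
}

#' Interhelical polar-contact matrix
#'
#' A symmetric 7x7 matrix whose entry (i, j) is the number of direct
#' residue-residue hydrogen-bond edges between helices i and j plus the
#' number of distinct residue pairs bridged by one or two waters between
#' helices i and j. Diagonal (intra-helix) contacts are not counted.
#'
#' @param g graph from [build_graph] with helix ids assigned.
#' @param n_helices matrix dimension (default 7).
#' @return Integer matrix `n_helices x n_helices`.
#' @export
interface_breakdown <- function(g, n_helices = 7L) {
  m <- matrix(0L, n_helices, n_helices,
              dimnames = list(seq_len(n_helices), seq_len(n_helices)))
  vn <- igraph::V(g)$name
  helix_of <- setNames(igraph::V(g)$helix, vn)
  kind_of <- setNames(igraph::V(g)$kind, vn)
  ends <- .edge_ends(g)
  add_pair <- function(acc, r1, r2) {
    h1 <- helix_of[[r1]]; h2 <- helix_of[[r2]]
    if (is.na(h1) || is.na(h2) || h1 == h2) return(acc)
    c(acc, paste(.ekey(r1, r2)))
  }
  # direct res-res edges
  if (nrow(ends)) {
    types <- igraph::E(g)$type
    for (k in seq_len(nrow(ends))) {
      if (types[k] != "res-res") next
      h1 <- helix_of[[ends[k, 1]]]; h2 <- helix_of[[ends[k, 2]]]
      if (is.na(h1) || is.na(h2) || h1 == h2) next
      m[h1, h2] <- m[h1, h2] + 1L
      m[h2, h1] <- m[h2, h1] + 1L
    }
  }
  # water-mediated residue-pair bridges (1 or 2 waters), distinct pairs
  adj <- .water_adjacency(g)
  res_neigh <- lapply(adj, function(x) c(x$static, x$switchable))
  # also residues of class "none" neighbouring waters count for interfaces
  if (nrow(ends)) {
    for (k in seq_len(nrow(ends))) {
      a <- ends[k, 1]; b <- ends[k, 2]
      for (pair in list(c(a, b), c(b, a))) {
        w <- pair[1]; o <- pair[2]
        if (kind_of[[w]] == "water" && kind_of[[o]] == "residue" &&
            !(o %in% res_neigh[[w]]))
          res_neigh[[w]] <- c(res_neigh[[w]], o)
      }
    }
  }
  bridged <- character()
  for (w in names(adj)) {
    rs <- unique(res_neigh[[w]])
    if (length(rs) >= 2L) {
      cmb <- utils::combn(sort(rs), 2L)
      for (c2 in seq_len(ncol(cmb)))
        bridged <- add_pair(bridged, cmb[1, c2], cmb[2, c2])
    }
    for (w2 in adj[[w]]$water) {
      for (r1 in unique(res_neigh[[w]]))
        for (r2 in unique(res_neigh[[w2]]))
          if (r1 != r2) bridged <- add_pair(bridged, r1, r2)
    }
  }
  for (bk in unique(bridged)) {
    rr <- strsplit(bk, "~", fixed = TRUE)[[1]]
    h1 <- helix_of[[rr[1]]]; h2 <- helix_of[[rr[2]]]
    m[h1, h2] <- m[h1, h2] + 1L
    m[h2, h1] <- m[h2, h1] + 1L
  }
  diag(m) <- 0L
  m
}

#' Classify a design's hydration relative to a reference count
#'
#' Designs with more static-switchable water-mediated hydrogen bonds than
#' the reference receptor are `Hyd_high`, fewer are `Hyd_low`, equal are
#' `reference_like`.
#'
#' @param count static-switchable count of the design.
#' @param reference reference receptor count (default 20).
#' @return `"Hyd_high"`, `"Hyd_low"` or `"reference_like"`.
#' @export
classify_hydration <- function(count, reference = 20L) {
  stopifnot(count >= 0, reference >= 0)
  if (count > reference) "Hyd_high" else if (count < reference) "Hyd_low"
  else "reference_like"
}

#' Summary network statistics for one structure
#'
#' @param g graph from [build_graph].
#' @param n_helices interface-matrix dimension.
#' @return A `network_stats` list: `n_water_mediated_total`,
#'   `n_static_switchable`, `interface_matrix`, `solvated_residues` (BW
#'   codes of residues with at least one water edge).
#' @export
network_stats <- function(g, n_helices = 7L) {
  solv <- character()
  ends <- .edge_ends(g)
  if (nrow(ends)) {
    kind_of <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
    bw_of <- setNames(igraph::V(g)$bw, igraph::V(g)$name)
    for (k in seq_len(nrow(ends))) {
      a <- ends[k, 1]; b <- ends[k, 2]
      if (kind_of[[a]] == "water" && kind_of[[b]] == "residue" && !is.na(bw_of[[b]]))
        solv <- c(solv, bw_of[[b]])
      if (kind_of[[b]] == "water" && kind_of[[a]] == "residue" && !is.na(bw_of[[a]]))
        solv <- c(solv, bw_of[[a]])
    }
  }
  structure(list(
    n_water_mediated_total = count_water_mediated_total(g),
    n_static_switchable = count_static_switchable(g),
    interface_matrix = interface_breakdown(g, n_helices),
    solvated_residues = sort(unique(solv))), class = "network_stats")
}

#' Compare the solvated-residue sets of two structures
#'
#' Reports the BW codes solvated in both structures and the shared fraction
#' relative to the query (`stats_a`) by default, or the Jaccard index.
#'
#' @param stats_a query `network_stats`.
#' @param stats_b reference `network_stats`.
#' @param denominator `"query"` (default) or `"jaccard"`.
#' @return list with `shared` (BW codes) and `fraction_shared` (2 decimals).
#' @export
compare_networks <- function(stats_a, stats_b, denominator = c("query", "jaccard")) {
  denominator <- match.arg(denominator)
  a <- stats_a$solvated_residues; b <- stats_b$solvated_residues
  if (!length(a)) stop("undefined fraction: query has no solvated residues")
  shared <- intersect(a, b)
  den <- if (denominator == "query") length(a) else length(union(a, b))
  list(shared = shared, fraction_shared = round(length(shared) / den, 2))
}

#' Export an interaction graph
#'
#' Writes the graph in Cytoscape-compatible SIF (edge type as the
#' interaction label) or GraphML (full node/edge attributes).
#'
#' @param g graph from [build_graph].
#' @param path output path.
#' @param format `"SIF"` or `"GraphML"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  if (format == "GraphML") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ends <- .edge_ends(g)
    lines <- character()
    if (nrow(ends)) {
      types <- igraph::E(g)$type
      lines <- sprintf("%s\t%s\t%s", ends[, 1], types, ends[, 2])
    }
    iso <- setdiff(igraph::V(g)$name, as.character(ends))
    writeLines(c(lines, iso), path)
  }
  invisible(path)
}

#' End-to-end network analysis of a model or ensemble
#'
#' For an ensemble: selects the lowest-energy fraction, clusters waters into
#' consensus nodes, rebuilds the lowest-energy model with consensus waters,
#' finds hydrogen bonds and returns the graph plus statistics. For a single
#' model the waters are used as-is.
#'
#' @param x a [structure_model] or `ensemble`.
#' @param annotation a `bw_annotation`.
#' @param criteria [hbond_criteria] or `NULL` for defaults.
#' @param fraction lowest-energy fraction for ensembles (default 0.10).
#' @param radius,min_support consensus-water clustering parameters.
#' @param reference_count reference static-switchable count for
#'   classification (default 20).
#' @return list with `graph`, `stats`, `class`, and (ensembles) `consensus`.
#' @export
analyze_network <- function(x, annotation, criteria = NULL, fraction = 0.10,
                            radius = 1.0, min_support = 2L,
                            reference_count = 20L) {
  consensus <- NULL
  if (inherits(x, "ensemble")) {
    sel <- select_lowest_fraction(x, fraction)
    consensus <- cluster_waters(sel, radius = radius, min_support = min_support)
    model <- consensus_model(sel$models[[1]], consensus)
  } else model <- x
  hb <- find_hbonds(model, criteria)
  g <- build_graph(model, hb, annotation)
  st <- network_stats(g)
  list(graph = g, stats = st,
       class = classify_hydration(st$n_static_switchable, reference_count),
       consensus = consensus)
}
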