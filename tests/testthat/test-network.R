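test_that("consensus water clustering merges, supports, and discards", {
  # same water position in every model -> one node with support 1
  ens <- water_ensemble(rep(list(rbind(c(0, 0, 0))), 5))
  cw <- cluster_waters(ens)
  expect_equal(nrow(cw), 1L)
  expect_equal(cw$support, 1)
  expect_equal(unlist(cw[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))

  # two positions 0.3 A apart merge into one cluster at radius 1.0
  ens2 <- water_ensemble(list(rbind(c(0, 0, 0)), rbind(c(0.3, 0, 0))))
  cw2 <- cluster_waters(ens2)
  expect_equal(nrow(cw2), 1L)
  expect_equal(cw2$x, 0.15)

  # a water present in only 1 of 10 models is dropped at min_support 2
  pos <- c(rep(list(rbind(c(0, 0, 0))), 9), list(rbind(c(0, 0, 0), c(9, 9, 9))))
  cw3 <- cluster_waters(water_ensemble(pos))
  expect_equal(nrow(cw3), 1L)
  expect_equal(cluster_waters(water_ensemble(pos), min_support = 1L) |> nrow(), 2L)
  expect_error(cluster_waters(water_ensemble(list(rbind(c(0,0,0)))), radius = 0))
})

test_that("graph construction collapses atom bonds to node-level edges", {
  # one water bonded to two serines -> 3 nodes, 2 res-water edges
  m <- tiny_model(
    atom_row(1, "CB", "SER", "A", 1, c(-4.3, 0, 0)),
    atom_row(2, "OG", "SER", "A", 1, c(-2.8, 0, 0)),
    atom_row(3, "CB", "SER", "A", 2, c(4.3, 0, 0)),
    atom_row(4, "OG", "SER", "A", 2, c(2.8, 0, 0)),
    atom_row(5, "O", "HOH", "W", 3, c(0, 0, 0)))
  g <- build_graph(m, find_hbonds(m))
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_setequal(igraph::E(g)$type, "res-water")
  expect_equal(count_water_mediated_total(g), 2L)

  # zero hbonds -> empty graph
  g0 <- build_graph(m, find_hbonds(m, hbond_criteria(max_heavy_distance = 2.5)))
  expect_equal(igraph::ecount(g0), 0L)
  expect_equal(count_water_mediated_total(g0), 0L)

  # direct side-chain contact -> one res-res edge
  m2 <- tiny_model(
    atom_row(1, "CB", "SER", "A", 1, c(-1.5, 0, 0)),
    atom_row(2, "OG", "SER", "A", 1, c(0, 0, 0)),
    atom_row(3, "CB", "SER", "A", 2, c(4.5, 0, 0)),
    atom_row(4, "OG", "SER", "A", 2, c(3.0, 0, 0)))
  g2 <- build_graph(m2, find_hbonds(m2))
  expect_equal(igraph::ecount(g2), 1L)
  expect_equal(igraph::E(g2)$type, "res-res")
  expect_equal(count_water_mediated_total(g2), 0L)
})

test_that("static-switchable counting follows the mediating-path edge rule", {
  nodes <- data.frame(
    name = c("Rs", "Rt", "Rn", "W1", "W2"),
    kind = c("residue", "residue", "residue", "water", "water"),
    class = c("static", "switchable", "none", "none", "none"),
    stringsAsFactors = FALSE)
  # single water bridging static and switchable: both edges count
  g <- toy_graph(nodes, data.frame(from = c("Rs", "W1"), to = c("W1", "Rt")))
  expect_equal(count_static_switchable(g), 2L)
  # two-water chain: all three edges count
  g2 <- toy_graph(nodes, data.frame(from = c("Rs", "W1", "W2"),
                                    to = c("W1", "W2", "Rt")))
  expect_equal(count_static_switchable(g2), 3L)
  # waters touching only static residues: nothing counts
  g3 <- toy_graph(nodes, data.frame(from = c("Rs", "Rs"), to = c("W1", "W2")))
  expect_equal(count_static_switchable(g3), 0L)
  # unclassified residues never mediate
  g4 <- toy_graph(nodes, data.frame(from = c("Rn", "W1"), to = c("W1", "Rt")))
  expect_equal(count_static_switchable(g4), 0L)
  # chains of three waters do not mediate
  nodes5 <- rbind(nodes, data.frame(name = "W3", kind = "water", class = "none"))
  g5 <- toy_graph(nodes5, data.frame(from = c("Rs", "W1", "W2", "W3"),
                                     to = c("W1", "W2", "W3", "Rt")))
  expect_equal(count_static_switchable(g5), 0L)
  # an edge on several paths is counted once: one water, two statics, one switchable
  nodes6 <- data.frame(
    name = c("Rs1", "Rs2", "Rt", "W1"),
    kind = c("residue", "residue", "residue", "water"),
    class = c("static", "static", "switchable", "none"),
    stringsAsFactors = FALSE)
  g6 <- toy_graph(nodes6, data.frame(from = c("Rs1", "Rs2", "W1"),
                                     to = c("W1", "W1", "Rt")))
  expect_equal(count_static_switchable(g6), 3L)
})

test_that("counting rules agree with the brute-force path oracle", {
  for (s in 1:40) {
    g <- random_toy_graph(s)
    expect_equal(count_static_switchable(g), oracle_static_switchable(g),
                 info = paste("seed", s))
  }
})

test_that("counts are monotone under edge addition", {
  for (s in 1:10) {
    g <- random_toy_graph(s, p_edge = 0.25)
    vn <- igraph::V(g)$name
    missing <- which(!(igraph::as_adjacency_matrix(g, sparse = FALSE) > 0) &
                       upper.tri(matrix(0, length(vn), length(vn))),
                     arr.ind = TRUE)
    if (!nrow(missing)) next
    pick <- missing[1, ]
    ka <- igraph::V(g)$kind[pick[1]]; kb <- igraph::V(g)$kind[pick[2]]
    type <- if (ka == "water" && kb == "water") "water-water"
            else if (ka == "water" || kb == "water") "res-water" else "res-res"
    g2 <- igraph::add_edges(g, c(pick[1], pick[2]),
                            attr = list(type = type, multiplicity = 1L))
    expect_gte(count_water_mediated_total(g2), count_water_mediated_total(g))
    expect_gte(count_static_switchable(g2), count_static_switchable(g))
  }
})

test_that("interface matrix counts direct and water-mediated helix contacts", {
  nodes <- data.frame(
    name = c("R2", "R7", "W1"),
    kind = c("residue", "residue", "water"),
    class = c("static", "switchable", "none"),
    helix = c(2L, 7L, NA),
    stringsAsFactors = FALSE)
  g <- toy_graph(nodes, data.frame(from = c("R2", "W1"), to = c("W1", "R7")))
  m <- interface_breakdown(g)
  expect_equal(m[2, 7], 1L)
  expect_equal(m[7, 2], 1L)
  expect_equal(sum(m), 2L)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  # empty graph -> zero matrix
  g0 <- toy_graph(nodes, data.frame(from = character(), to = character()))
  expect_true(all(interface_breakdown(g0) == 0))
  # symmetry on arbitrary random graphs
  for (s in 1:5) {
    mm <- interface_breakdown(random_toy_graph(s))
    expect_identical(mm, t(mm))
  }
})

test_that("hydration classes compare design counts to the reference", {
  expect_equal(classify_hydration(26, 20), "Hyd_high")
  expect_equal(classify_hydration(14, 20), "Hyd_low")
  expect_equal(classify_hydration(20, 20), "reference_like")
})

test_that("solvated side-chain comparison uses the query denominator", {
  sa <- structure(list(solvated_residues = c("2.50", "3.39", "7.45", "7.49", "6.48")),
                  class = "network_stats")
  sb <- structure(list(solvated_residues = c("2.50", "3.39", "1.50", "5.58", "7.53")),
                  class = "network_stats")
  cmp <- compare_networks(sa, sb)
  expect_equal(cmp$fraction_shared, 0.40)
  expect_setequal(cmp$shared, c("2.50", "3.39"))
  expect_equal(compare_networks(sa, sa)$fraction_shared, 1.0)
  sc <- structure(list(solvated_residues = c("9.99")), class = "network_stats")
  expect_equal(compare_networks(sa, sc)$fraction_shared, 0)
  s0 <- structure(list(solvated_residues = character()), class = "network_stats")
  expect_error(compare_networks(s0, sa), "undefined")
  # Jaccard alternative
  expect_equal(compare_networks(sa, sb, "jaccard")$fraction_shared,
               round(2 / 8, 2))
})

test_that("graph export produces loadable SIF and GraphML", {
  nodes <- data.frame(name = c("Rs", "Rt", "W1"),
                      kind = c("residue", "residue", "water"),
                      class = c("static", "switchable", "none"),
                      stringsAsFactors = FALSE)
  g <- toy_graph(nodes, data.frame(from = c("Rs", "W1"), to = c("W1", "Rt")))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, sif, "SIF")
  expect_equal(length(readLines(sif)), 2L)  # 2 interaction lines, no isolates
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "GraphML")
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  # empty graph is still a valid file
  g0 <- toy_graph(nodes, data.frame(from = character(), to = character()))
  export_graph(g0, sif, "SIF")
  expect_equal(length(readLines(sif)), 3L)  # isolated nodes listed singly
  expect_error(export_graph(g, sif, "DOT"))
})

test_that("ensemble analysis pipeline reproduces single-model counts", {
  fx <- random_planted_fixture(seed = 9)
  # ensemble of three jittered copies of the same model (waters within the
  # cluster radius) must give the same consensus counts
  jitter_model <- function(m, dx, id, e) {
    a <- m$atoms
    a$x <- a$x + ifelse(a$kind == "water", dx, 0)
    mm <- structure_model(a, id)
    mm$energy <- e
    mm
  }
  ens <- ensemble(list(jitter_model(fx$model, 0, "a", 1),
                       jitter_model(fx$model, 0.05, "b", 2),
                       jitter_model(fx$model, -0.05, "c", 3)))
  res <- analyze_network(ens, fx$annotation, fraction = 1)
  expect_equal(res$stats$n_water_mediated_total,
               fx$expected$n_water_mediated_total)
  expect_equal(res$stats$n_static_switchable,
               fx$expected$n_static_switchable)
})
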