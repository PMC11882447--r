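test_that("polar-atom chemistry table gives standard roles", {
  ser <- polar_atom_table("SER")
  expect_equal(ser$role[ser$name == "OG"], "both")
  expect_equal(ser$role[ser$name == "N"], "donor")
  expect_equal(ser$role[ser$name == "O"], "acceptor")
  hoh <- polar_atom_table("HOH")
  expect_equal(hoh$name, "O")
  expect_equal(hoh$role, "both")
  leu <- polar_atom_table("LEU")
  expect_setequal(leu$name, c("N", "O", "OXT"))  # backbone only
  pro <- polar_atom_table("PRO")
  expect_false("N" %in% pro$name)  # proline backbone N cannot donate
  expect_warning(unk <- polar_atom_table("XYZ"), "apolar")
  expect_equal(nrow(unk), 0L)
  # custom ligand definitions rescue unknown residues
  defs <- data.frame(resname = "LIG", atomname = "O1", role = "acceptor")
  lig <- polar_atom_table("LIG", defs)
  expect_equal(lig$name, "O1")
})

test_that("water pairs follow the heavy-atom distance window", {
  m <- waters_model(rbind(c(0, 0, 0), c(2.8, 0, 0)))
  expect_equal(nrow(find_hbonds(m)), 1L)
  expect_equal(find_hbonds(m)$distance, 2.8)
  m2 <- waters_model(rbind(c(0, 0, 0), c(4.5, 0, 0)))
  expect_equal(nrow(find_hbonds(m2)), 0L)
  m3 <- waters_model(rbind(c(0, 0, 0), c(2.0, 0, 0)))  # below minimum
  expect_equal(nrow(find_hbonds(m3)), 0L)
})

test_that("serine-water bonds respect the 3.5 A default cutoff boundary", {
  ser_water <- function(d) tiny_model(
    atom_row(1, "CB", "SER", "A", 1, c(-1.5, 0, 0)),
    atom_row(2, "OG", "SER", "A", 1, c(0, 0, 0)),
    atom_row(3, "O", "HOH", "W", 2, c(d * cos(pi / 6), d * sin(pi / 6), 0)))
  expect_equal(nrow(find_hbonds(ser_water(3.4))), 1L)
  expect_equal(nrow(find_hbonds(ser_water(3.6))), 0L)
})

test_that("the donor angle proxy rejects implausible approach geometry", {
  # acceptor-only partner forces SER OG to be the donor; water placed
  # behind the OG (antecedent side) gives an angle far below 90 degrees
  geom <- function(wx) tiny_model(
    atom_row(1, "CB", "SER", "A", 1, c(-1.5, 0, 0)),
    atom_row(2, "OG", "SER", "A", 1, c(0, 0, 0)),
    atom_row(3, "CG", "ASP", "A", 2, c(wx - 1.3, 1.2, 0)),
    atom_row(4, "OD1", "ASP", "A", 2, c(wx, 0.5, 0)))
  front <- geom(3.0)    # angle(CB, OG, OD1) > 90: bond
  behind <- geom(-3.0)  # angle < 90: rejected
  expect_equal(nrow(find_hbonds(front)), 1L)
  expect_equal(nrow(find_hbonds(behind)), 0L)
  # water donors skip the proxy: water behind the OG still bonds
  wb <- tiny_model(
    atom_row(1, "CB", "SER", "A", 1, c(-1.5, 0, 0)),
    atom_row(2, "OG", "SER", "A", 1, c(0, 0, 0)),
    atom_row(3, "O", "HOH", "W", 2, c(-2.0, 2.0, 0)))
  expect_equal(nrow(find_hbonds(wb)), 1L)
})

test_that("donor/acceptor compatibility is enforced", {
  # two acceptor-only carboxylate oxygens of different residues: no bond
  m <- tiny_model(
    atom_row(1, "CG", "ASP", "A", 1, c(-1.3, 0, 0)),
    atom_row(2, "OD1", "ASP", "A", 1, c(0, 0, 0)),
    atom_row(3, "CG", "ASP", "A", 2, c(4.1, 0, 0)),
    atom_row(4, "OD1", "ASP", "A", 2, c(2.8, 0, 0)))
  expect_equal(nrow(find_hbonds(m)), 0L)
  # lysine NZ (donor) to carboxylate O (acceptor): bond
  m2 <- tiny_model(
    atom_row(1, "CE", "LYS", "A", 1, c(-1.5, 0, 0)),
    atom_row(2, "NZ", "LYS", "A", 1, c(0, 0, 0)),
    atom_row(3, "CG", "ASP", "A", 2, c(4.1, 0, 0)),
    atom_row(4, "OD1", "ASP", "A", 2, c(2.8, 0, 0)))
  expect_equal(nrow(find_hbonds(m2)), 1L)
})

test_that("detection is invariant under rigid-body transforms", {
  fx <- random_planted_fixture(seed = 5)
  hb0 <- find_hbonds(fx$model)
  # rotate 40 degrees about z and translate
  th <- 40 * pi / 180
  a <- fx$model$atoms
  x <- a$x * cos(th) - a$y * sin(th) + 11
  y <- a$x * sin(th) + a$y * cos(th) - 3
  a$x <- x; a$y <- y; a$z <- a$z + 5
  m2 <- structure_model(a, "rotated")
  hb1 <- find_hbonds(m2)
  expect_equal(nrow(hb1), nrow(hb0))
  expect_equal(sort(hb1$distance), sort(hb0$distance), tolerance = 1e-9)
})

test_that("widening the distance cutoff never removes bonds", {
  fx <- random_planted_fixture(seed = 6)
  n1 <- nrow(find_hbonds(fx$model, hbond_criteria(max_heavy_distance = 3.2)))
  n2 <- nrow(find_hbonds(fx$model, hbond_criteria(max_heavy_distance = 3.5)))
  n3 <- nrow(find_hbonds(fx$model, hbond_criteria(max_heavy_distance = 3.8)))
  expect_true(n1 <= n2 && n2 <= n3)
  # determinism
  expect_identical(find_hbonds(fx$model), find_hbonds(fx$model))
})

test_that("explicit hydrogens tighten detection via the H-acceptor cutoff", {
  base <- list(
    atom_row(1, "CB", "SER", "A", 1, c(-1.5, 0, 0)),
    atom_row(2, "OG", "SER", "A", 1, c(0, 0, 0)),
    atom_row(3, "CG", "ASP", "A", 2, c(4.3, 0, 0)),
    atom_row(4, "OD1", "ASP", "A", 2, c(3.0, 0, 0)))
  # H on the donor pointing at the acceptor: bond kept
  hg_to <- atom_row(5, "HG", "SER", "A", 1, c(0.95, 0, 0), element = "H")
  expect_equal(nrow(find_hbonds(tiny_model_list(c(base, list(hg_to))))), 1L)
  # H pointing away: H-acceptor distance beyond 2.5 A, bond rejected
  hg_away <- atom_row(5, "HG", "SER", "A", 1, c(-0.4, 0.87, 0), element = "H")
  expect_equal(nrow(find_hbonds(tiny_model_list(c(base, list(hg_away))))), 0L)
})

test_that("criteria constructor validates the distance window", {
  expect_error(hbond_criteria(max_heavy_distance = 2.0, min_heavy_distance = 2.4))
  expect_silent(hbond_criteria())
})
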