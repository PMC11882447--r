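test_that("minimal PDB with one water parses to a water-only model", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       1.000   2.000   3.000  1.00  0.00           O",
    "END"), tmp)
  m <- read_structure(tmp)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$kind, "water")
  expect_equal(m$atoms$x, 1)
})

test_that("altloc conflicts resolve to highest occupancy, ties alphabetical", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  ASER A   1      11.104   6.134  -6.504  0.60 10.00           N",
    "ATOM      2  N  BSER A   1      99.000  99.000  99.000  0.40 10.00           N",
    "ATOM      3  CA ASER A   1      12.000   6.000  -6.000  0.50 10.00           C",
    "ATOM      4  CA BSER A   1      88.000  88.000  88.000  0.50 10.00           C"), tmp)
  m <- read_structure(tmp)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[m$atoms$name == "N"], 11.104)   # higher occupancy
  expect_equal(m$atoms$x[m$atoms$name == "CA"], 12.0)    # occupancy tie -> A
})

test_that("write/read roundtrip preserves names, numbering and coordinates", {
  fx <- random_planted_fixture(seed = 11)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fx$model, tmp)
  m2 <- read_structure(tmp)
  expect_equal(m2$atoms$name, fx$model$atoms$name)
  expect_equal(m2$atoms$resnum, fx$model$atoms$resnum)
  expect_equal(m2$atoms$chain, fx$model$atoms$chain)
  # PDB format precision: 3 decimals
  expect_lt(max(abs(m2$atoms$x - fx$model$atoms$x)), 5e-4 + 1e-9)
  expect_lt(max(abs(m2$atoms$z - fx$model$atoms$z)), 5e-4 + 1e-9)
  # waters come back as HETATM HOH records
  expect_equal(sum(m2$atoms$kind == "water"),
               sum(fx$model$atoms$kind == "water"))
  lines <- readLines(tmp)
  expect_equal(sum(grepl("^HETATM.*HOH", lines)),
               sum(fx$model$atoms$kind == "water"))
})

test_that("coordinates are written rounded to 3 decimals", {
  m <- tiny_model(atom_row(1, "O", "HOH", "W", 1, c(1.23456, 0, 0)))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, tmp)
  expect_equal(read_structure(tmp)$atoms$x, 1.235)
})

test_that("unparseable or empty coordinate input raises informative errors", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", tmp)
  expect_error(read_structure(tmp), "empty structure")
  writeLines(c(
    "ATOM      1  N   SER A   1      xx.xxx   6.134  -6.504  1.00 10.00",
    "END"), tmp)
  expect_error(read_structure(tmp), "line 1")
})

test_that("annotation TSV loads, deduplicates, and rejects conflicts", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tresnum\tbw\thelix\tclass",
               "# a comment",
               "A\t52\t2.50\t2\tstatic",
               "A\t52\t2.50\t2\tstatic",
               "A\t279\t7.49\t7\tswitchable"), tmp)
  ann <- load_annotation(tmp)
  expect_equal(nrow(ann$table), 2L)
  hit <- bw_lookup(ann, "A", 52)
  expect_equal(hit$bw, "2.50")
  expect_equal(hit$class, "static")
  expect_null(bw_lookup(ann, "A", 1))
  # repeated lookups are pure
  expect_identical(bw_lookup(ann, "A", 279), bw_lookup(ann, "A", 279))

  writeLines(c("chain\tresnum\tbw\thelix\tclass",
               "A\t52\t2.50\t2\tstatic",
               "A\t52\t2.51\t2\tstatic"), tmp)
  expect_error(load_annotation(tmp), "conflict")
  writeLines(c("chain\tresnum\tbw\thelix\tclass",
               "A\t52\tx.50\t2\tstatic"), tmp)
  expect_error(load_annotation(tmp), "malformed")
  writeLines(c("chain\tresnum\tbw\thelix\tclass",
               "A\t52\t2.50\t2\tweird"), tmp)
  expect_error(load_annotation(tmp), "static/switchable/none")
})

test_that("lowest-energy selection keeps ceil(fraction*N) with a floor of 1", {
  mk <- function(n) ensemble(lapply(seq_len(n), function(i) {
    m <- tiny_model(atom_row(1, "O", "HOH", "W", 1, c(i, 0, 0)))
    m$model_id <- paste0("m", i)
    m$energy <- as.numeric(n - i)  # ascending input = descending energy
    m
  }))
  sel <- select_lowest_fraction(mk(20), 0.10)
  expect_equal(length(sel$models), 2L)
  expect_equal(vapply(sel$models, function(m) m$energy, 1), c(0, 1))
  expect_equal(length(select_lowest_fraction(mk(5), 0.10)$models), 1L)

  # ties broken by input order
  tied <- ensemble(lapply(1:4, function(i) {
    m <- tiny_model(atom_row(1, "O", "HOH", "W", 1, c(i, 0, 0)))
    m$model_id <- paste0("t", i); m$energy <- 7; m
  }))
  sel2 <- select_lowest_fraction(tied, 0.5)
  expect_equal(vapply(sel2$models, function(m) m$model_id, ""), c("t1", "t2"))

  # subset invariant
  ids <- vapply(sel$models, function(m) m$model_id, "")
  expect_true(all(ids %in% paste0("m", 1:20)))

  noe <- mk(3); noe$models[[2]]$energy <- NULL
  expect_error(select_lowest_fraction(noe, 0.5), "missing energy")
  expect_error(select_lowest_fraction(mk(3), 0), "fraction")
})

test_that("multi-MODEL files return the requested model", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "HETATM    1  O   HOH A   1       1.000   0.000   0.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "HETATM    1  O   HOH A   1       2.000   0.000   0.000  1.00  0.00           O",
    "ENDMDL",
    "END"), tmp)
  expect_equal(read_structure(tmp, model = 1)$atoms$x, 1)
  expect_equal(read_structure(tmp, model = 2)$atoms$x, 2)
  expect_error(read_structure(tmp, model = 3), "out of range")
})
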