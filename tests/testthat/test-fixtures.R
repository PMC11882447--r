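test_that("bundle generation is deterministic and correctly annotated", {
  b1 <- make_bundle(seed = 2)
  b2 <- make_bundle(seed = 2)
  expect_identical(b1$model$atoms, b2$model$atoms)
  expect_identical(b1$annotation$table, b2$annotation$table)
  ann <- b1$annotation$table
  expect_equal(sort(unique(ann$helix)), 1:7)
  expect_setequal(ann$class[ann$helix %in% 1:5], "static")
  expect_setequal(ann$class[ann$helix %in% 6:7], "switchable")
  # 7 helices x 14 residues, synthetic BW codes helix.(40+index)
  expect_equal(nrow(ann), 98L)
  expect_equal(ann$bw[1], "1.41")
  # different seed rotates the bundle
  b3 <- make_bundle(seed = 3)
  expect_false(isTRUE(all.equal(b1$model$atoms$x, b3$model$atoms$x)))
})

test_that("a bare bundle has no water-mediated interactions", {
  bd <- make_bundle(seed = 2)
  g <- build_graph(bd$model, find_hbonds(bd$model), bd$annotation)
  expect_equal(count_water_mediated_total(g), 0L)
  expect_equal(count_static_switchable(g), 0L)
})

test_that("planted bridges carry their analytic ground truth", {
  fx <- random_planted_fixture(seed = 21, n_single = 2, n_chain2 = 1,
                               n_decoy = 1)
  singles <- sum(fx$bridges$kind == "single")
  chains <- sum(fx$bridges$kind == "chain2")
  expect_equal(singles, 3L)  # 2 static-switchable + 1 same-class decoy
  expect_equal(chains, 1L)
  # totals: every bridge contributes, only opposite-class ones mediate
  expect_equal(fx$expected$n_water_mediated_total, 2L * 3L + 3L)
  expect_equal(fx$expected$n_static_switchable, 2L * 2L + 3L)
  # analyzer reproduces the expectation exactly
  g <- build_graph(fx$model, find_hbonds(fx$model), fx$annotation)
  expect_equal(count_water_mediated_total(g),
               fx$expected$n_water_mediated_total)
  expect_equal(count_static_switchable(g), fx$expected$n_static_switchable)
})

test_that("infeasible bridge geometry is a placement error", {
  bd <- make_bundle(seed = 2)
  anchors <- hydronet:::.bundle_anchors(bd$model, bd$annotation)
  # pick two anchors far beyond single-bridge reach
  d <- as.matrix(dist(anchors[, c("x", "y", "z")]))
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  br <- data.frame(kind = "single",
                   resnum_a = anchors$resnum[far[1]],
                   resnum_b = anchors$resnum[far[2]])
  expect_error(plant_water_network(bd$model, bd$annotation, br),
               "infeasible")
  # residues without polar side chains cannot anchor bridges
  leu <- bd$model$atoms$resnum[bd$model$atoms$resname == "LEU"][1]
  br2 <- data.frame(kind = "single", resnum_a = leu, resnum_b = leu + 1L)
  expect_error(plant_water_network(bd$model, bd$annotation, br2), "anchor")
})

test_that("fixture files round-trip through the standard triplet", {
  fx <- random_planted_fixture(seed = 22)
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx, dir, "fx22")
  expect_true(all(file.exists(paths)))
  truth <- jsonlite::read_json(paths[["expected"]])
  m <- read_structure(paths[["pdb"]])
  ann <- load_annotation(paths[["annotation"]])
  g <- build_graph(m, find_hbonds(m), ann)
  expect_equal(count_water_mediated_total(g), truth$n_water_mediated_total)
  expect_equal(count_static_switchable(g), truth$n_static_switchable)
})

test_that("ion-site fixtures verify their planted minimum", {
  site <- make_ion_site_model(seed = 5)
  expect_equal(site$true_minimum, c(0, 0, 0), tolerance = 0.021)
  scorer <- make_default_scorer(site$model)
  # the recorded minimum scores better than its neighbourhood
  for (d in list(c(0.3, 0, 0), c(0, -0.3, 0), c(0, 0, 0.3)))
    expect_lt(site$min_score,
              scorer$score_one(site$true_minimum + d)$score)
  # same seed reproduces the site exactly
  site2 <- make_ion_site_model(seed = 5)
  expect_identical(site$model$atoms, site2$model$atoms)
  # stripping the carboxylates makes the site worse than bulk
  bulk <- bulk_reference(scorer)
  stripped <- make_default_scorer(strip_ion_site(site))
  occ <- occupancy(stripped$score_one(site$true_minimum)$score, bulk$energy)
  expect_gt(occ$delta_E, 0)
  expect_lt(occ$occupancy, 0.5)
})

test_that("activity datasets honour their generating relation", {
  # zero noise: perfect correlation with the generating sign
  d0 <- make_activity_dataset(noise_sd = 0, seed = 1)
  joined <- merge(d0$activity, d0$energy)
  expect_equal(abs(fit_activity_energy(joined)$pearson_r), 1)
  expect_lt(fit_activity_energy(joined)$slope, 0)
  # same seed reproduces tables exactly
  d1 <- make_activity_dataset(seed = 7)
  d2 <- make_activity_dataset(seed = 7)
  expect_identical(d1$activity, d2$activity)
  expect_identical(d1$energy, d2$energy)
  # basal activities stay strictly inside (0, 1) and clips are reported
  expect_true(all(d1$activity$basal_frac > 0 & d1$activity$basal_frac < 1))
  dc <- make_activity_dataset(intercept = 0.99, noise_sd = 0.3, seed = 3)
  expect_true(dc$n_clipped >= 0)
  expect_true(all(dc$activity$basal_frac <= 0.99))
  # calibrated noise reported when not supplied
  expect_gt(d1$noise_sd, 0)
  # generating slope sign recovered with small noise across seeds
  signs <- vapply(1:25, function(s) {
    d <- make_activity_dataset(noise_sd = 0.01, seed = s)
    fit_activity_energy(merge(d$activity, d$energy))$slope < 0
  }, logical(1))
  expect_true(all(signs))
  expect_error(make_activity_dataset(n_designs = 2), "at least 3")
})
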