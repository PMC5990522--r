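test_that("simulation is fully reproducible from its seed", {
  ps <- patient_preset("XB37")
  s1 <- simulate_cells(ps$model, noise_config(seed = 5), 40)
  s2 <- simulate_cells(ps$model, noise_config(seed = 5), 40)
  s3 <- simulate_cells(ps$model, noise_config(seed = 6), 40)
  expect_identical(s1$matrix$ref, s2$matrix$ref)
  expect_identical(s1$matrix$alt, s2$matrix$alt)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$matrix$alt, s3$matrix$alt))
})

test_that("clone frequencies must sum to one", {
  expect_error(clone_model(
    groups = list(g1 = "A"),
    clones = data.frame(clone_id = c("x", "y"), frequency = c(0.6, 0.3),
                        genotype = I(list("g1", character(0))))),
    "sum to 1")
})

test_that("a noiseless single clone genotypes perfectly", {
  model <- clone_model(
    groups = list(g1 = c("EVA", "EVB"), g2 = "EVC"),
    clones = data.frame(clone_id = "only", frequency = 1,
                        genotype = I(list(c("g1", "g2")))))
  sim <- simulate_cells(model, noise_config(mean_depth = 200,
                                            depth_dispersion = 500,
                                            ldo_prob = 0, ado_prob = 0,
                                            fp_prob = 0, seed = 3), 25)
  g <- call_genotypes(sim$matrix)
  expect_true(all(unclass(g) == 1L))
  qc <- cell_qc(sim$matrix)
  expect_true(all(qc$combined_rate == 0))
})

test_that("total amplification failure drives the LDO rate to one", {
  model <- clone_model(groups = list(g1 = "EVA"),
                       clones = data.frame(clone_id = "c", frequency = 1,
                                           genotype = I(list("g1"))))
  sim <- simulate_cells(model, noise_config(ldo_prob = 1, seed = 8), 10)
  expect_true(all(sim$matrix$ref + sim$matrix$alt < 4))
  expect_equal(cell_qc(sim$matrix)$ldo_rate, rep(1, 10))
})

test_that("measured ADO matches the configured probability", {
  model <- clone_model(groups = list(g1 = "EVA"),
                       clones = data.frame(clone_id = "c", frequency = 1,
                                           genotype = I(list("g1"))))
  # ~ 32 SNPs x 40 cells > 1000 heterozygous draws
  sim <- simulate_cells(model, noise_config(ldo_prob = 0, ado_prob = 0.10,
                                            fp_prob = 0, seed = 12), 40)
  qc <- cell_qc(sim$matrix)
  n <- 32 * 40
  se <- sqrt(0.1 * 0.9 / n)
  # ADO measured at covered SNPs: collapsed alleles plus rare sampling noise
  expect_lt(abs(mean(qc$ado_rate) - 0.10), 4 * se + 0.02)
})

test_that("patient presets encode the published architectures", {
  x09 <- patient_preset("X09")
  expect_equal(x09$n_cells, 187L)
  expect_equal(nrow(x09$model$clones), 5)
  expect_setequal(x09$model$clones$frequency, c(0.66, 0.25, 0.07, 0.01, 0.01))
  expect_equal(length(unlist(x09$model$groups)), 24)

  xb47 <- patient_preset("XB47")
  expect_equal(xb47$n_cells, 96L)
  expect_setequal(xb47$model$clones$frequency, c(0.28, 0.25, 0.12, 0.09, 0.26))

  xb37 <- patient_preset("XB37")
  expect_equal(xb37$model$clones$frequency[xb37$model$clones$clone_id == "wildtype"],
               1 / 115)

  for (nm in c("X09", "XB37", "XB41", "XB47")) {
    ps <- patient_preset(nm)
    expect_equal(sum(ps$model$clones$frequency), 1, tolerance = 1e-12)
    expect_equal(length(unlist(ps$model$groups)), 24)
    expect_equal(ps$model$n_snps, 32)
    # every clone genotype is a union of whole groups
    for (ev_set in ps$model$clone_events) {
      for (grp in ps$model$groups) {
        inside <- sum(grp %in% ev_set)
        expect_true(inside == 0 || inside == length(grp))
      }
    }
  }
  expect_error(patient_preset("XB99"))
})

test_that("fixtures are byte-identical under a fixed seed and reload cleanly", {
  ps <- patient_preset("XB47")
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  noise <- noise_config(seed = 21)
  f1 <- write_fixture(simulate_cells(ps$model, noise, 30), noise, dir1)
  f2 <- write_fixture(simulate_cells(ps$model, noise, 30), noise, dir2)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  noise3 <- noise_config(seed = 22)
  dir3 <- withr::local_tempdir()
  f3 <- write_fixture(simulate_cells(ps$model, noise3, 30), noise3, dir3)
  expect_false(identical(readLines(f1[["depths"]]), readLines(f3[["depths"]])))

  panel <- read_panel(f1[["panel"]])
  m <- read_depth_matrix(f1[["depths"]], panel)
  expect_equal(attr(m, "fill_ins"), 0)
  expect_equal(dim(m), c(30L, 56L))
})

test_that("realised clone proportions converge to the model frequencies", {
  ps <- patient_preset("XB47")
  sim <- simulate_cells(ps$model, noise_config(seed = 31), 4000)
  got <- table(sim$truth$clone_id) / 4000
  want <- stats::setNames(ps$model$clones$frequency, ps$model$clones$clone_id)
  expect_true(all(abs(got[names(want)] - want) < 0.025))
})

test_that("germline SNPs pass QC at the default noise levels", {
  ps <- patient_preset("X09")
  sim <- simulate_cells(ps$model, noise_config(seed = 14), ps$n_cells)
  qc <- cell_qc(sim$matrix)
  expect_lt(stats::median(qc$combined_rate), 1 / 3)
})
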