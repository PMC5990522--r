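test_that("locus drop-out counts SNPs under the read threshold", {
  expect_equal(locus_dropout_rate(rep(5, 32), rep(5, 32)), 0)
  expect_equal(locus_dropout_rate(rep(0, 32), rep(0, 32)), 1)
  # 8 of 32 SNPs at 3 reads, rest at 10
  ref <- c(rep(3, 8), rep(10, 24)); alt <- rep(0, 32)
  expect_equal(locus_dropout_rate(ref, alt), 0.25)
  # threshold is strict: exactly 4 reads is covered
  expect_equal(locus_dropout_rate(c(4, 3), c(0, 0)), 0.5)
  expect_error(locus_dropout_rate(numeric(0), numeric(0)), "germline")
})

test_that("allelic drop-out counts covered SNPs reading near-homozygous", {
  expect_equal(allelic_dropout_rate(rep(5, 32), rep(5, 32)), 0)
  expect_equal(allelic_dropout_rate(rep(10, 32), rep(0, 32)), 1)
  # 3 of 10 covered SNPs at minor fraction 1/21 < 0.10
  ref <- c(rep(20, 3), rep(6, 7)); alt <- c(rep(1, 3), rep(6, 7))
  expect_equal(allelic_dropout_rate(ref, alt), 0.3)
  # no SNP reaches min_reads -> 0 by convention
  expect_equal(allelic_dropout_rate(c(1, 1), c(0, 1)), 0)
  expect_error(allelic_dropout_rate(numeric(0), numeric(0)), "germline")
})

test_that("combined drop-out is a per-SNP union with LDO precedence", {
  expect_equal(combined_dropout_rate(rep(5, 32), rep(5, 32)), 0)
  # 8 LDO + 4 ADO among the remaining 24 -> 12/32
  ref <- c(rep(1, 8), rep(20, 4), rep(6, 20))
  alt <- c(rep(0, 8), rep(0, 4), rep(6, 20))
  expect_equal(combined_dropout_rate(ref, alt), 0.375)
  # all LDO caps the union at 1 regardless of allele balance
  expect_equal(combined_dropout_rate(rep(1, 32), rep(1, 32)), 1)
})

test_that("drop-out rates are monotone in their thresholds", {
  set.seed(5)
  ref <- rpois(32, 8); alt <- rpois(32, 6)
  for (r in 2:10)
    expect_gte(locus_dropout_rate(ref, alt, min_reads = r + 1),
               locus_dropout_rate(ref, alt, min_reads = r))
  for (f in seq(0.05, 0.4, by = 0.05))
    expect_gte(allelic_dropout_rate(ref, alt, minor_frac = f + 0.05),
               allelic_dropout_rate(ref, alt, minor_frac = f))
})

test_that("cell filtering applies the strict one-third cutoff", {
  panel <- make_panel(0, 3)
  # cell 1: 0/3 affected; cell 2: exactly 1/3 (one LDO SNP); cell 3: 2/3
  ref <- rbind(c(10, 10, 10), c(1, 10, 10), c(1, 1, 10))
  alt <- rbind(c(10, 10, 10), c(0, 10, 10), c(0, 0, 10))
  out <- filter_cells(make_adm(ref, alt, panel))
  expect_equal(out$qc$combined_rate, c(0, 1 / 3, 2 / 3))
  expect_equal(out$qc$passed, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(out$matrix$ref), 1)
  # a rate just below the cutoff is retained
  expect_true(combined_dropout_rate(c(3, rep(10, 9)), rep(5, 10)) < 1 / 3)
})

test_that("a constructed mix of good and bad cells filters exactly", {
  panel <- make_panel(0, 32)
  ref <- matrix(10, 10, 32); alt <- matrix(5, 10, 32)
  ref[7:10, 1:12] <- 1; alt[7:10, 1:12] <- 0  # 12/32 > 1/3 SNPs dropped out
  m <- make_adm(ref, alt, panel)
  out <- filter_cells(m)
  expect_equal(sum(out$qc$passed), 6)
  expect_equal(nrow(out$matrix$ref), 6)
})

test_that("pooled single-cell VAF is ratio of summed depths", {
  panel <- make_panel(1, 0)
  m <- make_adm(rbind(5, 10), rbind(5, 0), panel)
  expect_equal(aggregate_vaf(m, "EV01"), 0.25)
  m2 <- make_adm(rbind(0), rbind(7), panel)
  expect_equal(aggregate_vaf(m2, "EV01"), 1)
  m3 <- make_adm(rbind(0, 0), rbind(0, 0), panel)
  expect_true(is.na(aggregate_vaf(m3, "EV01")))
  expect_error(aggregate_vaf(m, "nope"), "unknown locus")
})

test_that("bulk concordance reports per-locus differences and correlation", {
  panel <- make_panel(4, 0)
  ref <- matrix(rep(c(60, 70, 80, 95), each = 2), 2, 4, byrow = FALSE)
  ref <- rbind(c(60, 70, 80, 95), c(60, 70, 80, 95))
  alt <- rbind(c(40, 30, 20, 5), c(40, 30, 20, 5))
  m <- make_adm(ref, alt, panel)
  bulk <- c(EV01 = 0.4, EV02 = 0.3, EV03 = 0.2, EV04 = 0.05)
  cc <- vaf_concordance(bulk, m)
  expect_equal(cc$difference, rep(0, 4))
  expect_equal(attr(cc, "correlation"), 1)

  # single-cell VAFs diluted by normal-cell admixture: negative differences,
  # rank correlation still perfect
  m_half <- make_adm(ref + (ref + alt) , alt, panel)  # double total, same alt
  cc2 <- vaf_concordance(bulk, m_half)
  expect_true(all(cc2$difference < 0))
  expect_equal(attr(cc2, "correlation"), 1)

  # one shared locus: row emitted, correlation not computable
  cc3 <- vaf_concordance(bulk["EV01"], m)
  expect_equal(nrow(cc3), 1)
  expect_true(is.na(attr(cc3, "correlation")))
  expect_error(vaf_concordance(c(XX = 0.5), m), "no shared")
})

test_that("mean LDO rate converges to the simulated failure probability", {
  model <- clone_model(groups = list(g1 = "EV01"),
                       clones = data.frame(clone_id = "c", frequency = 1,
                                           genotype = I(list("g1"))))
  sim <- simulate_cells(model, noise_config(ldo_prob = 0.12, ado_prob = 0,
                                            fp_prob = 0, seed = 99), 150)
  qc <- cell_qc(sim$matrix)
  n_draws <- 150 * 32
  se <- sqrt(0.12 * 0.88 / n_draws)
  expect_lt(abs(mean(qc$ldo_rate) - 0.12), 4 * se + 0.005)
})
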