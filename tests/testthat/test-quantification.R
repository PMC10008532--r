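make_gcn_fixture <- function() {
  # library of 10000 reads, 500 of them from the reference taxon
  # (450 primary + 50 secondary), dose fraction 0.5 -> 3.0e7 copies
  counts <- matrix(c(450, 50, 400, 8000, 1100), 1,
                   dimnames = list("s1", c("sv_ih", "sv_ih2", "sv_ah",
                                           "sv_x", "sv_y")))
  fx <- make_mc_fixture(counts)
  fx$assignment <- assign_mc_svs(fx$seqs, fx$refs, fx$table)
  fx$metadata <- data.frame(sample_id = "s1", pool_id = "P1",
                            biomass_mass = 50, mc_dose_fraction = 0.5,
                            stringsAsFactors = FALSE)
  fx
}

test_that("the spike-based copy estimator follows its defining formula", {
  fx <- make_gcn_fixture()
  g <- estimate_gcn(fx$table, fx$assignment, fx$metadata, fx$refs)
  expect_equal(g$ih_reads, 500)           # secondaries included
  expect_equal(g$dose_copies, 0.5 * 6.0e7)
  expect_equal(g$gcn, 10000 / 500 * 3.0e7) # = 6.0e8
  expect_equal(g$gcn, 6.0e8)
  expect_equal(g$log2_gcn, log2(6.0e8))
  expect_equal(g$flag, "ok")
})

test_that("a spike-only library estimates exactly the dosed copies", {
  counts <- matrix(c(9000, 1000, 0, 0, 0), 1,
                   dimnames = list("s1", c("sv_ih", "sv_ih2", "sv_ah",
                                           "sv_x", "sv_y")))
  fx <- make_mc_fixture(counts)
  a <- suppressWarnings(assign_mc_svs(fx$seqs, fx$refs, fx$table))
  md <- data.frame(sample_id = "s1", biomass_mass = 0,
                   mc_dose_fraction = 0.25, stringsAsFactors = FALSE)
  g <- estimate_gcn(fx$table, a, md, fx$refs)
  expect_equal(g$gcn, 0.25 * 6.0e7)
})

test_that("unspiked and failed libraries are flagged, not estimated", {
  fx <- make_gcn_fixture()
  md0 <- fx$metadata; md0$mc_dose_fraction <- 0
  g0 <- estimate_gcn(fx$table, fx$assignment, md0, fx$refs)
  expect_true(is.na(g0$gcn))
  expect_equal(g0$flag, "no_mc")

  counts <- matrix(c(0, 0, 400, 8000, 1100), 1,
                   dimnames = list("s1", c("sv_ih", "sv_ih2", "sv_ah",
                                           "sv_x", "sv_y")))
  fx2 <- make_mc_fixture(counts)
  a2 <- suppressWarnings(assign_mc_svs(fx2$seqs, fx2$refs, fx2$table))
  expect_warning(
    g2 <- estimate_gcn(fx2$table, a2, fx$metadata, fx2$refs),
    "no reference-taxon reads")
  expect_equal(g2$flag, "qc_fail")
  expect_true(is.na(g2$gcn))
})

test_that("the absolute-scale transformation follows its defining formula", {
  fx <- make_gcn_fixture()
  g <- estimate_gcn(fx$table, fx$assignment, fx$metadata, fx$refs)
  stripped <- strip_mc(fx$table, fx$assignment)
  tr <- transform_counts(stripped, g)
  # counts_j = 10000, gcn = 6.0e8, ih = 500:
  # a 1000-read SV -> 0.1 * 6.0e8 * 0.95 = 5.7e7
  expect_equal(tr["s1", "sv_y"] / 1100 * 1000, 5.7e7)
  expect_equal(unname(tr["s1", "sv_x"]), 8000 / 10000 * 6.0e8 * 0.95)

  # zero counts stay zero; proportions among sample SVs are preserved
  expect_equal(unname(tr["s1", ] / sum(tr["s1", ])),
               unname(counts(stripped)["s1", ] /
                        sum(counts(stripped)["s1", ])))
  # row-sum identity: 9100 sample (non-MC) reads of 10000 total
  expect_equal(unname(sum(tr["s1", ])),
               6.0e8 * (9100 / 10000) * (1 - 500 / 10000))
})

test_that("samples without a copy estimate are dropped with a warning", {
  sim <- SIM
  g <- suppressWarnings(
    estimate_gcn(sim$table, SIM_ASSIGN, sim$metadata, sim$refs))
  stripped <- strip_mc(sim$table, SIM_ASSIGN)
  expect_warning(tr <- transform_counts(stripped, g),
                 "without a copy estimate")
  expect_setequal(rownames(tr), g$sample_id[!is.na(g$gcn)])
  expect_true(all(tr >= 0))
})

test_that("outlier flagging is a fold rule on the group median", {
  mk <- function(gcn_vals) {
    out <- data.frame(sample_id = sprintf("s%d", seq_along(gcn_vals)),
                      total_reads = 1, ih_reads = 1, dose_copies = 1,
                      gcn = gcn_vals, log2_gcn = log2(gcn_vals),
                      flag = "ok", stringsAsFactors = FALSE)
    class(out) <- c("gcn_estimate", "data.frame")
    out
  }
  # all equal -> nothing flagged
  eq <- flag_outliers(mk(rep(1e9, 4)), rep("g", 4))
  expect_false(any(eq$flagged))
  # 9.84x below the group -> flagged; 2.0x above -> not (threshold 2.5)
  low <- flag_outliers(mk(c(1e9, 1e9, 1e9, 1e9 / 9.84)), rep("g", 4))
  expect_equal(low$flagged, c(FALSE, FALSE, FALSE, TRUE))
  hi <- flag_outliers(mk(c(1e9, 1e9, 1e9, 2e9)), rep("g", 4))
  expect_false(any(hi$flagged))
  # invariant to global rescaling of the group
  sc <- flag_outliers(mk(c(1e9, 1e9, 1e9, 1e9 / 9.84) * 37),
                      rep("g", 4))
  expect_equal(sc$flagged, low$flagged)
  # small groups are skipped
  expect_warning(sm <- flag_outliers(mk(c(1, 1)), rep("g", 2)),
                 "fewer than 3")
  expect_true(all(is.na(sm$flagged)))
})

test_that("dose recommendation inverts the expected read fraction", {
  refs <- make_refs()
  # no bias: one dose carries 2.0e8 effective copies
  rec <- recommend_dose(2.0e9, refs, band = c(0.01, 0.10))
  expect_equal(rec$dose_fraction[2], 0.1 / 0.9 * 2.0e9 / 2.0e8)
  expect_equal(rec$dose_fraction[2], 1.111111, tolerance = 1e-6)
  # vanishing target fraction -> vanishing dose
  tiny <- recommend_dose(2.0e9, refs, band = c(1e-12, 0.5))
  expect_lt(tiny$dose_fraction[1], 1e-10)
  # sample pool equal to one dose, 50% target -> exactly one dose
  half <- recommend_dose(2.0e8, refs, band = c(0.01, 0.5))
  expect_equal(half$dose_fraction[2], 1)
  # gram bias shrinks the effective pool and raises the dose
  biased <- recommend_dose(2.0e9, refs, gram_pos_efficiency = 0.5)
  expect_gt(biased$dose_fraction[1], rec$dose_fraction[1])

  expect_error(recommend_dose(0, refs), "sample_copies")
  expect_error(recommend_dose(1e9, refs, band = c(0, 0.5)), "band")
  expect_error(recommend_dose(1e9, refs, band = c(0.2, 0.1)), "band")
})

test_that("simulating at the recommended dose lands inside the band", {
  refs <- make_refs()
  g <- 0.336
  sample_copies <- 1.25 * 4e7
  mid <- sqrt(0.01 * 0.10)  # geometric mid-band target
  d <- recommend_dose(sample_copies, refs, band = c(mid, 0.5),
                      gram_pos_efficiency = g)$dose_fraction[1]
  design <- data.frame(sample_id = sprintf("r%02d", 1:40),
                       pool_id = "P1", biomass_mass = 1.25,
                       mc_dose_fraction = d, stringsAsFactors = FALSE)
  sim <- simulate_experiment(simulation_config(
    design = design, n_taxa = 50, replicate_sigma = 0, depth = 20000,
    gram_pos_efficiency = g, seed = 8))
  frac <- rowSums(counts(sim$table)[, sim$truth$mc_sv$sv_id]) /
    totals(sim$table)
  expect_gt(mean(frac), 0.01)
  expect_lt(mean(frac), 0.10)
})

test_that("ddPCR cross-validation recovers exact and shifted relations", {
  fx <- make_gcn_fixture()
  mk <- function(gcn_vals, ids = sprintf("s%d", seq_along(gcn_vals))) {
    out <- data.frame(sample_id = ids, total_reads = 1, ih_reads = 1,
                      dose_copies = 1, gcn = gcn_vals,
                      log2_gcn = log2(gcn_vals), flag = "ok",
                      stringsAsFactors = FALSE)
    class(out) <- c("gcn_estimate", "data.frame")
    out
  }
  g <- mk(c(1e8, 3e8, 9e8, 2.7e9))
  dd_eq <- data.frame(sample_id = g$sample_id, copies = g$gcn)
  fit <- ddpcr_crossval(g, dd_eq)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # doubled measurements: slope 1, intercept 1 on the log2 scale
  dd2 <- data.frame(sample_id = g$sample_id, copies = 2 * g$gcn)
  fit2 <- ddpcr_crossval(g, dd2)
  expect_equal(fit2$slope, 1, tolerance = 1e-12)
  expect_equal(fit2$intercept, 1, tolerance = 1e-12)
  # noisy pairs match the closed-form OLS solution
  noisy <- withr::with_seed(2, g$gcn * 2^rnorm(4, 0, 0.3))
  ddn <- data.frame(sample_id = g$sample_id, copies = noisy)
  fitn <- ddpcr_crossval(g, ddn)
  x <- log2(g$gcn); y <- log2(noisy)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2 <- slope^2 * sum((x - mean(x))^2) / sum((y - mean(y))^2)
  expect_equal(fitn$slope, slope, tolerance = 1e-12)
  expect_equal(fitn$r_squared, r2, tolerance = 1e-12)
  # unmatched ids are reported and excluded
  dd_extra <- rbind(dd_eq, data.frame(sample_id = "sX", copies = 1e7))
  expect_warning(fx3 <- ddpcr_crossval(g, dd_extra), "unmatched")
  expect_equal(fx3$excluded, "sX")
  expect_error(ddpcr_crossval(mk(c(1e8, 2e8)),
                              data.frame(sample_id = c("s1", "s2"),
                                         copies = c(1e8, 2e8))),
               "at least 3")
})

test_that("copy estimates are unbiased on simulated data and sharpen with depth", {
  design <- data.frame(sample_id = sprintf("r%02d", 1:30),
                       pool_id = "P1", biomass_mass = 1.25,
                       mc_dose_fraction = 0.5, stringsAsFactors = FALSE)
  rel_err <- sapply(c(2e3, 2e4), function(dep) {
    sim <- simulate_experiment(simulation_config(
      design = design, n_taxa = 40, replicate_sigma = 0, depth = dep,
      gram_pos_efficiency = 1, seed = 13))
    a <- assign_mc_svs(sim$sequences, sim$refs, sim$table)
    g <- estimate_gcn(sim$table, a, sim$metadata, sim$refs)
    median(abs(g$gcn - sim$truth$total_copies) / sim$truth$total_copies)
  })
  expect_lt(rel_err[2], rel_err[1])
  expect_lt(rel_err[2], 0.05)
})
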