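test_that("zero targets give an emphysema-free phantom with scores (0,0)", {
  ph <- generate_phantom(phantom_spec(shape = c(24L, 32L, 40L), seed = 3))
  expect_equal(ph$truth$achieved_cle_pct, 0)
  expect_equal(ph$truth$achieved_pse_pct, 0)
  expect_identical(ph$truth$scores$cle, 0L)
  expect_identical(ph$truth$scores$pse, 0L)
  expect_equal(sum(ph$truth$cle_mask), 0)
  # background false-LAA rate: parenchyma N(-850, 30) leaves essentially
  # nothing below -950 HU
  laa <- compute_laa950(ph$ct, ph$mask)
  expect_lt(laa$fraction, 1e-3)
})

test_that("greedy placement reaches its target and matches the LAA oracle", {
  ph <- small_phantom()   # targets 0.12 / 0.03, tolerance 0.02
  tr <- ph$truth
  expect_true(tr$converged)
  expect_lte(abs(tr$achieved_cle_pct - 0.12), 0.02)
  laa <- compute_laa950(ph$ct, ph$mask)
  expect_lt(abs(laa$fraction - (tr$achieved_cle_pct + tr$achieved_pse_pct)),
            0.005)
  # truth scores are derived from achieved percentages
  expect_identical(tr$scores$cle, percent_to_score("cle", tr$achieved_cle_pct))
  expect_identical(tr$scores$pse, percent_to_score("pse", tr$achieved_pse_pct))
})

test_that("subtype masks are disjoint, inside the lung, spatially stratified", {
  ph <- small_phantom()
  tr <- ph$truth
  expect_equal(sum(tr$cle_mask * tr$pse_mask), 0)
  expect_true(all(ph$mask$values[tr$cle_mask == 1] == 1))
  expect_true(all(ph$mask$values[tr$pse_mask == 1] == 1))
  # centrilobular blob mass sits deeper than paraseptal blob mass
  d <- emphysemap:::cpp_edt3d(as.numeric(ph$mask$values),
                              dim(ph$mask$values))
  expect_gt(mean(d[tr$cle_mask == 1]), mean(d[tr$pse_mask == 1]))
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  sp <- phantom_spec(shape = c(16L, 16L, 24L), seed = 11,
                     target_cle_pct = 0.08, radius_range = c(1L, 2L),
                     margin = 2L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$truth$cle_mask, b$truth$cle_mask)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(target_cle_pct = 0.6, target_pse_pct = 0.4),
               "0.9")
  expect_error(phantom_spec(radius_range = c(0L, 2L)), ">= 1")
  expect_error(sample_cohort_labels(0), ">= 1")
  expect_error(sample_cohort_labels(
    5, data.frame(cle = 0, pse = 0, prob = 0)), "empty")
})

test_that("a degenerate score distribution yields emphysema-free cohorts", {
  coh <- generate_cohort(4, data.frame(cle = 0, pse = 0, prob = 1),
                         seed = 2, shape = c(16L, 16L, 24L))
  expect_equal(nrow(coh$labels), 4)
  expect_true(all(coh$labels$cle_score == 0))
  expect_true(all(coh$labels$cle_pct == 0))
  expect_length(coh$phantoms, 4)
})

test_that("cohort score histogram stays inside exact multinomial bounds", {
  n <- 60
  dist <- data.frame(cle = 0:5, pse = 0L, prob = 1 / 6)
  plan <- sample_cohort_labels(n, dist, seed = 1)
  counts <- tabulate(plan$cle_score + 1L, 6L)
  # simultaneous 99% envelope from per-cell binomial quantiles
  # (Bonferroni-adjusted)
  alpha <- 0.01 / 6
  lo <- qbinom(alpha / 2, n, 1 / 6)
  hi <- qbinom(1 - alpha / 2, n, 1 / 6)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("cohort writing emits volumes, labels and a manifest", {
  d <- file.path(tempdir(), "cohort_out")
  generate_cohort(2, data.frame(cle = 1, pse = 1, prob = 1), seed = 9,
                  shape = c(16L, 16L, 24L), out_dir = d, keep = "none",
                  radius_range = c(1L, 2L), margin = 2L)
  expect_true(file.exists(file.path(d, "labels.csv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  labs <- read.csv(file.path(d, "labels.csv"))
  expect_equal(nrow(labs), 2)
  v <- load_volume(file.path(d, paste0(labs$id[1], "_ct.nii.gz")))
  expect_equal(dim(v$values), c(16L, 16L, 24L))
})
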