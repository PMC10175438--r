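test_that("phantom analytic truth follows chord * sqrt(g^2 + s^2)", {
  expect_equal(make_phantom(split_cylinder_spec(3, 0))$truth$total_area,
               50 * 3)
  expect_equal(make_phantom(split_cylinder_spec(3, 4))$truth$total_area,
               50 * 5)
  expect_equal(small_phantom(0, 0)$truth$total_area, 0)
  # off-centre cut: chord = 2 * sqrt(r^2 - d^2)
  sp <- phantom_spec(base = "cylinder", radius = 15, height = 20,
                     cuts = list(list(point = c(9, 0, 0),
                                      normal = c(1, 0, 0), gap = 2,
                                      step = 0)))
  ph <- make_phantom(sp)
  expect_equal(ph$truth$total_area, 2 * sqrt(15^2 - 9^2) * 2)
})

test_that("phantom spec validation rejects bad geometry", {
  expect_error(phantom_spec(bone_hu = 100), "226")
  expect_error(phantom_spec(cuts = list(list(point = c(0, 0, 0),
                                             normal = c(0, 0, 1)))),
               "vertical")
  expect_error(phantom_spec(cuts = list(list(point = c(0, 0, 0),
                                             normal = c(1, 0, 0),
                                             gap = -1))),
               "gap")
  expect_error(make_phantom(phantom_spec(
    base = "cylinder", radius = 10, height = 15,
    cuts = list(list(point = c(11, 0, 0), normal = c(1, 0, 0), gap = 1,
                     step = 0)))),
    "misses")
})

test_that("phantom rendering is deterministic and labels match the volume", {
  s <- split_cylinder_spec(2, 1, r = 10, h = 12)
  p1 <- make_phantom(s)
  p2 <- make_phantom(s)
  expect_identical(p1$labels$labels, p2$labels$labels)
  expect_identical(p1$volume$voxels, p2$volume$voxels)
  expect_equal(p1$meshes[[1]]$vertices, p2$meshes[[1]]$vertices)
  # every labelled voxel is bone and vice versa
  expect_identical(p1$labels$labels > 0, p1$volume$voxels > 0)
  expect_identical(p1$truth$n_fragments, 2L)
  # seeded HU noise is reproducible
  sn <- phantom_spec(base = "cylinder", radius = 8, height = 10,
                     noise_sd = 20)
  n1 <- make_phantom(sn, seed = 5)
  n2 <- make_phantom(sn, seed = 5)
  expect_identical(n1$volume$voxels, n2$volume$voxels)
})

test_that("measured gap area tracks phantom truth and improves with finer
           voxels", {
  truth <- 2 * 15 * sqrt(2^2 + 1^2)
  err <- sapply(c(1, 0.5), function(sp) {
    ph <- make_phantom(split_cylinder_spec(2, 1, r = 15, h = 20,
                                           spacing = sp))
    res <- measure_gap_area(ph$meshes, annotations = ph$annotations)
    abs(res$total_area - truth) / truth
  })
  expect_lt(err[2], 0.1)
  expect_lt(err[2], err[1] + 0.01)
})

test_that("simulated cohorts are deterministic and carry the group structure", {
  c1 <- simulate_cohort(n = 500, seed = 11)
  c2 <- simulate_cohort(n = 500, seed = 11)
  expect_identical(c1, c2)
  expect_s3_class(c1, "cohort")
  expect_true(all(c1$followup_years > 0))
  expect_true(all(c1$gap_area_mm2 >= 0))
  expect_identical(as.character(c1$prognosis),
                   as.character(classify_prognosis(c1$gap_area_mm2)))
  expect_identical(c1$high_risk, high_risk_flag(c1$gap_area_mm2))
  # byte-identical CSV on rerun
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(simulate_cohort(n = 200, seed = 3), f1)
  write_cohort(simulate_cohort(n = 200, seed = 3), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("event fraction increases with the baseline rate", {
  rates <- c(0.001, 0.005, 0.02, 0.08)
  frac <- vapply(rates, function(r)
    mean(simulate_cohort(n = 4000, baseline_rate = r, seed = 13)$tka),
    numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("an excellent-only cohort follows the exponential baseline", {
  co <- simulate_cohort(n = 6000, gap_median = 30, gap_sdlog = 0.3,
                        baseline_rate = 0.05, seed = 21)
  expect_true(all(co$prognosis == "excellent"))
  km <- km_estimate(co$followup_years, co$tka)
  for (tt in c(2, 5, 10)) {
    expect_lt(abs(km_surv(km, tt) - exp(-0.05 * tt)), 0.02)
  }
})

test_that("Cox regression on simulated groups recovers the true hazard
           ratios", {
  co <- simulate_cohort(n = 1e5, seed = 31)
  co$good <- as.integer(co$prognosis == "good")
  co$moderate <- as.integer(co$prognosis == "moderate")
  co$poor <- as.integer(co$prognosis == "poor")
  fit <- cox_fit(co, c("good", "moderate", "poor"))
  est <- coef(fit)
  truth <- log(c(good = 1.7, moderate = 6.8, poor = 14.3))
  for (g in names(truth)) {
    expect_lt(abs(est[[g]] - truth[[g]]) / truth[[g]], 0.1)
  }
})

test_that("a cohort with expected zero events warns", {
  expect_warning(simulate_cohort(n = 20, baseline_rate = 1e-7, seed = 2),
                 "no events")
})
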