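test_that("sub-space statistics use the stated conventions", {
  s <- subspace_stats(c(1, 1, 1, 1))
  expect_equal(unname(s["sd"]), 0)
  expect_equal(unname(s["IQR"]), 0)
  expect_true(is.na(s["K"]))   # zero variance: moments undefined

  # quantile oracle with linear interpolation: for (1,2,3,4),
  # Q1 = 1 + 0.75 * 1 = 1.75, Q3 = 3.25
  s2 <- subspace_stats(c(1, 2, 3, 4))
  expect_equal(unname(s2["m"]), 2.5)
  expect_equal(unname(s2["IQR"]), 1.5)

  set.seed(12)
  z <- rnorm(1e5)
  s3 <- subspace_stats(z)
  expect_lt(abs(s3["K"] - 3), 0.1)
  expect_lt(abs(s3["Sk"]), 0.05)

  expect_true(is.na(subspace_stats(c(-1, 1))["CV"])) # zero mean
  expect_true(all(is.na(subspace_stats(numeric(0)))))
})

test_that("occupancy and distance indices count and measure correctly", {
  # labels u,u,d,nc -> occupancy of u is 0.5
  od <- occupancy_and_distance(c(0.2, 0.4), 4, cbind(c(1, -1), c(0, 0)),
                               c(0, 0))
  expect_equal(unname(od["p"]), 0.5)

  # unit circle around the centroid -> dc = 1
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- cbind(cos(th), sin(th))
  od2 <- occupancy_and_distance(rnorm(32), 32, circ, c(0, 0))
  expect_equal(unname(od2["dc"]), 1, tolerance = 1e-12)

  # mean absolute deviation about the sub-space's own mean
  od3 <- occupancy_and_distance(c(1, 3), 10, cbind(0, 0), c(0, 0))
  expect_equal(unname(od3["d"]), 1)

  expect_true(all(is.na(occupancy_and_distance(numeric(0), 5,
                                               cbind(1, 1), c(0, 0)))))
})

test_that("characterization yields exactly the 168-index schema", {
  s <- quick_subject(seed = 14, duration_s = 600)
  ch <- baro_characterize(s$series, subject_id = "s14")
  f <- coef(ch)
  expect_length(f, 168)
  expect_identical(names(f), feature_schema())
  expect_equal(sum(is.na(f)), 0L)

  # occupancies sum to one per driver
  for (drv in c("SBP", "DBP")) {
    ps <- f[paste0(drv, "-dBBIp-", c("u", "nc", "d"))]
    expect_equal(sum(ps), 1, tolerance = 1e-12)
  }

  # theta - beta identity
  for (drv in c("SBP", "DBP")) for (z in c("u", "nc", "d")) {
    expect_equal(unname(f[paste0(drv, "-dBBI_TTthetabeta-", z)]),
                 unname(f[paste0(drv, "-dBBI_TTtheta-", z)] -
                        f[paste0(drv, "-dBBI_TTbeta-", z)]),
                 tolerance = 1e-12)
  }

  # normalized areas positive for non-degenerate sub-spaces
  an <- f[grepl("dBBI_TTAn-", names(f))]
  av <- f[grepl("dBBI_TTAv-", names(f))]
  expect_true(all(an > 0))
  expect_true(all(av > 0))
})

test_that("an empty sub-space leaves its block missing, schema intact", {
  # a threshold beyond the data range forces everything into no-change
  s <- quick_subject(seed = 15, duration_s = 300)
  ch <- baro_characterize(s$series,
                          pooled_thresholds = list(SBP = 10, DBP = 10))
  f <- coef(ch)
  expect_length(f, 168)
  up_block <- f[grepl("-u$", names(f)) & grepl("^SBP", names(f))]
  expect_true(all(is.na(up_block)))
  nc_block <- f[grepl("-nc$", names(f)) & grepl("^SBP", names(f))]
  expect_true(all(!is.na(nc_block)))
})

test_that("feature names survive a CSV round trip", {
  s <- quick_subject(seed = 16, duration_s = 300)
  ft <- characterize_cohort(list(a = list(subject_id = "a",
                                          series = s$series)))
  tmp <- file.path(tempdir(), "feat.csv")
  write_feature_table(ft, tmp)
  back <- read_feature_table(tmp)
  expect_identical(names(back), names(ft))
  expect_equal(unlist(back[feature_schema()]), unlist(ft[feature_schema()]),
               tolerance = 1e-9)
  schema <- jsonlite::read_json(paste0(tmp, ".schema.json"),
                                simplifyVector = TRUE)
  expect_equal(schema$n_indices, 168)
  expect_identical(schema$indices, feature_schema())
  unlink(c(tmp, paste0(tmp, ".schema.json")))
})

test_that("global vascular statistics are reported in physical units", {
  s <- quick_subject(seed = 17, duration_s = 600)
  f <- coef(baro_characterize(s$series))
  # sd of the physical-unit dSBP series is on the mmHg scale, not 1
  expect_gt(unname(f["dSBPsd"]), 0.2)
  expect_false(isTRUE(all.equal(unname(f["dSBPsd"]), 1)))
})
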