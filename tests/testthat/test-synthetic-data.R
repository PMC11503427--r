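test_that("lognormal moment matching round-trips mean and SD exactly", {
  for (ms in list(c(1.56, 1.21), c(133, 68), c(1.77, 0.98))) {
    mm <- moment_match_lognormal(ms[1], ms[2])
    mean_back <- exp(mm$mu_log + mm$sigma_log^2 / 2)
    var_back <- (exp(mm$sigma_log^2) - 1) * exp(2 * mm$mu_log + mm$sigma_log^2)
    expect_equal(mean_back, ms[1], tolerance = 1e-9)
    expect_equal(sqrt(var_back), ms[2], tolerance = 1e-9)
  }
  # sd -> 0 limit collapses onto log(mean)
  mm0 <- moment_match_lognormal(1, 1e-8)
  expect_equal(mm0$mu_log, 0, tolerance = 1e-8)
  expect_lt(mm0$sigma_log, 1e-7)
  expect_error(moment_match_lognormal(-1, 1), "mean")
})

test_that("the dependence spec validates its correlation matrix", {
  expect_s3_class(dependence_spec(), "dependence_spec")
  bad_asym <- diag(3); bad_asym[1, 2] <- 0.5
  expect_error(dependence_spec(bad_asym), "symmetric")
  bad_diag <- 0.5 * diag(3)
  expect_error(dependence_spec(bad_diag), "unit diagonal")
  bad_psd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(dependence_spec(bad_psd), "positive semi-definite")
})

test_that("generation is bit-reproducible for a fixed seed and varies across seeds", {
  c1 <- generate_cohort(dep = dependence_spec(seed = 5))
  c2 <- generate_cohort(dep = dependence_spec(seed = 5))
  c3 <- generate_cohort(dep = dependence_spec(seed = 6))
  expect_identical(strip_cohort(c1), strip_cohort(c2))
  expect_false(identical(c1$ui_ug_L, c3$ui_ug_L))
  expect_equal(nrow(c1), 1075)
  expect_equal(as.integer(table(c1$period)), c(427L, 268L, 355L, 25L))
})

test_that("per-period sample moments sit within 3 standard errors of their targets", {
  specs <- default_period_specs()
  co <- generate_cohort(specs, dependence_spec(outlier_rate = 0, seed = 12))
  for (p in names(specs)) {
    s <- specs[[p]]
    d <- co[co$period == p, ]
    se <- function(sd) 3 * sd / sqrt(s$n)
    expect_lt(abs(mean(d$tsh_uIU_mL) - s$tsh_mean), se(s$tsh_sd))
    expect_lt(abs(mean(d$ft4_ng_dL) - s$ft4_mean), se(s$ft4_sd) + 0.03)
    expect_lt(abs(mean(d$ui_ug_L) - s$ui_mean), se(s$ui_sd))
    expect_lt(abs(sd(d$ui_ug_L) - s$ui_sd), se(s$ui_sd) * 2)
  }
})

test_that("mean absolute error of the sample mean scales like 1/sqrt(n)", {
  # 200 small replicates of one period: MAE of the UI mean should sit near
  # the theoretical sd/sqrt(n) * sqrt(2/pi)
  spec <- list(T1 = period_spec(60, 1.56, 1.21, 1.31, 0.49, 133, 68, 0.08))
  set.seed(23)
  errs <- replicate(200, {
    co <- generate_cohort(spec, dependence_spec(outlier_rate = 0,
                                                stratum_boost = 0))
    abs(mean(co$ui_ug_L) - 133)
  })
  expected_mae <- 68 / sqrt(60) * sqrt(2 / pi)
  expect_gt(mean(errs), expected_mae * 0.7)
  expect_lt(mean(errs), expected_mae * 1.3)
})

test_that("anti-TPO positivity is Bernoulli at the spec rate, independent of UI", {
  spec <- list(T1 = period_spec(2000, 1.56, 1.21, 1.31, 0.49, 133, 68, 0.2))
  co <- generate_cohort(spec, dependence_spec(seed = 29))
  rate <- mean(co$anti_tpo_pos)
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
  # no association with UI
  expect_gt(t.test(co$ui_ug_L ~ co$anti_tpo_pos)$p.value, 0.01)
})

test_that("an identity copula without boost yields independent marginals", {
  co <- generate_cohort(dep = dependence_spec(stratum_boost = 0,
                                              outlier_rate = 0, seed = 31))
  n <- nrow(co)
  expect_lt(abs(cor(co$ft4_ng_dL, co$ui_ug_L)), 3 / sqrt(n))
  expect_lt(abs(cor(co$tsh_uIU_mL, co$ui_ug_L)), 3 / sqrt(n))
  expect_lt(abs(cor(co$ft4_ng_dL, co$tsh_uIU_mL)), 3 / sqrt(n))
})

test_that("a nontrivial copula induces the requested latent correlation", {
  C <- matrix(c(1, 0, 0,  0, 1, 0.6,  0, 0.6, 1), 3)
  spec <- list(T1 = period_spec(5000, 1.56, 1.21, 1.31, 0.49, 133, 68, 0.08))
  co <- generate_cohort(spec, dependence_spec(C, stratum_boost = 0,
                                              outlier_rate = 0, seed = 37))
  # rank (copula-scale) correlation of TSH and UI recovers ~0.6
  r_latent <- cor(qnorm(rank(co$tsh_uIU_mL) / 5001),
                  qnorm(rank(co$ui_ug_L) / 5001))
  expect_lt(abs(r_latent - 0.6), 0.05)
  expect_lt(abs(cor(qnorm(rank(co$ft4_ng_dL) / 5001),
                    qnorm(rank(co$ui_ug_L) / 5001))), 3 / sqrt(5000))
})

test_that("outlier injection inflates only the UI tail and is fence-recoverable", {
  spec <- list(T1 = period_spec(800, 1.56, 1.21, 1.31, 0.49, 133, 68, 0.08))
  no_out <- generate_cohort(spec, dependence_spec(outlier_rate = 0, seed = 41))
  with_out <- generate_cohort(spec, dependence_spec(outlier_rate = 0.05,
                                                    seed = 41))
  expect_identical(no_out$tsh_uIU_mL, with_out$tsh_uIU_mL)
  n_inflated <- sum(with_out$ui_ug_L != no_out$ui_ug_L)
  expect_lt(abs(n_inflated - 0.05 * 800), 3 * sqrt(800 * 0.05 * 0.95))
  expect_true(all(with_out$ui_ug_L >= no_out$ui_ug_L))
})
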