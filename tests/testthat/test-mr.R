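test_that("IVW equals the Wald ratio at k = 1 and the common ratio under homogeneity", {
  one <- instrument_set("v1", 0.2, 0.02, 0.1, 0.01)
  expect_equal(ivw(one)$theta, 0.1 / 0.2, tolerance = 1e-12)

  hom <- instrument_set(paste0("v", 1:4), c(0.1, 0.2, 0.3, 0.4), rep(0.01, 4),
                        c(0.1, 0.2, 0.3, 0.4) * 0.7, c(0.01, 0.02, 0.01, 0.03))
  expect_equal(ivw(hom)$theta, 0.7, tolerance = 1e-12)
  expect_equal(cochran_q(hom)$q, 0, tolerance = 1e-12)
  expect_equal(cochran_q(hom)$p, 1)
})

test_that("IVW matches a weighted-least-squares-through-origin oracle", {
  bx <- c(0.1, 0.2, 0.3); by <- c(0.05, 0.10, 0.15); sey <- rep(0.01, 3)
  ins <- instrument_set(paste0("v", 1:3), bx, rep(0.02, 3), by, sey)
  expect_equal(ivw(ins)$theta, 0.5, tolerance = 1e-12)

  set.seed(31)
  bx <- rnorm(6, 0.3, 0.1); by <- 0.4 * bx + rnorm(6, 0, 0.05)
  sey <- runif(6, 0.01, 0.05)
  ins <- instrument_set(paste0("v", 1:6), bx, rep(0.02, 6), by, sey)
  expect_equal(ivw(ins)$theta,
               unname(oracle_wls(bx, by, sey, intercept = FALSE)),
               tolerance = 1e-10)
})

test_that("IVW is invariant to jointly flipping an instrument's signs", {
  set.seed(32)
  bx <- rnorm(5, 0.2, 0.1); by <- 0.3 * bx + rnorm(5, 0, 0.02)
  sey <- runif(5, 0.01, 0.03)
  ins <- instrument_set(paste0("v", 1:5), bx, rep(0.02, 5), by, sey)
  flipped <- instrument_set(paste0("v", 1:5), bx * c(-1, 1, -1, 1, 1),
                            rep(0.02, 5), by * c(-1, 1, -1, 1, 1), sey)
  expect_equal(ivw(flipped)$theta, ivw(ins)$theta, tolerance = 1e-12)
  expect_error(ivw(instrument_set("v1", 0.1, 0.01, 0.1, 0)),
               class = "loadpaths_validation_error")
})

test_that("weighted median interpolates the cumulative-weight crossing", {
  eq <- instrument_set(paste0("v", 1:3), rep(1, 3), rep(0.1, 3),
                       c(1, 2, 9), rep(0.1, 3))
  expect_equal(weighted_median(eq, n_boot = 50, seed = 1)$theta, 2)

  same <- instrument_set(paste0("v", 1:3), c(0.1, 0.2, 0.3), rep(0.01, 3),
                         c(0.1, 0.2, 0.3) * 1.4, rep(0.01, 3))
  wm <- weighted_median(same, n_boot = 200, seed = 2)
  expect_equal(wm$theta, 1.4, tolerance = 1e-12)
  expect_lt(wm$se, 0.2)

  ## unequal weights: matches the brute-force oracle
  set.seed(33)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    bx <- runif(k, 0.1, 0.5); by <- runif(k, -0.2, 0.4)
    sey <- runif(k, 0.01, 0.1)
    ins <- instrument_set(paste0("v", seq_len(k)), bx, rep(0.02, k), by, sey)
    expect_equal(weighted_median(ins, n_boot = 10, seed = rep)$theta,
                 oracle_weighted_median(bx, by, sey), tolerance = 1e-10)
  }

  ## bounded by the extreme ratios
  ins <- instrument_set(paste0("v", 1:5), runif(5, 0.1, 0.4), rep(0.02, 5),
                        rnorm(5, 0.1, 0.2), runif(5, 0.01, 0.1))
  th <- weighted_median(ins, n_boot = 10, seed = 3)$theta
  ratios <- ins$beta_outcome / ins$beta_exposure
  expect_true(th >= min(ratios) && th <= max(ratios))
  expect_error(weighted_median(instrument_set(c("a", "b"), c(1, 1), c(1, 1),
                                              c(1, 1), c(1, 1))),
               class = "loadpaths_validation_error")
})

test_that("MR-Egger recovers slope and pleiotropy intercept", {
  bx <- c(0.1, 0.25, 0.4, 0.6)
  sey <- c(0.01, 0.02, 0.015, 0.03)
  exact <- instrument_set(paste0("v", 1:4), bx, rep(0.02, 4), 0.4 * bx, sey)
  fit <- mr_egger(exact)
  expect_equal(fit$theta, 0.4, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)

  affine <- instrument_set(paste0("v", 1:4), bx, rep(0.02, 4),
                           0.4 * bx + 0.02, sey)
  fit2 <- mr_egger(affine)
  expect_equal(fit2$theta, 0.4, tolerance = 1e-10)
  expect_equal(fit2$intercept, 0.02, tolerance = 1e-10)

  ## generic weighted regression oracle
  set.seed(34)
  by <- 0.4 * bx + 0.02 + rnorm(4, 0, 0.01)
  noisy <- instrument_set(paste0("v", 1:4), bx, rep(0.02, 4), by, sey)
  fit3 <- mr_egger(noisy)
  ocoef <- oracle_wls(bx, by, sey, intercept = TRUE)
  expect_equal(fit3$intercept, unname(ocoef[1]), tolerance = 1e-10)
  expect_equal(fit3$theta, unname(ocoef[2]), tolerance = 1e-10)

  expect_error(mr_egger(instrument_set(paste0("v", 1:3), rep(0.2, 3),
                                       rep(0.02, 3), c(0.1, 0.2, 0.1),
                                       rep(0.01, 3))),
               class = "loadpaths_validation_error")
})

test_that("MR-Egger with the intercept constrained to zero reproduces IVW", {
  set.seed(35)
  bx <- runif(5, 0.1, 0.5); by <- 0.3 * bx + rnorm(5, 0, 0.03)
  sey <- runif(5, 0.01, 0.05)
  ins <- instrument_set(paste0("v", 1:5), bx, rep(0.02, 5), by, sey)
  constrained <- unname(oracle_wls(bx, by, sey, intercept = FALSE))
  expect_equal(ivw(ins)$theta, constrained, tolerance = 1e-10)
})

test_that("Cochran's Q has its closed form for two symmetric instruments", {
  ## ratios theta +/- delta with equal weights w: Q = 2 w delta^2
  bx <- c(0.2, 0.2); sey <- c(0.01, 0.01)
  delta <- 0.15
  by <- bx * c(0.5 + delta, 0.5 - delta)
  ins <- instrument_set(c("a", "b"), bx, c(0.02, 0.02), by, sey)
  w <- bx[1]^2 / sey[1]^2
  expect_equal(cochran_q(ins)$q, 2 * w * delta^2, tolerance = 1e-10)
  expect_equal(cochran_q(ins)$df, 1L)
  expect_error(cochran_q(instrument_set("a", 0.1, 0.01, 0.1, 0.01)),
               class = "loadpaths_validation_error")
})

test_that("I2_GX measures exposure-association heterogeneity", {
  ## tiny exposure SEs with distinct betas: I2 -> 1
  strong <- instrument_set(paste0("v", 1:4), c(0.1, 0.2, 0.3, 0.4),
                           rep(1e-5, 4), rep(0.1, 4), rep(0.01, 4))
  expect_gt(i2_gx(strong)$i2_gx, 0.999)
  expect_false(i2_gx(strong)$weak_flag)

  ## identical exposure betas: Q_GX = 0, I2 = 0, flag raised
  flat <- instrument_set(paste0("v", 1:4), rep(0.2, 4), rep(0.02, 4),
                         rep(0.1, 4), rep(0.01, 4))
  expect_equal(i2_gx(flat)$i2_gx, 0)
  expect_true(i2_gx(flat)$weak_flag)

  ## hand-computed toy
  bx <- c(0.1, 0.3); sex <- c(0.1, 0.2)
  ins <- instrument_set(c("a", "b"), bx, sex, c(0.05, 0.1), c(0.01, 0.01))
  w <- 1 / sex^2
  mw <- sum(w * bx) / sum(w)
  q_gx <- sum((bx - mw)^2 / sex^2)
  expect_equal(i2_gx(ins)$q_gx, q_gx, tolerance = 1e-12)
  expect_equal(i2_gx(ins)$i2_gx, max(0, (q_gx - 1) / q_gx), tolerance = 1e-12)
})

test_that("leave-one-out exposes instruments that drive the estimate", {
  hom <- instrument_set(paste0("v", 1:4), c(0.1, 0.2, 0.3, 0.4), rep(0.02, 4),
                        c(0.1, 0.2, 0.3, 0.4) * 0.7, rep(0.01, 4))
  loo <- leave_one_out(hom)
  expect_equal(nrow(loo), 4L)
  expect_true(all(abs(loo$theta - 0.7) < 1e-10))

  ## planted outlier: dropping it moves the estimate toward the common ratio
  out <- instrument_set(paste0("v", 1:4), c(0.1, 0.2, 0.3, 0.4), rep(0.02, 4),
                        c(0.1 * 0.5, 0.2 * 0.5, 0.3 * 0.5, 0.4 * 3), rep(0.01, 4))
  full <- ivw(out)$theta
  loo2 <- leave_one_out(out)
  dropped_outlier <- loo2$theta[loo2$dropped == "v4"]
  expect_lt(abs(dropped_outlier - 0.5), abs(full - 0.5))
  expect_equal(dropped_outlier, 0.5, tolerance = 1e-10)

  two <- instrument_set(c("a", "b"), c(0.1, 0.2), c(0.02, 0.02),
                        c(0.05, 0.1), c(0.01, 0.01))
  loo3 <- leave_one_out(two)
  expect_true(all(loo3$single_instrument))
})

test_that("association scan recovers per-variant effects and drops degenerate variants", {
  set.seed(36)
  n <- 3000
  d <- data.frame(age = rnorm(n, 70, 7), sex = rbinom(n, 1, 0.5))
  d$v1 <- rbinom(n, 2L, 0.3)
  d$v2 <- rbinom(n, 2L, 0.2)
  d$mono <- 0L
  d$target <- 0.5 * d$v1 + 0.2 * d$v2 + rnorm(n)
  expect_warning(assoc_scan(d, "target", c("v1", "v2", "mono"), "linear"),
                 regexp = "mono")
  scan <- suppressWarnings(assoc_scan(d, "target", c("v1", "v2", "mono"),
                                      "linear"))
  expect_equal(nrow(scan), 2L)
  expect_lt(abs(scan$beta[scan$variant_id == "v1"] - 0.5),
            3 * scan$se[scan$variant_id == "v1"])
  expect_lt(abs(scan$beta[scan$variant_id == "v2"] - 0.2),
            3 * scan$se[scan$variant_id == "v2"])

  ## noiseless linear target: beta exact, se about zero
  d$pure <- 0.5 * d$v1
  pure <- assoc_scan(d, "pure", "v1", "linear")
  expect_equal(pure$beta, 0.5, tolerance = 1e-12)
  expect_lt(pure$se, 1e-10)
})

test_that("bidirectional MR detects planted one-way causation", {
  ## measure -> outcome causation only: the measure is built from the
  ## variants, the outcome from the measure plus noise (no direct paths)
  set.seed(37)
  n <- 4000
  k <- 6
  G <- sapply(1:k, function(j) rbinom(n, 2L, runif(1, 0.2, 0.4)))
  colnames(G) <- paste0("v", 1:k)
  effects <- runif(k, 0.15, 0.3)
  m <- as.numeric(G %*% effects) + rnorm(n)
  y <- 0.5 * m + rnorm(n)
  d <- data.frame(age = rnorm(n, 70, 7), sex = rbinom(n, 1, 0.5),
                  outcome = y, icv = rnorm(n))
  d$hippocampus__volume <- m
  d <- cbind(d, as.data.frame(G))
  attr(d, "outcome_family") <- "linear"
  mc <- measure_catalog()
  meas <- mc[mc$name == "hippocampus__volume", ]
  res <- run_bidirectional(d, meas, colnames(G), wm_boot = 100, seed = 38)
  fwd <- res[res$direction == "forward" & res$method == "IVW", ]
  expect_lt(abs(fwd$theta - 0.5), 4 * fwd$se)
  expect_lt(fwd$p, 1e-4)
  ## with one measure, FDR-adjusted p equals the raw p
  expect_equal(res$p_fdr, res$p, tolerance = 1e-12)
  ## diagnostics present and well-formed
  expect_true(all(res$k == k))
  expect_true(all(res$i2_gx >= 0 & res$i2_gx <= 1))
  loo <- attr(res, "leave_one_out")
  expect_length(loo, 2L)
  expect_equal(nrow(loo[["hippocampus__volume.forward"]]), k)
})
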