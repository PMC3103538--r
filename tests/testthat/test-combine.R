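pH <- seq(0, 14, 0.1)

test_that("ensemble averaging is the pointwise mean with M tracked", {
  c1 <- new_titration_curve(pH, rep(0.2, length(pH)), "s")
  c2 <- new_titration_curve(pH, rep(0.8, length(pH)), "s")
  expect_equal(ensemble_average(list(c1))$value, c1$value)   # M = 1 identity
  avg <- ensemble_average(list(c1, c2))
  expect_equal(avg$value, rep(0.5, length(pH)))
  expect_equal(attr(avg, "M"), 2L)
  bad <- new_titration_curve(seq(0, 13, 0.1), rep(0.5, 131), "s")
  expect_error(ensemble_average(list(c1, bad)), "same pH grid")
})

test_that("the snapshot average lies between the per-snapshot extremes", {
  set.seed(4)
  curves <- lapply(1:5, function(i)
    new_titration_curve(pH, hh_protonated(pH, 4.4 + rnorm(1, 0, 0.3)), "s"))
  avg <- ensemble_average(curves)
  lo <- do.call(pmin, lapply(curves, `[[`, "value"))
  hi <- do.call(pmax, lapply(curves, `[[`, "value"))
  expect_true(all(avg$value >= lo - 1e-12 & avg$value <= hi + 1e-12))
})

test_that("regime weights satisfy the three pH-limit contracts", {
  zero <- new_titration_curve(pH, rep(0, length(pH)), "t")
  one <- new_titration_curve(pH, rep(1, length(pH)), "t")
  ## strongly acidic: theta_carb = 0, theta_amino = 0 -> glu0 weight 1
  w <- regime_weights(zero, zero)
  expect_equal(unique(w$glu0), 1)
  expect_equal(unique(w$allC), 0)
  ## neutral: carboxyls deprotonated, aminos protonated -> allC weight 1
  w <- regime_weights(one, zero)
  expect_equal(unique(w$allC), 1)
  ## strongly basic: both deprotonated -> lys0 weight 1
  w <- regime_weights(one, one)
  expect_equal(unique(w$lys0), 1)
  bad <- new_titration_curve(pH, rep(0.5, length(pH)), "t")
  bad$value[3] <- 1.5
  expect_error(regime_weights(bad, zero), "0, 1")
})

test_that("weights sum to one at every grid point on realistic curves", {
  tc <- new_titration_curve(pH, 1 - hh_protonated(pH, 4.4), "t",
                            tracked = "deprotonated")
  ta <- new_titration_curve(pH, 1 - hh_protonated(pH, 10.4), "t",
                            tracked = "deprotonated")
  w <- regime_weights(tc, ta)
  expect_lt(max(abs(rowSums(w[, c("allC", "glu0", "lys0")]) - 1)), 1e-9)
  expect_true(all(w$allC >= 0 & w$glu0 >= 0 & w$lys0 >= 0))
  expect_true(all(w$allC <= 1 & w$glu0 <= 1 & w$lys0 <= 1))
})

test_that("combining regimes is a convex combination", {
  mk <- function(v) new_titration_curve(pH, rep(v, length(pH)), "s")
  curves <- list(allC = mk(0.0), glu0 = mk(0.5), lys0 = mk(1.0))
  wdf <- structure(data.frame(pH = pH, allC = 0.2, glu0 = 0.3, lys0 = 0.5),
                   class = c("regime_weights", "data.frame"))
  out <- combine_regimes(curves, wdf)
  expect_equal(unique(out$value), 0.65)
  ## identical curves: weights are irrelevant
  same <- list(allC = mk(0.3), glu0 = mk(0.3), lys0 = mk(0.3))
  expect_equal(unique(combine_regimes(same, wdf)$value), 0.3)
  ## degenerate weights return one regime's curve
  w100 <- structure(data.frame(pH = pH, allC = 0, glu0 = 1, lys0 = 0),
                    class = c("regime_weights", "data.frame"))
  expect_equal(combine_regimes(curves, w100)$value, curves$glu0$value)
  expect_error(combine_regimes(curves[1:2], wdf), "missing regime")
  ## bounded by the regime extremes
  tcurves <- list(allC = mk(0.1), glu0 = mk(0.4), lys0 = mk(0.9))
  cm <- combine_regimes(tcurves, wdf)
  expect_true(all(cm$value >= 0.1 & cm$value <= 0.9))
})

test_that("pk_half finds the Henderson-Hasselbalch midpoint by interpolation", {
  for (pk in c(4.4, 7.37, 9.93)) {
    cv <- new_titration_curve(pH, hh_protonated(pH, pk), "s", pk_mod = pk)
    expect_equal(as.numeric(pk_half(cv)), pk, tolerance = 0.005)
  }
})

test_that("pk_half is equivariant under a pH shift of the curve", {
  cv <- new_titration_curve(pH, hh_protonated(pH, 5.2), "s", pk_mod = 5.2)
  shifted <- new_titration_curve(pH, hh_protonated(pH - 1, 5.2), "s",
                                 pk_mod = 6.2)
  expect_equal(as.numeric(pk_half(shifted)) - as.numeric(pk_half(cv)), 1,
               tolerance = 1e-9)
})

test_that("pk_half flags multimodal and out-of-range curves", {
  ## non-monotone curve crossing 0.5 three times
  v <- hh_protonated(pH, 4) + 0.7 * exp(-(pH - 8)^2)
  v <- pmin(v, 1)
  cv <- new_titration_curve(pH, v, "s", pk_mod = 4)
  res <- pk_half(cv)
  expect_true(attr(res, "multimodal"))
  expect_equal(as.numeric(res), 4, tolerance = 0.05)  # crossing nearest pk_mod
  ## curve that never reaches 0.5
  flat <- new_titration_curve(pH, rep(0.9, length(pH)), "s")
  res2 <- pk_half(flat)
  expect_true(is.na(res2))
  expect_true(attr(res2, "out_of_range"))
})
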