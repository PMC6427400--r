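ref_fft_a <- normal_model(116.40, 10.09, 46)
ref_fft_c <- normal_model(162.25, 13.06, 97)
ref_diff_a <- normal_model(110.50, 12.56, 62)
ref_diff_c <- normal_model(158.00, 14.95, 100)
ref_aut_a <- normal_model(113.75, 7.97, 66)
ref_aut_c <- normal_model(160.81, 10.71, 111)

# minimal species profiles around the reference models, ungated
toy_profile <- function(label, aut, fft, diff) {
  list(species = label,
       models = list(f0_aut = aut, f0_fft = fft, f1_minus_f0 = diff),
       gates = list(f0_aut = c(-Inf, Inf), f0_fft = c(-Inf, Inf),
                    f1_minus_f0 = c(-Inf, Inf)))
}
prof_a <- toy_profile("fraterculus", ref_aut_a, ref_fft_a, ref_diff_a)
prof_c <- toy_profile("capitata", ref_aut_c, ref_fft_c, ref_diff_c)

test_that("equal-SD densities intersect at the midpoint of the means", {
  expect_equal(gaussian_intersection(113.75, 9, 160.81, 9), 137.28)
})

test_that("density intersection matches a grid search", {
  xs <- gaussian_intersection(116.40, 10.09, 162.25, 13.06)
  expect_equal(xs, oracle_intersection(116.40, 10.09, 162.25, 13.06),
               tolerance = 0.01)
  expect_equal(round(xs, 1), 137.1)

  set.seed(61)
  for (i in 1:100) {
    mu1 <- runif(1, 50, 150); mu2 <- mu1 + runif(1, 10, 100)
    sd1 <- runif(1, 3, 25); sd2 <- runif(1, 3, 25)
    xs <- gaussian_intersection(mu1, sd1, mu2, sd2)
    expect_lt(abs(xs - oracle_intersection(mu1, sd1, mu2, sd2)), 0.01)
  }
  expect_error(gaussian_intersection(100, 1, 100, 2), "differ")
})

test_that("misclassification probabilities reproduce the reported overlaps", {
  fft <- misclassification_probs(ref_fft_a, ref_fft_c)
  expect_lt(abs(fft$p_low_as_high - 0.0201), 5e-4)
  expect_lt(abs(fft$p_high_as_low - 0.0270), 5e-4)

  dif <- misclassification_probs(ref_diff_a, ref_diff_c)
  expect_lt(abs(dif$p_low_as_high - 0.0375), 5e-4)

  same <- misclassification_probs(normal_model(100, 5, 10),
                                  normal_model(100, 5, 10))
  expect_equal(c(same$p_low_as_high, same$p_high_as_low), c(0.5, 0.5))
})

test_that("swapping the models exchanges the two error probabilities", {
  p <- misclassification_probs(ref_aut_a, ref_aut_c)
  expect_error(misclassification_probs(ref_aut_c, ref_aut_a), "smaller")
  # mirror both models around a point: roles exchange
  mirror <- function(m) normal_model(300 - m$mu, m$sigma, m$n)
  q <- misclassification_probs(mirror(ref_aut_c), mirror(ref_aut_a))
  expect_equal(q$p_low_as_high, p$p_high_as_low, tolerance = 1e-12)
  expect_equal(q$p_high_as_low, p$p_low_as_high, tolerance = 1e-12)
})

test_that("per-feature votes and majority labels behave as designed", {
  model <- build_classifier(prof_a, prof_c)
  lo <- classify_event(list(f0_aut = 113, f0_fft = 114, f1_minus_f0 = 112), model)
  expect_equal(lo$label, "fraterculus")
  expect_length(lo$votes, 3)
  expect_equal(lo$confidence, 1)

  hi <- classify_event(list(f0_aut = 161, f0_fft = 163, f1_minus_f0 = 158), model)
  expect_equal(hi$label, "capitata")
  expect_equal(hi$confidence, 1)

  # one valid feature exactly on the boundary: no usable vote -> unknown
  xs <- model$boundaries$f0_aut$x_star
  tie <- classify_event(list(f0_aut = xs, f0_fft = NA, f1_minus_f0 = NA), model)
  expect_equal(tie$label, "unknown")

  none <- classify_event(list(f0_aut = NA, f0_fft = NA, f1_minus_f0 = NA), model)
  expect_equal(none$label, "unknown")

  # split 2-1 vote follows the majority with confidence 2/3
  split <- classify_event(list(f0_aut = 113, f0_fft = 163, f1_minus_f0 = 112), model)
  expect_equal(split$label, "fraterculus")
  expect_equal(split$confidence, 2 / 3)
})

test_that("likelihood rule agrees with majority on clear cases", {
  model <- build_classifier(prof_a, prof_c, rule = "likelihood")
  expect_equal(classify_event(list(f0_aut = 113, f0_fft = 114,
                                   f1_minus_f0 = 112), model)$label,
               "fraterculus")
  expect_equal(classify_event(list(f0_aut = 161, f0_fft = 163,
                                   f1_minus_f0 = 158), model)$label,
               "capitata")
})

test_that("empirical single-feature error matches the Gaussian-overlap tails", {
  set.seed(62)
  n <- 2000
  feats <- data.frame(
    f0_aut = c(rnorm(n, ref_aut_a$mu, ref_aut_a$sigma),
               rnorm(n, ref_aut_c$mu, ref_aut_c$sigma)),
    f0_fft = NA_real_, f1_minus_f0 = NA_real_,
    label = rep(c("fraterculus", "capitata"), each = n))
  model <- build_classifier(prof_a, prof_c)
  ev <- evaluate_classifier(model, feats)
  p <- misclassification_probs(ref_aut_a, ref_aut_c)
  expected <- (p$p_low_as_high + p$p_high_as_low) / 2
  mc_se <- sqrt(expected * (1 - expected) / (2 * n))
  expect_lt(abs(ev$per_feature$f0_aut$rate - expected), 3 * mc_se)
})

test_that("the intersection boundary is the minimum-error threshold", {
  set.seed(63)
  n <- 4000
  a <- rnorm(n, ref_aut_a$mu, ref_aut_a$sigma)
  c_ <- rnorm(n, ref_aut_c$mu, ref_aut_c$sigma)
  err_at <- function(thr) (sum(a > thr) + sum(c_ < thr)) / (2 * n)
  xs <- gaussian_intersection(ref_aut_a$mu, ref_aut_a$sigma,
                              ref_aut_c$mu, ref_aut_c$sigma)
  expect_lt(err_at(xs), err_at(xs - ref_aut_a$sigma))
  expect_lt(err_at(xs), err_at(xs + ref_aut_c$sigma))
})

test_that("degenerate evaluation inputs do not crash", {
  model <- build_classifier(prof_a, prof_c)
  feats <- data.frame(f0_aut = NA_real_, f0_fft = NA_real_,
                      f1_minus_f0 = NA_real_,
                      label = "fraterculus")
  ev <- evaluate_classifier(model, feats)
  expect_equal(ev$n_unknown, 1)
  expect_true(is.na(ev$error_rate))

  sep <- data.frame(f0_aut = c(100, 180), f0_fft = c(100, 180),
                    f1_minus_f0 = c(100, 180),
                    label = c("fraterculus", "capitata"))
  expect_equal(evaluate_classifier(model, sep)$error_rate, 0)
})
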