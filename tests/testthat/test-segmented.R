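test_that("noiseless piecewise data are recovered exactly from any start", {
  sim <- mk_piecewise(n_id = 6, psi = 35, slope_below = 0, slope_above = 2,
                      intercept = 1)
  d <- sim$points
  for (start in c(30, 33, 38, 41)) {
    f <- suppressWarnings(fit_segmented_lmm(d, "y", psi_init = start))
    expect_equal(f$psi, 35, tolerance = 1e-6)
    expect_equal(f$slope_below, 0, tolerance = 1e-8)
    expect_equal(f$slope_above, 2, tolerance = 1e-8)
    expect_true(f$converged)
  }
})

test_that("breakpoint estimates are equivariant to shifts and scales", {
  sim <- mk_piecewise(n_id = 8, psi = 36, slope_above = 0.05,
                      intercept = 0.05, rand_sd = 0.01, resid_sd = 0.01,
                      ta_jitter = 0.5, seed = 31)
  d <- sim$points
  f0 <- fit_segmented_lmm(d, "y")
  d_shift <- d; d_shift$ta <- d$ta + 5
  f_shift <- fit_segmented_lmm(d_shift, "y")
  expect_equal(f_shift$psi, f0$psi + 5, tolerance = 1e-3)
  d_scale <- d; d_scale$y <- d$y * 10
  f_scale <- fit_segmented_lmm(d_scale, "y")
  expect_equal(f_scale$psi, f0$psi, tolerance = 1e-3)
  expect_equal(f_scale$slope_above, f0$slope_above * 10, tolerance = 1e-3)
})

test_that("segmented never fits worse than linear on the same data by ML", {
  for (seed in 1:5) {
    sim <- mk_piecewise(n_id = 6, psi = 37, slope_above = 0.03,
                        intercept = 0.05, rand_sd = 0.01, resid_sd = 0.02,
                        ta_jitter = 0.5, seed = seed)
    lin <- fit_lmm(sim$points, y ~ ta, method = "ML")
    seg <- tryCatch(suppressWarnings(fit_segmented_lmm(sim$points, "y")),
                    error = function(e) NULL)
    if (!is.null(seg)) expect_gte(seg$loglik, lin$loglik - 1e-4)
  }
})

test_that("the mixed fit collapses to pooled OLS without grouping variance", {
  sim <- mk_piecewise(n_id = 6, psi = 36, slope_below = 0.02,
                      slope_above = 0.02, intercept = 1, rand_sd = 0,
                      resid_sd = 0.05, ta_jitter = 0.5, seed = 12)
  d <- sim$points
  f <- fit_lmm(d, y ~ ta, method = "REML")
  ols <- lm(y ~ ta, data = d)
  expect_equal(f$coefficients$estimate[2], unname(coef(ols)[2]),
               tolerance = 1e-3)
})

test_that("variance components are recovered on average", {
  vi <- vr <- numeric(50)
  for (s in 1:50) {
    sim <- mk_piecewise(n_id = 13, psi = 36, slope_below = 0.05,
                        slope_above = 0.05, intercept = 1, rand_sd = 0.5,
                        resid_sd = 0.3, ta_jitter = 0.5, seed = 1000 + s)
    f <- fit_lmm(sim$points, y ~ ta, method = "REML")
    vi[s] <- f$var_individual; vr[s] <- f$var_residual
  }
  expect_lt(abs(mean(vi) - 0.25) / 0.25, 0.25)
  expect_lt(abs(mean(vr) - 0.09) / 0.09, 0.25)
})

test_that("a balanced symmetric design gives a null group coefficient", {
  set.seed(44)
  d <- expand.grid(id = sprintf("i%02d", 1:10), ta = c(28, 32, 36, 40))
  d$sex <- ifelse(as.integer(sub("i", "", d$id)) <= 5, "female", "male")
  d$y <- 0.05 + 0.01 * d$ta + rnorm(nrow(d), 0, 0.01)
  f <- fit_lmm(d, y ~ ta + sex, method = "REML")
  sex_coef <- f$coefficients[grepl("sex", f$coefficients$term), ]
  expect_lt(abs(sex_coef$estimate), 3 * sex_coef$se)
})

test_that("model choice prefers the truth on clear-cut data", {
  # strong breakpoint: segmented wins decisively
  sim_seg <- mk_piecewise(n_id = 8, psi = 36, slope_above = 0.1,
                          intercept = 0.05, rand_sd = 0.01, resid_sd = 0.01,
                          ta_jitter = 0.5, seed = 5)
  lin <- fit_lmm(sim_seg$points, y ~ ta, method = "ML")
  seg <- fit_segmented_lmm(sim_seg$points, "y")
  ch <- choose_model(lin, seg)
  expect_equal(ch$preferred, "segmented")
  expect_lt(ch$p_value, 1e-6)
  expect_equal(ch$df, 2L)
  # p-values live in [0, 1]
  expect_gte(ch$p_value, 0); expect_lte(ch$p_value, 1)
})

test_that("breakpoint comparison follows interval overlap", {
  sim <- mk_piecewise(n_id = 8, psi = 36, slope_above = 0.1,
                      intercept = 0.05, rand_sd = 0.005, resid_sd = 0.005,
                      ta_jitter = 0.5, seed = 9)
  f <- fit_segmented_lmm(sim$points, "y")
  # reference per-sex intervals: disjoint in both variables
  a <- f; a$psi_ci <- c(36.9, 38.6)
  b <- f; b$psi_ci <- c(31.3, 34.8)
  cmp <- compare_breakpoints(a, b)
  expect_true(cmp$significant)
  expect_equal(cmp$gap, 36.9 - 34.8, tolerance = 1e-10)
  a2 <- f; a2$psi_ci <- c(33.1, 35.9)
  b2 <- f; b2$psi_ci <- c(27.6, 28.8)
  expect_true(compare_breakpoints(a2, b2)$significant)
  same <- compare_breakpoints(a, a)
  expect_false(same$significant)
  nc <- f; nc$converged <- FALSE
  expect_error(compare_breakpoints(nc, b), "converged")
})

test_that("backward elimination drops null terms and keeps real ones", {
  gen_two_sex <- function(seed, mass_beta = 0, inter_beta = 0) {
    set.seed(seed)
    d <- expand.grid(id = sprintf("i%02d", 1:12), ta = c(28, 32, 36, 40, 42))
    idx <- as.integer(sub("i", "", d$id))
    d$sex <- ifelse(idx <= 6, "female", "male")
    mass <- rnorm(12, 8, 1)[idx]
    d$mass_g <- mass
    b <- rnorm(12, 0, 0.01)[idx]
    d$y <- 0.05 + b + 0.01 * d$ta + mass_beta * mass +
      inter_beta * d$ta * (d$sex == "male") + rnorm(nrow(d), 0, 0.01)
    d
  }
  spec <- model_spec("y", c("ta", "sex", "mass", "ta:sex", "ta:mass"))
  # mass truly null: eliminated in most replicates
  dropped <- logical(20)
  for (s in 1:20) {
    red <- suppressWarnings(reduce_model(gen_two_sex(s), spec))
    dropped[s] <- !"mass" %in% red$spec$fixed
  }
  expect_gte(mean(dropped), 0.8)
  # strong Ta x Sex interaction: retained
  kept <- logical(10)
  for (s in 1:10) {
    red <- suppressWarnings(reduce_model(gen_two_sex(s, inter_beta = 0.02),
                                         spec))
    kept[s] <- "ta:sex" %in% red$spec$fixed
  }
  expect_gte(mean(kept), 0.9)
  # a single-term model comes back unchanged
  red1 <- suppressWarnings(reduce_model(gen_two_sex(1), model_spec("y", "ta")))
  expect_equal(red1$spec$fixed, "ta")
  expect_equal(nrow(red1$path), 0)
})

test_that("model specs respect marginality and always keep Ta", {
  sp <- model_spec("y", c("ta:sex"))
  expect_true(all(c("ta", "sex") %in% sp$fixed))
  expect_error(model_spec("y", "elevation"), "unknown")
})

test_that("estimated marginal means match raw and brute-force references", {
  # balanced, no covariates: group raw means exactly
  set.seed(21)
  d <- expand.grid(id = sprintf("i%02d", 1:8), ta = c(30, 35, 40))
  idx <- as.integer(sub("i", "", d$id))
  d$sex <- ifelse(idx <= 4, "female", "male")
  d$y <- 1 + 0.1 * d$ta + 0.5 * (d$sex == "male") + rnorm(nrow(d), 0, 0.05)
  f <- fit_lmm(d, model_spec("y", c("ta", "sex")), method = "REML")
  em <- estimated_marginal_means(f, by = "sex")
  raw <- tapply(d$y, d$sex, mean)
  expect_equal(sort(em$emmean), sort(as.numeric(raw)), tolerance = 1e-6)
  # unbalanced with covariate: equals prediction averaged over the grid
  d2 <- d[-(1:5), ]
  f2 <- fit_lmm(d2, model_spec("y", c("ta", "sex")), method = "REML")
  em2 <- estimated_marginal_means(f2, by = "sex")
  beta <- nlme::fixef(f2$fit)
  brute_f <- beta["(Intercept)"] + beta["ta"] * mean(d2$ta)
  brute_m <- brute_f + beta[grep("sex", names(beta))]
  expect_equal(em2$emmean[em2$sex == "female"], unname(brute_f),
               tolerance = 1e-6)
  expect_equal(em2$emmean[em2$sex == "male"], unname(brute_m),
               tolerance = 1e-6)
  # grouping term absent from the model
  f3 <- fit_lmm(d, model_spec("y", "ta"), method = "REML")
  expect_error(estimated_marginal_means(f3, by = "sex"), "not in the fitted")
})

test_that("delta-method and bootstrap intervals agree on a clean breakpoint", {
  sim <- mk_piecewise(n_id = 10, psi = 36, slope_above = 0.1,
                      intercept = 0.05, rand_sd = 0.01, resid_sd = 0.01,
                      ta_jitter = 0.5, seed = 77)
  d <- sim$points
  f <- fit_segmented_lmm(d, "y")
  delta_w <- diff(f$psi_ci)
  set.seed(101)
  ids <- unique(d$id)
  boots <- replicate(500, {
    take <- sample(ids, replace = TRUE)
    db <- do.call(rbind, lapply(seq_along(take), function(j) {
      dj <- d[d$id == take[j], ]; dj$id <- sprintf("b%02d", j); dj
    }))
    out <- tryCatch(suppressWarnings(
      fit_segmented_lmm(db, "y", psi_init = f$psi)$psi),
      error = function(e) NA_real_)
    out
  })
  boot_w <- diff(quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  expect_lt(abs(boot_w - delta_w) / boot_w, 0.3)
})

test_that("strictly linear data leave no estimable inflection", {
  sim <- mk_piecewise(n_id = 8, psi = 36, slope_below = 0.05,
                      slope_above = 0.05, intercept = 1, rand_sd = 0.02,
                      resid_sd = 0.05, ta_jitter = 0.5, seed = 3)
  lin <- fit_lmm(sim$points, y ~ ta, method = "ML")
  seg <- tryCatch(suppressWarnings(fit_segmented_lmm(sim$points, "y")),
                  error = function(e) NULL)
  no_inflection <- is.null(seg) ||
    choose_model(lin, seg)$preferred == "linear" ||
    diff(seg$psi_ci) > 0.8 * diff(range(sim$points$ta))
  expect_true(no_inflection)
})
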