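test_that("chi-square definition", {
  sig1 <- list(times = 0, amplitudes = 2 + 0.37)  # residual 2 at t=0 vs L
  p <- relax_params(Ss = 0, T2s_star = 20, b = 0.1, L = 0.37, T2L_star = 400)
  expect_equal(fid_chi2(sig1, 1, p), 4)
  # residuals (1, -1, 2) with unit sigma -> 6
  t3 <- c(0, 1, 2)
  model_vals <- fid_model(1, p, t3)
  sig3 <- list(times = t3, amplitudes = model_vals + c(1, -1, 2))
  expect_equal(fid_chi2(sig3, 1, p), 6, tolerance = 1e-12)
  # noise-free data at the generating parameters -> 0
  truth <- default_truth()
  sig0 <- gen_fid(truth, 2, acquisition_settings(noise_sd = 0))
  expect_equal(fid_chi2(sig0, 2, truth), 0)
})

test_that("Metropolis acceptance rule and chain record are consistent", {
  # delta chi2 = 2 -> acceptance probability exp(-1) = 0.3679; check by
  # long-run frequency on a two-state-like landscape is indirect, so check
  # the invariant instead: recorded chi2_min never exceeds chi2 at init
  truth <- default_truth()
  sig <- gen_fid(truth, 2, acquisition_settings(noise_sd = 0.01, seed = 2))
  init <- relax_params(Sg = 0.4, T2g_star = 14, Ss = 0.2, T2s_star = 22,
                       b = 0.3, L = 0.4, T2L_star = 350)
  ch <- run_mcmc(sig, 2, init, steps = 2000, seed = 5)
  expect_lte(ch$chi2_min, fid_chi2(sig, 2, init))
  expect_true(all(ch$chi2_values >= 0))
  expect_gte(ch$acceptance_rate, 0)
  expect_lte(ch$acceptance_rate, 1)
  # samples respect bounds (amplitudes non-negative, times positive)
  expect_true(all(ch$samples[, "Ss"] >= 0))
  expect_true(all(ch$samples[, "T2s_star"] > 0))
})

test_that("same seed gives an identical chain", {
  truth <- default_truth()
  sig <- gen_fid(truth, 2, acquisition_settings(noise_sd = 0.01, seed = 2))
  ch1 <- run_mcmc(sig, 2, truth, steps = 800, seed = 9)
  ch2 <- run_mcmc(sig, 2, truth, steps = 800, seed = 9)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$chi2_values, ch2$chi2_values)
})

test_that("Gaussian posterior: chain mean and sd match the conjugate closed form", {
  # linear model y = a t with known sigma: posterior of a is Gaussian with
  # mean sum(t y)/sum(t^2) and sd sigma/sqrt(sum(t^2))
  t <- seq(0, 1, length.out = 50)
  sigma <- 0.1
  set.seed(11)
  y <- 2 * t + stats::rnorm(50, 0, sigma)
  chi2_fun <- function(v) sum(((y - v[["a"]] * t) / sigma)^2)
  ch <- metropolis_chain(chi2_fun, c(a = 1), c(a = -10), c(a = 10),
                         steps = 50000, seed = 3)
  post <- ch$samples[(ch$burn_in + 1):nrow(ch$samples), "a"]
  mean_an <- sum(t * y) / sum(t^2)
  sd_an <- sigma / sqrt(sum(t^2))
  expect_lt(abs(mean(post) - mean_an), 3 * sd_an / sqrt(100))  # generous MC error
  expect_lt(abs(stats::sd(post) / sd_an - 1), 0.2)
  # marginal histogram sd agrees too
  pdf_a <- marginal_pdf(ch, "a")
  expect_lt(abs(pdf_a$mode - mean_an), 3 * sd_an)
})

test_that("marginal pdf normalises and handles constant chains", {
  chi2_fun <- function(v) 0  # flat landscape, all proposals accepted
  ch <- metropolis_chain(chi2_fun, c(a = 0.5), c(a = 0), c(a = 1),
                         steps = 2000, seed = 1)
  p <- marginal_pdf(ch, "a")
  expect_equal(sum(p$mass), 1, tolerance = 1e-12)
  expect_equal(sum(p$density * diff(p$breaks)), 1, tolerance = 1e-12)
  # constant chain: zero-width proposals never accepted off the start point
  ch_const <- metropolis_chain(function(v) 1e9 * (v[["a"]] != 0.5),
                               c(a = 0.5), c(a = 0), c(a = 1),
                               steps = 500, proposal_sd = c(a = 1e-30), seed = 1)
  p_const <- marginal_pdf(ch_const, "a")
  expect_equal(sum(p_const$mass > 0), 1)
})

test_that("model comparison selects the richer model on model-2 data", {
  truth <- default_truth()
  sig <- gen_fid(truth, 2, acquisition_settings(noise_sd = 0.005, seed = 3))
  f2 <- fit_fid(sig, 2)
  f1 <- fit_fid(sig, 1)
  ch2 <- run_mcmc(sig, 2, f2$params, steps = 2000, seed = 21)
  ch1 <- run_mcmc(sig, 1, f1$params, steps = 2000, seed = 22)
  cmp <- model_compare(ch1, ch2)
  expect_equal(cmp$selected, 2L)
  # oracle: direct least-squares chi2 ordering agrees
  expect_gt(f1$chi2_min, f2$chi2_min)
})

test_that("tie goes to the model with fewer parameters", {
  truth <- default_truth()
  sig <- gen_fid(truth, 2, acquisition_settings(noise_sd = 0.01, seed = 4))
  ch2 <- run_mcmc(sig, 2, truth, steps = 2000, seed = 1)
  cmp <- model_compare(ch2, ch2)
  expect_equal(cmp$selected, 1L)
})

test_that("chains from different data refuse comparison", {
  truth <- default_truth()
  sig_a <- gen_fid(truth, 2, acquisition_settings(noise_sd = 0.01, seed = 1))
  sig_b <- gen_fid(truth, 2, acquisition_settings(noise_sd = 0.01, seed = 2))
  ch_a <- run_mcmc(sig_a, 2, truth, steps = 2000, seed = 1)
  ch_b <- run_mcmc(sig_b, 2, truth, steps = 2000, seed = 1)
  expect_error(model_compare(ch_a, ch_b), "same data")
})

test_that("on model-1 data the extra parameter yields only a modest gain", {
  # nested-model behaviour: chi2 improvement of model 2 over model 1 on
  # model-1 data is of order one unit, not a systematic detection
  truth1 <- relax_params(Sg = 0, T2g_star = 12, Ss = 0.5, T2s_star = 25,
                         b = 0.45, L = 0.37, T2L_star = 400)
  gains <- vapply(1:8, function(s) {
    sig <- gen_fid(truth1, 1, acquisition_settings(noise_sd = 0.005, seed = s))
    f1 <- fit_fid(sig, 1, init = truth1)
    # start the richer model at the nested solution so its fit can only improve
    init2 <- relax_params(Sg = 0, T2g_star = 12, Ss = f1$params$Ss,
                          T2s_star = f1$params$T2s_star, b = f1$params$b,
                          L = f1$params$L, T2L_star = f1$params$T2L_star)
    f2 <- fit_fid(sig, 2, init = init2)
    f1$chi2_min - f2$chi2_min
  }, 0)
  expect_true(all(gains >= -1e-6))
  # median improvement consistent with ~2 extra free parameters
  expect_lt(stats::median(gains), 10)
})
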