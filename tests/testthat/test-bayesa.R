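# Oracle checks of each Gibbs conditional against its closed form, then
# fit-level behaviour of the sampler.

test_that("truncated-normal draws match closed-form moments and bounds", {
  set.seed(1)
  x <- segpred:::.cpp_rtruncnorm(100000, 0, 1, -Inf, 0)
  m_exp <- -dnorm(0) / pnorm(0)  # mean of N(0,1) truncated to (-Inf, 0]
  v_exp <- 1 - m_exp^2           # E[X^2] = 1 for half-normal at 0
  expect_lt(abs(mean(x) - m_exp), 3 * sqrt(v_exp / length(x)))
  expect_true(all(x <= 0))
  y <- segpred:::.cpp_rtruncnorm(10000, 2, 0.5, 1, 1.5)
  expect_true(all(y > 1 & y <= 1.5))
})

test_that("coefficient conditional matches the conjugate closed form", {
  set.seed(2)
  # single column, flat prior: posterior is N(wty/wtw, sigma2_e/wtw)
  w <- c(1, 2, -1, 0.5); yv <- c(0.3, 1.9, -0.7, 0.8); s2e <- 0.49
  wtw <- sum(w^2); wty <- sum(w * yv)
  b <- segpred:::.cpp_coef_draws(200000, wtw, wty, s2e, Inf)
  expect_lt(abs(mean(b) - wty / wtw), 4 * sqrt(s2e / wtw / length(b)))
  expect_lt(abs(var(b) - s2e / wtw), 0.02 * s2e / wtw)
  # shrinkage: prior variance -> 0 collapses the coefficient to 0
  b0 <- segpred:::.cpp_coef_draws(2000, wtw, wty, s2e, 1e-12)
  expect_lt(max(abs(b0)), 1e-4)
  # empty column -> prior draw N(0, sigma2_b)
  bp <- segpred:::.cpp_coef_draws(100000, 0, 0, s2e, 0.25)
  expect_lt(abs(mean(bp)), 4 * sqrt(0.25 / 1e5))
  expect_lt(abs(var(bp) - 0.25), 0.01)
  # general case vs closed form: c = wtw + s2e/s2b
  s2b <- 0.1; cc <- wtw + s2e / s2b
  bg <- segpred:::.cpp_coef_draws(200000, wtw, wty, s2e, s2b)
  expect_lt(abs(mean(bg) - wty / cc), 4 * sqrt(s2e / cc / length(bg)))
  expect_lt(abs(var(bg) - s2e / cc), 0.02 * s2e / cc)
})

test_that("scaled-inverse-chi-square draws match an independent inverse-gamma oracle", {
  set.seed(3)
  nu <- 4; S2 <- 0.004
  x <- segpred:::.cpp_rinvchisq(100000, nu, S2)
  # mean nu S2 / (nu - 2) = 0.008; compare within 3 SE (variance is finite
  # only in the tail-trimmed sense for nu = 4, so use a trimmed check too)
  expect_lt(abs(median(x) - nu * S2 / qchisq(0.5, nu)), 2e-4)
  # distributional match: Inv-chisq(nu, S2) == 1 / Gamma(nu/2, rate = nu S2/2)
  y <- 1 / rgamma(100000, shape = nu / 2, rate = nu * S2 / 2)
  expect_gt(suppressWarnings(stats::ks.test(x, y)$p.value), 0.001)
  # flat-prior residual update: Inv-chisq(n - 2, SSE/(n - 2))
  n <- 30; sse <- 12.5
  z <- segpred:::.cpp_rinvchisq(100000, n - 2, sse / (n - 2))
  zo <- 1 / rgamma(100000, shape = (n - 2) / 2, rate = sse / 2)
  expect_gt(suppressWarnings(stats::ks.test(z, zo)$p.value), 0.001)
})

test_that("cut-point conditional is uniform on the category gap", {
  set.seed(4)
  # M = 3, categories perfectly separated: category 2 latents max at 0.4,
  # category 3 latents min at 1.3 -> K_2 ~ Uniform(0.4, 1.3)
  y <- c(-0.5, -0.2, 0.1, 0.4, 1.3, 1.9)
  s <- c(1L, 1L, 2L, 2L, 3L, 3L)
  draws <- replicate(20000, segpred:::.cpp_cutpoint_draw(c(0, 1), y, s, 3L)[2])
  expect_true(all(draws > 0.4 & draws < 1.3))
  expect_lt(abs(mean(draws) - (0.4 + 1.3) / 2), 4 * (1.3 - 0.4) / sqrt(12 * 20000))
  expect_lt(abs(var(draws) - (1.3 - 0.4)^2 / 12), 0.01)
  # M = 2: no free cut-points, draw returns K_1 = 0 unchanged
  expect_identical(segpred:::.cpp_cutpoint_draw(c(0), y, pmin(s, 2L), 2L), 0)
})

test_that("MCMC schedule bookkeeping retains the right number of samples", {
  expect_equal(mcmc_config(1000, 0, 1)$retained, 1000L)
  expect_equal(mcmc_config(600, 100, 10)$retained, 50L)
  expect_error(mcmc_config(100, 100, 1), "exceed")
  sim <- shared_sim()
  tr <- sim_trait(sim$panel, n_qtl = 3, h2 = 0.9, seed = 8)
  fit <- bayesA(sim$panel, tr$phenotype, response = "gaussian",
                mcmc = mcmc_config(300, 100, 10), seed = 9)
  expect_equal(fit$retained, 20L)
  expect_equal(ncol(fit$beta), 20L)
  expect_equal(length(fit$sigma2_e), 20L)
})

test_that("noiseless single-marker trait is recovered with vanishing residual variance", {
  set.seed(10)
  calls <- matrix(paste(sample(c("A", "B"), 60, TRUE),
                        sample(c("A", "B"), 60, TRUE), sep = "|"),
                  30, 2, dimnames = list(paste0("i", 1:30), c("q", "neutral")))
  pan <- marker_panel(calls)
  X <- build_allele_design(pan)
  slope <- 1.7
  y <- slope * X[, "q:A"]  # exactly linear in the dosage of allele A
  fit <- bayesA(pan, y, response = "gaussian",
                mcmc = mcmc_config(3000, 1000, 5), seed = 11)
  bv <- predict(fit, pan)
  expect_gt(cor(bv, y), 0.999)
  # contrast between A and B effects recovers the slope
  b <- coef(fit)
  expect_equal(unname(b["q:A"] - b["q:B"]) / 2, slope / 2, tolerance = 0.02)
  expect_lt(mean(fit$sigma2_e), 0.01)
})

test_that("pure-noise phenotypes are shrunk toward zero effects", {
  sim <- shared_sim()
  set.seed(12)
  y <- rnorm(84)
  fit <- bayesA(sim$panel, y, response = "gaussian",
                mcmc = mcmc_config(1500, 500, 5), seed = 13)
  expect_lt(mean(abs(coef(fit))), 3 * sqrt(0.008))  # prior sd benchmark
})

test_that("ordinal fits keep cut-points ordered and latents inside their bins", {
  sim <- shared_sim()
  tr <- sim_trait(sim$panel, n_qtl = 4, h2 = 0.9, M = 4, seed = 14)
  fit <- bayesA(sim$panel, tr$phenotype, response = "ordinal",
                mcmc = mcmc_config(1500, 500, 5), seed = 15,
                save_latent = TRUE)
  K <- fit$cutpoints  # rows K_1..K_{M-1}, one column per retained sample
  expect_true(all(K[1, ] == 0))
  expect_true(all(apply(K, 2, function(k) all(diff(k) > 0))))
  s <- as.integer(tr$phenotype)
  for (n in seq_len(ncol(K))) {
    kfull <- c(-Inf, K[, n], Inf)
    y <- fit$latent[, n]
    expect_true(all(y > kfull[s] & y <= kfull[s + 1L]))
  }
})

test_that("ordinal truncation bounds hold for the extreme categories", {
  sim <- shared_sim()
  tr <- sim_trait(sim$panel, n_qtl = 4, h2 = 0.9, M = 4, seed = 16)
  fit <- bayesA(sim$panel, tr$phenotype, response = "ordinal",
                mcmc = mcmc_config(800, 300, 5), seed = 17, save_latent = TRUE)
  s <- as.integer(tr$phenotype)
  expect_true(all(fit$latent[s == 1, ] <= 0))
  Km1 <- fit$cutpoints[nrow(fit$cutpoints), ]
  expect_true(all(fit$latent[s == 4, ] > rep(Km1, each = sum(s == 4))))
})

test_that("fits are exactly reproducible under a fixed seed", {
  sim <- shared_sim()
  tr <- sim_trait(sim$panel, n_qtl = 3, h2 = 0.8, M = 3, seed = 18)
  f1 <- bayesA(sim$panel, tr$phenotype, mcmc = mcmc_config(400, 100, 5), seed = 19)
  f2 <- bayesA(sim$panel, tr$phenotype, mcmc = mcmc_config(400, 100, 5), seed = 19)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$cutpoints, f2$cutpoints)
  expect_identical(f1$sigma2_e, f2$sigma2_e)
})

test_that("missing phenotypes are dropped from the likelihood but still predicted", {
  sim <- shared_sim()
  tr <- sim_trait(sim$panel, n_qtl = 4, h2 = 0.9, M = 3, seed = 20)
  y <- tr$phenotype
  y[c(3, 10)] <- NA
  fit <- bayesA(sim$panel, y, mcmc = mcmc_config(600, 200, 5), seed = 21)
  expect_equal(length(fit$trained), 82L)
  bv <- predict(fit, sim$panel)
  expect_equal(length(bv), 84L)
  expect_true(all(is.finite(bv)))
})

test_that("genotype-effect model handles dominance; allelic model wins when additive", {
  set.seed(22)
  sim <- sim_panel(n = 120, n_markers = 30, n_groups = 3, depth = 1, seed = 2323)
  pan <- sim$panel
  X <- build_allele_design(pan)
  # purely additive trait at one multi-allelic marker
  tr_add <- sim_trait(pan, n_qtl = 3, h2 = 0.9, seed = 24)
  train <- pan[1:80, ]; test <- pan[81:120, ]
  acc <- function(model, phe, truth) {
    fit <- bayesA(train, phe[1:80], model = model, response = "gaussian",
                  mcmc = mcmc_config(1500, 500, 5), seed = 25)
    cor(predict(fit, test, unknown = "zero"), truth[81:120])
  }
  a_add <- suppressWarnings(acc("allelic", tr_add$phenotype, tr_add$genetic))
  g_add <- suppressWarnings(acc("genotype", tr_add$phenotype, tr_add$genetic))
  expect_gte(a_add, g_add - 0.05)
  # trait driven by heterozygosity at 5 markers (pure dominance)
  het <- rowSums(sapply(1:5, function(j) pan$hapA[, j] != pan$hapB[, j]))
  y_dom <- as.numeric(scale(het)) + rnorm(120, 0, 0.3)
  a_dom <- suppressWarnings(acc("allelic", y_dom, y_dom))
  g_dom <- suppressWarnings(acc("genotype", y_dom, y_dom))
  expect_gt(g_dom, a_dom)
})

test_that("the model object exposes the standard methods", {
  sim <- shared_sim()
  tr <- sim_trait(sim$panel, n_qtl = 3, h2 = 0.9, M = 3, seed = 26)
  fit <- bayesA(sim$panel, tr$phenotype, mcmc = mcmc_config(400, 100, 5),
                seed = 27)
  expect_output(print(fit), "BayesA allelic model \\(ordinal response\\)")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.bayesA")
  expect_output(print(sm), "residual variance")
  expect_named(sm$top_markers)
  b <- coef(fit)
  expect_equal(length(b), nrow(fit$beta))
  expect_true(is.numeric(attr(b, "intercept")))
  expect_identical(fitted(fit), predict(fit))
  expect_identical(unname(fitted(fit)),
                   unname(predict(fit, sim$panel, type = "bv")))
})

test_that("degenerate inputs are rejected with informative errors", {
  sim <- shared_sim()
  expect_error(bayesA(sim$panel, rep(1, 84)), "categories|constant")
  expect_error(bayesA(sim$panel, rep(NA_real_, 84)), "phenotyped")
  expect_error(bayesA(sim$panel, rep(2.5, 84), response = "gaussian"),
               "constant")
})
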