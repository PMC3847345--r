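test_that("cross enumeration counts unordered pairs without self-crosses", {
  expect_equal(nrow(enumerate_crosses(c("a", "b"))), 1L)
  ids <- paste0("p", 1:10)
  cr <- enumerate_crosses(ids)
  # brute-force double loop
  n_bf <- 0L
  for (i in 1:9) for (j in (i + 1):10) n_bf <- n_bf + 1L
  expect_equal(nrow(cr), n_bf)
  expect_true(all(cr$parentA < cr$parentB))  # lexicographic, no duplicates
  expect_error(enumerate_crosses("solo"), "at least 2")
})

test_that("posterior proportion matches brute-force indicator evaluation", {
  # 4 progeny, 2 traits, 3 retained samples, printed effect values
  calls <- rbind(par = c(q1 = "A|B", q2 = "C|D"),
                 pr1 = c(q1 = "A|A", q2 = "C|C"),
                 pr2 = c(q1 = "A|B", q2 = "C|D"),
                 pr3 = c(q1 = "B|B", q2 = "D|D"),
                 pr4 = c(q1 = "A|B", q2 = "D|D"))
  pan <- marker_panel(calls)
  P <- ncol(build_allele_design(pan))  # 4 columns: q1:A q1:B q2:C q2:D
  beta_t1 <- rbind(c(1, 0.5, 2), c(-1, 0, 0.3), c(0, 0, 0), c(0, 0, 0))
  beta_t2 <- rbind(c(0, 0, 0), c(0, 0, 0), c(0.2, 1, -0.5), c(-0.2, 0.4, 0))
  f1 <- manual_fit(pan, beta_t1, c(0, 0.1, -0.1))
  f2 <- manual_fit(pan, beta_t2, c(0.5, 0, 0))
  progeny <- pan[2:5, ]
  crit <- list(selection_criterion("t1", "greater", "par"),
               selection_criterion("t2", "less", "par"))
  rep_out <- posterior_proportion(list(t1 = f1, t2 = f2), progeny, crit,
                                  panel = pan)
  # brute force over every (sample, progeny) pair
  X <- build_allele_design(pan)
  p_bf <- numeric(3)
  for (n in 1:3) {
    g1 <- c(0, 0.1, -0.1)[n] + X %*% beta_t1[, n]
    g2 <- c(0.5, 0, 0)[n] + X %*% beta_t2[, n]
    ok <- (g1[2:5] > g1[1]) & (g2[2:5] < g2[1])
    p_bf[n] <- mean(ok)
  }
  expect_equal(unname(rep_out$p), p_bf)
  expect_equal(rep_out$mean, mean(p_bf))
})

test_that("strict inequalities give zero against an identical reference", {
  calls <- rbind(par = c(m = "A|A"), k1 = c(m = "A|A"), k2 = c(m = "A|A"))
  pan <- marker_panel(calls)
  P <- ncol(build_allele_design(pan))
  fit <- manual_fit(pan, matrix(rnorm(P * 4), P, 4), rnorm(4))
  rep_out <- posterior_proportion(list(t = fit), pan[2:3, ],
                                  selection_criterion("t", "greater", "par"),
                                  panel = pan)
  expect_true(all(rep_out$p == 0))
  # unbounded threshold criterion is always fulfilled
  rep_all <- posterior_proportion(list(t = fit), pan[2:3, ],
                                  selection_criterion("t", "greater", -Inf))
  expect_true(all(rep_all$p == 1))
})

test_that("proportion samples are multiples of 1/S and shrink under added criteria", {
  sim <- shared_sim()
  tr1 <- sim_trait(sim$panel, n_qtl = 3, h2 = 0.9, seed = 40)
  tr2 <- sim_trait(sim$panel, n_qtl = 3, h2 = 0.9, seed = 41)
  mc <- mcmc_config(400, 100, 10)
  f1 <- bayesA(sim$panel, tr1$phenotype, response = "gaussian", mcmc = mc, seed = 42)
  f2 <- bayesA(sim$panel, tr2$phenotype, response = "gaussian", mcmc = mc, seed = 43)
  S <- 73
  prog <- simulate_progeny(sim$panel, sim$map, 1, 2, S = S, seed = 44)
  c1 <- selection_criterion("t1", "greater", sim$panel$ids[5])
  c2 <- selection_criterion("t2", "less", sim$panel$ids[6])
  r1 <- posterior_proportion(list(t1 = f1, t2 = f2), prog, c1, panel = sim$panel)
  r12 <- posterior_proportion(list(t1 = f1, t2 = f2), prog, list(c1, c2),
                              panel = sim$panel)
  expect_true(all(abs(r1$p * S - round(r1$p * S)) < 1e-9))
  expect_true(all(r12$p <= r1$p + 1e-12))  # monotone intersection
  # invariant to progeny ordering
  perm <- sample(S)
  r_perm <- posterior_proportion(list(t1 = f1, t2 = f2), prog[perm, ], c1,
                                 panel = sim$panel)
  expect_equal(r_perm$p, r1$p)
})

test_that("chains with different retained lengths are rejected for joint criteria", {
  sim <- shared_sim()
  tr <- sim_trait(sim$panel, n_qtl = 3, h2 = 0.9, seed = 45)
  f1 <- bayesA(sim$panel, tr$phenotype, response = "gaussian",
               mcmc = mcmc_config(400, 100, 10), seed = 46)
  f2 <- bayesA(sim$panel, tr$phenotype, response = "gaussian",
               mcmc = mcmc_config(400, 100, 5), seed = 47)
  prog <- simulate_progeny(sim$panel, sim$map, 1, 2, S = 10, seed = 48)
  crit <- list(selection_criterion("a", "greater", 0),
               selection_criterion("b", "greater", 0))
  expect_error(posterior_proportion(list(a = f1, b = f2), prog, crit),
               "retained lengths")
})

test_that("cross ranking agrees with a single-QTL enumeration oracle", {
  # one big-effect biallelic QTL; deterministic single-sample chain
  set.seed(49)
  geno <- c("A|A", "A|B", "B|B", "A|B", "A|A", "B|B")
  calls <- cbind(q = paste(geno), n1 = "C|C")
  rownames(calls) <- paste0("p", 1:6)
  pan <- marker_panel(calls)
  map <- linkage_map(c("q", "n1"), c("lg1", "lg2"), c(0, 0))
  P <- ncol(build_allele_design(pan))  # q:A q:B n1:C
  beta <- matrix(c(1, 0, 0), P, 1)    # allele A worth +1, one retained sample
  fit <- manual_fit(pan, beta, 0)
  crit <- selection_criterion("t", "greater", 1.5)  # needs genotype A|A (bv 2)
  # oracle: expected proportion of A|A progeny from Mendelian gamete probs
  pA <- c(`A|A` = 1, `A|B` = 0.5, `B|B` = 0)
  exp_prop <- outer(pA[geno], pA[geno])
  cr <- enumerate_crosses(pan)
  oracle <- mapply(function(a, b) exp_prop[match(a, pan$ids), match(b, pan$ids)],
                   cr$parentA, cr$parentB)
  rk <- rank_crosses(pan, map, list(t = fit), crit, S = 4000, seed = 50)
  got <- rk$mean[match(paste(cr$parentA, cr$parentB),
                       paste(rk$parentA, rk$parentB))]
  expect_lt(max(abs(got - oracle)), 4 * sqrt(0.25 / 4000) + 1e-9)
  # best cross is between the two A|A homozygotes, worst has no A alleles
  expect_setequal(unlist(rk[1, c("parentA", "parentB")]), c("p1", "p5"))
  expect_equal(rk$mean[nrow(rk)], 0)
})

test_that("duplicated parents give matching posterior means and symmetric crosses match", {
  sim <- shared_sim()
  tr <- sim_trait(sim$panel, n_qtl = 3, h2 = 0.9, seed = 51)
  fit <- bayesA(sim$panel, tr$phenotype, response = "gaussian",
                mcmc = mcmc_config(400, 100, 10), seed = 52)
  crit <- selection_criterion("t", "greater", mean(tr$genetic))
  pa <- simulate_progeny(sim$panel, sim$map, 1, 2, S = 600, seed = 53)
  pb <- simulate_progeny(sim$panel, sim$map, 2, 1, S = 600, seed = 54)
  ra <- posterior_proportion(list(t = fit), pa, crit)
  rb <- posterior_proportion(list(t = fit), pb, crit)
  expect_lt(abs(ra$mean - rb$mean), 4 * sqrt(0.25 / 600))
})

test_that("complementary heterozygous parents show transgressive segregation", {
  calls <- rbind(pA = c(q1 = "A|a", q2 = "b|b"),
                 pB = c(q1 = "a|a", q2 = "B|b"))
  pan <- marker_panel(calls)
  map <- linkage_map(c("q1", "q2"), c("lg1", "lg2"), c(0, 0))
  P <- ncol(build_allele_design(pan))  # q1:A q1:a q2:B q2:b
  beta <- matrix(c(1, 0, 1, 0), P, 1)  # capital alleles worth +1
  fit <- manual_fit(pan, beta, 0)
  bv_par <- predict(fit, pan, type = "bv")
  prog <- simulate_progeny(pan, map, "pA", "pB", S = 400, seed = 55)
  bv_prog <- predict(fit, prog, type = "bv")
  expect_gt(max(bv_prog), max(bv_par))  # some progeny beat both parents
})
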