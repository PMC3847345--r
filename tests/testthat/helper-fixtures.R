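# Small fixtures built in code, shared across test files.

# deterministic 4-individual panel at 3 markers (phased), hand-checkable
toy_calls <- function(phased = TRUE) {
  sep <- if (phased) "|" else "/"
  g <- function(a, b) paste(a, b, sep = sep)
  rbind(i1 = c(m1 = g(120, 120), m2 = g(88, 92), m3 = g(200, 204)),
        i2 = c(m1 = g(120, 124), m2 = g(88, 88), m3 = g(204, 204)),
        i3 = c(m1 = g(124, 128), m2 = g(92, 92), m3 = g(200, 200)),
        i4 = c(m1 = g(128, 128), m2 = g(88, 92), m3 = g(200, 204)))
}

toy_panel <- function(phased = TRUE) marker_panel(toy_calls(phased))

toy_map <- function() {
  linkage_map(marker = c("m1", "m2", "m3"),
              group = c("lg1", "lg1", "lg2"),
              position = c(0, 10, 0))
}

# random multi-allelic panel for property tests
random_panel <- function(n, J, Lmax = 4, miss = 0, phased = TRUE, seed = 1) {
  set.seed(seed)
  sep <- if (phased) "|" else "/"
  calls <- matrix("", n, J,
                  dimnames = list(paste0("id", seq_len(n)),
                                  paste0("mk", seq_len(J))))
  for (j in seq_len(J)) {
    L <- sample(2:Lmax, 1L)
    lab <- as.character(100 + 2 * seq_len(L))
    a <- sample(lab, n, replace = TRUE)
    b <- sample(lab, n, replace = TRUE)
    calls[, j] <- paste(a, b, sep = sep)
  }
  if (miss > 0) {
    drop <- sample(length(calls), ceiling(miss * length(calls)))
    calls[drop] <- "./."
  }
  marker_panel(calls)
}

# hand-built bayesA-like object with printed posterior samples, for testing
# the prediction formulas independently of the sampler
manual_fit <- function(panel, beta, beta0, sigma2_e = NULL, cutpoints = NULL,
                       M = NULL, model = "allelic") {
  ns <- ncol(beta)
  X <- build_allele_design(panel)
  stopifnot(nrow(beta) == ncol(X))
  rownames(beta) <- colnames(X)
  structure(list(model = model,
                 response = if (is.null(M)) "gaussian" else "ordinal",
                 M = M,
                 ids = panel$ids, trained = panel$ids,
                 phenotype = rep(NA_real_, length(panel$ids)),
                 template = attr(X, "alleles"),
                 marker_of_col = attr(X, "marker"), markers = attr(X, "markers"),
                 beta0 = beta0, beta = beta,
                 sigma2_e = if (is.null(sigma2_e)) rep(1, ns) else sigma2_e,
                 cutpoints = cutpoints,
                 retained = ns,
                 mcmc = mcmc_config(ns, 0, 1)),
            class = "bayesA")
}

# shared mid-size synthetic dataset (generated once per test run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sim_panel(n = 84, n_markers = 80, n_groups = 5, depth = 2,
                          seed = 424242)
    cache
  }
})
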