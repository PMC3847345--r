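#' Common ratio of a geometric QTL-variance series
#'
#' Per-QTL additive-variance shares follow a geometric series
#' v_k proportional to lambda^(k-1). The effective number of QTL is the
#' concentration measure (sum v)^2 / sum v^2; this solves for the lambda in
#' (0, 1\] that attains a requested effective number.
#'
#' @param n_qtl number of QTL.
#' @param n_effective target effective number of QTL (in (1, n_qtl\]).
#' @param tol root-finding tolerance.
#' @return the common ratio lambda; exactly 1 when
#'   `n_effective == n_qtl` (equal variances).
#' @examples
#' solve_geometric_ratio(30, 10)  # about 0.82
#' @export
solve_geometric_ratio <- function(n_qtl, n_effective, tol = 1e-10) {
  if (n_effective <= 1 || n_effective > n_qtl)
    stop("'n_effective' must lie in (1, n_qtl]")
  if (n_effective == n_qtl) return(1)
  neff <- function(lam) {
    v <- lam^(seq_len(n_qtl) - 1)
    sum(v)^2 / sum(v^2)
  }
  stats::uniroot(function(lam) neff(lam) - n_effective,
                 lower = 1e-12, upper = 1 - 1e-12, tol = tol)$root
}

#' Plant additive QTL at panel markers
#'
#' Places QTL at the given markers, with QTL genotypes identical to the
#' marker genotypes. Per-QTL allele effects are drawn from a standard
#' normal, centred to zero mean under panel allele frequencies, then
#' rescaled so the QTL's additive variance over the observed panel
#' genotypes equals its share v_k of the total additive variance. Shares
#' follow the geometric series v_k proportional to lambda^(k-1), normalised
#' to `total_var`. No dominance or epistasis.
#'
#' @param panel a [marker_panel].
#' @param qtl_markers marker names or indices (polymorphic in the panel).
#' @param lambda geometric common ratio (see [solve_geometric_ratio]).
#' @param total_var total additive variance over the panel (default 1).
#' @return object of class `qtl_model`: `markers` (names), `effects` (list
#'   of per-allele effect vectors), `v` (target per-QTL variances),
#'   `lambda`.
#' @export
assign_qtl_effects <- function(panel, qtl_markers, lambda, total_var = 1) {
  stopifnot(inherits(panel, "marker_panel"))
  if (is.character(qtl_markers)) qtl_markers <- match(qtl_markers, panel$markers)
  if (anyNA(qtl_markers)) stop("unknown QTL marker name")
  if (anyDuplicated(qtl_markers)) stop("QTL markers must be distinct")
  K <- length(qtl_markers)
  v <- lambda^(seq_len(K) - 1)
  v <- v / sum(v) * total_var
  freqs <- allele_frequencies(panel)
  effects <- vector("list", K)
  for (k in seq_len(K)) {
    j <- qtl_markers[k]
    f <- freqs[[j]]
    a <- stats::rnorm(length(f))
    a <- a - sum(f * a)                      # zero mean at panel frequencies
    g <- a[panel$hapA[, j]] + a[panel$hapB[, j]]
    vg <- pop_var(g)  # variance at observed genotype frequencies
    if (!is.finite(vg) || vg <= 0)
      stop(sprintf("marker '%s' is monomorphic in the panel; choose another QTL marker",
                   panel$markers[j]))
    effects[[k]] <- a * sqrt(v[k] / vg)
  }
  structure(list(markers = panel$markers[qtl_markers],
                 marker_idx = qtl_markers, effects = effects,
                 v = v, lambda = lambda),
            class = "qtl_model")
}

pop_var <- function(x) mean((x - mean(x))^2)

#' True genetic values under a QTL model
#'
#' @param panel a [marker_panel] (training panel or simulated progeny)
#'   sharing the QTL markers' allele dictionaries.
#' @param qtl a `qtl_model` from [assign_qtl_effects].
#' @return named numeric vector: per individual, the sum over QTL of its
#'   two allele effects.
#' @export
genetic_values <- function(panel, qtl) {
  stopifnot(inherits(panel, "marker_panel"), inherits(qtl, "qtl_model"))
  idx <- match(qtl$markers, panel$markers)
  if (anyNA(idx)) stop("panel lacks QTL marker(s)")
  g <- numeric(length(panel$ids))
  for (k in seq_along(idx)) {
    j <- idx[k]
    a <- qtl$effects[[k]]
    if (anyNA(panel$hapA[, j]))
      stop("missing genotypes at a QTL marker; cannot compute genetic values")
    g <- g + a[panel$hapA[, j]] + a[panel$hapB[, j]]
  }
  names(g) <- panel$ids
  g
}

#' Simulate a continuous polygenic trait on a panel
#'
#' Draws a QTL set (markers plus geometric-series effects), adds Gaussian
#' environmental noise with variance total_VA * (1 - h2) / h2, and accepts
#' the draw when the realised heritability — the panel variance of genetic
#' values over the panel variance of phenotypes — falls within `window`.
#' Linkage disequilibrium between sampled QTL makes the realised
#' heritability vary around the target, hence the resampling.
#'
#' @param panel a [marker_panel].
#' @param n_qtl number of QTL markers to sample.
#' @param n_effective target effective number of QTL.
#' @param h2 target heritability.
#' @param window acceptance window for the realised heritability.
#' @param max_attempts cap on resampling attempts.
#' @param seed optional seed (local to the call).
#' @return list: `phenotype` (named), `genetic` (true genetic values),
#'   `qtl` (`qtl_model`), `h2_realized`, `attempts`.
#' @export
simulate_qtl_trait <- function(panel, n_qtl = 30, n_effective = 10,
                               h2 = 0.75, window = c(0.70, 0.80),
                               max_attempts = 1000, seed = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  if (h2 <= 0 || h2 > 1) stop("'h2' must be in (0, 1]")
  if (window[1] > h2 || window[2] < h2)
    stop("acceptance window must contain the target heritability")
  lambda <- solve_geometric_ratio(n_qtl, n_effective)
  # polymorphic markers only (a monomorphic QTL contributes no variance)
  poly <- which(vapply(seq_along(panel$markers), function(j) {
    aj <- c(panel$hapA[, j], panel$hapB[, j])
    length(unique(aj[!is.na(aj)])) > 1L
  }, TRUE))
  if (length(poly) < n_qtl)
    stop("panel has fewer polymorphic markers than requested QTL")
  noise_var <- (1 - h2) / h2  # total additive variance normalised to 1
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      qtl <- assign_qtl_effects(panel, sample(poly, n_qtl), lambda,
                                total_var = 1)
      g <- genetic_values(panel, qtl)
      e <- stats::rnorm(length(g), 0, sqrt(noise_var))
      y <- g + e
      h2_real <- stats::var(g) / stats::var(y)
      if (h2_real >= window[1] && h2_real <= window[2])
        return(list(phenotype = y, genetic = g, qtl = qtl,
                    h2_realized = h2_real, attempts = attempt))
    }
    stop(sprintf(paste0("no QTL draw reached realised heritability in [%.2f, %.2f] ",
                        "after %d attempts (target %.2f); check panel polymorphism"),
                 window[1], window[2], max_attempts, h2))
  })
}

#' Validation simulation study: true vs predicted progeny proportions
#'
#' Per replicate: a continuous trait with planted QTL is simulated on the
#' panel ([simulate_qtl_trait]); a continuous-response BayesA model is
#' fitted to the panel phenotypes; the panel is randomly paired into N/2
#' crosses; for each cross, `n_progeny` progeny are simulated once, and on
#' the same progeny set the true proportion (true genetic value above the
#' true panel mean) and the predicted proportion (posterior-mean breeding
#' value above the estimated panel mean) are computed. Accuracy is the
#' Pearson correlation of true vs predicted proportions across crosses;
#' the summary is its mean over replicates.
#'
#' @param panel phased [marker_panel].
#' @param map a [linkage_map].
#' @param n_replicates number of simulation replicates.
#' @param mcmc MCMC schedule for the per-replicate fits.
#' @param n_qtl,n_effective,h2,window passed to [simulate_qtl_trait].
#' @param n_progeny progeny per cross.
#' @param seed master seed; per-replicate seeds derive from it.
#' @return list of class `simstudy`: `per_cross` data frame (replicate,
#'   parentA, parentB, true_p, pred_p), `per_replicate` correlations,
#'   `mean_correlation`, and the realised heritabilities.
#' @export
run_simulation_study <- function(panel, map, n_replicates = 10,
                                 mcmc = mcmc_config(5000, 1000, 5),
                                 n_qtl = 30, n_effective = 10, h2 = 0.75,
                                 window = c(0.70, 0.80), n_progeny = 1000,
                                 seed = NULL) {
  stopifnot(inherits(panel, "marker_panel"), inherits(map, "linkage_map"))
  if (!panel$phased) stop("simulation study needs a phased panel")
  N <- length(panel$ids)
  res <- vector("list", n_replicates)
  cors <- numeric(n_replicates)
  h2s <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    # stage-isolated seeds: the simulated trait, the random pairing and the
    # progeny populations of a replicate are invariant to the MCMC schedule
    rs <- function(stage) if (is.null(seed)) NULL
                          else derive_seed(derive_seed(seed, r), stage)
    res[[r]] <- {
      tr <- simulate_qtl_trait(panel, n_qtl = n_qtl, n_effective = n_effective,
                               h2 = h2, window = window, seed = rs(1L))
      fit <- bayesA(panel, tr$phenotype, model = "allelic",
                    response = "gaussian", mcmc = mcmc, seed = rs(2L))
      bv_panel <- predict(fit, panel, type = "bv")
      thr_true <- mean(tr$genetic)
      thr_pred <- mean(bv_panel)
      perm <- with_seed(rs(3L), {
        use <- seq_len(N)
        if (N %% 2L == 1L) {
          warning("odd panel size; dropping one individual at random for pairing")
          use <- sort(sample(N, N - 1L))
        }
        sample(use)
      })
      A <- perm[seq(1L, length(perm), by = 2L)]
      B <- perm[seq(2L, length(perm), by = 2L)]
      true_p <- pred_p <- numeric(length(A))
      for (k in seq_along(A)) {
        prog <- simulate_progeny(panel, map, A[k], B[k], S = n_progeny,
                                 seed = rs(3L + k))
        true_p[k] <- mean(genetic_values(prog, tr$qtl) > thr_true)
        pred_p[k] <- mean(predict(fit, prog, type = "bv") > thr_pred)
      }
      list(df = data.frame(replicate = r,
                           parentA = panel$ids[A], parentB = panel$ids[B],
                           true_p = true_p, pred_p = pred_p,
                           stringsAsFactors = FALSE),
           h2 = tr$h2_realized)
    }
    h2s[r] <- res[[r]]$h2
    tp <- res[[r]]$df$true_p; pp <- res[[r]]$df$pred_p
    cors[r] <- if (stats::sd(tp) == 0 || stats::sd(pp) == 0) NA_real_
               else stats::cor(tp, pp)
  }
  excluded <- which(is.na(cors))
  if (length(excluded))
    message(sprintf("replicate(s) %s excluded: zero variance of proportions",
                    paste(excluded, collapse = ", ")))
  structure(list(per_cross = do.call(rbind, lapply(res, `[[`, "df")),
                 per_replicate = cors,
                 mean_correlation = mean(cors, na.rm = TRUE),
                 h2_realized = h2s),
            class = "simstudy")
}

#' @export
print.simstudy <- function(x, ...) {
  ok <- !is.na(x$per_replicate)
  cat(sprintf("simulation study: %d replicates, %d crosses each\n",
              length(x$per_replicate),
              sum(x$per_cross$replicate == x$per_cross$replicate[1L])))
  cat(sprintf("  realised h2: %.3f-%.3f\n", min(x$h2_realized), max(x$h2_realized)))
  cat(sprintf("  true-vs-predicted proportion correlation: mean %.3f (range %.3f-%.3f)\n",
              x$mean_correlation, min(x$per_replicate[ok]), max(x$per_replicate[ok])))
  invisible(x)
}
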