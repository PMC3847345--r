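#' MCMC schedule
#'
#' @param n_iter total Gibbs cycles.
#' @param burnin cycles discarded before sampling.
#' @param thin keep every `thin`-th post-burn-in state.
#' @return a list of class `mcmc_config` with the schedule and the implied
#'   number of retained samples. The default schedule (50000, 10000, 10)
#'   retains 4000 samples.
#' @examples
#' mcmc_config()$retained  # 4000
#' @export
mcmc_config <- function(n_iter = 50000, burnin = 10000, thin = 10) {
  n_iter <- as.integer(n_iter); burnin <- as.integer(burnin); thin <- as.integer(thin)
  if (n_iter <= burnin) stop("total cycles must exceed burn-in")
  if (thin < 1L) stop("thinning interval must be >= 1")
  retained <- (n_iter - burnin) %/% thin
  if (retained < 1L) stop("schedule retains no samples")
  structure(list(n_iter = n_iter, burnin = burnin, thin = thin,
                 retained = retained), class = "mcmc_config")
}

#' Prior hyperparameters for the marker-effect and residual variances
#'
#' Marker-effect variances get a scaled inverse chi-square prior
#' Inv-chisq(nu_g, S2_g); the residual variance gets Inv-chisq(nu_e, S2_e),
#' where the default (nu_e = -2, S2_e = 0) is the flat prior on sigma_e^2.
#' The default prior scale is 0.004 for the additive allelic model and
#' 0.012 for the genotype-effect model, whose per-genotype effects (additive
#' plus dominance) have larger variance than single-allele effects.
#'
#' @param model `"allelic"` or `"genotype"` (selects the default `S2_g`).
#' @param nu_g,S2_g prior df and scale of the marker-effect variances.
#' @param nu_e,S2_e prior df and scale of the residual variance.
#' @return a list of class `bayesA_hyper`.
#' @export
bayesA_hyper <- function(model = c("allelic", "genotype"),
                         nu_g = 4, S2_g = NULL, nu_e = -2, S2_e = 0) {
  model <- match.arg(model)
  if (is.null(S2_g)) S2_g <- if (model == "allelic") 0.004 else 0.012
  if (nu_g <= 2) warning("nu_g <= 2: prior variance of sigma_j^2 has no mean")
  structure(list(nu_g = nu_g, S2_g = S2_g, nu_e = nu_e, S2_e = S2_e),
            class = "bayesA_hyper")
}

#' Fit a BayesA (threshold) regression on genome-wide markers
#'
#' Bayesian shrinkage regression of a phenotype on genome-wide multi-allelic
#' marker genotypes, fitted by Gibbs sampling. Each marker has its own
#' effect variance with a scaled inverse chi-square prior (BayesA). Ordinal
#' phenotypes are handled with a latent continuous variable cut into
#' categories by ordered cut-points (threshold model): the latent variable,
#' the free cut-points, all effects and all variances are sampled jointly.
#' Continuous phenotypes are regressed directly.
#'
#' Two marker codings are available: the additive allelic model (one effect
#' per marker allele, regressor = allele dosage) and the genotype-effect
#' model (one effect per observed unordered genotype class, capturing
#' additive plus dominance variation).
#'
#' @param panel a [marker_panel] with the training individuals.
#' @param phenotype numeric vector aligned to `panel$ids` (or named by
#'   them). Integer codes `1..M` are treated as ordinal scores when
#'   `response = "ordinal"`; `NA` drops the individual from the likelihood
#'   (its breeding value can still be predicted).
#' @param model marker coding, `"allelic"` (default) or `"genotype"`.
#' @param response `"ordinal"` or `"gaussian"`; default `"auto"` picks
#'   ordinal for integer-valued phenotypes with at most 10 levels.
#' @param M number of ordinal categories; defaults to `max(phenotype)`.
#' @param hyper a [bayesA_hyper] prior specification.
#' @param mcmc an [mcmc_config] schedule.
#' @param seed optional integer seed (local to the call).
#' @param fix_residual_variance if `TRUE`, fixes sigma_e^2 = 1 instead of
#'   sampling it (conventional in some threshold models; default `FALSE`,
#'   identifiability being ensured by fixing the first cut-point at 0).
#' @param save_latent retain the latent-variable samples (ordinal mode).
#' @return an object of class `bayesA`: posterior samples of the intercept,
#'   effects, variances and cut-points, plus the design template needed to
#'   build matching designs for new individuals. Use [coef()], [predict()],
#'   [summary()] on it.
#' @seealso [predict.bayesA], [loocv], [posterior_proportion]
#' @export
bayesA <- function(panel, phenotype, model = c("allelic", "genotype"),
                   response = c("auto", "ordinal", "gaussian"), M = NULL,
                   hyper = NULL, mcmc = mcmc_config(), seed = NULL,
                   fix_residual_variance = FALSE, save_latent = FALSE) {
  stopifnot(inherits(panel, "marker_panel"))
  model <- match.arg(model)
  response <- match.arg(response)
  if (is.null(hyper)) hyper <- bayesA_hyper(model)
  stopifnot(inherits(hyper, "bayesA_hyper"), inherits(mcmc, "mcmc_config"))

  y <- align_phenotype(phenotype, panel$ids)
  obs <- !is.na(y)
  if (sum(obs) < 3L) stop("need at least 3 phenotyped individuals")
  if (response == "auto") {
    yv <- y[obs]
    response <- if (all(yv == round(yv)) && min(yv) >= 1 &&
                    length(unique(yv)) <= 10 && max(yv) <= 10)
      "ordinal" else "gaussian"
  }
  ordinal <- response == "ordinal"
  if (ordinal) {
    s <- as.integer(round(y))
    if (any(abs(y[obs] - s[obs]) > 1e-8))
      stop("ordinal response must contain integer scores")
    if (is.null(M)) M <- max(s[obs])
    if (M < 2L) stop("ordinal response needs at least 2 categories")
    if (any(s[obs] < 1L | s[obs] > M))
      stop("ordinal scores outside 1..M")
    if (length(unique(s[obs])) < 2L)
      stop("need at least 2 occupied score categories")
  } else {
    if (stats::var(y[obs]) == 0) stop("constant phenotype: nothing to fit")
  }

  X <- if (model == "allelic") build_allele_design(panel)
       else build_genotype_design(panel)
  Xf <- X[obs, , drop = FALSE]

  res <- with_seed(seed, .cpp_bayesa_gibbs(
    Xf, as.integer(attr(X, "marker")),
    if (ordinal) numeric(sum(obs)) else as.numeric(y[obs]),
    if (ordinal) as.integer(y[obs]) else integer(sum(obs)),
    ordinal, if (ordinal) as.integer(M) else 0L,
    hyper$nu_g, hyper$S2_g, hyper$nu_e, hyper$S2_e,
    mcmc$n_iter, mcmc$burnin, mcmc$thin,
    isTRUE(fix_residual_variance), isTRUE(save_latent)))

  rownames(res$beta) <- colnames(X)
  rownames(res$sigma2_marker) <- attr(X, "markers")
  fitted_bv <- as.numeric(mean(res$beta0) + X %*% rowMeans(res$beta))
  names(fitted_bv) <- panel$ids
  fit <- structure(list(
    call = match.call(),
    model = model, response = response, M = if (ordinal) M else NULL,
    hyper = hyper, mcmc = mcmc, seed = seed,
    ids = panel$ids, trained = panel$ids[obs], phenotype = y,
    template = if (model == "allelic") attr(X, "alleles") else attr(X, "classes"),
    marker_of_col = attr(X, "marker"), markers = attr(X, "markers"),
    fitted = fitted_bv,
    beta0 = res$beta0, beta = res$beta,
    sigma2_marker = res$sigma2_marker, sigma2_e = res$sigma2_e,
    cutpoints = res$cutpoints, latent = res$latent,
    retained = res$retained), class = "bayesA")
  fit
}

align_phenotype <- function(phenotype, ids) {
  if (!is.null(names(phenotype))) {
    if (!all(ids %in% names(phenotype)))
      stop("phenotype is named but lacks some panel individuals")
    phenotype <- phenotype[ids]
  }
  if (length(phenotype) != length(ids))
    stop("phenotype length does not match the number of individuals")
  as.numeric(phenotype)
}

#' @export
print.bayesA <- function(x, ...) {
  cat(sprintf("BayesA %s model (%s response)\n", x$model, x$response))
  cat(sprintf("  %d phenotyped individuals, %d markers, %d effect columns\n",
              length(x$trained), length(x$markers), nrow(x$beta)))
  cat(sprintf("  MCMC: %d cycles, %d burn-in, thin %d -> %d retained samples\n",
              x$mcmc$n_iter, x$mcmc$burnin, x$mcmc$thin, x$retained))
  if (x$response == "ordinal")
    cat(sprintf("  %d ordinal categories; posterior-mean cut-points: %s\n",
                x$M, paste(sprintf("%.3f", rowMeans(x$cutpoints)), collapse = ", ")))
  invisible(x)
}

#' Estimated breeding values of the training individuals
#'
#' @param object a fitted [bayesA] model.
#' @param ... ignored.
#' @return named numeric vector: posterior-mean breeding value of every
#'   panel individual the model was built on (including any with missing
#'   phenotypes).
#' @export
fitted.bayesA <- function(object, ...) object$fitted

#' @export
summary.bayesA <- function(object, ...) {
  bv <- object$fitted
  out <- list(
    model = object$model, response = object$response,
    retained = object$retained,
    sigma2_e = mean(object$sigma2_e),
    top_markers = sort(rowMeans(object$sigma2_marker), decreasing = TRUE)[
      seq_len(min(5L, nrow(object$sigma2_marker)))],
    fit_correlation = if (any(!is.na(object$phenotype)))
      stats::cor(bv[!is.na(object$phenotype)],
                 object$phenotype[!is.na(object$phenotype)]) else NA_real_)
  class(out) <- "summary.bayesA"
  out
}

#' @export
print.summary.bayesA <- function(x, ...) {
  cat(sprintf("BayesA %s model, %s response; %d retained samples\n",
              x$model, x$response, x$retained))
  cat(sprintf("  posterior-mean residual variance: %.4f\n", x$sigma2_e))
  cat(sprintf("  cor(estimated breeding values, observed phenotype): %.3f\n",
              x$fit_correlation))
  cat("  largest posterior-mean marker variances:\n")
  print(round(x$top_markers, 5))
  invisible(x)
}

#' Posterior-mean marker effects
#'
#' @param object a fitted [bayesA] model.
#' @param ... ignored.
#' @return named numeric vector of posterior-mean effects, one per design
#'   column (`"marker:allele"` or `"marker:genotype"`), with the
#'   posterior-mean intercept as attribute `"intercept"`.
#' @export
coef.bayesA <- function(object, ...) {
  b <- rowMeans(object$beta)
  attr(b, "intercept") <- mean(object$beta0)
  b
}
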