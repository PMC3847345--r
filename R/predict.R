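# design matrix for (new) individuals with columns matching a fitted model
design_for <- function(object, panel, unknown = c("error", "zero")) {
  unknown <- match.arg(unknown)
  if (!all(panel$markers %in% object$markers))
    stop("panel contains markers absent from the fitted design: ",
         paste(utils::head(setdiff(panel$markers, object$markers), 3), collapse = ", "))
  X <- if (object$model == "allelic")
    build_allele_design(panel, alleles = object$template, unknown = unknown)
  else build_genotype_design(panel, classes = object$template)
  idx <- match(colnames(X), rownames(object$beta))
  if (anyNA(idx)) stop("internal error: design columns do not match the chain")
  list(X = X, idx = idx)
}

#' Predict breeding values and ordinal scores from a fitted model
#'
#' Breeding values are the genetic part of the linear predictor,
#' intercept + sum of allele (or genotype-class) effects; the residual is
#' excluded since its expectation is zero. `type = "bv"` returns the
#' posterior mean over retained samples (the estimated breeding value);
#' `type = "samples"` returns the per-cycle values, one column per retained
#' MCMC sample. `type = "score"` predicts ordinal categories: per retained
#' sample a phenotype is drawn from N(linear predictor, sigma_e^2) and
#' binned by that sample's cut-points; the prediction is the modal category
#' over samples, ties broken to the lower category.
#'
#' @param object a fitted [bayesA] model.
#' @param newdata a [marker_panel]; default: the training panel design.
#' @param type `"bv"`, `"samples"` or `"score"`.
#' @param unknown passed to [build_allele_design] for alleles absent from
#'   the training design (`"error"` or `"zero"`).
#' @param seed optional seed for the score-prediction draws.
#' @param ... ignored.
#' @return named numeric vector (`"bv"`), matrix individuals x samples
#'   (`"samples"`), or named integer vector of categories (`"score"`).
#' @export
predict.bayesA <- function(object, newdata = NULL,
                           type = c("bv", "samples", "score"),
                           unknown = c("error", "zero"), seed = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "bv") return(object$fitted)
    stop("supply 'newdata' (a marker_panel); the fit stores only its training breeding values")
  }
  stopifnot(inherits(newdata, "marker_panel"))
  d <- design_for(object, newdata, unknown = match.arg(unknown))
  B <- object$beta[d$idx, , drop = FALSE]
  if (type == "bv") {
    bv <- as.numeric(mean(object$beta0) + d$X %*% rowMeans(B))
    names(bv) <- newdata$ids
    return(bv)
  }
  G <- sweep(d$X %*% B, 2L, object$beta0, `+`)
  rownames(G) <- newdata$ids
  if (type == "samples") return(G)
  # ordinal score prediction
  if (object$response != "ordinal")
    stop("score prediction requires an ordinal-response fit")
  with_seed(seed, {
    n <- nrow(G); ns <- ncol(G); M <- object$M
    draws <- G + matrix(stats::rnorm(n * ns), n, ns) *
      rep(sqrt(object$sigma2_e), each = n)
    cat_draw <- matrix(1L, n, ns)
    for (m in seq_len(M - 1L))  # K_1..K_{M-1} are rows of object$cutpoints
      cat_draw <- cat_draw + (draws > rep(object$cutpoints[m, ], each = n))
    s <- integer(n)
    for (i in seq_len(n)) {
      tab <- tabulate(cat_draw[i, ], nbins = M)
      s[i] <- which.max(tab)  # which.max takes the first (lowest) on ties
    }
    names(s) <- newdata$ids
    s
  })
}

#' Estimated breeding values of a panel
#'
#' Convenience wrapper: posterior-mean breeding values of the given
#' individuals under a fitted model.
#'
#' @param object a fitted [bayesA] model.
#' @param panel a [marker_panel].
#' @return named numeric vector of posterior-mean breeding values.
#' @export
breeding_values <- function(object, panel) {
  predict(object, newdata = panel, type = "bv")
}

#' Leave-one-out cross-validation of genomic prediction
#'
#' Each phenotyped individual is removed in turn, the model is refitted on
#' the remainder, and the left-out individual's breeding value (and ordinal
#' score, for ordinal responses) is predicted from its markers alone.
#' Prediction accuracy is the Pearson correlation between the
#' cross-validated breeding values and the breeding values estimated on the
#' whole data; ordinal accuracy is the coincidence of predicted and
#' observed scores. A fold whose training set loses an entire score
#' category is flagged and excluded from the coincidence denominator.
#'
#' @inheritParams bayesA
#' @param mcmc MCMC schedule for the refits; a reduced schedule (the
#'   default here) keeps LOOCV fast, at a small cost in Monte Carlo noise.
#' @param seed optional master seed; per-fold seeds are derived from it.
#' @return list with `bv_loo` (predicted breeding values), `score_loo`,
#'   `bv_full` (whole-data estimates), `correlation`, `coincidence`,
#'   `confusion` (observed x predicted counts) and `flagged_folds`.
#' @export
loocv <- function(panel, phenotype, model = c("allelic", "genotype"),
                  response = c("auto", "ordinal", "gaussian"), M = NULL,
                  hyper = NULL, mcmc = mcmc_config(4000, 1000, 5),
                  seed = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  model <- match.arg(model); response <- match.arg(response)
  y <- align_phenotype(phenotype, panel$ids)
  obs <- which(!is.na(y))
  if (length(obs) < 3L) stop("LOOCV needs at least 3 phenotyped individuals")

  full <- bayesA(panel, y, model = model, response = response, M = M,
                 hyper = hyper, mcmc = mcmc,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, 0L))
  ordinal <- full$response == "ordinal"
  if (ordinal && is.null(M)) M <- full$M
  bv_full <- predict(full, panel, type = "bv")

  n <- length(panel$ids)
  bv_loo <- rep(NA_real_, n); names(bv_loo) <- panel$ids
  score_loo <- if (ordinal) rep(NA_integer_, n) else NULL
  if (ordinal) names(score_loo) <- panel$ids
  flagged <- logical(n)
  for (k in seq_along(obs)) {
    i <- obs[k]
    train <- panel[-i, ]
    yt <- y[-i]
    if (ordinal) {
      lost <- setdiff(unique(y[obs]), unique(yt[!is.na(yt)]))
      flagged[i] <- length(lost) > 0L
    }
    fit_i <- bayesA(train, yt, model = model, response = full$response,
                    M = M, hyper = hyper, mcmc = mcmc,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, k))
    suppressWarnings({
      bv_loo[i] <- predict(fit_i, panel[i, ], type = "bv", unknown = "zero")
      if (ordinal)
        score_loo[i] <- predict(fit_i, panel[i, ], type = "score",
                                unknown = "zero",
                                seed = if (is.null(seed)) NULL else derive_seed(seed, k + n))
    })
  }
  out <- list(bv_loo = bv_loo, score_loo = score_loo, bv_full = bv_full,
              correlation = stats::cor(bv_loo[obs], bv_full[obs]),
              flagged_folds = panel$ids[flagged])
  if (ordinal) {
    keep <- obs[!flagged[obs]]
    cc <- coincidence(y[keep], score_loo[keep], M = M)
    out$coincidence <- cc$fraction
    out$confusion <- cc$table
  }
  out
}

derive_seed <- function(seed, k) (as.integer(seed) + 7919L * k) %% 2147483629L

#' Coincidence of predicted and observed ordinal scores
#'
#' @param observed,predicted integer score vectors of equal length.
#' @param M number of categories (default: largest score seen).
#' @return list with `fraction` (proportion of exact matches) and `table`
#'   (M x M contingency table, rows = observed, columns = predicted).
#' @examples
#' coincidence(c(1, 2, 2, 3), c(1, 2, 3, 3))$fraction  # 0.75
#' @export
coincidence <- function(observed, predicted, M = NULL) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  if (length(observed) < 1L) stop("need at least one pair of scores")
  observed <- as.integer(observed); predicted <- as.integer(predicted)
  if (anyNA(observed) || anyNA(predicted)) stop("scores must be non-missing")
  if (is.null(M)) M <- max(observed, predicted)
  tab <- table(factor(observed, levels = seq_len(M)),
               factor(predicted, levels = seq_len(M)),
               dnn = c("observed", "predicted"))
  list(fraction = sum(diag(tab)) / sum(tab), table = tab)
}

#' Genetic correlation of two traits' breeding values
#'
#' Pearson correlation of the posterior-mean breeding values of the same
#' individuals under two trait models.
#'
#' @param bv1,bv2 named numeric vectors of breeding values (aligned, or
#'   named by individual so they can be aligned).
#' @return Pearson correlation coefficient.
#' @export
genetic_correlation <- function(bv1, bv2) {
  if (!is.null(names(bv1)) && !is.null(names(bv2))) {
    if (!setequal(names(bv1), names(bv2)))
      stop("breeding-value sets cover different individuals")
    bv2 <- bv2[names(bv1)]
  } else if (length(bv1) != length(bv2)) {
    stop("breeding-value sets have different lengths and no names to align by")
  }
  if (stats::sd(bv1) == 0 || stats::sd(bv2) == 0)
    stop("genetic correlation undefined: a breeding-value set has zero variance")
  stats::cor(bv1, bv2)
}
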