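#' Selection criterion for progeny
#'
#' A criterion compares progeny breeding values for one trait with a
#' reference: either a named parent/cultivar (whose breeding value is
#' recomputed at every MCMC cycle, so its uncertainty propagates) or a
#' fixed numeric threshold. Comparisons are strict.
#'
#' @param trait trait label; must match a name in the fitted-chain list
#'   given to [posterior_proportion] / [rank_crosses].
#' @param direction `"greater"` or `"less"` (e.g. `"less"` for an earlier
#'   harvest time on a scale where small means early).
#' @param reference an individual id (character) or a numeric threshold.
#' @return an object of class `selection_criterion`.
#' @examples
#' selection_criterion("harvest_time", "less", "Kosui")
#' @export
selection_criterion <- function(trait, direction = c("greater", "less"),
                                reference) {
  direction <- match.arg(direction)
  ok <- length(reference) == 1L && (is.character(reference) || is.numeric(reference))
  if (!ok)
    stop("'reference' must be a single individual id or a numeric threshold")
  structure(list(trait = as.character(trait), direction = direction,
                 reference = reference), class = "selection_criterion")
}

#' @export
print.selection_criterion <- function(x, ...) {
  cat(sprintf("criterion: %s %s %s\n", x$trait,
              if (x$direction == "greater") ">" else "<",
              format(x$reference)))
  invisible(x)
}

#' Per-cycle breeding-value samples of simulated progeny
#'
#' For each retained MCMC sample n and progeny i, the breeding value is
#' the cycle-n intercept plus that cycle's allele (or genotype-class) effects
#' over the progeny's genotype. Progeny alleles absent from the training
#' design contribute zero (with a warning); this cannot occur for progeny
#' simulated from training parents.
#'
#' @param object a fitted [bayesA] model.
#' @param progeny a [marker_panel] (e.g. from [simulate_progeny]).
#' @return numeric matrix, progeny x retained samples.
#' @export
progeny_bv_samples <- function(object, progeny) {
  predict(object, newdata = progeny, type = "samples", unknown = "zero")
}

#' Posterior distribution of the proportion of acceptable progeny
#'
#' For each retained MCMC cycle n, the proportion `p[n]` of simulated
#' progeny whose cycle-n breeding values satisfy every selection criterion
#' is computed; criteria referencing a parent compare against that parent's
#' cycle-n breeding value. Aggregating `p[n]` over cycles gives the
#' posterior distribution of the proportion, whose spread reflects the
#' uncertainty of the marker-effect estimates. Multi-trait criteria pair
#' chains by cycle index, so all chains must retain the same number of
#' samples.
#'
#' @param fits named list of fitted [bayesA] models, one per trait.
#' @param progeny a [marker_panel] of S (simulated) progeny.
#' @param criteria a [selection_criterion] or list of them.
#' @param panel panel holding any reference individuals named in the
#'   criteria (only needed then).
#' @return object of class `cross_report`: `p` (vector of per-cycle
#'   proportions, each a multiple of 1/S), `mean`, `quantiles`, `S`,
#'   `parents` (if `progeny` carries them) and per-trait posterior-mean
#'   progeny breeding values.
#' @export
posterior_proportion <- function(fits, progeny, criteria, panel = NULL) {
  if (inherits(fits, "bayesA")) fits <- stats::setNames(list(fits), criteria_traits(criteria)[1L])
  if (inherits(criteria, "selection_criterion")) criteria <- list(criteria)
  stopifnot(all(vapply(criteria, inherits, TRUE, "selection_criterion")),
            inherits(progeny, "marker_panel"))
  traits <- criteria_traits(criteria)
  if (!all(traits %in% names(fits)))
    stop("no fitted chain for trait(s): ",
         paste(setdiff(traits, names(fits)), collapse = ", "))
  ns <- unique(vapply(fits[traits], function(f) f$retained, 0L))
  if (length(ns) != 1L)
    stop("chains have different retained lengths; refit with equal MCMC schedules")
  S <- length(progeny$ids)

  ok <- matrix(TRUE, S, ns)
  bv_mean <- list()
  for (cr in criteria) {
    f <- fits[[cr$trait]]
    G <- progeny_bv_samples(f, progeny)
    bv_mean[[cr$trait]] <- rowMeans(G)
    ref <- if (is.character(cr$reference)) {
      if (is.null(panel)) stop("criteria reference individuals; supply 'panel'")
      if (!cr$reference %in% panel$ids)
        stop(sprintf("reference individual '%s' not in panel", cr$reference))
      as.numeric(predict(f, panel[cr$reference, ], type = "samples"))
    } else rep(as.numeric(cr$reference), ns)
    ok <- ok & if (cr$direction == "greater") G > rep(ref, each = S)
               else G < rep(ref, each = S)
  }
  p <- colMeans(ok)
  structure(list(p = p, mean = mean(p),
                 quantiles = stats::quantile(p, c(0.025, 0.5, 0.975)),
                 S = S, retained = ns,
                 parents = attr(progeny, "parents"),
                 progeny_bv = bv_mean,
                 criteria = criteria),
            class = "cross_report")
}

criteria_traits <- function(criteria) {
  if (inherits(criteria, "selection_criterion")) return(criteria$trait)
  vapply(criteria, function(cr) cr$trait, "")
}

#' @export
print.cross_report <- function(x, ...) {
  if (!is.null(x$parents))
    cat(sprintf("cross %s x %s\n", x$parents[1L], x$parents[2L]))
  cat(sprintf("posterior proportion of progeny fulfilling %d criterion/criteria (S = %d):\n",
              length(x$criteria), x$S))
  cat(sprintf("  mean %.4f;  2.5%% %.4f, median %.4f, 97.5%% %.4f\n",
              x$mean, x$quantiles[1L], x$quantiles[2L], x$quantiles[3L]))
  invisible(x)
}

#' Posterior histogram of a cross report
#'
#' @param x a `cross_report`.
#' @param breaks passed to [hist()].
#' @param ... further arguments to [hist()].
#' @export
plot.cross_report <- function(x, breaks = seq(0, 1, by = 0.05), ...) {
  graphics::hist(x$p, breaks = breaks, freq = FALSE,
                 main = if (!is.null(x$parents))
                   sprintf("%s x %s", x$parents[1L], x$parents[2L]) else "",
                 xlab = "proportion of progeny fulfilling criteria", ...)
  invisible(x)
}

#' Enumerate all candidate crosses
#'
#' All unordered pairs of distinct panel individuals (no self-crosses), in
#' deterministic lexicographic order of the id vector.
#'
#' @param panel a [marker_panel], or a character vector of ids.
#' @return data frame with columns `parentA`, `parentB`; `choose(N, 2)` rows.
#' @examples
#' nrow(enumerate_crosses(letters[1:10]))  # 45
#' @export
enumerate_crosses <- function(panel) {
  ids <- if (inherits(panel, "marker_panel")) panel$ids else as.character(panel)
  if (length(ids) < 2L) stop("need at least 2 individuals to form a cross")
  pairs <- utils::combn(sort(ids), 2L)
  data.frame(parentA = pairs[1L, ], parentB = pairs[2L, ],
             stringsAsFactors = FALSE)
}

#' Rank all candidate crosses by posterior proportion of acceptable progeny
#'
#' For every unordered parent pair, simulates `S` progeny from the phased
#' parental haplotypes, computes the posterior distribution of the
#' proportion of progeny fulfilling the selection criteria, and ranks
#' crosses by the posterior mean (ties broken lexicographically by cross
#' label). Per-cross simulation seeds are derived deterministically from
#' `seed`, so a run is exactly reproducible.
#'
#' @param panel phased [marker_panel] of candidate parents.
#' @param map a [linkage_map].
#' @param fits named list of fitted [bayesA] models (one per criterion trait).
#' @param criteria [selection_criterion] or list of them.
#' @param S progeny per cross.
#' @param seed master seed (integer).
#' @param top keep only the best `top` crosses in the returned table.
#' @param keep_reports also return the per-cross `cross_report` objects
#'   (posterior histograms); off by default to save memory.
#' @return data frame of class `cross_ranking`: `parentA`, `parentB`,
#'   `mean`, `q2.5`, `q97.5`, sorted by decreasing posterior mean.
#' @export
rank_crosses <- function(panel, map, fits, criteria, S = 1000, seed = NULL,
                         top = Inf, keep_reports = FALSE) {
  stopifnot(inherits(panel, "marker_panel"))
  crosses <- enumerate_crosses(panel)
  nc <- nrow(crosses)
  means <- numeric(nc); qlo <- numeric(nc); qhi <- numeric(nc)
  reports <- if (keep_reports) vector("list", nc) else NULL
  for (k in seq_len(nc)) {
    prog <- tryCatch(
      simulate_progeny(panel, map, crosses$parentA[k], crosses$parentB[k],
                       S = S,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, k)),
      error = function(e) stop(sprintf("cross %s x %s: %s", crosses$parentA[k],
                                       crosses$parentB[k], conditionMessage(e))))
    rep_k <- posterior_proportion(fits, prog, criteria, panel = panel)
    means[k] <- rep_k$mean
    qlo[k] <- rep_k$quantiles[1L]; qhi[k] <- rep_k$quantiles[3L]
    if (keep_reports) reports[[k]] <- rep_k
  }
  ord <- order(-means, crosses$parentA, crosses$parentB)
  out <- data.frame(parentA = crosses$parentA[ord], parentB = crosses$parentB[ord],
                    mean = means[ord], q2.5 = qlo[ord], q97.5 = qhi[ord],
                    stringsAsFactors = FALSE)
  if (is.finite(top)) out <- utils::head(out, top)
  rownames(out) <- NULL
  class(out) <- c("cross_ranking", "data.frame")
  if (keep_reports) attr(out, "reports") <- reports[ord]
  out
}
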