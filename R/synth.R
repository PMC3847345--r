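#' Simulate a linkage map with realistic marker spacing
#'
#' Adjacent-marker gaps are drawn from a log-normal distribution
#' parameterised by the target mean and median spacing (median < mean gives
#' the right-skewed gap distribution typical of real maps). The draw is
#' repeated until the realised mean spacing is within 20% of the target.
#'
#' @param n_markers total markers.
#' @param n_groups number of linkage groups.
#' @param mean_spacing,median_spacing target mean and median adjacent gap
#'   in cM; the median must not exceed the mean.
#' @param seed optional seed (local to the call).
#' @return a [linkage_map] with markers `M001`, `M002`, ... on groups
#'   `LG01`, `LG02`, ...
#' @export
sim_linkage_map <- function(n_markers = 333, n_groups = 17,
                            mean_spacing = 4.0, median_spacing = 2.7,
                            seed = NULL) {
  if (n_markers < n_groups) stop("need at least one marker per linkage group")
  if (median_spacing > mean_spacing || median_spacing <= 0)
    stop("need 0 < median_spacing <= mean_spacing (right-skewed gaps)")
  mu <- log(median_spacing)
  sigma <- sqrt(2 * (log(mean_spacing) - mu))
  per_group <- rep(n_markers %/% n_groups, n_groups) +
    rep(c(1L, 0L), c(n_markers %% n_groups, n_groups - n_markers %% n_groups))
  with_seed(seed, {
    for (try in 1:50) {
      pos <- unlist(lapply(per_group, function(m)
        cumsum(c(0, stats::rlnorm(m - 1L, mu, sigma)))))
      gaps <- unlist(lapply(split(pos, rep(seq_len(n_groups), per_group)), diff))
      if (length(gaps) == 0L ||
          abs(mean(gaps) - mean_spacing) <= 0.2 * mean_spacing) break
    }
    linkage_map(marker = sprintf("M%03d", seq_len(n_markers)),
                group = sprintf("LG%02d", rep(seq_len(n_groups), per_group)),
                position = pos)
  })
}

#' Simulate a phased multi-allelic breeding panel
#'
#' Founder haplotypes are drawn marker-by-marker from Dirichlet-distributed
#' allele frequencies (multi-allelic, SSR-like). The panel is then
#' propagated through `depth` generations of random crossing via the
#' meiosis simulator, which creates the linkage disequilibrium and kinship
#' structure of a breeding germplasm collection while keeping the true
#' phase known.
#'
#' @param map a [linkage_map] (e.g. from [sim_linkage_map]); its markers
#'   define the panel markers.
#' @param n panel size (also the number of founders).
#' @param alleles_per_marker integer vector to sample the allele count per
#'   marker from.
#' @param depth generations of random crossing (0 = unrelated founders,
#'   no LD beyond chance).
#' @param seed optional seed (local to the call).
#' @return a phased [marker_panel] of `n` individuals.
#' @export
sim_founder_panel <- function(map, n = 84, alleles_per_marker = 2:8,
                              depth = 3, seed = NULL) {
  stopifnot(inherits(map, "linkage_map"))
  J <- nrow(map)
  with_seed(seed, {
    alleles <- lapply(seq_len(J), function(j) {
      L <- if (length(alleles_per_marker) == 1L) alleles_per_marker
           else sample(alleles_per_marker, 1L)
      sprintf("%d", 100L + 4L * seq_len(L))  # SSR-like fragment sizes
    })
    names(alleles) <- map$marker
    hapA <- matrix(NA_integer_, n, J)
    hapB <- matrix(NA_integer_, n, J)
    for (j in seq_len(J)) {
      L <- length(alleles[[j]])
      f <- stats::rgamma(L, 1); f <- f / sum(f)
      hapA[, j] <- sample.int(L, n, replace = TRUE, prob = f)
      hapB[, j] <- sample.int(L, n, replace = TRUE, prob = f)
    }
    panel <- new_marker_panel(sprintf("G0_%03d", seq_len(n)), map$marker,
                              alleles, hapA, hapB, phased = TRUE)
    layout <- map_layout(panel, map)
    for (gen in seq_len(depth)) {
      newA <- matrix(NA_integer_, n, J)
      newB <- matrix(NA_integer_, n, J)
      for (i in seq_len(n)) {
        par <- sample.int(n, 2L)  # two distinct random parents
        newA[i, ] <- gamete_matrix(panel, par[1L], layout, 1L)
        newB[i, ] <- gamete_matrix(panel, par[2L], layout, 1L)
      }
      panel <- new_marker_panel(sprintf("G%d_%03d", gen, seq_len(n)),
                                map$marker, alleles, newA, newB, phased = TRUE)
    }
    panel$ids <- sprintf("cv%03d", seq_len(n))
    dimnames(panel$hapA)[[1]] <- dimnames(panel$hapB)[[1]] <- panel$ids
    panel
  })
}

#' Simulate a pear-like breeding dataset
#'
#' Convenience generator producing the study conditions assumed throughout:
#' a phased panel of 84 diploid individuals genotyped at 333 multi-allelic
#' markers on 17 linkage groups with mean/median adjacent spacing near
#' 4.0/2.7 cM, and LD from 3 generations of random crossing.
#'
#' @param n,n_markers,n_groups,depth override the defaults.
#' @param seed optional seed (local to the call).
#' @return list with `panel` (phased [marker_panel]) and `map`
#'   ([linkage_map]).
#' @export
sim_panel <- function(n = 84, n_markers = 333, n_groups = 17, depth = 3,
                      seed = NULL) {
  with_seed(seed, {
    map <- sim_linkage_map(n_markers, n_groups)
    panel <- sim_founder_panel(map, n = n, depth = depth)
    list(panel = panel, map = map)
  })
}

#' Simulate an ordinal or continuous trait on a panel
#'
#' Genetic values come from planted QTL (geometric variance series, see
#' [assign_qtl_effects]); Gaussian noise is added at the target
#' heritability. For ordinal traits the continuous phenotype is cut into
#' `M` categories, either at supplied `cutpoints` (strictly increasing) or
#' at phenotype quantiles matching `category_probs` (default: equal
#' frequencies). The generating truth (genetic values, QTL, cut-points) is
#' returned so parameter-recovery tests can score the fitted model.
#'
#' @param panel a [marker_panel].
#' @param n_qtl number of QTL.
#' @param n_effective target effective QTL number (defaults to `n_qtl`,
#'   i.e. equal variances).
#' @param h2 heritability of the continuous phenotype, in (0, 1].
#' @param M number of ordinal categories; `NULL` for a continuous trait.
#' @param cutpoints optional strictly increasing vector of M-1 cut-points
#'   on the phenotype scale.
#' @param category_probs optional target category frequencies (length M).
#' @param seed optional seed (local to the call).
#' @return list: `phenotype` (scores 1..M, or continuous), `continuous`
#'   (the underlying continuous phenotype), `genetic`, `qtl`, `cutpoints`
#'   (ordinal only), `h2_realized`.
#' @export
sim_trait <- function(panel, n_qtl = 5, n_effective = n_qtl, h2 = 0.75,
                      M = NULL, cutpoints = NULL, category_probs = NULL,
                      seed = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  if (h2 <= 0 || h2 > 1) stop("'h2' must be in (0, 1]")
  if (!is.null(M) && M < 2L) stop("ordinal traits need at least 2 categories")
  if (!is.null(cutpoints) && any(diff(cutpoints) <= 0))
    stop("cut-points must be strictly increasing")
  with_seed(seed, {
    lambda <- if (n_effective == n_qtl) 1 else solve_geometric_ratio(n_qtl, n_effective)
    poly <- which(vapply(seq_along(panel$markers), function(j) {
      aj <- c(panel$hapA[, j], panel$hapB[, j])
      length(unique(aj[!is.na(aj)])) > 1L
    }, TRUE))
    if (length(poly) < n_qtl) stop("too few polymorphic markers for the requested QTL")
    qtl <- assign_qtl_effects(panel, sample(poly, n_qtl), lambda, total_var = 1)
    g <- genetic_values(panel, qtl)
    noise_sd <- sqrt((1 - h2) / h2)
    y <- g + if (noise_sd > 0) stats::rnorm(length(g), 0, noise_sd) else 0
    out <- list(continuous = y, genetic = g, qtl = qtl,
                h2_realized = stats::var(g) / stats::var(y))
    if (is.null(M)) {
      out$phenotype <- y
    } else {
      if (is.null(cutpoints)) {
        if (is.null(category_probs)) category_probs <- rep(1 / M, M)
        if (length(category_probs) != M) stop("'category_probs' must have length M")
        cutpoints <- stats::quantile(y, cumsum(category_probs)[-M], names = FALSE)
        if (any(diff(cutpoints) <= 0))
          cutpoints <- cutpoints + seq_along(cutpoints) * 1e-9
      }
      if (length(cutpoints) != M - 1L) stop("need M - 1 cut-points")
      # score m iff K_{m-1} < y <= K_m
      s <- findInterval(y, cutpoints, left.open = TRUE) + 1L
      s <- pmin(pmax(s, 1L), M)
      names(s) <- panel$ids
      out$phenotype <- s
      out$cutpoints <- cutpoints
    }
    out
  })
}
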