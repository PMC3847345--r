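#' Haldane's map function
#'
#' Converts a map distance in cM to a recombination fraction assuming no
#' crossover interference: r = (1 - exp(-2 d)) / 2 with d in Morgans.
#'
#' @param d map distance(s) in centiMorgans, non-negative.
#' @return recombination fraction(s) in \[0, 0.5).
#' @examples
#' haldane(c(0, 10, 50))
#' @export
haldane <- function(d) {
  if (anyNA(d) || any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

# Per linkage group: marker indices into the panel and recombination
# fractions between adjacent mapped markers; unmapped markers segregate
# freely (r = 0.5 to everything, drawn independently).
map_layout <- function(panel, map) {
  idx <- match(map$marker, panel$markers)
  if (anyNA(idx))
    stop("linkage map contains markers absent from the panel: ",
         paste(map$marker[is.na(idx)][seq_len(min(3, sum(is.na(idx))))],
               collapse = ", "))
  groups <- split(seq_len(nrow(map)), map$group)
  layout <- lapply(groups, function(rows) {
    list(cols = idx[rows], r = haldane(diff(map$position[rows])))
  })
  unmapped <- setdiff(seq_along(panel$markers), idx)
  if (length(unmapped))
    warning(sprintf("%d marker(s) not on the linkage map segregate independently (r = 0.5)",
                    length(unmapped)))
  list(groups = layout, unmapped = unmapped)
}

# S gametes from one phased parent: S x J matrix of allele indices.
# Within a linkage group the starting haplotype is uniform and adjacent
# intervals switch independently with probability r (no interference).
gamete_matrix <- function(panel, parent_row, layout, S) {
  hapA <- panel$hapA[parent_row, ]
  hapB <- panel$hapB[parent_row, ]
  if (anyNA(hapA) || anyNA(hapB))
    stop(sprintf("parent '%s' has missing genotypes; gamete simulation needs complete phased data",
                 panel$ids[parent_row]))
  J <- length(panel$markers)
  G <- matrix(NA_integer_, S, J)
  for (grp in layout$groups) {
    cols <- grp$cols
    m <- length(cols)
    cur <- sample.int(2L, S, replace = TRUE) - 1L  # 0 = hapA, 1 = hapB
    for (k in seq_len(m)) {
      if (k > 1L)  # switch haplotype across interval k-1 with prob r
        cur <- (cur + as.integer(stats::runif(S) < grp$r[k - 1L])) %% 2L
      j <- cols[k]
      G[, j] <- ifelse(cur == 1L, hapB[j], hapA[j])
    }
  }
  for (j in layout$unmapped) {
    pick <- stats::runif(S) < 0.5
    G[, j] <- ifelse(pick, hapB[j], hapA[j])
  }
  G
}

#' Simulate gametes of a phased parent
#'
#' Draws `S` gametes by simulating meioses along the linkage map: per
#' linkage group the transmitted haplotype starts at either parental
#' haplotype with probability 1/2 and switches across each adjacent-marker
#' interval independently with the Haldane recombination fraction of the
#' interval (no interference). Markers absent from the map are transmitted
#' with free recombination (r = 0.5) and a warning.
#'
#' @param panel a phased [marker_panel].
#' @param parent individual id (or index) of the parent.
#' @param map a [linkage_map].
#' @param S number of gametes.
#' @param seed optional integer seed (local to the call).
#' @return integer matrix (S x J) of transmitted allele indices, columns
#'   aligned to `panel$markers`.
#' @export
simulate_gametes <- function(panel, parent, map, S, seed = NULL) {
  stopifnot(inherits(panel, "marker_panel"), inherits(map, "linkage_map"))
  if (!panel$phased)
    stop("panel is not phased; supply phased haplotypes (a|b calls) to simulate gametes")
  if (S < 1L) stop("'S' must be at least 1")
  if (is.character(parent)) parent <- match(parent, panel$ids)
  if (is.na(parent)) stop("unknown parent id")
  layout <- map_layout(panel, map)
  with_seed(seed, gamete_matrix(panel, parent, layout, S))
}

#' Simulate an F1 progeny population for one cross
#'
#' Each progeny receives one simulated gamete from each parent
#' (see [simulate_gametes]). The default population size of 1000 is the
#' size used throughout cross ranking.
#'
#' @param panel a phased [marker_panel] containing both parents.
#' @param map a [linkage_map].
#' @param parentA,parentB ids (or indices) of the two parents.
#' @param S progeny population size.
#' @param seed optional integer seed (local to the call).
#' @return a phased `marker_panel` of S progeny (class also
#'   `progeny_population`), with attributes `parents` and `seed`.
#' @export
simulate_progeny <- function(panel, map, parentA, parentB, S = 1000, seed = NULL) {
  stopifnot(inherits(panel, "marker_panel"), inherits(map, "linkage_map"))
  if (!panel$phased) stop("panel is not phased; cannot simulate progeny")
  if (S < 1L) stop("progeny population size must be at least 1")
  if (is.character(parentA)) parentA <- match(parentA, panel$ids)
  if (is.character(parentB)) parentB <- match(parentB, panel$ids)
  if (is.na(parentA) || is.na(parentB)) stop("unknown parent id")
  layout <- map_layout(panel, map)
  out <- with_seed(seed, {
    hA <- gamete_matrix(panel, parentA, layout, S)
    hB <- gamete_matrix(panel, parentB, layout, S)
    list(hA = hA, hB = hB)
  })
  ids <- sprintf("%s_x_%s_%04d", panel$ids[parentA], panel$ids[parentB], seq_len(S))
  prog <- new_marker_panel(ids, panel$markers, panel$alleles,
                           out$hA, out$hB, phased = TRUE)
  class(prog) <- c("progeny_population", class(prog))
  attr(prog, "parents") <- panel$ids[c(parentA, parentB)]
  attr(prog, "seed") <- seed
  prog
}

# run code under a locally-set seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
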