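#' Linkage map
#'
#' Ordered table of marker positions used to simulate recombination.
#' Positions are in centiMorgans; within a linkage group they must be
#' non-decreasing (co-located markers are allowed and never recombine).
#'
#' @param marker marker names.
#' @param group linkage-group labels (arbitrary strings).
#' @param position map positions in cM, non-negative.
#' @return a data frame of class `linkage_map` with columns `marker`,
#'   `group`, `position`, sorted by group then position (ties keep input
#'   order).
#' @export
linkage_map <- function(marker, group, position) {
  marker <- as.character(marker)
  group <- as.character(group)
  position <- as.numeric(position)
  if (length(marker) != length(group) || length(marker) != length(position))
    stop("'marker', 'group' and 'position' must have equal length")
  if (anyDuplicated(marker))
    stop("duplicated marker in linkage map: ",
         marker[duplicated(marker)][1L])
  if (anyNA(position) || any(position < 0))
    stop("map positions must be non-negative and non-missing")
  ord <- order(group, position, seq_along(marker))
  df <- data.frame(marker = marker[ord], group = group[ord],
                   position = position[ord], stringsAsFactors = FALSE)
  class(df) <- c("linkage_map", "data.frame")
  df
}

#' @export
print.linkage_map <- function(x, ...) {
  gaps <- map_spacings(x)
  cat(sprintf("linkage_map: %d markers in %d linkage groups\n",
              nrow(x), length(unique(x$group))))
  if (length(gaps))
    cat(sprintf("  adjacent spacing: mean %.2f cM, median %.2f cM (non-zero gaps)\n",
                mean(gaps), stats::median(gaps)))
  invisible(x)
}

#' Adjacent-marker spacings of a map
#'
#' @param map a [linkage_map].
#' @param include_zero keep zero gaps between co-located markers?
#'   The conventional summary of map density excludes them.
#' @return numeric vector of adjacent-marker distances in cM.
#' @export
map_spacings <- function(map, include_zero = FALSE) {
  stopifnot(inherits(map, "linkage_map"))
  gaps <- unlist(lapply(split(map$position, map$group), diff), use.names = FALSE)
  if (!include_zero) gaps <- gaps[gaps > 0]
  gaps
}
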