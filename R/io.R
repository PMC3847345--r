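#' Read and write marker genotype tables
#'
#' Tab-separated text with a header line `id<TAB>marker1<TAB>...`; one row
#' per individual. Cells are `a/b` (unphased), `a|b` (phased) or `./.`
#' (missing); all non-missing cells must use the same separator. Writing a
#' panel and reading it back reproduces the identical object.
#'
#' @param path file path.
#' @return [read_genotypes()] returns a [marker_panel].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("genotype file needs an id column and at least one marker column")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicated individual id '%s' in %s (line %d)",
                 ids[duplicated(ids)][1L], path,
                 which(duplicated(ids))[1L] + 1L))
  calls <- as.matrix(df[, -1L, drop = FALSE])
  rownames(calls) <- ids
  marker_panel(calls)
}

#' @param panel a [marker_panel].
#' @rdname read_genotypes
#' @export
write_genotypes <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  sep <- if (panel$phased) "|" else "/"
  J <- length(panel$markers)
  cells <- matrix("./.", length(panel$ids), J)
  for (j in seq_len(J)) {
    lab <- panel$alleles[[j]]
    obs <- !is.na(panel$hapA[, j])
    cells[obs, j] <- paste(lab[panel$hapA[obs, j]], lab[panel$hapB[obs, j]],
                           sep = sep)
  }
  df <- data.frame(id = panel$ids, cells, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("id", panel$markers)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write linkage map tables
#'
#' Tab-separated with header `marker<TAB>linkage_group<TAB>cM`.
#'
#' @param path file path.
#' @return [read_map()] returns a [linkage_map].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("marker", "linkage_group", "cM")
  if (!all(need %in% names(df)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(suppressWarnings(as.numeric(df$cM))))
  if (length(bad))
    stop(sprintf("non-numeric cM value '%s' at line %d of %s",
                 df$cM[bad[1L]], bad[1L] + 1L, path))
  linkage_map(df$marker, df$linkage_group, as.numeric(df$cM))
}

#' @param map a [linkage_map].
#' @rdname read_map
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "linkage_map"))
  df <- data.frame(marker = map$marker, linkage_group = map$group,
                   cM = map$position)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Tab-separated with header `id<TAB>trait1<TAB>...`; `NA` marks missing
#' values. Ordinal traits may declare their category count via
#' `categories`, in which case out-of-range scores are rejected with the
#' offending individual named.
#'
#' @param path file path.
#' @param categories optional named list/vector giving the number of
#'   ordinal categories per trait (e.g. `c(harvest_time = 4)`).
#' @return [read_phenotypes()] returns a data frame, one row per
#'   individual, first column `id`.
#' @export
read_phenotypes <- function(path, categories = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1L] != "id") stop("phenotype file must start with an 'id' column")
  if (anyDuplicated(df$id))
    stop("duplicated individual id in phenotype file: ",
         df$id[duplicated(df$id)][1L])
  for (tr in names(categories)) {
    if (!tr %in% names(df)) stop("declared trait not in file: ", tr)
    v <- df[[tr]]
    bad <- which(!is.na(v) & (v < 1 | v > categories[[tr]] | v != round(v)))
    if (length(bad))
      stop(sprintf("score %s out of declared range 1..%d for trait '%s', individual '%s'",
                   format(v[bad[1L]]), categories[[tr]], tr, df$id[bad[1L]]))
  }
  df
}

#' @param phenotypes data frame with first column `id`.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a cross-ranking table
#'
#' @param ranking a `cross_ranking` from [rank_crosses].
#' @param path file path (TSV: parentA, parentB, posterior mean, 2.5% and
#'   97.5% posterior quantiles of the proportion).
#' @export
write_cross_report <- function(ranking, path) {
  stopifnot(inherits(ranking, "data.frame"))
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
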