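#' Diploid multi-allelic marker panel
#'
#' A `marker_panel` holds diploid genotypes of N individuals at J markers,
#' where each marker may carry an arbitrary number of alleles (SSR-style).
#' Genotypes are stored as a pair of allele indices per individual and
#' marker; when `phased = TRUE` the pair is ordered (haplotype A, haplotype
#' B), which is required to simulate gametes.
#'
#' @param calls character matrix (individuals x markers) of genotype calls.
#'   Each cell is `"a/b"` (unphased), `"a|b"` (phased) or `"./."` (missing),
#'   where `a`, `b` are arbitrary allele labels (e.g. SSR fragment sizes).
#'   All cells must use the same separator.
#' @param ids individual identifiers; defaults to `rownames(calls)`.
#' @param markers marker names; defaults to `colnames(calls)`.
#'
#' @return an object of class `marker_panel` with elements `ids`,
#'   `markers` (names), `alleles` (list of per-marker allele label vectors),
#'   `hapA`, `hapB` (integer matrices of 1-based allele indices, `NA` =
#'   missing) and `phased`.
#' @examples
#' calls <- rbind(ind1 = c(m1 = "120/124", m2 = "88/88"),
#'                ind2 = c(m1 = "124/124", m2 = "88/92"))
#' pan <- marker_panel(calls)
#' allele_frequencies(pan)
#' @export
marker_panel <- function(calls, ids = rownames(calls), markers = colnames(calls)) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("'calls' must be a character matrix of genotype calls")
  n <- nrow(calls); J <- ncol(calls)
  if (n < 1L || J < 1L) stop("panel needs at least one individual and one marker")
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(markers)) markers <- paste0("m", seq_len(J))
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (anyDuplicated(markers)) stop("marker names must be unique")

  phased_cell <- grepl("|", calls, fixed = TRUE)
  unphased_cell <- grepl("/", calls, fixed = TRUE)
  bad <- !(phased_cell | unphased_cell)
  if (any(bad)) {
    w <- arrayInd(which(bad)[1L], dim(calls))
    stop(sprintf("malformed genotype call '%s' for individual '%s' at marker '%s'",
                 calls[which(bad)[1L]], ids[w[1L]], markers[w[2L]]))
  }
  missing_cell <- calls %in% c("./.", ".|.")
  phased <- all(phased_cell | missing_cell) && any(phased_cell)

  parts <- strsplit(calls, "[/|]")
  lens <- lengths(parts)
  if (any(lens != 2L)) {
    w <- which(lens != 2L, arr.ind = FALSE)[1L]
    stop(sprintf("genotype call '%s' does not contain exactly two alleles", calls[w]))
  }
  a1 <- matrix(vapply(parts, `[`, "", 1L), n, J)
  a2 <- matrix(vapply(parts, `[`, "", 2L), n, J)
  a1[missing_cell] <- NA_character_
  a2[missing_cell] <- NA_character_
  half_missing <- xor(is.na(a1) | a1 == ".", is.na(a2) | a2 == ".")
  if (any(half_missing))
    stop("half-missing genotype calls (one allele '.') are not supported")

  alleles <- vector("list", J)
  hapA <- matrix(NA_integer_, n, J, dimnames = list(ids, markers))
  hapB <- hapA
  for (j in seq_len(J)) {
    lab <- sort(unique(c(a1[, j], a2[, j])))
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0L)
      stop(sprintf("marker '%s' has all genotypes missing", markers[j]))
    alleles[[j]] <- lab
    hapA[, j] <- match(a1[, j], lab)
    hapB[, j] <- match(a2[, j], lab)
  }
  names(alleles) <- markers
  new_marker_panel(ids, markers, alleles, hapA, hapB, phased)
}

#' @noRd
new_marker_panel <- function(ids, markers, alleles, hapA, hapB, phased) {
  stopifnot(length(ids) == nrow(hapA), length(markers) == ncol(hapA),
            identical(dim(hapA), dim(hapB)))
  dimnames(hapA) <- dimnames(hapB) <- list(ids, markers)
  for (j in seq_along(markers)) {
    aj <- c(hapA[, j], hapB[, j])
    aj <- aj[!is.na(aj)]
    if (length(aj) && (min(aj) < 1L || max(aj) > length(alleles[[j]])))
      stop(sprintf("allele index out of range at marker '%s'", markers[j]))
  }
  structure(list(ids = as.character(ids), markers = as.character(markers),
                 alleles = alleles, hapA = hapA, hapB = hapB,
                 phased = isTRUE(phased)),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  nall <- lengths(x$alleles)
  cat(sprintf("marker_panel: %d individuals x %d markers (%s)\n",
              length(x$ids), length(x$markers),
              if (x$phased) "phased" else "unphased"))
  cat(sprintf("  alleles per marker: %d-%d (mean %.1f)\n",
              min(nall), max(nall), mean(nall)))
  nmiss <- sum(is.na(x$hapA))
  if (nmiss > 0L)
    cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nmiss,
                100 * nmiss / length(x$hapA)))
  invisible(x)
}

#' @export
dim.marker_panel <- function(x) c(length(x$ids), length(x$markers))

#' Subset a marker panel
#'
#' @param x a [marker_panel].
#' @param i individuals (indices or ids).
#' @param j markers (indices or names).
#' @param ... ignored.
#' @return a `marker_panel` restricted to the selected individuals/markers.
#' @export
`[.marker_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ids)
  if (missing(j)) j <- seq_along(x$markers)
  if (is.character(i)) i <- match(i, x$ids)
  if (is.character(j)) j <- match(j, x$markers)
  if (anyNA(i)) stop("unknown individual id in subset")
  if (anyNA(j)) stop("unknown marker name in subset")
  new_marker_panel(x$ids[i], x$markers[j], x$alleles[j],
                   x$hapA[i, j, drop = FALSE], x$hapB[i, j, drop = FALSE],
                   x$phased)
}

#' Per-marker allele frequencies
#'
#' Frequencies are tallied over the 2N allele draws of the panel, excluding
#' missing genotypes.
#'
#' @param panel a [marker_panel].
#' @return named list; element j is a named numeric vector of frequencies
#'   over the alleles of marker j, summing to 1.
#' @export
allele_frequencies <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  J <- length(panel$markers)
  out <- vector("list", J)
  for (j in seq_len(J)) {
    aj <- c(panel$hapA[, j], panel$hapB[, j])
    aj <- aj[!is.na(aj)]
    if (length(aj) == 0L)
      stop(sprintf("marker '%s' has no non-missing genotypes", panel$markers[j]))
    cnt <- tabulate(aj, nbins = length(panel$alleles[[j]]))
    f <- cnt / sum(cnt)
    names(f) <- panel$alleles[[j]]
    out[[j]] <- f
  }
  names(out) <- panel$markers
  out
}

#' Allele-dosage design matrix
#'
#' Builds the regressor matrix of the additive allelic model: one column per
#' (marker, allele), entry = number of copies (0, 1 or 2) of that allele
#' carried by the individual. Missing genotypes are mean-imputed with twice
#' the panel allele frequency, which preserves column means.
#'
#' @param panel a [marker_panel].
#' @param alleles template allele dictionary (list as in `panel$alleles`);
#'   defaults to the panel's own. Supply the training panel's dictionary to
#'   build a prediction design with matching columns.
#' @param unknown what to do with a panel allele label absent from the
#'   template: `"error"` (default) or `"zero"` (contributes no dosage; used
#'   for externally supplied progeny, with a warning).
#' @return numeric matrix (individuals x total allele count) with
#'   column names `"marker:allele"` and attribute `marker` giving the
#'   marker index of each column.
#' @export
build_allele_design <- function(panel, alleles = NULL,
                                unknown = c("error", "zero")) {
  stopifnot(inherits(panel, "marker_panel"))
  unknown <- match.arg(unknown)
  template <- !is.null(alleles)
  if (!template) alleles <- panel$alleles
  if (!identical(names(alleles), panel$markers)) {
    if (!all(panel$markers %in% names(alleles)))
      stop("template allele dictionary lacks markers: ",
           paste(setdiff(panel$markers, names(alleles)), collapse = ", "))
    alleles <- alleles[panel$markers]
  }
  n <- length(panel$ids); J <- length(panel$markers)
  L <- lengths(alleles)
  P <- sum(L)
  off <- cumsum(c(0L, L[-J]))
  X <- matrix(0, n, P, dimnames = list(panel$ids, NULL))
  marker_of_col <- rep.int(seq_len(J), L)
  colnames(X) <- paste(rep.int(panel$markers, L), unlist(alleles), sep = ":")
  freqs <- NULL
  warned <- FALSE
  for (j in seq_len(J)) {
    # map panel allele indices into template columns
    amap <- match(panel$alleles[[j]], alleles[[j]])
    if (anyNA(amap)) {
      missing_lab <- panel$alleles[[j]][is.na(amap)]
      if (unknown == "error")
        stop(sprintf("marker '%s': allele label(s) %s not in template",
                     panel$markers[j], paste(sQuote(missing_lab), collapse = ", ")))
      if (!warned) {
        warning(sprintf(
          "allele(s) absent from the training design (first: marker '%s', allele '%s'); their effects are treated as 0",
          panel$markers[j], missing_lab[1L]))
        warned <- TRUE
      }
    }
    a1 <- amap[panel$hapA[, j]]
    a2 <- amap[panel$hapB[, j]]
    obs <- !is.na(panel$hapA[, j])
    # one index per row within each call, so '+ 1' accumulates correctly
    # across the two haplotypes (homozygotes get dosage 2)
    k1 <- which(obs & !is.na(a1))
    if (length(k1)) {
      i1 <- cbind(k1, off[j] + a1[k1])
      X[i1] <- X[i1] + 1
    }
    k2 <- which(obs & !is.na(a2))
    if (length(k2)) {
      i2 <- cbind(k2, off[j] + a2[k2])
      X[i2] <- X[i2] + 1
    }
    if (any(!obs)) {
      if (is.null(freqs)) freqs <- allele_frequencies(panel)
      f <- freqs[[j]]
      for (l in seq_along(f)) {
        if (!is.na(amap[l])) X[!obs, off[j] + amap[l]] <- 2 * f[l]
      }
    }
  }
  attr(X, "marker") <- marker_of_col
  attr(X, "markers") <- panel$markers
  attr(X, "alleles") <- alleles
  attr(X, "model") <- "allelic"
  X
}

#' Genotype-class indicator design matrix
#'
#' Builds the regressors of the genotype-effect model: one indicator column
#' per distinct unordered genotype observed at each marker. Unobserved
#' allele combinations get no column, avoiding over-parameterization. The
#' per-marker genotype effect absorbs both additive and dominance effects.
#'
#' @param panel a [marker_panel].
#' @param classes template list of observed genotype classes per marker
#'   (as produced by this function, stored in its `"classes"` attribute);
#'   defaults to the classes observed in `panel`.
#' @return numeric indicator matrix with attribute `marker` (marker index
#'   per column) and `classes` (list of class labels per marker). A missing
#'   genotype is imputed with the observed class frequencies; a genotype
#'   not matching any template class contributes no indicator.
#' @export
build_genotype_design <- function(panel, classes = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  n <- length(panel$ids); J <- length(panel$markers)
  # unordered genotype label per cell: "a/b" with allele labels sorted
  geno_label <- function(j) {
    la <- panel$alleles[[j]][panel$hapA[, j]]
    lb <- panel$alleles[[j]][panel$hapB[, j]]
    lo <- ifelse(la <= lb, la, lb)
    hi <- ifelse(la <= lb, lb, la)
    paste(lo, hi, sep = "/")
  }
  labs <- lapply(seq_len(J), geno_label)
  if (is.null(classes)) {
    classes <- lapply(seq_len(J), function(j)
      sort(unique(labs[[j]][!is.na(panel$hapA[, j])])))
    names(classes) <- panel$markers
  } else {
    if (!all(panel$markers %in% names(classes)))
      stop("template genotype classes lack markers present in the panel")
    classes <- classes[panel$markers]
  }
  G <- lengths(classes)
  P <- sum(G)
  off <- cumsum(c(0L, G[-J]))
  X <- matrix(0, n, P, dimnames = list(panel$ids, NULL))
  colnames(X) <- paste(rep.int(panel$markers, G), unlist(classes), sep = ":")
  for (j in seq_len(J)) {
    obs <- !is.na(panel$hapA[, j])
    idx <- match(labs[[j]], classes[[j]])
    k1 <- which(obs & !is.na(idx))
    if (length(k1)) X[cbind(k1, off[j] + idx[k1])] <- 1
    if (any(!obs) && G[j] > 0L) {
      fr <- tabulate(idx[obs], nbins = G[j])
      fr <- fr / sum(fr)
      for (k in which(!obs)) X[k, off[j] + seq_len(G[j])] <- fr
    }
  }
  attr(X, "marker") <- rep.int(seq_len(J), G)
  attr(X, "markers") <- panel$markers
  attr(X, "classes") <- classes
  attr(X, "model") <- "genotype"
  X
}
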