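## Population-genetic summary statistics and genetic distances
##
## Convention used everywhere: only the unambiguous bases A, C, G, T enter a
## comparison. IUPAC ambiguity codes (unphased heterozygous sites) and
## missing symbols are excluded site-wise ("pairwise deletion"), never
## half-counted.

.asAlnMatrix <- function(x) {
  if (methods::is(x, "LocusAlignment")) return(alignmentMatrix(x))
  if (methods::is(x, "DNAStringSet")) return(as.matrix(x))
  if (is.matrix(x)) return(toupper(x))
  if (is.character(x)) {
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("alignment error: sequences differ in length")
    return(matrix(toupper(unlist(strsplit(x, "", fixed = TRUE))),
                  nrow = length(x), byrow = TRUE,
                  dimnames = list(names(x), NULL)))
  }
  stop("cannot interpret input as an alignment")
}

#' Names and order of the default summary-statistic vector
#'
#' 13 statistics for the three focal populations: per-population segregating
#' sites and mean pairwise differences, pooled segregating sites, pairwise
#' between-population mean differences, and pairwise Hudson FST. Observed
#' and simulated vectors always share this definition and order.
#'
#' @return character vector of statistic names.
#' @export
statNames <- function() {
  pops <- c("chilensis", "pallatangae", "albiceps")
  c(paste0("S_", pops), paste0("pi_", pops), "S_total",
    paste0("d_", .PAIR_NAMES), paste0("fst_", .PAIR_NAMES))
}

#' Raw p-distance between two aligned sequences
#'
#' Proportion of differing sites among sites where both sequences carry an
#' unambiguous base (pairwise deletion of missing data and ambiguity
#' codes).
#'
#' @param seqA,seqB aligned sequences (character strings or vectors of
#'   single symbols) of equal length.
#' @return the p-distance, or `NA` when no site is comparable (undefined,
#'   distinct from 0).
#' @export
pairwisePDistance <- function(seqA, seqB) {
  a <- if (length(seqA) == 1L) strsplit(toupper(seqA), "")[[1]] else toupper(seqA)
  b <- if (length(seqB) == 1L) strsplit(toupper(seqB), "")[[1]] else toupper(seqB)
  if (length(a) != length(b)) stop("sequences differ in length")
  ok <- a %in% .UNAMBIGUOUS & b %in% .UNAMBIGUOUS
  if (!any(ok)) return(NA_real_)
  sum(a[ok] != b[ok]) / sum(ok)
}

## pairwise difference counts (not proportions) with pairwise deletion
.pairDiffCounts <- function(m1, m2 = NULL) {
  ok1 <- matrix(m1 %in% .UNAMBIGUOUS, nrow = nrow(m1))
  if (is.null(m2)) {
    n <- nrow(m1)
    if (n < 2L) return(numeric(0))
    out <- numeric(n * (n - 1) / 2); k <- 0L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- ok1[i, ] & ok1[j, ]
      k <- k + 1L
      out[k] <- sum(m1[i, ok] != m1[j, ok])
    }
    return(out)
  }
  ok2 <- matrix(m2 %in% .UNAMBIGUOUS, nrow = nrow(m2))
  out <- numeric(nrow(m1) * nrow(m2)); k <- 0L
  for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2))) {
    ok <- ok1[i, ] & ok2[j, ]
    k <- k + 1L
    out[k] <- sum(m1[i, ok] != m2[j, ok])
  }
  out
}

## same, as proportions over comparable sites (NA when none comparable)
.pairDistProps <- function(m1, m2 = NULL) {
  ok1 <- matrix(m1 %in% .UNAMBIGUOUS, nrow = nrow(m1))
  pair <- function(mi, mj, oki, okj) {
    ok <- oki & okj
    if (!any(ok)) return(NA_real_)
    sum(mi[ok] != mj[ok]) / sum(ok)
  }
  if (is.null(m2)) {
    n <- nrow(m1)
    if (n < 2L) return(numeric(0))
    out <- numeric(n * (n - 1) / 2); k <- 0L
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      k <- k + 1L
      out[k] <- pair(m1[i, ], m1[j, ], ok1[i, ], ok1[j, ])
    }
    return(out)
  }
  ok2 <- matrix(m2 %in% .UNAMBIGUOUS, nrow = nrow(m2))
  out <- numeric(nrow(m1) * nrow(m2)); k <- 0L
  for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2))) {
    k <- k + 1L
    out[k] <- pair(m1[i, ], m2[j, ], ok1[i, ], ok2[j, ])
  }
  out
}

#' Number of segregating sites within a sample
#'
#' Columns where at least two distinct unambiguous bases occur in the set.
#'
#' @param pop an alignment (see [alignmentMatrix()] conventions) with at
#'   least 2 sequences.
#' @return integer count.
#' @export
segregatingSites <- function(pop) {
  m <- .asAlnMatrix(pop)
  if (nrow(m) < 2L) stop("insufficient data: at least 2 sequences required")
  counts <- vapply(.UNAMBIGUOUS, function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  sum(rowSums(counts > 0) >= 2)
}

#' Mean number of pairwise differences within a sample
#'
#' Average over all unordered pairs of the count of differing unambiguous
#' sites; expressed per locus, not per site.
#'
#' @inheritParams segregatingSites
#' @return numeric mean pairwise difference count.
#' @export
meanPairwiseDifferences <- function(pop) {
  m <- .asAlnMatrix(pop)
  if (nrow(m) < 2L) stop("insufficient data: at least 2 sequences required")
  mean(.pairDiffCounts(m))
}

#' Hudson-type pairwise FST between two population samples
#'
#' `1 - piw / pib`, where `piw` is the average of the two within-population
#' mean pairwise difference counts and `pib` the mean between-population
#' pairwise difference count; clamped to `[-1, 1]`. Undefined (NA) when the
#' between-population mean is 0.
#'
#' @param popX,popY alignments with at least 2 sequences each, over the same
#'   columns.
#' @return FST estimate, or `NA` when undefined.
#' @export
pairwiseFst <- function(popX, popY) {
  mx <- .asAlnMatrix(popX); my <- .asAlnMatrix(popY)
  if (nrow(mx) < 2L || nrow(my) < 2L)
    stop("insufficient data: at least 2 sequences per population")
  piw <- mean(c(mean(.pairDiffCounts(mx)), mean(.pairDiffCounts(my))))
  pib <- mean(.pairDiffCounts(mx, my))
  if (pib == 0) return(NA_real_)
  max(-1, min(1, 1 - piw / pib))
}

#' Net between-group mean p-distance
#'
#' Mean between-group raw p-distance minus the average of the two
#' within-group means; singleton groups contribute a within-group mean of 0.
#' Pairwise deletion applies throughout.
#'
#' @param groupX,groupY non-empty alignments over the same columns.
#' @return net distance (can be slightly negative).
#' @export
netBetweenGroupDistance <- function(groupX, groupY) {
  mx <- .asAlnMatrix(groupX); my <- .asAlnMatrix(groupY)
  if (nrow(mx) < 1L || nrow(my) < 1L) stop("groups must be non-empty")
  between <- mean(.pairDistProps(mx, my), na.rm = TRUE)
  withinX <- if (nrow(mx) > 1L) mean(.pairDistProps(mx), na.rm = TRUE) else 0
  withinY <- if (nrow(my) > 1L) mean(.pairDistProps(my), na.rm = TRUE) else 0
  between - (withinX + withinY) / 2
}

.lociForMarkerSet <- function(dataset, markerSet) {
  keep <- switch(markerSet,
                 nuclear = "autosomal",
                 mitochondrial = "mitochondrial",
                 stop("markerSet must be nuclear or mitochondrial"))
  sel <- Filter(function(a) a@inheritance == keep, dataset@loci)
  if (length(sel) == 0L) stop("no loci in marker set '", markerSet, "'")
  sel
}

.popMatrices <- function(dataset, aln, pops) {
  tab <- dataset@samples
  m <- alignmentMatrix(aln)
  lapply(pops, function(p) {
    ids <- tab$sample_id[tab$taxon == p]
    m[rownames(m) %in% ids, , drop = FALSE]
  })
}

## per-locus raw statistics for 3 populations; NA where undefined
.locusRawStats <- function(popMats) {
  S <- pi <- rep(NA_real_, 3)
  for (p in 1:3) {
    if (nrow(popMats[[p]]) >= 2L) {
      S[p] <- segregatingSites(popMats[[p]])
      pi[p] <- mean(.pairDiffCounts(popMats[[p]]))
    }
  }
  pooled <- do.call(rbind, popMats)
  Stot <- if (nrow(pooled) >= 2L) segregatingSites(pooled) else NA_real_
  d <- rep(NA_real_, 3)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (q in 1:3) {
    a <- pairs[[q]][1]; b <- pairs[[q]][2]
    if (nrow(popMats[[a]]) >= 1L && nrow(popMats[[b]]) >= 1L)
      d[q] <- mean(.pairDiffCounts(popMats[[a]], popMats[[b]]))
  }
  list(S = S, pi = pi, Stot = Stot, d = d)
}

## aggregate a list of per-locus raw stats into the 13-component vector;
## shared by the observed route and (in compiled form) the simulator
.aggregateRawStats <- function(rawList) {
  pick <- function(f) t(vapply(rawList, f, numeric(3)))
  Smat <- pick(function(x) x$S)
  piMat <- pick(function(x) x$pi)
  dMat <- pick(function(x) x$d)
  Stot <- vapply(rawList, function(x) x$Stot, 0)
  colMean <- function(m) apply(m, 2, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  fst <- rep(NA_real_, 3)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (q in 1:3) {
    a <- pairs[[q]][1]; b <- pairs[[q]][2]
    ok <- !is.na(piMat[, a]) & !is.na(piMat[, b]) & !is.na(dMat[, q])
    if (!any(ok)) next
    pib <- mean(dMat[ok, q])
    piw <- mean((piMat[ok, a] + piMat[ok, b]) / 2)
    fst[q] <- if (pib <= 0) 0 else max(-1, min(1, 1 - piw / pib))
  }
  out <- c(colMean(Smat), colMean(piMat),
           if (all(is.na(Stot))) NA_real_ else mean(Stot, na.rm = TRUE),
           colMean(dMat), fst)
  names(out) <- statNames()
  out
}

#' Observed summary-statistic vector of a multilocus dataset
#'
#' Computes, per locus of the chosen marker set and per focal population,
#' segregating sites and mean pairwise differences, plus pooled segregating
#' sites, pairwise between-population mean differences and pairwise Hudson
#' FST, then aggregates across loci: arithmetic means, except FST which is
#' the ratio of across-locus means (`1 - mean(piw)/mean(pib)`, 0 when the
#' between-population mean is 0). The ordering is [statNames()] and is
#' identical for simulated vectors.
#'
#' @param dataset a [MultiLocusDataset-class]
#' @param markerSet `"nuclear"` (autosomal loci; the Z-linked class is
#'   excluded) or `"mitochondrial"`.
#' @param pops the three focal taxa, in deme order. Fixed by design.
#' @return named numeric vector of length 13.
#' @export
observedStatVector <- function(dataset,
                               markerSet = c("nuclear", "mitochondrial"),
                               pops = focalTaxa()) {
  markerSet <- match.arg(markerSet)
  stopifnot(identical(pops, focalTaxa()))
  sel <- .lociForMarkerSet(dataset, markerSet)
  tab <- dataset@samples
  for (p in pops) {
    nAny <- max(vapply(sel, function(a)
      sum(names(sequences(a)) %in% tab$sample_id[tab$taxon == p]), 0))
    if (nAny < 2)
      stop("population '", p, "' has fewer than 2 sequences at every locus")
  }
  raw <- lapply(sel, function(a)
    .locusRawStats(.popMatrices(dataset, a, pops)))
  out <- .aggregateRawStats(raw)
  if (anyNA(out)) stop("undefined statistics in observed vector")
  out
}

#' Net between-taxa distance matrix
#'
#' Symmetric matrix of net between-group mean raw p-distances, with
#' pairwise deletion. For the nuclear marker set, distances are computed per
#' autosomal locus and averaged across loci; the mitochondrial matrix uses
#' the single mitochondrial locus.
#'
#' @param dataset a [MultiLocusDataset-class]
#' @param markerSet `"nuclear"` or `"mitochondrial"`.
#' @param taxa which taxon labels to include (default: all labels present).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(dataset,
                           markerSet = c("nuclear", "mitochondrial"),
                           taxa = NULL) {
  markerSet <- match.arg(markerSet)
  sel <- .lociForMarkerSet(dataset, markerSet)
  tab <- dataset@samples
  if (is.null(taxa)) taxa <- unique(tab$taxon)
  k <- length(taxa)
  acc <- matrix(0, k, k, dimnames = list(taxa, taxa))
  cnt <- matrix(0L, k, k)
  for (a in sel) {
    m <- alignmentMatrix(a)
    mats <- lapply(taxa, function(p)
      m[rownames(m) %in% tab$sample_id[tab$taxon == p], , drop = FALSE])
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (nrow(mats[[i]]) < 1L || nrow(mats[[j]]) < 1L) next
      d <- netBetweenGroupDistance(mats[[i]], mats[[j]])
      if (!is.na(d)) {
        acc[i, j] <- acc[i, j] + d
        cnt[i, j] <- cnt[i, j] + 1L
      }
    }
  }
  out <- acc / ifelse(cnt > 0, cnt, NA)
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  diag(out) <- 0
  out
}
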