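## Approximate Bayesian Computation over reference tables:
## rejection sampling with Epanechnikov weighting, multinomial-logistic
## model choice, cross-validation, goodness of fit, posterior predictive
## checks, and regression-adjusted parameter estimation.

.statsOf <- function(x) {
  if (methods::is(x, "ReferenceTable")) x@stats else as.matrix(x)
}

## scale every statistic by its median absolute deviation across the table
## (SD fallback when MAD is 0; dropped with a warning when both are 0)
.normalizeStats <- function(stats, obs) {
  if (length(obs) != ncol(stats))
    stop("dimension mismatch: observed vector has ", length(obs),
         " statistics, table has ", ncol(stats))
  sc <- apply(stats, 2, stats::mad)
  zero <- sc == 0
  sc[zero] <- apply(stats[, zero, drop = FALSE], 2, stats::sd)
  keep <- sc > 0 & !is.na(sc)
  if (!all(keep))
    warning("statistic(s) with zero spread dropped: ",
            paste(colnames(stats)[!keep], collapse = ", "))
  list(table = sweep(stats[, keep, drop = FALSE], 2, sc[keep], "/"),
       obs = as.numeric(obs)[keep] / sc[keep],
       scale = sc, keep = keep)
}

#' Normalized Euclidean distances from an observed vector to a table
#'
#' Each statistic is scaled by its median absolute deviation across the
#' table (standard-deviation fallback when the MAD is 0; a statistic with
#' zero spread is dropped with a warning), then the Euclidean distance of
#' every table row to the observed vector is returned.
#'
#' @param obs observed statistic vector (ordering must match the table).
#' @param table a [ReferenceTable-class] or a numeric statistic matrix.
#' @return numeric vector of distances, one per table row.
#' @export
statDistances <- function(obs, table) {
  st <- .statsOf(table)
  nz <- .normalizeStats(st, obs)
  sqrt(colSums((t(nz$table) - nz$obs)^2))
}

#' Rejection sampling at a tolerance level
#'
#' Retains the `ceiling(tolerance * N)` rows with the smallest distances
#' (boundary ties broken deterministically by row index) and assigns
#' Epanechnikov weights `1 - (d / dmax)^2` relative to the acceptance
#' radius `dmax`; when the radius is 0 all weights are 1.
#'
#' @param distances numeric distances (e.g. from [statDistances()]).
#' @param tolerance retained fraction, in (0, 1].
#' @return list with `index` (retained rows, closest first), `weights`,
#'   `distances` (of retained rows) and `radius`.
#' @export
rejectionSample <- function(distances, tolerance) {
  if (!is.numeric(tolerance) || tolerance <= 0 || tolerance > 1)
    stop("tolerance must lie in (0, 1]")
  n <- length(distances)
  nKeep <- ceiling(tolerance * n)
  ord <- order(distances, seq_len(n))
  idx <- ord[seq_len(nKeep)]
  d <- distances[idx]
  radius <- max(d)
  w <- if (radius > 0) 1 - (d / radius)^2 else rep(1, nKeep)
  list(index = idx, weights = w, distances = d, radius = radius)
}

## multinomial logistic fit of model label on scaled statistics, evaluated
## at the observed point; mild L2 regularization (decay) for separability
.multinomAt <- function(x, labels, xObs, decay) {
  df <- as.data.frame(x)
  colnames(df) <- paste0("s", seq_len(ncol(x)))
  df$.model <- factor(labels)
  newd <- as.data.frame(matrix(xObs, nrow = 1))
  colnames(newd) <- paste0("s", seq_len(ncol(x)))
  fit <- nnet::multinom(.model ~ ., data = df, trace = FALSE,
                        decay = decay, maxit = 500, MaxNWts = 5000)
  p <- predict(fit, newdata = newd, type = "probs")
  lev <- levels(df$.model)
  if (length(lev) == 2L) p <- c(1 - p, p)
  setNames(as.numeric(p), lev)
}

#' Posterior model probabilities by multinomial logistic regression
#'
#' Pools the per-model reference tables, normalizes the statistics jointly,
#' retains the `tolerance` fraction of pooled rows closest to the observed
#' vector, and regresses the model label on the retained (scaled)
#' statistics with a multinomial logistic model, evaluated at the observed
#' point. Equal prior weight per model is assumed (equal table sizes).
#'
#' @param obs observed statistic vector.
#' @param tables named list of [ReferenceTable-class] objects (or statistic
#'   matrices), one per model.
#' @param tolerance retained fraction of the pooled table.
#' @param decay L2 regularization strength of the logistic fit.
#' @return named numeric vector of posterior probabilities, summing to 1.
#' @export
modelPosterior <- function(obs, tables, tolerance, decay = 0.01) {
  if (length(tables) < 2L) stop("at least 2 models required")
  codes <- names(tables)
  if (is.null(codes))
    codes <- vapply(tables, function(t)
      if (methods::is(t, "ReferenceTable")) t@model@code else "?", "")
  statList <- lapply(tables, .statsOf)
  pooled <- do.call(rbind, statList)
  labels <- rep(codes, vapply(statList, nrow, 0L))
  nz <- .normalizeStats(pooled, obs)
  d <- sqrt(colSums((t(nz$table) - nz$obs)^2))
  rs <- rejectionSample(d, tolerance)
  keptLabels <- labels[rs$index]
  present <- codes[codes %in% unique(keptLabels)]
  probs <- setNames(rep(0, length(codes)), codes)
  if (length(present) == 0L) stop("no rows retained")
  if (length(present) == 1L) {
    warning("only model ", present, " retained at this tolerance")
    probs[present] <- 1
    return(probs)
  }
  if (length(present) < length(codes))
    warning("model(s) with zero retained rows: ",
            paste(setdiff(codes, present), collapse = ", "))
  p <- .multinomAt(nz$table[rs$index, , drop = FALSE], keptLabels,
                   nz$obs, decay)
  probs[names(p)] <- pmax(p, 0)
  probs / sum(probs)
}

#' Bayes-factor matrix from posterior model probabilities
#'
#' `BF[i, j] = p_i / p_j` under equal model priors; entries are `Inf` where
#' the denominator probability is 0.
#'
#' @param posteriors named numeric vector of model posterior probabilities.
#' @return square numeric matrix.
#' @export
bayesFactors <- function(posteriors) {
  bf <- outer(posteriors, posteriors, "/")
  dimnames(bf) <- list(names(posteriors), names(posteriors))
  bf
}

#' Cross-validated model classification (confusion and soft matrices)
#'
#' For each model, `nPseudo` reference-table rows are treated in turn as
#' pseudo-observed data, held out, and classified against the remainder
#' with [modelPosterior()]. Hard classification counts the argmax model
#' (confusion matrix, rows = generating model, rows sum to `nPseudo`);
#' soft classification averages the posterior probability vector.
#'
#' @param tables named list of [ReferenceTable-class] objects.
#' @param tolerance retained fraction of the pooled table.
#' @param nPseudo pseudo-observed datasets per model.
#' @param decay L2 regularization of the logistic fit.
#' @return list with `confusion` (counts), `soft` (mean posterior
#'   probabilities) and `accuracy` (overall diagonal proportion).
#' @export
crossValidateModelChoice <- function(tables, tolerance, nPseudo = 100,
                                     decay = 0.01) {
  stopifnot(nPseudo >= 1)
  codes <- names(tables)
  k <- length(codes)
  confusion <- matrix(0L, k, k, dimnames = list(true = codes, inferred = codes))
  soft <- matrix(0, k, k, dimnames = list(true = codes, inferred = codes))
  for (i in seq_len(k)) {
    st <- .statsOf(tables[[i]])
    rows <- sample.int(nrow(st), nPseudo)
    for (r in rows) {
      holdout <- tables
      holdout[[i]] <- st[-r, , drop = FALSE]
      p <- suppressWarnings(
        modelPosterior(st[r, ], holdout, tolerance, decay = decay))
      best <- names(p)[which.max(p)]
      confusion[i, best] <- confusion[i, best] + 1L
      soft[i, ] <- soft[i, ] + p[codes]
    }
    soft[i, ] <- soft[i, ] / nPseudo
  }
  list(confusion = confusion, soft = soft,
       accuracy = sum(diag(confusion)) / (k * nPseudo))
}

## median retained distance of a pseudo-observed vector against a table
.gofStat <- function(obs, stats, tolerance) {
  nz <- .normalizeStats(stats, obs)
  d <- sqrt(colSums((t(nz$table) - nz$obs)^2))
  stats::median(rejectionSample(d, tolerance)$distances)
}

#' Goodness-of-fit test of a model against observed statistics
#'
#' Test statistic: the median normalized distance from the observed vector
#' to its retained set. The null distribution re-computes the same
#' statistic for `nNull` rows of the reference table treated as
#' pseudo-observations (each held out); the p-value is the fraction of null
#' statistics at least as large as the observed one.
#'
#' @param obs observed statistic vector.
#' @param table a [ReferenceTable-class] (or statistic matrix).
#' @param tolerance retained fraction.
#' @param nNull number of null pseudo-observations (>= 100 recommended).
#' @return list with `p.value`, `observed` (the test statistic) and `null`
#'   (the null distribution).
#' @export
goodnessOfFit <- function(obs, table, tolerance, nNull = 500) {
  st <- .statsOf(table)
  observed <- suppressWarnings(.gofStat(obs, st, tolerance))
  rows <- sample.int(nrow(st), min(nNull, nrow(st)))
  null <- vapply(rows, function(r)
    suppressWarnings(.gofStat(st[r, ], st[-r, , drop = FALSE], tolerance)),
    0)
  list(p.value = mean(null >= observed), observed = observed, null = null)
}

#' Posterior predictive check
#'
#' Resamples parameter draws from the weighted retained set, simulates
#' `nRep` statistic vectors under them, and reports for each statistic the
#' fraction of replicates at least as large as the observed value (tail
#' probabilities near 0 or 1 flag statistics the model cannot reproduce).
#'
#' @param posterior a [PosteriorResult-class]
#' @param model the fitted [DemographicModel-class]
#' @param request the [SimulationRequest-class] used for the table.
#' @param obs observed statistic vector.
#' @param nRep number of posterior predictive replicates.
#' @return named numeric vector of tail probabilities (one per statistic).
#' @export
posteriorPredictiveCheck <- function(posterior, model, request, obs,
                                     nRep = 100) {
  stopifnot(nrow(posterior@retained) > 0)
  idx <- sample.int(nrow(posterior@retained), nRep, replace = TRUE,
                    prob = posterior@weights / sum(posterior@weights))
  sims <- t(vapply(idx, function(i)
    simulateStatVector(model, posterior@retained[i, ], request),
    numeric(length(statNames()))))
  setNames(colMeans(sims >= rep(as.numeric(obs), each = nRep)),
           statNames())
}

.weightedQuantile <- function(x, w, p) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  stats::approx(cw, x[ord], xout = p, rule = 2, ties = "ordered")$y
}

.weightedMode <- function(x, w) {
  if (length(unique(x)) == 1L) return(x[1])
  den <- suppressWarnings(
    stats::density(x, weights = w / sum(w), bw = stats::bw.nrd0(x)))
  den$x[which.max(den$y)]
}

#' ABC parameter estimation with optional regression adjustment
#'
#' Retained draws are mapped to an open scale (logit of the position inside
#' their uniform prior bounds), optionally regression-adjusted toward the
#' observed statistics, back-transformed and summarized with Epanechnikov
#' weights. Adjustment methods: `"rejection"` (none), `"loclinear"`
#' (weighted local-linear fit, the deterministic default) and `"neuralnet"`
#' (single-hidden-layer regression, 5 units, weight decay 0.01, 10 restarts
#' aggregated by their element-wise median). A degenerate regression
#' (collinear statistics) falls back to rejection with a warning.
#'
#' Summaries: minimum and maximum of the retained draws; weighted 2.5%,
#' median and 97.5% by weighted quantiles of the adjusted draws; weighted
#' mean; weighted mode as the peak of a Gaussian-kernel density (Silverman
#' bandwidth). The logit transform guarantees adjusted draws respect the
#' prior bounds.
#'
#' @param obs observed statistic vector.
#' @param table a single-model [ReferenceTable-class]
#' @param tolerance retained fraction.
#' @param method `"loclinear"`, `"rejection"` or `"neuralnet"`.
#' @param sizeNet hidden units of the neural-net adjustment.
#' @param decayNet weight decay of the neural-net adjustment.
#' @param restarts neural-net restarts (median-aggregated).
#' @return a [PosteriorResult-class]
#' @export
estimateParameters <- function(obs, table, tolerance,
                               method = c("loclinear", "rejection",
                                          "neuralnet"),
                               sizeNet = 5, decayNet = 0.01, restarts = 10) {
  method <- match.arg(method)
  stopifnot(methods::is(table, "ReferenceTable"))
  nz <- .normalizeStats(table@stats, obs)
  d <- sqrt(colSums((t(nz$table) - nz$obs)^2))
  rs <- rejectionSample(d, tolerance)

  pars <- colnames(table@params)
  bounds <- vapply(table@priors@bounds[pars], identity, numeric(2))
  retained <- table@params[rs$index, , drop = FALSE]
  lo <- bounds[1, ]; hi <- bounds[2, ]
  z <- stats::qlogis(sweep(sweep(retained, 2, lo), 2, hi - lo, "/"))

  X <- nz$table[rs$index, , drop = FALSE]
  Xc <- sweep(X, 2, nz$obs)          # statistics centered at the observation
  zAdj <- z

  if (method == "loclinear") {
    fit <- stats::lm.wfit(cbind(1, Xc), z, rs$weights)
    beta <- fit$coefficients[-1, , drop = FALSE]
    if (anyNA(beta)) {
      warning("degenerate local-linear regression; falling back to rejection")
      method <- "rejection"
    } else {
      zAdj <- z - Xc %*% beta
    }
  } else if (method == "neuralnet") {
    preds <- vector("list", restarts)
    for (r in seq_len(restarts)) {
      fit <- nnet::nnet(x = X, y = z, size = sizeNet, decay = decayNet,
                        linout = TRUE, trace = FALSE, maxit = 500,
                        MaxNWts = 10000)
      predTab <- predict(fit, X)
      predObs <- predict(fit, matrix(nz$obs, nrow = 1))
      preds[[r]] <- z - predTab + matrix(predObs, nrow(z), ncol(z),
                                         byrow = TRUE)
    }
    arr <- array(unlist(preds), dim = c(nrow(z), ncol(z), restarts))
    zAdj <- apply(arr, c(1, 2), stats::median)
    dimnames(zAdj) <- dimnames(z)
  }

  adjusted <- sweep(sweep(stats::plogis(zAdj), 2, hi - lo, "*"), 2, lo, "+")
  colnames(adjusted) <- pars

  w <- rs$weights
  summaryTable <- rbind(
    "Minimum" = apply(retained, 2, min),
    "Weighted 2.5%" = apply(adjusted, 2, .weightedQuantile, w = w, p = 0.025),
    "Weighted Median" = apply(adjusted, 2, .weightedQuantile, w = w, p = 0.5),
    "Weighted Mean" = apply(adjusted, 2, stats::weighted.mean, w = w),
    "Weighted Mode" = apply(adjusted, 2, .weightedMode, w = w),
    "Weighted 97.5%" = apply(adjusted, 2, .weightedQuantile, w = w, p = 0.975),
    "Maximum" = apply(retained, 2, max))

  methods::new("PosteriorResult", modelCode = table@model@code,
               method = method, tolerance = tolerance,
               retained = retained, adjusted = adjusted,
               weights = w, distances = rs$distances,
               summaryTable = summaryTable, bounds = bounds)
}
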