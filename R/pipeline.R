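## Config-driven orchestration of the two analysis tracks
##
## Stage 1 compares the five symmetric-flow models (A-E) on either marker
## set; stage 2 (nuclear only, run when stage 1 supports a model with
## chilensis-albiceps gene flow) compares the equal-flow model D against
## the asymmetric model F and the isolation-with-migration model G.
## Paper-style defaults: tolerance 10% for set 1, 5% for set 2, 1% for
## parameter estimation.

.STAGE1_MODELS <- c("A", "B", "C", "D", "E")
.STAGE2_MODELS <- c("D", "F", "G")

#' Read and validate a run configuration (YAML)
#'
#' Recognised fields: `manifest` (dataset manifest path), `markerSet`,
#' `nSim` (simulations per model), `tolerances` (`modelSet1`, `modelSet2`,
#' `estimation`), `stage2` (`auto`/`always`/`never`), `estimationMethod`,
#' `mu` (named `nuclear`/`mitochondrial` rates), `seed`, `outDir`,
#' `cacheDir`. Missing fields take the defaults above.
#'
#' @param path YAML file path.
#' @return a validated config list (class `"RunConfig"`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(markerSet = "nuclear", nSim = 1e6,
                   tolerances = list(modelSet1 = 0.10, modelSet2 = 0.05,
                                     estimation = 0.01),
                   stage2 = "auto", estimationMethod = "neuralnet",
                   mu = as.list(defaultMutationRates()),
                   seed = NULL, outDir = NULL, cacheDir = NULL)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$tolerances))
    if (is.null(cfg$tolerances[[nm]]))
      cfg$tolerances[[nm]] <- defaults$tolerances[[nm]]
  tol <- unlist(cfg$tolerances)
  if (any(tol <= 0 | tol > 1)) stop("tolerances must lie in (0, 1]")
  if (!cfg$markerSet %in% c("nuclear", "mitochondrial"))
    stop("markerSet must be nuclear or mitochondrial")
  if (!is.null(cfg$manifest) && !file.exists(cfg$manifest))
    stop("manifest not found: ", cfg$manifest)
  class(cfg) <- "RunConfig"
  cfg
}

## simple on-disk cache for reference tables, keyed by the run structure
.requestKey <- function(model, request, nSim) {
  v <- c(request@lengths, request@mu, as.vector(request@sampleCounts),
         match(request@inheritance, c("autosomal", "mitochondrial")))
  sprintf("%s_%s_%d_%08x", model@code, model@markerSet, as.integer(nSim),
          sum(round(v * seq_along(v) * 1e6)) %% .Machine$integer.max)
}

.cachedReferenceTable <- function(model, request, nSim, priors, cacheDir,
                                  fixed = NULL) {
  if (is.null(cacheDir))
    return(buildReferenceTable(model, request, nSim, priors, fixed = fixed))
  dir.create(cacheDir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(cacheDir, paste0("ref_", .requestKey(model, request, nSim),
                                  ".rds"))
  if (file.exists(f)) {
    tab <- readRDS(f)
    if (identical(colnames(tab@stats), statNames()) &&
        nrow(tab@stats) == nSim)
      return(tab)
    warning("stale reference table ", basename(f), "; rebuilding")
  }
  tab <- buildReferenceTable(model, request, nSim, priors, fixed = fixed)
  saveRDS(tab, f)
  tab
}

#' Two-stage ABC model selection on a multilocus dataset
#'
#' Builds (or loads) reference tables, computes the observed statistic
#' vector and runs model choice with validation. Stage 1 compares models
#' A-E at `tolerances["set1"]`; stage 2 (nuclear marker set only) compares
#' D, F and G at `tolerances["set2"]`, and runs when stage 1 supports a
#' model featuring chilensis-albiceps gene flow (C, D or E), always, or
#' never, per `stage2`.
#'
#' @param dataset a [MultiLocusDataset-class]
#' @param markerSet `"nuclear"` or `"mitochondrial"`.
#' @param nSim simulations per model (the motivating study used 1,000,000).
#' @param tolerances named numeric `c(set1 = , set2 = )`.
#' @param mu optional per-class mutation rates `c(nuclear, mitochondrial)`.
#' @param stage2 `"auto"`, `"always"` or `"never"`.
#' @param nPseudo cross-validation pseudo-observations per model (0 skips
#'   cross-validation).
#' @param nNull null replicates of the goodness-of-fit test (0 skips it).
#' @param priors optional [PriorSet-class] override.
#' @param cacheDir optional directory for cached reference tables.
#' @param outDir optional directory for CSV reports.
#' @return list (class `"modelSelectionReport"`) with `observed`, `stage1`
#'   and (possibly NULL) `stage2`; each stage holds `posterior`,
#'   `bayesFactors`, `cv`, `gof`, `tables` and its tolerance.
#' @export
runModelSelection <- function(dataset,
                              markerSet = c("nuclear", "mitochondrial"),
                              nSim = 1e6,
                              tolerances = c(set1 = 0.10, set2 = 0.05),
                              mu = NULL, stage2 = c("auto", "always", "never"),
                              nPseudo = 100, nNull = 200, priors = NULL,
                              cacheDir = NULL, outDir = NULL) {
  markerSet <- match.arg(markerSet)
  stage2 <- match.arg(stage2)
  if (stage2 == "always" && markerSet == "mitochondrial")
    stop("scope error: model set 2 (F, G) is tested on nuclear loci only")
  request <- requestFromDataset(dataset, markerSet, mu = mu)
  if (is.null(priors)) priors <- defaultPriors(markerSet)
  obs <- observedStatVector(dataset, markerSet)

  runStage <- function(codes, tol) {
    tables <- lapply(codes, function(code)
      .cachedReferenceTable(getModel(code, markerSet), request, nSim,
                            priors, cacheDir))
    names(tables) <- codes
    posterior <- suppressWarnings(modelPosterior(obs, tables, tol))
    best <- names(posterior)[which.max(posterior)]
    cv <- if (nPseudo > 0)
      crossValidateModelChoice(tables, tol, nPseudo = nPseudo) else NULL
    gof <- if (nNull > 0)
      goodnessOfFit(obs, tables[[best]], tol, nNull = nNull) else NULL
    list(posterior = posterior, bayesFactors = bayesFactors(posterior),
         best = best, cv = cv, gof = gof, tolerance = tol, tables = tables)
  }

  s1 <- runStage(.STAGE1_MODELS, tolerances[["set1"]])
  s2 <- NULL
  doStage2 <- markerSet == "nuclear" &&
    (stage2 == "always" ||
       (stage2 == "auto" && s1$best %in% c("C", "D", "E")))
  if (doStage2) s2 <- runStage(.STAGE2_MODELS, tolerances[["set2"]])

  report <- list(observed = obs, markerSet = markerSet, nSim = nSim,
                 stage1 = s1, stage2 = s2, request = request)
  class(report) <- "modelSelectionReport"
  if (!is.null(outDir)) .writeSelectionReport(report, outDir)
  report
}

.writeSelectionReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (stage in c("stage1", "stage2")) {
    s <- report[[stage]]
    if (is.null(s)) next
    utils::write.csv(
      data.frame(model = names(s$posterior), posterior = s$posterior),
      file.path(outDir, paste0(stage, "_posterior.csv")), row.names = FALSE)
    utils::write.csv(s$bayesFactors,
                     file.path(outDir, paste0(stage, "_bayes_factors.csv")))
    if (!is.null(s$cv)) {
      utils::write.csv(s$cv$confusion,
                       file.path(outDir, paste0(stage, "_confusion.csv")))
      utils::write.csv(s$cv$soft,
                       file.path(outDir, paste0(stage, "_soft.csv")))
    }
  }
  invisible(outDir)
}

#' @export
print.modelSelectionReport <- function(x, ...) {
  cat(sprintf("Model selection (%s track)\n", x$markerSet))
  cat(sprintf("  stage 1 (A-E, tolerance %g): best model %s\n",
              x$stage1$tolerance, x$stage1$best))
  print(round(x$stage1$posterior, 4))
  if (!is.null(x$stage2)) {
    cat(sprintf("  stage 2 (D/F/G, tolerance %g): best model %s\n",
                x$stage2$tolerance, x$stage2$best))
    print(round(x$stage2$posterior, 4))
  }
  invisible(x)
}

## report column order and labels mirroring the study's tables:
## albiceps, chilensis, pallatangae sizes, the two splits, migration rates
.reportColumns <- function(pars) {
  pref <- c(N_A = "Ne_albiceps", N_C = "Ne_chilensis", N_P = "Ne_pallatangae",
            T_CP = "T_CP", T_A = "T_A", m_CP = "m_CP", m_CA = "m_CA",
            m_PA = "m_PA", m = "m")
  ord <- intersect(names(pref), pars)
  setNames(ord, pref[ord])
}

#' ABC parameter estimation for one model, report-shaped
#'
#' Estimates the model's parameters from a reference table and lays the
#' weighted summaries out in the column order of the study's reports
#' (albiceps, chilensis, pallatangae effective sizes, the two divergence
#' times, then migration rates), rows Minimum / Weighted 2.5% / Weighted
#' Median / Weighted Mean / Weighted Mode / Weighted 97.5% / Maximum.
#'
#' @param dataset a [MultiLocusDataset-class]
#' @param modelCode the model to fit (e.g. `"G"`).
#' @param markerSet `"nuclear"` or `"mitochondrial"`.
#' @param nSim simulations (ignored when `table` is supplied).
#' @param tolerance retained fraction (paper default 1%).
#' @param method adjustment method (paper used `"neuralnet"`).
#' @param table optional pre-built [ReferenceTable-class] for the model.
#' @param mu,priors,cacheDir,outDir as in [runModelSelection()].
#' @return list (class `"parameterEstimationReport"`) with `posterior` (a
#'   [PosteriorResult-class]) and `summary` (the shaped table).
#' @export
runParameterEstimation <- function(dataset, modelCode = "G",
                                   markerSet = c("nuclear", "mitochondrial"),
                                   nSim = 1e6, tolerance = 0.01,
                                   method = "neuralnet", table = NULL,
                                   mu = NULL, priors = NULL,
                                   cacheDir = NULL, outDir = NULL) {
  markerSet <- match.arg(markerSet)
  model <- getModel(modelCode, markerSet)
  if (is.null(priors)) priors <- defaultPriors(markerSet)
  if (is.null(table)) {
    request <- requestFromDataset(dataset, markerSet, mu = mu)
    table <- .cachedReferenceTable(model, request, nSim, priors, cacheDir)
  }
  obs <- observedStatVector(dataset, markerSet)
  post <- suppressWarnings(
    estimateParameters(obs, table, tolerance, method = method))
  cols <- .reportColumns(colnames(post@retained))
  shaped <- posteriorSummary(post)[, cols, drop = FALSE]
  colnames(shaped) <- names(cols)
  out <- list(posterior = post, summary = shaped, model = modelCode,
              markerSet = markerSet, tolerance = tolerance, method = method)
  class(out) <- "parameterEstimationReport"
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(shaped, file.path(outDir, paste0(
      "estimation_", modelCode, "_", markerSet, ".csv")))
    ## prior/posterior density dump, consumable by any plotter
    dens <- do.call(rbind, lapply(colnames(post@retained), function(p) {
      d <- suppressWarnings(stats::density(
        post@adjusted[, p], weights = post@weights / sum(post@weights),
        bw = stats::bw.nrd0(post@adjusted[, p])))
      data.frame(parameter = p, x = d$x, density = d$y)
    }))
    utils::write.csv(dens, file.path(outDir, paste0(
      "posterior_density_", modelCode, "_", markerSet, ".csv")),
      row.names = FALSE)
  }
  out
}

#' @export
print.parameterEstimationReport <- function(x, ...) {
  cat(sprintf("Parameter estimation: model %s (%s track), %s at tolerance %g\n",
              x$model, x$markerSet, x$method, x$tolerance))
  print(signif(x$summary, 3))
  invisible(x)
}
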