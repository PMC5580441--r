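## Pseudo-observed datasets with the structure the analysis assumes:
## three focal populations, a panel of 7 autosomal loci (3711 bp total)
## plus one mitochondrial locus (1118 bp), variable per-locus sample
## presence, optional IUPAC-coded heterozygous sites.

#' ScenarioPreset: a fully specified generating scenario
#'
#' @slot model the generating [DemographicModel-class].
#' @slot params named "true" parameter vector (inside prior support).
#' @slot lengths per-locus lengths (bp).
#' @slot inheritance per-locus inheritance class.
#' @slot mu per-locus per-site mutation rates.
#' @slot nSamples named integer vector: individuals per focal population.
#' @slot coverage expected fraction of sequenced sample-locus combinations.
#'
#' @export
setClass("ScenarioPreset",
  representation(model = "DemographicModel", params = "numeric",
                 lengths = "numeric", inheritance = "character",
                 mu = "numeric", nSamples = "numeric",
                 coverage = "numeric"),
  validity = function(object) {
    if (any(object@lengths <= 0)) return("locus lengths must be positive")
    if (object@coverage <= 0 || object@coverage > 1)
      return("coverage must lie in (0, 1]")
    if (any(object@nSamples < 0)) return("sample counts must be >= 0")
    TRUE
  })

setMethod("show", "ScenarioPreset", function(object) {
  cat(sprintf(
    "ScenarioPreset: model %s, %d loci, %d individuals, coverage %.3f\n",
    object@model@code, length(object@lengths), sum(object@nSamples),
    object@coverage))
})

#' Default locus panel
#'
#' Seven autosomal loci summing to 3711 bp plus one mitochondrial locus of
#' 1118 bp, mirroring the multilocus structure of the motivating dataset.
#'
#' @return data.frame with columns `name`, `length`, `inheritance`.
#' @export
defaultLocusPanel <- function() {
  data.frame(
    name = c(paste0("anl", 1:7), "nd2"),
    length = c(480, 505, 520, 530, 540, 555, 581, 1118),
    inheritance = c(rep("autosomal", 7), "mitochondrial"),
    stringsAsFactors = FALSE)
}

#' Mid-prior parameter vector for a model
#'
#' Midpoint of every uniform prior; for models F and G the two migration
#' rates take the midpoints of the upper and lower halves of their shared
#' prior so that the ordering `m_CP > m_CA` holds.
#'
#' @param model a [DemographicModel-class]
#' @param priors a [PriorSet-class]
#' @return named numeric vector.
#' @export
midPriorParameters <- function(model, priors = defaultPriors(model@markerSet)) {
  b <- priors@bounds
  mid <- vapply(model@freeParams, function(p) mean(b[[p]]), 0)
  if (all(c("m_CP", "m_CA") %in% names(mid))) {
    mb <- b[["m_CP"]]
    mid["m_CP"] <- mb[1] + 0.75 * diff(mb)
    mid["m_CA"] <- mb[1] + 0.25 * diff(mb)
  }
  mid
}

#' Construct a generating scenario
#'
#' Defaults mirror the motivating study: the default locus panel
#' ([defaultLocusPanel()]), 41 focal individuals (19 chilensis,
#' 12 pallatangae, 10 albiceps), 67.4% sample-locus coverage, mid-prior
#' "true" parameters and the default mutation rates.
#'
#' @param model model code or a [DemographicModel-class] (default `"G"`).
#' @param params named true parameter vector (default [midPriorParameters()]).
#' @param nSamples named individuals per focal population.
#' @param coverage expected sequenced fraction of sample-locus pairs.
#' @param mu `c(nuclear, mitochondrial)` per-site mutation rates.
#' @param panel locus panel data.frame (see [defaultLocusPanel()]).
#' @return a [ScenarioPreset-class]
#' @export
scenarioPreset <- function(model = "G", params = NULL,
                           nSamples = c(chilensis = 19, pallatangae = 12,
                                        albiceps = 10),
                           coverage = 0.674,
                           mu = defaultMutationRates(),
                           panel = defaultLocusPanel()) {
  if (is.character(model)) model <- getModel(model)
  if (is.null(params)) params <- midPriorParameters(model)
  muVec <- unname(mu[ifelse(panel$inheritance == "mitochondrial",
                            "mitochondrial", "nuclear")])
  methods::new("ScenarioPreset", model = model, params = params,
               lengths = setNames(panel$length, panel$name),
               inheritance = panel$inheritance, mu = muVec,
               nSamples = nSamples[focalTaxa()], coverage = coverage)
}

#' Easy recovery scenario at desk scale
#'
#' Mid-prior parameters with elevated mutation rates (2e-8 nuclear, 2e-7
#' mitochondrial) and a small fully sequenced sample (5 individuals per
#' population), so that reduced reference tables carry enough signal for
#' recovery experiments.
#'
#' @inheritParams scenarioPreset
#' @return a [ScenarioPreset-class]
#' @export
easyPreset <- function(model = "G", params = NULL) {
  scenarioPreset(model = model, params = params,
                 nSamples = c(chilensis = 5, pallatangae = 5, albiceps = 5),
                 coverage = 1,
                 mu = c(nuclear = 2e-8, mitochondrial = 2e-7))
}

#' Bernoulli sample-locus presence matrix with a per-population floor
#'
#' Presence is Bernoulli(`coverage`); any locus leaving a focal population
#' with fewer than 2 sequences has that population's entries redrawn.
#'
#' @param nSamples named integer vector of individuals per population.
#' @param nLoci number of loci.
#' @param coverage presence probability, in (0, 1].
#' @return logical matrix, individuals x loci.
#' @export
makeMissingnessMask <- function(nSamples, nLoci, coverage) {
  if (coverage <= 0 || coverage > 1) stop("coverage must lie in (0, 1]")
  if (any(nSamples < 2))
    stop("infeasible constraint: every focal population needs >= 2 individuals")
  n <- sum(nSamples)
  pop <- rep(names(nSamples), nSamples)
  m <- matrix(stats::runif(n * nLoci) < coverage, n, nLoci)
  for (l in seq_len(nLoci)) {
    for (p in unique(pop)) {
      rows <- which(pop == p)
      guard <- 0L
      while (sum(m[rows, l]) < 2L) {
        m[rows, l] <- stats::runif(length(rows)) < coverage
        guard <- guard + 1L
        if (guard > 1e5) stop("infeasible constraint: coverage too low")
      }
    }
  }
  rownames(m) <- paste0(substr(pop, 1, 3), "_",
                        unlist(lapply(nSamples, seq_len)))
  m
}

## request mirroring a preset's presence matrix (counts in sequences)
.requestFromMask <- function(preset, mask) {
  pop <- rep(focalTaxa(), preset@nSamples)
  counts <- t(vapply(seq_along(preset@lengths), function(l)
    vapply(focalTaxa(), function(p) sum(mask[pop == p, l]), 0L),
    integer(3)))
  simulationRequest(lengths = unname(preset@lengths),
                    sampleCounts = counts,
                    inheritance = preset@inheritance,
                    mu = preset@mu,
                    lociNames = names(preset@lengths))
}

#' Generate a pseudo-observed multilocus dataset
#'
#' Simulates genealogies and infinite-sites mutations for every locus of
#' the preset under its true parameters, assembles a
#' [MultiLocusDataset-class] (one sequence per sampled individual; derived
#' alleles `T` on an `A` background), and optionally writes per-locus
#' FASTA, a popmap TSV and a YAML manifest. A nonzero `hetRate` replaces
#' that fraction of sites per sequence with the IUPAC code `W` (an
#' unphased A/T heterozygote) to exercise the I/O rules; statistics exclude
#' such sites by design, so statistical tests use `hetRate = 0`.
#'
#' @param preset a [ScenarioPreset-class]
#' @param dir optional output directory for FASTA/popmap/manifest.
#' @param hetRate per-site probability of IUPAC injection.
#' @return list with `dataset` (a [MultiLocusDataset-class]), `truth` (the
#'   generating parameter vector) and `preset`.
#' @export
generatePseudoObserved <- function(preset, dir = NULL, hetRate = 0) {
  stopifnot(methods::is(preset, "ScenarioPreset"))
  pop <- rep(focalTaxa(), preset@nSamples)
  mask <- makeMissingnessMask(preset@nSamples, length(preset@lengths),
                              preset@coverage)
  ids <- rownames(mask)
  samples <- data.frame(sample_id = ids, taxon = pop,
                        stringsAsFactors = FALSE)
  request <- .requestFromMask(preset, mask)

  lociList <- list()
  for (l in seq_along(preset@lengths)) {
    present <- which(mask[, l])
    ## order by deme so the request's count expansion matches
    present <- present[order(match(pop[present], focalTaxa()))]
    gen <- simulateGenealogy(preset@model, preset@params, request, locus = l)
    aln <- dropMutations(gen, unname(preset@lengths[l]),
                         preset@mu[l], sampleIds = ids[present])
    seqs <- as.character(sequences(aln))
    if (hetRate > 0) {
      L <- preset@lengths[l]
      for (i in seq_along(seqs)) {
        hit <- which(stats::runif(L) < hetRate)
        if (length(hit)) {
          s <- strsplit(seqs[i], "")[[1]]
          s[hit] <- "W"
          seqs[i] <- paste0(s, collapse = "")
        }
      }
    }
    lociList[[names(preset@lengths)[l]]] <-
      newLocusAlignment(seqs, locusName = names(preset@lengths)[l],
                        inheritance = preset@inheritance[l])
  }
  dataset <- newMultiLocusDataset(samples, lociList)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(lociList))
      writeFastaAlignment(lociList[[nm]], file.path(dir, paste0(nm, ".fasta")))
    utils::write.table(samples[, c("sample_id", "taxon")],
                       file.path(dir, "popmap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    manifest <- list(
      popmap = "popmap.tsv",
      truth = as.list(preset@params),
      model = preset@model@code,
      loci = lapply(seq_along(lociList), function(l) list(
        name = names(lociList)[l],
        fasta = paste0(names(lociList)[l], ".fasta"),
        inheritance = preset@inheritance[l])))
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  list(dataset = dataset, truth = preset@params, preset = preset)
}

#' Parameter-recovery and model-choice validation suite
#'
#' Loops generate-observe-estimate: draws true parameters from the prior,
#' generates a pseudo-observed dataset under the preset's panel, computes
#' its observed statistic vector and estimates parameters against a shared
#' reference table. Reports per-parameter coverage of the weighted 95%
#' interval, median relative bias of the weighted median, and (when
#' `modelSet` is given) model-choice accuracy against reference tables for
#' the competing models.
#'
#' @param model generating model code (default `"G"`).
#' @param nDatasets number of synthetic datasets.
#' @param tableSize reference-table rows per model.
#' @param tolerance ABC tolerance for estimation (and model choice).
#' @param preset the panel/mutation-rate scenario (default [easyPreset()]).
#' @param markerSet marker set analysed (default nuclear).
#' @param method estimation method (default `"rejection"`: deterministic
#'   and calibration-safe for coverage assessment).
#' @param modelSet optional character vector of competing model codes.
#' @return list with `coverage`, `relativeBias`, `accuracy` (or NA),
#'   `nDatasets` and the reference table(s) used.
#' @export
recoverySuite <- function(model = "G", nDatasets = 100, tableSize = 50000,
                          tolerance = 0.02, preset = easyPreset(model),
                          markerSet = "nuclear", method = "rejection",
                          modelSet = NULL) {
  mod <- preset@model
  priors <- defaultPriors(mod@markerSet)
  maskFull <- preset@coverage >= 1
  if (!maskFull)
    stop("recoverySuite assumes a fully sequenced preset (coverage = 1)")
  mask <- matrix(TRUE, sum(preset@nSamples), length(preset@lengths))
  rownames(mask) <- paste0(substr(rep(focalTaxa(), preset@nSamples), 1, 3),
                           "_", unlist(lapply(preset@nSamples, seq_len)))
  requestAll <- .requestFromMask(preset, mask)
  sel <- which(if (markerSet == "nuclear")
    preset@inheritance == "autosomal" else
      preset@inheritance == "mitochondrial")
  request <- simulationRequest(
    lengths = requestAll@lengths[sel],
    sampleCounts = requestAll@sampleCounts[sel, , drop = FALSE],
    inheritance = requestAll@inheritance[sel],
    mu = requestAll@mu[sel],
    lociNames = requestAll@lociNames[sel])

  table <- buildReferenceTable(mod, request, tableSize, priors)
  tables <- NULL
  if (!is.null(modelSet)) {
    tables <- lapply(modelSet, function(code) {
      if (code == mod@code) return(table)
      buildReferenceTable(getModel(code, mod@markerSet), request, tableSize,
                          priors)
    })
    names(tables) <- modelSet
  }

  pars <- colnames(table@params)
  hits <- matrix(0L, nDatasets, length(pars), dimnames = list(NULL, pars))
  bias <- matrix(NA_real_, nDatasets, length(pars),
                 dimnames = list(NULL, pars))
  correct <- rep(NA, nDatasets)
  for (dIdx in seq_len(nDatasets)) {
    truth <- drawParameters(mod, priors, 1)[1, ]
    pd <- generatePseudoObserved(
      scenarioPreset(mod, params = truth, nSamples = preset@nSamples,
                     coverage = 1,
                     mu = c(nuclear = preset@mu[which(
                       preset@inheritance == "autosomal")[1]],
                       mitochondrial = preset@mu[which(
                         preset@inheritance == "mitochondrial")[1]])))
    obs <- observedStatVector(pd$dataset, markerSet)
    post <- suppressWarnings(
      estimateParameters(obs, table, tolerance, method = method))
    s <- posteriorSummary(post)
    hits[dIdx, ] <- as.integer(truth[pars] >= s["Weighted 2.5%", pars] &
                               truth[pars] <= s["Weighted 97.5%", pars])
    bias[dIdx, ] <- (s["Weighted Median", pars] - truth[pars]) / truth[pars]
    if (!is.null(tables)) {
      p <- suppressWarnings(modelPosterior(obs, tables, tolerance))
      correct[dIdx] <- names(p)[which.max(p)] == mod@code
    }
  }
  list(coverage = colMeans(hits),
       relativeBias = apply(bias, 2, stats::median),
       accuracy = if (is.null(tables)) NA_real_ else mean(correct),
       nDatasets = nDatasets,
       table = table, tables = tables)
}
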