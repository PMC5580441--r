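## Simulation of multilocus data under a demographic model draw
##
## The event-driven structured coalescent (continuous-time approximation of
## the Wright-Fisher model) lives in src/coalescent.cpp; this file provides
## the typed interface, the infinite-sites mutation stage, and
## reference-table construction.

#' Default per-site per-generation mutation rates
#'
#' Order-of-magnitude avian conventions: 1e-9 for nuclear loci, 1e-8 for
#' the mitochondrial locus. Every analysis that depends on rates takes them
#' from its [SimulationRequest-class], so they are always explicit.
#'
#' @return named numeric vector `c(nuclear, mitochondrial)`.
#' @export
defaultMutationRates <- function() c(nuclear = 1e-9, mitochondrial = 1e-8)

#' Construct a SimulationRequest
#'
#' @param lengths per-locus lengths in bp.
#' @param sampleCounts loci x 3 matrix of gene-copy counts per focal
#'   population (chilensis, pallatangae, albiceps); a vector is recycled
#'   across loci.
#' @param inheritance per-locus `"autosomal"` or `"mitochondrial"` (scaling:
#'   a deme of N individuals holds 2N autosomal but N mitochondrial
#'   copies).
#' @param mu per-locus per-site mutation rates; defaults to
#'   [defaultMutationRates()] by inheritance class.
#' @param lociNames optional locus names.
#' @return a [SimulationRequest-class]
#' @export
simulationRequest <- function(lengths, sampleCounts,
                              inheritance = rep("autosomal", length(lengths)),
                              mu = NULL, lociNames = NULL) {
  nl <- length(lengths)
  if (is.null(lociNames)) lociNames <- paste0("locus", seq_len(nl))
  if (is.null(dim(sampleCounts)))
    sampleCounts <- matrix(sampleCounts, nrow = nl, ncol = 3, byrow = TRUE)
  if (is.null(mu)) mu <- unname(defaultMutationRates()[
    ifelse(inheritance == "mitochondrial", "mitochondrial", "nuclear")])
  if (length(mu) == 1L) mu <- rep(mu, nl)
  storage.mode(sampleCounts) <- "integer"
  colnames(sampleCounts) <- focalTaxa()
  methods::new("SimulationRequest", lociNames = lociNames,
               lengths = as.numeric(lengths), mu = as.numeric(mu),
               inheritance = inheritance, sampleCounts = sampleCounts)
}

#' Derive a SimulationRequest mirroring an observed dataset
#'
#' Simulated sample sizes mirror the observed per-locus presence of the
#' focal taxa (missing sample-locus combinations respected), since observed
#' statistics are computed on exactly those sequences. The Z-linked class
#' is never simulated.
#'
#' @param dataset a [MultiLocusDataset-class]
#' @param markerSet `"nuclear"` or `"mitochondrial"`.
#' @param mu optional per-locus mutation rates (default by class).
#' @return a [SimulationRequest-class]
#' @export
requestFromDataset <- function(dataset,
                               markerSet = c("nuclear", "mitochondrial"),
                               mu = NULL) {
  markerSet <- match.arg(markerSet)
  sel <- .lociForMarkerSet(dataset, markerSet)
  if (!is.null(mu) && !is.null(names(mu)) &&
      all(c("nuclear", "mitochondrial") %in% names(mu)))
    mu <- unname(mu[ifelse(vapply(sel, inheritance, "") == "mitochondrial",
                           "mitochondrial", "nuclear")])
  tab <- dataset@samples
  counts <- t(vapply(sel, function(a) {
    ids <- names(sequences(a))
    vapply(focalTaxa(), function(p)
      sum(ids %in% tab$sample_id[tab$taxon == p]), 0L)
  }, integer(3)))
  simulationRequest(
    lengths = vapply(sel, alignmentLength, 0),
    sampleCounts = counts,
    inheritance = vapply(sel, inheritance, ""),
    mu = mu,
    lociNames = vapply(sel, locusName, ""))
}

.ploidyFactor <- function(inheritance)
  ifelse(inheritance == "mitochondrial", 1, 2)

## map a (model, params) draw onto the C++ simulator's inputs
.demoRow <- function(params) {
  p <- as.list(params)
  c(p$N_C, p$N_P, p$N_A, p$T_CP, p$T_A)
}

.migRow <- function(model, params)
  as.vector(t(.migrationMatrix(model, as.list(params))))

#' Simulate a gene genealogy for one locus
#'
#' Event-driven structured coalescent: within-deme coalescence at rate
#' k(k-1)/2 divided by the deme size in gene copies, competing with
#' per-lineage migration at the model's active backward rates; lineages in
#' pallatangae join chilensis at `T_CP` and everything joins albiceps'
#' ancestor at `T_A`.
#'
#' @param model a [DemographicModel-class]
#' @param params named parameter vector (one row of [drawParameters()]).
#' @param request a [SimulationRequest-class]
#' @param locus locus index within the request.
#' @return a [GeneGenealogy-class]
#' @export
simulateGenealogy <- function(model, params, request, locus = 1L) {
  counts <- request@sampleCounts[locus, ]
  leafDeme <- rep.int(0:2, counts)
  sizes <- .ploidyFactor(request@inheritance[locus]) *
    .demoRow(params)[1:3]
  res <- .sim_genealogy_cpp(as.integer(leafDeme), sizes,
                            .demoRow(params)[4], .demoRow(params)[5],
                            .migRow(model, params), model@tIso)
  methods::new("GeneGenealogy", parent = res$parent,
               nodeTime = res$nodeTime,
               leafDeme = as.integer(leafDeme + 1L))
}

#' Total branch length of a genealogy, in generations
#' @param genealogy a [GeneGenealogy-class]
#' @return numeric scalar.
#' @export
totalBranchLength <- function(genealogy) {
  p <- genealogy@parent
  sum(genealogy@nodeTime[p[!is.na(p)]] - genealogy@nodeTime[!is.na(p)])
}

#' Convert a GeneGenealogy to an ape phylo tree
#' @param genealogy a [GeneGenealogy-class]
#' @return an `ape::phylo` object (requires the ape package).
#' @export
asPhylo <- function(genealogy) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for asPhylo()")
  n <- length(genealogy@leafDeme)
  remap <- function(v) ifelse(v <= n, v, 3L * n - v)
  child <- which(!is.na(genealogy@parent))
  edge <- cbind(remap(genealogy@parent[child]), remap(child))
  len <- genealogy@nodeTime[genealogy@parent[child]] -
    genealogy@nodeTime[child]
  tr <- list(edge = edge, edge.length = len, Nnode = n - 1L,
             tip.label = paste0("t", seq_len(n)))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Mutation count is Poisson with mean (total branch length x mu x length);
#' each mutation lands on a branch chosen proportionally to its length and
#' on its own site (distinct uniform positions). Should the mutation count
#' exceed the site budget, a finite-sites fallback reuses positions with
#' allele toggling, with a warning. Derived alleles are written as `T` on an
#' `A` background.
#'
#' @param genealogy a [GeneGenealogy-class]
#' @param lengthBp locus length in bp.
#' @param mu per-site per-generation mutation rate.
#' @param sampleIds optional sequence names (default `seq_1 ... seq_n`).
#' @return a [LocusAlignment-class] of simulated sequences.
#' @export
dropMutations <- function(genealogy, lengthBp, mu, sampleIds = NULL) {
  n <- length(genealogy@leafDeme)
  if (is.null(sampleIds)) sampleIds <- paste0("seq_", seq_len(n))
  par <- genealogy@parent
  child <- which(!is.na(par))
  blen <- genealogy@nodeTime[par[child]] - genealogy@nodeTime[child]
  nmut <- stats::rpois(1, sum(blen) * mu * lengthBp)

  seqm <- matrix("A", nrow = n, ncol = lengthBp)
  if (nmut > 0) {
    ## leaf sets below every node (children precede parents)
    desc <- vector("list", 2L * n - 1L)
    for (v in seq_len(n)) desc[[v]] <- v
    ord <- order(child)
    for (v in child[ord]) {
      p <- par[v]
      desc[[p]] <- c(desc[[p]], desc[[v]])
    }
    branches <- sample(child, nmut, replace = TRUE, prob = blen)
    if (nmut <= lengthBp) {
      sites <- sample.int(lengthBp, nmut)
      for (k in seq_len(nmut))
        seqm[desc[[branches[k]]], sites[k]] <- "T"
    } else {
      warning("mutation count ", nmut, " exceeds locus length ", lengthBp,
              "; finite-sites fallback with allele toggling")
      sites <- sample.int(lengthBp, nmut, replace = TRUE)
      for (k in seq_len(nmut)) {
        rows <- desc[[branches[k]]]
        seqm[rows, sites[k]] <- ifelse(seqm[rows, sites[k]] == "A", "T", "A")
      }
    }
  }
  seqs <- setNames(apply(seqm, 1, paste0, collapse = ""), sampleIds)
  newLocusAlignment(seqs, locusName = "simulated", inheritance = "autosomal")
}

#' Simulate one summary-statistic vector under a parameter draw
#'
#' Simulates every locus of the request independently (free recombination
#' between loci, none within) and computes the identical statistic
#' definition and ordering used by [observedStatVector()].
#'
#' @inheritParams simulateGenealogy
#' @return named numeric vector of length 13 ([statNames()]).
#' @export
simulateStatVector <- function(model, params, request) {
  stats <- .build_reference_cpp(
    matrix(.demoRow(params), nrow = 1),
    matrix(.migRow(model, params), nrow = 1),
    model@tIso,
    request@sampleCounts,
    request@lengths, request@mu,
    .ploidyFactor(request@inheritance))
  setNames(as.vector(stats), statNames())
}

#' Build an ABC reference table for one model
#'
#' Draws `nSim` parameter vectors from the priors (constraints enforced)
#' and simulates one multilocus statistic vector per draw.
#'
#' @param model a [DemographicModel-class]
#' @param request a [SimulationRequest-class]
#' @param nSim number of simulations (the motivating study used 1,000,000
#'   per model; reduced tables are standard at desk scale).
#' @param priors a [PriorSet-class]
#' @param fixed optional named numeric vector pinning some parameters to
#'   constants instead of their priors (e.g. `c(m_CP = 1e-4)`).
#' @param orderedRates see [drawParameters()].
#' @return a [ReferenceTable-class]
#' @export
buildReferenceTable <- function(model, request, nSim,
                                priors = defaultPriors(model@markerSet),
                                fixed = NULL, orderedRates = TRUE) {
  params <- drawParameters(model, priors, n = nSim,
                           orderedRates = orderedRates)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), colnames(params))
    if (length(bad)) stop("fixed parameters not in model: ",
                          paste(bad, collapse = ", "))
    for (nm in names(fixed)) params[, nm] <- fixed[[nm]]
  }
  demo <- cbind(params[, "N_C"], params[, "N_P"], params[, "N_A"],
                params[, "T_CP"], params[, "T_A"])
  migs <- matrix(0, nrow = nSim, ncol = 9)
  for (e in model@migEdges) {
    i <- e$pair[1] - 1L; j <- e$pair[2] - 1L
    migs[, 3 * i + j + 1] <- params[, e$param]
    migs[, 3 * j + i + 1] <- params[, e$param]
  }
  stats <- .build_reference_cpp(demo, migs, rep(model@tIso, nSim),
                                request@sampleCounts, request@lengths,
                                request@mu,
                                .ploidyFactor(request@inheritance))
  colnames(stats) <- statNames()
  methods::new("ReferenceTable", model = model, params = params,
               stats = stats, priors = priors, request = request)
}
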