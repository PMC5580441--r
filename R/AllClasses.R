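## S4 class definitions

#' Focal population labels, in the fixed deme order used throughout
#'
#' Deme order is chilensis (C), pallatangae (P), albiceps (A); the model
#' topology is ((C, P), A). All parameter vectors, sample-count matrices,
#' migration matrices and statistic vectors follow this order.
#'
#' @export
focalTaxa <- function() c("chilensis", "pallatangae", "albiceps")

.TAXON_VOCAB <- c("albiceps", "chilensis", "pallatangae", "other")
.MISSING_SYMBOLS <- c("N", "-", "?")
.UNAMBIGUOUS <- c("A", "C", "G", "T")
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.PAIR_NAMES <- c("CP", "CA", "PA")

#' LocusAlignment: one locus's aligned sequences
#'
#' Wraps a [Biostrings::DNAStringSet] of equal-width sequences together with
#' the locus name and its inheritance class (autosomal, z_linked or
#' mitochondrial). Row names are sample identifiers.
#'
#' @slot locusName single character, locus identifier.
#' @slot inheritance one of `"autosomal"`, `"z_linked"`, `"mitochondrial"`.
#' @slot sequences a `DNAStringSet`, all of identical width, named by sample.
#'
#' @export
setClass("LocusAlignment",
  representation(locusName = "character",
                 inheritance = "character",
                 sequences = "ANY"),
  validity = function(object) {
    msg <- character()
    if (length(object@locusName) != 1L || !nzchar(object@locusName))
      msg <- c(msg, "locusName must be a single non-empty string")
    if (!object@inheritance %in% c("autosomal", "z_linked", "mitochondrial"))
      msg <- c(msg, "inheritance must be autosomal, z_linked or mitochondrial")
    if (!methods::is(object@sequences, "DNAStringSet"))
      msg <- c(msg, "sequences must be a DNAStringSet")
    else {
      w <- Biostrings::width(object@sequences)
      if (length(w) == 0L) msg <- c(msg, "alignment has no sequences")
      else if (length(unique(w)) != 1L)
        msg <- c(msg, "ragged alignment: sequences differ in length")
      else if (w[1] == 0L) msg <- c(msg, "alignment length must be positive")
      if (is.null(names(object@sequences)) ||
          anyDuplicated(names(object@sequences)))
        msg <- c(msg, "sequences must carry unique sample names")
    }
    if (length(msg)) msg else TRUE
  })

#' MultiLocusDataset: samples, loci and the sample-locus presence matrix
#'
#' @slot samples data.frame with columns `sample_id`, `taxon` and optionally
#'   `locality`; taxon labels come from the controlled vocabulary
#'   (albiceps, chilensis, pallatangae, other).
#' @slot loci named list of [LocusAlignment-class] objects.
#' @slot presence logical matrix, samples x loci, TRUE where the sample was
#'   sequenced for the locus; consistent with alignment rows.
#'
#' @export
setClass("MultiLocusDataset",
  representation(samples = "data.frame",
                 loci = "list",
                 presence = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!all(c("sample_id", "taxon") %in% colnames(object@samples)))
      msg <- c(msg, "samples needs columns sample_id and taxon")
    else {
      if (anyDuplicated(object@samples$sample_id))
        msg <- c(msg, "duplicate sample_id in sample table")
      if (!all(object@samples$taxon %in% .TAXON_VOCAB))
        msg <- c(msg, "taxon outside controlled vocabulary")
    }
    if (length(object@loci) < 1L)
      msg <- c(msg, "at least one locus required")
    if (!all(vapply(object@loci, methods::is, TRUE, "LocusAlignment")))
      msg <- c(msg, "loci must all be LocusAlignment objects")
    for (nm in names(object@loci)) {
      rows <- names(sequences(object@loci[[nm]]))
      if (!all(rows %in% object@samples$sample_id)) {
        msg <- c(msg, sprintf("locus %s has rows absent from sample table", nm))
        break
      }
    }
    if (!identical(sort(colnames(object@presence)), sort(names(object@loci))))
      msg <- c(msg, "presence matrix columns must match locus names")
    if (length(msg)) msg else TRUE
  })

#' PriorSet: independent uniform priors on the demographic parameters
#'
#' Bounds (per marker class) on effective sizes (individuals), divergence
#' times (generations) and per-lineage per-generation migration
#' probabilities. All priors are uniform.
#'
#' @slot bounds named list; each element a numeric `c(lower, upper)`.
#' @slot markerSet `"nuclear"` or `"mitochondrial"`.
#'
#' @export
setClass("PriorSet",
  representation(bounds = "list", markerSet = "character"),
  validity = function(object) {
    ok <- vapply(object@bounds,
                 function(b) is.numeric(b) && length(b) == 2L && b[1] < b[2],
                 TRUE)
    if (!all(ok)) return("every prior needs numeric bounds with lower < upper")
    if (!object@markerSet %in% c("nuclear", "mitochondrial"))
      return("markerSet must be nuclear or mitochondrial")
    TRUE
  })

#' DemographicModel: one of the seven gene-flow models (A-G)
#'
#' Three demes on the fixed topology ((chilensis, pallatangae), albiceps)
#' with constant sizes, split times `T_CP` < `T_A`, and model-specific
#' migration edges between terminal demes. Model G restricts gene flow to
#' backward times at or beyond `tIso` (isolation since the current
#' interglacial).
#'
#' @slot code model code, one of `"A"` to `"G"`.
#' @slot markerSet `"nuclear"` or `"mitochondrial"`.
#' @slot freeParams character vector naming the model's free parameters.
#' @slot migEdges list of edges; each edge is `list(pair = c(i, j), param)`
#'   with demes indexed 1 = chilensis, 2 = pallatangae, 3 = albiceps.
#' @slot tIso backward time (generations) before which gene flow is shut
#'   off; 0 for all models except G.
#'
#' @export
setClass("DemographicModel",
  representation(code = "character", markerSet = "character",
                 freeParams = "character", migEdges = "list",
                 tIso = "numeric"),
  validity = function(object) {
    if (!object@code %in% LETTERS[1:7]) return("model code must be A..G")
    if (!object@markerSet %in% c("nuclear", "mitochondrial"))
      return("markerSet must be nuclear or mitochondrial")
    if (object@tIso < 0) return("tIso must be non-negative")
    TRUE
  })

#' SimulationRequest: structure of the data to simulate
#'
#' Mirrors the observed dataset: per-locus lengths, per-site mutation rates,
#' inheritance scaling, and per-locus gene-copy counts for the three focal
#' populations (autosomal loci carry 2 copies per sampled individual,
#' mitochondrial loci 1).
#'
#' @slot lociNames character vector of locus names.
#' @slot lengths numeric vector of locus lengths (bp).
#' @slot mu numeric vector of per-site per-generation mutation rates.
#' @slot inheritance character vector, `"autosomal"` or `"mitochondrial"`.
#' @slot sampleCounts integer matrix, loci x 3 (chilensis, pallatangae,
#'   albiceps), in gene copies.
#'
#' @export
setClass("SimulationRequest",
  representation(lociNames = "character", lengths = "numeric",
                 mu = "numeric", inheritance = "character",
                 sampleCounts = "matrix"),
  validity = function(object) {
    n <- length(object@lociNames)
    if (length(object@lengths) != n || length(object@mu) != n ||
        length(object@inheritance) != n || nrow(object@sampleCounts) != n)
      return("per-locus slots must have one entry per locus")
    if (any(object@lengths <= 0) || any(object@mu < 0))
      return("lengths must be positive and mutation rates non-negative")
    if (ncol(object@sampleCounts) != 3L)
      return("sampleCounts needs 3 columns (chilensis, pallatangae, albiceps)")
    if (any(object@sampleCounts < 0) ||
        any(rowSums(object@sampleCounts) < 2))
      return("each locus needs a total of at least 2 gene copies")
    if (!all(object@inheritance %in% c("autosomal", "mitochondrial")))
      return("simulated loci are autosomal or mitochondrial")
    TRUE
  })

#' GeneGenealogy: a simulated coalescent tree
#'
#' Binary genealogy over sampled gene copies. Nodes `1..n` are leaves (time
#' 0); internal nodes are numbered in order of coalescence so a child's
#' index is always below its parent's.
#'
#' @slot parent integer vector over all `2n - 1` nodes; `NA` at the root.
#' @slot nodeTime numeric node times in generations.
#' @slot leafDeme integer deme of each leaf (1 = chilensis, 2 = pallatangae,
#'   3 = albiceps).
#'
#' @export
setClass("GeneGenealogy",
  representation(parent = "integer", nodeTime = "numeric",
                 leafDeme = "integer"),
  validity = function(object) {
    n <- length(object@leafDeme)
    if (length(object@parent) != 2 * n - 1) return("parent has wrong length")
    if (sum(is.na(object@parent)) != 1L) return("exactly one root expected")
    if (any(object@nodeTime[seq_len(n)] != 0))
      return("leaves must be at time 0")
    TRUE
  })

#' ReferenceTable: the substrate of all ABC operations
#'
#' One row per simulation: a parameter draw from the prior and the summary
#' statistics of the dataset simulated under it.
#'
#' @slot model the generating [DemographicModel-class].
#' @slot params numeric matrix of draws (columns named by free parameters).
#' @slot stats numeric matrix of statistic vectors (13 columns by default).
#' @slot priors the [PriorSet-class] the draws came from.
#' @slot request the [SimulationRequest-class] used.
#'
#' @export
setClass("ReferenceTable",
  representation(model = "DemographicModel", params = "matrix",
                 stats = "matrix", priors = "PriorSet",
                 request = "SimulationRequest"),
  validity = function(object) {
    if (nrow(object@params) != nrow(object@stats))
      return("params and stats must have one row per simulation")
    if (anyNA(object@stats)) return("reference table contains missing values")
    TRUE
  })

#' PosteriorResult: retained draws, weights and weighted summaries
#'
#' @slot modelCode generating model code.
#' @slot method `"rejection"`, `"loclinear"` or `"neuralnet"`.
#' @slot tolerance the retained fraction.
#' @slot retained matrix of retained (unadjusted) parameter draws.
#' @slot adjusted matrix of regression-adjusted draws (equal to `retained`
#'   under the rejection method).
#' @slot weights Epanechnikov weights of the retained draws.
#' @slot distances normalized distances of the retained draws.
#' @slot summaryTable 7 x p matrix: Minimum, Weighted 2.5%, Weighted Median,
#'   Weighted Mean, Weighted Mode, Weighted 97.5%, Maximum.
#' @slot bounds 2 x p matrix of prior bounds.
#'
#' @export
setClass("PosteriorResult",
  representation(modelCode = "character", method = "character",
                 tolerance = "numeric", retained = "matrix",
                 adjusted = "matrix", weights = "numeric",
                 distances = "numeric", summaryTable = "matrix",
                 bounds = "matrix"),
  validity = function(object) {
    if (nrow(object@retained) != length(object@weights))
      return("one weight per retained draw required")
    if (any(object@weights < 0)) return("weights must be non-negative")
    TRUE
  })
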