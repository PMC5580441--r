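## Generics, accessors and show methods

#' @describeIn LocusAlignment-class accessor for the locus name
#' @param x a `LocusAlignment`
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))

#' @describeIn LocusAlignment-class accessor for the inheritance class
#' @export
setGeneric("inheritance", function(x) standardGeneric("inheritance"))

#' @describeIn LocusAlignment-class accessor for the underlying
#'   `DNAStringSet`
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @describeIn LocusAlignment-class alignment length in bp
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @describeIn MultiLocusDataset-class the sample metadata table
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

#' @describeIn MultiLocusDataset-class named list of loci
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @describeIn MultiLocusDataset-class sample-locus presence matrix
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @describeIn PriorSet-class named list of `c(lower, upper)` bounds
#' @param x a `PriorSet`
#' @export
setGeneric("priorBounds", function(x) standardGeneric("priorBounds"))

#' @describeIn DemographicModel-class names of the free parameters
#' @param x a `DemographicModel`
#' @export
setGeneric("freeParameters", function(x) standardGeneric("freeParameters"))

#' @describeIn DemographicModel-class model code (A..G)
#' @export
setGeneric("modelCode", function(x) standardGeneric("modelCode"))

#' @describeIn PosteriorResult-class the 7-row weighted summary table
#' @param x a `PosteriorResult`
#' @export
setGeneric("posteriorSummary", function(x) standardGeneric("posteriorSummary"))

setMethod("locusName", "LocusAlignment", function(x) x@locusName)
setMethod("inheritance", "LocusAlignment", function(x) x@inheritance)
setMethod("sequences", "LocusAlignment", function(x) x@sequences)
setMethod("alignmentLength", "LocusAlignment",
          function(x) Biostrings::width(x@sequences)[1])

setMethod("sampleTable", "MultiLocusDataset", function(x) x@samples)
setMethod("loci", "MultiLocusDataset", function(x) x@loci)
setMethod("presenceMatrix", "MultiLocusDataset", function(x) x@presence)

setMethod("priorBounds", "PriorSet", function(x) x@bounds)
setMethod("freeParameters", "DemographicModel", function(x) x@freeParams)
setMethod("modelCode", "DemographicModel", function(x) x@code)
setMethod("modelCode", "ReferenceTable", function(x) x@model@code)
setMethod("modelCode", "PosteriorResult", function(x) x@modelCode)
setMethod("posteriorSummary", "PosteriorResult", function(x) x@summaryTable)

setMethod("show", "LocusAlignment", function(object) {
  cat(sprintf("LocusAlignment '%s' (%s): %d sequences x %d bp\n",
              object@locusName, object@inheritance,
              length(object@sequences), alignmentLength(object)))
})

setMethod("show", "MultiLocusDataset", function(object) {
  tab <- table(factor(object@samples$taxon, levels = .TAXON_VOCAB))
  cat(sprintf("MultiLocusDataset: %d samples, %d loci (%.1f%% coverage)\n",
              nrow(object@samples), length(object@loci),
              100 * mean(object@presence)))
  cat("  taxa:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat("  "); show(object@loci[[1]])
  if (length(object@loci) > 1L)
    cat(sprintf("  ... and %d more loci\n", length(object@loci) - 1L))
})

setMethod("show", "DemographicModel", function(object) {
  edges <- if (length(object@migEdges) == 0L) "none" else
    paste(vapply(object@migEdges, function(e)
      sprintf("%s<->%s (%s)", focalTaxa()[e$pair[1]], focalTaxa()[e$pair[2]],
              e$param), ""), collapse = ", ")
  cat(sprintf("DemographicModel %s (%s markers)\n", object@code,
              object@markerSet))
  cat("  topology: ((chilensis, pallatangae), albiceps)\n")
  cat("  migration edges:", edges, "\n")
  if (object@tIso > 0)
    cat(sprintf("  gene flow only at backward times >= %g generations\n",
                object@tIso))
  cat("  free parameters:", paste(object@freeParams, collapse = ", "), "\n")
})

setMethod("show", "PriorSet", function(object) {
  cat(sprintf("PriorSet (%s markers), uniform priors:\n", object@markerSet))
  for (nm in names(object@bounds))
    cat(sprintf("  %-6s [%g, %g]\n", nm, object@bounds[[nm]][1],
                object@bounds[[nm]][2]))
})

setMethod("show", "ReferenceTable", function(object) {
  cat(sprintf("ReferenceTable: model %s, %d simulations, %d statistics\n",
              object@model@code, nrow(object@stats), ncol(object@stats)))
})

setMethod("show", "GeneGenealogy", function(object) {
  n <- length(object@leafDeme)
  cat(sprintf("GeneGenealogy: %d gene copies, TMRCA %.1f generations\n",
              n, max(object@nodeTime)))
})

setMethod("show", "PosteriorResult", function(object) {
  cat(sprintf(
    "PosteriorResult: model %s, method %s, tolerance %g, %d retained\n",
    object@modelCode, object@method, object@tolerance,
    nrow(object@retained)))
  print(signif(object@summaryTable, 4))
})
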