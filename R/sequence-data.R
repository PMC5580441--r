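## Reading, validating and preprocessing multilocus alignments

.VALID_SYMBOLS <- c(.UNAMBIGUOUS, .IUPAC_AMBIG, .MISSING_SYMBOLS)

#' Character matrix view of an alignment
#' @param aln a [LocusAlignment-class]
#' @return character matrix, samples x columns
#' @export
alignmentMatrix <- function(aln) {
  stopifnot(methods::is(aln, "LocusAlignment"))
  as.matrix(aln@sequences)
}

#' Construct a LocusAlignment from named sequences
#'
#' Symbols are uppercase-normalized; anything outside the DNA alphabet
#' (A, C, G, T), the IUPAC ambiguity codes or the missing symbols
#' (N, -, ?) is rejected, naming the offending record and column.
#'
#' @param seqs named character vector of aligned sequences.
#' @param locusName locus identifier.
#' @param inheritance `"autosomal"`, `"z_linked"` or `"mitochondrial"`.
#' @return a [LocusAlignment-class]
#' @export
newLocusAlignment <- function(seqs, locusName,
                              inheritance = c("autosomal", "z_linked",
                                              "mitochondrial")) {
  inheritance <- match.arg(inheritance)
  if (length(seqs) == 0L)
    stop("format error: no sequences for locus '", locusName, "'")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("format error: unnamed records in locus '", locusName, "'")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment error: ragged alignment in locus '", locusName,
         "' (lengths ", paste(sort(unique(lens)), collapse = ", "), ")")
  for (i in seq_along(seqs)) {
    sym <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!sym %in% .VALID_SYMBOLS)
    if (length(bad))
      stop(sprintf(
        "format error: illegal symbol '%s' in record '%s', column %d of locus '%s'",
        sym[bad[1]], names(seqs)[i], bad[1], locusName))
  }
  ## '?' is not in the DNAStringSet alphabet; store it as '-' but keep the
  ## distinction irrelevant downstream (both are missing symbols)
  stored <- gsub("?", "-", seqs, fixed = TRUE)
  methods::new("LocusAlignment", locusName = locusName,
               inheritance = inheritance,
               sequences = Biostrings::DNAStringSet(stored))
}

#' Read one locus from a multi-record FASTA file
#'
#' Accepts wrapped or unwrapped FASTA. Sequences are uppercase-normalized;
#' IUPAC ambiguity codes (unphased heterozygous sites) are preserved.
#'
#' @param path path to the FASTA file.
#' @param locusName locus identifier to attach.
#' @param inheritance inheritance class of the locus.
#' @return a [LocusAlignment-class]
#' @export
readFastaAlignment <- function(path, locusName = basename(path),
                               inheritance = c("autosomal", "z_linked",
                                               "mitochondrial")) {
  inheritance <- match.arg(inheritance)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("format error reading '", path, "': ",
                         conditionMessage(e)))
  if (length(set) == 0L) stop("format error: empty FASTA file '", path, "'")
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  newLocusAlignment(seqs, locusName = locusName, inheritance = inheritance)
}

#' Write a LocusAlignment to FASTA
#' @param aln a [LocusAlignment-class]
#' @param path output file path
#' @export
writeFastaAlignment <- function(aln, path) {
  stopifnot(methods::is(aln, "LocusAlignment"))
  Biostrings::writeXStringSet(aln@sequences, filepath = path)
  invisible(path)
}

#' Load a sample-to-taxon table (popmap)
#'
#' Two-column delimited text: sample_id and taxon. Taxa outside the
#' controlled vocabulary (albiceps, chilensis, pallatangae) are mapped to
#' `"other"` (outgroups, excluded from ABC analyses) unless `strict`.
#'
#' @param path path to the TSV file.
#' @param strict error (rather than map to "other") on unknown taxa.
#' @return data.frame with columns `sample_id` and `taxon`, in file order.
#' @export
loadPopmap <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("sample_id", "taxon"),
                           colClasses = "character",
                           comment.char = "#", strip.white = TRUE)
  if (anyDuplicated(tab$sample_id))
    stop("metadata error: duplicate sample_id '",
         tab$sample_id[duplicated(tab$sample_id)][1], "'")
  unknown <- !tab$taxon %in% .TAXON_VOCAB
  if (any(unknown)) {
    if (strict)
      stop("metadata error: taxon '", tab$taxon[unknown][1],
           "' outside controlled vocabulary")
    tab$taxon[unknown] <- "other"
  }
  tab
}

#' Assemble a MultiLocusDataset
#'
#' @param samples data.frame with `sample_id` and `taxon` columns (e.g. from
#'   [loadPopmap()]).
#' @param lociList named list of [LocusAlignment-class] objects (names
#'   default to their `locusName`s).
#' @return a [MultiLocusDataset-class]; the presence matrix is derived from
#'   the alignment rows.
#' @export
newMultiLocusDataset <- function(samples, lociList) {
  if (is.null(names(lociList)) || any(!nzchar(names(lociList))))
    names(lociList) <- vapply(lociList, locusName, "")
  pres <- sapply(lociList, function(a)
    samples$sample_id %in% names(sequences(a)))
  pres <- matrix(pres, nrow = nrow(samples),
                 dimnames = list(samples$sample_id, names(lociList)))
  methods::new("MultiLocusDataset", samples = samples, loci = lociList,
               presence = pres)
}

#' Read a dataset manifest (YAML) into a MultiLocusDataset
#'
#' The manifest lists the popmap path and, per locus, a name, FASTA path and
#' inheritance class:
#' \preformatted{
#' popmap: popmap.tsv
#' loci:
#'   - {name: nd2, fasta: nd2.fasta, inheritance: mitochondrial}
#'   - {name: locus1, fasta: locus1.fasta, inheritance: autosomal}
#' }
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path path to the YAML manifest.
#' @return a [MultiLocusDataset-class]
#' @export
readDatasetManifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  samples <- loadPopmap(resolve(cfg$popmap))
  lociList <- lapply(cfg$loci, function(x)
    readFastaAlignment(resolve(x$fasta), locusName = x$name,
                       inheritance = x$inheritance))
  names(lociList) <- vapply(cfg$loci, `[[`, "", "name")
  newMultiLocusDataset(samples, lociList)
}

#' Trim terminal columns containing missing data
#'
#' Restricts the alignment to the maximal contiguous column block such that
#' no leading or trailing column contains a missing symbol (N, -, ?) in any
#' row; interior missing data are untouched. IUPAC ambiguity codes are real
#' (unphased) data and are never treated as missing here.
#'
#' @param aln a [LocusAlignment-class]
#' @return the trimmed [LocusAlignment-class]
#' @export
trimTerminalMissing <- function(aln) {
  m <- alignmentMatrix(aln)
  hasMissing <- apply(m, 2, function(col) any(col %in% .MISSING_SYMBOLS))
  clean <- which(!hasMissing)
  if (length(clean) == 0L)
    stop("empty alignment after trimming: every column has missing data")
  keep <- seq(min(clean), max(clean))
  methods::new("LocusAlignment", locusName = aln@locusName,
               inheritance = aln@inheritance,
               sequences = Biostrings::subseq(aln@sequences,
                                              start = min(clean),
                                              end = max(clean)))
}

#' Concatenate loci of one inheritance class into a single alignment
#'
#' Rows are the union of samples present at any selected locus; a sample
#' missing from a locus is padded with `N` over that locus's span. Useful
#' for trimming on the concatenation rather than per locus.
#'
#' @param dataset a [MultiLocusDataset-class]
#' @param inheritance which class of loci to concatenate.
#' @return a [LocusAlignment-class] named `"concat"`.
#' @export
concatenateLoci <- function(dataset, inheritance = "autosomal") {
  sel <- Filter(function(a) a@inheritance == inheritance, dataset@loci)
  if (length(sel) == 0L) stop("no loci of inheritance class ", inheritance)
  ids <- unique(unlist(lapply(sel, function(a) names(sequences(a)))))
  parts <- lapply(sel, function(a) {
    m <- as.character(sequences(a))
    pad <- strrep("N", alignmentLength(a))
    out <- setNames(rep(pad, length(ids)), ids)
    out[names(m)] <- m
    out
  })
  cat_seqs <- setNames(do.call(paste0, parts), ids)
  newLocusAlignment(cat_seqs, locusName = "concat", inheritance = inheritance)
}

#' Count variable and parsimony-informative sites
#'
#' A column is variable when at least two distinct unambiguous bases
#' (A, C, G, T) occur in it; it is parsimony-informative when at least two
#' distinct unambiguous bases each occur in at least two rows. Ambiguity
#' codes and missing symbols are ignored column-wise.
#'
#' @param aln a [LocusAlignment-class] with at least 2 rows.
#' @return named integer vector `c(variable, parsimony_informative)`.
#' @export
countSites <- function(aln) {
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2L)
    stop("insufficient data: at least 2 sequences required")
  counts <- vapply(.UNAMBIGUOUS, function(b) colSums(m == b),
                   numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  variable <- sum(rowSums(counts > 0) >= 2)
  informative <- sum(rowSums(counts >= 2) >= 2)
  c(variable = variable, parsimony_informative = informative)
}
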