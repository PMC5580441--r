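test_that("FASTA alignments parse, normalize case and keep IUPAC codes", {
  p <- writeTempFasta(c(a = "acgt", b = "ACGT"))
  aln <- readFastaAlignment(p, locusName = "l1", inheritance = "autosomal")
  expect_s4_class(aln, "LocusAlignment")
  expect_equal(alignmentLength(aln), 4)
  expect_equal(length(sequences(aln)), 2)
  expect_equal(unname(as.character(sequences(aln))[1]), "ACGT")

  ## wrapped FASTA reads identically to unwrapped
  s <- setNames(replicate(3, paste0(sample(c("A", "C", "G", "T"), 120,
                                           replace = TRUE), collapse = "")),
                c("x", "y", "z"))
  a1 <- readFastaAlignment(writeTempFasta(s), "l", "autosomal")
  a2 <- readFastaAlignment(writeTempFasta(s, width = 50), "l", "autosomal")
  expect_identical(as.character(sequences(a1)), as.character(sequences(a2)))

  ## heterozygous sites scored as degenerate bases are preserved
  aln <- readFastaAlignment(writeTempFasta(c(a = "ACRT", b = "ACGT")),
                            "het", "autosomal")
  expect_equal(unname(alignmentMatrix(aln)["a", 3]), "R")
})

test_that("malformed alignments are rejected with informative errors", {
  expect_error(readFastaAlignment(writeTempFasta(c(a = "ACGT", b = "ACGTA")),
                                  "bad", "autosomal"),
               "ragged")
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(readFastaAlignment(empty, "e", "autosomal"), "empty|format")
  expect_error(readFastaAlignment(writeTempFasta(c(a = "ACXT")), "x",
                                  "autosomal"),
               "illegal symbol 'X' in record 'a', column 3")
  expect_error(readFastaAlignment(tempfile(), "m", "autosomal"), "not found")
})

test_that("popmap loading enforces unique ids and the taxon vocabulary", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("s1\talbiceps", "s2\tchilensis", "s3\tpallatangae"), p)
  tab <- loadPopmap(p)
  expect_equal(tab$sample_id, c("s1", "s2", "s3"))
  expect_equal(tab$taxon, c("albiceps", "chilensis", "pallatangae"))

  writeLines(c("B123\talbiceps", "B123\tchilensis"), p)
  expect_error(loadPopmap(p), "duplicate sample_id 'B123'")

  ## outgroup taxa map to "other" unless strict
  writeLines(c("s1\talbiceps", "s2\tchiriquensis"), p)
  expect_equal(loadPopmap(p)$taxon[2], "other")
  expect_error(loadPopmap(p, strict = TRUE), "chiriquensis")
})

test_that("terminal-missing trimming keeps the maximal clean block", {
  aln <- alnFromStrings(c("NACGT-", "AACGTA"))
  tr <- trimTerminalMissing(aln)
  expect_equal(alignmentLength(tr), 4)
  expect_equal(unname(as.character(sequences(tr))), c("ACGT", "ACGT"))

  ## identity when ends are clean; interior missing untouched
  aln2 <- alnFromStrings(c("ACN-GT", "ACGTGT"))
  tr2 <- trimTerminalMissing(aln2)
  expect_equal(as.character(sequences(tr2)), as.character(sequences(aln2)))

  ## idempotence
  expect_equal(as.character(sequences(trimTerminalMissing(tr))),
               as.character(sequences(tr)))

  ## IUPAC codes are data, not missing
  aln3 <- alnFromStrings(c("RACGT", "AACGT"))
  expect_equal(alignmentLength(trimTerminalMissing(aln3)), 5)

  expect_error(trimTerminalMissing(alnFromStrings(c("NNN", "AAN"))),
               "empty alignment")
})

test_that("trimming applies to the concatenation of autosomal loci", {
  set.seed(42)
  l1 <- alnFromStrings(c(a = "NNACGT", b = "ATACGT"), "l1")
  l2 <- alnFromStrings(c(a = "ACGT", b = "ACGA"), "l2")
  l3 <- alnFromStrings(c(a = "GGTANN", b = "GGTTAA"), "l3")
  samples <- data.frame(sample_id = c("a", "b"),
                        taxon = c("chilensis", "chilensis"))
  ds <- newMultiLocusDataset(samples, list(l1 = l1, l2 = l2, l3 = l3))
  cc <- concatenateLoci(ds, "autosomal")
  expect_equal(alignmentLength(cc), 16)
  expect_equal(alignmentLength(trimTerminalMissing(cc)), 12)
})

test_that("site counts match a brute-force column scan", {
  expect_equal(unname(countSites(alnFromStrings(c("AAAA", "AAAA")))), c(0, 0))
  expect_equal(unname(countSites(alnFromStrings(
    c("AAAT", "AAAC", "AAAT", "AAAC")))), c(1, 1))

  set.seed(7)
  for (r in 1:5) {
    m <- randomAln(10, 500, ambigFrac = 0.02, missingFrac = 0.05)
    got <- countSites(alnFromStrings(matToStrings(m)))
    expect_equal(unname(got), bruteCountSites(m))
    ## invariance under row and column permutation
    m2 <- m[sample(nrow(m)), sample(ncol(m))]
    got2 <- countSites(alnFromStrings(matToStrings(m2)))
    expect_equal(unname(got2), unname(got))
    expect_lte(got["parsimony_informative"], got["variable"])
  }
  expect_error(countSites(alnFromStrings("ACGT")), "insufficient")
})

test_that("dataset manifests round-trip through YAML", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("s1\tchilensis", "s2\tchilensis", "s3\tpallatangae"),
             file.path(dir, "popmap.tsv"))
  seqs <- c(s1 = "ACGT", s2 = "ACGA", s3 = "ACTT")
  writeFastaAlignment(alnFromStrings(seqs, "l1"),
                      file.path(dir, "l1.fasta"))
  yaml::write_yaml(list(popmap = "popmap.tsv",
                        loci = list(list(name = "l1", fasta = "l1.fasta",
                                         inheritance = "autosomal"))),
                   file.path(dir, "manifest.yaml"))
  ds <- readDatasetManifest(file.path(dir, "manifest.yaml"))
  expect_s4_class(ds, "MultiLocusDataset")
  expect_equal(names(loci(ds)), "l1")
  expect_true(all(presenceMatrix(ds)))
})
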