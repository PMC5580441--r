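# Shared builders for small in-code fixtures.

alnFromStrings <- function(seqs, locusName = "toy",
                           inheritance = "autosomal") {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  newLocusAlignment(seqs, locusName = locusName, inheritance = inheritance)
}

writeTempFasta <- function(seqs, width = NULL) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    if (is.null(width)) cat(s, "\n", sep = "", file = con)
    else {
      starts <- seq(1, nchar(s), by = width)
      for (st in starts)
        cat(substr(s, st, min(st + width - 1, nchar(s))), "\n",
            sep = "", file = con)
    }
  }
  close(con)
  path
}

# a small fully sequenced request over the easy nuclear panel
easyNuclearRequest <- function(nPerPop = 5L) {
  pre <- easyPreset("G")
  sel <- which(pre@inheritance == "autosomal")
  simulationRequest(lengths = unname(pre@lengths[sel]),
                    sampleCounts = matrix(nPerPop, length(sel), 3),
                    inheritance = pre@inheritance[sel],
                    mu = pre@mu[sel],
                    lociNames = names(pre@lengths)[sel])
}

# single-population request: n gene copies in chilensis, theta per locus set
# through a mitochondrial locus of N gene copies
singleDemeRequest <- function(n, thetaLocus, N = 1e4, L = 1000) {
  simulationRequest(lengths = L, sampleCounts = c(n, 0L, 0L),
                    inheritance = "mitochondrial",
                    mu = thetaLocus / (2 * N) / L)
}

singleDemeParams <- function(N = 1e4)
  c(N_C = N, N_P = N, N_A = N, T_CP = 1e12, T_A = 1e13)
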