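# Independent brute-force implementations of every statistic, used as
# oracles. These deliberately share no code with the package: plain loops
# over characters.

UNAMB <- c("A", "C", "G", "T")

randomAln <- function(n, L, ambigFrac = 0, missingFrac = 0) {
  pool <- UNAMB
  m <- matrix(sample(pool, n * L, replace = TRUE), n, L)
  if (ambigFrac > 0) {
    hit <- which(matrix(runif(n * L) < ambigFrac, n, L))
    m[hit] <- sample(c("R", "Y", "W", "K"), length(hit), replace = TRUE)
  }
  if (missingFrac > 0) {
    hit <- which(matrix(runif(n * L) < missingFrac, n, L))
    m[hit] <- sample(c("N", "-"), length(hit), replace = TRUE)
  }
  rownames(m) <- paste0("s", seq_len(n))
  m
}

matToStrings <- function(m) setNames(apply(m, 1, paste0, collapse = ""),
                                     rownames(m))

bruteSeg <- function(m) {
  s <- 0L
  for (j in seq_len(ncol(m))) {
    bases <- m[, j][m[, j] %in% UNAMB]
    if (length(unique(bases)) >= 2) s <- s + 1L
  }
  s
}

brutePDist <- function(a, b) {
  diff <- comp <- 0L
  for (k in seq_along(a)) {
    if (a[k] %in% UNAMB && b[k] %in% UNAMB) {
      comp <- comp + 1L
      if (a[k] != b[k]) diff <- diff + 1L
    }
  }
  if (comp == 0L) NA_real_ else diff / comp
}

bruteDiffCount <- function(a, b) {
  d <- 0L
  for (k in seq_along(a))
    if (a[k] %in% UNAMB && b[k] %in% UNAMB && a[k] != b[k]) d <- d + 1L
  d
}

brutePi <- function(m) {
  n <- nrow(m); tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + bruteDiffCount(m[i, ], m[j, ]); cnt <- cnt + 1
  }
  tot / cnt
}

bruteBetween <- function(mx, my) {
  tot <- 0; cnt <- 0
  for (i in seq_len(nrow(mx))) for (j in seq_len(nrow(my))) {
    tot <- tot + bruteDiffCount(mx[i, ], my[j, ]); cnt <- cnt + 1
  }
  tot / cnt
}

bruteFst <- function(mx, my) {
  piw <- (brutePi(mx) + brutePi(my)) / 2
  pib <- bruteBetween(mx, my)
  if (pib == 0) return(NA_real_)
  max(-1, min(1, 1 - piw / pib))
}

bruteNet <- function(mx, my) {
  between <- mean(sapply(seq_len(nrow(mx)), function(i)
    sapply(seq_len(nrow(my)), function(j) brutePDist(mx[i, ], my[j, ]))),
    na.rm = TRUE)
  within <- function(m) {
    n <- nrow(m)
    if (n < 2) return(0)
    v <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      v <- c(v, brutePDist(m[i, ], m[j, ]))
    mean(v, na.rm = TRUE)
  }
  between - (within(mx) + within(my)) / 2
}

bruteCountSites <- function(m) {
  v <- pi_inf <- 0L
  for (j in seq_len(ncol(m))) {
    bases <- m[, j][m[, j] %in% UNAMB]
    tab <- table(bases)
    if (length(tab) >= 2) v <- v + 1L
    if (sum(tab >= 2) >= 2) pi_inf <- pi_inf + 1L
  }
  c(v, pi_inf)
}
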