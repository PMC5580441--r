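## The seven gene-flow models (A-G) and their uniform priors
##
## Deme order everywhere: 1 = chilensis (C), 2 = pallatangae (P),
## 3 = albiceps (A); topology ((C, P), A) with splits T_CP < T_A.
## Migration parameters are backward per-lineage per-generation
## probabilities; "symmetric" gene flow means one shared rate per pair,
## applied in both directions. Edges connect terminal demes only: between
## T_CP and T_A the C+P ancestor exchanges no migrants with albiceps.

.MODEL_EDGES <- list(
  A = list(),
  B = list(list(pair = c(1L, 2L), param = "m_CP")),
  C = list(list(pair = c(1L, 3L), param = "m_CA")),
  D = list(list(pair = c(1L, 2L), param = "m"),
           list(pair = c(1L, 3L), param = "m")),
  E = list(list(pair = c(1L, 2L), param = "m_CP"),
           list(pair = c(1L, 3L), param = "m_CA"),
           list(pair = c(2L, 3L), param = "m_PA")),
  F = list(list(pair = c(1L, 2L), param = "m_CP"),
           list(pair = c(1L, 3L), param = "m_CA")),
  G = list(list(pair = c(1L, 2L), param = "m_CP"),
           list(pair = c(1L, 3L), param = "m_CA")))

.BASE_PARAMS <- c("N_C", "N_P", "N_A", "T_CP", "T_A")

#' Default uniform priors
#'
#' Effective sizes in individuals, 10 to 100,000 (mitochondrial marker set:
#' upper bound 25,000, one quarter of the autosomal bound); divergence of
#' chilensis and pallatangae 10,000 to 2,000,000 generations; divergence of
#' albiceps from their ancestor 1,000,000 to 7,000,000 generations;
#' migration probability 1e-8 to 1e-4 per lineage per generation. All
#' priors are uniform.
#'
#' @param markerSet `"nuclear"` or `"mitochondrial"`.
#' @return a [PriorSet-class]
#' @export
defaultPriors <- function(markerSet = c("nuclear", "mitochondrial")) {
  markerSet <- match.arg(markerSet)
  nMax <- if (markerSet == "nuclear") 1e5 else 2.5e4
  nb <- c(10, nMax)
  bounds <- list(N_C = nb, N_P = nb, N_A = nb,
                 T_CP = c(1e4, 2e6), T_A = c(1e6, 7e6),
                 m = c(1e-8, 1e-4), m_CP = c(1e-8, 1e-4),
                 m_CA = c(1e-8, 1e-4), m_PA = c(1e-8, 1e-4))
  methods::new("PriorSet", bounds = bounds, markerSet = markerSet)
}

#' Retrieve one of the seven demographic models
#'
#' Models A-E form set 1 (tested on both marker sets); the asymmetric-flow
#' model F and the isolation-with-migration model G form set 2 and are
#' defined for the nuclear marker set only.
#'
#' Migration structure: A none; B chilensis-pallatangae only; C
#' chilensis-albiceps only; D both pairs with a single shared rate; E all
#' three pairs; F both of D's pairs with independent rates ordered
#' `m_CP > m_CA`; G as F but with gene flow shut off at backward times below
#' `tIso` (default 20,000 generations, i.e. roughly the start of the
#' current interglacial at a 1-year generation time).
#'
#' @param code model code `"A"` to `"G"`.
#' @param markerSet `"nuclear"` or `"mitochondrial"`.
#' @param tIso isolation window for model G, backward generations.
#' @return a [DemographicModel-class]
#' @export
getModel <- function(code, markerSet = c("nuclear", "mitochondrial"),
                     tIso = 20000) {
  markerSet <- match.arg(markerSet)
  if (!code %in% LETTERS[1:7]) stop("unknown model code '", code, "'")
  if (markerSet == "mitochondrial" && code %in% c("F", "G"))
    stop("scope error: models F and G are defined for nuclear loci only")
  edges <- .MODEL_EDGES[[code]]
  free <- c(.BASE_PARAMS, unique(vapply(edges, `[[`, "", "param")))
  methods::new("DemographicModel", code = code, markerSet = markerSet,
               freeParams = free, migEdges = edges,
               tIso = if (code == "G") tIso else 0)
}

#' Draw parameter vectors from the priors
#'
#' Independent uniform draws for every free parameter of the model, with
#' the joint constraints `T_CP < T_A` and, for models F and G,
#' `m_CP > m_CA`, enforced by redrawing the violating rows.
#'
#' @param model a [DemographicModel-class]
#' @param priors a [PriorSet-class] (defaults to [defaultPriors()] for the
#'   model's marker set).
#' @param n number of draws.
#' @param orderedRates enforce `m_CP > m_CA` for models F/G (the default);
#'   set `FALSE` for independent priors without the ordering constraint.
#' @return numeric matrix, `n` rows, columns named by the free parameters.
#' @export
drawParameters <- function(model, priors = defaultPriors(model@markerSet),
                           n = 1L, orderedRates = TRUE) {
  free <- model@freeParams
  b <- priors@bounds[free]
  if (anyNA(names(b))) stop("priors missing for some free parameters")
  draw <- function(k, parNames) {
    vapply(parNames, function(p)
      stats::runif(k, b[[p]][1], b[[p]][2]), numeric(k))
  }
  out <- matrix(draw(n, free), nrow = n,
                dimnames = list(NULL, free))
  violates <- function(m) {
    v <- m[, "T_CP"] >= m[, "T_A"]
    if (orderedRates && all(c("m_CP", "m_CA") %in% colnames(m)))
      v <- v | m[, "m_CP"] <= m[, "m_CA"]
    v
  }
  guard <- 0L
  repeat {
    bad <- which(violates(out))
    if (length(bad) == 0L) break
    guard <- guard + length(bad)
    if (guard > 1e6) stop("internal error: constraint resampling not terminating")
    out[bad, ] <- matrix(draw(length(bad), free), nrow = length(bad))
  }
  out
}

## 3x3 backward migration-rate matrix during the active window
.migrationMatrix <- function(model, params) {
  m <- matrix(0, 3, 3, dimnames = list(focalTaxa(), focalTaxa()))
  for (e in model@migEdges) {
    r <- params[[e$param]]
    m[e$pair[1], e$pair[2]] <- r
    m[e$pair[2], e$pair[1]] <- r
  }
  m
}

#' Backward migration rates active at a given time
#'
#' Per-lineage backward migration probabilities between demes at backward
#' time `t`. Edges return 0 outside their window: for model G at
#' `t < tIso` (isolation during the current interglacial), and for every
#' model once an endpoint deme has merged (`t >= T_CP`; between the two
#' splits the C+P ancestor exchanges no migrants with albiceps).
#'
#' @param model a [DemographicModel-class]
#' @param params named parameter vector (one row of [drawParameters()]).
#' @param t backward time in generations.
#' @return 3x3 numeric matrix (rows: source deme, backward in time).
#' @export
activeMigrationRates <- function(model, params, t) {
  stopifnot(t >= 0)
  params <- as.list(params)
  zero <- matrix(0, 3, 3, dimnames = list(focalTaxa(), focalTaxa()))
  if (t >= params$T_CP) return(zero)
  if (model@tIso > 0 && t < model@tIso) return(zero)
  .migrationMatrix(model, params)
}
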