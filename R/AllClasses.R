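#' @import methods
#' @importFrom stats approx coef lm median optim qf rnorm runif sd setNames
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## GeneNetworkSpec
## ---------------------------------------------------------------------------

#' Gene network specification
#'
#' Static description of a gene circuit: the regulated ("gap") genes, the
#' external input genes (regulators that are not themselves regulated by the
#' circuit), and the modelled antero-posterior (A--P) range in percent egg
#' length (0\% = anterior pole).
#'
#' @slot gapGenes character vector of regulated gene identifiers.
#' @slot externalInputs character vector of external input identifiers.
#' @slot apRange numeric(2), modelled A--P interval in \% egg length.
#'
#' @export
setClass("GeneNetworkSpec",
  representation(gapGenes = "character",
                 externalInputs = "character",
                 apRange = "numeric"))

setValidity("GeneNetworkSpec", function(object) {
  msg <- character()
  if (length(object@gapGenes) < 1L)
    msg <- c(msg, "at least one gap gene is required")
  if (anyDuplicated(c(object@gapGenes, object@externalInputs)))
    msg <- c(msg, "gene identifiers must be unique and gap genes disjoint from external inputs")
  if (length(object@apRange) != 2L || any(!is.finite(object@apRange)))
    msg <- c(msg, "apRange must be two finite numbers")
  else if (!(object@apRange[1] >= 0 && object@apRange[1] < object@apRange[2] &&
             object@apRange[2] <= 100))
    msg <- c(msg, "apRange must satisfy 0 <= lo < hi <= 100")
  if (length(msg)) msg else TRUE
})

#' Create a gene network specification
#'
#' @param gapGenes regulated gene identifiers; defaults to the four
#'   \emph{Drosophila} trunk gap genes.
#' @param externalInputs external input identifiers; defaults to the two
#'   maternal gradients and the two terminal gap genes.
#' @param apRange modelled A--P interval (\% egg length).
#' @return A [GeneNetworkSpec-class] object.
#' @examples
#' geneNetworkSpec()
#' @export
geneNetworkSpec <- function(gapGenes = c("hb", "Kr", "gt", "kni"),
                            externalInputs = c("bcd", "cad", "tll", "hkb"),
                            apRange = c(35, 87)) {
  new("GeneNetworkSpec", gapGenes = gapGenes,
      externalInputs = externalInputs, apRange = as.numeric(apRange))
}

#' @describeIn geneNetworkSpec Gap gene names of a spec.
#' @param object,x a \code{GeneNetworkSpec}.
#' @export
gapGenes <- function(object) object@gapGenes

#' @describeIn geneNetworkSpec External input names of a spec.
#' @export
externalInputs <- function(object) object@externalInputs

#' @describeIn geneNetworkSpec Modelled A--P range.
#' @export
apRange <- function(object) object@apRange

setMethod("show", "GeneNetworkSpec", function(object) {
  cat("GeneNetworkSpec:", length(object@gapGenes), "gap genes (",
      paste(object@gapGenes, collapse = ", "), "),",
      length(object@externalInputs), "external inputs (",
      paste(object@externalInputs, collapse = ", "), "), trunk",
      object@apRange[1], "-", object@apRange[2], "% A-P\n")
})

## ---------------------------------------------------------------------------
## NucleusLattice
## ---------------------------------------------------------------------------

#' One-dimensional nucleus lattice
#'
#' Spatial discretisation of the A--P axis into equally wide nucleus bins.
#' At cleavage cycle 13 ("C13") the whole axis holds 50 nuclei, at cycle 14A
#' ("C14A") 100; a custom lattice discretises an arbitrary interval.  The
#' lattice stores the contiguous 0-based axis indices of the nuclei whose
#' spatial span intersects the modelled (closed) trunk interval, together
#' with their bin-centre positions.
#'
#' @slot stage one of "C13", "C14A", "custom".
#' @slot nAxis integer, nuclei along the whole axis (or in the custom range).
#' @slot indices contiguous 0-based nucleus indices inside the trunk.
#' @slot positions \% A--P centre of each retained nucleus.
#' @export
setClass("NucleusLattice",
  representation(stage = "character", nAxis = "integer",
                 indices = "integer", positions = "numeric"))

setValidity("NucleusLattice", function(object) {
  msg <- character()
  if (length(object@indices) == 0L)
    msg <- c(msg, "lattice has no nuclei")
  if (length(object@indices) > 1L &&
      any(diff(object@indices) != 1L))
    msg <- c(msg, "nucleus indices must be contiguous")
  if (length(object@indices) != length(object@positions))
    msg <- c(msg, "indices and positions must have equal length")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NucleusLattice", function(object) {
  cat("NucleusLattice (", object@stage, "): ", length(object@indices),
      " nuclei, indices ", min(object@indices), "..", max(object@indices),
      ", centres ", round(min(object@positions), 2), "-",
      round(max(object@positions), 2), "% A-P\n", sep = "")
})

#' Number of nuclei in a lattice
#' @param lattice a [NucleusLattice-class].
#' @return integer count of nuclei.
#' @export
nNuclei <- function(lattice) length(lattice@indices)

#' Nucleus centre positions
#' @param lattice a [NucleusLattice-class].
#' @return numeric \% A--P positions of the nucleus centres.
#' @export
nucleusPositions <- function(lattice) lattice@positions

## ---------------------------------------------------------------------------
## DivisionSchedule
## ---------------------------------------------------------------------------

#' Hybrid-time schedule of a gene circuit
#'
#' Times are in minutes from the start of cleavage cycle 13.  The default
#' schedule runs from t = 0 to gastrulation at t = 71.100 min, with mitosis
#' (synthesis shut off) during [16, 21] min, an instantaneous nuclear
#' division at 21 min, and the nine data time points C13 and T1--T8.
#'
#' @slot tStart,tEnd start and end of the simulated interval (min).
#' @slot mitosis numeric(2) mitosis interval, or numeric(0) for none.
#' @slot tDivision numeric(1) division time, or numeric(0) for none.
#' @slot dataTimes named, strictly increasing times with expression data.
#' @export
setClass("DivisionSchedule",
  representation(tStart = "numeric", tEnd = "numeric",
                 mitosis = "numeric", tDivision = "numeric",
                 dataTimes = "numeric"))

setValidity("DivisionSchedule", function(object) {
  msg <- character()
  if (object@tEnd <= object@tStart)
    msg <- c(msg, "tEnd must exceed tStart")
  dt <- object@dataTimes
  if (length(dt) == 0L || is.null(names(dt)))
    msg <- c(msg, "dataTimes must be a named numeric vector")
  if (length(dt) > 1L && any(diff(dt) <= 0))
    msg <- c(msg, "dataTimes must be strictly increasing")
  if (length(dt) && (min(dt) < object@tStart || max(dt) > object@tEnd))
    msg <- c(msg, "dataTimes must lie within [tStart, tEnd]")
  if (length(object@mitosis) == 2L &&
      !(object@mitosis[1] > object@tStart && object@mitosis[2] < object@tEnd &&
        object@mitosis[1] < object@mitosis[2]))
    msg <- c(msg, "mitosis interval must lie strictly inside (tStart, tEnd)")
  if (!length(object@mitosis) %in% c(0L, 2L))
    msg <- c(msg, "mitosis must be numeric(0) or numeric(2)")
  if (length(object@tDivision) > 1L)
    msg <- c(msg, "at most one division event is supported")
  if (length(msg)) msg else TRUE
})

#' Create a division schedule
#'
#' @param tStart,tEnd simulated interval (min).
#' @param mitosis mitosis interval (synthesis off), numeric(2) or numeric(0).
#' @param tDivision instantaneous division time, numeric(1) or numeric(0).
#' @param dataTimes named numeric vector of data time points (min).
#' @return A [DivisionSchedule-class].
#' @examples
#' divisionSchedule()  # the default C13 -> C14A schedule
#' @export
divisionSchedule <- function(tStart = 0, tEnd = 71.100,
                             mitosis = c(16.0, 21.0), tDivision = 21.0,
                             dataTimes = c(C13 = 10.550, T1 = 24.225,
                                           T2 = 30.475, T3 = 36.725,
                                           T4 = 42.975, T5 = 49.225,
                                           T6 = 55.475, T7 = 61.725,
                                           T8 = 67.975)) {
  new("DivisionSchedule", tStart = tStart, tEnd = tEnd,
      mitosis = as.numeric(mitosis), tDivision = as.numeric(tDivision),
      dataTimes = dataTimes)
}

#' @describeIn divisionSchedule Named data time points of a schedule.
#' @param schedule a \code{DivisionSchedule}.
#' @export
dataTimes <- function(schedule) schedule@dataTimes

setMethod("show", "DivisionSchedule", function(object) {
  cat("DivisionSchedule: t in [", object@tStart, ",", object@tEnd, "] min")
  if (length(object@mitosis))
    cat(", mitosis [", object@mitosis[1], ",", object@mitosis[2], "]")
  if (length(object@tDivision))
    cat(", division at", object@tDivision)
  cat("\n  data times:",
      paste(names(object@dataTimes), "=", object@dataTimes, collapse = ", "),
      "\n")
})

## ---------------------------------------------------------------------------
## CircuitParameters
## ---------------------------------------------------------------------------

#' Gene circuit parameters
#'
#' The full parameter set theta of a gene circuit: the G x G interconnectivity
#' matrix \code{W} (rows = target genes, columns = regulators; entry (a, b) is
#' the regulatory weight of gap gene b on gap gene a), the G x M external
#' input matrix \code{E} (columns = inputs), per-gene maximum synthesis rates
#' \code{R} (concentration/min), diffusion rates \code{D} (1/min, at the
#' cycle-13 nucleus spacing), decay rates \code{lambda} (1/min) and threshold
#' parameters \code{h} (dimensionless, uniform maternal factors).
#'
#' \code{mask} holds logical structures of the same shapes, with \code{TRUE}
#' marking parameters that are free during fitting; \code{FALSE} entries keep
#' the value stored in the object.  The default mask fixes all \code{h} at
#' -2.5 and the Hkb column of \code{E} at 0 for every target except
#' \emph{hb}.
#'
#' @slot spec the [GeneNetworkSpec-class].
#' @slot W,E regulatory weight matrices (targets in rows).
#' @slot R,D,lambda,h named per-gene numeric vectors.
#' @slot mask named list of logicals (\code{W}, \code{E}, \code{R}, \code{D},
#'   \code{lambda}, \code{h}); \code{TRUE} = free.
#' @export
setClass("CircuitParameters",
  representation(spec = "GeneNetworkSpec", W = "matrix", E = "matrix",
                 R = "numeric", D = "numeric", lambda = "numeric",
                 h = "numeric", mask = "list"))

setValidity("CircuitParameters", function(object) {
  g <- object@spec@gapGenes; m <- object@spec@externalInputs
  G <- length(g); M <- length(m)
  msg <- character()
  if (!all(dim(object@W) == c(G, G)))
    msg <- c(msg, "W must be G x G")
  if (!all(dim(object@E) == c(G, M)))
    msg <- c(msg, "E must be G x M")
  for (nm in c("R", "D", "lambda", "h"))
    if (length(slot(object, nm)) != G)
      msg <- c(msg, sprintf("%s must have one entry per gap gene", nm))
  if (any(object@R <= 0)) msg <- c(msg, "R must be positive")
  if (any(object@D < 0)) msg <- c(msg, "D must be non-negative")
  if (any(object@lambda <= 0)) msg <- c(msg, "lambda must be positive")
  need <- c("W", "E", "R", "D", "lambda", "h")
  if (!all(need %in% names(object@mask)))
    msg <- c(msg, "mask must have elements W, E, R, D, lambda, h")
  else {
    ok <- vapply(need, function(nm)
      identical(dim(object@mask[[nm]]), dim(slot(object, nm))) &&
        length(object@mask[[nm]]) == length(slot(object, nm)), logical(1))
    if (!all(ok)) msg <- c(msg, "mask shapes must match parameter shapes")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CircuitParameters", function(object) {
  g <- object@spec@gapGenes
  cat("CircuitParameters for", length(g), "gap genes,",
      length(object@spec@externalInputs), "external inputs;",
      sum(unlist(object@mask)), "free /",
      length(unlist(object@mask)), "total parameters\n")
  cat("W (target rows x regulator columns):\n")
  print(round(object@W, 4))
})
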