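## Data preparation: boundary splines, median aggregation, profile assembly,
## post-processing (binning, spatial and temporal intensity scaling, x200),
## approximate WLS weights, posterior-Kr removal and the packaged boundary
## table fixture.

## ---------------------------------------------------------------------------
## ExpressionDataset
## ---------------------------------------------------------------------------

#' Expression dataset for model fitting
#'
#' A \linkS4class{SummarizedExperiment} with genes in rows and (time class,
#' nucleus) pairs in columns, carrying two assays: \code{value}, the target
#' concentration of each gene at each nucleus and time point, and
#' \code{weight}, the positive weight used by the weighted least squares
#' cost.  Column metadata holds \code{time_class}, \code{time_min},
#' \code{stage}, \code{nucleus_index} and \code{ap_position}; columns are
#' ordered by time, then by nucleus index.
#'
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("value", "weight") %in% a))
    return("assays 'value' and 'weight' are required")
  v <- SummarizedExperiment::assay(object, "value")
  w <- SummarizedExperiment::assay(object, "weight")
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (any(!is.finite(w)) || any(w <= 0))
    msg <- c(msg, "weights must be finite and positive")
  cd <- SummarizedExperiment::colData(object)
  need <- c("time_class", "time_min", "stage", "nucleus_index", "ap_position")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain",
                        paste(need, collapse = ", ")))
  else if (is.unsorted(cd$time_min))
    msg <- c(msg, "columns must be ordered by time")
  if (length(msg)) msg else TRUE
})

#' Construct an expression dataset from per-time slices
#'
#' @param slices list with one element per time point, each a list with
#'   \code{label}, \code{time} (min), \code{stage}, \code{lattice}
#'   (a [NucleusLattice-class]), \code{values} and \code{weights}
#'   (gene x nucleus matrices).
#' @param genes gene identifiers (row names).
#' @return An [ExpressionDataset-class].
#' @export
expressionDataset <- function(slices, genes) {
  ord <- order(vapply(slices, `[[`, numeric(1), "time"))
  slices <- slices[ord]
  vals <- do.call(cbind, lapply(slices, `[[`, "values"))
  wts <- do.call(cbind, lapply(slices, `[[`, "weights"))
  rownames(vals) <- rownames(wts) <- genes
  cd <- do.call(rbind, lapply(slices, function(s)
    data.frame(time_class = s$label, time_min = s$time,
               stage = s$lattice@stage,
               nucleus_index = s$lattice@indices,
               ap_position = s$lattice@positions)))
  colnames(vals) <- colnames(wts) <-
    paste(cd$time_class, cd$nucleus_index, sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(value = vals, weight = wts),
    colData = S4Vectors::DataFrame(cd))
  new("ExpressionDataset", se)
}

#' @describeIn expressionDataset Target concentration matrix (genes x
#'   time-nucleus columns).
#' @param dataset an \code{ExpressionDataset}.
#' @export
datasetValues <- function(dataset)
  SummarizedExperiment::assay(dataset, "value")

#' @describeIn expressionDataset WLS weight matrix.
#' @export
datasetWeights <- function(dataset)
  SummarizedExperiment::assay(dataset, "weight")

#' @describeIn expressionDataset Total number of data points (genes x
#'   columns).
#' @export
nDataPoints <- function(dataset) length(datasetValues(dataset))

#' @describeIn expressionDataset Named vector of data times (min) per time
#'   class.
#' @export
datasetTimes <- function(dataset) {
  cd <- SummarizedExperiment::colData(dataset)
  i <- !duplicated(cd$time_class)
  setNames(cd$time_min[i], cd$time_class[i])
}

setMethod("show", "ExpressionDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("ExpressionDataset:", nrow(object), "genes x", ncol(object),
      "(time, nucleus) columns =", nDataPoints(object), "data points\n")
  cat("  time classes:", paste(unique(cd$time_class), collapse = ", "), "\n")
  cat("  value range:", paste(signif(range(datasetValues(object)), 4),
                              collapse = " - "), "\n")
})

## ---------------------------------------------------------------------------
## BoundarySpline
## ---------------------------------------------------------------------------

#' Expression boundary spline
#'
#' One rising or falling edge of an expression domain, represented by three
#' control points: \code{(x0, y0)} where staining approaches background,
#' \code{(x2, y2)} where it approaches maximum, and the midpoint
#' \code{(x1, y1)} with x1 = (x0 + x2)/2.  The interpolating curve is a
#' monotone two-piece cubic with zero first derivative at both end knots,
#' normalised so the value is 0 at the start point and 1 at the end point.
#' For rising boundaries x0 < x2 (domain posterior of the edge); for falling
#' boundaries x0 > x2 (domain anterior of the edge).
#'
#' @slot gene,timeClass,id,polarity,embryo character annotation fields.
#' @slot x0,y0,x1,y1,x2,y2 control point coordinates (\% A--P, relative
#'   intensity).
#' @export
setClass("BoundarySpline",
  representation(gene = "character", timeClass = "character",
                 id = "character", polarity = "character",
                 embryo = "character",
                 x0 = "numeric", y0 = "numeric", x1 = "numeric",
                 y1 = "numeric", x2 = "numeric", y2 = "numeric"))

setValidity("BoundarySpline", function(object) {
  msg <- character()
  if (object@x0 == object@x2) msg <- c(msg, "x0 and x2 must differ")
  if (!object@polarity %in% c("rising", "falling"))
    msg <- c(msg, "polarity must be 'rising' or 'falling'")
  else if (object@polarity == "rising" && object@x0 >= object@x2)
    msg <- c(msg, "rising boundary requires x0 < x2")
  else if (object@polarity == "falling" && object@x0 <= object@x2)
    msg <- c(msg, "falling boundary requires x0 > x2")
  if (abs(object@x1 - (object@x0 + object@x2) / 2) > 1e-9)
    msg <- c(msg, "x1 must be the midpoint of x0 and x2")
  if (length(msg)) msg else TRUE
})

#' Create a boundary spline
#'
#' @param gene,timeClass,id annotation labels; \code{id} is unique per
#'   boundary and encodes the domain and edge (e.g. "Kr.central.A").
#' @param polarity "rising" (anterior edge of a domain) or "falling"
#'   (posterior edge).
#' @param x0,x2 start (background) and end (maximum) positions, \% A--P.
#' @param y0,y2 normalised intensities at the anchors (defaults 0 and 1).
#' @param embryo embryo identifier or "median".
#' @return A [BoundarySpline-class].
#' @export
boundarySpline <- function(gene, timeClass, id, polarity, x0, x2,
                           y0 = 0, y2 = 1, embryo = "median") {
  new("BoundarySpline", gene = gene, timeClass = timeClass, id = id,
      polarity = polarity, embryo = embryo,
      x0 = x0, y0 = y0, x1 = (x0 + x2) / 2, y1 = (y0 + y2) / 2,
      x2 = x2, y2 = y2)
}

## monotone two-piece cubic through (0,0),(1/2,1/2),(1,1) with zero end
## slopes; s is clamped to [0,1]
.edgeShape <- function(s) {
  s <- pmin(1, pmax(0, s))
  lower <- s <= 0.5
  out <- numeric(length(s))
  u <- s[lower] / 0.5
  out[lower] <- u * u * (2 - u) / 2
  u <- (1 - s[!lower]) / 0.5
  out[!lower] <- 1 - u * u * (2 - u) / 2
  out
}

#' Evaluate a boundary spline
#'
#' Normalised expression intensity at positions \code{x}: 0 at the start
#' anchor x0, 1 at the end anchor x2, interpolated by the monotone cubic in
#' between; positions outside the span are clamped to the nearest anchor
#' value.  Because x0 sits on the background side for both polarities, the
#' returned value is the expression level across the edge for rising and
#' falling boundaries alike.
#'
#' @param b a [BoundarySpline-class].
#' @param x positions (\% A--P), vectorised.
#' @return normalised intensities in [y0, y2].
#' @export
boundaryProfile <- function(b, x) {
  s <- (x - b@x0) / (b@x2 - b@x0)
  b@y0 + (b@y2 - b@y0) * .edgeShape(s)
}

#' Median boundary of a group of embryos
#'
#' Coordinate-wise medians of the start and end anchor points of several
#' individual-embryo boundaries with the same gene, time class and boundary
#' id; the midpoint is recomputed.  For even group sizes the median is the
#' mean of the two central values.
#'
#' @param group list of [BoundarySpline-class] objects.
#' @return A [BoundarySpline-class] with embryo id "median".
#' @export
medianBoundary <- function(group) {
  if (length(group) == 0L) stop("group must be non-empty")
  ids <- vapply(group, slot, character(1), "id")
  if (length(unique(ids)) != 1L)
    stop("mixed boundary ids in group: ", paste(unique(ids), collapse = ", "))
  b <- group[[1]]
  boundarySpline(b@gene, b@timeClass, b@id, b@polarity,
                 x0 = median(vapply(group, slot, numeric(1), "x0")),
                 x2 = median(vapply(group, slot, numeric(1), "x2")),
                 y0 = median(vapply(group, slot, numeric(1), "y0")),
                 y2 = median(vapply(group, slot, numeric(1), "y2")),
                 embryo = "median")
}

## ---------------------------------------------------------------------------
## annotation tables
## ---------------------------------------------------------------------------

#' Boundary annotation tables
#'
#' Annotation tables are data frames with columns \code{embryo_id},
#' \code{gene}, \code{time_class}, \code{boundary_id}, \code{polarity},
#' \code{x0}, \code{y0}, \code{x2}, \code{y2}.
#' \code{splinesFromAnnotations} converts rows to [BoundarySpline-class]
#' objects; \code{medianAnnotations} aggregates embryos to one median
#' boundary per (gene, time class, boundary id) group;
#' \code{readBoundaryAnnotations} / \code{writeBoundaryAnnotations} handle
#' the TSV on-disk form.
#'
#' @param annotations annotation data frame.
#' @return \code{splinesFromAnnotations}: list of splines;
#'   \code{medianAnnotations}: annotation data frame with one "median" row
#'   per group.
#' @export
splinesFromAnnotations <- function(annotations) {
  lapply(seq_len(nrow(annotations)), function(i) {
    r <- annotations[i, ]
    boundarySpline(r$gene, r$time_class, r$boundary_id, r$polarity,
                   x0 = r$x0, x2 = r$x2, y0 = r$y0, y2 = r$y2,
                   embryo = as.character(r$embryo_id))
  })
}

#' @rdname splinesFromAnnotations
#' @export
medianAnnotations <- function(annotations) {
  key <- interaction(annotations$gene, annotations$time_class,
                     annotations$boundary_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(annotations, key), function(d) {
    data.frame(embryo_id = "median", gene = d$gene[1],
               time_class = d$time_class[1], boundary_id = d$boundary_id[1],
               polarity = d$polarity[1],
               x0 = median(d$x0), y0 = median(d$y0),
               x2 = median(d$x2), y2 = median(d$y2))
  }))
  rownames(out) <- NULL
  out
}

#' @rdname splinesFromAnnotations
#' @param path TSV file path.
#' @export
readBoundaryAnnotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "gene", "time_class", "boundary_id", "polarity",
            "x0", "y0", "x2", "y2")
  if (!all(need %in% colnames(df)))
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  df
}

#' @rdname splinesFromAnnotations
#' @export
writeBoundaryAnnotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## profile assembly
## ---------------------------------------------------------------------------

## expression value of an ordered set of boundaries of one gene/time at
## arbitrary positions x; the workhorse behind assembleProfile and the
## time-invariant external input profiles
.profileValue <- function(boundaries, x) {
  if (length(boundaries) == 0L) return(numeric(length(x)) * 0)
  lo <- vapply(boundaries, function(b) min(b@x0, b@x2), numeric(1))
  hi <- vapply(boundaries, function(b) max(b@x0, b@x2), numeric(1))
  ord <- order(lo)
  boundaries <- boundaries[ord]; lo <- lo[ord]; hi <- hi[ord]
  ids <- vapply(boundaries, slot, character(1), "id")
  if (length(boundaries) > 1L && any(lo[-1] < hi[-length(hi)])) {
    k <- which(lo[-1] < hi[-length(hi)])[1]
    stop("overlapping boundary spans: ", ids[k], " and ", ids[k + 1L])
  }
  pol <- vapply(boundaries, slot, character(1), "polarity")
  if (length(pol) > 1L && any(pol[-1] == pol[-length(pol)]))
    stop("boundaries must alternate rising/falling along the axis (ids: ",
         paste(ids, collapse = ", "), ")")
  state0 <- if (pol[1] == "falling") 1 else 0
  out <- numeric(length(x))
  for (j in seq_along(x)) {
    xi <- x[j]
    k <- which(xi >= lo & xi <= hi)
    if (length(k)) {
      out[j] <- boundaryProfile(boundaries[[k[1]]], xi)
    } else {
      nPassed <- sum(hi <= xi)
      out[j] <- (state0 + nPassed) %% 2
    }
  }
  out
}

#' Assemble a per-nucleus expression profile from median boundaries
#'
#' Combines the median boundaries of one gene at one time class into an
#' integrated, normalised expression profile sampled at the nucleus centres
#' of \code{lattice} (i.e. binned to the 50- or 100-bin axis): spline values
#' across each boundary span, plateau value 1 between a rising boundary and
#' the next falling one, 0 outside.  The result is independent of the input
#' ordering; overlapping spans of the same gene are an error.
#'
#' @param boundaries list of [BoundarySpline-class] objects (one gene, one
#'   time class).
#' @param lattice a [NucleusLattice-class].
#' @return numeric vector of normalised intensities, one per nucleus.
#' @export
assembleProfile <- function(boundaries, lattice)
  .profileValue(boundaries, nucleusPositions(lattice))

## ---------------------------------------------------------------------------
## scaling functions and post-processing
## ---------------------------------------------------------------------------

#' Spatial intensity scaling along the A--P axis
#'
#' Linear scaling of expression intensity from x1.0 at mid-embryo (50\%
#' A--P) down to x0.5 at both poles: 1 - |x - 50|/100.  Reflects the higher
#' staining intensity of central versus terminal gap domains.
#'
#' @param x position(s) in \% A--P, within [0, 100].
#' @return multiplier(s) in [0.5, 1].
#' @examples
#' spatialScalingFactor(c(0, 25, 50, 100))  # 0.5 0.75 1.0 0.5
#' @export
spatialScalingFactor <- function(x) {
  if (any(x < 0 | x > 100)) stop("x must lie within [0, 100] % A-P")
  1 - abs(x - 50) / 100
}

#' Temporal intensity scaling across C13--C14A
#'
#' The unique second-degree (quadratic) curve through the three anchor
#' conditions: 0.1 at the onset of expression (t = 0 min), 1.0 at around T5
#' (t = 48 min) and 0.7 at gastrulation (t = 71.1 min), capturing gradual
#' mRNA accumulation and late degradation.
#'
#' @param t time(s) in minutes, within the anchor range.
#' @param anchorsT,anchorsY the three anchor times and values.
#' @return multiplier(s).
#' @examples
#' temporalScalingFactor(c(0, 48, 71.1))  # 0.1 1.0 0.7
#' @export
temporalScalingFactor <- function(t, anchorsT = c(0, 48, 71.1),
                                  anchorsY = c(0.1, 1.0, 0.7)) {
  if (any(t < min(anchorsT) | t > max(anchorsT)))
    stop("t must lie within [", min(anchorsT), ", ", max(anchorsT), "] min")
  A <- cbind(anchorsT^2, anchorsT, 1)
  cf <- as.numeric(solve(A, anchorsY))
  cf[1] * t^2 + cf[2] * t + cf[3]
}

#' Approximate WLS weights from normalised expression
#'
#' v = 1 / (epsilon + yhat)^2, with yhat the normalised (0--1) staining
#' intensity before concentration scaling.  The weight is strictly
#' decreasing in expression level (variation grows with expression), so
#' non-expressing regions get the largest weights and ectopic expression is
#' penalised most.
#'
#' @param yhat normalised intensities in [0, 1].
#' @param epsilon positive regulariser bounding the weight at yhat = 0
#'   (default 0.1, giving a maximum weight of 100).
#' @return positive weights.
#' @export
makeWeights <- function(yhat, epsilon = 0.1) {
  if (epsilon <= 0) stop("epsilon must be positive")
  1 / (epsilon + yhat)^2
}

#' Apply intensity post-processing to a normalised dataset
#'
#' Multiplies the (already binned) normalised profile values by the spatial
#' scaling, the temporal scaling and the constant factor 200, in that order,
#' putting mRNA data on the concentration scale of the circuit models.
#' Weights are left untouched (they are defined on the normalised scale).
#'
#' @param dataset a normalised [ExpressionDataset-class].
#' @param factor constant concentration factor (default 200).
#' @return the scaled [ExpressionDataset-class].
#' @export
postprocess <- function(dataset, factor = 200) {
  if (isTRUE(S4Vectors::metadata(dataset)$scaled))
    stop("dataset is already on the concentration scale")
  cd <- SummarizedExperiment::colData(dataset)
  mult <- spatialScalingFactor(cd$ap_position) *
    temporalScalingFactor(cd$time_min) * factor
  v <- datasetValues(dataset)
  v <- sweep(v, 2, mult, `*`)
  SummarizedExperiment::assay(dataset, "value") <- v
  S4Vectors::metadata(dataset)$scaled <- TRUE
  dataset
}

## ---------------------------------------------------------------------------
## dataset assembly
## ---------------------------------------------------------------------------

#' Build a model-fitting dataset from boundary annotations
#'
#' Runs the full data preparation pipeline: median aggregation per (gene,
#' time class, boundary id), profile assembly binned to the stage lattice
#' (C13 before the division time, C14A after), approximate WLS weights from
#' the normalised profiles, and -- unless \code{scale = FALSE} -- the
#' intensity post-processing (spatial x temporal x 200).
#'
#' @param annotations boundary annotation data frame (see
#'   [splinesFromAnnotations()]).
#' @param spec a [GeneNetworkSpec-class].
#' @param schedule a [DivisionSchedule-class]; its data times define the
#'   time classes of the dataset.
#' @param epsilon weight regulariser, see [makeWeights()].
#' @param scale apply [postprocess()]?
#' @return An [ExpressionDataset-class] covering every gap gene, time class
#'   and trunk nucleus.
#' @export
assembleDataset <- function(annotations, spec = geneNetworkSpec(),
                            schedule = divisionSchedule(), epsilon = 0.1,
                            scale = TRUE) {
  ann <- medianAnnotations(annotations)
  genes <- gapGenes(spec)
  pre <- buildLattice("C13", apRange(spec))
  post <- buildLattice("C14A", apRange(spec))
  tDiv <- if (length(schedule@tDivision)) schedule@tDivision else Inf
  dts <- dataTimes(schedule)
  slices <- lapply(seq_along(dts), function(k) {
    lab <- names(dts)[k]; tm <- dts[[k]]
    lat <- if (tm < tDiv) pre else post
    vals <- matrix(0, length(genes), nNuclei(lat))
    for (gi in seq_along(genes)) {
      sub <- ann[ann$gene == genes[gi] & ann$time_class == lab, ,
                 drop = FALSE]
      if (nrow(sub))
        vals[gi, ] <- assembleProfile(splinesFromAnnotations(sub), lat)
    }
    list(label = lab, time = tm, lattice = lat, values = vals,
         weights = makeWeights(vals, epsilon))
  })
  ds <- expressionDataset(slices, genes)
  if (scale) ds <- postprocess(ds)
  ds
}

## ---------------------------------------------------------------------------
## posterior Kr removal
## ---------------------------------------------------------------------------

#' Remove the late posterior Kr domain
#'
#' The posterior \emph{Kr} domain arising in late C14A is under terminal-gap
#' and Forkhead control outside the modelled network and is removed from the
#' fitting data.  On an annotation table, rows whose boundary id marks a Kr
#' posterior domain are dropped (with a warning and no change if absent).
#' On an [ExpressionDataset-class], any contiguous Kr expression run lying
#' posterior of the main (maximum-containing) domain is zeroed at late time
#' classes.  The operation is idempotent.
#'
#' @param x annotation data frame or [ExpressionDataset-class].
#' @param lateFrom time (min) from which a time class counts as late C14A.
#' @param ... unused.
#' @return object of the same class as \code{x}.
#' @export
setGeneric("dropPosteriorKr", function(x, ...) standardGeneric("dropPosteriorKr"))

#' @rdname dropPosteriorKr
#' @export
setMethod("dropPosteriorKr", "data.frame", function(x, ...) {
  hit <- x$gene == "Kr" & grepl("post", x$boundary_id, ignore.case = TRUE)
  if (!any(hit)) {
    warning("no posterior Kr boundaries found; annotations unchanged")
    return(x)
  }
  x[!hit, , drop = FALSE]
})

#' @rdname dropPosteriorKr
#' @export
setMethod("dropPosteriorKr", "ExpressionDataset",
          function(x, lateFrom = 52, ...) {
  if (!"Kr" %in% rownames(x)) {
    warning("no Kr row in dataset; unchanged")
    return(x)
  }
  v <- datasetValues(x)
  cd <- SummarizedExperiment::colData(x)
  changed <- FALSE
  for (lab in unique(cd$time_class[cd$time_min >= lateFrom])) {
    cols <- which(cd$time_class == lab)
    row <- v["Kr", cols]
    on <- row > 0
    if (!any(on)) next
    r <- rle(on)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs) < 2L) next
    mainRun <- runs[which.max(vapply(runs, function(k)
      max(row[starts[k]:ends[k]]), numeric(1)))]
    for (k in runs)
      if (starts[k] > ends[mainRun]) {
        row[starts[k]:ends[k]] <- 0
        changed <- TRUE
      }
    v["Kr", cols] <- row
  }
  if (!changed)
    warning("no posterior Kr domain found; dataset unchanged")
  SummarizedExperiment::assay(x, "value") <- v
  x
})

## ---------------------------------------------------------------------------
## packaged boundary-table fixture
## ---------------------------------------------------------------------------

#' Load the packaged mRNA boundary-position table as a fitting dataset
#'
#' The package ships the published median mRNA boundary positions of the
#' four trunk gap genes (six domains, nine time classes) as a plain-text
#' table.  Each printed position is the start anchor x0 of a boundary
#' spline; the end anchor is placed \code{width} \% A--P into the domain
#' (posterior for rising "A" edges, anterior for falling "P" edges).  Where
#' a domain is too narrow for two full-width edges, both spans are shrunk
#' symmetrically so they meet at the domain midpoint.  The boundaries are
#' assembled and post-processed into the standard nine-time-class dataset
#' (27 C13 + 8 x 53 C14A nuclei per gene = 1804 data points).
#'
#' @param width default boundary width, \% A--P.
#' @param spec,schedule network spec and schedule (defaults as published).
#' @param epsilon weight regulariser.
#' @param scale apply concentration scaling (see [postprocess()])?
#' @return An [ExpressionDataset-class]; the median annotation table used is
#'   stored in \code{metadata(.)$annotations}.
#' @export
loadTable2Fixture <- function(width = 5, spec = geneNetworkSpec(),
                              schedule = divisionSchedule(), epsilon = 0.1,
                              scale = TRUE) {
  path <- system.file("extdata", "mrna_boundary_positions.tsv",
                      package = "gapCircuits", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  ann <- fixtureAnnotations(tab, width)
  ds <- assembleDataset(ann, spec, schedule, epsilon, scale)
  S4Vectors::metadata(ds)$annotations <- ann
  ds
}

#' Convert a printed boundary-position table to spline annotations
#'
#' @param tab data frame with columns \code{gene}, \code{time_class},
#'   \code{domain}, \code{boundary} ("A"/"P") and \code{position}.
#' @param width default boundary width, \% A--P.
#' @return boundary annotation data frame (embryo id "median").
#' @export
fixtureAnnotations <- function(tab, width = 5) {
  rows <- lapply(split(tab, interaction(tab$gene, tab$time_class,
                                        tab$domain, drop = TRUE)),
                 function(d) {
    a <- d[d$boundary == "A", ]; p <- d[d$boundary == "P", ]
    w <- width
    if (nrow(a) == 1L && nrow(p) == 1L) {
      half <- (p$position - a$position) / 2
      if (half <= 0)
        stop("domain ", d$gene[1], ".", d$domain[1], " at ", d$time_class[1],
             " has posterior edge anterior of its anterior edge")
      w <- min(width, half)
    }
    out <- NULL
    if (nrow(a) == 1L)
      out <- rbind(out, data.frame(
        embryo_id = "median", gene = a$gene, time_class = a$time_class,
        boundary_id = paste(a$gene, a$domain, "A", sep = "."),
        polarity = "rising", x0 = a$position, y0 = 0,
        x2 = a$position + w, y2 = 1))
    if (nrow(p) == 1L)
      out <- rbind(out, data.frame(
        embryo_id = "median", gene = p$gene, time_class = p$time_class,
        boundary_id = paste(p$gene, p$domain, "P", sep = "."),
        polarity = "falling", x0 = p$position, y0 = 0,
        x2 = p$position - w, y2 = 1))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
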