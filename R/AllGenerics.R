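#' @rdname TraceSet-class
#' @param object,x a \linkS4class{TraceSet} or \linkS4class{TissueGraph}.
#' @export
setGeneric("traceMatrix", function(x) standardGeneric("traceMatrix"))

#' @rdname TraceSet-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname TraceSet-class
#' @export
setGeneric("stimulusOnset", function(x) standardGeneric("stimulusOnset"))

#' @rdname TraceSet-class
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname TraceSet-class
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname TissueGraph-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname TissueGraph-class
#' @export
setGeneric("boundaryCells", function(x) standardGeneric("boundaryCells"))

#' @rdname TissueGraph-class
#' @export
setGeneric("interiorCells", function(x) standardGeneric("interiorCells"))

#' @rdname TissueGraph-class
#' @export
setGeneric("cellGeometry", function(x) standardGeneric("cellGeometry"))

setMethod("traceMatrix", "TraceSet", function(x) x@values)
setMethod("frameRate", "TraceSet", function(x) x@frameRate)
setMethod("stimulusOnset", "TraceSet", function(x) x@stimulusOnset)
setMethod("timePoints", "TraceSet", function(x)
  (seq_len(nrow(x@values)) - 1L) / x@frameRate)
setMethod("cellIds", "TraceSet", function(x) colnames(x@values))

#' @describeIn TraceSet-class number of frames and cells.
#' @export
setMethod("dim", "TraceSet", function(x) dim(x@values))

setMethod("show", "TraceSet", function(object) {
  cat("TraceSet:", ncol(object@values), "cells,",
      nrow(object@values), "frames @", object@frameRate, "Hz\n")
  if (!is.na(object@stimulusOnset))
    cat("  stimulus onset:", object@stimulusOnset, "s\n")
})

#' @describeIn TraceSet-class subset cells by id or index.
#' @param i cell ids (character) or indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TraceSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, colnames(x@values))
  new("TraceSet", values = x@values[, i, drop = FALSE],
      frameRate = x@frameRate, stimulusOnset = x@stimulusOnset)
})

setMethod("adjacencyMatrix", "TissueGraph", function(x) x@adjacency)
setMethod("boundaryCells", "TissueGraph", function(x)
  names(x@boundary)[x@boundary])
setMethod("interiorCells", "TissueGraph", function(x)
  names(x@boundary)[!x@boundary])
setMethod("cellGeometry", "TissueGraph", function(x) x@geometry)
setMethod("cellIds", "TissueGraph", function(x) rownames(x@adjacency))

#' @describeIn TissueGraph-class number of cells in the graph.
#' @export
setMethod("length", "TissueGraph", function(x) nrow(x@adjacency))

setMethod("show", "TissueGraph", function(object) {
  n <- nrow(object@adjacency)
  cat("TissueGraph:", n, "cells,",
      sum(object@adjacency) / 2, "edges,",
      sum(object@boundary), "boundary /", sum(!object@boundary),
      "interior\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nCells, "cells,",
      object@driveMode, "drive,", object@duration, "s @",
      object@frameRate, "Hz, seed", object@rngSeed, "\n")
})
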