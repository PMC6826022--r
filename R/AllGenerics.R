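#' @name accessors
#' @title Accessors for fishheart data classes
#' @description Slot accessors for [BiplaneVideo-class], [ForceTrace-class],
#'   [DopplerWaveform-class] and [HeartFunctionSummary-class] objects.
#' @param object an object of one of the fishheart classes.
#' @return The slot value (see the class documentation for units).
NULL

#' @rdname accessors
#' @export
setGeneric("planeLong", function(object) standardGeneric("planeLong"))
#' @rdname accessors
#' @export
setGeneric("planeShort", function(object) standardGeneric("planeShort"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("traceMarks", function(object) standardGeneric("traceMarks"))
#' @rdname accessors
#' @export
setGeneric("crossSectionalArea",
           function(object) standardGeneric("crossSectionalArea"))
#' @rdname accessors
#' @export
setGeneric("cycleTable", function(object) standardGeneric("cycleTable"))
#' @rdname accessors
#' @export
setGeneric("cycleMeans", function(object) standardGeneric("cycleMeans"))

#' @rdname accessors
setMethod("planeLong", "BiplaneVideo", function(object) object@planeLong)
#' @rdname accessors
setMethod("planeShort", "BiplaneVideo", function(object) object@planeShort)
#' @rdname accessors
setMethod("pixelSize", "BiplaneVideo", function(object) object@pixelSize)
#' @rdname accessors
setMethod("frameRate", "BiplaneVideo", function(object) object@frameRate)
#' @rdname accessors
setMethod("nFrames", "BiplaneVideo",
          function(object) dim(object@planeLong)[3])
#' @rdname accessors
setMethod("traceMarks", "ForceTrace", function(object) object@marks)
#' @rdname accessors
setMethod("crossSectionalArea", "ForceTrace", function(object) object@csa)
#' @rdname accessors
setMethod("cycleTable", "HeartFunctionSummary", function(object) object@cycles)
#' @rdname accessors
setMethod("cycleMeans", "HeartFunctionSummary", function(object) object@means)

setMethod("show", "BiplaneVideo", function(object) {
  d <- dim(object@planeLong)
  cat("BiplaneVideo:", d[3], "frames,", d[1], "x", d[2], "px/plane\n")
  cat("  pixel size:", object@pixelSize, "mm/px, frame rate:",
      object@frameRate, "fps (",
      round(d[3] / object@frameRate, 2), "s )\n")
})

setMethod("show", "ForceTrace", function(object) {
  cat("ForceTrace:", length(object@time), "samples over",
      round(diff(range(object@time)), 3), "s\n")
  cat("  marks (s):",
      paste(names(object@marks), round(object@marks, 3),
            sep = "=", collapse = ", "), "\n")
  if (!is.na(object@csa)) cat("  CSA:", object@csa, "um^2\n")
})

setMethod("show", "DopplerWaveform", function(object) {
  cat("DopplerWaveform:", length(object@time), "samples over",
      round(diff(range(object@time)), 3), "s;",
      nrow(object@events), "annotated cycles\n")
})

setMethod("show", "HeartFunctionSummary", function(object) {
  cat("HeartFunctionSummary over", nrow(object@cycles), "cardiac cycles\n")
  m <- object@means
  cat(sprintf("  EDV %.3f mm^3  ESV %.3f mm^3  EF %.3f  FS %.3f  FAC %.3f\n",
              m[["edv"]], m[["esv"]], m[["ef"]], m[["fs"]], m[["fac"]]))
  cat(sprintf("  max contraction vel %.3f 1/s  max relaxation vel %.3f 1/s  loop area %.4f strain^2/s\n",
              m[["max_contraction_velocity"]],
              m[["max_relaxation_velocity"]], m[["loop_area"]]))
})
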