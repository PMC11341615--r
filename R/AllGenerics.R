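#' Detector/isocenter magnification factor
#'
#' The ratio SID/SOD: a structure at the isocenter appears scaled by this
#' factor on the detector plane. Used to convert the filtered diaphragm
#' trace (detector scale) to isocenter scale before respiratory gating,
#' and to re-project 3D errors onto the image plane in the error budget.
#'
#' @param object a [CArmGeometry-class].
#' @return numeric scalar > 1.
#' @examples
#' magnification(CArmGeometry(sid_mm = 1200, sod_mm = 800))  # 1.5
#' @export
setGeneric("magnification", function(object) standardGeneric("magnification"))

#' @describeIn magnification ratio `sid_mm / sod_mm`.
#' @export
setMethod("magnification", "CArmGeometry",
          function(object) object@sid_mm / object@sod_mm)

#' Accessors for runs, frames and reports
#'
#' @param object an object of this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "XRRun", function(object) object@frames)

#' @rdname accessors
#' @export
setGeneric("rPeaks", function(object) standardGeneric("rPeaks"))
#' @rdname accessors
#' @export
setMethod("rPeaks", "XRRun", function(object) object@r_peaks_s)

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setMethod("geometry", "XRRun", function(object) object@geometry)

#' @rdname accessors
#' @export
setGeneric("runs", function(object) standardGeneric("runs"))
#' @rdname accessors
#' @export
setMethod("runs", "SyntheticStudy", function(object) object@runs)
#' @rdname accessors
#' @export
setMethod("runs", "StudyBundle", function(object) object@runs)

#' @rdname accessors
#' @export
setGeneric("cmrMarker", function(object) standardGeneric("cmrMarker"))
#' @rdname accessors
#' @export
setMethod("cmrMarker", "SyntheticStudy", function(object) object@cmr_marker)
#' @rdname accessors
#' @export
setMethod("cmrMarker", "StudyBundle", function(object) object@cmr_marker)

#' @rdname accessors
#' @export
setGeneric("studyTruth", function(object) standardGeneric("studyTruth"))
#' @rdname accessors
#' @export
setMethod("studyTruth", "SyntheticStudy", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("studyTruth", "StudyBundle", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("categoryTable", function(object) standardGeneric("categoryTable"))
#' @rdname accessors
#' @export
setMethod("categoryTable", "AccuracyReport", function(object) object@categories)

#' @rdname accessors
#' @export
setGeneric("pairTable", function(object) standardGeneric("pairTable"))
#' @rdname accessors
#' @export
setMethod("pairTable", "AccuracyReport", function(object) object@pairs)

#' @rdname accessors
#' @export
setGeneric("pairSummary", function(object) standardGeneric("pairSummary"))
#' @rdname accessors
#' @export
setMethod("pairSummary", "AccuracyReport", function(object) object@pair_summary)
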