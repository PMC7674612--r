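#' @export
setGeneric("exprsMat", function(x) standardGeneric("exprsMat"))

#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @export
setGeneric("sampleBatch", function(x) standardGeneric("sampleBatch"))

#' @export
setGeneric("sampleGrade", function(x) standardGeneric("sampleGrade"))

#' @export
setGeneric("sampleRecurrence", function(x) standardGeneric("sampleRecurrence"))

#' @export
setGeneric("metageneScores", function(x) standardGeneric("metageneScores"))

#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))

#' @export
setGeneric("pGrade3", function(x) standardGeneric("pGrade3"))

#' @export
setGeneric("clusterPolarityOf", function(x) standardGeneric("clusterPolarityOf"))

#' @export
setGeneric("reclassLabels", function(x) standardGeneric("reclassLabels"))
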