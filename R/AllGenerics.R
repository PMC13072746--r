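#' @rdname ProteinDataset-accessors
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))

#' @rdname ProteinDataset-accessors
#' @export
setGeneric("datasetName<-", function(x, value) standardGeneric("datasetName<-"))

#' @rdname ProteinDataset-accessors
#' @export
setGeneric("pdbIds", function(x) standardGeneric("pdbIds"))

#' @rdname ProteinDataset-accessors
#' @export
setGeneric("chainLengths", function(x) standardGeneric("chainLengths"))

#' @rdname ProteinDataset-accessors
#' @export
setGeneric("lnKf", function(x) standardGeneric("lnKf"))

#' @rdname ProteinDataset-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname datasetOverlap
#' @export
setGeneric("datasetOverlap", function(A, B) standardGeneric("datasetOverlap"))

#' @rdname datasetOverlap
#' @export
setGeneric("datasetDifference",
           function(A, B) standardGeneric("datasetDifference"))

#' @rdname evaluateExternal
#' @export
setGeneric("evaluateExternal",
           function(object, test, minLength = NULL, ...)
               standardGeneric("evaluateExternal"))
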