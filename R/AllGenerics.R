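#' Accessor generics
#'
#' Small accessor generics shared by the package's S4 classes. Accessors are
#' the supported way to read object contents; slot access is an internal
#' detail.
#'
#' @param x An object of one of the package's S4 classes.
#' @param ... Additional arguments passed to methods.
#' @return The requested component (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))

#' @rdname accessors
#' @export
setGeneric("proportions")   # promotes base::proportions to a generic

#' @rdname accessors
#' @export
setGeneric("fitResiduals", function(x) standardGeneric("fitResiduals"))

#' @rdname accessors
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("cellTypeNames", function(x) standardGeneric("cellTypeNames"))

#' @rdname accessors
#' @export
setGeneric("refMeans", function(x) standardGeneric("refMeans"))

#' @rdname accessors
#' @export
setGeneric("refVariability", function(x) standardGeneric("refVariability"))

#' @rdname accessors
#' @param k Number of clusters to extract results for.
#' @export
setGeneric("consensusMatrix", function(x, k) standardGeneric("consensusMatrix"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x, k) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("deltaArea", function(x) standardGeneric("deltaArea"))

#' @rdname accessors
#' @export
setGeneric("subtypes", function(x) standardGeneric("subtypes"))

#' @rdname accessors
#' @export
setGeneric("clusterToName", function(x) standardGeneric("clusterToName"))

#' @rdname accessors
#' @export
setGeneric("enrichment", function(x) standardGeneric("enrichment"))
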