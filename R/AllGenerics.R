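#' @rdname getNumLoci
#' @export
setGeneric("getNumLoci", function(x) standardGeneric("getNumLoci"))

#' @rdname getLocusNames
#' @export
setGeneric("getLocusNames", function(x) standardGeneric("getLocusNames"))

#' @rdname getLocusNames
#' @export
setGeneric("setLocusNames", function(x, value) standardGeneric("setLocusNames"))

#' @rdname getNumSequences
#' @export
setGeneric("getNumSequences",
  function(x, loci = NULL, exclude.gap.only = TRUE)
    standardGeneric("getNumSequences"))

#' @rdname getSequenceNames
#' @export
setGeneric("getSequenceNames",
  function(x, loci = NULL, exclude.gap.only = TRUE)
    standardGeneric("getSequenceNames"))

#' @rdname getSequences
#' @export
setGeneric("getSequences",
  function(x, ids = NULL, loci = NULL, simplify = TRUE)
    standardGeneric("getSequences"))

#' @rdname getLabels
#' @export
setGeneric("getLabels", function(x) standardGeneric("getLabels"))

#' @rdname concatenateLoci
#' @export
setGeneric("concatenateLoci",
  function(x, loci = NULL) standardGeneric("concatenateLoci"))

#' @rdname compressSitePatterns
#' @export
setGeneric("compressSitePatterns",
  function(x) standardGeneric("compressSitePatterns"))
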