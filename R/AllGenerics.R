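#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @export
setGeneric("nodeActivity", function(x) standardGeneric("nodeActivity"))

#' @export
setGeneric("nodeActivity<-", function(x, value) standardGeneric("nodeActivity<-"))

#' @export
setGeneric("linkTable", function(x) standardGeneric("linkTable"))

#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' @export
setGeneric("spreadProb", function(model, L, time) standardGeneric("spreadProb"))

#' @export
setGeneric("stepFactor", function(model, L, time) standardGeneric("stepFactor"))

#' @export
setGeneric("spreadParams", function(x, ...) standardGeneric("spreadParams"))

#' @export
setGeneric("divisions", function(x) standardGeneric("divisions"))
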