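#' @name strainforge-generics
#' @title Accessor generics for strainforge classes
#' @description Standard accessors for the [GEM] and [PanModel] classes.
#' @param object a strainforge object
#' @param value replacement value
NULL

#' @rdname strainforge-generics
#' @export
setGeneric("metabolites", function(object) standardGeneric("metabolites"))

#' @rdname strainforge-generics
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' @rdname strainforge-generics
#' @export
setGeneric("stoichMatrix", function(object) standardGeneric("stoichMatrix"))

#' @rdname strainforge-generics
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname strainforge-generics
#' @export
setGeneric("objectiveReaction",
           function(object) standardGeneric("objectiveReaction"))

#' @rdname strainforge-generics
#' @export
setGeneric("objectiveReaction<-",
           function(object, value) standardGeneric("objectiveReaction<-"))

#' @rdname strainforge-generics
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname strainforge-generics
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname strainforge-generics
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))

#' @rdname strainforge-generics
#' @export
setGeneric("panUnion", function(object) standardGeneric("panUnion"))
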