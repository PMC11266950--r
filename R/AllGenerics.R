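#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family for the package's S4 containers; prefer these over
#' direct slot access.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the corresponding component (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname accessors
#' @export
setGeneric("effectScale", function(x) standardGeneric("effectScale"))

#' @rdname accessors
#' @export
setGeneric("r2Total", function(x) standardGeneric("r2Total"))

#' @rdname accessors
#' @export
setGeneric("pairsTable", function(x) standardGeneric("pairsTable"))

#' @rdname accessors
#' @export
setGeneric("unmatched", function(x) standardGeneric("unmatched"))

#' @rdname accessors
#' @export
setGeneric("caseFraction", function(x) standardGeneric("caseFraction"))

#' @rdname accessors
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' @rdname accessors
#' @export
setGeneric("thetaHat", function(x) standardGeneric("thetaHat"))

#' @rdname accessors
#' @export
setGeneric("seUsed", function(x) standardGeneric("seUsed"))

#' @rdname accessors
#' @export
setGeneric("seFixed", function(x) standardGeneric("seFixed"))

#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("cochranQ", function(x) standardGeneric("cochranQ"))

#' @rdname accessors
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))

#' @rdname accessors
#' @export
setGeneric("fValue", function(x) standardGeneric("fValue"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("effectAllele", function(x) standardGeneric("effectAllele"))

#' @rdname accessors
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname accessors
#' @export
setGeneric("qMatrix", function(x) standardGeneric("qMatrix"))

#' @rdname accessors
#' @export
setGeneric("significantCells", function(x) standardGeneric("significantCells"))
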