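#' @rdname MiRNA-class
#' @param object,x a `MiRNA`, `DuplexStructure` or `ArchitectureReport`.
#' @export
setGeneric("mirnaId", function(x) standardGeneric("mirnaId"))

#' @rdname MiRNA-class
#' @export
setGeneric("mirnaSequence", function(x) standardGeneric("mirnaSequence"))

#' @rdname MiRNA-class
#' @param extended if `TRUE` return the extended seed (positions 2-8),
#'   otherwise the core seed (positions 2-7).
#' @export
setGeneric("seedSequence",
           function(x, extended = FALSE) standardGeneric("seedSequence"))

#' @rdname MiRNA-class
#' @export
setGeneric("threePrimeWindow",
           function(x) standardGeneric("threePrimeWindow"))

#' @rdname MiRNA-class
#' @export
setGeneric("threePrimeWindowLength",
           function(x) standardGeneric("threePrimeWindowLength"))

#' @rdname DuplexStructure-class
#' @param x a `DuplexStructure`.
#' @export
setGeneric("duplexEnergy", function(x) standardGeneric("duplexEnergy"))

#' @rdname DuplexStructure-class
#' @export
setGeneric("duplexPairs", function(x) standardGeneric("duplexPairs"))

#' @rdname ArchitectureReport-class
#' @param x an `ArchitectureReport`.
#' @export
setGeneric("seedClass", function(x) standardGeneric("seedClass"))

#' @rdname ArchitectureReport-class
#' @export
setGeneric("centralMismatchRunLength",
           function(x) standardGeneric("centralMismatchRunLength"))

#' @rdname ArchitectureReport-class
#' @export
setGeneric("threePrimePairRunLength",
           function(x) standardGeneric("threePrimePairRunLength"))

#' @rdname ArchitectureReport-class
#' @export
setGeneric("threePrimeMfeValue",
           function(x) standardGeneric("threePrimeMfeValue"))

#' @rdname ArchitectureReport-class
#' @export
setGeneric("pairingMap", function(x) standardGeneric("pairingMap"))
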