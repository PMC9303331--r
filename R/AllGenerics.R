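#' Accessor generics
#'
#' Small accessor family for the fitted-result classes; prefer these over
#' direct slot access.
#'
#' @param object an object of the documented classes
#' @return a numeric (or logical) scalar
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pEC50", function(object) standardGeneric("pEC50"))
#' @rdname accessors
#' @export
setGeneric("ec50nM", function(object) standardGeneric("ec50nM"))
#' @rdname accessors
#' @export
setGeneric("pIC50", function(object) standardGeneric("pIC50"))
#' @rdname accessors
#' @export
setGeneric("ic50nM", function(object) standardGeneric("ic50nM"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("isSaturating", function(object) standardGeneric("isSaturating"))
#' @rdname accessors
#' @export
setGeneric("bmaxCpm", function(object) standardGeneric("bmaxCpm"))
#' @rdname accessors
#' @export
setGeneric("kdNM", function(object) standardGeneric("kdNM"))
#' @rdname accessors
#' @export
setGeneric("kiNM", function(object) standardGeneric("kiNM"))
#' @rdname accessors
#' @export
setGeneric("kOn", function(object) standardGeneric("kOn"))
#' @rdname accessors
#' @export
setGeneric("kOff", function(object) standardGeneric("kOff"))
#' @rdname accessors
#' @export
setGeneric("kObs", function(object) standardGeneric("kObs"))
#' @rdname accessors
#' @export
setGeneric("rateConstant", function(object) standardGeneric("rateConstant"))
#' @rdname accessors
#' @export
setGeneric("amplitude", function(object) standardGeneric("amplitude"))
#' @rdname accessors
#' @export
setGeneric("standardErrors", function(object) standardGeneric("standardErrors"))
#' @rdname accessors
#' @export
setGeneric("pA2", function(object) standardGeneric("pA2"))
#' @rdname accessors
#' @export
setGeneric("a2nM", function(object) standardGeneric("a2nM"))
#' @rdname accessors
#' @export
setGeneric("schildSlope", function(object) standardGeneric("schildSlope"))

#' @rdname accessors
#' @export
setMethod("pEC50", "LogisticFit", function(object) object@pec50)
#' @rdname accessors
#' @export
setMethod("ec50nM", "LogisticFit", function(object) object@ec50_nM)
#' @rdname accessors
#' @export
setMethod("isConverged", "LogisticFit", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("isSaturating", "LogisticFit", function(object) !object@na_call)

#' @rdname accessors
#' @export
setMethod("pIC50", "EquilibriumResult", function(object) object@pic50)
#' @rdname accessors
#' @export
setMethod("ic50nM", "EquilibriumResult", function(object) object@ic50_nM)
#' @rdname accessors
#' @export
setMethod("bmaxCpm", "EquilibriumResult", function(object) object@bmax_cpm)
#' @rdname accessors
#' @export
setMethod("kdNM", "EquilibriumResult", function(object) object@kd_nM)
#' @rdname accessors
#' @export
setMethod("kiNM", "EquilibriumResult", function(object) object@ki_nM)

#' @rdname accessors
#' @export
setMethod("bmaxCpm", "SystemParams", function(object) object@bmax_cpm)
#' @rdname accessors
#' @export
setMethod("kdNM", "SystemParams", function(object) object@kd_nM)
#' @rdname accessors
#' @export
setMethod("kOn", "SystemParams", function(object) object@kon)
#' @rdname accessors
#' @export
setMethod("kOff", "SystemParams", function(object) object@koff)

#' @rdname accessors
#' @export
setMethod("rateConstant", "KineticFit", function(object) object@rate)
#' @rdname accessors
#' @export
setMethod("amplitude", "KineticFit", function(object) object@amplitude)
#' @rdname accessors
#' @export
setMethod("isConverged", "KineticFit", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("standardErrors", "KineticFit", function(object)
  c(rate = object@se_rate, amplitude = object@se_amplitude))

#' @rdname accessors
#' @export
setMethod("kObs", "KineticConstants", function(object) object@kobs)
#' @rdname accessors
#' @export
setMethod("kOff", "KineticConstants", function(object) object@koff)
#' @rdname accessors
#' @export
setMethod("kOn", "KineticConstants", function(object) object@kon)
#' @rdname accessors
#' @export
setMethod("kdNM", "KineticConstants", function(object) object@kd_nM)
#' @rdname accessors
#' @export
setMethod("standardErrors", "KineticConstants", function(object)
  c(kobs = object@se_kobs, koff = object@se_koff, kon = object@se_kon,
    kd_nM = object@se_kd))

#' @rdname accessors
#' @export
setMethod("pA2", "SchildFit", function(object) object@pa2)
#' @rdname accessors
#' @export
setMethod("a2nM", "SchildFit", function(object) object@a2_nM)
#' @rdname accessors
#' @export
setMethod("schildSlope", "SchildFit", function(object) object@slope)
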