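#' @rdname AssociationTable-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("variants", function(object) standardGeneric("variants"))

#' @rdname AssociationTable-class
#' @export
setMethod("variants", "AssociationTable", function(object) object@variants)

#' @rdname AssociationTable-class
#' @export
setGeneric("variantIds", function(object) standardGeneric("variantIds"))

#' @rdname AssociationTable-class
#' @export
setMethod("variantIds", "AssociationTable",
          function(object) object@variants$variant_id)

#' @rdname HarmonizedInstruments-class
#' @export
setMethod("variantIds", "HarmonizedInstruments",
          function(object) object@instruments$variant_id)

#' @rdname LDMatrix-class
#' @export
setMethod("variantIds", "LDMatrix", function(object) rownames(object@r2))

#' @rdname AssociationTable-class
#' @export
setGeneric("traitType", function(object) standardGeneric("traitType"))

#' @rdname AssociationTable-class
#' @export
setMethod("traitType", "AssociationTable", function(object) object@traitType)

#' @rdname AssociationTable-class
#' @export
setGeneric("traitLabel", function(object) standardGeneric("traitLabel"))

#' @rdname AssociationTable-class
#' @export
setMethod("traitLabel", "AssociationTable", function(object) object@traitLabel)

#' @rdname AssociationTable-class
#' @export
setGeneric("rejectedRows", function(object) standardGeneric("rejectedRows"))

#' @rdname AssociationTable-class
#' @export
setMethod("rejectedRows", "AssociationTable", function(object) object@rejected)

#' @rdname HarmonizedInstruments-class
#' @export
setGeneric("instruments", function(object) standardGeneric("instruments"))

#' @rdname HarmonizedInstruments-class
#' @export
setMethod("instruments", "HarmonizedInstruments",
          function(object) object@instruments)

#' @rdname HarmonizedInstruments-class
#' @export
setGeneric("exclusions", function(object) standardGeneric("exclusions"))

#' @rdname HarmonizedInstruments-class
#' @export
setMethod("exclusions", "HarmonizedInstruments",
          function(object) object@exclusions)

#' @rdname LDMatrix-class
#' @export
setGeneric("ldValues", function(object) standardGeneric("ldValues"))

#' @rdname LDMatrix-class
#' @export
setMethod("ldValues", "LDMatrix", function(object) object@r2)

#' @rdname MREstimate-class
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))

#' @rdname MREstimate-class
#' @export
setMethod("estimate", "MREstimate", function(object)
  c(b = object@b, se = object@se, or = object@or, ci_low = object@ciLow,
    ci_high = object@ciHigh, pval = object@pval, k = object@k))

#' @rdname SensitivityReport-class
#' @export
setGeneric("looTable", function(object) standardGeneric("looTable"))

#' @rdname SensitivityReport-class
#' @export
setMethod("looTable", "SensitivityReport", function(object) object@loo)

setMethod("length", "AssociationTable", function(x) nrow(x@variants))
setMethod("length", "HarmonizedInstruments",
          function(x) nrow(x@instruments))

setMethod("show", "AssociationTable", function(object) {
  cat(sprintf("AssociationTable '%s' (%s): %d variants",
              object@traitLabel, object@traitType, nrow(object@variants)))
  if (nrow(object@rejected))
    cat(sprintf(", %d rows rejected at read", nrow(object@rejected)))
  cat("\n")
  if (nrow(object@variants))
    print(utils::head(object@variants, 4L), row.names = FALSE)
})

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d x %d squared correlations\n",
              nrow(object@r2), ncol(object@r2)))
})

setMethod("show", "HarmonizedInstruments", function(object) {
  cat(sprintf("HarmonizedInstruments: %s -> %s, %d instruments (%d excluded)\n",
              object@exposureLabel, object@outcomeLabel,
              nrow(object@instruments), nrow(object@exclusions)))
  if (nrow(object@instruments))
    print(utils::head(object@instruments[, c("variant_id", "beta_exp",
                                             "beta_out", "wald_ratio",
                                             "wald_se")], 4L),
          row.names = FALSE)
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s (k = %d): b = %.4f, SE = %.4f, OR = %.3f (%.3f-%.3f), p = %.3g\n",
              object@method, object@k, object@b, object@se, object@or,
              object@ciLow, object@ciHigh, object@pval))
})

setMethod("show", "SensitivityReport", function(object) {
  cat(sprintf("Cochran's Q (IVW):   Q = %.3f, df = %d, p = %.4f\n",
              object@qIvw[["Q"]], object@qIvw[["df"]], object@qIvw[["pval"]]))
  cat(sprintf("Cochran's Q (Egger): Q = %.3f, df = %d, p = %.4f\n",
              object@qEgger[["Q"]], object@qEgger[["df"]],
              object@qEgger[["pval"]]))
  cat(sprintf("Egger intercept: b = %.4f (P = %.4f)\n",
              object@eggerIntercept[["estimate"]],
              object@eggerIntercept[["pval"]]))
  cat(sprintf("Leave-one-out: %d rows\n", nrow(object@loo)))
})
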