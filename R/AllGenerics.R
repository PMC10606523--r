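#' @rdname ParameterizedStructure-class
#' @param x object
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname ParameterizedStructure-class
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname EnergyLedger-class
#' @param x object
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname EnergyLedger-class
#' @export
setGeneric("intrinsicPka", function(x) standardGeneric("intrinsicPka"))

#' @rdname EnergyLedger-class
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' @rdname TitrationResult-class
#' @param x object
#' @export
setGeneric("protonationFractions",
           function(x) standardGeneric("protonationFractions"))

#' @rdname TitrationResult-class
#' @export
setGeneric("pkaHalf", function(x) standardGeneric("pkaHalf"))

#' @rdname TitrationResult-class
#' @export
setGeneric("mcError", function(x) standardGeneric("mcError"))

setMethod("atoms", "ParameterizedStructure", function(x) x@atoms)
setMethod("chainIds", "ParameterizedStructure", function(x) x@chains)
setMethod("siteIds", "EnergyLedger", function(x) x@siteIds)
setMethod("siteIds", "TitrationResult", function(x) x@siteIds)
setMethod("siteIds", "MicrostateModel", function(x) x@siteIds)
setMethod("intrinsicPka", "EnergyLedger", function(x) {
  stats::setNames(x@intrinsicPka, x@siteIds)
})
setMethod("intrinsicPka", "MicrostateModel", function(x) {
  stats::setNames(x@intrinsicPka, x@siteIds)
})
setMethod("interactionMatrix", "EnergyLedger", function(x) x@W)
setMethod("interactionMatrix", "MicrostateModel", function(x) x@W)
setMethod("protonationFractions", "TitrationResult", function(x) x@fractions)
setMethod("pkaHalf", "TitrationResult", function(x) {
  stats::setNames(x@pkaHalf, x@siteIds)
})
setMethod("mcError", "TitrationResult", function(x) {
  stats::setNames(x@mcError, x@siteIds)
})

setMethod("show", "ParameterizedStructure", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[, c("chain", "resno")]))
  cat("ParameterizedStructure:", nrow(a), "atoms,", nres, "residues,",
      length(object@chains), "chain(s)\n")
  if (nrow(a)) {
    cat("  charges:", if (all(is.na(a$charge))) "unset" else "assigned", "\n")
  }
  invisible(object)
})

setMethod("show", "TitratableSite", function(object) {
  cat(sprintf("TitratableSite %s (%s, model pKa %.2f)\n", object@siteId,
              object@acidOrBase, object@modelPka))
  invisible(object)
})

setMethod("show", "DielectricMap", function(object) {
  d <- object@grid@dims
  cat(sprintf("DielectricMap: %d x %d x %d nodes, h = %.2f A\n",
              d[1], d[2], d[3], object@grid@spacing))
  tab <- table(factor(object@labels, levels = .REGION,
                      labels = names(.REGION)))
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(object)
})

setMethod("show", "EnergyLedger", function(object) {
  cat("EnergyLedger, frame", object@frameId, "\n")
  print(ledgerTable(object), digits = 3)
  invisible(object)
})

setMethod("show", "TitrationResult", function(object) {
  cat(sprintf("TitrationResult (%s): %d sites, pH %.1f..%.1f\n",
              object@method, length(object@siteIds), min(object@pHGrid),
              max(object@pHGrid)))
  print(data.frame(siteId = object@siteIds, pKa = round(object@pkaHalf, 3),
                   mcError = signif(object@mcError, 3)))
  invisible(object)
})

setMethod("show", "MicrostateModel", function(object) {
  cat("MicrostateModel:", length(object@siteIds), "sites\n")
  invisible(object)
})

#' Energy ledger as a data.frame
#'
#' @param ledger an \linkS4class{EnergyLedger}
#' @return data.frame with one row per site
#' @export
ledgerTable <- function(ledger) {
  data.frame(siteId = ledger@siteIds, modelPka = ledger@modelPka,
             bornShift = ledger@bornShift,
             backgroundShift = ledger@backgroundShift,
             intrinsicPka = ledger@intrinsicPka)
}
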