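#' @describeIn EnvStack-class names of the seven environmental variables.
#' @param stack an [EnvStack-class].
#' @export
envVars <- function(stack) names(stack@fields)

#' @describeIn EnvStack-class extract one variable's matrix.
#' @param var variable name, one of \code{envVars(stack)}.
#' @export
envField <- function(stack, var) {
  if (!var %in% names(stack@fields))
    stopf("unknown environmental variable '%s'", var)
  stack@fields[[var]]
}

#' @describeIn EnvStack-class replace one variable's matrix (revalidates).
#' @param value replacement matrix.
#' @export
`envField<-` <- function(stack, var, value) {
  if (!var %in% names(stack@fields))
    stopf("unknown environmental variable '%s'", var)
  stack@fields[[var]] <- value
  validObject(stack)
  stack
}

#' @describeIn EnvStack-class logical matrix, TRUE on ocean cells
#'   (depth < 0 on the static bathymetry).
#' @export
oceanMask <- function(stack) stack@fields$depth < 0

#' @describeIn EnvStack-class the [GridSpec-class] of the stack.
#' @export
envGrid <- function(stack) stack@grid

setMethod("show", "EnvStack", function(object) {
  m <- oceanMask(object)
  cat(sprintf("EnvStack [%s / %s / %s]: %d x %d grid, %d ocean cells\n",
              object@esm, object@scenario, object@period,
              nLat(object@grid), nLon(object@grid), sum(m)))
  for (v in names(object@fields)) {
    x <- object@fields[[v]][m]
    cat(sprintf("  %-8s %8.2f .. %8.2f\n", v,
                suppressWarnings(min(x, na.rm = TRUE)),
                suppressWarnings(max(x, na.rm = TRUE))))
  }
})

setMethod("show", "HsiMap", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf("HsiMap '%s' [%s / %s / %s]: %d valid cells, HSI %.3f .. %.3f\n",
              object@species, object@esm, object@scenario, object@period,
              length(v), min(v), max(v)))
})

setMethod("show", "BinaryHabitat", function(object) {
  s <- object@suitable
  cat(sprintf("BinaryHabitat (threshold %.4f): %d suitable of %d valid cells\n",
              object@threshold, sum(s, na.rm = TRUE), sum(!is.na(s))))
})

setMethod("show", "AssociationMatrix", function(object) {
  cat(sprintf("AssociationMatrix: %d species, %d significant pairs\n",
              length(object@species),
              sum(object@significant[upper.tri(object@significant)])))
  print(round(object@correlation, 2))
})

setMethod("show", "ProtectedAreaSet", function(object) {
  cat(sprintf("ProtectedAreaSet: %d current, %d negotiated polygon(s)\n",
              sum(object@status == "current"),
              sum(object@status == "negotiated")))
})

#' @describeIn AssociationMatrix-class posterior-mean correlation matrix.
#' @param x an [AssociationMatrix-class].
#' @export
associationCorrelation <- function(x) x@correlation

#' @describeIn AssociationMatrix-class logical significance mask.
#' @export
associationSignificant <- function(x) x@significant
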