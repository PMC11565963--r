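#' @rdname BarcodeExperiment-accessors
#' @export
setGeneric("editIds", function(x) standardGeneric("editIds"))

#' @rdname BarcodeExperiment-accessors
#' @export
setGeneric("barcodeIds", function(x) standardGeneric("barcodeIds"))

#' @rdname BarcodeExperiment-accessors
#' @export
setGeneric("isNeutral", function(x) standardGeneric("isNeutral"))

#' @rdname BarcodeExperiment-accessors
#' @export
setGeneric("neutralEdits", function(x) standardGeneric("neutralEdits"))

#' @rdname BarcodeExperiment-accessors
#' @export
setGeneric("removedBarcodes", function(x) standardGeneric("removedBarcodes"))

#' @rdname FitnessFit-accessors
#' @export
setGeneric("hyperfitness", function(x) standardGeneric("hyperfitness"))

#' @rdname FitnessFit-accessors
#' @export
setGeneric("replicateFitness", function(x) standardGeneric("replicateFitness"))

#' @rdname FitnessFit-accessors
#' @export
setGeneric("meanFitness", function(x) standardGeneric("meanFitness"))

#' @rdname classify
#' @export
setGeneric("classify", function(x, intervalMass = 0.95) standardGeneric("classify"))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("strainData", function(x) standardGeneric("strainData"))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("strainTree", function(x) standardGeneric("strainTree"))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("presenceSet", function(x, variant) standardGeneric("presenceSet"))

#' @rdname SimulationTruth-accessors
#' @export
setGeneric("trueS", function(x) standardGeneric("trueS"))

#' @rdname SimulationTruth-accessors
#' @export
setGeneric("trueMeanFitness", function(x) standardGeneric("trueMeanFitness"))

#' @rdname SimulationTruth-accessors
#' @export
setGeneric("outlierBarcodes", function(x) standardGeneric("outlierBarcodes"))
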