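#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers: \code{profiles}
#' extracts the profile list of a [ProfileDataset-class]; \code{parameters}
#' and \code{fitStats} the parameter table and goodness-of-fit statistics of a
#' [FitResult-class]; \code{states} and \code{rateTable} the state table and
#' edge list of an [ExchangeModel-class]; \code{nAtoms}, \code{nFrames} and
#' \code{getFrame} address a [StructureEnsemble-class]; \code{freeEnergy} the
#' grid of a [Landscape-class].
#'
#' @param x the object.
#' @param i frame index (1-based) for \code{getFrame}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setMethod("profiles", "ProfileDataset", function(x) x@profiles)

#' @rdname accessors
#' @export
setGeneric("parameters", function(x) standardGeneric("parameters"))
#' @rdname accessors
#' @export
setMethod("parameters", "FitResult", function(x) x@parameters)

#' @rdname accessors
#' @export
setGeneric("fitStats", function(x) standardGeneric("fitStats"))
#' @rdname accessors
#' @export
setMethod("fitStats", "FitResult", function(x) x@stats)

#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))
#' @rdname accessors
#' @export
setMethod("states", "ExchangeModel", function(x) x@states)

#' @rdname accessors
#' @export
setGeneric("rateTable", function(x) standardGeneric("rateTable"))
#' @rdname accessors
#' @export
setMethod("rateTable", "ExchangeModel", function(x) x@rates)

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setMethod("nAtoms", "StructureEnsemble", function(x) nrow(x@atoms))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "StructureEnsemble", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setMethod("getFrame", "StructureEnsemble", function(x, i) {
  stopifnot(i >= 1, i <= dim(x@coords)[3])
  x@coords[, , i, drop = TRUE]
})

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setMethod("atomTable", "StructureEnsemble", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setMethod("freeEnergy", "Landscape", function(x) x@free)

#' Flatten a ProfileDataset to a long-format data.frame
#'
#' One row per data point with all acquisition metadata repeated, matching
#' the columns of the on-disk TSV dialect (see [writeProfiles()]).
#'
#' @param x a [ProfileDataset-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame.
#' @export
as.data.frame.ProfileDataset <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  do.call(rbind, lapply(x@profiles, function(p) {
    data.frame(experiment = p@experiment, residue = p@residue,
               nucleus = p@nucleus, temperature_K = p@temperatureK,
               B0_MHz_1H = p@B0_MHz_1H,
               field_Hz = if (p@experiment == "cest") p@meta$B1_Hz
                          else if (p@experiment == "r1rho") p@meta$omega1_Hz
                          else NA_real_,
               time_s = if (p@experiment == "cest") p@meta$Tex_s
                        else if (p@experiment == "cpmg") p@meta$Tcp_s
                        else NA_real_,
               observe = if (is.null(p@meta$observe)) NA_character_
                         else p@meta$observe,
               x = p@data$x, y = p@data$y, sigma = p@data$sigma,
               stringsAsFactors = FALSE)
  }))
}

#' Number of profiles in a dataset
#' @param x a ProfileDataset.
#' @export
setMethod("length", "ProfileDataset", function(x) length(x@profiles))
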