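#' @include AllClasses.R
NULL

#' Accessors for curvotaxis data objects
#'
#' Small generic accessors used across the package instead of direct slot
#' access: \code{heights()}, \code{spacing()}, \code{gridOrigin()} for
#' [HeightMap-class] and related grids; \code{bandEdges()}, \code{bandArea()},
#' \code{bandLabels()} for [HeightBands-class]; \code{minima()},
#' \code{maxima()}, \code{saddles()} for [ExtremaSet-class];
#' \code{basinLabels()} for [BasinMap-class]; \code{meanH()},
#' \code{gaussK()}, \code{principalCurvatures()} for [CurvatureField-class].
#'
#' @param x an object of the documented class.
#' @return The slot contents (matrix, numeric vector or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("bandEdges", function(x) standardGeneric("bandEdges"))
#' @rdname accessors
#' @export
setGeneric("bandArea", function(x) standardGeneric("bandArea"))
#' @rdname accessors
#' @export
setGeneric("bandLabels", function(x) standardGeneric("bandLabels"))
#' @rdname accessors
#' @export
setGeneric("minima", function(x) standardGeneric("minima"))
#' @rdname accessors
#' @export
setGeneric("maxima", function(x) standardGeneric("maxima"))
#' @rdname accessors
#' @export
setGeneric("saddles", function(x) standardGeneric("saddles"))
#' @rdname accessors
#' @export
setGeneric("basinLabels", function(x) standardGeneric("basinLabels"))
#' @rdname accessors
#' @export
setGeneric("meanH", function(x) standardGeneric("meanH"))
#' @rdname accessors
#' @export
setGeneric("gaussK", function(x) standardGeneric("gaussK"))
#' @rdname accessors
#' @export
setGeneric("principalCurvatures", function(x) standardGeneric("principalCurvatures"))

#' Peak-to-valley height range of an ideal landscape
#'
#' For the sum form the range is \eqn{4B} (each cosine contributes \eqn{2B});
#' for the product form it is \eqn{2A}.
#'
#' @param x a [SinusoidSpec-class].
#' @return Peak-to-valley range in µm.
#' @export
setGeneric("heightRange", function(x) standardGeneric("heightRange"))
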