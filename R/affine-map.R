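#' Construct a 2-D affine map
#'
#' An affine map is the linear part \eqn{\mathcal{A}} of the image-domain
#' transformation \eqn{x' = \mathcal{A} x}; translations are excluded (a
#' common fixation point is assumed to project to the origin of both
#' image coordinate systems). The object is a plain 2x2 numeric matrix
#' with class `"affine_map"`.
#'
#' @param a11,a12,a21,a22 Entries of the 2x2 matrix. Alternatively,
#'   `a11` may be a 2x2 numeric matrix and the remaining arguments
#'   omitted.
#' @return An `affine_map` object (a classed 2x2 matrix).
#' @examples
#' affine_map(2, 0, 0, 1)
#' affine_map(rot2_matrix(pi / 3))
#' @export
affine_map <- function(a11, a12 = NULL, a21 = NULL, a22 = NULL) {
  if (is.matrix(a11)) {
    m <- a11
    if (!all(dim(m) == c(2L, 2L))) {
      stop("invalid input: affine map must be a 2x2 matrix", call. = FALSE)
    }
  } else {
    m <- matrix(c(a11, a21, a12, a22), 2L, 2L)
  }
  storage.mode(m) <- "double"
  stopifnot_finite(m, "affine map entries")
  structure(m, class = c("affine_map", "matrix"))
}

#' Coerce to an affine map
#' @param x A 2x2 numeric matrix or `affine_map`.
#' @return An `affine_map`.
#' @export
as_affine_map <- function(x) {
  if (inherits(x, "affine_map")) return(x)
  affine_map(as.matrix(x))
}

#' Rotation matrix by a given angle
#'
#' Counter-clockwise rotation in the standard right-handed image
#' coordinate convention (`x1` horizontal, `x2` vertical).
#'
#' @param theta Rotation angle in radians.
#' @return A 2x2 rotation matrix.
#' @export
rot2_matrix <- function(theta) rot2(theta)

#' @export
print.affine_map <- function(x, ...) {
  cat("<affine_map>\n")
  print(unclass(x), ...)
  invisible(x)
}

## JSON / text IO -----------------------------------------------------------

#' Read and write affine maps
#'
#' Maps are exchanged either as JSON objects
#' `{"a11":..., "a12":..., "a21":..., "a22":...}` or as 2-line
#' whitespace-separated text (one matrix row per line).
#'
#' @param path File path.
#' @param format `"json"` or `"text"`; `read_affine_map()` guesses from
#'   the file extension when omitted.
#' @param map An `affine_map` (or coercible matrix).
#' @return `read_affine_map()` returns an `affine_map`;
#'   `write_affine_map()` returns `path` invisibly.
#' @export
read_affine_map <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "text")
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    affine_map(obj$a11, obj$a12, obj$a21, obj$a22)
  } else {
    m <- as.matrix(read.table(path, header = FALSE))
    dimnames(m) <- NULL
    affine_map(m)
  }
}

#' @rdname read_affine_map
#' @export
write_affine_map <- function(map, path, format = NULL) {
  map <- as_affine_map(map)
  format <- format %||% (if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "text")
  if (format == "json") {
    jsonlite::write_json(
      list(a11 = map[1, 1], a12 = map[1, 2], a21 = map[2, 1], a22 = map[2, 2]),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(unclass(map), path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
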