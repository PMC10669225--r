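#' Framed rigid transforms
#'
#' A `framed_transform` is a 4x4 homogeneous rigid transform (rotation block
#' plus translation in mm) tagged with the names of its source (`from`) and
#' target (`to`) coordinate frames. It is the currency every kinematic chain
#' in the package is written in: joint chains, jaw poses, marker/camera
#' chains and registration results are all framed transforms.
#'
#' @param matrix 4x4 numeric homogeneous matrix.
#' @param from,to frame names (character scalars) or `NA` for an untagged
#'   elementary block.
#' @param validate check rigid-transform invariants (default `TRUE`).
#' @return An object of class `framed_transform`.
#' @export
framed_transform <- function(matrix, from = NA_character_, to = NA_character_,
                             validate = TRUE) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix) || !identical(dim(matrix), c(4L, 4L)))
    stop("invalid-argument: 'matrix' must be a numeric 4x4 matrix")
  x <- structure(list(matrix = matrix,
                      from = as.character(from), to = as.character(to)),
                 class = "framed_transform")
  if (validate) validate_framed_transform(x)
  x
}

#' @rdname framed_transform
#' @param x a `framed_transform`.
#' @param tol orthonormality tolerance.
#' @export
validate_framed_transform <- function(x, tol = 1e-9) {
  m <- x$matrix
  if (any(!is.finite(m))) stop("invalid-argument: non-finite transform entries")
  if (!all(m[4, ] == c(0, 0, 0, 1)))
    stop("invalid-argument: last row of a homogeneous transform must be [0,0,0,1]")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("invalid-argument: rotation block is not orthonormal")
  if (abs(det(R) - 1) > tol)
    stop("invalid-argument: rotation block must have determinant +1")
  invisible(x)
}

#' @export
print.framed_transform <- function(x, ...) {
  cat(sprintf("<framed_transform %s -> %s>\n",
              ifelse(is.na(x$from), "?", x$from),
              ifelse(is.na(x$to), "?", x$to)))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Identity transform
#' @param frame optional frame name used for both ends.
#' @export
identity_transform <- function(frame = NA_character_) {
  framed_transform(diag(4), from = frame, to = frame, validate = FALSE)
}

rot3 <- function(axis, angle) {
  c <- cos(angle); s <- sin(angle)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3),
         y = matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3),
         z = matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3),
         stop("invalid-argument: axis must be one of 'x','y','z'"))
}

#' Elementary rotation transform
#'
#' Rotation about a principal axis, the building block of the articulator
#' joint chain and of the mandibular pose Rz*Ry*Rx composition.
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle angle in radians.
#' @export
make_rotation <- function(axis, angle) {
  if (!is.numeric(angle) || length(angle) != 1L || !is.finite(angle))
    stop("invalid-argument: 'angle' must be a finite scalar (radians)")
  m <- diag(4)
  m[1:3, 1:3] <- rot3(match.arg(axis, c("x", "y", "z")), angle)
  framed_transform(m, validate = FALSE)
}

#' Pure translation transform
#' @param t length-3 numeric offset in mm.
#' @export
make_translation <- function(t) {
  if (!is.numeric(t) || length(t) != 3L || any(!is.finite(t)))
    stop("invalid-argument: 't' must be a finite 3-vector (mm)")
  m <- diag(4)
  m[1:3, 4] <- t
  framed_transform(m, validate = FALSE)
}

#' Compose two framed transforms
#'
#' `compose(A, B)` applies `B` first, then `A`; when both transforms carry
#' frame tags, `B`'s target frame must equal `A`'s source frame and the
#' result maps `B$from` to `A$to`. Composing untagged blocks is allowed.
#'
#' @param A,B `framed_transform` objects.
#' @export
compose <- function(A, B) {
  stopifnot(inherits(A, "framed_transform"), inherits(B, "framed_transform"))
  if (!is.na(A$from) && !is.na(B$to) && A$from != B$to)
    stop(sprintf("frame-mismatch: cannot compose '%s->%s' after '%s->%s'",
                 B$from, B$to, A$from, A$to))
  framed_transform(A$matrix %*% B$matrix,
                   from = B$from, to = A$to, validate = FALSE)
}

#' Invert a rigid transform
#'
#' Uses the closed form `[R^T | -R^T t]`; frame tags are swapped.
#' @param T a `framed_transform`.
#' @export
invert <- function(T) {
  stopifnot(inherits(T, "framed_transform"))
  R <- T$matrix[1:3, 1:3]
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -t(R) %*% T$matrix[1:3, 4]
  framed_transform(m, from = T$to, to = T$from, validate = FALSE)
}

#' Apply a transform to points
#'
#' @param T a `framed_transform`.
#' @param pts a length-3 vector or an N x 3 matrix of points (mm).
#' @return Points in the same shape as the input.
#' @export
apply_transform <- function(T, pts) {
  stopifnot(inherits(T, "framed_transform"))
  R <- T$matrix[1:3, 1:3]; tr <- T$matrix[1:3, 4]
  if (is.null(dim(pts))) {
    if (length(pts) != 3L) stop("invalid-argument: point must be a 3-vector")
    return(drop(R %*% pts + tr))
  }
  stopifnot(ncol(pts) == 3L)
  sweep(pts %*% t(R), 2L, tr, "+")
}

#' Mirror a transform across the sagittal plane (x = 0)
#'
#' Conjugates by the reflection diag(-1,1,1); maps a right-side chain to its
#' left-side counterpart. The result is again a proper rigid transform.
#' @param T a `framed_transform`.
#' @export
mirror_transform <- function(T) {
  S <- diag(c(-1, 1, 1, 1))
  framed_transform(S %*% T$matrix %*% S, from = T$from, to = T$to,
                   validate = FALSE)
}

#' Serialize / deserialize a transform to JSON
#'
#' Format: `{"from": str, "to": str, "matrix": [16 numbers, row-major]}`.
#' @param T a `framed_transform`.
#' @param path file path.
#' @export
write_transform_json <- function(T, path) {
  jsonlite::write_json(
    list(from = T$from, to = T$to,
         matrix = as.vector(t(T$matrix))),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$matrix) || length(x$matrix) != 16L)
    stop("format-error: transform JSON must carry 16 row-major matrix entries")
  framed_transform(matrix(as.numeric(x$matrix), 4, 4, byrow = TRUE),
                   from = if (is.null(x$from)) NA_character_ else x$from,
                   to = if (is.null(x$to)) NA_character_ else x$to)
}
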