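# Internal geometry helpers shared across the package.

# Coerce a landmark matrix: k x 2 numeric, finite.
as_shape_matrix <- function(x, arg = deparse(substitute(x))) {
  x <- as.matrix(x)
  if (ncol(x) != 2L)
    stop(sprintf("'%s' must be a k x 2 coordinate matrix", arg), call. = FALSE)
  storage.mode(x) <- "double"
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite coordinates", arg), call. = FALSE)
  x
}

shape_centroid <- function(x) colMeans(x)

center_shape <- function(x) sweep(x, 2L, colMeans(x))

# 2x2 rotation matrix, counter-clockwise by theta radians.
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

# Flatten k x 2 -> length-2k vector (x1, y1, x2, y2, ...) and back.
flatten_shape <- function(x) as.vector(t(x))

unflatten_shape <- function(v) matrix(v, ncol = 2L, byrow = TRUE)

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
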