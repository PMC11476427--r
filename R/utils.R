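# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed and a component tag
#'
#' A single master seed drives the whole pipeline; each component draws from
#' its own sub-stream so that changing one stage does not shift the random
#' numbers seen by another.
#'
#' @param master integer master seed.
#' @param tag character component tag, e.g. `"geometry"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- as.numeric(master) %% 2147483647
  for (k in utf8ToInt(tag)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Trapezoidal quadrature of y(t) over t.
trapz <- function(t, y) {
  n <- length(t)
  sum((t[-1] - t[-n]) * (y[-1] + y[-n])) / 2
}

# Shoelace signed area of a polygon given as an n x 2 matrix (not closed).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# areas of all triangles of a mesh
tri_areas <- function(m) {
  p <- m$nodes; t <- m$tris
  abs((p[t[, 2], 1] - p[t[, 1], 1]) * (p[t[, 3], 2] - p[t[, 1], 2]) -
        (p[t[, 3], 1] - p[t[, 1], 1]) * (p[t[, 2], 2] - p[t[, 1], 2])) / 2
}

stop_module <- function(module, msg, ...) {
  stop(sprintf("[%s] %s", module, sprintf(msg, ...)), call. = FALSE)
}
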