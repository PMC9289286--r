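# 1D reference-domain mesh.

#' Create a one-dimensional interval mesh
#'
#' Nodes of the reference interval `[0, L]` with linear element
#' connectivity. Uniform by default; an explicit strictly increasing node
#' vector may be supplied instead.
#'
#' @param L Domain length (cm). The reference myocardial strip is 8 cm.
#' @param n_elems Number of elements (default 400).
#' @param nodes Optional explicit node positions; overrides `L`/`n_elems`
#'   spacing but must start at 0 and end at `L`.
#' @return Object of class `myo_mesh`: list with `L`, `n_elems`, `nodes`,
#'   element sizes `h` and lumped nodal weights `w`.
#' @examples
#' m <- mesh_1d(8, 400)
#' range(diff(m$nodes))
#' @export
mesh_1d <- function(L = 8, n_elems = 400, nodes = NULL) {
  stopifnot(L > 0, n_elems >= 1)
  if (is.null(nodes)) {
    nodes <- seq(0, L, length.out = n_elems + 1)
  } else {
    if (any(diff(nodes) <= 0)) stop("nodes must be strictly increasing")
    if (abs(nodes[1]) > 1e-14 || abs(nodes[length(nodes)] - L) > 1e-12 * L)
      stop("nodes must span [0, L]")
    n_elems <- length(nodes) - 1L
  }
  h <- diff(nodes)
  w <- c(h / 2, 0) + c(0, h / 2)  # lumped (row-sum) mass weights
  structure(list(L = L, n_elems = as.integer(n_elems), nodes = nodes,
                 h = h, w = w),
            class = "myo_mesh")
}

#' @export
print.myo_mesh <- function(x, ...) {
  cat("1D mesh on [0, ", format(x$L), "] cm: ", x$n_elems, " elements, ",
      length(x$nodes), " nodes\n", sep = "")
  invisible(x)
}
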