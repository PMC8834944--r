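#' Areal adjacency structures
#'
#' An `ndi_adjacency` object stores the neighbourhood graph of a set of areal
#' units (e.g. census block groups) as named neighbour lists. It is the
#' structure required by the intrinsic CAR priors of the shared-component
#' model: the pairwise-difference penalty runs over its edges, and its number
#' of connected components determines the rank deficiency of the ICAR
#' precision.
#'
#' @param neighbors named list; element `i` holds the character ids of the
#'   units adjacent to unit `names(neighbors)[i]`. Must be symmetric and free
#'   of self-neighbours.
#' @return An object of class `ndi_adjacency` with elements `ids`,
#'   `neighbors` (list of integer indices into `ids`) and `n_islands`, the
#'   number of connected components of the graph.
#' @examples
#' adj <- ndi_adjacency(list(a = "b", b = "a", c = character()))
#' adj$n_islands  # 2: the pair {a,b} and the isolated unit c
#' @export
ndi_adjacency <- function(neighbors) {
  ids <- names(neighbors)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("`neighbors` must be a named list with unique non-empty names")
  idx <- lapply(seq_along(neighbors), function(i) {
    nb <- as.character(neighbors[[i]])
    if (ids[i] %in% nb)
      stop("unit '", ids[i], "' lists itself as a neighbor")
    m <- match(nb, ids)
    if (anyNA(m))
      stop("unit '", ids[i], "' has unknown neighbor(s): ",
           paste(nb[is.na(m)], collapse = ", "))
    sort(unique(m))
  })
  # symmetry
  for (i in seq_along(idx)) {
    for (j in idx[[i]]) {
      if (!(i %in% idx[[j]]))
        stop("asymmetric adjacency: '", ids[i], "' lists '", ids[j],
             "' but not vice versa")
    }
  }
  structure(
    list(ids = ids, neighbors = idx, n_islands = n_graph_components(idx)),
    class = "ndi_adjacency"
  )
}

# connected components by breadth-first search over neighbour lists
n_graph_components <- function(idx) {
  n <- length(idx)
  if (n == 0L) return(0L)
  comp <- integer(n)
  ncomp <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      for (j in idx[[i]]) {
        if (comp[j] == 0L) {
          comp[j] <- ncomp
          queue <- c(queue, j)
        }
      }
    }
  }
  ncomp
}

#' Rook adjacency on a rectangular lattice
#'
#' Builds the rook-move (shared edge) neighbourhood graph for an
#' `nrow x ncol` lattice of areal units, the simplest connected areal graph.
#' Unit ids are `"BG0001", "BG0002", ...` in row-major order.
#'
#' @param nrow,ncol positive integers; the lattice must have at least 4 cells.
#' @return An [ndi_adjacency] object with `nrow * ncol` units.
#' @export
lattice_adjacency <- function(nrow, ncol) {
  stopifnot(nrow >= 1, ncol >= 1)
  if (nrow * ncol < 4) stop("lattice must have at least 4 cells")
  n <- nrow * ncol
  ids <- sprintf("BG%04d", seq_len(n))
  nbrs <- vector("list", n)
  cell <- function(r, c) (r - 1L) * ncol + c
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      i <- cell(r, c)
      nb <- integer()
      if (r > 1L) nb <- c(nb, cell(r - 1L, c))
      if (r < nrow) nb <- c(nb, cell(r + 1L, c))
      if (c > 1L) nb <- c(nb, cell(r, c - 1L))
      if (c < ncol) nb <- c(nb, cell(r, c + 1L))
      nbrs[[i]] <- ids[sort(nb)]
    }
  }
  names(nbrs) <- ids
  ndi_adjacency(nbrs)
}

# flatten to 0-based CSR-style arrays for the C++ sampler
adjacency_arrays <- function(adj) {
  stopifnot(inherits(adj, "ndi_adjacency"))
  lens <- vapply(adj$neighbors, length, integer(1))
  list(
    idx = as.integer(unlist(adj$neighbors, use.names = FALSE) - 1L),
    start = as.integer(c(0L, cumsum(lens))),
    n_components = adj$n_islands
  )
}

# graph Laplacian (dense); used by the exact ICAR simulator
adjacency_laplacian <- function(adj) {
  n <- length(adj$ids)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- adj$neighbors[[i]]
    L[i, i] <- length(nb)
    L[i, nb] <- -1
  }
  L
}

#' @export
print.ndi_adjacency <- function(x, ...) {
  cat("ndi_adjacency:", length(x$ids), "units,",
      sum(lengths(x$neighbors)) / 2, "edges,",
      x$n_islands, "connected component(s)\n")
  invisible(x)
}
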