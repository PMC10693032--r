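#' Orthonormal isometric log-ratio basis (pivot coordinates)
#'
#' Builds the pivot-coordinate (sequential binary partition) ilr basis for a
#' set of named compositional parts. Coordinate `j` contrasts part `j` against
#' the geometric mean of parts `j+1, ..., K`, with the standard orthonormal
#' scaling `sqrt((K-j)/(K-j+1))`. The basis matrix `V` (K x (K-1)) satisfies
#' `t(V) %*% V = I` and has zero column sums, i.e. its columns live in the
#' clr plane.
#'
#' Reported composition-scale effects and overall tests computed through this
#' basis are invariant to the pivot order; only the raw ilr coefficients
#' depend on it.
#'
#' @param cell_types character vector of K >= 2 distinct part names, in the
#'   order used for the sequential partition.
#' @return An object of class `ilr_basis`: a list with `cell_types` and the
#'   contrast matrix `V`.
#' @examples
#' b <- ilr_basis(c("a", "b"))
#' b$V  # (1/sqrt(2), -1/sqrt(2))
#' @export
ilr_basis <- function(cell_types) {
  if (!is.character(cell_types) || length(cell_types) < 2L)
    stop("`cell_types` must be a character vector of length >= 2")
  if (anyDuplicated(cell_types))
    stop("duplicate cell-type names: ",
         paste(unique(cell_types[duplicated(cell_types)]), collapse = ", "))
  K <- length(cell_types)
  V <- matrix(0, K, K - 1L, dimnames = list(cell_types, paste0("ilr", seq_len(K - 1L))))
  for (j in seq_len(K - 1L)) {
    s <- sqrt((K - j) / (K - j + 1))
    V[j, j] <- s
    V[(j + 1L):K, j] <- -s / (K - j)
  }
  structure(list(cell_types = cell_types, V = V), class = "ilr_basis")
}

#' Isometric log-ratio transform and its inverse
#'
#' `ilr_transform()` maps strictly positive compositions to (K-1)-dimensional
#' real coordinates: rows are log-transformed, centred by their geometric mean
#' (clr) and projected on the basis contrasts. `ilr_inverse()` maps
#' coordinates back to strictly positive rows summing to one; the round trip
#' is the identity to ~1e-15.
#'
#' @param comp numeric matrix (or vector) of compositions, one row per sample,
#'   columns matching `basis$cell_types` (matched by name when column names
#'   are present). All entries must be strictly positive: run
#'   [replace_zeros()] first if the composition contains rounded zeros.
#' @param basis an [ilr_basis()] object.
#' @return `ilr_transform()`: an N x (K-1) matrix of ilr coordinates.
#' @export
ilr_transform <- function(comp, basis) {
  stopifnot(inherits(basis, "ilr_basis"))
  x <- as_composition_matrix(comp, basis$cell_types)
  if (any(x <= 0))
    stop("compositions must be strictly positive for log-ratio transforms; ",
         "apply replace_zeros() to impute rounded zeros first")
  lx <- log(x)
  clr <- lx - rowMeans(lx)
  z <- clr %*% basis$V
  rownames(z) <- rownames(x)
  z
}

#' @param coords numeric matrix (or vector) of ilr coordinates, N x (K-1).
#' @return `ilr_inverse()`: an N x K matrix of strictly positive compositions
#'   with unit row sums, columns named by `basis$cell_types`.
#' @rdname ilr_transform
#' @export
ilr_inverse <- function(coords, basis) {
  stopifnot(inherits(basis, "ilr_basis"))
  z <- if (is.matrix(coords)) coords else matrix(coords, nrow = 1L)
  if (ncol(z) != length(basis$cell_types) - 1L)
    stop("coords must have K-1 = ", length(basis$cell_types) - 1L, " columns")
  clr <- z %*% t(basis$V)
  # subtract row max before exponentiating for numerical safety
  clr <- clr - apply(clr, 1L, max)
  p <- exp(clr)
  p <- p / rowSums(p)
  colnames(p) <- basis$cell_types
  rownames(p) <- rownames(z)
  p
}

# Coerce a composition input (vector, matrix, data.frame or cell_composition)
# to a plain matrix with columns ordered like `cell_types`.
as_composition_matrix <- function(comp, cell_types = NULL) {
  if (inherits(comp, "cell_composition")) comp <- comp$values
  if (is.data.frame(comp)) comp <- as.matrix(comp)
  if (!is.matrix(comp)) comp <- matrix(comp, nrow = 1L,
                                       dimnames = list(NULL, names(comp)))
  if (!is.null(cell_types)) {
    if (!is.null(colnames(comp))) {
      missing <- setdiff(cell_types, colnames(comp))
      if (length(missing))
        stop("composition is missing parts: ", paste(missing, collapse = ", "))
      comp <- comp[, cell_types, drop = FALSE]
    } else if (ncol(comp) != length(cell_types)) {
      stop("composition has ", ncol(comp), " parts but basis has ",
           length(cell_types))
    } else {
      colnames(comp) <- cell_types
    }
  }
  storage.mode(comp) <- "double"
  comp
}

# Closure: rescale rows to unit sum.
close_rows <- function(x) x / rowSums(x)
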