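#' Estimate cell-type proportions by constrained projection
#'
#' Reference-based deconvolution of bulk methylation beta values: for each
#' sample, solves the quadratic program
#' `minimize ||b - R w||^2 subject to w >= 0 and sum(w) <= 1`
#' over the CpGs shared between bulk and panel, then renormalizes the
#' solution to sum exactly one. This is the constrained-projection estimator
#' used with sorted-cell methylation references; the QP is solved exactly by
#' the dual active-set method of `quadprog::solve.QP`.
#'
#' CpGs are aligned by identifier (intersection, order-insensitive); the
#' number of dropped CpGs is reported via `message()`. An equality-constrained
#' variant (`sum(w) == 1` inside the QP) is available through `constraint`.
#'
#' @param bulk a `bulk_methylation` object, or an N x L matrix of beta values
#'   with CpG identifiers as column names.
#' @param panel a `reference_panel` object, or an L x K matrix with CpG row
#'   names and cell-type column names.
#' @param constraint `"sum_le_one"` (default: inequality + renormalization) or
#'   `"sum_to_one"` (equality inside the QP).
#' @param min_overlap minimum number of shared CpGs required (default 100;
#'   lower it for small synthetic panels). Always at least K.
#' @return object of class `cell_composition`: list with `sample_ids`,
#'   `cell_types` and the N x K `values` matrix of proportions (unit row
#'   sums, nonnegative entries).
#' @examples
#' panel <- generate_reference_panel(K = 2, markers_per_type = 1,
#'                                   contrast = 1, jitter_sd = 0)
#' bulk <- matrix(c(0.3, 0.7), 1, dimnames = list("s1", panel$cpg_ids))
#' estimate_composition(bulk, panel, min_overlap = 2)$values  # 0.3, 0.7
#' @export
estimate_composition <- function(bulk, panel,
                                 constraint = c("sum_le_one", "sum_to_one"),
                                 min_overlap = 100L) {
  constraint <- match.arg(constraint)
  B <- if (inherits(bulk, "bulk_methylation")) bulk$values else as.matrix(bulk)
  R <- if (inherits(panel, "reference_panel")) panel$values else as.matrix(panel)
  if (is.null(colnames(B)) || is.null(rownames(R)))
    stop("bulk columns and panel rows must carry CpG identifiers")
  K <- ncol(R)
  shared <- intersect(colnames(B), rownames(R))
  n_dropped <- (ncol(B) - length(shared)) + (nrow(R) - length(shared))
  if (length(shared) < K)
    stop("only ", length(shared), " shared CpGs between bulk and panel; ",
         "need at least K = ", K)
  if (length(shared) < max(min_overlap, K))
    stop("only ", length(shared), " shared CpGs; below the minimum overlap of ",
         max(min_overlap, K))
  if (n_dropped > 0)
    message("dropped ", n_dropped, " CpGs absent from the bulk/panel intersection")
  B <- B[, shared, drop = FALSE]
  R <- R[shared, , drop = FALSE]
  if (any(B < 0 | B > 1)) stop("bulk beta values must lie in [0, 1]")
  if (qr(R)$rank < K) stop("reference panel is rank deficient on shared CpGs")

  Dmat <- crossprod(R)
  if (constraint == "sum_le_one") {
    Amat <- cbind(diag(K), rep(-1, K))
    bvec <- c(rep(0, K), -1)
    meq <- 0L
  } else {
    Amat <- cbind(rep(1, K), diag(K))
    bvec <- c(1, rep(0, K))
    meq <- 1L
  }
  n <- nrow(B)
  W <- matrix(0, n, K)
  ids <- rownames(B)
  if (is.null(ids)) ids <- paste0("sample", seq_len(n))
  for (i in seq_len(n)) {
    dvec <- crossprod(R, B[i, ])
    w <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = meq)$solution
    w[abs(w) < 1e-12] <- 0          # clamp active-set round-off to exact zero
    if (sum(w) <= 0)
      stop("degenerate sample `", ids[i], "`: constrained projection is all zero")
    W[i, ] <- w / sum(w)
  }
  dimnames(W) <- list(ids, colnames(R))
  structure(list(sample_ids = ids, cell_types = colnames(R), values = W),
            class = "cell_composition")
}

#' Replace rounded zeros by multiplicative simple replacement
#'
#' Log-ratio transforms are undefined at zero, but constrained-projection
#' estimates can contain exact ("rounded") zeros. Multiplicative replacement
#' sets each zero entry to `delta` -- a detection-limit-like small value --
#' and rescales the nonzero entries of that row by `1 - z * delta` (z = the
#' row's zero count), so rows still sum to one and the ratios among the
#' originally nonzero parts are preserved exactly. Rows without zeros are
#' returned unchanged. This is the simple multiplicative strategy, not a
#' model-based (e.g. PLS/clustering) imputation; for small `delta` the two
#' agree in preserving the simplex geometry.
#'
#' @param comp a `cell_composition` object or matrix of unit-sum proportions.
#' @param delta replacement value, in (0, 1/K) (default 1e-3).
#' @return object (or matrix) of the same shape with strictly positive
#'   entries.
#' @examples
#' replace_zeros(matrix(c(0.5, 0.5, 0), 1), delta = 0.01)  # 0.495 0.495 0.01
#' @export
replace_zeros <- function(comp, delta = 1e-3) {
  obj <- comp
  x <- if (inherits(comp, "cell_composition")) comp$values else as.matrix(comp)
  K <- ncol(x)
  if (!is.numeric(delta) || delta <= 0 || delta >= 1 / K)
    stop("`delta` must lie in (0, 1/K) = (0, ", format(1 / K), ")")
  if (any(x < 0)) stop("proportions must be nonnegative")
  zero <- x == 0
  if (any(rowSums(!zero) == 0L)) {
    bad <- which(rowSums(!zero) == 0L)
    stop("degenerate all-zero composition row(s): ",
         paste(utils::head(rownames(x)[bad], 5L), collapse = ", "))
  }
  z <- rowSums(zero)
  idx <- which(z > 0L)
  for (i in idx) {
    x[i, ] <- x[i, ] * (1 - z[i] * delta)
    x[i, zero[i, ]] <- delta
  }
  if (inherits(obj, "cell_composition")) {
    obj$values <- x
    obj
  } else {
    x
  }
}
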