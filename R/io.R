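#' Read and write the pipeline's CSV formats
#'
#' Plain-CSV conventions used throughout: the reference panel is CpGs x cell
#' types with a `cpg_id` first column; bulk methylation is samples x CpGs
#' with a `sample_id` first column; compositions are samples x cell types
#' with a `sample_id` first column; the cohort table is one row per sample.
#'
#' @param path file path.
#' @return `read_reference_panel()`: a `reference_panel`;
#'   `read_bulk_matrix()`: a `bulk_methylation`; `read_composition()`: a
#'   `cell_composition`.
#' @name placomp_io
NULL

#' @rdname placomp_io
#' @export
read_reference_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "cpg_id")
    stop("panel CSV must have `cpg_id` as its first column")
  R <- as.matrix(df[, -1L, drop = FALSE])
  rownames(R) <- df$cpg_id
  if (any(R < 0 | R > 1)) stop("panel beta values must lie in [0, 1]")
  structure(list(cpg_ids = df$cpg_id, cell_types = colnames(R), values = R),
            class = "reference_panel")
}

#' @param panel a `reference_panel`.
#' @rdname placomp_io
#' @export
write_reference_panel <- function(panel, path) {
  df <- data.frame(cpg_id = panel$cpg_ids, panel$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname placomp_io
#' @export
read_bulk_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("bulk CSV must have `sample_id` as its first column")
  B <- as.matrix(df[, -1L, drop = FALSE])
  rownames(B) <- df$sample_id
  structure(list(sample_ids = df$sample_id, cpg_ids = colnames(B), values = B),
            class = "bulk_methylation")
}

#' @param bulk a `bulk_methylation`.
#' @rdname placomp_io
#' @export
write_bulk_matrix <- function(bulk, path) {
  df <- data.frame(sample_id = bulk$sample_ids, bulk$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname placomp_io
#' @export
read_composition <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("composition CSV must have `sample_id` as its first column")
  W <- as.matrix(df[, -1L, drop = FALSE])
  rownames(W) <- df$sample_id
  structure(list(sample_ids = df$sample_id, cell_types = colnames(W),
                 values = W),
            class = "cell_composition")
}

#' @param comp a `cell_composition`.
#' @rdname placomp_io
#' @export
write_composition <- function(comp, path) {
  df <- data.frame(sample_id = comp$sample_ids, comp$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a complete simulated dataset to a directory
#'
#' Writes `panel.csv`, `cohort.csv`, `bulk.csv`, `truth_compositions.csv`
#' (sample x cell-type true mixing weights), `truth_gamma.csv` (injected
#' ilr-scale effects) and a `params.json` sidecar recording the seed and all
#' generator parameters, so a simulation can be reloaded and re-analysed
#' exactly.
#'
#' @param sim a [generate_cohort()] result (list with `cohort`, `truth`).
#' @param panel the [generate_reference_panel()] used for mixing.
#' @param bulk the [mix_bulk()] output.
#' @param dir output directory (created if needed).
#' @param params optional named list of generator parameters to record.
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, panel, bulk, dir, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reference_panel(panel, file.path(dir, "panel.csv"))
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  write_bulk_matrix(bulk, file.path(dir, "bulk.csv"))
  truth_df <- data.frame(sample_id = rownames(sim$truth$compositions),
                         sim$truth$compositions, check.names = FALSE)
  utils::write.csv(truth_df, file.path(dir, "truth_compositions.csv"),
                   row.names = FALSE)
  gamma_df <- data.frame(predictor = rownames(sim$truth$gamma),
                         sim$truth$gamma, check.names = FALSE)
  utils::write.csv(gamma_df, file.path(dir, "truth_gamma.csv"),
                   row.names = FALSE)
  sidecar <- c(list(seed = sim$truth$seed, noise_sd = sim$truth$noise_sd,
                    composition_noise_sd = sim$truth$composition_noise_sd,
                    n = nrow(sim$cohort),
                    cell_types = sim$truth$cell_types),
               params)
  jsonlite::write_json(sidecar, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Stacked-bar plot of per-sample cell-type composition
#'
#' Each participant is one bar, sorted by decreasing proportion of the first
#' (most abundant) cell type.
#'
#' @param comp a `cell_composition` or composition matrix.
#' @param sort_by cell type to sort bars by (default the first column).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted matrix.
#' @export
plot_composition <- function(comp, sort_by = NULL, ...) {
  W <- if (inherits(comp, "cell_composition")) comp$values else as.matrix(comp)
  if (is.null(sort_by)) sort_by <- colnames(W)[1L]
  W <- W[order(W[, sort_by], decreasing = TRUE), , drop = FALSE]
  cols <- grDevices::hcl.colors(ncol(W), "Spectral")
  graphics::barplot(t(W), col = cols, border = NA, space = 0,
                    names.arg = rep("", nrow(W)),
                    ylab = "proportion", xlab = "participants", ...)
  graphics::legend("topright", legend = colnames(W), fill = cols,
                   bg = "white", cex = 0.7)
  invisible(W)
}
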