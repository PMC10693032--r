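#' The six placental cell types
#'
#' Order used throughout: syncytiotrophoblast, trophoblasts, stromal,
#' endothelial, Hofbauer (placental macrophages), nRBC (nucleated red blood
#' cells).
#'
#' @return character vector of length 6.
#' @export
placental_cell_types <- function() {
  c("syncytiotrophoblast", "trophoblasts", "stromal",
    "endothelial", "hofbauer", "nrbc")
}

#' Default sex-specific baseline compositions
#'
#' Mean cell-type proportions by infant sex in a 226-pair pregnancy cohort
#' (female: 0.623/0.099/0.129/0.102/0.010/0.036; male:
#' 0.644/0.084/0.125/0.096/0.014/0.036), closed to sum exactly one.
#'
#' @return named list with elements `female` and `male`, each a named
#'   6-part composition.
#' @export
default_baseline_composition <- function() {
  ct <- placental_cell_types()
  f <- c(0.623, 0.099, 0.129, 0.102, 0.010, 0.036)
  m <- c(0.644, 0.084, 0.125, 0.096, 0.014, 0.036)
  list(female = stats::setNames(f / sum(f), ct),
       male   = stats::setNames(m / sum(m), ct))
}

#' Generate a synthetic methylation reference panel
#'
#' Builds a marker-based CpG x cell-type beta-value panel: each cell type gets
#' `markers_per_type` marker CpGs that are hypermethylated (beta ~ 0.5 +
#' contrast/2) in that type and hypomethylated (beta ~ 0.5 - contrast/2) in
#' all others, plus small seeded Gaussian jitter, clipped to [0,1]. The
#' resulting matrix has full column rank. It stands in for a published sorted
#' placental-cell reference; it is synthetic and makes no claim about real
#' CpG coordinates.
#'
#' @param K number of cell types (>= 2).
#' @param markers_per_type marker CpGs per cell type (>= 1).
#' @param contrast beta-value separation between on- and off-target cells, in
#'   (0, 1]. `contrast = 1` with `jitter_sd = 0` gives a 0/1 design.
#' @param jitter_sd SD of Gaussian jitter added to each entry (default 0.03).
#' @param seed integer RNG seed.
#' @param cell_types optional type names (default the six placental types for
#'   K = 6, otherwise `cell1, cell2, ...`).
#' @return object of class `reference_panel`: list with `cpg_ids`,
#'   `cell_types` and the L x K `values` matrix.
#' @examples
#' p <- generate_reference_panel(K = 6, markers_per_type = 100,
#'                               contrast = 0.6, seed = 7)
#' qr(p$values)$rank  # 6
#' @export
generate_reference_panel <- function(K = 6L, markers_per_type = 100L,
                                     contrast = 0.6, jitter_sd = 0.03,
                                     seed = 1L, cell_types = NULL) {
  if (!is.numeric(K) || K < 2L) stop("`K` must be a count >= 2")
  if (!is.numeric(markers_per_type) || markers_per_type < 1L)
    stop("`markers_per_type` must be a count >= 1")
  if (!is.numeric(contrast) || contrast <= 0 || contrast > 1)
    stop("`contrast` must lie in (0, 1]")
  K <- as.integer(K); m <- as.integer(markers_per_type)
  if (is.null(cell_types))
    cell_types <- if (K == 6L) placental_cell_types() else paste0("cell", seq_len(K))
  L <- K * m
  hi <- 0.5 + contrast / 2
  lo <- 0.5 - contrast / 2
  R <- matrix(lo, L, K)
  for (j in seq_len(K)) R[((j - 1L) * m + 1L):(j * m), j] <- hi
  if (jitter_sd > 0) {
    set.seed(as.integer(seed))
    R <- R + matrix(stats::rnorm(L * K, 0, jitter_sd), L, K)
    R <- pmin(pmax(R, 0), 1)
  }
  cpg_ids <- sprintf("cg%06d", seq_len(L))
  dimnames(R) <- list(cpg_ids, cell_types)
  if (qr(R)$rank < K)
    stop("generated panel is rank deficient; increase contrast or markers_per_type")
  structure(list(cpg_ids = cpg_ids, cell_types = cell_types, values = R),
            class = "reference_panel")
}

# Predictors that generate_cohort() knows how to inject effects for.
cohort_effect_predictors <- function() {
  c("pm25_t1", "pm25_t2", "pm25_t3", "sex_male", "maternal_age",
    "gestational_age")
}

#' Generate a synthetic pregnancy cohort with known compositional truth
#'
#' Draws phenotypes, trimester-average PM2.5 exposures and true cell-type
#' compositions for `n` mother-infant pairs. Defaults emulate the descriptive
#' statistics of a 226-pair urban pregnancy cohort: exposures with means
#' (8.25, 8.24, 8.56) ug/m3 and SDs (1.36, 1.34, 1.77), cross-trimester
#' correlation 0.4, sex-specific baseline compositions, and categorical
#' covariate frequencies near the cohort's.
#'
#' Each sample's true composition is
#' `ilr_inverse(ilr(baseline_sex) + t(Gamma) %*% x + eps)`, where `x` holds
#' the effect predictors (exposures on the IQR-standardized scale, so each
#' `Gamma` row is a per-IQR ilr-scale effect), and `eps` is Gaussian with SD
#' `composition_noise_sd` per ilr coordinate. With an empty `effect_spec` and
#' zero noise every sample sits exactly at its sex's baseline.
#'
#' @param n cohort size (>= 1).
#' @param sex_ratio probability of a female infant (default 101/226).
#' @param baseline_composition list with strictly positive unit-sum
#'   compositions `female` and `male` (default [default_baseline_composition()]).
#' @param effect_spec named list mapping predictor names (subset of
#'   `pm25_t1/t2/t3`, `sex_male`, `maternal_age`, `gestational_age`) to
#'   (K-1)-vectors of ilr-scale effects. Exposure predictors are
#'   IQR-standardized and continuous covariates mean-centred before the
#'   effect is applied. A `:female` or `:male` suffix (e.g. `pm25_t1:male`)
#'   restricts the effect to that sex stratum.
#' @param exposure_means,exposure_sds length-3 trimester PM2.5 means and SDs
#'   (ug/m3); draws are truncated at zero.
#' @param exposure_cor cross-trimester exposure correlation (default 0.4).
#' @param composition_noise_sd SD of the per-coordinate ilr noise
#'   (default 0.25, which reproduces cohort-scale proportion SDs, e.g.
#'   syncytiotrophoblast SD ~ 0.065).
#' @param noise_sd beta-value noise SD recorded in the truth container and
#'   used by [mix_bulk()] (default 0.02).
#' @param seed integer RNG seed.
#' @return list with `cohort` (data.frame: sample_id, sex, maternal_age,
#'   race_ethnicity, gestational_age, season_of_birth, preeclampsia,
#'   eclampsia, pm25_t1..t3) and `truth` (class `ground_truth`: `compositions`
#'   N x K, `gamma` P x (K-1), `seed`, `noise_sd`, `composition_noise_sd`).
#' @export
generate_cohort <- function(n,
                            sex_ratio = 101 / 226,
                            baseline_composition = default_baseline_composition(),
                            effect_spec = list(),
                            exposure_means = c(8.25, 8.24, 8.56),
                            exposure_sds = c(1.36, 1.34, 1.77),
                            exposure_cor = 0.4,
                            composition_noise_sd = 0.25,
                            noise_sd = 0.02,
                            seed = 1L) {
  if (!is.numeric(n) || n < 1L) stop("`n` must be a count >= 1")
  n <- as.integer(n)
  for (s in c("female", "male")) {
    b <- baseline_composition[[s]]
    if (is.null(b) || any(b <= 0) || abs(sum(b) - 1) > 1e-8)
      stop("baseline composition for `", s,
           "` must be strictly positive and sum to 1")
  }
  K <- length(baseline_composition$female)
  ct <- names(baseline_composition$female)
  if (is.null(ct)) ct <- if (K == 6L) placental_cell_types() else paste0("cell", seq_len(K))
  known <- cohort_effect_predictors()
  if (length(effect_spec)) {
    for (key in names(effect_spec)) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
      if (!(parts[1L] %in% known) ||
          (length(parts) == 2L && !parts[2L] %in% c("female", "male")) ||
          length(parts) > 2L)
        stop("unknown effect predictor `", key, "`; use one of ",
             paste(known, collapse = ", "),
             ", optionally suffixed `:female` or `:male` for a sex-specific effect")
    }
    if (any(vapply(effect_spec, length, 1L) != K - 1L))
      stop("each effect must be a (K-1)-vector (K-1 = ", K - 1L, ")")
  }

  set.seed(as.integer(seed))
  sex <- ifelse(stats::runif(n) < sex_ratio, "female", "male")
  maternal_age <- stats::rnorm(n, 30.57, 5.59)
  race <- sample(c("White", "Black", "Hispanic", "Other"), n, replace = TRUE,
                 prob = c(0.3186, 0.4027, 0.2035, 0.0619))
  season <- sample(c("Spring", "Summer", "Fall", "Winter"), n, replace = TRUE,
                   prob = c(0.2611, 0.2389, 0.2301, 0.2699))
  gestational_age <- stats::rnorm(n, 38.96, 1.50)
  while (any(out <- gestational_age <= 20 | gestational_age >= 45))
    gestational_age[out] <- stats::rnorm(sum(out), 38.96, 1.50)
  preeclampsia <- stats::runif(n) < 15 / 226
  eclampsia <- stats::runif(n) < 2 / 226

  # correlated, zero-truncated trimester exposures
  S <- matrix(exposure_cor, 3, 3); diag(S) <- 1
  cholS <- chol(S)
  draw_expo <- function(m) {
    z <- matrix(stats::rnorm(m * 3), m, 3) %*% cholS
    sweep(sweep(z, 2, exposure_sds, "*"), 2, exposure_means, "+")
  }
  pm <- draw_expo(n)
  while (any(neg <- apply(pm <= 0, 1L, any)))
    pm[neg, ] <- draw_expo(sum(neg))
  colnames(pm) <- c("pm25_t1", "pm25_t2", "pm25_t3")

  # effect design: standardized exposures, centred covariates
  xcols <- list(
    pm25_t1 = as.numeric(iqr_standardize(pm[, 1L])),
    pm25_t2 = as.numeric(iqr_standardize(pm[, 2L])),
    pm25_t3 = as.numeric(iqr_standardize(pm[, 3L])),
    sex_male = as.numeric(sex == "male"),
    maternal_age = maternal_age - mean(maternal_age),
    gestational_age = gestational_age - mean(gestational_age)
  )
  predictors <- union(known, names(effect_spec))
  gamma <- matrix(0, length(predictors), K - 1L,
                  dimnames = list(predictors, paste0("ilr", seq_len(K - 1L))))
  for (nm in names(effect_spec)) gamma[nm, ] <- effect_spec[[nm]]
  # sex-specific keys multiply the base predictor by the sex indicator
  for (nm in setdiff(predictors, known)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    xcols[[nm]] <- xcols[[parts[1L]]] * as.numeric(sex == parts[2L])
  }

  basis <- ilr_basis(ct)
  z0 <- rbind(female = as.numeric(ilr_transform(baseline_composition$female, basis)),
              male   = as.numeric(ilr_transform(baseline_composition$male, basis)))
  coords <- z0[sex, , drop = FALSE]
  if (length(effect_spec)) {
    X <- do.call(cbind, xcols[predictors])
    coords <- coords + X %*% gamma
  }
  if (composition_noise_sd > 0)
    coords <- coords + matrix(stats::rnorm(n * (K - 1L), 0, composition_noise_sd),
                              n, K - 1L)
  W <- ilr_inverse(coords, basis)

  sample_id <- sprintf("S%04d", seq_len(n))
  rownames(W) <- sample_id
  cohort <- data.frame(sample_id = sample_id, sex = sex,
                       maternal_age = maternal_age, race_ethnicity = race,
                       gestational_age = gestational_age,
                       season_of_birth = season,
                       preeclampsia = preeclampsia, eclampsia = eclampsia,
                       pm, stringsAsFactors = FALSE)
  truth <- structure(list(compositions = W, gamma = gamma,
                          seed = as.integer(seed), noise_sd = noise_sd,
                          composition_noise_sd = composition_noise_sd,
                          cell_types = ct),
                     class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Mix bulk methylation profiles from a panel and true compositions
#'
#' Forward model for deconvolution testing: bulk beta values
#' `B = W %*% t(R)` plus independent Gaussian noise with SD `truth$noise_sd`,
#' clipped to [0, 1].
#'
#' @param panel a [generate_reference_panel()] object (or any
#'   `reference_panel`).
#' @param truth a `ground_truth` object whose compositions have one column per
#'   panel cell type.
#' @param seed RNG seed for the noise (default derived from `truth$seed`).
#' @return object of class `bulk_methylation`: list with `sample_ids`,
#'   `cpg_ids` and the N x L `values` matrix.
#' @export
mix_bulk <- function(panel, truth, seed = truth$seed + 10007L) {
  stopifnot(inherits(panel, "reference_panel"))
  W <- truth$compositions
  if (ncol(W) != ncol(panel$values))
    stop("truth has ", ncol(W), " cell types but panel has ", ncol(panel$values))
  B <- W %*% t(panel$values)
  if (truth$noise_sd > 0) {
    set.seed(as.integer(seed))
    B <- B + matrix(stats::rnorm(length(B), 0, truth$noise_sd),
                    nrow(B), ncol(B))
  }
  B <- pmin(pmax(B, 0), 1)
  dimnames(B) <- list(rownames(W), panel$cpg_ids)
  structure(list(sample_ids = rownames(W), cpg_ids = panel$cpg_ids,
                 values = B),
            class = "bulk_methylation")
}
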