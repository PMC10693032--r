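# Shared fixtures and independent oracles, built in code at test time.

# Exhaustive grid search over the unit simplex (step `step`) minimizing
# ||b - R w||^2 -- the brute-force oracle for the constrained projection.
grid_search_simplex <- function(R, b, step = 1e-3) {
  K <- ncol(R)
  s <- seq(0, 1, by = step)
  if (K == 2L) {
    W <- cbind(s, 1 - s)
  } else if (K == 3L) {
    W <- as.matrix(expand.grid(w1 = s, w2 = s))
    W <- W[rowSums(W) <= 1 + 1e-12, , drop = FALSE]
    W <- cbind(W, 1 - rowSums(W))
  } else {
    stop("grid oracle implemented for K <= 3")
  }
  D <- crossprod(R)
  d <- drop(crossprod(R, b))
  obj <- rowSums((W %*% D) * W) - 2 * drop(W %*% d)
  W[which.min(obj), ]
}

# Uniform random points strictly inside the simplex.
runif_simplex <- function(n, K) {
  x <- matrix(stats::rexp(n * K), n, K)
  x / rowSums(x)
}

# Independent linear-interpolation quantile (the type-7 convention),
# written from the definition rather than via stats::quantile.
interp_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# Cohort where the male stratum duplicates the female stratum exactly.
mirrored_cohort <- function() {
  half <- data.frame(
    sample_id = sprintf("F%02d", 1:12),
    maternal_age = rep(c(25, 30, 35), 4),
    gestational_age = rep(c(38, 39, 40, 41), 3),
    race_ethnicity = rep(c("White", "Black", "Hispanic", "Other"), 3),
    season_of_birth = rep(c("Spring", "Summer", "Fall", "Winter"), 3),
    preeclampsia = rep(c(TRUE, FALSE, FALSE), 4),
    eclampsia = rep(c(TRUE, FALSE, FALSE), 4),
    pm25_t1 = rep(c(7, 8, 9, 10), 3),
    pm25_t2 = rep(c(6, 8, 10), 4),
    pm25_t3 = rep(c(7.5, 8.5, 9.5, 10.5), 3),
    stringsAsFactors = FALSE
  )
  male <- half
  male$sample_id <- sprintf("M%02d", 1:12)
  rbind(cbind(half, sex = "female", stringsAsFactors = FALSE),
        cbind(male, sex = "male", stringsAsFactors = FALSE))
}
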