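# shared fixtures and independent brute-force oracles

full_mask <- function(img) roi_mask(matrix(TRUE, nrow(img$values), ncol(img$values)))

# small isotropic GRF reused across tests (cached per session)
.fixture_env <- new.env()
small_grf <- function(seed = 9, n = 256, corr_len = 0.5, sigma_phi = 0.4) {
  key <- sprintf("grf_%d_%d_%g_%g", seed, n, corr_len, sigma_phi)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- gen_grf_phase(texture_spec(
      shape = c(n, n), pixel_size = 0.05, sigma_phi = sigma_phi,
      corr_len = corr_len, seed = seed))
  .fixture_env[[key]]
}

# exhaustive concordant-pair AUC (positive class scores LOW here, like g)
brute_force_auc_low_positive <- function(is_pos, g) {
  pos <- g[is_pos]; neg <- g[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p < q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive Youden search over a dense threshold sweep
brute_force_youden <- function(is_pos, g) {
  cand <- sort(unique(c(g - 1e-9, g + 1e-9, min(g) - 1, max(g) + 1)))
  best_j <- -Inf; best_t <- NA
  for (t in cand) {
    sens <- mean(g[is_pos] < t); spec <- mean(g[!is_pos] >= t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_t <- t }
  }
  list(j = best_j, threshold = best_t)
}

expect_parameter_error <- function(expr)
  expect_error(expr, class = "qpianiso_error_parameter")
expect_data_error <- function(expr)
  expect_error(expr, class = "qpianiso_error_data")
expect_stat_error <- function(expr)
  expect_error(expr, class = "qpianiso_error_stat")
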