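# shared fixture builders; everything is generated in code at test time

centered_grid <- function(n = 16L, vox = 3) {
  half <- (n - 1) / 2 * vox
  make_grid(rep(n, 3L), vox, origin_mm = rep(-half, 3))
}

# minimal stimulation table straight from vectors
toy_records <- function(subject, x, y, z, ...) {
  beh <- list(...)
  df <- data.frame(subject_id = as.character(subject), x_mm = x, y_mm = y,
                   z_mm = z, stringsAsFactors = FALSE)
  for (b in names(beh)) df[[b]] <- as.integer(beh[[b]])
  as_stim_table(df, names(beh))
}

# compound-symmetric noise: n rows in subject blocks, V voxels, correlation rho
cs_noise <- function(blocks, V, rho, sd = 1) {
  n <- sum(lengths(blocks))
  E <- matrix(rnorm(n * V, 0, sd * sqrt(1 - rho)), n, V)
  for (rows in blocks)
    E[rows, ] <- E[rows, ] +
      matrix(rnorm(V, 0, sd * sqrt(rho)), length(rows), V, byrow = TRUE)
  E
}

# brute-force generalised least squares t statistic for a single voxel
gls_oracle_t <- function(X, y, V, contrast) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  df <- nrow(X) - qr(X)$rank
  sigma2 <- drop(t(r) %*% Vi %*% r) / df
  se <- sqrt(sigma2 * drop(t(contrast) %*% solve(XtVi %*% X) %*% contrast))
  drop(t(contrast) %*% beta) / se
}

# Mann-Whitney AUC: mean over (pos, neg) pairs of 1[w1 > w0] + 0.5 * 1[w1 == w0]
mw_auc <- function(weights, labels) {
  w1 <- weights[labels == 1]; w0 <- weights[labels == 0]
  cmp <- outer(w1, w0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# two-sided Fisher p by explicit enumeration over tables with fixed margins
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  prob <- vapply(support, function(ai)
    choose(m, ai) * choose(n2, k - ai) / choose(m + n2, k), 1)
  p_obs <- prob[match(a, support)]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

world_of_peak <- function(t_map) {
  peak <- which.max(t_map$values)
  grid_world(t_map$grid, dysmap:::linear_vox(t_map$grid, peak))
}
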