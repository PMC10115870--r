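test_that("design matrices carry subject indicators, rank and df", {
  # reference-sized cohort: 477 rows over 37 subjects -> rank 38, df 439
  cfg <- synthetic_config(n_subjects = 37, loci_per_subject = c(8, 18),
                          total_loci = 477, seed = 2)
  coh <- generate_cohort(cfg)
  d <- build_design(coh$records, "positive_motor")
  expect_identical(nrow(d$X), 477L)
  expect_identical(d$rank, 38L)
  expect_identical(d$df, 439L)
  expect_true(all(rowSums(d$X[, -d$behaviour_col]) == 1))

  rec <- toy_records(c("A", "A", "B", "B"), 1:4, 0, 0, beh = c(1, 0, 1, 0))
  d2 <- build_design(rec, "beh")
  expect_identical(d2$rank, 3L)
  expect_identical(d2$df, 1L)

  rec1 <- toy_records(c("A", "A", "B"), 1:3, 0, 0, beh = c(1, 1, 1))
  expect_error(build_design(rec1, "beh"), "degenerate")
  expect_error(build_design(rec, "nope"), "not present")
})

test_that("non-sphericity estimation recovers compound-symmetry rho", {
  blocks <- split(1:200, rep(1:20, each = 10))
  rec <- toy_records(rep(sprintf("S%02d", 1:20), each = 10), 0, 0, 0,
                     beh = rep_len(c(1, 0), 200))
  d <- build_design(rec, "beh")

  set.seed(21)
  ns0 <- estimate_nonsphericity(cs_noise(blocks, 30, 0), d)
  expect_lt(abs(ns0$rho), 0.05)

  # true rho 0.5, 40 subjects x 10 rows, 20 replicates
  blocks40 <- split(1:400, rep(1:40, each = 10))
  rec40 <- toy_records(rep(sprintf("S%02d", 1:40), each = 10), 0, 0, 0,
                       beh = rep_len(c(1, 0), 400))
  d40 <- build_design(rec40, "beh")
  set.seed(22)
  rhos <- replicate(20, estimate_nonsphericity(
    cs_noise(blocks40, 20, 0.5), d40)$rho)
  expect_lt(abs(mean(rhos) - 0.5), 0.1)
  expect_true(all(abs(rhos - 0.5) < 0.15))

  # rho = 0: whitening is the identity and GLS equals OLS exactly
  ns_id <- dysmap:::new_nonsphericity(0, d$subject_blocks, 200)
  M <- matrix(rnorm(400), 200)
  expect_identical(whiten(ns_id, M), M)

  # whitening makes V-distributed noise white: W V W' = I
  ns5 <- dysmap:::new_nonsphericity(0.5, d$subject_blocks, 200)
  V <- dysmap:::nonsphericity_V(ns5)
  W <- whiten(ns5, diag(200))
  expect_equal(W %*% V %*% t(W), diag(200), tolerance = 1e-10)

  # all-singleton blocks: rho 0 with a notice (such a design has no residual
  # df, so the estimator is exercised on a bare design list)
  d_s <- list(X = cbind(diag(4), c(1, 0, 1, 0)),
              subject_blocks = as.list(1:4), behaviour_col = 5L)
  expect_message(
    ns_s <- estimate_nonsphericity(matrix(rnorm(40), 4), d_s), "singleton")
  expect_identical(ns_s$rho, 0)
})

test_that("GLM fit matches lm on a hand-sized example and scales correctly", {
  rec <- toy_records(c("A", "A", "A", "B", "B", "B"), 1:6, 0, 0,
                     beh = c(1, 0, 0, 1, 1, 0))
  d <- build_design(rec, "beh")
  set.seed(31)
  y <- rnorm(6)
  fit <- fit_glm(matrix(y, 6, 1), d)
  lmfit <- lm(y ~ 0 + d$X)
  expect_equal(drop(fit$beta), unname(coef(lmfit)), tolerance = 1e-10)
  tt <- t_contrast(fit)
  expect_equal(tt[1], unname(summary(lmfit)$coefficients["d$Xbeh", "t value"]),
               tolerance = 1e-10)

  # t is invariant to positive scaling of Y
  fit2 <- fit_glm(matrix(3.7 * y, 6, 1), d)
  expect_equal(t_contrast(fit2)[1], tt[1], tolerance = 1e-10)

  # sign-flipped behaviour coding negates the t map
  rec_f <- rec; rec_f$beh <- 1L - rec_f$beh
  fit_f <- fit_glm(matrix(y, 6, 1), build_design(rec_f, "beh"))
  expect_equal(t_contrast(fit_f)[1], -tt[1], tolerance = 1e-10)

  # exact fit: zero residual variance is flagged and t set to 0
  y_exact <- d$X %*% c(1, 2, 3)
  fit_e <- fit_glm(matrix(y_exact, 6, 1), d)
  expect_lt(fit_e$sigma2[1], 1e-20)
  expect_message(t_e <- t_contrast(fit_e), "zero-variance")
  expect_identical(t_e[1], 0)

  expect_error(t_contrast(fit, rep(0, ncol(d$X))), "zeros")
})

test_that("whitened fit equals brute-force GLS on small instances", {
  set.seed(41)
  for (rep in 1:20) {
    sizes <- sample(1:3, 3, TRUE)
    subj <- rep(c("A", "B", "C"), sizes)
    n <- length(subj)
    beh <- rbinom(n, 1, 0.5)
    if (length(unique(beh)) < 2) next
    rec <- toy_records(subj, seq_len(n), 0, 0, beh = beh)
    d <- tryCatch(build_design(rec, "beh"), error = function(e) NULL)
    if (is.null(d) || d$df < 1 || qr(d$X)$rank < ncol(d$X)) next
    rho <- runif(1, -0.2, 0.8)
    ns <- dysmap:::new_nonsphericity(rho, d$subject_blocks, n)
    y <- rnorm(n)
    fit <- fit_glm(matrix(y, n, 1), d, ns)
    t_pkg <- t_contrast(fit)[1]
    cvec <- c(rep(0, ncol(d$X) - 1), 1)
    t_or <- gls_oracle_t(d$X, y, dysmap:::nonsphericity_V(ns), cvec)
    expect_equal(t_pkg, t_or, tolerance = 1e-8)
    expect_identical(fit$df, n - qr(d$X)$rank)  # df untouched by whitening
  }
})

test_that("null t statistics follow Student-t(df)", {
  rec <- toy_records(rep(sprintf("S%d", 1:10), each = 8), 0, 0, 0,
                     beh = rep_len(c(1, 1, 0, 0), 80))
  d <- build_design(rec, "beh")
  set.seed(51)
  Y <- matrix(rnorm(80 * 2000), 80)
  tt <- t_contrast(fit_glm(Y, d))
  ks <- stats::ks.test(stats::pt(tt, df = d$df), "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("uncorrected critical t reproduces the printed display threshold", {
  expect_equal(round(critical_t_uncorrected(0.001, 439), 2), 3.11)
  expect_equal(critical_t_uncorrected(0.5, 439), 0)
  expect_equal(critical_t_uncorrected(0.05, 10), 1.812, tolerance = 5e-4)

  # strictly decreasing in p; decreasing in df toward the normal quantile
  ps <- c(0.0005, 0.001, 0.01, 0.05, 0.2)
  expect_true(all(diff(vapply(ps, critical_t_uncorrected, 1, df = 30)) < 0))
  dfs <- c(5, 10, 50, 500, 5000)
  tq <- vapply(dfs, function(d) critical_t_uncorrected(0.01, d), 1)
  expect_true(all(diff(tq) < 0))
  expect_gt(min(tq), stats::qnorm(0.99))
})

test_that("permutation maxT matches exhaustive enumeration on a toy", {
  rec <- toy_records(rep(c("A", "B"), each = 3), 1:6, 0, 0,
                     beh = c(1, 0, 0, 1, 1, 0))
  d <- build_design(rec, "beh")
  set.seed(61)
  Y <- matrix(rnorm(6 * 12), 6)
  alpha <- 0.1  # 9 distinct arrangements < 1/alpha -> exact enumeration
  expect_warning(
    thr <- fwe_threshold_maxT(Y, d, mask = rep(1, 12), alpha = alpha,
                              n_perm = 500),
    "enumeration")
  expect_identical(thr$method, "perm_maxT_exact")
  expect_identical(thr$n_perm, 9L)

  # oracle: refit the full GLM for every arrangement and take max t
  arr <- expand.grid(a = 1:3, b = 1:3)
  combos_a <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  combos_b <- list(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  maxT_or <- apply(arr, 1, function(r) {
    rec_p <- rec
    rec_p$beh <- as.integer(c(combos_a[[r[1]]], combos_b[[r[2]]]))
    suppressMessages(
      max(t_contrast(fit_glm(Y, build_design(rec_p, "beh")))))
  })
  expect_equal(sort(thr$maxT), sort(maxT_or), tolerance = 1e-8)
  k <- ceiling((1 - alpha) * 9)
  expect_equal(thr$critical_t, sort(maxT_or)[k], tolerance = 1e-8)

  # alpha = 1 boundary: critical t is the minimum of the maxT distribution
  thr1 <- suppressWarnings(
    fwe_threshold_maxT(Y, d, mask = rep(1, 12), alpha = 1, n_perm = 500))
  expect_equal(thr1$critical_t, min(maxT_or), tolerance = 1e-8)
})

test_that("cluster extraction finds 26-connected components", {
  g <- centered_grid(10, 2)
  sig <- numeric(1000); tval <- numeric(1000)
  blob1 <- dysmap:::vox_linear(g, rbind(c(1, 1, 1), c(2, 2, 2), c(2, 1, 1)))
  blob2 <- dysmap:::vox_linear(g, rbind(c(7, 7, 7), c(7, 7, 8)))
  sig[c(blob1, blob2)] <- 1
  tval[blob1] <- c(3, 5, 4); tval[blob2] <- c(6, 2)
  cl <- extract_clusters(new_volume(g, sig), new_volume(g, tval))
  expect_identical(nrow(cl), 2L)
  expect_equal(cl$extent_voxels, c(2L, 3L))       # sorted by peak t desc
  expect_equal(cl$peak_t, c(6, 5))
  expect_equal(sum(cl$extent_voxels), sum(sig))
  expect_equal(c(cl$peak_x_mm[2], cl$peak_y_mm[2], cl$peak_z_mm[2]),
               unname(grid_world(g, c(2, 2, 2))))

  one <- numeric(1000); one[dysmap:::vox_linear(g, c(5, 5, 5))] <- 1
  cl1 <- extract_clusters(new_volume(g, one), new_volume(g, one * 4))
  expect_identical(cl1$extent_voxels, 1L)

  cl0 <- extract_clusters(new_volume(g, 0), new_volume(g, 0))
  expect_identical(nrow(cl0), 0L)
})

test_that("df is invariant to whitening across random designs", {
  set.seed(71)
  for (i in 1:50) {
    ns_subj <- sample(3:6, 1)
    sizes <- sample(2:5, ns_subj, TRUE)
    subj <- rep(sprintf("S%d", seq_len(ns_subj)), sizes)
    beh <- rbinom(length(subj), 1, 0.5)
    if (length(unique(beh)) < 2) next
    rec <- toy_records(subj, seq_along(subj), 0, 0, beh = beh)
    d <- build_design(rec, "beh")
    rho <- runif(1, 0, 0.7)
    ns <- dysmap:::new_nonsphericity(rho, d$subject_blocks, length(subj))
    fit_w <- fit_glm(matrix(rnorm(length(subj) * 3), length(subj)), d, ns)
    expect_identical(fit_w$df, d$df)
    expect_identical(fit_w$rank, d$rank)
  }
})
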