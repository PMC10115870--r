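#' Repeated-measures voxel-wise GLM
#'
#' A single-level repeated-measures design: per-subject indicator columns
#' absorb subject mean differences, and one binary behaviour regressor carries
#' the effect of interest. The dependent variable is the per-voxel density (or
#' connectivity) value, fit independently at every in-mask voxel. Residual
#' non-sphericity from within-subject correlation is modelled as compound
#' symmetry with a single pooled correlation and removed by prewhitening,
#' which leaves the residual degrees of freedom unchanged. Inference is a
#' planned one-tailed t contrast on the behaviour column, with peak-level
#' family-wise error control by within-subject permutation of the behaviour
#' labels (maxT).
#'
#' @name glm_inference
NULL

#' Build the repeated-measures design matrix
#'
#' @param records a `stim_table`.
#' @param behaviour name of the behaviour column to model.
#' @return a `dys_design`: `X` (one indicator column per subject plus the
#'   binary behaviour column), `subject_blocks` (row-index list per subject),
#'   `behaviour_col`, `behaviour`, `rank`, `df`.
#' @export
build_design <- function(records, behaviour) {
  stopifnot(inherits(records, "stim_table"))
  if (!behaviour %in% names(records))
    stop("behaviour '", behaviour, "' not present in records", call. = FALSE)
  subj <- as.character(records$subject_id)
  subjects <- sort(unique(subj))
  if (length(subjects) < 2L)
    stop("need >= 2 subjects for a repeated-measures design", call. = FALSE)
  b <- as.numeric(records[[behaviour]])
  if (length(unique(b)) < 2L)
    stop("degenerate design: behaviour '", behaviour,
         "' is constant across all records", call. = FALSE)
  n <- nrow(records)
  X <- matrix(0, n, length(subjects) + 1L,
              dimnames = list(NULL, c(subjects, behaviour)))
  X[cbind(seq_len(n), match(subj, subjects))] <- 1
  X[, length(subjects) + 1L] <- b
  r <- qr(X)$rank
  if (n - r <= 0L)
    stop("degenerate design: residual degrees of freedom <= 0", call. = FALSE)
  structure(
    list(X = X,
         subject_blocks = split(seq_len(n), factor(subj, levels = subjects)),
         behaviour_col = ncol(X), behaviour = behaviour,
         rank = r, df = n - r),
    class = "dys_design")
}

#' @export
print.dys_design <- function(x, ...) {
  cat(sprintf("<dys_design> %d rows, %d subjects + '%s', rank %d, df %d\n",
              nrow(x$X), length(x$subject_blocks), x$behaviour, x$rank, x$df))
  invisible(x)
}

#' Estimate within-subject non-sphericity (compound symmetry)
#'
#' A single correlation `rho`, pooled across voxels, is estimated from OLS
#' residuals of a reduced model holding a global intercept plus the
#' non-subject regressors. The reduced model is deliberate: residuals of the
#' full design (which contains per-subject indicators) have within-block
#' correlation near -1/(m-1) whatever the true error correlation, because the
#' subject columns absorb the shared component; estimating against the
#' reduced model is the bias guard that keeps rho identifiable.
#'
#' @param Y numeric matrix, rows = stimulations, columns = voxels.
#' @param design a `dys_design`.
#' @param mask_idx optional column indices of `Y` to pool over.
#' @return a `dys_nonsphericity`: `rho` (clipped to the SPD-valid open range),
#'   `blocks`, `n`.
#' @export
estimate_nonsphericity <- function(Y, design, mask_idx = NULL) {
  blocks <- design$subject_blocks
  n <- nrow(design$X)
  stopifnot(nrow(Y) == n)
  sizes <- lengths(blocks)
  if (all(sizes < 2L)) {
    message("all subject blocks are singletons; rho set to 0")
    return(new_nonsphericity(0, blocks, n))
  }
  if (!is.null(mask_idx)) Y <- Y[, mask_idx, drop = FALSE]
  keep <- which(apply(Y, 2L, stats::sd) > 0)
  if (!length(keep)) return(new_nonsphericity(0, blocks, n))
  Y <- Y[, keep, drop = FALSE]

  Xr <- cbind(1, design$X[, design$behaviour_col])
  R <- stats::lm.fit(Xr, Y)$residuals
  if (is.null(dim(R))) R <- matrix(R, ncol = 1L)

  cov_sum <- 0; var_sum <- 0; n_pair <- 0; n_var <- 0
  for (rows in blocks) {
    m <- length(rows)
    if (m < 2L) next
    Rb <- R[rows, , drop = FALSE]
    s <- colSums(Rb)
    sq <- colSums(Rb^2)
    cov_sum <- cov_sum + sum((s^2 - sq) / 2)
    var_sum <- var_sum + sum(sq)
    n_pair <- n_pair + ncol(R) * m * (m - 1) / 2
    n_var <- n_var + ncol(R) * m
  }
  rho <- (cov_sum / n_pair) / (var_sum / n_var)
  m_max <- max(sizes)
  rho <- min(max(rho, -1 / (m_max - 1) + 1e-3), 1 - 1e-3)
  new_nonsphericity(rho, blocks, n)
}

new_nonsphericity <- function(rho, blocks, n) {
  structure(list(rho = rho, blocks = blocks, n = n),
            class = "dys_nonsphericity")
}

#' @export
print.dys_nonsphericity <- function(x, ...) {
  cat(sprintf("<dys_nonsphericity> compound symmetry, rho = %.4f over %d blocks\n",
              x$rho, length(x$blocks)))
  invisible(x)
}

#' Whitening transform W = V^{-1/2} applied to rows of a matrix
#'
#' V is block diagonal with unit-diagonal compound-symmetry blocks
#' (1 - rho) I + rho J; its inverse square root is a I + b J with
#' a = 1/sqrt(1 - rho) and b = (1/sqrt(1 + (m-1) rho) - a)/m, so the product
#' is applied in closed form per block.
#'
#' @param ns a `dys_nonsphericity`.
#' @param M numeric matrix (or vector) with `ns$n` rows.
#' @return whitened matrix of the same shape.
#' @export
whiten <- function(ns, M) {
  vec <- is.null(dim(M))
  if (vec) M <- matrix(M, ncol = 1L)
  stopifnot(nrow(M) == ns$n)
  rho <- ns$rho
  if (rho == 0) return(if (vec) drop(M) else M)
  out <- M
  a <- 1 / sqrt(1 - rho)
  for (rows in ns$blocks) {
    m <- length(rows)
    if (m == 1L) next
    b <- (1 / sqrt(1 + (m - 1) * rho) - a) / m
    blk <- M[rows, , drop = FALSE]
    out[rows, ] <- a * blk +
      matrix(b * colSums(blk), m, ncol(M), byrow = TRUE)
  }
  if (vec) drop(out) else out
}

## error covariance implied by a dys_nonsphericity (for oracles/tests)
nonsphericity_V <- function(ns) {
  V <- diag(ns$n)
  for (rows in ns$blocks)
    V[rows, rows] <- (1 - ns$rho) * diag(length(rows)) + ns$rho
  V
}

#' Fit the voxel-wise GLM
#'
#' Per voxel: beta = pinv(WX) W y; sigma2 = ||W y - W X beta||^2 / df with
#' df = n - rank(X), unchanged by whitening.
#'
#' @param Y rows-by-voxels response matrix (densities or connectivities).
#' @param design a `dys_design`.
#' @param ns a `dys_nonsphericity` (or `NULL` for OLS).
#' @param mask optional binary `vol_volume` or logical/0-1 vector over
#'   columns of `Y`; out-of-mask voxels are skipped.
#' @param grid optional `vol_grid` for rebuilding map volumes.
#' @return a `glm_fit`: `beta` (p x V_mask), `sigma2`, `df`, `rank`,
#'   `XtX_pinv`, `design`, `ns`, `mask_idx`, `grid`, `n_vox`.
#' @export
fit_glm <- function(Y, design, ns = NULL, mask = NULL, grid = NULL) {
  stopifnot(nrow(Y) == nrow(design$X))
  if (is.null(ns)) ns <- new_nonsphericity(0, design$subject_blocks, nrow(Y))
  if (inherits(mask, "vol_volume")) {
    if (is.null(grid)) grid <- mask$grid
    mask <- as.numeric(mask$values) != 0
  }
  mask_idx <- if (is.null(mask)) seq_len(ncol(Y)) else which(as.logical(mask))
  if (!length(mask_idx)) stop("mask is empty", call. = FALSE)

  Xw <- whiten(ns, design$X)
  Yw <- whiten(ns, Y[, mask_idx, drop = FALSE])
  sv <- svd(Xw)
  tol <- max(dim(Xw)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  r <- sum(pos)
  df <- nrow(Xw) - r
  ginv_d <- ifelse(pos, 1 / sv$d, 0)
  beta <- sv$v %*% (ginv_d * crossprod(sv$u, Yw))
  res <- Yw - Xw %*% beta
  sigma2 <- colSums(res^2) / df
  y_scale <- mean(Yw^2)
  XtX_pinv <- sv$v %*% (ginv_d^2 * t(sv$v))
  structure(
    list(beta = beta, sigma2 = sigma2, df = df, rank = r,
         XtX_pinv = XtX_pinv, XtX = crossprod(Xw), y_scale = y_scale,
         design = design, ns = ns, mask_idx = mask_idx,
         grid = grid, n_vox = ncol(Y)),
    class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d voxels, rank %d, df %d, rho %.3f\n",
              length(x$mask_idx), x$rank, x$df, x$ns$rho))
  invisible(x)
}

#' t contrast on a fitted GLM
#'
#' t = c' beta / sqrt(sigma2 * c' (X'X)^+ c) per voxel. Voxels with zero
#' residual variance get t = 0 (their count is reported via a message).
#'
#' @param fit a `glm_fit`.
#' @param contrast numeric vector of length ncol(X); default selects the
#'   behaviour column.
#' @return a `vol_volume` t map when the fit has a grid, else a numeric
#'   vector over all voxels (zero outside the mask).
#' @export
t_contrast <- function(fit, contrast = NULL) {
  p <- ncol(fit$design$X)
  if (is.null(contrast)) {
    contrast <- numeric(p); contrast[fit$design$behaviour_col] <- 1
  }
  stopifnot(length(contrast) == p)
  if (all(contrast == 0)) stop("contrast is all zeros", call. = FALSE)
  # estimability: c must lie in the row space of X
  proj <- fit$XtX_pinv %*% (fit$XtX %*% contrast)
  if (max(abs(proj - contrast)) > 1e-8 * max(1, max(abs(contrast))))
    stop("contrast is not estimable under this design", call. = FALSE)
  cvar <- drop(t(contrast) %*% fit$XtX_pinv %*% contrast)
  num <- drop(crossprod(contrast, fit$beta))
  ok <- fit$sigma2 > 1e-12 * max(fit$y_scale, 1e-300)
  tv <- numeric(length(num))
  tv[ok] <- num[ok] / sqrt(fit$sigma2[ok] * cvar)
  if (any(!ok))
    message(sum(!ok), " zero-variance voxel(s) set to t = 0")
  full <- numeric(fit$n_vox)
  full[fit$mask_idx] <- tv
  if (!is.null(fit$grid)) new_volume(fit$grid, full) else full
}

#' One-tailed uncorrected critical t
#'
#' Upper-tail Student-t quantile: the display threshold used for uncorrected
#' maps (p = 0.001 by default).
#'
#' @param p one-tailed p value in (0, 1).
#' @param df residual degrees of freedom.
#' @return critical t value.
#' @examples
#' critical_t_uncorrected(0.001, 439)  # 3.11
#' @export
critical_t_uncorrected <- function(p, df) {
  stopifnot(p > 0, p < 1, df > 0)
  stats::qt(1 - p, df = df)
}

#' Peak-level FWE threshold by within-subject permutation (maxT)
#'
#' The behaviour labels are permuted within each subject's rows (subjects are
#' the exchangeability blocks), the full model is refit for every permutation,
#' and the maximum in-mask t is recorded. The critical value is the
#' (1 - alpha) empirical quantile of the maxT distribution including the
#' observed statistic, with ties resolved conservatively (ceiling index). If
#' the number of distinct within-block label arrangements is below 1/alpha, a
#' warning is issued and all distinct arrangements are enumerated exactly.
#'
#' @param Y rows-by-voxels response matrix.
#' @param design a `dys_design`.
#' @param ns a `dys_nonsphericity` (or `NULL`).
#' @param mask binary `vol_volume` or logical/0-1 vector over columns of `Y`.
#' @param alpha peak-level FWE rate (default 0.05).
#' @param n_perm number of permutations including the observed one
#'   (default 2000).
#' @param seed RNG seed for the permutations.
#' @param grid optional `vol_grid` for the output maps.
#' @param chunk permutations processed per block (memory control).
#' @return a `threshold_result`: `critical_t`, `alpha`, `method`, `t_map`,
#'   `sig_map`, `clusters`, `maxT`, `df`, `n_perm`.
#' @export
fwe_threshold_maxT <- function(Y, design, ns = NULL, mask = NULL,
                               alpha = 0.05, n_perm = 2000, seed = NULL,
                               grid = NULL, chunk = 256L) {
  stopifnot(alpha > 0, alpha <= 1, n_perm >= 2)
  if (is.null(ns)) ns <- new_nonsphericity(0, design$subject_blocks, nrow(Y))
  if (inherits(mask, "vol_volume")) {
    if (is.null(grid)) grid <- mask$grid
    mask <- as.numeric(mask$values) != 0
  }
  mask_idx <- if (is.null(mask)) seq_len(ncol(Y)) else which(as.logical(mask))
  if (!length(mask_idx)) stop("mask is empty", call. = FALSE)
  n <- nrow(Y)
  blocks <- design$subject_blocks
  b_obs <- design$X[, design$behaviour_col]

  # distinct within-block arrangements of the observed labels
  n_distinct <- prod(vapply(blocks, function(rows)
    choose(length(rows), sum(b_obs[rows])), 1))
  enumerate <- n_distinct < 1 / alpha
  if (enumerate)
    warning(sprintf(
      "only %.0f distinct within-subject permutations (< 1/alpha = %.0f); falling back to exact enumeration",
      n_distinct, 1 / alpha), call. = FALSE)

  # whiten once; residualise against the nuisance (subject) columns
  Xw <- whiten(ns, design$X)
  Z <- Xw[, -design$behaviour_col, drop = FALSE]
  qz <- qr(Z)
  Yr <- qr.resid(qz, whiten(ns, Y[, mask_idx, drop = FALSE]))
  SSEred <- colSums(Yr^2)
  rank_full <- qr(Xw)$rank
  df <- n - rank_full

  if (enumerate) {
    B0 <- enumerate_block_labels(b_obs, blocks)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    B0 <- matrix(b_obs, n, n_perm)
    for (p in 2:n_perm)
      for (rows in blocks)
        B0[rows, p] <- b_obs[rows[sample.int(length(rows))]]
  }
  P <- ncol(B0)

  # t = sqrt(df) u / sqrt(1 - u^2) with u = (b'y) / (|b| |y|) on the
  # nuisance-residualised whitened data; t is strictly increasing in u, so
  # per-permutation maxima need only the row max of the scaled cross-product.
  ok_v <- SSEred > 1e-12 * max(SSEred, 1e-300)  # exclude zero-variance voxels
  inv_se <- ifelse(ok_v, 1 / sqrt(SSEred), 0)
  u_to_t <- function(u) {
    u <- pmin(pmax(u, -1), 1)
    sqrt(df) * u / sqrt(pmax(1 - u^2, 1e-12))
  }
  maxT <- numeric(P)
  t_obs <- NULL
  for (start in seq(1L, P, by = chunk)) {
    idx <- start:min(start + chunk - 1L, P)
    Br <- qr.resid(qz, whiten(ns, B0[, idx, drop = FALSE]))
    bb <- colSums(Br^2)
    U <- crossprod(Br, Yr)                        # |idx| x V
    U <- U * ifelse(bb > 1e-10, 1 / sqrt(bb), 0)  # row-recycled scaling
    U <- U * rep(inv_se, each = length(idx))
    maxT[idx] <- u_to_t(apply(U, 1L, max))
    if (start == 1L) {
      t_obs <- u_to_t(U[1L, ])
      t_obs[!ok_v] <- 0
    }
  }

  k <- max(1L, ceiling((1 - alpha) * P))
  critical_t <- sort(maxT)[k]

  t_full <- numeric(ncol(Y)); t_full[mask_idx] <- t_obs
  sig_full <- numeric(ncol(Y))
  sig_full[mask_idx] <- as.numeric(t_obs >= critical_t & t_obs != 0)
  t_map <- if (!is.null(grid)) new_volume(grid, t_full) else t_full
  sig_map <- if (!is.null(grid)) new_volume(grid, sig_full) else sig_full
  clusters <- if (!is.null(grid))
    extract_clusters(sig_map, t_map) else NULL

  structure(
    list(critical_t = critical_t, alpha = alpha,
         method = if (enumerate) "perm_maxT_exact" else "perm_maxT",
         t_map = t_map, sig_map = sig_map, clusters = clusters,
         maxT = maxT, df = df, n_perm = P),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  nsig <- if (inherits(x$sig_map, "vol_volume")) sum(x$sig_map$values) else sum(x$sig_map)
  cat(sprintf("<threshold_result> %s: critical t = %.3f (alpha %.3g, %d perms), %d significant voxel(s)\n",
              x$method, x$critical_t, x$alpha, x$n_perm, as.integer(nsig)))
  invisible(x)
}

## all distinct within-block arrangements of a binary label vector
enumerate_block_labels <- function(b, blocks, cap = 250000L) {
  per_block <- lapply(blocks, function(rows) {
    k <- sum(b[rows]); m <- length(rows)
    sel <- utils::combn(m, k, simplify = FALSE)
    lapply(sel, function(s) { v <- numeric(m); v[s] <- 1; v })
  })
  counts <- vapply(per_block, length, 1L)
  if (prod(counts) > cap)
    stop("exact enumeration would exceed ", cap, " arrangements", call. = FALSE)
  grid_idx <- do.call(expand.grid, lapply(counts, seq_len))
  n <- length(b)
  B <- matrix(0, n, nrow(grid_idx))
  for (p in seq_len(nrow(grid_idx)))
    for (j in seq_along(blocks))
      B[blocks[[j]], p] <- per_block[[j]][[grid_idx[p, j]]]
  # put the observed arrangement first
  obs <- which(colSums(abs(B - b)) == 0)[1]
  if (obs != 1L) B[, c(1L, obs)] <- B[, c(obs, 1L)]
  B
}

#' Extract clusters from a thresholded map
#'
#' 26-connected components of the significant voxels, reported with voxel
#' extent, peak t and peak world coordinate, sorted by peak t descending.
#'
#' @param sig_map binary `vol_volume`.
#' @param t_map `vol_volume` of t statistics on the same grid.
#' @return data.frame: `cluster_id`, `extent_voxels`, `peak_t`,
#'   `peak_x_mm`, `peak_y_mm`, `peak_z_mm`.
#' @export
extract_clusters <- function(sig_map, t_map) {
  stopifnot(inherits(sig_map, "vol_volume"), inherits(t_map, "vol_volume"),
            grids_equal(sig_map$grid, t_map$grid))
  grid <- sig_map$grid
  lin <- which(sig_map$values != 0)
  empty <- data.frame(cluster_id = integer(), extent_voxels = integer(),
                      peak_t = numeric(), peak_x_mm = numeric(),
                      peak_y_mm = numeric(), peak_z_mm = numeric())
  if (!length(lin)) return(empty)
  sh <- grid$shape
  off <- as.matrix(expand.grid(i = -1:1, j = -1:1, k = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  inside <- logical(prod(sh)); inside[lin] <- TRUE
  comp <- integer(prod(sh))
  cid <- 0L
  for (v in lin) {
    if (comp[v]) next
    cid <- cid + 1L
    queue <- v; comp[v] <- cid
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      ijk <- linear_vox(grid, cur)
      nb <- sweep(off, 2L, as.integer(ijk), "+")
      nb <- nb[in_grid(grid, nb), , drop = FALSE]
      nl <- vox_linear(grid, nb)
      nl <- nl[inside[nl] & comp[nl] == 0L]
      if (length(nl)) { comp[nl] <- cid; queue <- c(queue, nl) }
    }
  }
  rows <- lapply(seq_len(cid), function(id) {
    members <- which(comp == id)
    tv <- t_map$values[members]
    peak <- members[which.max(tv)]
    w <- grid_world(grid, linear_vox(grid, peak))
    data.frame(cluster_id = id, extent_voxels = length(members),
               peak_t = max(tv), peak_x_mm = w[1], peak_y_mm = w[2],
               peak_z_mm = w[3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak_t), ]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
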