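#' ROI vs voxel-wise predictive benchmarking
#'
#' Quantifies the localisation information in the inferred maps by using them
#' as spatial priors for classifying held-out stimulations: the voxel-wise
#' (SPM-style) arm thresholds the focal t map at its permutation FWE critical
#' t, the ROI arm marks atlas parcels significantly associated with the
#' behaviour by Fisher's exact test under FDR control. Both arms are refit on
#' each bootstrap's mapping split and evaluated on its held-out test split.
#'
#' @name roi_predictive
NULL

#' Construct a parcellation from an integer label volume
#' @param label_volume `vol_volume` with non-negative integer labels
#'   (0 = background).
#' @return a `parcellation`: `label_volume`, `region_ids`.
#' @export
as_parcellation <- function(label_volume) {
  stopifnot(inherits(label_volume, "vol_volume"))
  v <- label_volume$values
  if (any(v < 0) || any(v != round(v)))
    stop("parcellation labels must be non-negative integers", call. = FALSE)
  structure(list(label_volume = label_volume,
                 region_ids = sort(unique(as.integer(v[v > 0])))),
            class = "parcellation")
}

#' Assign stimulation loci to enclosing ROIs
#'
#' @param parcellation a `parcellation`.
#' @param records a `stim_table` (or an n x 3 world coordinate matrix).
#' @return integer vector of region labels (0 = background).
#' @export
assign_roi <- function(parcellation, records) {
  coords <- if (inherits(records, "stim_table")) stim_coords(records)
            else rbind_coords(records)
  grid <- parcellation$label_volume$grid
  vox <- matrix(grid_voxel(grid, coords), ncol = 3L)
  ok <- in_grid(grid, vox)
  if (!all(ok))
    stop(sprintf("locus %d at (%s) mm is outside the parcellation grid",
                 which(!ok)[1],
                 paste(signif(coords[which(!ok)[1], ], 4), collapse = ", ")),
         call. = FALSE)
  as.integer(parcellation$label_volume$values[vox_linear(grid, vox)])
}

#' Fisher's exact test for one 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration (sum of table
#' probabilities not exceeding the observed one, at fixed margins). The odds
#' ratio is the sample OR a*d / (b*c), with the Haldane +0.5 correction
#' applied to all cells iff any cell is zero.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list(`odds_ratio`, `p_value`, `degenerate`).
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (all(cells == 0))
    return(list(odds_ratio = 1, p_value = 1, degenerate = TRUE))
  if (any(cells == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  m <- a + b          # row-1 margin
  n2 <- c + d         # row-2 margin
  k <- a + c          # column-1 margin
  lo <- max(0L, k - n2); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p_value = p, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values numeric vector of p values in [0, 1].
#' @return q values, clipped to 1, monotone over the sorted p.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  if (!m) return(numeric())
  o <- order(p_values)
  q_sorted <- p_values[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' ROI association map from training loci
#'
#' Per region: 2x2 table of in-region vs out-of-region against behaviour
#' present vs absent over the training loci; Fisher's exact test; BH-FDR over
#' tested regions; significance at q < 0.05 with OR > 1 (a region predicting
#' absence should not label positives). Regions containing no training locus
#' are excluded.
#'
#' @param records training `stim_table`.
#' @param parcellation a `parcellation`.
#' @param behaviour behaviour column.
#' @param q_threshold FDR level (default 0.05).
#' @return a `roi_stats` data.frame: `region`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`, `q_value`, `significant`, plus attribute
#'   `n_background` (training loci falling in background).
#' @export
build_roi_map <- function(records, parcellation, behaviour,
                          q_threshold = 0.05) {
  stopifnot(nrow(records) >= 1L)
  labels <- assign_roi(parcellation, records)
  y <- as.integer(records[[behaviour]])
  n_background <- sum(labels == 0L)
  present <- sort(unique(labels[labels > 0L]))
  rows <- lapply(present, function(rid) {
    inr <- labels == rid
    a <- sum(inr & y == 1L); b <- sum(inr & y == 0L)
    c_ <- sum(!inr & y == 1L); d <- sum(!inr & y == 0L)
    fe <- fisher_exact(a, b, c_, d)
    data.frame(region = rid, a = a, b = b, c = c_, d = d,
               odds_ratio = fe$odds_ratio, p_value = fe$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < q_threshold & out$odds_ratio > 1
  structure(out, n_background = n_background,
            class = c("roi_stats", "data.frame"))
}

#' Voxel-wise (SPM-style) map from training loci
#'
#' Runs the full focal pipeline on the training split and thresholds the t
#' map at the permutation FWE critical t, yielding a binary predictor map.
#'
#' @param records training `stim_table`.
#' @param behaviour behaviour column.
#' @param grid analysis `vol_grid`.
#' @param ... passed to [run_focal_pipeline()].
#' @return list(`t_map`, `sig_map`, `critical_t`, `pipeline`).
#' @export
build_spm_map <- function(records, behaviour, grid, ...) {
  if (sum(records[[behaviour]] == 1L) < 2L ||
      sum(records[[behaviour]] == 0L) < 2L) {
    warning("fewer than 2 training loci in one behaviour class; empty map",
            call. = FALSE)
    empty <- new_volume(grid, 0)
    return(list(t_map = empty, sig_map = empty, critical_t = Inf,
                pipeline = NULL))
  }
  pl <- run_focal_pipeline(records, behaviour, grid, ...)
  list(t_map = pl$threshold$t_map, sig_map = pl$threshold$sig_map,
       critical_t = pl$threshold$critical_t, pipeline = pl)
}

#' ROC curve and AUC from continuous weights
#'
#' Threshold sweep over the unique weights (ties grouped), trapezoidal AUC —
#' identical to the Mann-Whitney statistic U / (n1 n0) with ties counted 1/2.
#'
#' @param weights numeric predictor per case.
#' @param labels binary outcome per case (both classes required).
#' @return list(`fpr`, `tpr`, `auc`).
#' @export
roc_auc <- function(weights, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute a ROC", call. = FALSE)
  thr <- sort(unique(weights), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(weights >= t & labels == 1L) / n1, 1)
  fpr <- vapply(thr, function(t) sum(weights >= t & labels == 0L) / n0, 1)
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

confusion_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / n,
       balanced_accuracy = mean(c(
         if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         if (tn + fp > 0) tn / (tn + fp) else NA_real_), na.rm = TRUE),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall_tpr = if (tp + fn > 0) tp / (tp + fn) else 0,
       fpr = if (fp + tn > 0) fp / (fp + tn) else 0)
}

## vertical interpolation of a ROC polyline onto a fixed FPR grid
interp_roc <- function(roc, fpr_grid) {
  f <- c(roc$fpr, 1); t <- c(roc$tpr, 1)
  stats::approx(f, t, xout = fpr_grid, method = "linear", ties = max,
                rule = 2)$y
}

#' Bootstrap comparison of SPM-map vs ROI-map predictors
#'
#' For each bootstrap: a stratified mapping/test split of the stimulation
#' records (stratified on the behaviour label; `group_by_subject = TRUE`
#' splits whole subjects instead), both arms fitted on the mapping split, and
#' each test locus labelled positive iff it falls inside the arm's
#' significant region. Confusion metrics are recorded per bootstrap; ROC
#' curves use the unthresholded weights (t value at the locus for the SPM
#' arm, odds ratio of the enclosing region for the ROI arm, 0 for
#' background), vertically averaged on a fixed 101-point FPR grid.
#'
#' @param records a `stim_table`.
#' @param parcellation a `parcellation` on the analysis grid.
#' @param behaviour behaviour column.
#' @param grid analysis `vol_grid`.
#' @param n_boot number of bootstraps (default 100).
#' @param test_frac held-out fraction (default 0.2).
#' @param seed RNG seed.
#' @param group_by_subject split whole subjects instead of records.
#' @param ... passed to [run_focal_pipeline()] (e.g. `n_perm`, `fwhm_mm`).
#' @return an `eval_report`: `metrics` (per bootstrap x arm data.frame),
#'   `roc` (mean/sd TPR per arm on `fpr_grid`), `auc` (per bootstrap x arm),
#'   `summary` (mean metrics per arm), `n_skipped_roc`.
#' @export
bootstrap_evaluate <- function(records, parcellation, behaviour, grid,
                               n_boot = 100, test_frac = 0.2, seed = NULL,
                               group_by_subject = FALSE, ...) {
  stopifnot(n_boot >= 1, test_frac > 0, test_frac < 1)
  if (!is.null(seed)) set.seed(seed)
  y_all <- as.integer(records[[behaviour]])
  fpr_grid <- seq(0, 1, length.out = 101L)
  arms <- c("spm", "roi")
  metrics <- list(); aucs <- list()
  tpr_acc <- list(spm = NULL, roi = NULL)
  n_skipped <- 0L

  for (b in seq_len(n_boot)) {
    test_idx <- sample_split(records, y_all, test_frac, group_by_subject)
    train <- as_stim_table(records[-test_idx, , drop = FALSE],
                           stim_behaviours(records))
    test <- as_stim_table(records[test_idx, , drop = FALSE],
                          stim_behaviours(records))
    y_test <- as.integer(test[[behaviour]])

    spm <- build_spm_map(train, behaviour, grid, ...)
    roi <- build_roi_map(train, parcellation, behaviour)

    # SPM arm: test locus positive iff inside the FWE-significant region
    vox <- matrix(grid_voxel(grid, stim_coords(test)), ncol = 3L)
    ok <- in_grid(grid, vox)
    lin <- rep(NA_integer_, nrow(test))
    lin[ok] <- vox_linear(grid, vox[ok, , drop = FALSE])
    spm_weight <- ifelse(ok, spm$t_map$values[lin], 0)
    spm_pred <- as.integer(ok & spm$sig_map$values[lin] != 0)

    # ROI arm: positive iff inside a significant region; weight = region OR
    test_labels <- assign_roi(parcellation, test)
    ridx <- match(test_labels, roi$region)
    roi_weight <- ifelse(is.na(ridx), 0, roi$odds_ratio[ridx])
    roi_pred <- as.integer(!is.na(ridx) & roi$significant[ridx])

    for (arm in arms) {
      pred <- if (arm == "spm") spm_pred else roi_pred
      wt <- if (arm == "spm") spm_weight else roi_weight
      cm <- confusion_metrics(sum(pred == 1 & y_test == 1),
                              sum(pred == 1 & y_test == 0),
                              sum(pred == 0 & y_test == 1),
                              sum(pred == 0 & y_test == 0))
      metrics[[length(metrics) + 1L]] <-
        data.frame(bootstrap = b, arm = arm, as.data.frame(cm))
      if (length(unique(y_test)) == 2L) {
        roc <- roc_auc(wt, y_test)
        aucs[[length(aucs) + 1L]] <-
          data.frame(bootstrap = b, arm = arm, auc = roc$auc)
        tpr_acc[[arm]] <- rbind(tpr_acc[[arm]], interp_roc(roc, fpr_grid))
      } else if (arm == "spm") {
        n_skipped <- n_skipped + 1L
      }
    }
  }

  metrics <- do.call(rbind, metrics)
  aucs <- do.call(rbind, aucs)
  roc_curves <- lapply(tpr_acc, function(m) {
    if (is.null(m)) return(NULL)
    list(fpr = fpr_grid, tpr_mean = colMeans(m),
         tpr_sd = apply(m, 2L, stats::sd))
  })
  num_cols <- setdiff(names(metrics), c("bootstrap", "arm"))
  summary <- do.call(rbind, lapply(arms, function(arm) {
    sub <- metrics[metrics$arm == arm, num_cols]
    out <- as.data.frame(as.list(colMeans(sub)))
    out$mean_auc <- if (!is.null(aucs)) mean(aucs$auc[aucs$arm == arm]) else NA
    cbind(arm = arm, out)
  }))
  structure(list(metrics = metrics, auc = aucs, roc = roc_curves,
                 fpr_grid = fpr_grid, summary = summary,
                 n_skipped_roc = n_skipped, behaviour = behaviour,
                 n_boot = n_boot, test_frac = test_frac),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> '%s', %d bootstraps (%.0f%% held out)\n",
              x$behaviour, x$n_boot, 100 * x$test_frac))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

sample_split <- function(records, y, test_frac, group_by_subject) {
  n <- nrow(records)
  if (group_by_subject) {
    subjects <- unique(records$subject_id)
    k <- max(1L, round(test_frac * length(subjects)))
    test_subj <- sample(subjects, k)
    idx <- which(records$subject_id %in% test_subj)
  } else {
    idx <- unlist(lapply(split(seq_len(n), y), function(rows) {
      k <- max(1L, round(test_frac * length(rows)))
      sample(rows, min(k, length(rows)))
    }), use.names = FALSE)
  }
  sort(idx)
}
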