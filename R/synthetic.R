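#' Synthetic cohorts, truth maps and connectomes
#'
#' Generates data with the statistical structure the inference assumes:
#' clustered per-subject electrode placement (surface grids, depth
#' trajectories or uniform scatter), within-subject outcome correlation via
#' subject random intercepts on the log-odds scale, location-dependent
#' Bernoulli outcomes driven by spherical ground-truth regions, and a
#' distance-decaying connectome with designated long-range bundles. Outcomes
#' come from a logistic model even though the analysis fits a linear GLM on
#' densities: the pipeline is deliberately tested under its own model
#' mismatch, as with real data.
#'
#' @name synthetic_data
NULL

#' Synthetic cohort configuration
#'
#' @param n_subjects number of subjects (default 37, the reference cohort).
#' @param loci_per_subject integer range c(lo, hi) of stimulations per
#'   subject (default c(8, 18), bracketing the reference mean of ~13).
#' @param total_loci optional exact total; per-subject counts are adjusted
#'   within the range to hit it (477 in the reference cohort).
#' @param grid analysis `vol_grid` (default 40 x 48 x 40 at 3 mm, centred on
#'   the origin, sized for test speed; reference-scale grids are reachable).
#' @param sampling_mode one of `"grid_electrodes"`, `"depth_trajectories"`,
#'   `"uniform"`.
#' @param behaviours behaviour names (default the five reference categories).
#' @param truth_regions list of lists with fields `center` (mm), `radius_mm`,
#'   `behaviour`, `effect_logodds`.
#' @param baseline_logodds baseline outcome log-odds (default -2, a ~12%
#'   base rate typical of evoked responses).
#' @param subject_sd SD of subject random intercepts on log-odds
#'   (default 0.5).
#' @param connectome list(`n_nodes`, `decay_length_mm`, `bundles`) where each
#'   bundle is list(`center_a`, `center_b`, `radius_mm`, `weight`).
#' @param seed RNG seed.
#' @return a `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 37L,
                             loci_per_subject = c(8L, 18L),
                             total_loci = NULL,
                             grid = make_grid(c(40L, 48L, 40L), 3,
                                              origin_mm = c(-58.5, -70.5, -58.5)),
                             sampling_mode = c("uniform", "grid_electrodes",
                                               "depth_trajectories"),
                             behaviours = c("positive_motor", "negative_motor",
                                            "sensory", "speech", "silent"),
                             truth_regions = list(),
                             baseline_logodds = -2,
                             subject_sd = 0.5,
                             connectome = list(n_nodes = 600L,
                                               decay_length_mm = 15,
                                               bundles = list()),
                             seed = 1L) {
  sampling_mode <- match.arg(sampling_mode)
  stopifnot(n_subjects >= 2L, length(loci_per_subject) == 2L,
            loci_per_subject[1] >= 1L,
            loci_per_subject[2] >= loci_per_subject[1],
            subject_sd >= 0)
  for (tr in truth_regions) {
    stopifnot(all(c("center", "radius_mm", "behaviour", "effect_logodds") %in%
                    names(tr)), tr$radius_mm > 0,
              tr$behaviour %in% behaviours)
    vox <- grid_voxel(grid, tr$center)
    if (!in_grid(grid, vox))
      stop("truth region centred at (", paste(tr$center, collapse = ", "),
           ") mm lies outside the grid", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 loci_per_subject = as.integer(loci_per_subject),
                 total_loci = if (!is.null(total_loci)) as.integer(total_loci),
                 grid = grid, sampling_mode = sampling_mode,
                 behaviours = behaviours, truth_regions = truth_regions,
                 baseline_logodds = baseline_logodds, subject_sd = subject_sd,
                 connectome = connectome, seed = as.integer(seed)),
            class = "synthetic_config")
}

logistic <- function(x) 1 / (1 + exp(-x))

## world-mm bounding box of voxel centers
grid_bbox <- function(grid) {
  corners <- as.matrix(expand.grid(c(0, grid$shape[1] - 1),
                                   c(0, grid$shape[2] - 1),
                                   c(0, grid$shape[3] - 1)))
  w <- grid_world(grid, corners)
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

#' Generate a synthetic cohort
#'
#' @param cfg a `synthetic_config`.
#' @return list(`records` (a `stim_table`), `truth`): `truth` carries
#'   per-behaviour binary ground-truth volumes, per-subject intercepts and
#'   the latent per-record outcome probabilities.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  rng <- seq.int(cfg$loci_per_subject[1], cfg$loci_per_subject[2])
  counts <- rng[sample.int(length(rng), cfg$n_subjects, replace = TRUE)]
  if (!is.null(cfg$total_loci)) {
    while (sum(counts) != cfg$total_loci) {
      i <- sample.int(cfg$n_subjects, 1L)
      if (sum(counts) < cfg$total_loci &&
          counts[i] < cfg$loci_per_subject[2]) counts[i] <- counts[i] + 1L
      else if (sum(counts) > cfg$total_loci &&
               counts[i] > cfg$loci_per_subject[1]) counts[i] <- counts[i] - 1L
    }
  }
  bbox <- grid_bbox(cfg$grid)
  span <- bbox["hi", ] - bbox["lo", ]
  intercepts <- stats::rnorm(cfg$n_subjects, 0, cfg$subject_sd)

  coord_list <- lapply(seq_len(cfg$n_subjects), function(s)
    place_subject_loci(counts[s], cfg$sampling_mode, bbox, span))
  coords <- do.call(rbind, coord_list)
  subj <- rep(sprintf("S%02d", seq_len(cfg$n_subjects)), counts)

  df <- data.frame(subject_id = subj, x_mm = coords[, 1], y_mm = coords[, 2],
                   z_mm = coords[, 3], stringsAsFactors = FALSE)
  probs <- matrix(NA_real_, nrow(df), length(cfg$behaviours),
                  dimnames = list(NULL, cfg$behaviours))
  for (bname in cfg$behaviours) {
    eta <- cfg$baseline_logodds + intercepts[match(subj, unique(subj))]
    for (tr in cfg$truth_regions) {
      if (tr$behaviour != bname) next
      d <- sqrt(colSums((t(coords) - as.numeric(tr$center))^2))
      eta <- eta + tr$effect_logodds * (d <= tr$radius_mm)
    }
    probs[, bname] <- logistic(eta)
    df[[bname]] <- stats::rbinom(nrow(df), 1L, probs[, bname])
  }
  records <- as_stim_table(df, cfg$behaviours)

  truth_vols <- lapply(cfg$behaviours, function(bname) {
    v <- numeric(prod(cfg$grid$shape))
    regs <- Filter(function(tr) tr$behaviour == bname, cfg$truth_regions)
    if (length(regs)) {
      centers <- grid_world(cfg$grid, linear_vox(cfg$grid,
                                                 seq_len(prod(cfg$grid$shape))))
      for (tr in regs) {
        d <- sqrt(colSums((t(centers) - as.numeric(tr$center))^2))
        v[d <= tr$radius_mm] <- 1
      }
    }
    new_volume(cfg$grid, v)
  })
  names(truth_vols) <- cfg$behaviours

  list(records = records,
       truth = list(volumes = truth_vols, intercepts = intercepts,
                    probabilities = probs, counts = counts))
}

place_subject_loci <- function(m, mode, bbox, span) {
  margin <- 0.08 * span
  lo <- bbox["lo", ] + margin; hi <- bbox["hi", ] - margin
  runifv <- function() lo + stats::runif(3) * (hi - lo)
  if (mode == "uniform") {
    coords <- matrix(stats::runif(3 * m), m, 3)
    return(sweep(sweep(coords, 2, hi - lo, "*"), 2, lo, "+"))
  }
  if (mode == "grid_electrodes") {
    # planar contact lattice: rows x cols patch, 10 mm pitch, axis-aligned
    # plane with small jitter
    axis <- sample(3L, 1L)
    ncol_ <- ceiling(sqrt(m))
    origin <- runifv()
    idx <- seq_len(m) - 1L
    uv <- cbind(idx %% ncol_, idx %/% ncol_) * 10
    dims <- setdiff(1:3, axis)
    coords <- matrix(rep(origin, each = m), m, 3)
    coords[, dims[1]] <- origin[dims[1]] + uv[, 1]
    coords[, dims[2]] <- origin[dims[2]] + uv[, 2]
    coords <- coords + matrix(stats::rnorm(3 * m, 0, 0.5), m, 3)
  } else {
    # depth trajectory: collinear contacts at 5 mm spacing along a random
    # direction from a random entry point
    origin <- runifv()
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    coords <- matrix(rep(origin, each = m), m, 3) +
      outer((seq_len(m) - 1L) * 5, dir) +
      matrix(stats::rnorm(3 * m, 0, 0.3), m, 3)
  }
  # clamp into the sampled box so every locus stays on the grid
  coords <- pmin(pmax(coords, matrix(lo, nrow(coords), 3, byrow = TRUE)),
                 matrix(hi, nrow(coords), 3, byrow = TRUE))
  coords
}

#' Generate a synthetic distance-decay connectome
#'
#' Nodes are placed on the grid's grey-matter shell (voxel centers whose
#' radius from the grid center falls between 55% and 95% of the maximum),
#' subsampled to `n_nodes`. Edge weight is exp(-d_ij / decay_length) with
#' weights below exp(-6) dropped for sparsity, plus additive bundle weights
#' between node sets within `radius_mm` of each bundle's two centers.
#'
#' @param cfg a `synthetic_config` (uses `cfg$connectome`, `cfg$grid`,
#'   `cfg$seed`).
#' @return a `connectome_graph`.
#' @export
generate_connectome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cc <- cfg$connectome
  stopifnot(cc$n_nodes >= 2L, cc$decay_length_mm > 0)
  set.seed(cfg$seed + 1L)
  grid <- cfg$grid
  centers <- grid_world(grid, linear_vox(grid, seq_len(prod(grid$shape))))
  mid <- colMeans(grid_bbox(grid))
  r <- sqrt(colSums((t(centers) - mid)^2))
  rmax <- max(r)
  shell <- which(r >= 0.55 * rmax & r <= 0.95 * rmax)
  if (length(shell) < cc$n_nodes)
    stop("grid too small for ", cc$n_nodes, " shell nodes", call. = FALSE)
  nodes <- sort(sample(shell, cc$n_nodes))
  xyz <- centers[nodes, , drop = FALSE]

  d <- as.matrix(stats::dist(xyz))
  W <- exp(-d / cc$decay_length_mm)
  W[W < exp(-6)] <- 0
  diag(W) <- 0
  for (bd in cc$bundles) {
    in_a <- sqrt(colSums((t(xyz) - as.numeric(bd$center_a))^2)) <= bd$radius_mm
    in_b <- sqrt(colSums((t(xyz) - as.numeric(bd$center_b))^2)) <= bd$radius_mm
    if (any(in_a & in_b))
      warning("bundle regions overlap", call. = FALSE)
    W[in_a, in_b] <- W[in_a, in_b] + bd$weight
    W[in_b, in_a] <- W[in_b, in_a] + bd$weight
  }
  new_connectome(methods::as(Matrix::Matrix(W, sparse = TRUE),
                             "CsparseMatrix"), xyz, grid)
}

#' Null cohort: behaviour labels permuted within subjects
#'
#' Destroys any location-behaviour association while preserving each
#' subject's outcome rates — the randomisation check used to confirm results
#' are attributable to the behavioural regressor.
#'
#' @param records a `stim_table`.
#' @param seed RNG seed.
#' @return a `stim_table` with every behaviour column permuted within each
#'   subject's rows.
#' @export
make_null_cohort <- function(records, seed = NULL) {
  stopifnot(inherits(records, "stim_table"), nrow(records) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(records)
  blocks <- split(seq_len(nrow(out)), out$subject_id)
  for (bname in stim_behaviours(records)) {
    for (rows in blocks)
      out[[bname]][rows] <- out[[bname]][rows[sample.int(length(rows))]]
  }
  as_stim_table(out, stim_behaviours(records))
}
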