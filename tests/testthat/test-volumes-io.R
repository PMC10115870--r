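test_that("grids map indices to world coordinates and back exactly", {
  g <- make_grid(c(10, 10, 10), 1.5, origin_mm = c(0, 0, 0))
  expect_equal(grid_world(g, c(2, 0, 0)), c(3, 0, 0))
  expect_equal(grid_world(g, c(0, 0, 0)), c(0, 0, 0))

  # 2 mm grid matches the connectome sampling resolution
  g2 <- make_grid(c(8, 8, 8), 2)
  expect_equal(unname(g2$voxel_size_mm), c(2, 2, 2))

  set.seed(11)
  idx <- cbind(sample(0:9, 100, TRUE), sample(0:9, 100, TRUE),
               sample(0:9, 100, TRUE))
  expect_identical(grid_voxel(g, grid_world(g, idx)), idx * 1)

  expect_error(make_grid(c(4, 4, 4), c(1, 0, 1)), "positive")
  expect_error(make_grid(c(0, 4, 4), 1), "shape")
})

test_that("half-way world points break ties toward the lower voxel index", {
  g <- make_grid(c(10, 10, 10), 2, origin_mm = c(0, 0, 0))
  expect_equal(grid_voxel(g, c(1, 0, 0)), c(0, 0, 0))   # midpoint of 0 and 1
  expect_equal(grid_voxel(g, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(grid_voxel(g, c(1.01, 0, 0)), c(1, 0, 0))
})

test_that("kernel geometry: sigma, truncation radius, FWHM half-height", {
  k <- build_gaussian_kernel(10, 1.5)
  expect_equal(k$sigma_mm, 4.2466, tolerance = 1e-4)
  expect_equal(k$truncation_radius_mm / k$sigma_mm, 2.5003, tolerance = 1e-4)
  expect_equal(k$truncation_radius_mm, 10.62, tolerance = 1e-3)

  # chi-3 quantile against an independent numerical CDF-inversion oracle
  chi3_cdf <- function(r) sqrt(2 / pi) *
    stats::integrate(function(x) x^2 * exp(-x^2 / 2), 0, r)$value
  r_oracle <- stats::uniroot(function(r) chi3_cdf(r) - 0.9, c(1, 5),
                             tol = 1e-10)$root
  expect_equal(k$truncation_radius_mm / k$sigma_mm, r_oracle,
               tolerance = 1e-6)

  # weight at distance fwhm/2 is half the peak weight (stencil at 5 mm voxels)
  k5 <- build_gaussian_kernel(10, 5)
  centre <- (dim(k5$weights) + 1) / 2
  expect_equal(k5$weights[centre[1] + 1, centre[2], centre[3]],
               0.5 * k5$weights[centre[1], centre[2], centre[3]])

  expect_error(build_gaussian_kernel(-1, 1.5), "positive")
  expect_error(build_gaussian_kernel(10, 1.5, mass_fraction = 1), "(0, 1)",
               fixed = TRUE)
})

test_that("truncation encloses the stated continuous mass for many FWHMs", {
  chi3_mass <- function(r_over_sigma) sqrt(2 / pi) *
    stats::integrate(function(x) x^2 * exp(-x^2 / 2), 0, r_over_sigma)$value
  for (fwhm in c(4, 6, 8, 10, 12, 16)) {
    k <- build_gaussian_kernel(fwhm, 1.5, mass_fraction = 0.9)
    expect_equal(chi3_mass(k$truncation_radius_mm / k$sigma_mm), 0.9,
                 tolerance = 0.005)
  }

  # per-axis variant: the cube encloses the same continuous mass
  kpa <- build_gaussian_kernel(10, 1.5, truncation = "per_axis")
  r <- kpa$truncation_radius_mm / kpa$sigma_mm
  expect_equal((2 * pnorm(r) - 1)^3, 0.9, tolerance = 0.005)
  expect_lt(kpa$truncation_radius_mm, kpa$sigma_mm * 2.5003)
})

test_that("smoothing conserves mass, is linear, and spreads with FWHM", {
  g <- centered_grid(17, 2)
  imp <- new_volume(g, {v <- numeric(17^3); v[dysmap:::vox_linear(g, c(8, 8, 8))] <- 1; v})
  for (fwhm in c(6, 10)) {
    sm <- smooth_volume(imp, fwhm)
    expect_equal(sum(sm$values), 1, tolerance = 1e-6)
  }
  expect_gt(max(smooth_volume(imp, 6)$values),
            max(smooth_volume(imp, 10)$values))

  cst <- new_volume(g, 2.5)
  expect_equal(smooth_volume(cst, 6, renormalise_boundary = TRUE)$values,
               cst$values, tolerance = 1e-12)

  set.seed(3)
  g8 <- make_grid(c(8, 8, 8), 2)
  X <- new_volume(g8, rnorm(512)); Y <- new_volume(g8, rnorm(512))
  lin <- smooth_volume(new_volume(g8, 2 * X$values - 3 * Y$values), 6)
  expect_equal(lin$values,
               2 * smooth_volume(X, 6)$values - 3 * smooth_volume(Y, 6)$values,
               tolerance = 1e-8)
})

test_that("NIfTI round trip preserves shape, affine and values", {
  set.seed(7)
  g <- make_grid(c(8, 8, 8), c(1.5, 2, 2.5), origin_mm = c(-10, 4, 7))
  v <- new_volume(g, runif(512))
  for (ext in c(".nii", ".nii.gz")) {
    p <- tempfile(fileext = ext)
    write_volume(v, p)
    v2 <- read_volume(p)
    expect_identical(v2$grid$shape, g$shape)
    expect_lt(max(abs(v2$grid$affine - g$affine)), 1e-4)
    expect_lt(max(abs(v2$values - v$values)), 1e-6)
  }
})

test_that("NIfTI IO keeps non-axis-aligned affines and rejects bad magic", {
  th <- 0.3
  rot <- rbind(c(cos(th), -sin(th), 0, 2), c(sin(th), cos(th), 0, -3),
               c(0, 0, 1.5, 4), c(0, 0, 0, 1))
  v <- new_volume(dysmap:::new_grid(c(5L, 5L, 5L), rot), seq_len(125))
  p <- tempfile(fileext = ".nii")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_lt(max(abs(v2$grid$affine - rot)), 1e-4)

  bad <- tempfile(fileext = ".nii")
  writeBin(as.raw(rep(0L, 400)), bad)
  expect_error(read_volume(bad), "sizeof_hdr")
  raw348 <- readBin(p, "raw", 1e6)
  raw348[345:348] <- as.raw(c(88, 88, 88, 0))
  writeBin(raw348, bad)
  expect_error(read_volume(bad), "magic")
})

test_that("NIfTI IO agrees with nibabel as independent oracle", {
  set.seed(19)
  g <- make_grid(c(6, 7, 8), c(2, 2, 2), origin_mm = c(-6, -7, -8))
  v <- new_volume(g, rnorm(6 * 7 * 8))
  p <- tempfile(fileext = ".nii")
  write_volume(v, p)
  out <- tempfile(fileext = ".txt")
  script <- sprintf(paste0(
    "import nibabel, numpy as np\n",
    "img = nibabel.load(%s)\n",
    "np.savetxt(%s, np.concatenate([img.affine.ravel(), ",
    "np.asarray(img.dataobj).ravel(order='F')]))\n"),
    deparse(p), deparse(out))
  status <- system2("python", "-", input = script)
  expect_identical(status, 0L)
  vals <- scan(out, quiet = TRUE)
  expect_lt(max(abs(matrix(vals[1:16], 4, byrow = TRUE) - g$affine)), 1e-4)
  expect_lt(max(abs(vals[-(1:16)] - as.numeric(v$values))), 1e-6)

  # and read a nibabel-written float32 file back
  p2 <- tempfile(fileext = ".nii")
  script2 <- sprintf(paste0(
    "import nibabel, numpy as np\n",
    "aff = np.diag([2.0, 2.0, 2.0, 1.0]); aff[:3, 3] = [-6, -7, -8]\n",
    "data = np.arange(24, dtype=np.float32).reshape(2, 3, 4, order='F')\n",
    "nibabel.save(nibabel.Nifti1Image(data, aff), %s)\n"), deparse(p2))
  expect_identical(system2("python", "-", input = script2), 0L)
  v3 <- read_volume(p2)
  expect_equal(as.numeric(v3$values), 0:23)
  expect_equal(v3$grid$affine[1:3, 4], c(-6, -7, -8))
})

test_that("stimulation tables parse, validate and round-trip", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tx_mm\ty_mm\tz_mm\tpositive_motor\tsensory",
               "S01\t1.5\t-2\t3\t1\t1",
               "S01\t4\t5\t6\t0\t0",
               "S02\t7\t8\t9\t1\t0"), p)
  rec <- read_stimulation_table(p)
  expect_s3_class(rec, "stim_table")
  expect_identical(nrow(rec), 3L)
  expect_identical(stim_behaviours(rec), c("positive_motor", "sensory"))
  # one locus may carry several behaviours: classification is not exclusive
  expect_identical(unname(unlist(rec[1, c("positive_motor", "sensory")])),
                   c(1L, 1L))

  p2 <- tempfile(fileext = ".tsv")
  write_stimulation_table(rec, p2)
  expect_identical(read_stimulation_table(p2), rec)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tx_mm\ty_mm\tz_mm\tsensory",
               "S01\t1\t2\t3\t0", "S02\tNA\t5\t6\t1"), bad)
  expect_error(read_stimulation_table(bad), "row 2")
  writeLines(c("subject_id\tx_mm\ty_mm\tz_mm\tsensory",
               "S01\t1\t2\t3\t2"), bad)
  expect_error(read_stimulation_table(bad), "\\{0,1\\}.*row 1")
  writeLines(c("subject_id\tx_mm\tz_mm\tsensory", "S01\t1\t3\t0"), bad)
  expect_error(read_stimulation_table(bad), "y_mm")
})
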