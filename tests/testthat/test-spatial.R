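# Spatial descriptors: normalization, thresholding, regional counts, mask
# percentages, moments/entropy, cluster metrics, mirror symmetry.

test_that("znormalize_map standardizes with the sample-SD convention", {
  z <- znormalize_map(array(c(1, 2, 3, 4), c(4, 1, 1)))
  expect_equal(as.vector(z), c(-1.161895, -0.3872983, 0.3872983, 1.161895),
               tolerance = 1e-6)
  # idempotence
  expect_equal(znormalize_map(z), z, tolerance = 1e-10)
  # degenerate input
  expect_nc_error(znormalize_map(array(7, c(3, 3, 3))), "degenerate")
})

test_that("threshold_top_fraction retains exactly floor(f*N) top-|Z| voxels", {
  withr::local_seed(1)
  z1000 <- array(rnorm(1000), c(10, 10, 10))
  expect_length(threshold_top_fraction(z1000, 0.05)$voxels, 50L)

  z100 <- array(1:100, c(100, 1, 1))
  th <- threshold_top_fraction(z100, 0.05)
  expect_equal(th$voxels, 96:100)

  expect_nc_error(threshold_top_fraction(z1000, 1.5), "input")
  expect_nc_error(threshold_top_fraction(array(0, c(4, 4, 4)), 0.05), "degenerate")
  # fraction so small that no voxel survives
  expect_nc_error(threshold_top_fraction(array(rnorm(8), c(2, 2, 2)), 0.05), "input")
})

test_that("thresholding matches the full-sort oracle, including heavy ties", {
  for (s in 1:30) {
    withr::local_seed(s)
    z <- array(sample(round(rnorm(60), 1), 216, replace = TRUE), c(6, 6, 6))
    z <- z + rnorm(216) * (s %% 2)   # alternate tie-heavy and generic maps
    if (max(z) == min(z)) next
    f <- runif(1, 0.02, 0.5)
    expect_identical(threshold_top_fraction(z, f)$voxels, oracle_top_fraction(z, f))
  }
})

test_that("thresholded sets are nested as the fraction grows", {
  withr::local_seed(3)
  z <- array(sample(seq(-3, 3, 0.5), 512, TRUE), c(8, 8, 8))
  fr <- c(0.05, 0.1, 0.2, 0.4)
  sets <- lapply(fr, function(f) threshold_top_fraction(z, f)$voxels)
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("regional counts follow atlas table order and a per-voxel oracle", {
  atlas <- tiny_space$atlas
  dm <- dim(atlas$labelmap)

  vox_r3 <- which(atlas$labelmap == 3)[1:7]
  counts <- aal_region_counts(make_thmap(vox_r3, dm), atlas)
  expect_equal(unname(counts), c(0, 0, 7, 0, 0, 0))
  expect_named(counts, atlas$regions$name)

  bg <- which(atlas$labelmap == 0)[1:11]
  expect_equal(unname(aal_region_counts(make_thmap(bg, dm), atlas)), rep(0, 6))

  for (s in 1:5) {
    withr::local_seed(s)
    vox <- sample(prod(dm), 200)
    expect_equal(
      unname(aal_region_counts(make_thmap(vox, dm), atlas)),
      oracle_region_counts(sort(vox), atlas$labelmap, atlas$regions$code)
    )
  }

  bad <- make_thmap(1:5, c(8L, 8L, 8L))
  expect_nc_error(aal_region_counts(bad, atlas), "consistency")
})

test_that("mask percentages use the suprathreshold denominator and conserve", {
  ms <- tiny_space$maskset
  dm <- dim(ms$gray)

  th_gray <- make_thmap(which(ms$gray)[1:20], dm)
  pct <- mask_percentages(th_gray, ms)
  expect_equal(unname(pct[["gray"]]), 100)
  expect_equal(sum(pct), 100)   # phantom masks are disjoint

  vox <- c(which(ms$ventricles)[1], which(ms$gray)[1:3])
  pct2 <- mask_percentages(make_thmap(vox, dm), ms)
  expect_equal(unname(pct2[["ventricles"]]), 25)

  # permutation invariance of the voxel enumeration
  th_shuf <- th_gray
  ord <- sample(length(th_shuf$voxels))
  th_shuf$voxels <- th_shuf$voxels[ord]
  th_shuf$zvalues <- th_shuf$zvalues[ord]
  expect_equal(mask_percentages(th_shuf, ms), pct)
})

test_that("map moments match analytic values and the large-sample normal limit", {
  half <- array(rep(c(-1, 1), each = 32), c(4, 4, 4))
  m <- map_moments(half)
  expect_equal(unname(m[["skewness"]]), 0)
  expect_equal(unname(m[["kurtosis"]]), 1)

  withr::local_seed(99)
  gauss <- array(rnorm(1e6), c(100, 100, 100))
  mg <- map_moments(gauss)
  expect_lt(abs(mg[["kurtosis"]] - 3), 0.05)
  expect_lt(abs(mg[["skewness"]]), 0.01)

  # uniform occupancy of all 100 bins -> maximal entropy ln(100)
  unif <- array(rep(1:100, each = 5), c(500, 1, 1))
  expect_equal(unname(map_moments(unif)[["entropy"]]), log(100))

  expect_nc_error(map_moments(array(1, c(3, 3, 3))), "degenerate")
})

test_that("peak/cluster metrics handle blobs and isolated peaks", {
  dm <- c(20L, 20L, 20L)
  # single spherical blob
  z <- array(0, dm)
  ctr <- c(10, 10, 10)
  idx <- arrayInd(seq_len(prod(dm)), dm)
  d2 <- rowSums(sweep(idx, 2, ctr)^2)
  z[d2 <= 9] <- 6 - sqrt(d2[d2 <= 9])
  th <- threshold_top_fraction(z, 0.01)
  cl <- peak_cluster_metrics(z, th)
  expect_equal(cl$n_peaks, 1L)
  expect_equal(cl$avg_peak_distance, 0)
  expect_equal(cl$cluster_size_min, cl$cluster_size_max)

  # two isolated single-voxel peaks 12 mm apart (4 voxels at 3 mm)
  z2 <- array(0, dm)
  z2[8, 10, 10] <- 5
  z2[12, 10, 10] <- 4.5
  th2 <- make_thmap(c(which(z2 == 5), which(z2 == 4.5)), dm,
                    voxel_dims = c(3, 3, 3))
  cl2 <- peak_cluster_metrics(z2, th2)
  expect_equal(cl2$n_peaks, 2L)
  expect_equal(cl2$avg_peak_distance, 12)
  expect_equal(unname(cl2$cluster_sizes), c(1L, 1L))
  expect_equal(cl2$cluster_size_mean, 1)
})

test_that("peak and cluster metrics equal the exhaustive-scan oracle", {
  for (s in 1:6) {
    withr::local_seed(s)
    dm <- c(10L, 10L, 10L)
    z <- array(rnorm(prod(dm)), dm)
    # plant up to 10 hot blobs
    for (b in 1:10) {
      c0 <- sample(2:9, 3, TRUE)
      z[c0[1], c0[2], c0[3]] <- z[c0[1], c0[2], c0[3]] + runif(1, 3, 8)
    }
    th <- threshold_top_fraction(z, 0.1)
    got <- peak_cluster_metrics(z, th)
    want <- oracle_peaks_clusters(z, th$voxels)
    expect_identical(got$peak_voxels, want$peaks)
    expect_identical(as.integer(got$cluster_sizes), as.integer(want$sizes))
  }
})

test_that("mirror symmetry scores reflection overlap about the first-axis midline", {
  dm <- c(10L, 10L, 10L)
  lin <- function(i, j, k) i + (j - 1) * 10 + (k - 1) * 100

  sym <- c(lin(2, 5, 5), lin(9, 5, 5), lin(4, 3, 7), lin(7, 3, 7))
  expect_equal(mirror_symmetry(make_thmap(sym, dm)), 100)

  one_side <- c(lin(2, 5, 5), lin(3, 6, 6), lin(4, 2, 2))
  expect_equal(mirror_symmetry(make_thmap(one_side, dm)), 0)

  half <- c(lin(2, 5, 5), lin(9, 5, 5), lin(3, 2, 2), lin(4, 9, 9))
  expect_equal(mirror_symmetry(make_thmap(half, dm)), 50)

  # reflection invariance
  withr::local_seed(8)
  vox <- sample(1000, 80)
  co <- arrayInd(vox, dm)
  co[, 1] <- 11L - co[, 1]
  refl <- co[, 1] + (co[, 2] - 1) * 10 + (co[, 3] - 1) * 100
  expect_equal(mirror_symmetry(make_thmap(refl, dm)),
               mirror_symmetry(make_thmap(vox, dm)))
})
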