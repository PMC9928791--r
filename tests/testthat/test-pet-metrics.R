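# independent oracle: connected-component labelling by iterative minimum-
# label propagation over the 26-neighbourhood (no shared code with the
# package's region grower)
cc_oracle <- function(mask, start) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  labels[mask] <- seq_len(sum(mask))
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  repeat {
    changed <- FALSE
    idx <- which(mask, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      for (o in seq_len(nrow(nb))) {
        w <- v + nb[o, ]
        if (any(w < 1) || any(w > dims)) next
        if (mask[w[1], w[2], w[3]] &&
            labels[w[1], w[2], w[3]] < labels[v[1], v[2], v[3]]) {
          labels[v[1], v[2], v[3]] <- labels[w[1], w[2], w[3]]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  which(labels == labels[start[1], start[2], start[3]], arr.ind = TRUE)
}

sorted_key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))

test_that("threshold segmentation recovers exact phantom ground truth", {
  ph <- generate_phantom(phantom_spec(
    c(25, 25, 25), c(2, 2, 2), background_suv = 1,
    lesions = list(list(center = c(13, 13, 13), radius_mm = 10,
                        peak_suv = 10))))
  roi <- segment_threshold(ph$volume, c(13, 13, 13))
  # background 1 < 4.1 threshold: ROI is exactly the sphere mask
  expect_identical(sorted_key(roi$voxel_indices),
                   sorted_key(which(ph$masks[[1]], arr.ind = TRUE)))
  expect_equal(roi$mtv_cc, ph$truth_mtv_cc[1], tolerance = 1e-12)
  expect_equal(roi$tlg, roi$mtv_cc * roi$suv_mean, tolerance = 1e-12)
  expect_lte(roi$suv_mean, roi$suv_max)
})

test_that("single hot voxel yields exact hand-computed metrics", {
  arr <- array(0, c(5, 5, 5)); arr[3, 3, 3] <- 20
  roi <- segment_threshold(pet_volume(arr, c(4, 4, 4)), c(3, 3, 3))
  expect_equal(roi$mtv_cc, 0.064, tolerance = 1e-12)   # 64 mm^3
  expect_equal(roi$suv_mean, 20)
  expect_equal(roi$tlg, 1.28, tolerance = 1e-12)
})

test_that("segmentation edge cases error informatively", {
  zero <- pet_volume(array(0, c(5, 5, 5)), c(4, 4, 4))
  expect_error(segment_threshold(zero, c(2, 2, 2)), "empty lesion")
  vol <- pet_volume(array(1, c(5, 5, 5)), c(4, 4, 4))
  expect_error(segment_threshold(vol, c(9, 2, 2)), "outside the grid")
  expect_error(segment_gradient(vol, c(3, 3, 3)), "degenerate")
  # threshold just above 0 on an all-positive volume grabs the whole grid
  roi <- segment_threshold(vol, c(3, 3, 3), fraction = 1e-9)
  expect_equal(nrow(roi$voxel_indices), 125)
})

test_that("threshold segmentation matches the exhaustive labelling oracle", {
  set.seed(42)
  for (trial in 1:6) {
    arr <- array(runif(8^3, 0, 10), c(8, 8, 8))
    vol <- pet_volume(arr, c(2, 2, 2))
    seedpt <- sample(2:7, 3, replace = TRUE)
    if (arr[seedpt[1], seedpt[2], seedpt[3]] == 0) next
    roi <- segment_threshold(vol, seedpt, fraction = 0.41)
    # recompute with the oracle at the converged local max / threshold
    mask <- arr >= 0.41 * roi$suv_max
    peak <- roi$voxel_indices[which.max(arr[roi$voxel_indices]), ]
    expect_identical(sorted_key(roi$voxel_indices),
                     sorted_key(cc_oracle(mask, peak)))
  }
})

test_that("threshold fraction is monotone and SUV scaling is equivariant", {
  ph <- generate_phantom(phantom_spec(
    c(21, 21, 21), c(2, 2, 2), background_suv = 0.5,
    lesions = list(list(center = c(11, 11, 11), radius_mm = 9, peak_suv = 8,
                        profile = "gaussian")),
    noise_sd = 0.2, seed = 3L))
  fractions <- c(0.2, 0.3, 0.41, 0.6, 0.8)
  sizes <- vapply(fractions, function(f)
    nrow(segment_threshold(ph$volume, c(11, 11, 11), f)$voxel_indices),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # scaling all SUV by c > 0: identical voxel set, metrics scale by c
  roi1 <- segment_threshold(ph$volume, c(11, 11, 11))
  for (c_scale in c(0.5, 3)) {
    vol_c <- pet_volume(ph$volume$suv * c_scale, ph$volume$voxel_spacing_mm)
    roi_c <- segment_threshold(vol_c, c(11, 11, 11))
    expect_identical(sorted_key(roi_c$voxel_indices),
                     sorted_key(roi1$voxel_indices))
    expect_equal(roi_c$suv_max, c_scale * roi1$suv_max, tolerance = 1e-12)
    expect_equal(roi_c$tlg, c_scale * roi1$tlg, tolerance = 1e-12)
    expect_equal(roi_c$mtv_cc, roi1$mtv_cc, tolerance = 1e-12)
  }
})

test_that("gradient segmentation agrees with thresholding on sharp edges", {
  ph <- generate_phantom(phantom_spec(
    c(25, 25, 25), c(2, 2, 2), background_suv = 1,
    lesions = list(list(center = c(13, 13, 13), radius_mm = 10,
                        peak_suv = 10))))
  thr <- segment_threshold(ph$volume, c(13, 13, 13))
  grd <- segment_gradient(ph$volume, c(11, 13, 13))  # off-center seed
  expect_equal(grd$mtv_cc, thr$mtv_cc, tolerance = 0.10)
})

test_that("gradient ROI of a Gaussian lesion sits between 41% and support", {
  ph <- generate_phantom(phantom_spec(
    c(41, 41, 41), c(1, 1, 1), background_suv = 0.5,
    lesions = list(list(center = c(21, 21, 21), radius_mm = 10,
                        peak_suv = 10, profile = "gaussian"))))
  thr <- segment_threshold(ph$volume, c(21, 21, 21))
  grd <- segment_gradient(ph$volume, c(19, 21, 21))
  expect_gt(grd$mtv_cc, thr$mtv_cc)
  expect_lte(grd$mtv_cc, ph$truth_mtv_cc[1] * 1.05)
})

test_that("patient metrics aggregate ROIs per their invariants", {
  mk <- function(coords, smax, smean, mtv)
    structure(list(voxel_indices = coords, suv_max = smax, suv_mean = smean,
                   mtv_cc = mtv, tlg = mtv * smean), class = "lesion_roi")
  a <- mk(cbind(1:4, 1, 1), 5, 4, 1.0)
  b <- mk(cbind(1:8, 3, 3), 8, 3, 2.0)
  m <- compute_patient_metrics(list(a, b))
  expect_equal(m$global_suvmax, 8)
  expect_equal(m$total_mtv_cc, 3.0)
  expect_equal(m$total_tlg, 10.0)   # 1*4 + 2*3
  expect_equal(m$roi_count, 2)
  expect_lte(m$total_tlg, m$total_mtv_cc * m$global_suvmax)
  single <- compute_patient_metrics(list(a))
  expect_equal(single$global_suvmax, a$suv_max)
  expect_equal(single$total_tlg, a$tlg)
  expect_error(compute_patient_metrics(list()), "at least one")
  overlap <- mk(cbind(4:6, 1, 1), 2, 1, 0.5)
  expect_error(compute_patient_metrics(list(a, overlap)), "1 and 2 overlap")
})

test_that("batch metrics extraction follows the cohort schema", {
  arr <- array(0.1, c(14, 8, 8))
  arr[3, 4, 4] <- 12; arr[4, 4, 4] <- 9     # lesion 1, patient A
  arr[10, 4, 4] <- 6; arr[11, 4, 4] <- 5    # lesion 2, patient A
  arr[12, 7, 7] <- 7                        # lesion 1, patient B
  vol <- pet_volume(arr, c(2, 2, 2))
  seeds <- data.frame(patient_id = c("A", "A", "B"), lesion_id = 1:3,
                      i = c(3, 10, 12), j = c(4, 4, 7), k = c(4, 4, 7))
  res <- pet_metrics_from_seeds(vol, seeds, "threshold")
  expect_equal(nrow(res$per_lesion), 3)
  pa <- res$per_patient[res$per_patient$patient_id == "A", ]
  expect_equal(pa$n_roi, 2)
  expect_equal(pa$suvmax, 12)
  expect_equal(pa$mtv_cc, sum(res$per_lesion$mtv_cc[1:2]), tolerance = 1e-12)
})
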