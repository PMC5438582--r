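test_that("NIfTI round-trip preserves HU values and spacing", {
  vol <- tiny_volume(c(6, 7, 8), spacing = c(2, 2, 3))
  vol$voxels[3, 4, 5] <- 100
  vol$voxels[1, 1, 1] <- -1000
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    save_volume(vol, path)
    back <- load_volume(path, format = "nifti")
    expect_identical(back$voxels, vol$voxels)
    expect_equal(back$spacing, vol$spacing)
    unlink(path)
  }
})

test_that("NIfTI writer agrees with an independent reader (nibabel)", {
  vol <- tiny_volume(c(4, 5, 6), spacing = c(0.8, 0.8, 3))
  vol$voxels[2, 3, 4] <- 55
  path <- tempfile(fileext = ".nii")
  save_volume(vol, path)
  script <- paste(
    "import nibabel, sys",
    sprintf("img = nibabel.load('%s')", path),
    "d = img.get_fdata()",
    "print(d.shape[0], d.shape[1], d.shape[2])",
    "print(float(d[3, 2, 1]))",   # disk [x,y,z] = internal [col,row,slice]
    "print(*[round(float(z), 5) for z in img.header.get_zooms()])",
    sep = "; ")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  expect_equal(as.numeric(strsplit(out[1], " ")[[1]]), c(6, 5, 4))
  expect_equal(as.numeric(out[2]), 55)
  expect_equal(as.numeric(strsplit(out[3], " ")[[1]]),
               c(0.8, 0.8, 3), tolerance = 1e-5)
  unlink(path)
})

test_that("DICOM series round-trip applies rescale and orders slices", {
  vol <- tiny_volume(c(5, 6, 7), hu = 0, spacing = c(2, 2, 3))
  vol$voxels[] <- round(matrix(rnorm(prod(dim(vol$voxels)), -90, 50)))
  dir <- tempfile("dcm")
  save_volume(vol, dir, format = "dicom_dir")
  expect_length(list.files(dir, pattern = "\\.dcm$"), 5L)
  back <- load_volume(dir, format = "dicom_dir")
  expect_equal(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing)
  # RescaleIntercept -1024 with raw 1024 is HU 0
  one <- ctcomp:::read_dicom_file(list.files(dir, full.names = TRUE)[1])
  expect_true(all(abs(one$pixels - vol$voxels[1, , ]) < 1e-9))
  unlink(dir, recursive = TRUE)
})

test_that("DICOM reader errors name missing rescale tags and mixed spacing", {
  vol <- tiny_volume(c(3, 4, 4))
  dir <- tempfile("dcm")
  save_volume(vol, dir, format = "dicom_dir")
  f1 <- file.path(dir, "slice_0001.dcm")
  bytes <- readBin(f1, "raw", file.size(f1))
  # excise the (0028,1052) RescaleIntercept element (8-byte header + "-1024\0")
  tag <- as.raw(c(0x28, 0x00, 0x52, 0x10))
  pos <- which(bytes[-(1:131)] == tag[1])
  hit <- pos[vapply(pos, function(p) all(bytes[131 + p + 0:3] == tag), TRUE)][1]
  start <- 131 + hit
  writeBin(bytes[-(start:(start + 13L))], f1)
  expect_error(read_dicom_series(dir), "0028,1052")
  unlink(dir, recursive = TRUE)

  dir2 <- tempfile("dcm")
  save_volume(vol, dir2, format = "dicom_dir")
  # rewrite one slice with different pixel spacing
  ctcomp:::write_dicom_slice(vol$voxels[2, , ], spacing = c(5, 5, 1), z = 1,
                    instance = 2, path = file.path(dir2, "slice_0002.dcm"))
  expect_error(read_dicom_series(dir2), "mixed")
  unlink(dir2, recursive = TRUE)
})

test_that("femoral_fraction_slice interpolates from the distal end", {
  lm <- landmark_set(10, 20, femur_proximal = 200, femur_distal = 100,
                     n_slices = 300)
  expect_identical(femoral_fraction_slice(lm, 0.5), 150L)
  expect_identical(femoral_fraction_slice(lm, 0.15), 115L)
  lm2 <- landmark_set(10, 20, femur_proximal = 139, femur_distal = 40)
  expect_identical(femoral_fraction_slice(lm2, 0.85), 124L)  # 124.15 rounds
  expect_error(femoral_fraction_slice(lm, 1.2), "fraction")
  # monotone in fraction, in both axial orientations
  for (lmx in list(lm, landmark_set(1, 2, femur_proximal = 40,
                                    femur_distal = 139))) {
    idx <- vapply(seq(0, 1, by = 0.05),
                  function(f) femoral_fraction_slice(lmx, f), 0L)
    d <- diff(idx) * sign(lmx$femur_proximal - lmx$femur_distal)
    expect_true(all(d >= 0))
  }
})

test_that("voxel volume and container invariants", {
  expect_equal(voxel_volume_liters(tiny_volume(spacing = c(1, 1, 1))), 1e-6)
  expect_equal(voxel_volume_liters(tiny_volume(spacing = c(2, 2, 3))),
               1.2e-5)
  expect_equal(voxel_volume_liters(tiny_volume(spacing = c(0.8, 0.8, 3))),
               1.92e-6)
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(ct_volume(array(5000, c(2, 2, 2)), c(1, 1, 1)), "HU")
  expect_error(landmark_set(1, 2, 5, 5), "positive length")
  expect_error(landmark_set(1, 2, 50, 40, n_slices = 45), "bounds")
})

test_that("landmark files parse and validate", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# subject 1", "l3l4: 30", "l4l5: 40",
               "femur_proximal: 60", "femur_distal: 120"), path)
  lm <- read_landmarks(path, n_slices = 128)
  expect_identical(lm$l4l5, 40)
  writeLines(c("l3l4: 30", "l4l5: 40"), path)
  expect_error(read_landmarks(path), "femur_proximal")
  unlink(path)
})
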