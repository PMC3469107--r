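test_that("ct_volume validates geometry and clips implausible HU", {
  v <- ct_volume(array(-1000, c(3, 32, 32)), spacing = c(2.5, 0.7, 0.7))
  expect_identical(dim(v), c(3L, 32L, 32L))
  expect_error(ct_volume(array(0, c(3, 8, 8))), "16x16")
  expect_error(ct_volume(array(0, c(3, 32, 32)), spacing = c(0, 1, 1)),
               "positive")
  a <- array(0, c(1, 16, 16))
  a[1, 1, 1] <- 5000
  a[1, 2, 2] <- -2000
  expect_warning(v2 <- ct_volume(a), "clipped")
  expect_equal(v2$voxels[1, 1, 1], 3100)
  expect_equal(v2$voxels[1, 2, 2], -1100)
})

test_that("NIfTI volume round trip is lossless for grid, spacing and origin", {
  vox <- array(pmin(pmax(round(stats::rnorm(8 * 16 * 16, -500, 200)),
                         -1000), 500), c(8, 16, 16))
  v <- ct_volume(vox, spacing = c(2.5, 0.7, 0.7), origin = c(-10, 5, 2))
  path <- file.path(withr::local_tempdir(), "vol.nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_identical(v2$voxels, v$voxels)
  # geometry survives at the format's (float32 header) precision
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-6)
})

test_that("constant volume round-trips and bad output paths fail cleanly", {
  v <- ct_volume(array(-1000, c(3, 16, 16)), spacing = c(2.5, 0.7, 0.7))
  path <- file.path(withr::local_tempdir(), "const.nii.gz")
  write_volume(v, path)
  expect_identical(read_volume(path)$voxels, v$voxels)
  bad <- file.path(tempdir(), "no_such_dir_xyz", "x.nii.gz")
  expect_error(write_volume(v, bad), "directory")
  expect_false(file.exists(bad))
  expect_error(read_volume(file.path(tempdir(), "missing.nii.gz")), "exist")
})

test_that("label maps round-trip losslessly and labels are never renumbered", {
  g <- array(0L, c(4, 16, 16))
  g[1, 1:3, 1:3] <- 1L
  g[3, 5:9, 5:9] <- 5L
  lm <- label_map(g)
  expect_identical(lm$labels, c(1L, 5L))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "lm.nii.gz")
  write_labelmap(lm, path)
  lm2 <- read_labelmap(path)
  expect_identical(lm2$grid, lm$grid)
  expect_identical(lm2$labels, c(1L, 5L))

  empty <- label_map(array(0L, c(2, 16, 16)))
  p2 <- file.path(dir, "empty.nii.gz")
  write_labelmap(empty, p2)
  expect_identical(read_labelmap(p2)$grid, empty$grid)
  expect_length(read_labelmap(p2)$labels, 0)

  # a float-valued file is not a label map
  v <- ct_volume(array(0.5, c(2, 16, 16)) + array(runif(512), c(2, 16, 16)))
  p3 <- file.path(dir, "float.nii.gz")
  write_volume(v, p3)
  expect_error(read_labelmap(p3), "non-integer")
})

test_that("DICOM rescale converts stored values to HU", {
  dir <- withr::local_tempdir()
  hu <- matrix(0, 16, 16)
  hu[3, 5] <- 100  # asymmetric pattern checks row/col order too
  ptxquant:::write_dicom_slice(hu, file.path(dir, "a.dcm"),
                               position = c(0, 0, 0), slope = 1,
                               intercept = -1024)
  v <- read_volume(dir, format_hint = "dicom_dir")
  expect_equal(v$voxels[1, , ], hu)
  expect_equal(v$voxels[1, 3, 5], 100)
  expect_equal(v$voxels[1, 1, 1], 0)  # stored 1024 * 1 - 1024
})

test_that("DICOM slices sort by physical position, never filename", {
  dir <- withr::local_tempdir()
  # filenames deliberately ordered against z position
  ptxquant:::write_dicom_slice(matrix(10, 16, 16), file.path(dir, "a.dcm"),
                               position = c(0, 0, 5.0), spacing_rc = c(0.7, 0.7))
  ptxquant:::write_dicom_slice(matrix(20, 16, 16), file.path(dir, "b.dcm"),
                               position = c(0, 0, 0.0), spacing_rc = c(0.7, 0.7))
  ptxquant:::write_dicom_slice(matrix(30, 16, 16), file.path(dir, "c.dcm"),
                               position = c(0, 0, 2.5), spacing_rc = c(0.7, 0.7))
  v <- read_volume(dir)
  expect_equal(v$voxels[, 1, 1], c(20, 30, 10))  # z = 0, 2.5, 5
  expect_equal(v$spacing, c(2.5, 0.7, 0.7))
})

test_that("mixed DICOM series and missing rescale tags are rejected", {
  dir <- withr::local_tempdir()
  ptxquant:::write_dicom_slice(matrix(0, 16, 16), file.path(dir, "a.dcm"),
                               position = c(0, 0, 0), series_uid = "1.2.3.1")
  ptxquant:::write_dicom_slice(matrix(0, 16, 16), file.path(dir, "b.dcm"),
                               position = c(0, 0, 2.5), series_uid = "1.2.3.2")
  expect_error(read_volume(dir), "mixed DICOM series")

  # a slice with no rescale slope/intercept must not be silently assumed HU
  dir2 <- withr::local_tempdir()
  el <- function(...) ptxquant:::.dcm_element(...)
  sel <- function(...) ptxquant:::.dcm_str_el(...)
  uel <- function(...) ptxquant:::.dcm_us_el(...)
  px <- writeBin(rep(0L, 256), raw(), size = 2L, endian = "little")
  meta <- c(el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
            sel(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  body <- c(sel(0x0020, 0x000e, "UI", "1.2.3"),
            uel(0x0028, 0x0010, 16L), uel(0x0028, 0x0011, 16L),
            el(0x7fe0, 0x0010, "OW", px))
  writeBin(c(raw(128), charToRaw("DICM"),
             el(0x0002, 0x0000, "UL", ptxquant:::.raw_u32(length(meta))),
             meta, body),
           file.path(dir2, "norescale.dcm"))
  expect_error(read_volume(dir2), "rescale")
})

test_that("the fixture writer is readable by an independent DICOM parser", {
  has_pydicom <- tryCatch({
    out <- suppressWarnings(system2("python", c("-c", "import pydicom"),
                                    stdout = TRUE, stderr = TRUE))
    is.null(attr(out, "status"))
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!has_pydicom) {
    succeed("python/pydicom not available; cross-parser check not run")
    return(invisible())
  }
  dir <- withr::local_tempdir()
  hu <- matrix(seq(-1000, by = 1, length.out = 256), 16, 16)
  f <- file.path(dir, "x.dcm")
  ptxquant:::write_dicom_slice(hu, f, position = c(1, 2, 3),
                               spacing_rc = c(0.7, 0.8), slope = 1,
                               intercept = -1024)
  script <- sprintf(paste0(
    "import pydicom, sys\n",
    "ds = pydicom.dcmread(r'%s')\n",
    "arr = ds.pixel_array * float(ds.RescaleSlope) + float(ds.RescaleIntercept)\n",
    "print(arr[2, 4], float(ds.PixelSpacing[0]), float(ds.PixelSpacing[1]),",
    " float(ds.ImagePositionPatient[2]))\n"), f)
  sf <- file.path(dir, "check.py")
  writeLines(script, sf)
  out <- system2("python", sf, stdout = TRUE)
  vals <- as.numeric(strsplit(trimws(out[length(out)]), " +")[[1]])
  expect_equal(vals[1], hu[3, 5])
  expect_equal(vals[2:3], c(0.7, 0.8))
  expect_equal(vals[4], 3)
})
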