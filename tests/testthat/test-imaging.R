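test_that("geometric transforms preserve shape, range and identities", {
  set.seed(14)
  m <- matrix(runif(32 * 32), 32, 32)
  expect_equal(img_rotate(m, 0), m, tolerance = 1e-12)
  expect_equal(img_shear(m, 0, 0), m, tolerance = 1e-12)
  expect_equal(img_translate(m, 0, 0), m, tolerance = 1e-12)
  expect_equal(img_rescale(m, 1), m, tolerance = 1e-12)
  expect_identical(img_reflect(img_reflect(m, "x"), "x"), m)
  expect_identical(img_reflect(img_reflect(m, "y"), "y"), m)
  for (out in list(img_rotate(m, 37), img_shear(m, 0.1, -0.1),
                   img_translate(m, 2.5, -1.5), img_rescale(m, 0.9))) {
    expect_equal(dim(out), c(32L, 32L))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("90-degree rotation matches the index-permutation oracle", {
  set.seed(15)
  m <- matrix(runif(16 * 16), 16, 16)
  r90 <- img_rotate(m, 90)
  n <- nrow(m)
  oracle <- matrix(0, n, n)
  for (rp in 1:n) for (cp in 1:n) oracle[rp, cp] <- m[cp, n + 1 - rp]
  expect_equal(r90, oracle, tolerance = 1e-10)
  # four quarter turns restore the image
  r360 <- img_rotate(img_rotate(img_rotate(r90, 90), 90), 90)
  expect_equal(r360, m, tolerance = 1e-10)
})

test_that("integer translation is an exact shift with background fill", {
  m <- matrix(0.5, 8, 8)
  m[3, 4] <- 1
  tr <- img_translate(m, dx = 2, dy = 1)
  expect_equal(tr[4, 6], 1)
  expect_equal(tr[3, 4], 0.5)
})

test_that("salt-and-pepper corrupts exactly the requested pixel count", {
  set.seed(16)
  m <- matrix(runif(100 * 100, 0.3, 0.7), 100, 100)
  expect_identical(salt_pepper(m, 0), m)
  sp <- salt_pepper(m, 0.05)
  expect_equal(sum(sp != m), 500)
  expect_true(all(sp[sp != m] %in% c(0, 1)))
  all_noise <- salt_pepper(m, 1)
  expect_true(all(all_noise %in% c(0, 1)))
})

test_that("augmentation reaches the target count, keeps originals and labels", {
  d <- tiny_smear_data(6, seed = 20)          # 12 images
  aug <- augment_dataset(d, 40, seed = 77)
  expect_equal(nrow(aug), 40)
  expect_equal(sum(aug$provenance == "synthetic"), 12)
  # class ratio within one image of the balanced source
  tab <- table(aug$label)
  expect_lte(abs(tab[1] - tab[2]), 1)
  # all outputs remain valid images with the source labels
  expect_true(all(vapply(aug$image, function(im) all(im >= 0 & im <= 1),
                         logical(1))))
  # identical seed reproduces the set; target == input returns unchanged
  aug2 <- augment_dataset(d, 40, seed = 77)
  expect_identical(aug$image, aug2$image)
  same <- augment_dataset(d, nrow(d))
  expect_identical(same$image, d$image)
  expect_error(augment_dataset(d, 5), "below the input size")
})

test_that("synthetic smears are balanced, deterministic and separable", {
  d <- generate_synthetic_smears(50, seed = 123)
  expect_equal(nrow(d), 100)
  expect_equal(as.numeric(table(d$label)), c(50, 50))
  expect_true(all(vapply(d$image, function(im) all(im >= 0 & im <= 1),
                         logical(1))))
  d2 <- generate_synthetic_smears(50, seed = 123)
  expect_identical(d$image, d2$image)
  # blast-class dark-nucleus area exceeds lymphocyte-class area
  areas <- vapply(d$image, nucleus_area_fraction, numeric(1))
  expect_gt(mean(areas[d$label == "leukemic"]),
            mean(areas[d$label == "normal"]))
  # area interval separation built into the generator
  expect_gt(min(areas[d$label == "leukemic"]),
            max(areas[d$label == "normal"]))
})

test_that("smear config rejects overlapping class radius intervals", {
  expect_error(smear_config(blast_radius = c(0.1, 0.2),
                            lymph_radius = c(0.15, 0.25)),
               "strictly above")
})

test_that("the area-threshold baseline clears 80% on default synthetic data", {
  d <- generate_synthetic_smears(100, seed = 9)
  clf <- train_area_classifier(d)
  expect_gt(clf$train_accuracy, 0.8)
  held <- generate_synthetic_smears(50, seed = 10)
  acc <- mean(predict(clf, held) == held$label)
  expect_gt(acc, 0.8)
})

test_that("capsnet input resizing produces the flattened matrix form", {
  d <- tiny_smear_data(3, seed = 30)
  arch <- capsnet_architecture()
  X <- as_capsnet_input(d, arch)
  expect_equal(dim(X), c(6L, 256L))
  expect_true(all(X >= 0 & X <= 1))
  # an image already at target size is passed through unchanged
  m <- matrix(runif(256), 16, 16)
  expect_equal(as.vector(as_capsnet_input(m, arch)), as.vector(m))
})

test_that("class-per-directory datasets read back with luminance conversion", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "normal"))
  dir.create(file.path(root, "leukemic"))
  # grayscale PNG round-trips its pixel values
  gray <- matrix(seq(0, 1, length.out = 64), 8, 8)
  png::writePNG(gray, file.path(root, "normal", "a.png"))
  # RGB PNG is converted to luminance
  rgb <- array(0, c(8, 8, 3))
  rgb[, , 1] <- 1   # pure red
  png::writePNG(rgb, file.path(root, "leukemic", "b.png"))
  # CSV pixel matrix
  utils::write.csv(gray, file.path(root, "leukemic", "c.csv"),
                   row.names = FALSE)
  d <- read_image_dataset(root)
  expect_equal(nrow(d), 3)
  expect_equal(levels(d$label), c("leukemic", "normal"))
  g <- d$image[[which(d$label == "normal")]]
  expect_equal(g, gray, tolerance = 1e-2)   # 8-bit quantization
  red <- d$image[[1]]
  expect_equal(unique(round(as.vector(red), 3)), 0.299)
  expect_error(read_image_dataset(file.path(root, "normal")),
               "no class sub-directories")
})

test_that("VOC annotations round-trip and errors are raised for bad input", {
  objs <- tibble::tibble(
    label = c("blast", "lymphocyte"),
    xmin = c(10L, 200L), ymin = c(20L, 220L),
    xmax = c(110L, 260L), ymax = c(130L, 300L)
  )
  path <- withr::local_tempfile(fileext = ".xml")
  write_voc_annotations(objs, path, filename = "smear001.jpg",
                        width = 2592, height = 1944)
  back <- read_voc_annotations(path)
  expect_equal(as.data.frame(back), as.data.frame(objs))

  # empty annotation file
  empty <- tibble::tibble(label = character(), xmin = integer(),
                          ymin = integer(), xmax = integer(),
                          ymax = integer())
  path2 <- withr::local_tempfile(fileext = ".xml")
  write_voc_annotations(empty, path2)
  expect_equal(nrow(read_voc_annotations(path2)), 0)

  # malformed XML and invalid boxes are errors naming the file
  path3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<annotation><object>", path3)
  expect_error(read_voc_annotations(path3), "failed to parse")
  bad <- tibble::tibble(label = "x", xmin = 50L, ymin = 1L,
                        xmax = 50L, ymax = 10L)
  path4 <- withr::local_tempfile(fileext = ".xml")
  expect_error(write_voc_annotations(bad, path4), "min must be below max")
  path5 <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0("<annotation><object><name>x</name><bndbox>",
                    "<xmin>90</xmin><ymin>1</ymin><xmax>10</xmax>",
                    "<ymax>20</ymax></bndbox></object></annotation>"), path5)
  expect_error(read_voc_annotations(path5), "invalid box")
})
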