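test_that("crop honors the half-open ROI convention and pixel provenance", {
  set.seed(7)
  img <- random_image(10, 10)
  expect_identical(unclass(crop(img, c(0, 10, 0, 10))), unclass(img))
  sub <- crop(img, c(2, 5, 3, 7))
  expect_identical(dim(sub), c(3L, 4L, 3L))
  expect_identical(unclass(sub)[1, 1, ], unclass(img)[3, 4, ])
  for (rep in 1:20) {  # random ROI round trips
    ys <- sort(sample(0:10, 2)); xs <- sort(sample(0:10, 2))
    if (ys[1] == ys[2] || xs[1] == xs[2]) next
    s <- crop(img, c(ys, xs))
    expect_identical(dim(s)[1:2], c(ys[2] - ys[1], xs[2] - xs[1]))
    expect_identical(unclass(s)[1, 1, ], unclass(img)[ys[1] + 1, xs[1] + 1, ])
  }
})

test_that("invalid ROIs raise bounds errors naming the offending coordinate", {
  img <- random_image(10, 10)
  expect_error(crop(img, c(5, 5, 0, 10)), "empty ROI")
  expect_error(crop(img, c(0, 11, 0, 10)), "yend")
  expect_error(crop(img, c(-1, 5, 0, 10)), "ystart")
  expect_error(crop(img, c(0, 10, 0, 12)), "xend")
})

test_that("to_binary marks exactly the non-black pixels", {
  black <- raster_image(array(0L, dim = c(6, 6, 3)))
  expect_false(any(to_binary(black)))
  one <- unclass(black); one[3, 4, 2] <- 1L
  m <- to_binary(raster_image(one))
  expect_identical(sum(m), 1L)
  expect_true(m[3, 4])
  set.seed(11)
  img <- random_image(9, 13)
  x <- unclass(img)
  brute <- x[, , 1] > 0 | x[, , 2] > 0 | x[, , 3] > 0
  expect_identical(to_binary(img), brute)
})

test_that("find_contours matches the flood-fill oracle on random masks", {
  set.seed(21)
  for (rep in 1:60) {
    m <- random_mask(sample(3:12, 1), sample(3:12, 1), p = runif(1, 0.1, 0.6))
    got <- find_contours(m)
    ref <- oracle_components(m)
    expect_identical(length(got), length(ref))
    got_sets <- lapply(got, function(ct)
      sort(unname((ct$pixels[, "col"] - 1L) * nrow(m) + ct$pixels[, "row"])))
    key <- function(s) vapply(s, `[`, integer(1), 1L)
    expect_identical(got_sets[order(key(got_sets))], ref[order(key(ref))])
    expect_identical(sort(vapply(got, `[[`, integer(1), "area")),
                     sort(lengths(ref)))
  }
})

test_that("8-connectivity joins diagonals; empty masks give empty contour lists", {
  d <- matrix(FALSE, 6, 6); diag(d) <- TRUE
  expect_length(find_contours(d), 1L)
  two <- matrix(FALSE, 3, 9); two[1:3, 1:3] <- TRUE; two[1:3, 7:9] <- TRUE
  cts <- find_contours(two)
  expect_length(cts, 2L)
  expect_identical(vapply(cts, `[[`, integer(1), "area"), c(9L, 9L))
  expect_identical(find_contours(matrix(FALSE, 4, 4)), list())
})

test_that("contour_chop removes components below the threshold and is monotone", {
  m <- matrix(FALSE, 20, 30)
  m[2:11, 2:11] <- TRUE            # area 100
  m[15:19, 25] <- TRUE             # area 5
  img <- mask_to_image(m)
  chopped <- contour_chop(img, 10)
  expect_identical(to_binary(chopped), m & !(col(m) == 25))
  expect_identical(unclass(contour_chop(img, 0)), unclass(img))
  expect_false(any(to_binary(contour_chop(img, 101))))
  expect_error(contour_chop(img, -1), ">= 0")
  set.seed(31)
  for (rep in 1:10) {   # monotone: larger threshold keeps a subset
    im <- mask_to_image(random_mask(15, 15, 0.35))
    a <- to_binary(contour_chop(im, 3))
    b <- to_binary(contour_chop(im, 7))
    expect_true(all(a | !b))
  }
})

test_that("morphological opening erodes specks, keeps blocks, and is idempotent", {
  speck <- matrix(FALSE, 9, 9); speck[5, 5] <- TRUE
  expect_false(any(to_binary(morphological_open(mask_to_image(speck)))))
  block <- matrix(FALSE, 14, 14); block[3:12, 3:12] <- TRUE
  opened <- morphological_open(mask_to_image(block))
  expect_identical(to_binary(opened), block)
  set.seed(17)
  for (rep in 1:8) {
    img <- mask_to_image(random_mask(16, 16, 0.45))
    o1 <- morphological_open(img)
    expect_identical(unclass(morphological_open(o1)), unclass(o1))
    expect_true(all(to_binary(img) | !to_binary(o1)))  # opening shrinks
  }
  expect_error(morphological_open(mask_to_image(speck), kernel = 4), "odd")
  expect_error(morphological_open(mask_to_image(speck), kernel = 0), "odd")
})

test_that("contour_cut crops to qualifying components and reports the ROI", {
  m <- matrix(FALSE, 12, 14); m[3:6, 4:9] <- TRUE  # 4x6 blob
  res <- contour_cut(mask_to_image(m), min_area = 0)
  expect_identical(res$roi, c(2L, 6L, 3L, 9L))
  expect_identical(dim(res$image)[1:2], c(4L, 6L))
  # speck outside the blob's box is excluded from the box computation
  m2 <- m; m2[11, 13] <- TRUE
  res2 <- contour_cut(mask_to_image(m2), min_area = 10)
  expect_identical(res2$roi, c(2L, 6L, 3L, 9L))
  # a small component inside the qualifying box is retained: cropping only
  m3 <- matrix(FALSE, 12, 14)
  m3[3:6, 1:3] <- TRUE; m3[3:6, 10:12] <- TRUE   # two areas of 12 (> 10)
  m3[4, 6] <- TRUE                               # speck between them
  res3 <- contour_cut(mask_to_image(m3), min_area = 10)
  expect_identical(res3$roi, c(2L, 6L, 0L, 12L))
  expect_identical(sum(to_binary(res3$image)), sum(m3))
  # padding clamps at the image border
  resp <- contour_cut(mask_to_image(m), min_area = 0, padding = 3)
  expect_identical(resp$roi, c(0L, 9L, 0L, 12L))
})

test_that("contour_cut raises an empty-plant error carrying component areas", {
  m <- matrix(FALSE, 8, 8); m[2:3, 2:3] <- TRUE
  err <- tryCatch(contour_cut(mask_to_image(m), min_area = 10),
                  error = function(e) e)
  expect_s3_class(err, "empty_plant_error")
  expect_match(conditionMessage(err), "empty plant")
  expect_identical(err$areas, 4L)
  expect_s3_class(tryCatch(contour_cut(mask_to_image(matrix(FALSE, 4, 4)), 0),
                           error = function(e) e), "empty_plant_error")
})

test_that("every operator propagates an all-background image except contour_cut", {
  black <- raster_image(array(0L, dim = c(8, 8, 3)))
  expect_identical(unclass(color_filter(black, "g > b")), unclass(black))
  expect_identical(unclass(contour_chop(black, 5)), unclass(black))
  expect_identical(unclass(morphological_open(black)), unclass(black))
  expect_error(contour_cut(black, 0), class = "empty_plant_error")
})
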