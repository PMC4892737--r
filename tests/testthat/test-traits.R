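test_that("raw moments match hand-computed single- and four-pixel cases", {
  m <- matrix(FALSE, 8, 8); m[5, 4] <- TRUE        # (row 4, col 3), 0-based
  M <- raw_moments(m)
  expect_identical(M["M0", "M0"], 1)
  expect_identical(M["M1", "M0"], 3)                # M10 = x
  expect_identical(M["M0", "M1"], 4)                # M01 = y
  expect_identical(M["M1", "M1"], 12)
  sq <- matrix(FALSE, 4, 4); sq[1:2, 1:2] <- TRUE   # rows/cols {0,1}
  Ms <- raw_moments(sq)
  expect_identical(Ms["M0", "M0"], 4)
  expect_identical(Ms["M1", "M0"], 2)
  expect_identical(Ms["M0", "M1"], 2)
  expect_identical(Ms["M1", "M1"], 1)
})

test_that("raw moments equal the double-loop oracle on random masks", {
  set.seed(53)
  for (rep in 1:25) {
    m <- random_mask(sample(10:50, 1), sample(10:50, 1), runif(1, 0.05, 0.5))
    expect_identical(unname(unclass(raw_moments(m))), oracle_moments(m))
  }
})

test_that("moments obey the exact integer-translation rule", {
  set.seed(59)
  for (rep in 1:10) {
    m <- matrix(FALSE, 40, 40)
    m[5:20, 5:20] <- random_mask(16, 16, 0.4)
    dx <- sample(1:10, 1); dy <- sample(1:10, 1)
    shifted <- matrix(FALSE, 40, 40)
    shifted[(5 + dy):(20 + dy), (5 + dx):(20 + dx)] <- m[5:20, 5:20]
    M0 <- raw_moments(m); M1 <- raw_moments(shifted)
    expect_equal(M1["M1", "M0"], M0["M1", "M0"] + dx * M0["M0", "M0"])
    expect_equal(M1["M0", "M1"], M0["M0", "M1"] + dy * M0["M0", "M0"])
    com0 <- center_of_mass(m); com1 <- center_of_mass(shifted)
    expect_equal(unname(com1 - com0), c(dx, dy))
  }
})

test_that("centroid, dimensions, and area handle point and box cases", {
  one <- matrix(FALSE, 8, 8); one[5, 4] <- TRUE
  expect_equal(center_of_mass(one), c(x = 3, y = 4))
  expect_identical(unname(mask_dimensions(one)), c(1L, 1L))
  blob <- matrix(FALSE, 10, 12); blob[3:6, 4:9] <- TRUE
  expect_identical(unname(mask_dimensions(blob)), c(4L, 6L))
  sym <- matrix(FALSE, 21, 21); sym[9:13, 9:13] <- TRUE
  expect_equal(unname(center_of_mass(sym)), c(10, 10))
  expect_identical(pixel_area(matrix(FALSE, 3, 3)), 0L)
  expect_identical(pixel_area(matrix(TRUE, 10, 10)), 100L)
  expect_error(center_of_mass(matrix(FALSE, 2, 2)), "empty")
  expect_error(mask_dimensions(matrix(FALSE, 2, 2)), "empty")
  set.seed(61)
  for (rep in 1:10) {
    m <- random_mask(20, 20, 0.3)
    expect_identical(as.numeric(pixel_area(m)), raw_moments(m)["M0", "M0"])
  }
})

test_that("projected shoot area is the sum of the two side views", {
  expect_identical(projected_shoot_area(0, 0), 0)
  expect_identical(projected_shoot_area(1200, 1350), 2550)
  expect_identical(projected_shoot_area(1350, 1200),
                   projected_shoot_area(1200, 1350))  # view order irrelevant
  expect_error(projected_shoot_area(-1, 5), ">= 0")
})

test_that("convex hull area matches the brute-force membership oracle", {
  set.seed(67)
  for (rep in 1:12) {
    m <- random_mask(sample(6:14, 1), sample(6:14, 1), 0.3)
    if (sum(m) < 3) next
    ref <- oracle_hull_area(m)
    if (is.null(ref)) next
    got <- convex_hull_metrics(m)
    expect_identical(got$hull_area, ref)
    expect_gte(got$hull_area, pixel_area(m))
    expect_gt(got$density, 0); expect_lte(got$density, 1)
  }
})

test_that("filled rectangles have density exactly one; sparse frames do not", {
  rect <- matrix(FALSE, 15, 20); rect[4:12, 3:17] <- TRUE
  ch <- convex_hull_metrics(rect)
  expect_identical(ch$hull_area, sum(rect))
  expect_equal(ch$density, 1)
  corners <- matrix(FALSE, 10, 10)
  corners[1, 1] <- corners[10, 10] <- corners[1, 10] <- corners[10, 1] <- TRUE
  ch2 <- convex_hull_metrics(corners)
  expect_identical(ch2$hull_area, 100L)
  expect_equal(ch2$density, 0.04)
  line <- matrix(FALSE, 8, 8); line[3, 2:7] <- TRUE  # collinear foreground
  expect_identical(convex_hull_metrics(line)$hull_area, 6)
  expect_equal(convex_hull_metrics(line)$density, 1)
})

test_that("color histogram counts foreground pixels into fixed-width bins", {
  green <- raster_image(array(rep(c(0L, 200L, 0L), each = 20), dim = c(4, 5, 3)))
  h <- color_histogram(green, matrix(TRUE, 4, 5))
  expect_identical(unname(h$counts[, "g"]), c(0L, 0L, 0L, 0L, 0L, 0L, 20L, 0L))
  expect_identical(colSums(h$counts), c(r = 20, g = 20, b = 20))
  he <- color_histogram(green, matrix(FALSE, 4, 5))
  expect_true(he$empty)
  expect_true(all(he$counts == 0L))
  expect_true(all(is.na(he$proportions)))
  expect_error(color_histogram(green, matrix(TRUE, 4, 5), bins = 7), "divide")
  set.seed(71)
  for (rep in 1:8) {
    img <- random_image(10, 10)
    mask <- random_mask(10, 10, 0.5)
    h <- color_histogram(img, mask)
    expect_equal(unname(colSums(h$counts)), rep(sum(mask), 3))
    if (sum(mask) > 0)
      expect_equal(unname(colSums(h$proportions)), rep(1, 3), tolerance = 1e-9)
    x <- unclass(img)   # brute-force recount of one bin
    expect_identical(h$counts[3, "r"], sum(x[, , 1][mask] %/% 32L == 2L))
  }
})

test_that("composite traits hit the documented identities on square fixtures", {
  sq <- matrix(TRUE, 10, 10)
  tr <- composite_traits(sq, sq, sq)
  val <- function(nm) tr$value[tr$trait == nm]
  expect_equal(val("GH1"), 1)
  expect_equal(val("Den1_SV"), 1)
  expect_equal(val("Den2_SV"), 1)
  expect_equal(val("PSA"), 200)
  expect_equal(val("PSA"), projected_shoot_area(pixel_area(sq), pixel_area(sq)))
  expect_equal(val("CA_SV"), 100)
  expect_equal(val("M00_TV"), 100)
  expect_error(composite_traits(sq, NULL, sq), "sv90")
})

test_that("ratio traits stay in range over random synthetic plants", {
  for (s in 1:25) {
    g0 <- generate_plant_image(plant_spec(1000 + s))
    g1 <- generate_plant_image(plant_spec(2000 + s))
    gt <- generate_plant_image(plant_spec(3000 + s))
    tr <- composite_traits(g0$truth$mask, g1$truth$mask, gt$truth$mask)
    val <- function(nm) tr$value[tr$trait == nm]
    for (nm in c("Den1_SV", "Den1_TV", "Den2_SV", "Den2_TV", "Den3_SV",
                 "Den3_TV", "GH2", "GH3", "GH4")) {
      expect_gte(val(nm), 0)
      expect_lte(val(nm), 1)
    }
    expect_gt(val("GH1"), 0)
    expect_equal(val("PSA"), g0$truth$count + g1$truth$count)
  }
})

test_that("traits are invariant to background padding except the centroid", {
  set.seed(83)
  m <- matrix(FALSE, 30, 30); m[8:22, 10:20] <- random_mask(15, 11, 0.6)
  if (!any(m)) m[10, 12] <- TRUE
  pad <- matrix(FALSE, 40, 42); pad[6:35, 7:36] <- m  # pad by (5, 6)
  a <- extract_base_traits(m); b <- extract_base_traits(pad)
  for (nm in c("area", "height", "width", "hull_area", "density", "elongation"))
    expect_equal(b[[nm]], a[[nm]], info = nm)
  expect_equal(b[["centroid_y"]], a[["centroid_y"]] + 5)
  expect_equal(b[["centroid_x"]], a[["centroid_x"]] + 6)
})
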