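test_that("PSNR has its closed form, infinite marker, and noise monotonicity", {
  img <- matrix(100, 16, 16)
  expect_identical(psnr(img, img), Inf)

  offset <- img + 16
  expect_equal(psnr(img, offset), 20 * log10(255 / 16), tolerance = 1e-12)

  set.seed(1)
  base <- matrix(runif(32 * 32, 60, 200), 32, 32)
  lo <- add_noise(base, "gaussian", 5)
  hi <- add_noise(lo, "gaussian", 10)   # nested: strictly more corrupted
  expect_gt(psnr(base, lo), psnr(base, hi))

  expect_error(psnr(img, matrix(0, 8, 8)), "dimensions differ")
})

test_that("noise injection matches its models", {
  img <- matrix(128, 40, 40)
  expect_identical(add_noise(img, "gaussian", 0), img)

  set.seed(2)
  sp <- add_noise(img, "salt-pepper", 1)
  expect_true(all(sp %in% c(0, 255)))

  # gaussian moment check away from clip boundaries
  set.seed(3)
  sds <- replicate(10, sd(add_noise(img, "gaussian", 10) - img))
  expect_lt(abs(mean(sds) - 10), 1)
})

test_that("filters preserve constants, reject salt, and approach identity", {
  flat <- matrix(77, 12, 12)
  expect_equal(apply_filter(flat, filter_spec("median", 2)), flat)
  expect_equal(apply_filter(flat, filter_spec("weighted", 1, 5)), flat)

  salted <- flat
  salted[6, 6] <- 255
  cleaned <- apply_filter(salted, filter_spec("median", 1))
  expect_equal(cleaned[6, 6], 77)

  # weighted local mean tends to the identity as the center weight grows;
  # use a smooth image so the neighbour term is representative
  grad <- outer(1:32, 1:32, function(i, j) (i + j) * 3)
  out <- apply_filter(grad, filter_spec("weighted", 1, 1e3))
  expect_lt(max(abs(out - grad)), 1)

  expect_error(apply_filter(matrix(0, 3, 3), filter_spec("median", 2)),
               "window larger")
})

test_that("filter outputs stay within the declared intensity range", {
  set.seed(4)
  img <- matrix(runif(400, 0, 255), 20, 20)
  for (sp in list(filter_spec("median", 1), filter_spec("weighted", 2, 3))) {
    out <- apply_filter(img, sp)
    expect_true(all(out >= 0 & out <= 255))
  }
})

test_that("filter optimization improves a salt-and-pepper phantom", {
  ph <- make_phantom()
  set.seed(0)
  noisy <- add_noise(ph$image, "salt-pepper", 0.05)

  # degenerate input returns the infinite marker immediately
  clean <- optimize_filter(ph$image, ph$image)
  expect_identical(clean$psnr_db, Inf)

  cfg <- optimizer_config(dimensionality = 3, iterations = 8, seed = 0,
                          use_ga_seeding = FALSE, sharing_radius = "off")
  opt <- optimize_filter(noisy, ph$image, config = cfg)
  expect_gte(opt$psnr_db, opt$noisy_psnr_db)
  expect_s3_class(opt$spec, "filter_spec")
})

test_that("segmentation recovers disk geometry and splits touching nodules", {
  expect_equal(segment_nodules(matrix(0, 32, 32))$region_count, 0L)

  ph <- make_phantom()
  seg <- segment_nodules(ph$image)
  expect_equal(seg$region_count, 3L)
  # each segmented region overlaps exactly one true disk with IoU >= 0.9,
  # and its boundary trace encloses that disk's center
  for (k in 1:3) {
    ious <- sapply(1:3, function(g)
      sum(seg$labels == k & ph$mask == g) /
        sum(seg$labels == k | ph$mask == g))
    expect_gte(max(ious), 0.9)
  }

  # touching disks, centers farther apart than their radii: thresholding
  # alone gives one component, the watershed yields two regions
  sp <- phantom_spec(nodules = list(
    list(center = c(60, 54), radius = 10, intensity = 200),
    list(center = c(60, 70), radius = 10, intensity = 200)),
    allow_overlap = TRUE)
  ph2 <- make_phantom(sp)
  bin <- ph2$image > otsu_threshold(ph2$image)
  expect_equal(max(igwolf:::label_components(bin)), 1L)
  expect_equal(segment_nodules(ph2$image)$region_count, 2L)
})

test_that("boundary traces are closed 8-connected rim paths", {
  ph <- make_phantom()
  seg <- segment_nodules(ph$image)
  for (b in seg$boundaries) {
    steps <- pmax(abs(diff(b$row)), abs(diff(b$col)))
    expect_true(all(steps <= 1))
    n <- nrow(b)
    expect_lte(max(abs(b$row[1] - b$row[n]), abs(b$col[1] - b$col[n])), 1)
    # every trace pixel lies on its region's rim
    for (i in seq_len(n))
      expect_gt(seg$labels[b$row[i], b$col[i]], 0)
  }
})

test_that("histogram-based segmentation is invariant to intensity rescaling", {
  ph <- make_phantom()
  s1 <- segment_nodules(ph$image)
  s2 <- segment_nodules(ph$image * 2.5)
  expect_identical(s1$labels, s2$labels)
})

test_that("PGM round-trips images through plain text", {
  ph <- make_phantom(phantom_spec(side = 32L, nodules = list(
    list(center = c(16, 16), radius = 6, intensity = 210))))
  path <- tempfile(fileext = ".pgm")
  write_pgm(ph$image, path)
  back <- read_pgm(path)
  expect_equal(back, ph$image)
})
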