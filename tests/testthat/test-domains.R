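test_that("registry enforces unique contiguous ids and valid geometry", {
  reg <- register_domains(list(
    domain_spec("a", 5, c(64, 64), "pixel"),
    domain_spec("b", 9, c(64, 64), "pixel")
  ))
  expect_s3_class(reg, "domain_registry")
  expect_equal(registry_size(reg), 2L)
  expect_equal(reg[["a"]]$domain_id, 0L)

  expect_error(register_domains(list(
    domain_spec("a", 5, c(64, 64), "pixel", domain_id = 0L),
    domain_spec("b", 5, c(64, 64), "pixel", domain_id = 0L)
  )), "duplicate")
  expect_error(register_domains(list(
    domain_spec("a", 5, c(64, 64), "pixel"),
    domain_spec("a", 5, c(64, 64), "pixel")
  )), "duplicate")
  expect_error(domain_spec("a", 5, c(60, 64), "pixel"), "divisible by 16")
  expect_error(domain_spec("a", 0, c(64, 64), "pixel"), "num_landmarks")
  expect_error(register_domains(list()), "at least one")
})

test_that("samples load from PNG/CSV and JSON with count validation", {
  dir <- withr::local_tempdir()
  set.seed(3)
  img <- matrix(runif(48 * 32), 48, 32)      # 32 wide, 48 tall
  png::writePNG(img, file.path(dir, "im.png"))
  lm <- cbind(x = c(3.5, 20, 28), y = c(5, 30.25, 40))
  write_landmarks(lm, file.path(dir, "im.csv"))
  spec <- domain_spec("t", 3, c(32, 48), "pixel")

  s <- load_sample(file.path(dir, "im.png"), file.path(dir, "im.csv"), spec)
  expect_s3_class(s, "landmark_sample")
  expect_equal(nrow(s$landmarks), 3L)
  expect_equal(unname(s$landmarks[, "x"]), lm[, "x"])
  expect_equal(s$spacing$unit, "px")
  expect_equal(dim(s$image), c(48L, 32L))
  # 8-bit PNG round trip
  expect_lt(max(abs(s$image - img)), 1 / 255)

  jsonlite::write_json(list(landmarks = lapply(seq_len(3), function(i)
    lm[i, ])), file.path(dir, "im.json"))
  s2 <- load_sample(file.path(dir, "im.png"), file.path(dir, "im.json"), spec)
  expect_equal(s2$landmarks, s$landmarks)

  bad <- domain_spec("t6", 6, c(32, 48), "pixel")
  expect_error(load_sample(file.path(dir, "im.png"),
                           file.path(dir, "im.csv"), bad), "expected 6")
})

test_that("resize maps coordinates linearly and preserves physical distances", {
  img <- matrix(runif(300 * 242), 300, 242)
  # use the full-size geometry scaled for speed: the coordinate math is the
  # same linear map regardless of the pixel data
  big <- landmark_sample(0L, matrix(0, 2400, 1935),
                         rbind(c(967.5, 1200), c(0, 0)),
                         spacing(0.1, 0.1, "mm"))
  rs <- resize_sample(big, c(416, 512))
  expect_equal(unname(rs$landmarks[1L, ]), c(208, 256))

  # identity resize leaves coordinates and spacing untouched
  s <- landmark_sample(0L, img, rbind(c(10.25, 20.5), c(100, 200)),
                       spacing(0.1, 0.2, "mm"))
  id <- resize_sample(s, c(ncol(img), nrow(img)))
  expect_identical(id$landmarks, s$landmarks)
  expect_identical(id$spacing, s$spacing)

  # halving the width doubles sx; physical distances invariant
  half <- resize_sample(s, c(ncol(img) / 2, nrow(img)))
  expect_equal(half$spacing$sx, 0.2)
  d0 <- sqrt(sum(((s$landmarks[1L, ] - s$landmarks[2L, ]) *
                    c(s$spacing$sx, s$spacing$sy))^2))
  d1 <- sqrt(sum(((half$landmarks[1L, ] - half$landmarks[2L, ]) *
                    c(half$spacing$sx, half$spacing$sy))^2))
  expect_equal(d1, d0, tolerance = 1e-12)

  # there-and-back recovers coordinates to numerical precision
  back <- resize_sample(half, c(ncol(img), nrow(img)))
  expect_lt(max(abs(back$landmarks - s$landmarks)), 1e-9)
})

test_that("wrist-width spacing follows the reference-distance formula", {
  expect_equal(hand_spacing(rbind(c(0, 0), c(50, 0)), 50, c(1, 2))$sx, 1.0)
  expect_equal(hand_spacing(rbind(c(0, 0), c(100, 0)), 50, c(1, 2))$sx, 0.5)
  # homogeneous in the reference width
  lm <- rbind(c(3, 4), c(30, 40), c(9, 9), c(1, 1), c(17, 2))
  s1 <- hand_spacing(lm, 50, c(1, 5))
  s2 <- hand_spacing(lm, 100, c(1, 5))
  expect_equal(s2$sx, 2 * s1$sx)
  expect_equal(s1$sx, s1$sy)    # isotropic
  expect_error(hand_spacing(rbind(c(1, 1), c(1, 1)), 50, c(1, 2)),
               "coincident")
})

test_that("z-score normalization gives zero mean, unit sd, zeros for flats", {
  expect_equal(zscore_normalize(matrix(5, 4, 4)), matrix(0, 4, 4))
  expect_equal(as.numeric(zscore_normalize(matrix(c(0, 2), 1, 2))),
               c(-1, 1))
  set.seed(9)
  z <- zscore_normalize(matrix(rnorm(500, 3, 7), 20, 25))
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)
})
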