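# Generator: populations, the drift law, rendering, dataset writing.

test_that("make_population respects counts, stages, uniqueness, determinism", {
  pop <- make_population(8, 4, 5, seed = 7)
  expect_length(pop, 17)
  stages <- vapply(pop, `[[`, "", "life_stage")
  expect_equal(sum(stages == "adult"), 8)
  expect_equal(sum(stages == "juvenile"), 4)
  expect_equal(sum(stages == "neonate"), 5)
  ids <- vapply(pop, `[[`, "", "shark_id")
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(vapply(pop, function(s) s$n_spots >= 1, TRUE)))
  # adults never drift, immature stages do
  dr <- vapply(pop, `[[`, 0, "drift_rate")
  expect_equal(unname(dr[stages == "adult"]), rep(0, 8))
  expect_equal(unname(dr[stages == "juvenile"]), rep(0.02, 4))
  expect_equal(unname(dr[stages == "neonate"]), rep(0.08, 5))

  expect_length(make_population(0, 0, 0, seed = 1), 0)
  expect_error(make_population(-1, 0, 0, seed = 1), "counts")
  expect_identical(make_population(2, 1, 1, seed = 3),
                   make_population(2, 1, 1, seed = 3))
})

test_that("drift law: zero-rate fixed point, determinism, survival fraction", {
  pop <- make_population(1, 0, 1, seed = 21)
  adult <- pop[[1]]; neonate <- pop[[2]]
  base <- drift_pattern(adult, 0)
  for (t in c(1, 4, 9)) expect_identical(drift_pattern(adult, t), base)
  expect_identical(drift_pattern(neonate, 5), drift_pattern(neonate, 5))

  # survival of original spots after t steps is Binomial(n, (1-rate)^t):
  # pool survivors over many independent sharks and check the 99% CI
  t <- 3; rate <- 0.08
  survived <- 0L; total <- 0L
  pop2 <- make_population(0, 0, 60, seed = 77)
  for (spec in pop2) {
    s0 <- drift_pattern(spec, 0); st <- drift_pattern(spec, t)
    survived <- survived + sum(st$id %in% s0$id)
    total <- total + nrow(s0)
  }
  p_hat <- survived / total
  p_exp <- (1 - rate)^t
  se <- sqrt(p_exp * (1 - p_exp) / total)
  expect_lt(abs(p_hat - p_exp), 2.58 * se + 1e-12)
})

test_that("drift displacement matches the Monte-Carlo oracle of the walk", {
  # oracle: direct simulation of the stated random walk (per-axis Gaussian
  # steps of sd rate*L), independent of drift_pattern's implementation
  rate <- 0.08; L <- 110; t <- 5
  oracle <- patchid:::with_seed(1234, {
    n <- 4000
    dx <- matrix(rnorm(n * t, 0, rate * L), n, t)
    dy <- matrix(rnorm(n * t, 0, rate * L), n, t)
    mean(sqrt(rowSums(dx)^2 + rowSums(dy)^2))
  })
  # implementation: displacement of surviving spots, pooled over sharks
  pop <- make_population(0, 0, 50, seed = 31)
  disp <- unlist(lapply(pop, function(spec) {
    spec$drift_rate <- rate; spec$body_length <- L
    s0 <- drift_pattern(spec, 0); st <- drift_pattern(spec, t)
    keep <- st$id %in% s0$id
    m0 <- s0[match(st$id[keep], s0$id), ]
    sqrt((st$x[keep] - m0$x)^2 + (st$y[keep] - m0$y)^2)
  }))
  se <- sd(disp) / sqrt(length(disp))
  expect_gt(length(disp), 500)
  expect_lt(abs(mean(disp) - oracle), 3 * se)
})

test_that("render: nuisance-only variation, adult stability, box angles", {
  pop <- make_population(1, 0, 0, seed = 3)
  cfg1 <- patchid:::render_config(view_angle = 20, render_seed = 1,
                                  noise_sd = 0.02)
  cfg2 <- patchid:::render_config(view_angle = 20, render_seed = 2,
                                  noise_sd = 0.02)
  s1 <- render(pop[[1]], 0, cfg1); s2 <- render(pop[[1]], 0, cfg2)
  expect_identical(s1$mask, s2$mask)          # geometry fixed
  expect_false(identical(s1$image, s2$image)) # noise differs

  # adult spot layer is pixel-identical across time
  cfg <- patchid:::render_config(view_angle = 45, render_seed = 9)
  expect_identical(render(pop[[1]], 0, cfg)$image,
                   render(pop[[1]], 4, cfg)$image)

  # box angle equals the view angle (mod 360), all four boxes
  for (ang in c(0, 33.25, 180, 271.5)) {
    cfgA <- patchid:::render_config(view_angle = ang, render_seed = 1)
    s <- render(pop[[1]], 0, cfgA)
    for (b in s$boxes)
      expect_lt(abs(b$angle - (ang %% 360) * pi / 180), 1e-6)
  }

  # every spot pixel inside the mask; boxes inside the dilated mask bbox
  s <- render(pop[[1]], 0, patchid:::render_config(view_angle = 30,
                                                   render_seed = 2))
  dark <- which(s$image[, , 1] > 0 & s$image[, , 1] < 0.3, arr.ind = TRUE)
  expect_true(all(s$mask[dark] == 1))
  bb <- which(s$mask == 1, arr.ind = TRUE)
  pad <- 0.1 * c(diff(range(bb[, 1])), diff(range(bb[, 2])))
  for (b in s$boxes) {
    cs <- c(cos(b$angle), sin(b$angle))
    corners_x <- b$cx + c(-1, 1, 1, -1) * b$w / 2 * cs[1] -
      c(-1, -1, 1, 1) * b$h / 2 * cs[2]
    corners_y <- b$cy + c(-1, 1, 1, -1) * b$w / 2 * cs[2] +
      c(-1, -1, 1, 1) * b$h / 2 * cs[1]
    expect_true(all(corners_y + 1 >= min(bb[, 1]) - pad[1] &
                    corners_y + 1 <= max(bb[, 1]) + pad[1]))
    expect_true(all(corners_x + 1 >= min(bb[, 2]) - pad[2] &
                    corners_x + 1 <= max(bb[, 2]) + pad[2]))
  }

  # body must fit
  big <- pop[[1]]; big$body_length <- 400
  expect_error(render(big, 0, cfg), "fit")
})

test_that("write_dataset: counts, markers, determinism, round-trips", {
  fx <- fixture_dataset()
  mf <- fx$manifest
  # 4 sharks x (3 baseline + 2 time)
  expect_equal(nrow(mf), 4 * 5)
  expect_equal(sum(mf$series == "baseline"), 12)
  for (sid in unique(mf$shark_id))
    expect_setequal(mf$time_marker[mf$shark_id == sid & mf$series == "time"],
                    c("T0", "T1"))
  # all annotation XMLs round-trip with tiny coordinate error
  for (i in seq_len(nrow(mf))) {
    boxes <- read_rolabelimg(mf$annotation_path[i])
    expect_setequal(names(boxes), c("head", "pec", "FDF", "FDB"))
  }
  # manifest re-write determinism
  d2 <- file.path(tempdir(), "patchid_fixture_rerun")
  mp2 <- write_dataset(fx$population, 3, 2, d2, seed = 5,
                       time_replicates = 1, image_size = c(192, 192))
  m1 <- readLines(fx$manifest_path); m2 <- readLines(mp2)
  expect_identical(gsub(fx$dir, "", m1, fixed = TRUE),
                   gsub(d2, "", m2, fixed = TRUE))
  # and the rendered pixels are identical too
  f1 <- read_image(fx$manifest$image_path[1])
  f2 <- read_image(read_manifest(mp2)$image_path[1])
  expect_identical(f1, f2)
  unlink(d2, recursive = TRUE)

  expect_error(write_dataset(fx$population, 0, 0, tempfile(), 1),
               "baseline_replicates")
})

test_that("baseline-only dataset counts rows as population x replicates", {
  pop <- make_population(2, 0, 0, seed = 13)
  d <- tempfile()
  mf <- read_manifest(write_dataset(pop, 2, 0, d, seed = 3,
                                    image_size = c(192, 192)))
  expect_equal(nrow(mf), 4)
  expect_true(all(mf$series == "baseline"))
  expect_true(all(mf$time_marker == ""))
  unlink(d, recursive = TRUE)
})
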