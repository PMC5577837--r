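random_cloud <- function(n, sigma = diag(3)) {
  L <- chol(sigma)
  p <- matrix(rnorm(n * 3), n, 3) %*% L
  tibble::tibble(east = p[, 1], north = p[, 2], z = p[, 3])
}

test_that("eigen decomposition matches known covariance structure", {
  set.seed(1)
  # collinear horizontal points: all variance on MC1, horizontal
  s <- seq(0, 100, length.out = 50)
  line <- tibble::tibble(east = s * cos(0.7), north = s * sin(0.7), z = -400)
  es <- eigen_shape(line)
  expect_equal(es$values[1] / sum(es$values), 1)
  expect_equal(sqrt(sum(es$vectors[1:2, 1]^2)), 1)
  # isotropic cloud: eigenvalue shares 1/3 +- 0.01
  iso <- random_cloud(1e5)
  shares <- eigen_shape(iso)$values / sum(eigen_shape(iso)$values)
  expect_true(all(abs(shares - 1 / 3) < 0.01))
  # known anisotropic covariance: eigenvalues within 2% of analytic
  sig <- diag(c(100, 25, 4))
  known <- random_cloud(2e4, sig)
  ev <- eigen_shape(known)$values
  expect_true(all(abs(ev - c(100, 25, 4)) / c(100, 25, 4) < 0.05))
  # degenerate inputs
  expect_error(eigen_shape(line[1:3, ]), "at least 4")
  still <- tibble::tibble(east = rep(1, 5), north = rep(2, 5), z = rep(-3, 5))
  expect_error(eigen_shape(still), "degenerate")
})

test_that("the first eigenvector points along the net displacement", {
  set.seed(2)
  s <- sort(runif(200, 0, 500))
  track <- tibble::tibble(east = -s / sqrt(2), north = -s / sqrt(2),
                          z = -450 + rnorm(200, 0, 2))
  v1 <- eigen_shape(track)$vectors[, 1]
  disp <- c(track$east[200] - track$east[1], track$north[200] - track$north[1])
  expect_gt(sum(v1[1:2] * disp), 0)
})

test_that("MC1 extents follow the quantile geometry", {
  # uniform horizontal segment of length 100: q90 - q10 = 80
  s <- seq(0, 100, length.out = 2001)
  seg <- tibble::tibble(east = s, north = 0, z = -400)
  v1 <- eigen_shape(seg)$vectors[, 1]
  ext <- mc1_extents(seg, v1)
  expect_equal(ext$mc1_horizontal_extent, 80, tolerance = 1e-3)
  expect_equal(ext$mc1_vertical_extent, 0)
  # 45-degree incline: L/sqrt(2) each
  incl <- tibble::tibble(east = s / sqrt(2), north = 0, z = -400 + s / sqrt(2))
  v1i <- eigen_shape(incl)$vectors[, 1]
  exti <- mc1_extents(incl, v1i)
  expect_equal(exti$mc1_horizontal_extent, exti$mc1_vertical_extent,
               tolerance = 1e-9)
  expect_equal(exti$mc1_horizontal_extent, 80 / sqrt(2), tolerance = 1e-3)
})

test_that("plane widths equal 1-D quantile oracles on constructed waveforms", {
  n <- 4000
  s <- seq(0, 400, length.out = n)
  # planar horizontal zigzag about a north-running MC1
  lateral <- 10 * (2 * abs((s / 40) %% 1 - 0.5) - 0.5) * 2   # triangular, +-10
  zig <- tibble::tibble(east = lateral, north = s, z = -400)
  v1 <- eigen_shape(zig)$vectors[, 1]
  w <- plane_widths(zig, v1)
  oracle_h <- diff(quantile(lateral - mean(lateral), c(0.1, 0.9), names = FALSE))
  expect_equal(w$horizontal_width, oracle_h, tolerance = 0.02)
  expect_equal(w$vertical_width, 0, tolerance = 1e-6)
  # straight line: both widths 0
  ln <- tibble::tibble(east = s, north = s, z = -400)
  wl <- plane_widths(ln, eigen_shape(ln)$vectors[, 1])
  expect_equal(wl$horizontal_width, 0, tolerance = 1e-9)
  expect_equal(wl$vertical_width, 0, tolerance = 1e-9)
  # vertical sinusoid about a horizontal MC1 (cosine phase: orthogonal to s
  # over whole periods, so MC1 stays exactly horizontal)
  wave <- 7 * cos(2 * pi * s / 50)
  sine <- tibble::tibble(east = s, north = 0, z = -400 + wave)
  ws <- plane_widths(sine, eigen_shape(sine)$vectors[, 1])
  oracle_v <- diff(quantile(wave - mean(wave), c(0.1, 0.9), names = FALSE))
  expect_equal(ws$vertical_width, oracle_v, tolerance = 0.02)
})

test_that("signed-distance widths equal a brute-force projection oracle", {
  set.seed(3)
  for (rep in 1:5) {
    p <- random_cloud(500, diag(c(60, 20, 5))) |>
      dplyr::mutate(z = z - 400)
    es <- eigen_shape(p)
    v1 <- es$vectors[, 1]
    w <- plane_widths(p, v1)
    centred <- sweep(as.matrix(p), 2, colMeans(as.matrix(p)))
    na <- c(v1[2], -v1[1], 0); na <- na / sqrt(sum(na^2))
    nb <- c(v1[2] * na[3] - v1[3] * na[2],
            v1[3] * na[1] - v1[1] * na[3],
            v1[1] * na[2] - v1[2] * na[1])
    nb <- nb / sqrt(sum(nb^2))
    expect_equal(w$horizontal_width,
                 diff(quantile(centred %*% na, c(0.1, 0.9), names = FALSE)),
                 tolerance = 1e-9)
    expect_equal(w$vertical_width,
                 diff(quantile(centred %*% nb, c(0.1, 0.9), names = FALSE)),
                 tolerance = 1e-9)
  }
})

test_that("total dispersion equals the covariance trace and metrics are rotation invariant", {
  set.seed(4)
  p <- random_cloud(800, diag(c(50, 10, 3))) |> dplyr::mutate(z = z - 300)
  m <- shape_metrics(p)
  expect_equal(m$total_dispersion, sum(diag(cov(as.matrix(p)))),
               tolerance = 1e-9)
  # horizontal rotation: scalar metrics unchanged
  th <- 0.83
  rot <- tibble::tibble(east = cos(th) * p$east - sin(th) * p$north,
                        north = sin(th) * p$east + cos(th) * p$north,
                        z = p$z)
  mr <- shape_metrics(rot)
  for (cl in c("total_dispersion", "mc1_dispersion", "horizontality",
               "mc1_horizontal_extent", "mc1_vertical_extent",
               "horizontal_width", "vertical_width")) {
    expect_equal(mr[[cl]], m[[cl]], tolerance = 1e-6)
  }
  # translation invariance
  mt <- shape_metrics(dplyr::mutate(p, east = east + 1e4, north = north - 5e3))
  expect_equal(mt$total_dispersion, m$total_dispersion, tolerance = 1e-6)
})

test_that("assembled metrics reflect the simulated geometry", {
  # perfectly linear bottom: MC1 dispersion ~ 1
  dep <- simulate_deployment(quiet_config(seed = 13, n_dives = 1,
                                          bottom_linearity = 1,
                                          layer_thickness = 1,
                                          current_velocity = c(0, 0)))
  tb <- dep$truth$dives
  pos <- dep$truth$positions
  bp <- pos[pos$time >= tb$bottom_start[1] - 1 & pos$time <= tb$bottom_end[1] - 1, ]
  m <- shape_metrics(bp[, c("east", "north", "z")])
  expect_gt(m$mc1_dispersion, 0.99)
  # near-vertical MC1 flags the width planes
  vert <- tibble::tibble(east = rnorm(100, 0, 0.01), north = rnorm(100, 0, 0.01),
                         z = seq(-500, -400, length.out = 100))
  expect_true(plane_widths(vert, eigen_shape(vert)$vectors[, 1])$width_flagged)
  # fewer than 4 positions: all-missing row
  expect_true(is.na(shape_metrics(bp[1:3, c("east", "north", "z")])$total_dispersion))
})

test_that("vertical width grows with simulated layer thickness", {
  med_vw <- vapply(c(10, 40, 80), function(th) {
    dep <- simulate_deployment(sim_config(seed = 50 + th, n_dives = 4,
                                          duty_cycle = 24, layer_thickness = th,
                                          prey_intensity = 0))
    depth_c <- zero_offset_correct(dep$frame$depth)
    dives <- delimit_bottom(find_dives(depth_c), depth_c)
    vw <- vapply(seq_len(nrow(dives)), function(k) {
      bidx <- dives$descent_end[k]:dives$ascent_start[k]
      pos <- dep$truth$positions[match(depth_c$time[bidx], dep$truth$positions$time), ]
      shape_metrics(pos[, c("east", "north", "z")])$vertical_width
    }, numeric(1))
    median(vw)
  }, numeric(1))
  expect_true(all(diff(med_vw) > 0))
})
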