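# A small synthetic depth record: two dives separated by surface intervals.
make_depth <- function(profile) {
  tibble::tibble(time = seq_along(profile) - 1, depth = profile)
}

u_dive <- function(max_depth = 300, rate = 1.5, flat = 300) {
  c(seq(0, max_depth, by = rate), rep(max_depth, flat),
    seq(max_depth, 0, by = -rate))
}

test_that("zero-offset correction removes constant and drifting offsets", {
  prof <- c(rep(0, 120), u_dive(200), rep(0, 120), u_dive(300), rep(0, 120))
  # constant +3 m offset
  cor3 <- zero_offset_correct(make_depth(prof + 3))
  surf <- cor3$depth[prof == 0]
  expect_lt(abs(median(surf)), 0.01)
  # within-dive differences unchanged
  expect_equal(diff(cor3$depth), diff(prof))
  # linear drift 0 -> 2 m over the record: each surface interval reads ~0
  drift <- seq(0, 2, length.out = length(prof))
  cord <- zero_offset_correct(make_depth(prof + drift))
  runs <- divebottom3d:::true_runs(prof == 0)
  for (k in seq_len(nrow(runs))) {
    expect_lt(abs(median(cord$depth[runs$start[k]:runs$end[k]])), 0.1)
  }
  # idempotence on an already-zeroed trace
  twice <- zero_offset_correct(cor3)
  expect_lt(max(abs(twice$depth - cor3$depth)), 1e-9)
  # no surface interval: global-minimum correction with a warning
  expect_warning(nos <- zero_offset_correct(make_depth(prof + 50),
                                            surface_threshold = 10), "minimum")
  expect_equal(min(nos$depth), 0)
})

test_that("dives are maximal runs deeper than the threshold", {
  prof <- c(rep(0, 60), seq(0, 400, by = 2), rep(400, 100),
            seq(400, 0, by = -2), rep(0, 60))
  d <- find_dives(make_depth(prof))
  expect_equal(nrow(d), 1)
  expect_equal(d$max_depth, 400)
  expect_true(all(prof[d$start:d$end] > 15))
  expect_equal(nrow(find_dives(make_depth(rep(2, 100)))), 0)
})

test_that("dive detection equals a brute-force scan on a random walk", {
  set.seed(12)
  prof <- pmax(cumsum(rnorm(3000, 0, 2)), 0)
  d <- find_dives(make_depth(prof), threshold = 15)
  deep <- prof > 15
  oracle <- divebottom3d:::true_runs(deep)
  expect_equal(d$start, oracle$start)
  expect_equal(d$end, oracle$end)
})

test_that("bottom delimitation handles U- and V-dives as the polynomial model implies", {
  # square U-dive: bottom covers >= 90% of the flat section
  prof <- c(rep(0, 60), u_dive(300, 1.5, 300), rep(0, 60))
  dep <- make_depth(prof)
  d <- delimit_bottom(find_dives(dep), dep)
  flat <- which(prof == 300)
  covered <- max(flat[1], d$descent_end):min(flat[length(flat)], d$ascent_start)
  expect_gte(length(covered) / length(flat), 0.9)
  expect_equal(d$bottom_duration, d$ascent_start - d$descent_end)

  # V-dive at |vz| = 2: a short bottom centred at the vertex
  vprof <- c(rep(0, 60), seq(0, 400, by = 2), seq(398, 0, by = -2), rep(0, 60))
  vdep <- make_depth(vprof)
  dv <- delimit_bottom(find_dives(vdep), vdep)
  vert <- which.max(vprof)
  expect_true(dv$descent_end <= vert && vert <= dv$ascent_start)
  expect_lt(dv$bottom_duration, 200)  # far shorter than the 400-s dive

  # degenerate dive below 5 samples: empty bottom with a warning
  tiny <- make_depth(c(0, 16, 17, 18, 16, 0))
  expect_warning(dt <- delimit_bottom(find_dives(tiny), tiny), "short")
  expect_true(is.na(dt$descent_end))
  expect_equal(dt$bottom_duration, 0)
})

test_that("bottom delimitation is invariant to a constant depth shift", {
  prof <- c(rep(0, 60), u_dive(250, 1.25, 240), rep(0, 60))
  dep <- make_depth(prof)
  d1 <- delimit_bottom(find_dives(dep), dep)
  shifted <- make_depth(prof + 120)
  d2 <- delimit_bottom(
    dplyr::mutate(d1, start = start, end = end), shifted)
  expect_equal(d1$descent_end, d2$descent_end)
  expect_equal(d1$ascent_start, d2$ascent_start)
})

test_that("descent, bottom and ascent partition every simulated dive", {
  dep <- simulate_deployment(sim_config(seed = 9, n_dives = 4, duty_cycle = 24))
  depth_c <- zero_offset_correct(dep$frame$depth)
  d <- delimit_bottom(find_dives(depth_c), depth_c)
  for (k in seq_len(nrow(d))) {
    if (is.na(d$descent_end[k])) next
    descent <- d$start[k]:d$descent_end[k]
    bottom <- d$descent_end[k]:d$ascent_start[k]
    ascent <- d$ascent_start[k]:d$end[k]
    expect_equal(sort(unique(c(descent, bottom, ascent))), d$start[k]:d$end[k])
  }
})

test_that("recovered bottom overlaps the simulator truth (Jaccard)", {
  dep <- simulate_deployment(sim_config(seed = 23, n_dives = 8, duty_cycle = 24))
  depth_c <- zero_offset_correct(dep$frame$depth)
  d <- delimit_bottom(find_dives(depth_c), depth_c)
  tb <- dep$truth$dives
  jac <- vapply(seq_len(nrow(d)), function(k) {
    if (is.na(d$descent_end[k])) return(0)
    est <- d$descent_end[k]:d$ascent_start[k]
    tru <- tb$bottom_start[k]:tb$bottom_end[k]
    length(intersect(est, tru)) / length(union(est, tru))
  }, numeric(1))
  expect_gte(mean(jac), 0.8)
})

test_that("drift dives are flagged from low bottom speed and vertical-rate variability", {
  dives <- tibble::tibble(dive_id = 1:3, bottom_duration = c(400, 400, 50))
  flagged <- flag_drift_dives(dives,
                              speed_sd = c(0.05, 0.4, 0.05),
                              vz_sd = c(0.05, 0.7, 0.05))
  expect_equal(flagged$is_drift, c(TRUE, FALSE, FALSE))  # short bottom never drift
  expect_warning(
    m <- flag_drift_dives(dives, speed_sd = c(NA, 0.4, 0.05),
                          vz_sd = c(0.05, 0.7, 0.05)),
    "missing")
  expect_false(m$is_drift[1])
})

test_that("a simulated drift dive is flagged and removed by the pipeline", {
  dep <- simulate_deployment(sim_config(seed = 31, n_dives = 3,
                                        n_drift_dives = 1, duty_cycle = 24))
  expect_equal(sum(dep$truth$dives$is_drift), 1)
  out <- run_pipeline(dep$frame, dep$fixes, pipeline_control(n_samples = 1e4))
  expect_equal(nrow(out), 3)
  drift_id <- dep$truth$dives$dive_id[dep$truth$dives$is_drift]
  expect_false(drift_id %in% out$dive_id)
})
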