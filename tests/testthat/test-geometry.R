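test_that("DLT calibrate/project/reconstruct round trip is exact at zero noise", {
  pts <- ref_cube_points()
  cams <- default_camera_rig()
  for (cc in cams) {
    px <- dlt_project(cc, pts)
    cal <- dlt_calibrate(pts, px)
    expect_lt(cal$residual, 1e-8)
    expect_equal(cal$coefficients, cc$coefficients, tolerance = 1e-8)
  }
  px1 <- dlt_project(cams[[1]], rbind(c(1, 2, 3)))
  px2 <- dlt_project(cams[[2]], rbind(c(1, 2, 3)))
  rec <- dlt_reconstruct(cams, rbind(px1, px2))
  expect_equal(rec, c(1, 2, 3), tolerance = 1e-6)
})

test_that("DLT round trip holds for random non-degenerate rigs (property)", {
  set.seed(21)
  pts <- ref_cube_points()
  for (i in 1:10) {
    az <- runif(2, 0, 2 * pi); el <- runif(2, -0.4, 0.4)
    centers <- lapply(1:2, function(k)
      400 * c(cos(el[k]) * cos(az[k]), cos(el[k]) * sin(az[k]), sin(el[k])))
    if (abs(sum(centers[[1]] * centers[[2]])) / (400 * 400) > 0.95) next
    cams <- lapply(centers, function(cn)
      pinhole_camera(cn, c(0, 0, 0),
                     up = if (abs(cn[3]) > 350) c(0, 1, 0) else c(0, 0, 1)))
    target <- runif(3, -15, 15)
    px <- lapply(cams, function(cc) dlt_project(cc, rbind(target)))
    rec <- dlt_reconstruct(cams, do.call(rbind, px))
    expect_equal(rec, target, tolerance = 1e-6)
    cal <- dlt_calibrate(pts, dlt_project(cams[[1]], pts))
    expect_lt(cal$residual, 1e-7)
  }
})

test_that("calibration residual tracks pixel noise (Monte-Carlo oracle)", {
  set.seed(22)
  pts <- ref_cube_points()
  cam <- default_camera_rig()[[1]]
  res <- replicate(10, {
    px <- dlt_project(cam, pts) + matrix(rnorm(2 * nrow(pts), 0, 0.5),
                                         ncol = 2)
    dlt_calibrate(pts, px)$residual
  })
  # expected RMS ~ 0.5 * sqrt(1 - 11 / (2 * 27)) = 0.446
  expect_equal(mean(res), 0.446, tolerance = 0.15)
})

test_that("DLT preconditions are enforced", {
  pts <- ref_cube_points()
  cam <- default_camera_rig()[[1]]
  px <- dlt_project(cam, pts)
  expect_error(dlt_calibrate(pts[1:5, ], px[1:5, ]), "at least 6")
  copl <- pts; copl[, 3] <- 0
  expect_error(dlt_calibrate(copl, dlt_project(cam, copl)), "rank-deficient")
  expect_error(dlt_reconstruct(list(cam), px[1, , drop = FALSE]),
               "at least 2")
  # near-parallel rays: same camera twice
  expect_error(dlt_reconstruct(list(cam, cam), rbind(px[1, ], px[1, ])),
               "ill-conditioned")
})

test_that("compute_iaa matches hand-computed and symmetric cases", {
  # antennae at +/-45 degrees from the midline
  expect_equal(compute_iaa(c(0, 1, 0), c(1, 2, 0), c(0, -1, 0), c(1, -2, 0)),
               90, tolerance = 1e-10)
  # parallel antennae
  expect_equal(compute_iaa(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0)),
               0, tolerance = 1e-4)  # acos() precision near cos = 1
  # hand computation: cos = 3 / (3 * sqrt(6))
  expect_equal(compute_iaa(c(0, 0, 0), c(1, 2, 2), c(1, 0, 0), c(2, -1, 2)),
               65.90516, tolerance = 1e-4)
  expect_error(compute_iaa(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "zero-length")
})

test_that("compute_iaa is invariant under rigid motion and scaling (property)", {
  set.seed(23)
  for (i in 1:20) {
    pts <- lapply(1:4, function(j) runif(3, -5, 5))
    base <- compute_iaa(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    R <- Rz %*% Rx
    shift <- runif(3, -10, 10)
    s <- runif(1, 0.1, 4)
    tp <- lapply(pts, function(p) as.numeric(s * R %*% p + shift))
    expect_equal(compute_iaa(tp[[1]], tp[[2]], tp[[3]], tp[[4]]), base,
                 tolerance = 1e-8)
  }
})

test_that("digitization_error is 0 for rigid noise-free geometry", {
  frames <- lapply(1:10, function(i) {
    th <- i / 10
    list(left_base = c(0, 1, 0), left_tip = c(3 * cos(th), 1 + 3 * sin(th), 0),
         right_base = c(0, -1, 0),
         right_tip = c(3 * cos(th), -1 - 3 * sin(th), 0))
  })
  expect_equal(unname(digitization_error(frames)), c(0, 0), tolerance = 1e-12)
  expect_error(digitization_error(frames[1]), "at least 2")
})

test_that("flight_speeds recovers constant velocity and the airspeed relation", {
  fps <- 500
  tt <- (0:499) / fps
  # constant velocity 0.4 m/s upwind (+x), positions in mm
  pos <- cbind(400 * tt, 0 * tt, 0 * tt)
  fs <- flight_speeds(pos, fps, windspeed_vector = 3)
  expect_equal(fs$mean_groundspeed, 0.4, tolerance = 1e-9)
  expect_equal(fs$mean_airspeed, 3.4, tolerance = 1e-9)  # collinear sum

  # stationary (tethered) bee: airspeed magnitude equals windspeed
  fs2 <- flight_speeds(cbind(rep(0, 100), 0, 0), fps,
                       windspeed_vector = 2)
  expect_equal(fs2$mean_groundspeed, 0, tolerance = 1e-12)
  expect_equal(fs2$mean_airspeed, 2, tolerance = 1e-12)

  expect_error(flight_speeds(pos[1, , drop = FALSE], fps), "at least 2")
  expect_error(flight_speeds(pos, fps, smooth_window = 4), "odd")
})

test_that("angular_speed implements grating speed per unit distance", {
  # (tf / sf) / d in rad/s, converted to deg/s
  expect_equal(angular_speed(25, 0.44, 10), (25 / 0.44 / 10) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(angular_speed(25, 0.44, 10), 325.545, tolerance = 1e-3)
  expect_equal(angular_speed(1.8, 0.44, 10), 23.439, tolerance = 1e-3)
  expect_equal(angular_speed(0, 0.44, 10), 0)
  expect_error(angular_speed(5, 0, 10))
  expect_error(angular_speed(-1, 0.44, 10))
})
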