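zero_cfg <- feature_config(zc_threshold = 0, ssc_threshold = 0,
                           wamp_threshold = 0)

test_that("time-domain features match hand-evaluated values", {
  z <- rep(0, 10)
  suppressMessages(
    v <- compute_td_features(z, c("VAR", "WL", "RMS", "MAV", "ZC", "SSC",
                                  "WAMP", "SK", "KU"), zero_cfg))
  expect_equal(unname(v[c("VAR", "WL", "RMS", "MAV", "ZC", "SSC", "WAMP")]),
               rep(0, 7))
  expect_equal(unname(v[c("SK", "KU")]), c(0, 0))  # zero-variance convention

  w <- compute_td_features(c(1, -1, 1, -1), c("RMS", "MAV", "WL", "ZC"),
                           zero_cfg)
  expect_equal(unname(w), c(1, 1, 6, 3))

  x <- rnorm(20)
  sym <- c(x, -x)
  expect_equal(unname(compute_td_features(sym, "SK", zero_cfg)), 0,
               tolerance = 1e-12)
})

test_that("event counts respect their amplitude thresholds", {
  x <- c(0.5, -0.5, 0.5, -0.5)
  cfg_hi <- feature_config(zc_threshold = 2, ssc_threshold = 2,
                           wamp_threshold = 2)
  expect_equal(unname(compute_td_features(x, c("ZC", "WAMP"), cfg_hi)),
               c(0, 0))
  expect_equal(unname(compute_td_features(x, c("ZC", "WAMP"), zero_cfg)),
               c(3, 3))
  # SSC counts interior extrema above threshold
  y <- c(0, 1, 0, 1, 0)
  expect_equal(unname(compute_td_features(y, "SSC", zero_cfg)), 3)
  expect_equal(unname(compute_td_features(y, "SSC", cfg_hi)), 0)
})

test_that("pair features: correlation and angle", {
  a <- c(1.2, -0.3, 0.8, 2.0)
  expect_equal(unname(compute_pair_features(a, a)), c(1, 0), tolerance = 1e-8)
  expect_equal(unname(compute_pair_features(c(1, 0), c(0, 1))["ANG"]), pi / 2)
  v <- compute_pair_features(a, -a)
  expect_equal(unname(v["COR"]), -1)
  expect_equal(unname(v["ANG"]), pi, tolerance = 1e-8)
  expect_error(compute_pair_features(c(0, 0), c(1, 2)), "zero-norm")
  expect_error(compute_pair_features(c(1, 1), c(1, 2)), "zero-variance")
})

test_that("frequency-domain features recover spectral structure", {
  fs <- 100
  t <- (0:199) / fs
  s <- sin(2 * pi * 10 * t)
  v <- compute_fd_features(s, fs, c("MDF", "MNF", "MAXF"))
  bin <- fs / length(s)
  expect_equal(unname(v["MAXF"]), 10)
  expect_lt(abs(v["MNF"] - 10), bin + 1e-9)
  expect_lt(abs(v["MDF"] - 10), bin + 1e-9)

  set.seed(4)
  wn <- rnorm(4096)
  mnf <- compute_fd_features(wn, fs, "MNF")
  expect_lt(abs(mnf - fs / 4), 2)          # flat spectrum mean ~ fs/4

  a <- compute_fd_features(wn, fs, "AR4")
  expect_length(a, 4)
  expect_true(all(abs(a) < 3 / sqrt(length(wn))))  # Yule-Walker on iid noise

  expect_error(compute_fd_features(rep(0, 50), fs, "MNF"), "constant")
})

test_that("layout arithmetic matches the reference feature counts", {
  # VAR x 3 channels -> 3; {MAV, RMS} x 3 -> 6; AR4 x 3 -> 12
  lay3 <- feature_layout(data.frame(type = "VAR", target = as.character(1:3)))
  expect_identical(layout_width(lay3), 3L)
  lay6 <- feature_layout(data.frame(type = rep(c("MAV", "RMS"), each = 3),
                                    target = as.character(rep(1:3, 2))))
  expect_identical(layout_width(lay6), 6L)
  lay12 <- feature_layout(data.frame(type = "AR4", target = as.character(1:3)))
  expect_identical(layout_width(lay12), 12L)

  expect_identical(layout_width(full_layout()), 60L)
  expect_identical(layout_width(preselected_layout()), 45L)
  expect_identical(layout_width(preselected_layout(drop_hip_zc = TRUE)), 44L)

  expect_error(feature_layout(data.frame(type = c("VAR", "VAR"),
                                         target = c("1", "1"))), "duplicate")
  # pair targets are unordered
  expect_error(feature_layout(data.frame(type = c("COR", "COR"),
                                         target = c("1-3", "3-1"))), "duplicate")
})

test_that("expanded column count matches enumeration on random layouts", {
  set.seed(9)
  scalar <- c("SSC", "ZC", "WL", "VAR", "MAV", "RMS", "WAMP", "SK", "KU",
              "MDF", "MNF", "MAXF")
  for (rep in 1:20) {
    n_s <- sample(0:6, 1)
    n_ar <- sample(0:3, 1)
    ent <- data.frame(type = character(0), target = character(0))
    if (n_s > 0)
      ent <- rbind(ent, data.frame(type = sample(scalar, n_s),
                                   target = as.character(sample(1:3, n_s, TRUE))))
    if (n_ar > 0)
      ent <- rbind(ent, data.frame(type = "AR4",
                                   target = as.character(sample(1:3, n_ar))))
    ent <- ent[!duplicated(ent), ]
    lay <- feature_layout(ent)
    expect_identical(layout_width(lay),
                     sum(ent$type != "AR4") + 4L * sum(ent$type == "AR4"))
  }
})

test_that("TD invariances: time reversal and positive scaling", {
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(40)
    rev_inv <- c("VAR", "MAV", "RMS", "WAMP", "SK", "KU", "ZC")
    expect_equal(compute_td_features(rev(x), rev_inv, zero_cfg),
                 compute_td_features(x, rev_inv, zero_cfg))
    c_ <- runif(1, 0.5, 3)
    f1 <- compute_td_features(x, c("MAV", "RMS", "WL", "VAR", "SK", "KU"),
                              zero_cfg)
    f2 <- compute_td_features(c_ * x, c("MAV", "RMS", "WL", "VAR", "SK", "KU"),
                              zero_cfg)
    expect_equal(unname(f2[c("MAV", "RMS", "WL")]),
                 unname(c_ * f1[c("MAV", "RMS", "WL")]))
    expect_equal(unname(f2["VAR"]), unname(c_^2 * f1["VAR"]))
    expect_equal(unname(f2[c("SK", "KU")]), unname(f1[c("SK", "KU")]))
    y <- rnorm(40)
    expect_equal(compute_pair_features(c_ * x, y),
                 compute_pair_features(x, y), tolerance = 1e-10)
  }
})

test_that("feature tables assemble in layout order with carried labels", {
  rec <- tiny_recording(seconds = 2, seed = 2)
  frames <- segment_frames(rec, windowing_config(250, 50, "overlapped"))
  lay <- preselected_layout(drop_hip_zc = TRUE)
  tab <- build_feature_table(frames, lay, fs = rec$fs)
  expect_identical(dim(tab$values), c(length(frames), 44L))
  expect_identical(tab$labels, vapply(frames, `[[`, "", "label"))
  # row k equals the concatenated features of frame k (spot-check row 3)
  expect_equal(unname(tab$values[3, "WL@2"]),
               unname(compute_td_features(frames[[3]]$data[, 2], "WL")))
  expect_error(build_feature_table(frames, feature_layout(
    data.frame(type = "VAR", target = "7"))), "channel")
})

test_that("normalization: population convention, held-out application, errors", {
  tab <- feature_table(cbind(a = c(2, 4, 6), b = c(1, 0, -1)), c("x", "y", "x"))
  ntab <- normalize_table(tab)
  expect_lt(max(abs(colMeans(ntab$values))), 1e-10)
  expect_lt(max(abs(colMeans(ntab$values^2) - 1)), 1e-10)
  # x = 6 in column [2,4,6]: (6 - 4) / sqrt(8/3)
  expect_equal(unname(ntab$values[3, "a"]), 2 / sqrt(8 / 3), tolerance = 1e-12)
  # idempotence
  expect_equal(normalize_table(ntab)$values, ntab$values, tolerance = 1e-12)
  # held-out rows get the same transform
  new <- apply_normalization(ntab, feature_table(cbind(a = 8, b = 2), "x"))
  expect_equal(unname(new$values[1, 1]), (8 - 4) / sqrt(8 / 3))
  expect_error(normalize_table(feature_table(cbind(a = c(1, 1), b = 1:2),
                                             c("x", "y"))),
               "zero-variance column\\(s\\): a")
})

test_that("feature-table CSV round-trips with layout-encoding header", {
  tab <- build_feature_table(
    segment_frames(tiny_recording(1, seed = 6), windowing_config(250, 50, "overlapped")),
    preselected_layout(), fs = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table_csv(tab, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_true(all(c("SSC@1", "COR@1-2", "AR4.1@1", "label") %in% header))
  back <- read_feature_table_csv(path)
  expect_equal(back$values, tab$values, tolerance = 1e-6)
  expect_identical(back$labels, tab$labels)
  expect_identical(layout_width(back$layout), 45L)
})
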