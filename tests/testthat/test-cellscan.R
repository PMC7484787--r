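# minimal fit_maps stand-in for morphology-only tests
fake_maps <- function(n, tau_m = 1200, intensity = 500) {
  fields <- c("a1", "a2", "tau1", "tau2", "tau_m", "ratio", "asym", "chi2",
              "intensity")
  maps <- lapply(fields, function(f) matrix(1, n, n))
  names(maps) <- fields
  maps$tau_m[] <- tau_m
  maps$intensity[] <- intensity
  structure(list(maps = maps, valid = matrix(TRUE, n, n),
                 pixel_pitch = 0.3, power = 1, channel_width = DW),
            class = "fit_maps")
}

fake_cube <- function(n, depth = 80) {
  make_cube(array(1, c(n, n, 256)), DW, 1, girf, 0.3, depth = depth)
}

disc <- function(n, cy, cx, r) {
  yy <- matrix(seq_len(n), n, n)
  (yy - cy)^2 + (t(yy) - cx)^2 <= r^2
}

test_that("flat background yields no candidates; size filter rejects giant blobs", {
  flat <- matrix(100, 40, 40)
  expect_length(detect_bright_spots(flat, 0.3), 0)
  # a 30 um blob (r = 50 px at 0.3 um pitch) is rejected by the size cut
  big <- flat
  big[disc(40, 20, 20, 19)] <- 1000 # fills most of the frame: > 25 um
  masks <- detect_bright_spots(big, 0.8) # 0.8 um pitch -> 30 um diameter
  expect_length(masks, 0)
})

test_that("planted cells at in vitro intensities are recovered within 2 um", {
  sc <- scene_config(image_size = 96, field_of_view = 96 * 150 / 512,
                     cells = list(
                       list(class = "resting_mc", center_um = c(7, 7),
                            context = "in_vitro"),
                       list(class = "activated_mc", center_um = c(21, 7),
                            context = "in_vitro"),
                       list(class = "resting_mc", center_um = c(14, 21),
                            context = "in_vitro")))
  scn <- render_scene(sc, seed = 7)
  totals <- apply(bin_decays(scn$cube, 3)$counts, c(1, 2), sum)
  masks <- detect_bright_spots(totals / scn$cube$power, scn$cube$pixel_pitch)
  expect_length(masks, 3)
  truth_px <- cbind(scn$truth$center_y_um, scn$truth$center_x_um) /
    scn$cube$pixel_pitch
  for (m in masks) {
    cen <- colMeans(which(m, arr.ind = TRUE))
    err_um <- min(sqrt(rowSums((truth_px - matrix(cen, nrow(truth_px), 2,
                                                  byrow = TRUE))^2))) *
      scn$cube$pixel_pitch
    expect_lt(err_um, 2)
  }
})

test_that("disc masks are circular, 3:1 ellipses are not", {
  n <- 64
  dmask <- disc(n, 32, 32, 15)
  fm <- fake_maps(n)
  rec <- measure_cell(dmask, fm, fake_cube(n))
  expect_gte(rec$circularity, 0.85)
  expect_equal(rec$shape_flag, 1L)
  expect_lt(abs(rec$equivalent_diameter - 2 * 15 * 0.3), 0.3)

  yy <- matrix(seq_len(n), n, n)
  ellipse <- ((yy - 32) / 26)^2 + ((t(yy) - 32) / (26 / 3))^2 <= 1
  rec_e <- measure_cell(ellipse, fm, fake_cube(n))
  expect_lt(rec_e$circularity, 0.8)
  expect_equal(rec_e$shape_flag, 0L)
})

test_that("diameter estimator is accurate to one pixel pitch on planted discs", {
  n <- 96
  for (d_um in c(6, 8, 10, 14)) {
    r_px <- d_um / 2 / 0.3
    rec <- measure_cell(disc(n, 48, 48, r_px), fake_maps(n), fake_cube(n))
    expect_lt(abs(rec$equivalent_diameter - d_um), 0.3 + 0.15)
  }
})

test_that("uniform-parameter cells average to the per-pixel values exactly", {
  n <- 32
  fm <- fake_maps(n, tau_m = 987, intensity = 321)
  rec <- measure_cell(disc(n, 16, 16, 8), fm, fake_cube(n))
  expect_equal(rec$fit_summary$tau_m, 987)
  expect_equal(rec$mean_intensity, 321)
  expect_equal(length(rec$decay_curve), 256)
  expect_equal(max(rec$decay_curve), 1)
  expect_false(rec$partial)
  border <- disc(n, 2, 16, 4)
  expect_true(measure_cell(border, fm, fake_cube(n))$partial)
})

test_that("search cascade reproduces the published gate outcomes", {
  rec <- function(depth, d, tau_m, int, circ = 0.9) {
    list(depth = depth, equivalent_diameter = d, mean_intensity = int,
         circularity = circ, shape_flag = as.integer(circ >= 0.8),
         fit_summary = list(tau_m = tau_m))
  }
  crit <- search_criteria()
  # healthy in vivo long-lifetime MC: dim, tau_m 1171 -> resting
  expect_equal(mc_search(rec(90, 10, 1171, 300), crit), "resting_mc")
  # short-lifetime population: bright, elongated, tau_m 678 -> activated
  expect_equal(mc_search(rec(90, 9, 678, 800, circ = 0.5), crit),
               "activated_mc")
  # above the papillary dermis: rejected regardless of signature
  expect_equal(mc_search(rec(50, 10, 1171, 300), crit), "not_mc")
  # fibroblast-sized
  expect_equal(mc_search(rec(90, 22, 1171, 300), crit), "not_mc")
  # outside the size window
  expect_equal(mc_search(rec(90, 4, 1171, 300), crit), "not_mc")
  # intensity floor
  expect_equal(mc_search(rec(90, 10, 1171, 100), crit), "not_mc")
  # the 800-1,000 ps gap defers to the classifier
  expect_equal(mc_search(rec(90, 10, 900, 400), crit), "ambiguous_mc")
})

test_that("search labels are order-independent and deterministic", {
  set.seed(55)
  recs <- lapply(1:20, function(i) {
    list(depth = sample(c(50, 90), 1), equivalent_diameter = runif(1, 3, 25),
         mean_intensity = runif(1, 50, 1000),
         fit_summary = list(tau_m = runif(1, 300, 1600)))
  })
  l1 <- vapply(recs, mc_search, "")
  l2 <- vapply(rev(recs), mc_search, "")
  expect_identical(l1, rev(l2))
  expect_identical(l1, vapply(recs, mc_search, ""))
})

test_that("rule cascade recalls planted mast cells and excludes fibroblasts", {
  # one scene per in vitro class (ground-truth parameters pinned to the
  # class means so the gates see typical members), imaged at depth 90 um
  tab <- cell_class_table()
  classes <- tab[tab$context == "in_vitro", ]
  labels <- character(0)
  for (i in seq_len(nrow(classes))) {
    spec <- classes[i, ]
    params <- data.frame(tau1 = spec$tau1_mean, tau2 = spec$tau2_mean,
                         ratio = spec$ratio_mean,
                         intensity = spec$intensity_mean,
                         diameter = spec$diameter_mean,
                         shape_flag = as.integer(spec$p_circular >= 0.5))
    npx <- max(72, ceiling((spec$diameter_mean * 1.8) / (150 / 512)))
    fov <- npx * 150 / 512
    sc <- scene_config(image_size = npx, field_of_view = fov, depth = 90,
                       cells = list(list(class = spec$class,
                                         context = "in_vitro",
                                         center_um = c(fov / 2, fov / 2),
                                         params = params)))
    scn <- render_scene(sc, seed = 100 + i)
    totals <- apply(bin_decays(scn$cube, 3)$counts, c(1, 2), sum)
    masks <- detect_bright_spots(totals / scn$cube$power,
                                 scn$cube$pixel_pitch)
    if (length(masks) == 0) {
      labels[spec$class] <- "undetected"
      next
    }
    m <- masks[[which.max(vapply(masks, sum, 0))]]
    # fit a regular subsample of the mask; the cell mean needs no more
    stride <- outer(seq_len(nrow(m)) %% 3 == 0, seq_len(ncol(m)) %% 3 == 0,
                    `&`)
    fmap <- fit_image(scn$cube, roi = m & stride)
    labels[spec$class] <- mc_search(measure_cell(m, fmap, scn$cube))
  }
  mc_classes <- grep("mc$", names(labels), value = TRUE)
  recalled <- labels[mc_classes] %in%
    c("resting_mc", "activated_mc", "ambiguous_mc")
  expect_gte(mean(recalled), 0.8)
  expect_equal(unname(labels["fibroblast"]), "not_mc")
})
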