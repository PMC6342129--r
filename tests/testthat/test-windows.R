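test_that("detection centroid is the mean of detected-at coordinates", {
  det <- tibble::tibble(detector_id = 1:4,
                        x = c(0, 2, 5, 0), y = c(0, 0, 7, 2))
  expect_equal(unname(detection_centroid(c(1, 1, 0, 0), det)), c(1, 0))
  expect_equal(unname(detection_centroid(c(0, 0, 1, 0), det)), c(5, 7))
  lattice <- tibble::tibble(detector_id = 1:4,
                            x = c(0, 0, 2, 2), y = c(0, 2, 0, 2))
  expect_equal(unname(detection_centroid(rep(1, 4), lattice)), c(1, 1))
  expect_error(detection_centroid(c(0, 0, 0, 0), det), "no detections")
})

test_that("AC and detector windows have the stated geometry", {
  w <- ac_window(c(0, 0), 10)
  expect_equal(unlist(w[, 1:4]),
               c(x_lo = -5, x_hi = 5, y_lo = -5, y_hi = 5))
  sigma <- 2
  expect_equal(ac_window(c(0, 0), 5 * sigma)$width, 10)
  expect_equal(ac_window(c(0, 0), 3 * sigma)$width, 6)
  # extension of 2 sigma around a 5-sigma AC window -> 18 du
  expect_equal(detector_window(ac_window(c(0, 0), 10), 2 * sigma)$width, 18)
  expect_equal(detector_window(w, 0)[, 1:4], w[, 1:4])
  expect_equal(detector_window(ac_window(c(1, 1), 6), 2)$width, 10)
  expect_error(ac_window(c(0, 0), 0), "width")
  expect_error(detector_window(w, -1), "extension")
})

test_that("half-open detector indexing yields the known counts", {
  det <- detector_grid(50, 50)
  # worst case: a width-18 window never holds more than 18 points per axis
  offs <- seq(0, 0.9, by = 0.1)
  counts <- vapply(offs, function(o) {
    w <- tibble::tibble(x_lo = 16 + o - 9, x_hi = 16 + o + 9,
                        y_lo = 16 + o - 9, y_hi = 16 + o + 9, width = 18)
    length(detectors_in_window(w, det))
  }, numeric(1))
  expect_equal(max(counts), 324)
  expect_true(all(counts <= 324))
  whole <- tibble::tibble(x_lo = -1, x_hi = 50, y_lo = -1, y_hi = 50,
                          width = 51)
  expect_length(detectors_in_window(whole, det), 2500)
  empty <- tibble::tibble(x_lo = 0.25, x_hi = 0.75, y_lo = 0.25,
                          y_hi = 0.75, width = 0.5)
  expect_length(detectors_in_window(empty, det), 0)
  idx <- detectors_in_window(whole, det)
  expect_identical(idx, sort(idx))
})

test_that("augmentation tiles partition the domain per layer", {
  dom <- scr_domain(detector_grid(50, 50), buffer = 4)  # 58 x 58 du
  tl <- tile_windows(dom, 10, n_layers = 1)
  expect_equal(nrow(tl), 36)
  expect_equal(max(tl$x_hi) - max(tl$x_lo), 8)  # truncated edge tile
  expect_equal(nrow(tile_windows(dom, 10, n_layers = 2)), 72)
  # every random point lies in exactly one tile (half-open membership)
  set.seed(7)
  px <- runif(200, dom$bounds[1], dom$bounds[2])
  py <- runif(200, dom$bounds[3], dom$bounds[4])
  hits <- vapply(seq_along(px), function(k) {
    sum(px[k] >= tl$x_lo & px[k] < tl$x_hi &
          py[k] >= tl$y_lo & py[k] < tl$y_hi)
  }, numeric(1))
  expect_true(all(hits == 1))
  one <- tile_windows(scr_domain(bounds = c(0, 10, 0, 10)), 10)
  expect_equal(nrow(one), 1)
  expect_warning(tile_windows(scr_domain(bounds = c(0, 5, 0, 5)), 10),
                 "exceeds")
})

test_that("prop_habitat is the suitable area over the nominal window area", {
  dom <- scr_domain(bounds = c(0, 20, 0, 20))
  inside <- tibble::tibble(x_lo = 5, x_hi = 9, y_lo = 5, y_hi = 9, width = 4)
  expect_equal(prop_habitat(inside, dom), 1)
  # half the window protrudes past the domain edge
  half <- tibble::tibble(x_lo = -2, x_hi = 2, y_lo = 5, y_hi = 9, width = 4)
  expect_equal(prop_habitat(half, dom), 0.5)
  outside <- tibble::tibble(x_lo = 30, x_hi = 34, y_lo = 0, y_hi = 4,
                            width = 4)
  expect_equal(prop_habitat(outside, dom), 0)
  # non-suitable cells reduce the proportion by their area
  hab <- matrix(1L, 20, 20); hab[1:10, 1:10] <- 0L
  dom2 <- scr_domain(bounds = c(0, 20, 0, 20), habitat = hab)
  w <- tibble::tibble(x_lo = 8, x_hi = 12, y_lo = 8, y_hi = 12, width = 4)
  expect_equal(prop_habitat(w, dom2), 0.75)
  # monotone under window growth in all-suitable habitat
  widths <- seq(1, 30, by = 1.7)
  props <- vapply(widths, function(wd) {
    prop_habitat(ac_window(c(10, 10), wd), dom)
  }, numeric(1))
  expect_true(all(diff(props) <= 1e-12))
})

test_that("LESS index honours its build-time contracts", {
  d <- tiny_dataset(N = 20, seed = 5)
  li <- less_index(d$captures, d$detectors, d$domain, ac_width = 10,
                   extension = 4, n_expected = 20)
  expect_s3_class(li, "less_index")
  expect_equal(li$n_detected, d$captures$n_detected)
  expect_gt(li$n_augmented, 4 * 20)
  expect_true(all(li$n_detectors <= 324))
  expect_true(all(li$windows$prop_habitat >= 0 &
                    li$windows$prop_habitat <= 1))
  expect_equal(li$n_detectors,
               rowSums(li$detector_index > 0))
  # every detection is inside its owner's detector index
  for (i in seq_len(li$n_detected)) {
    hits <- which(d$captures$y[i, ] > 0)
    expect_true(all(hits %in% li$detector_index[i, ]))
  }
  # a window too small to hold all detections fails loudly
  y2 <- matrix(0L, 1, nrow(d$detectors))
  y2[1, c(1, nrow(d$detectors))] <- 1L  # opposite corners
  expect_error(
    less_index(y2, d$detectors, d$domain, ac_width = 2, extension = 0),
    "outside its detector window"
  )
})

test_that("excluded detectors are far: exclusion bound on detection prob", {
  d <- tiny_dataset(N = 20, seed = 5)
  sigma <- 2; extension <- 2 * sigma
  li <- less_index(d$captures, d$detectors, d$domain, ac_width = 10,
                   extension = extension, n_expected = 20)
  p0 <- 0.07
  bound <- p0 * exp(-extension^2 / (2 * sigma^2))
  for (i in seq_len(min(5, li$n_detected))) {
    w <- li$windows[i, ]
    excl <- setdiff(seq_len(nrow(d$detectors)),
                    li$detector_index[i, seq_len(li$n_detectors[i])])
    if (length(excl) == 0) next
    # distance from the AC window to each excluded detector
    dx <- pmax(w$x_lo - d$detectors$x[excl],
               d$detectors$x[excl] - w$x_hi, 0)
    dy <- pmax(w$y_lo - d$detectors$y[excl],
               d$detectors$y[excl] - w$y_hi, 0)
    dist <- sqrt(dx^2 + dy^2)
    expect_true(all(detection_prob(dist, p0, sigma) <= bound + 1e-12))
  }
})

test_that("LESS index JSON export round-trips the indexing arrays", {
  d <- tiny_dataset(N = 8, seed = 9)
  li <- less_index(d$captures, d$detectors, d$domain, ac_width = 10,
                   extension = 4, n_layers = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_less_index(li, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_detected, li$n_detected)
  expect_equal(back$n_detectors, li$n_detectors)
  expect_equal(back$prop_habitat, li$windows$prop_habitat)
  i <- li$n_detected + 1
  expect_equal(back$detector_index[[i]],
               li$detector_index[i, seq_len(li$n_detectors[i])])
})
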