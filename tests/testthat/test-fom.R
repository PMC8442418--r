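test_that("figure of merit scales as Ip*It/(l*dq)", {
  expect_equal(figure_of_merit(1, 1, 1, 1), 1)
  base <- figure_of_merit(2e-18, 5e-18, 2.5, 15)
  expect_equal(figure_of_merit(2e-18, 5e-18, 2.5, 30), base / 2)
  expect_equal(figure_of_merit(4e-18, 5e-18, 2.5, 15), base * 2)
  expect_equal(figure_of_merit(2e-18, 5e-18, 5, 15), base / 2)
  expect_equal(figure_of_merit(2.8e-18, 1.4e-17, 3.4, 15),
               2.8e-18 * 1.4e-17 / (3.4 * 15))
  expect_error(figure_of_merit(1, 1, 1, 0), "l must be")
  expect_error(figure_of_merit(1, 1, 0, 1), "delta_q")
})

test_that("ranking normalizes by the best candidate and is scale invariant", {
  rec <- fom_record(path = c("a", "b", "c"),
                    I_p = c(1, 1, 1), I_t = c(1, 1, 1), delta_q = c(1, 1, 1),
                    omega = c(7.7e-37, 1.7e-37, 7.6e-38))
  ranked <- rank_paths(rec)
  expect_equal(ranked$path, c("a", "b", "c"))
  expect_equal(ranked$rank, 1:3)
  expect_equal(round(ranked$omega_norm, 2), c(1, 0.22, 0.10))
  # multiplying all omegas by k > 0 leaves omega_norm unchanged
  rec2 <- rec; rec2$omega <- rec2$omega * 3.7e5
  expect_equal(rank_paths(rec2)$omega_norm, ranked$omega_norm)
  # single record normalizes to 1
  expect_equal(rank_paths(rec[1, , drop = FALSE])$omega_norm, 1)
})

test_that("exact ties break by orientation then index", {
  rec <- data.frame(path = c("p1", "p2", "p3"),
                    orientation = c("row", "column", "column"),
                    index = c(5L, 9L, 2L),
                    omega = c(1, 1, 1))
  ranked <- rank_paths(rec)
  expect_equal(ranked$path, c("p3", "p2", "p1"))
  expect_equal(ranked$omega_norm, rep(1, 3))
})

test_that("exclusion policy drops radiosensitive paths and promotes the runner-up", {
  rec <- data.frame(path = c("best", "second"),
                    orientation = c("row", "row"), index = 1:2,
                    omega = c(10, 4),
                    intersects_excluded = c(TRUE, FALSE))
  # default: warn, keep
  expect_warning(kept <- rank_paths(rec), "excluded")
  expect_equal(kept$path[1], "best")
  expect_equal(kept$omega_norm[kept$path == "second"], 0.4)
  # drop: runner-up becomes the reference
  dropped <- rank_paths(rec, exclusion = "drop")
  expect_equal(dropped$omega_norm[dropped$path == "second"], 1)
  expect_true(is.na(dropped$rank[dropped$path == "best"]))
  expect_match(dropped$excluded_reason[dropped$path == "best"], "excluded")
  all_ex <- data.frame(omega = 1, intersects_excluded = TRUE)
  expect_error(rank_paths(all_ex, exclusion = "drop"), "all paths excluded")
})

test_that("mask scans score candidates and flag target-free paths", {
  mask <- make_embedded_disk_mask(disk_phantom_spec(r_lobe = 1.5))
  ranked <- evaluate_mask_scan(mask, default_medium(), test_beam(),
                               stride = 4L, n_q = 1024)
  expect_true(all(ranked$omega[!ranked$candidate] == 0))
  expect_true(all(ranked$omega[ranked$candidate] > 0))
  expect_equal(max(ranked$omega_norm, na.rm = TRUE), 1)
  expect_equal(sum(ranked$omega_norm == 1, na.rm = TRUE), 1)
  expect_true(all(is.na(ranked$omega_norm[!ranked$candidate])))
  # omega strictly decreasing along the ranking
  cand <- ranked[!is.na(ranked$rank), ]
  expect_true(all(diff(cand$omega[order(cand$rank)]) <= 0))
})

test_that("mirrored targets tie and exclusion promotes the survivor", {
  ps <- 0.1
  spec <- phantom_spec(
    grid = c(180, 180), pixel_size = ps,
    head = list(center = c(9, 9), semi_axes = c(8, 7)),
    lobes = list(list(center = c(5, 9), semi_axes = c(1.5, 1.5)),
                 list(center = c(13, 9), semi_axes = c(1.5, 1.5))))
  mask <- make_embedded_disk_mask(spec)
  ranked <- evaluate_mask_scan(mask, default_medium(), test_beam(),
                               orientations = "column", stride = 1L,
                               n_q = 1024)
  cand <- ranked[!is.na(ranked$rank), ]
  # the two mirror-image best columns tie in omega
  expect_equal(cand$omega[1], cand$omega[2], tolerance = 1e-9)
  expect_equal(abs(cand$index[1] - 91) , abs(cand$index[2] - 91), tolerance = 1)

  # covering one mirror twin with an excluded zone promotes the other
  spec_ex <- phantom_spec(
    grid = c(180, 180), pixel_size = ps,
    head = list(center = c(9, 9), semi_axes = c(8, 7)),
    lobes = list(list(center = c(5, 9), semi_axes = c(1.5, 1.5)),
                 list(center = c(13, 9), semi_axes = c(1.5, 1.5))),
    excluded_zones = list(list(center = c(5, 5), semi_axes = c(2, 1.5))))
  mask_ex <- make_embedded_disk_mask(spec_ex)
  ranked_ex <- evaluate_mask_scan(mask_ex, default_medium(), test_beam(),
                                  orientations = "column", stride = 1L,
                                  exclusion = "drop", n_q = 1024)
  top <- ranked_ex[which(ranked_ex$rank == 1), ]
  expect_gt(top$index, 91)  # survivor is on the right-hand lobe
  expect_equal(top$omega_norm, 1)
})

test_that("published lobe path summaries load with all twelve paths", {
  ref <- reference_path_summaries()
  expect_equal(nrow(ref), 12)
  expect_setequal(unique(ref$region), c("temporal", "frontal"))
  expect_true(all(ref$I_p > 0 & ref$delta_q > 0 & ref$omega > 0))
})

test_that("ranked tables write deterministically with --top filtering", {
  rec <- fom_record(path = letters[1:4], I_p = c(4, 3, 2, 1),
                    I_t = rep(1, 4), delta_q = rep(1, 4), l = rep(2, 4))
  ranked <- rank_paths(rec)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_fom_table(ranked, f1, top = 3)
  write_fom_table(ranked, f2, top = 3)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(readLines(f1)), 1 + 3)
})
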