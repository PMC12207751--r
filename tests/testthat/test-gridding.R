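mk_seg <- function(x0, y0, x1, y1, ss = 0, effort = TRUE, id = "T1",
                   altitude = "high") {
  data.frame(transect_id = id, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
             altitude = altitude, sea_state = ss, julian_day = 180,
             year = 2021, effort = effort)
}

test_that("a straight crossing strip has rectangle effort, off-effort none", {
  g <- build_grid(c(0, 12, 0, 12), 4)
  seg <- mk_seg(6, 4, 6, 8)          # 4 km through the central cell
  ef <- effort_per_cell(g, seg)
  expect_equal(nrow(ef), 1L)
  expect_equal(ef$cell, 5L)
  expect_equal(ef$effort_km2, 4 * 0.4, tolerance = 1e-12)
  expect_equal(ef$line_km, 4, tolerance = 1e-12)
  seg_off <- mk_seg(6, 4, 6, 8, effort = FALSE)
  expect_equal(nrow(effort_per_cell(g, seg_off)), 0L)
})

test_that("diagonal strips match the convex polygon-intersection oracle", {
  g <- build_grid(c(0, 12, 0, 12), 4)
  set.seed(5)
  for (r in 1:20) {
    p0 <- runif(2, 1, 11); p1 <- runif(2, 1, 11)
    if (sum((p1 - p0)^2) < 1) next
    seg <- mk_seg(p0[1], p0[2], p1[1], p1[2])
    ef <- effort_per_cell(g, seg)
    rect <- oracle_strip_rect(p0, p1, 0.2)
    for (k in seq_len(nrow(ef))) {
      cr <- cell_rect(g, ef$cell[k])
      cellpoly <- rbind(c(cr[1], cr[3]), c(cr[2], cr[3]),
                        c(cr[2], cr[4]), c(cr[1], cr[4]))
      expect_equal(ef$effort_km2[k], convex_intersection_area(rect, cellpoly),
                   tolerance = 1e-9)
    }
  }
})

test_that("splitting a transect into abutting on-effort legs leaves effort unchanged", {
  g <- build_grid(c(0, 24, 0, 24), 4)
  whole <- mk_seg(7, 2, 7, 22)
  split2 <- rbind(mk_seg(7, 2, 7, 13.37), mk_seg(7, 13.37, 7, 22))
  e1 <- effort_per_cell(g, whole)
  e2 <- effort_per_cell(g, split2)
  expect_equal(e1$cell, e2$cell)
  expect_equal(e1$effort_km2, e2$effort_km2, tolerance = 1e-9)
  # overlapping on-effort intervals are unioned, not double counted
  overlap <- rbind(mk_seg(7, 2, 7, 16), mk_seg(7, 10, 7, 22))
  e3 <- effort_per_cell(g, overlap)
  expect_equal(e3$effort_km2, e1$effort_km2, tolerance = 1e-9)
})

test_that("effort never exceeds the cell area and zero-length segments are dropped", {
  s <- quick_survey(seed = 3)
  expect_true(all(s$records$effort_km2 <= 16 + 1e-9))
  g <- build_grid(c(0, 12, 0, 12), 4)
  expect_message(ef <- effort_per_cell(g, rbind(mk_seg(6, 4, 6, 4),
                                                mk_seg(2, 1, 2, 3))),
                 "zero-length")
  expect_equal(nrow(ef), 1L)
})

test_that("count aggregation conserves individuals and zero-fills surveyed cells", {
  g <- build_grid(c(0, 12, 0, 12), 4)
  seg <- mk_seg(6, 0, 6, 12)
  ef <- effort_per_cell(g, seg)
  si <- data.frame(transect_id = "T1",
                   x = c(6.1, 5.9, 6.0, 6.05), y = c(1, 1.5, 5, 5.2),
                   group_size = c(1, 2, 1, 3))
  rec <- aggregate_counts(g, si, ef)
  expect_equal(sum(rec$count), sum(si$group_size))
  expect_equal(rec$count[rec$cell == 2], 3L)
  expect_equal(rec$count[rec$cell == 5], 4L)
  expect_equal(rec$count[rec$cell == 8], 0L)
  # no sightings: all surveyed cells get zero counts
  rec0 <- aggregate_counts(g, si[0, ], ef)
  expect_true(all(rec0$count == 0L))
  # sightings outside any surveyed strip raise a consistency warning
  si_out <- rbind(si, data.frame(transect_id = "T1", x = 1, y = 1,
                                 group_size = 2))
  expect_warning(rec2 <- aggregate_counts(g, si_out, ef), "outside")
  expect_equal(sum(rec2$count), sum(si_out$group_size))
  expect_error(aggregate_counts(g, data.frame(transect_id = "T1", x = 40,
                                              y = 1, group_size = 1), ef),
               "outside the grid")
})

test_that("count conservation holds on simulated surveys", {
  s <- quick_survey(seed = 6, intercept = -0.8)
  expect_equal(sum(s$records$count), sum(s$sightings$group_size))
})

test_that("dual-altitude subset keeps exactly the cells surveyed at both altitudes", {
  rec <- data.frame(cell = c(1, 1, 2, 3, 3, 3),
                    transect_id = c("B1", "F1", "B1", "B2", "F2", "F3"),
                    altitude = c("high", "low", "high", "high", "low", "low"))
  d <- dual_altitude_subset(rec)
  expect_setequal(unique(d$cell), c(1, 3))
  expect_equal(nrow(d[d$cell == 3, ]), 3L)   # all passes retained
  # brute-force membership oracle on a simulated design
  s <- quick_survey(seed = 8, fine_region = c(0, 48, 0, 48),
                    broad_spacing_km = 8)
  d2 <- dual_altitude_subset(s$records)
  oracle <- vapply(split(s$records$altitude, s$records$cell),
                   function(a) any(a == "high") && any(a == "low"), TRUE)
  expect_setequal(unique(d2$cell),
                  as.integer(names(oracle))[oracle])
})
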