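test_that("core/edge classification matches the forced tiny cases", {
  # 3x3 marsh in water: 1 core, 8 edge, all unvegetated exposure
  lc <- make_lc(block_codes(5, 3, bg = 1L))
  ce <- classify_core_edge(lc)
  expect_equal(ce$n_core, 1)
  expect_equal(ce$n_edge, 8)
  expect_equal(ce$n_unveg_edge, 8)
  expect_equal(area_to_edge_ratio(ce), 1 / 8)
  expect_equal(unvegetated_edge_ratio(ce), 1)

  # single marsh cell
  lc1 <- make_lc(block_codes(3, 1, bg = 1L))
  ce1 <- classify_core_edge(lc1)
  expect_equal(ce1$n_core, 0)
  expect_equal(ce1$n_edge, 1)

  # 5x5 marsh surrounded by vegetated natural upland: all edges vegetated
  lc2 <- make_lc(block_codes(7, 5, bg = 4L))
  ce2 <- classify_core_edge(lc2)
  expect_equal(ce2$n_core, 9)
  expect_equal(ce2$n_edge, 16)
  expect_equal(ce2$n_unveg_edge, 0)
  expect_equal(ce2$n_veg_edge, 16)
  expect_equal(area_to_edge_ratio(ce2), 9 / 16)
  expect_equal(unvegetated_edge_ratio(ce2), 0)
})

test_that("edge convention: all-marsh grid has no edge, ratio uses n_core/1", {
  lc <- make_lc(matrix(2L, 4, 4))
  ce <- classify_core_edge(lc)
  expect_equal(ce$n_edge, 0)
  expect_equal(ce$n_core, 16)
  expect_equal(area_to_edge_ratio(ce), 16)
  expect_equal(unvegetated_edge_ratio(ce), 0)
})

test_that("no marsh in mask gives missing metrics", {
  lc <- make_lc(matrix(1L, 3, 3))
  ce <- classify_core_edge(lc)
  expect_true(is.na(area_to_edge_ratio(ce)))
  expect_true(is.na(unvegetated_edge_ratio(ce)))
  expect_error(classify_core_edge(lc, mask = matrix(FALSE, 3, 3)), "empty")
})

test_that("square-block ratio follows the closed form (s-2)^2/(4s-4)", {
  for (s in 3:10) {
    lc <- make_lc(block_codes(s + 4, s, bg = 1L))
    ce <- classify_core_edge(lc)
    expect_equal(area_to_edge_ratio(ce), (s - 2)^2 / (4 * s - 4), label = s)
  }
  # monotone in s
  vals <- sapply(3:10, function(s)
    area_to_edge_ratio(classify_core_edge(make_lc(block_codes(s + 4, s)))))
  expect_true(all(diff(vals) > 0))
})

test_that("classification matches the brute-force oracle on random grids", {
  ct <- default_class_table()
  for (seed in 1:5) {
    set.seed(seed)
    codes <- matrix(sample(c(1L, 2L, 3L, 4L, NA), 15 * 15, replace = TRUE),
                    15, 15)
    lc <- make_lc(ifelse(is.na(codes), NA_integer_, codes))
    for (conn in c(4, 8)) {
      got <- classify_core_edge(lc, connectivity = conn)
      exp <- oracle_core_edge(lc$values, ct, full_mask(lc$values), conn)
      expect_equal(got$n_core, exp$n_core)
      expect_equal(got$n_edge, exp$n_edge)
      expect_equal(got$n_unveg_edge, exp$n_unveg_edge)
    }
  }
})

test_that("core/edge counts are invariant under grid translation and code relabeling", {
  set.seed(42)
  codes <- matrix(sample(c(1L, 2L, 4L), 100, replace = TRUE), 10, 10)
  a <- classify_core_edge(make_lc(codes))
  shifted <- land_cover_grid(codes, default_class_table(), 30,
                             origin = c(5000, 9000))
  b <- classify_core_edge(shifted)
  expect_equal(a$n_core, b$n_core)
  expect_equal(a$n_edge, b$n_edge)
  # relabel open water as unvegetated flat (equivalent flags for edges)
  codes2 <- codes
  codes2[codes2 == 1L] <- 3L
  c2 <- classify_core_edge(make_lc(codes2))
  expect_equal(a$n_core, c2$n_core)
  expect_equal(a$n_edge, c2$n_edge)
  expect_equal(a$n_unveg_edge, c2$n_unveg_edge)
})

test_that("landcover fractions reproduce the arithmetic cases", {
  cs <- 30
  # 10x10 grid: left half developed-high (0.9), right half natural
  codes <- cbind(matrix(8L, 10, 5), matrix(4L, 10, 5))
  lc <- make_lc(codes, cs)
  unit <- whole_grid_unit(lc)
  f <- landcover_fractions(lc, unit = unit, buffer_m = 0)
  expect_equal(unname(f["pct_impervious"]), 45)
  expect_equal(unname(f["pct_natural"]), 50)
  expect_equal(unname(f["pct_agricultural"]), 0)

  # all natural
  f2 <- landcover_fractions(make_lc(matrix(4L, 6, 6)), unit = unit,
                            buffer_m = 0)
  expect_equal(unname(f2), c(0, 100, 0))

  # checkerboard agriculture / water
  codes3 <- matrix(ifelse((row(matrix(0, 8, 8)) + col(matrix(0, 8, 8))) %% 2 == 0,
                          5L, 1L), 8, 8)
  f3 <- landcover_fractions(make_lc(codes3), unit = whole_grid_unit(make_lc(codes3)),
                            buffer_m = 0)
  expect_equal(unname(f3["pct_agricultural"]), 50)
})

test_that("the 150 m buffer extends membership beyond the unit polygon", {
  # unit covers only the west half; east half is developed
  codes <- cbind(matrix(4L, 10, 5), matrix(8L, 10, 5))
  lc <- make_lc(codes)
  cs <- lc$cell_size
  unit <- marsh_unit("U1", rbind(c(0, 0), c(5 * cs, 0), c(5 * cs, 10 * cs),
                                 c(0, 10 * cs)))
  inside_only <- landcover_fractions(lc, unit = unit, buffer_m = 0)
  buffered <- landcover_fractions(lc, unit = unit, buffer_m = 150)
  expect_equal(unname(inside_only["pct_impervious"]), 0)
  expect_gt(unname(buffered["pct_impervious"]), 0)
  # buffered denominator: 5 + 5 buffer columns = all 100 cells at 150 m
  expect_equal(unname(buffered["pct_natural"]), 50)
})

test_that("exclusive classes keep pct_natural + pct_agricultural <= 100", {
  set.seed(8)
  for (i in 1:5) {
    codes <- matrix(sample(c(1L, 2L, 4L, 5L, 7L), 64, replace = TRUE), 8, 8)
    lc <- make_lc(codes)
    f <- landcover_fractions(lc, unit = whole_grid_unit(lc), buffer_m = 0)
    expect_lte(f[["pct_natural"]] + f[["pct_agricultural"]], 100)
  }
})
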