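test_that("interval validation rejects malformed spans", {
  expect_error(gi("1", 100, 100), "start >= end")
  expect_error(gi("1", 200, 100), "start >= end")
  expect_error(gi("1", -5, 100), ">= 0")
  expect_silent(gi("1", 0, 1))
})

test_that("intersection reproduces the overlapping-duplication coordinates", {
  dup5 <- gi("10", 134492316, 134941539)
  dup6 <- gi("10", 134543728, 134955025)
  ov <- gi_intersect(dup5, dup6)
  expect_equal(ov$start, 134543728)
  expect_equal(ov$end, 134941539)

  dup3 <- gi("X", 6442757, 8115638)
  dup4 <- gi("X", 6404592, 6907093)
  ov2 <- gi_intersect(dup3, dup4)
  expect_equal(ov2$start, 6442757)
  expect_equal(ov2$end, 6907093)
})

test_that("intersection identity, disjointness and chromosome separation", {
  a <- gi("1", 100, 500)
  expect_equal(gi_intersect(a, a)[, c("start", "end")],
               a[, c("start", "end")])
  expect_null(gi_intersect(gi("1", 0, 100), gi("1", 200, 300)))
  expect_null(gi_intersect(gi("1", 0, 100), gi("2", 0, 100)))
  # chr-prefix tolerance
  expect_equal(gi_intersect(gi("chr1", 0, 100), gi("1", 50, 150))$start, 50)
})

test_that("reciprocal overlap: identity, nesting, published pair, symmetry", {
  a <- gi("1", 0, 1000)
  expect_equal(reciprocal_overlap(a, a), 1.0)
  half <- gi("1", 250, 750) # nested, half the size
  expect_equal(reciprocal_overlap(half, a), 0.5)
  expect_equal(reciprocal_overlap(a, half), 0.5)

  dup5 <- gi("10", 134492316, 134941539)
  dup6 <- gi("10", 134543728, 134955025)
  ro <- reciprocal_overlap(dup5, dup6)
  expect_equal(ro, min(397811 / 449223, 397811 / 411297))
  expect_gt(ro, 0.5)

  # property: symmetry and the containment bound over random pairs
  set.seed(11)
  for (i in 1:200) {
    s1 <- sample(0:1000, 1); e1 <- s1 + sample(1:500, 1)
    s2 <- sample(0:1000, 1); e2 <- s2 + sample(1:500, 1)
    x <- gi("7", s1, e1); y <- gi("7", s2, e2)
    expect_identical(reciprocal_overlap(x, y), reciprocal_overlap(y, x))
    isect <- gi_intersect(x, y)
    w <- if (is.null(isect)) 0 else gi_width(isect)
    expect_lte(w, min(gi_width(x), gi_width(y)))
    contained <- (s1 <= s2 && e2 <= e1) || (s2 <= s1 && e1 <= e2)
    expect_identical(w == min(gi_width(x), gi_width(y)), contained)
  }
})

test_that("reciprocal overlap agrees with IRanges on random pairs", {
  skip_if_not_installed("IRanges")
  set.seed(23)
  for (i in 1:50) {
    s1 <- sample(0:1000, 1); e1 <- s1 + sample(1:500, 1)
    s2 <- sample(0:1000, 1); e2 <- s2 + sample(1:500, 1)
    # IRanges is 1-based closed; shift our half-open [s, e) to [s+1, e]
    w <- IRanges::width(IRanges::pintersect(
      IRanges::IRanges(s1 + 1, e1), IRanges::IRanges(s2 + 1, e2),
      resolve.empty = "max.start"))
    expected <- if (w <= 0) 0 else min(w / (e1 - s1), w / (e2 - s2))
    expect_equal(reciprocal_overlap(gi("1", s1, e1), gi("1", s2, e2)),
                 expected)
  }
})

test_that("size labels floor and match every printed table cell", {
  fixture <- read.delim(table1_fixture()$cnvs, stringsAsFactors = FALSE)
  expect_identical(format_size(fixture$end - fixture$start),
                   table1_expected_labels)
  expect_identical(format_size(999), "0 Kb")
  expect_identical(format_size(182706), "182 Kb") # floored, not rounded up
  expect_identical(format_size(999999), "999 Kb")
  expect_identical(format_size(1000000), "1.00 Mb")
  expect_identical(format_size(1672881), "1.67 Mb")
  expect_error(format_size(-1), ">= 0")

  # monotone non-decreasing under numeric ordering within a unit
  bp <- sort(c(0, 500, 1500, 49999, 50000, 999999, 1e6, 1672881, 2e6))
  kb <- as.numeric(sub(" Kb", "", grep("Kb", format_size(bp), value = TRUE)))
  expect_false(is.unsorted(kb))
  mb <- as.numeric(sub(" Mb", "", grep("Mb", format_size(bp), value = TRUE)))
  expect_false(is.unsorted(mb))
})

test_that("BED round-trip preserves intervals and sorts output", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), f)
  expect_equal(nrow(read_bed(f)), 0L)

  writeLines("10\t134492316\t134941539\tcase5", f)
  one <- read_bed(f)
  expect_equal(nrow(one), 1L)
  expect_equal(gi_width(one), 449223)
  expect_identical(one$label, "case5")

  x <- gi(c("2", "1", "1"), c(500, 900, 100), c(900, 1000, 300),
          label = c("c", "b", "a"))
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f2)
  back <- read_bed(f2)
  expect_identical(back, gi_sort(x))
  # write(read(f)) is a fixed point
  f3 <- withr::local_tempfile(fileext = ".bed")
  write_bed(back, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("BED parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t10\t20", "1\t30\tx"), f)
  expect_error(read_bed(f), "line 2.*non-integer")
  writeLines(c("1\t10\t20", "1\t50\t40"), f)
  expect_error(read_bed(f), "line 2.*start >= end")
  writeLines("1\t10", f)
  expect_error(read_bed(f), "line 1.*fewer than 3")
})

test_that("union length merges overlapping intervals before measuring", {
  x <- gi(c("1", "1"), c(0, 20), c(30, 60))
  expect_equal(gi_union_length(x), 60)
  expect_equal(gi_union_length(gi("1", 0, 10)), 10)
  expect_equal(gi_union_length(x[0, ]), 0)
})
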