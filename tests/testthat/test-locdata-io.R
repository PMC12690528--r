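test_that("localization CSV write -> read round-trips every field", {
  tab <- localization_table(
    x_nm = c(10.125, 0.1 + 0.2, 1234.56789, 5),
    y_nm = c(-3.5, 2e-3, 999.999, 7),
    frame = 1:4, uncertainty_nm = c(5, 15.5, 19.9, 0),
    channel = c("561", "647", "561", "647")
  )
  p <- withr::local_tempfile(fileext = ".csv")
  write_localizations(tab, p)
  back <- read_localizations(p)
  expect_identical(back$x_nm, tab$x_nm)
  expect_identical(back$y_nm, tab$y_nm)
  expect_identical(back$uncertainty_nm, tab$uncertainty_nm)
  expect_identical(back$frame, tab$frame)
  expect_identical(back$channel, tab$channel)

  empty <- localization_table()
  write_localizations(empty, p)
  expect_identical(readLines(p),
                   "x_nm,y_nm,frame,uncertainty_nm,channel")
  expect_equal(nrow(read_localizations(p)), 0L)
})

test_that("unparseable rows error naming the row, or warn+skip when permissive", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,frame,uncertainty_nm,channel",
               "1,2,1,5,561", "3,4,2,6,647", "5,6,3,NA,561"), p)
  expect_error(read_localizations(p), "row\\(s\\) 3")
  expect_warning(tab <- read_localizations(p, permissive = TRUE),
                 "rows dropped")
  expect_equal(nrow(tab), 2L)

  expect_error(read_localizations(tempfile()), "not found")
  writeLines(c("a,b", "1,2"), p)
  expect_error(read_localizations(p), "missing")
})

test_that("alternative column dialects are honored and frame is optional", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("X [nm],Y [nm],sigma [nm],color",
               "100,200,8,647", "300,400,12,647"), p)
  tab <- read_localizations(
    p, loc_dialect(x = "X [nm]", y = "Y [nm]", uncertainty = "sigma [nm]",
                   channel = "color", frame = NA))
  expect_equal(tab$x_nm, c(100, 300))
  expect_equal(tab$frame, c(0L, 0L))
})

test_that("precision filter keeps strictly sub-threshold records and is idempotent", {
  tab <- localization_table(1:5, 1:5, 1L, c(5, 15, 19.9, 20, 25), "561")
  f <- suppressMessages(filter_by_precision(tab, 20))
  expect_equal(f$uncertainty_nm, c(5, 15, 19.9))
  expect_identical(suppressMessages(filter_by_precision(f, 20)), f)
  expect_message(filter_by_precision(tab, 20), "retained 3, discarded 2")

  zero <- localization_table(1:3, 1:3, 1L, 0, "561")
  expect_equal(nrow(suppressMessages(filter_by_precision(zero, 20))), 3L)
  empty <- localization_table()
  expect_equal(nrow(suppressMessages(filter_by_precision(empty, 20))), 0L)
  expect_error(filter_by_precision(tab, 0), "positive")
  # input unmodified
  expect_equal(nrow(tab), 5L)
})

test_that("ROI extraction is boundary inclusive, channel-partitioned, origin-shifted", {
  tab <- localization_table(
    x_nm = c(10, 1000, 100, 50), y_nm = c(10, 1000, 40, 60),
    frame = 1L, uncertainty_nm = 5,
    channel = c("561", "561", "561", "647")
  )
  roi <- roi_spec("r1", list(xmin = 0, ymin = 0, xmax = 100, ymax = 100),
                  "test", ref_channel = "561")
  out <- extract_roi(tab, roi)
  expect_named(out, c("561", "647"))
  # boundary point (100, 40) included; coordinates ROI-local
  expect_equal(sort(out[["561"]]$x_nm), c(10, 100))
  expect_equal(out[["647"]]$x_nm, 50)
  # disjoint channel partition
  expect_equal(sum(vapply(out, nrow, integer(1L))), 3L)

  far <- roi_spec("r2", list(xmin = 5000, ymin = 5000, xmax = 6000,
                             ymax = 6000), "test", ref_channel = "561")
  expect_error(extract_roi(tab, far), "empty reference channel")
})

test_that("polygon ROIs include boundary points and reject outside points", {
  tri <- rbind(c(0, 0), c(200, 0), c(0, 200))
  roi <- roi_spec("tri", tri, "test", ref_channel = "561")
  tab <- localization_table(c(10, 150, 100), c(10, 150, 0), 1L, 5, "561")
  out <- extract_roi(tab, roi)
  # (150,150) outside the triangle; (100,0) on its edge
  expect_equal(sort(out[["561"]]$x_nm), c(10, 100))
})

test_that("ROI files round-trip through JSON", {
  rois <- list(
    roi_spec("a", list(xmin = 0, ymin = 0, xmax = 100, ymax = 50),
             "cond1", "561"),
    roi_spec("b", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
             "cond2", "647")
  )
  p <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, p)
  back <- read_rois(p)
  expect_equal(back[[1L]]$bounds$xmax, 100)
  expect_equal(back[[1L]]$condition, "cond1")
  expect_true(is.matrix(back[[2L]]$bounds))
  expect_equal(back[[2L]]$bounds, rois[[2L]]$bounds)
})

test_that("filtering commutes with ROI extraction and never leaks outside points", {
  set.seed(11)
  for (rep in 1:20) {
    tab <- random_loc_table(200)
    x0 <- runif(1, 0, 500); y0 <- runif(1, 0, 500)
    roi <- roi_spec("p", list(xmin = x0, ymin = y0,
                              xmax = x0 + runif(1, 50, 400),
                              ymax = y0 + runif(1, 50, 400)),
                    "prop", ref_channel = "561")
    res <- tryCatch(
      suppressMessages(
        extract_roi(filter_by_precision(tab, 20), roi)),
      error = function(e) NULL)  # ref channel may be empty by chance
    if (is.null(res)) next
    alt <- lapply(suppressMessages(
      extract_roi(tab, roi)), filter_by_precision, 20, quiet = TRUE)
    alt <- alt[vapply(alt, nrow, integer(1L)) > 0L]
    expect_equal(lapply(res, as.data.frame),
                 lapply(alt[names(res)], as.data.frame))
    org <- c(x0, y0)
    for (ch in res) {
      expect_true(all(ch$x_nm >= 0 & ch$x_nm <= roi$bounds$xmax - x0))
      expect_true(all(ch$y_nm >= 0 & ch$y_nm <= roi$bounds$ymax - y0))
    }
  }
})

test_that("invalid tables and ROIs are rejected at construction", {
  expect_error(localization_table(Inf, 1), "finite")
  expect_error(localization_table(1, 1, 1L, -2, "561"), ">= 0")
  expect_error(localization_table(1, 1, 1L, 5, ""), "non-empty")
  expect_error(roi_spec("r", list(xmin = 0, ymin = 0, xmax = 0,
                                  ymax = 10), "c", "561"), "degenerate")
})
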