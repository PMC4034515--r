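test_that("box averaging matches direct summation", {
  expect_equal(box_average(c(0, 0, 3, 0, 0), 1), c(0, 1, 1, 1, 0))
  expect_equal(box_average(c(6), 1), 6)
  expect_equal(box_average(rep(2.5, 4), 3), rep(2.5, 4))
  expect_error(box_average(1:5, 0), "half_width")
  expect_error(box_average(numeric(0), 1), "nonempty")

  set.seed(11)
  for (rep in 1:25) {
    x <- rnorm(sample(1:40, 1))
    h <- sample(1:5, 1)
    for (edge in c("truncate", "mirror")) {
      expect_equal(box_average(x, h, edge), naive_box(x, h, edge),
                   tolerance = 1e-12)
    }
  }
})

test_that("cascade averaging equals composed brute-force box filters", {
  set.seed(23)
  for (rep in 1:100) {
    x <- rnorm(sample(1:50, 1))
    got <- suppressWarnings(cascade_average(x, 4))
    want <- naive_cascade(x, 4)
    for (n in 1:4) expect_equal(got[[n]], want[[n]], tolerance = 1e-12)
  }
  # mirror edge rule too
  x <- rnorm(30)
  got <- cascade_average(x, 4, "mirror")
  want <- naive_cascade(x, 4, "mirror")
  for (n in 1:4) expect_equal(got[[n]], want[[n]], tolerance = 1e-12)
})

test_that("cascade preserves constants and stays within the input range", {
  for (edge in c("truncate", "mirror")) {
    const <- suppressWarnings(cascade_average(rep(3.7, 6), 5, edge))
    for (f in const) expect_identical(f, rep(3.7, 6))
    one <- suppressWarnings(cascade_average(42, 3, edge))
    for (f in one) expect_identical(f, 42)
  }
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(sample(12:60, 1))
    for (f in cascade_average(x, 5)) {
      expect_true(all(f >= min(x) - 1e-12 & f <= max(x) + 1e-12))
    }
  }
})

test_that("cascade is linear and shift-covariant in the interior", {
  set.seed(9)
  f <- rnorm(45); g <- rnorm(45); a <- 2.3; b <- -0.7
  lhs <- cascade_average(a * f + b * g, 4)
  fa <- cascade_average(f, 4); gb <- cascade_average(g, 4)
  for (n in 1:4) {
    expect_equal(lhs[[n]], a * fa[[n]] + b * gb[[n]], tolerance = 1e-12)
  }

  # interior positions at distance > sum of half-widths from both ends
  x <- rnorm(60)
  shifted <- c(rnorm(3), x)          # shift input right by 3
  fx <- cascade_average(x, 4)[[4]]
  fs <- cascade_average(shifted, 4)[[4]]
  margin <- sum(1:4)                 # 10
  interior <- (margin + 1):(60 - margin)
  expect_equal(fs[interior + 3], fx[interior], tolerance = 1e-12)
})

test_that("the level u is the whole-chain mean of the raw series", {
  expect_equal(mean_level(c(1, -1)), 0)
  expect_equal(mean_level(c(2, 2, 2)), 2)
  expect_error(mean_level(numeric(0)), "nonempty")
  # u comes from f0, not from the smoothed series
  x <- c(rep(1, 5), rep(-1, 15))
  prof <- hydro_profile(paste(rep(c("L", "K"), c(5, 15)), collapse = ""),
                        "H3", n = 2)
  expect_equal(prof$u, mean(x))
})

test_that("profiles carry all passes and export per-residue tables", {
  expect_warning(cascade_average(1:5, 4), "window width")
  prof <- hydro_profile("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", "H1", n = 4)
  expect_s3_class(prof, "hydro_profile")
  expect_length(prof$passes, 4)
  expect_identical(prof$series, prof$passes[["f4"]])
  tab <- profile_table(prof)
  expect_identical(names(tab),
                   c("position", "residue", "f0", "f1", "f2", "f3", "f4", "u"))
  expect_equal(nrow(tab), length(prof$f0))
  expect_equal(tab$f0, prof$f0)
  expect_equal(tab$f4, prof$series)
  expect_true(all(tab$u == prof$u))
  # explicit constant level overrides the mean
  prof2 <- hydro_profile("MKTAYIAKQR", "H1", n = 2, level = 0.25)
  expect_equal(prof2$u, 0.25)
})
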