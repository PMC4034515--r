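test_that("segments are the maximal runs strictly above the level", {
  expect_equal(detect_segments(c(0, 1, 1, 0), u = 0.5)[, c("start", "end")],
               data.frame(start = 2L, end = 3L))
  two <- detect_segments(c(1, 0, 1), u = 0.5)
  expect_equal(two$start, c(1L, 3L))
  expect_equal(two$end, c(1L, 3L))
  # a value exactly at the level counts as below
  expect_equal(nrow(detect_segments(c(0.5), u = 0.5)), 0L)

  # covered positions are exactly {k : f(k) > u}
  set.seed(31)
  for (rep in 1:20) {
    f <- rnorm(80); u <- rnorm(1, sd = 0.5)
    segs <- detect_segments(f, u = u)
    expect_identical(covered_positions(segs), which(f > u))
    expect_false(is.unsorted(segs$start, strictly = TRUE))
  }
})

test_that("raising the level never enlarges coverage", {
  set.seed(17)
  f <- cascade_average(rnorm(120), 4)[[4]]
  us <- sort(rnorm(8, sd = 0.2))
  cov <- lapply(us, function(u) covered_positions(detect_segments(f, u = u)))
  for (i in seq_along(us)[-1]) {
    expect_true(all(cov[[i]] %in% cov[[i - 1]]))
    expect_lte(length(cov[[i]]), length(cov[[i - 1]]))
  }
})

test_that("segments classify by N-terminal position and length", {
  params <- segmentation_params()
  segs <- make_segments(c(11, 100, 143), c(23, 105, 166), kind = "hydrophobic_region")
  got <- classify_segments(segs, 400, params)
  expect_equal(got$kind, c("signal_peptide", "hydrophobic_region", "tmd"))
  # overlapping input is rejected
  bad <- make_segments(c(10, 20), c(25, 40))
  expect_error(classify_segments(bad, 100, params), "disjoint")
  expect_error(classify_segments(make_segments(5, 200), 100, params),
               "out of range")
})

test_that("merged double domains split from the outer boundaries", {
  s1 <- split_merged_segment(c(89, 151))
  expect_equal(s1$start, c(89L, 131L))
  expect_equal(s1$end, c(109L, 151L))
  s2 <- split_merged_segment(c(246, 312))
  expect_equal(s2$start, c(246L, 292L))
  expect_equal(s2$end, c(266L, 312L))
  expect_true(all(s1$kind == "tmd") && all(s1$source == "split"))
  # children stay inside the parent and have length L_avg + 1 each
  expect_true(all(s1$start >= 89 & s1$end <= 151))
  expect_equal(s1$end - s1$start + 1L, c(21L, 21L))
  expect_error(split_merged_segment(c(10, 40)), "too narrow")

  wide <- make_segments(c(5, 89), c(20, 151))
  out <- split_wide_segments(wide)
  expect_equal(out$start, c(5L, 89L, 131L))
  expect_equal(out$source, c("detected", "split", "split"))
})

test_that("planted noiseless topographies are recovered end to end", {
  arch <- block_architecture(
    c("loop", "tmd", "loop", "tmd", "loop", "tmd", "loop"),
    c(25, 21, 20, 17, 30, 28, 22), seed = 101)
  gp <- generate_block_protein(arch, id = "planted3")
  pred <- predict_topography(gp$sequence, "H3", n = 4)
  tmds <- pred$segments[pred$segments$kind == "tmd", ]
  expect_equal(nrow(tmds), 3L)
  truth <- gp$annotation$tmds
  expect_true(all(abs(tmds$start - truth$start) <= 5))
  expect_true(all(abs(tmds$end - truth$end) <= 5))

  # all-hydrophilic chain: nothing ever exceeds the level
  philic <- paste(rep(hydrophilic_residues, 8), collapse = "")
  none <- predict_topography(philic, "H3", n = 4)
  expect_equal(nrow(none$segments[none$segments$kind == "tmd", ]), 0L)

  # prediction output is disjoint, sorted, within bounds, deterministic
  expect_true(all(pred$segments$start >= 1 &
                    pred$segments$end <= gp$sequence$length))
  expect_identical(pred$segments,
                   predict_topography(gp$sequence, "H3", n = 4)$segments)
})

test_that("opt-in splitting applies only to over-wide tmd segments", {
  arch <- block_architecture(c("loop", "tmd", "loop"), c(30, 60, 30),
                             seed = 7)
  gp <- generate_block_protein(arch)
  plain <- predict_topography(gp$sequence, "H3", n = 4)
  split <- predict_topography(gp$sequence, "H3", n = 4,
                              params = segmentation_params(split_enabled = TRUE))
  expect_equal(sum(plain$segments$source == "split"), 0L)
  stmd <- split$segments[split$segments$source == "split", ]
  expect_equal(nrow(stmd), 2L)
  ptmd <- plain$segments[plain$segments$kind == "tmd", ]
  expect_true(all(stmd$start >= min(ptmd$start) & stmd$end <= max(ptmd$end)))
})
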