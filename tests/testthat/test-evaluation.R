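test_that("a prediction evaluated against itself scores perfectly", {
  ref <- make_reference("X1", c(10, 40, 80), c(30, 60, 100))
  pred <- make_segments(c(10, 40, 80), c(30, 60, 100))
  for (tol in c(0, 3, 6)) {
    ev <- match_domains(pred, ref, tolerance = tol)
    expect_equal(ev$n_resolved, 3L)
    expect_equal(ev$n_boundaries_ok, 6L)
    expect_true(all(ev$per_domain$dev_left == 0))
    expect_true(all(ev$per_domain$dev_right == 0))
  }
})

test_that("a merged prediction spanning two domains resolves neither", {
  # the published serotonin-receptor case: one 89-151 segment covers the
  # 2nd (91-113) and 3rd (130-151) reference domains
  ref <- make_reference("P41595",
                        c(57, 91, 130, 172, 217, 325, 361),
                        c(79, 113, 151, 192, 239, 345, 382))
  pred <- make_segments(c(54, 89, 173, 215, 325, 356),
                        c(81, 151, 194, 243, 352, 381))
  ev <- match_domains(pred, ref, tolerance = 6)
  expect_equal(ev$n_resolved, 5L)
  expect_equal(ev$n_revealed, 6L)           # merged region counted once
  expect_false(ev$per_domain$resolved[2])
  expect_false(ev$per_domain$resolved[3])
  # unresolved boundaries count as failures
  expect_false(any(ev$per_domain$ok_left[2:3]))

  # after the outer-boundary split all seven resolve
  ev2 <- match_domains(split_wide_segments(pred), ref, tolerance = 6)
  expect_equal(ev2$n_resolved, 7L)
  expect_equal(ev2$n_boundaries_ok, 13L)    # only 352 vs 345 deviates > 6
})

test_that("overlap keeps resolution but shifted boundaries fail the tolerance", {
  ref <- make_reference("S", c(20, 60), c(40, 80))
  pred <- make_segments(c(30, 70), c(50, 90))   # +10 shift, overlap retained
  ev <- match_domains(pred, ref, tolerance = 6)
  expect_equal(ev$n_resolved, 2L)
  expect_equal(ev$n_boundaries_ok, 0L)
})

test_that("boundary agreement is monotone in the tolerance", {
  set.seed(41)
  ref <- make_reference("M", c(10, 50, 90, 130), c(30, 70, 110, 150))
  pred <- make_segments(c(10, 50, 90, 130) + sample(-9:9, 4),
                        c(30, 70, 110, 150) + sample(-9:9, 4))
  oks <- vapply(0:12, function(tol) {
    ev <- match_domains(pred, ref, tolerance = tol)
    # verdict conservation: every boundary is counted exactly once
    expect_equal(nrow(ev$per_domain) * 2L, ev$n_boundaries)
    ev$n_boundaries_ok
  }, numeric(1))
  expect_true(all(diff(oks) >= 0))
})

test_that("protein identity and input order are enforced", {
  ref <- make_reference("A", 10, 30)
  pred_obj <- predict_topography(
    generate_block_protein(block_architecture(
      c("loop", "tmd", "loop"), c(20, 20, 20), seed = 3), id = "B")$sequence,
    "H3", n = 4)
  expect_error(match_domains(pred_obj, ref), "id mismatch")
  expect_error(match_domains(make_segments(c(20, 10), c(40, 30)), ref),
               "sorted")
})

test_that("aggregation sums counts and reports published-style percentages", {
  perfect <- match_domains(make_segments(c(10, 40), c(30, 60)),
                           make_reference("p", c(10, 40), c(30, 60)))
  expect_equal(aggregate_reports(list(perfect))$pct_resolved, 100)
  expect_equal(aggregate_reports(list(perfect))$pct_boundaries_ok, 100)

  # a cohort resolving 34 of 35 domains reads 97% at integer precision
  ref7 <- make_reference("q", seq(10, 250, 40), seq(30, 270, 40))
  full <- match_domains(make_segments(seq(10, 250, 40), seq(30, 270, 40)), ref7)
  merged <- match_domains(
    make_segments(c(10, 50, 130, 170, 210, 250),
                  c(30, 110, 150, 190, 230, 270)), ref7)
  expect_equal(merged$n_revealed, 6L)
  agg <- aggregate_reports(c(rep(list(full), 4), list(merged)))
  expect_equal(agg$n_ref_tmds, 35)
  expect_equal(agg$n_revealed, 34)
  expect_equal(round(agg$pct_revealed), 97)

  expect_error(aggregate_reports(list()), "no reports")
  expect_error(aggregate_reports(list(match_domains(
    make_segments(10, 30), make_reference("p", 10, 30), tolerance = 3),
    perfect)), "different tolerances")
})
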