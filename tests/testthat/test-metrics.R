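pair_from <- function(pred, gt) {
  depth_pair(matrix(pred, 1), matrix(gt, 1))
}

test_that("worked examples of the individual metrics", {
  expect_equal(abs_rel(pair_from(c(1, 2, 4), c(1, 1, 2))), 100 * (0 + 1 + 1) / 3,
               tolerance = 1e-12)
  gt <- runif(20, 1, 10)
  expect_equal(abs_rel(pair_from(2 * gt, gt)), 100)
  expect_equal(abs_rel(pair_from(gt, gt)), 0)
  expect_equal(rmse(pair_from(3, 1)), 2)
  expect_equal(sq_rel(pair_from(3, 1)), 4)
  expect_equal(rmse(pair_from(gt, gt)), 0)
})

test_that("delta accuracy uses a strict 1.25^n threshold", {
  p <- pair_from(1.0, 1.3)
  expect_equal(delta_accuracy(p, 1), 0)    # 1.3 >= 1.25
  expect_equal(delta_accuracy(p, 2), 100)  # 1.3 < 1.5625
  gt <- c(1, 2, 4, 0.5, 8)  # binary-exact so 1.25*gt/gt is exactly 1.25
  expect_equal(delta_accuracy(pair_from(1.25 * gt, gt), 1), 0)  # boundary
  ident <- pair_from(gt, gt)
  expect_equal(sapply(1:3, delta_accuracy, pair = ident), c(100, 100, 100))
})

test_that("silog variance form is scale-invariant, printed form is not", {
  gt <- runif(30, 0.5, 10)
  for (c in c(0.3, 1, 1.94)) {
    expect_equal(silog(pair_from(c * gt, gt)), 0, tolerance = 1e-12)
  }
  expect_gt(silog(pair_from(2 * gt, gt), form = "printed"), 0)
  # two-pixel hand computation: d = {log 2, 0}
  p <- pair_from(c(2, 1), c(1, 1))
  expect_equal(silog(p), log(2)^2 / 4, tolerance = 1e-12)
  expect_equal(silog(p, "printed"), 3 * log(2)^2 / 4, tolerance = 1e-12)
})

test_that("silog loss reduces to alpha * sd(d) at lambda = 1 and masks nulls", {
  set.seed(31)
  pred <- matrix(runif(100, 1, 10), 10)
  gt <- matrix(runif(100, 1, 10), 10)
  gt[sample(100, 30)] <- 0
  p <- depth_pair(pred, gt)
  d <- log(pred[p$mask]) - log(gt[p$mask])
  expect_equal(silog_loss(p, lambda = 1, alpha = 10),
               10 * sqrt(mean(d^2) - mean(d)^2), tolerance = 1e-12)
  expect_equal(silog_loss(pair_from(gt[gt > 0], gt[gt > 0])), 0)
  # perturbing masked-out pixels never changes the loss
  pred2 <- pred
  pred2[!p$mask] <- 999
  expect_identical(silog_loss(depth_pair(pred2, gt)), silog_loss(p))
})

test_that("log metrics reject non-positive predictions with a pixel count", {
  pred <- matrix(c(1, -1, 0, 2), 2)
  gt <- matrix(c(1, 1, 1, 1), 2)
  p <- depth_pair(pred, gt)
  expect_error(silog(p), "2 masked prediction")
  expect_error(rmse_log(p), "2 masked prediction")
  expect_error(delta_accuracy(p, 1), "2 masked prediction")
  expect_silent(abs_rel(p))  # ratio metrics need only gt > 0
})

test_that("all eight metrics match the brute-force oracle on random pairs", {
  set.seed(32)
  for (i in 1:20) {
    rp <- random_masked_pair(40, 40, dropout = 0.3)
    p <- depth_pair(rp$pred, rp$label)
    o <- oracle_metrics(rp$pred, rp$label, p$mask)
    r <- evaluate_depth(p)
    for (key in names(r))
      expect_equal(r[[key]], o[[key]], tolerance = 1e-12, label = key)
    expect_equal(silog(p, "printed"), o$silog_printed, tolerance = 1e-12)
    expect_equal(p$n, o$n)
  }
})

test_that("metric invariances: pixel permutation, joint scaling, delta ordering", {
  set.seed(33)
  for (i in 1:5) {
    rp <- random_masked_pair(30, 30)
    p <- depth_pair(rp$pred, rp$label)
    r <- evaluate_depth(p)
    expect_true(r$delta1 <= r$delta2 && r$delta2 <= r$delta3)
    expect_lte(r$delta3, 100)
    # permutation invariance
    perm <- sample(900)
    p2 <- depth_pair(matrix(rp$pred[perm], 30), matrix(rp$label[perm], 30))
    expect_equal(evaluate_depth(p2)[], r[], tolerance = 1e-12)
    # joint scaling: scale-free metrics unchanged, rmse scales by c
    c0 <- 3.7
    p3 <- depth_pair(c0 * rp$pred, depth_map(c0 * rp$label, max_range = Inf))
    r3 <- evaluate_depth(p3)
    for (key in c("abs_rel", "silog", "delta1", "delta2", "delta3",
                  "rmse_log", "sq_rel"))
      expect_equal(r3[[key]], r[[key]], tolerance = 1e-9, label = key)
    expect_equal(r3$rmse, c0 * r$rmse, tolerance = 1e-9)
  }
})

test_that("evaluation errors when no valid pixels remain", {
  expect_error(depth_pair(matrix(1, 2, 2), matrix(0, 2, 2)), "no valid")
  expect_error(depth_pair(matrix(1, 2, 2), matrix(10, 2, 2),
                          min_depth = 0, max_depth = 5), "no valid")
  expect_error(depth_pair(matrix(1, 2, 2), matrix(1, 3, 3)), "shapes differ")
})

test_that("dataset aggregation is the unweighted mean of per-image reports", {
  set.seed(34)
  reports <- lapply(1:3, function(i) {
    rp <- random_masked_pair(20, 20)
    evaluate_depth(depth_pair(rp$pred, rp$label))
  })
  m <- mean_report(reports)
  expect_equal(m$abs_rel, mean(sapply(reports, `[[`, "abs_rel")))
  expect_equal(m$rmse, mean(sapply(reports, `[[`, "rmse")))
  expect_equal(attr(m, "n"), 3)
})

test_that("chamfer distance identities and worked example", {
  set.seed(35)
  a <- matrix(runif(60, -5, 5), 20, 3)
  b <- matrix(runif(30, -5, 5), 10, 3)
  expect_equal(chamfer_distance(a, a), 0)
  expect_equal(chamfer_distance(a, b), chamfer_distance(b, a))
  expect_gte(chamfer_distance(a, b), 0)
  expect_equal(chamfer_distance(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1)), 2)
  expect_equal(chamfer_distance(matrix(c(0, 0, 0), 1), matrix(c(1, 0, 0), 1),
                                squared = FALSE), 2)
  expect_equal(chamfer_distance(matrix(c(0, 0, 0), 1), matrix(c(2, 0, 0), 1)), 8)
  expect_equal(chamfer_distance(matrix(c(0, 0, 0), 1), matrix(c(2, 0, 0), 1),
                                squared = FALSE), 4)
  expect_error(chamfer_distance(a[0, ], b), "non-empty")
})

test_that("chamfer distance matches the brute-force oracle", {
  set.seed(36)
  for (i in 1:5) {
    a <- matrix(runif(3 * sample(3:15, 1), -2, 2), ncol = 3)
    b <- matrix(runif(3 * sample(3:15, 1), -2, 2), ncol = 3)
    expect_equal(chamfer_distance(a, b), oracle_chamfer(a, b), tolerance = 1e-12)
    expect_equal(chamfer_distance(a, b, squared = FALSE),
                 oracle_chamfer(a, b, squared = FALSE), tolerance = 1e-12)
  }
})

test_that("metric report serializes with the conventional keys", {
  set.seed(37)
  rp <- random_masked_pair(20, 20)
  r <- evaluate_depth(depth_pair(rp$pred, rp$label))
  f <- withr::local_tempfile(fileext = ".json")
  write_metric_report(r, f)
  j <- jsonlite::read_json(f)
  expect_named(j, c("abs_rel", "rmse", "silog", "delta1", "delta2", "delta3",
                    "rmse_log", "sq_rel"))
  expect_equal(j$abs_rel, r$abs_rel)
})
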