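test_that("confusion counts equal an exhaustive double-loop tally", {
  ones <- matrix(1L, 2, 2)
  zeros <- matrix(0L, 2, 2)
  expect_equal(confusion_counts(ones, ones), list(tp = 4L, fp = 0L, fn = 0L, tn = 0L))
  expect_equal(confusion_counts(ones, zeros)$fp, 4L)
  set.seed(21)
  for (i in 1:10) {
    a <- random_binary_mask(8, 8)
    b <- random_binary_mask(8, 8)
    expect_equal(confusion_counts(a, b), brute_confusion(a, b))
  }
  expect_error(confusion_counts(matrix(2, 2, 2), matrix(1, 2, 2)), "binary")
  expect_error(confusion_counts(matrix(1, 2, 2), matrix(1, 3, 3)), "differ")
})

test_that("overlap metrics follow their formulas and conventions", {
  m <- overlap_metrics(list(tp = 2, fp = 1, fn = 1, tn = 12))
  expect_equal(m$dice, 4 / 6)
  expect_equal(m$jaccard, 0.5)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$specificity, 12 / 13)

  empty <- overlap_metrics(list(tp = 0, fp = 0, fn = 0, tn = 9))
  expect_equal(empty$dice, 1)
  expect_equal(empty$jaccard, 1)
  expect_equal(empty$specificity, 1)

  pred_empty <- overlap_metrics(list(tp = 0, fp = 0, fn = 5, tn = 4))
  expect_equal(pred_empty$dice, 0)
  expect_equal(pred_empty$recall, 0)

  set.seed(22)
  for (i in 1:30) {
    c <- as.list(rmultinom(1, 64, runif(4, 0.05, 1))[, 1])
    names(c) <- c("tp", "fp", "fn", "tn")
    m <- overlap_metrics(c)
    expect_equal(m$f1, m$dice, tolerance = 1e-12)
    expect_equal(m$jaccard, m$dice / (2 - m$dice), tolerance = 1e-12)
  }
})

test_that("surface distances match the exhaustive all-pairs oracle", {
  a <- matrix(0L, 6, 6); a[1, 1] <- 1L
  b <- matrix(0L, 6, 6); b[1, 4] <- 1L
  expect_equal(hd95(a, b), 3.0)
  expect_equal(assd(a, b), 3.0)
  expect_equal(assd(a, b, spacing = c(2, 2)), 6.0)

  disc <- random_disc_mask(10, 10)
  expect_equal(hd95(disc, disc), 0)
  expect_equal(assd(disc, disc), 0)

  set.seed(23)
  for (i in 1:15) {
    p <- random_disc_mask(10, 10)
    g <- random_disc_mask(10, 10)
    sp <- c(runif(1, 0.5, 2), runif(1, 0.5, 2))
    expect_equal(hd95(p, g, sp), brute_hd95(p, g, sp), tolerance = 1e-9)
    expect_equal(assd(p, g, sp), brute_assd(p, g, sp), tolerance = 1e-9)
    # symmetry
    expect_equal(hd95(p, g, sp), hd95(g, p, sp), tolerance = 1e-12)
    expect_equal(assd(p, g, sp), assd(g, p, sp), tolerance = 1e-12)
  }

  empty <- matrix(0L, 6, 6)
  expect_equal(hd95(empty, empty), 0)
  und <- hd95(a, empty)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("region-wise evaluation aggregates the three tumor regions", {
  set.seed(24)
  labs <- matrix(0L, 16, 16)
  labs[4:12, 4:12] <- 2L
  labs[6:10, 6:10] <- 1L
  labs[7:9, 7:9] <- 4L
  rep_perfect <- evaluate_regions(labs, labs)
  expect_equal(rep_perfect["WT", "dice"], 1)
  expect_equal(rep_perfect["TC", "dice"], 1)
  expect_equal(rep_perfect["ET", "dice"], 1)
  expect_equal(rep_perfect["Average", "hd95_mm"], 0)

  # prediction misses ET entirely: dice 0, surface distance undefined
  pred <- labs
  pred[pred == 4L] <- 1L
  rep_miss <- evaluate_regions(pred, labs)
  expect_equal(rep_miss["ET", "dice"], 0)
  expect_true(is.na(rep_miss["ET", "hd95_mm"]))
  expect_equal(attr(rep_miss, "n_undefined"), 1L)
  # averages recomputed by hand over defined entries
  expect_equal(rep_miss["Average", "dice"], mean(rep_miss[1:3, "dice"]))
  expect_equal(rep_miss["Average", "hd95_mm"], mean(rep_miss[1:2, "hd95_mm"]))

  d <- withr::local_tempdir()
  write_metric_report(rep_miss, file.path(d, "r.csv"), file.path(d, "r.json"))
  back <- read.csv(file.path(d, "r.csv"))
  expect_equal(back$region, c("WT", "TC", "ET", "Average"))
  expect_equal(back$dice, rep_miss$dice)
})
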