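test_that("exclusivity metrics reproduce the worked two-pixel example", {
  img <- example_image()
  expect_equal(overall_exclusivity(img), 0.25)
  expect_equal(unname(organelle_exclusivity(img)), c(0.4, 0.1, NA), tolerance = 1e-12)
  pw <- pairwise_exclusivity(img)
  expect_equal(pw["ch0", "ch1"], 0.4, ignore_attr = TRUE)
  expect_equal(pw["ch0", "ch2"], 0.8, ignore_attr = TRUE)
  expect_equal(pw["ch1", "ch0"], 0.5, ignore_attr = TRUE)
  expect_equal(pw["ch1", "ch2"], 0.1, ignore_attr = TRUE)
  # channel 3 is nowhere the argmax: its whole row is undefined, as is the diagonal
  expect_true(all(is.na(pw["ch2", ])))
  expect_true(all(is.na(diag(pw))))
})

test_that("degenerate channel patterns give the expected margins", {
  same <- multichannel_image(array(0.4, c(3, 2, 2, 2)))
  expect_equal(overall_exclusivity(same), 0)
  expect_true(all(pairwise_exclusivity(same)[1, -1] == 0))
  # ties go to the lowest channel index
  expect_equal(unname(organelle_exclusivity(same)), c(0, NA, NA))

  onehot <- multichannel_image(array(rep(c(1, 0, 0), 8), c(3, 2, 2, 2)))
  expect_equal(overall_exclusivity(onehot), 1)
  expect_error(overall_exclusivity(multichannel_image(array(1, c(1, 2, 2, 2)))),
               "two channels")
})

test_that("metrics match the brute-force sorting oracle on random images", {
  for (s in 1:20) {
    img <- random_mc_image(4, c(4, 6, 6), seed = 100 + s)
    oc <- oracle_exclusivity(img$data)
    expect_equal(overall_exclusivity(img), oc$overall, tolerance = 1e-12)
    expect_equal(unname(organelle_exclusivity(img)), oc$per_organelle, tolerance = 1e-12)
    expect_equal(unname(pairwise_exclusivity(img)), oc$pairwise,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("overall equals the occupancy-weighted per-organelle sum", {
  for (s in 1:10) {
    rep_ <- exclusivity_report(random_mc_image(3, c(4, 8, 8), seed = 300 + s))
    defined <- !is.na(rep_$per_organelle)
    expect_equal(rep_$overall,
                 sum(rep_$occupancy[defined] * rep_$per_organelle[defined]),
                 tolerance = 1e-10)
    # pointwise-min inequality against every defined pairwise entry
    for (o in which(defined)) {
      row <- rep_$pairwise[o, ]
      expect_true(all(rep_$per_organelle[o] <= row[!is.na(row)] + 1e-12))
    }
  }
})

test_that("overall exclusivity is invariant to channel order and common offsets,
           and scales linearly with intensity", {
  img <- random_mc_image(4, c(4, 6, 6), seed = 9)
  base <- overall_exclusivity(img)
  perm <- img; perm$data <- img$data[c(3, 1, 4, 2), , , ]
  expect_equal(overall_exclusivity(perm), base, tolerance = 1e-12)
  shifted <- img; shifted$data <- img$data + 5
  expect_equal(overall_exclusivity(shifted), base, tolerance = 1e-10)
  scaled <- img; scaled$data <- img$data * 3.7
  expect_equal(overall_exclusivity(scaled), 3.7 * base, tolerance = 1e-10)
})

test_that("region masks restrict the pixel set", {
  img <- example_image()
  region <- array(c(TRUE, FALSE), c(1, 1, 2))
  expect_equal(overall_exclusivity(img, region), 0.4)
  expect_error(overall_exclusivity(img, array(FALSE, c(1, 1, 2))), "no pixels")
})

test_that("loss terms match hand computations", {
  expect_equal(exclusivity_loss(c(0.2, 0.9), c(0.5, 0.4)), -0.4)
  expect_equal(exclusivity_loss(c(1, 1), c(1, 1)), 0)
  expect_equal(exclusivity_loss(rep(1, 8), rep(0, 8)), -1)
  expect_error(exclusivity_loss(1:4, 1:5), "matching shapes")

  expect_equal(mse(c(0, 1), c(1, 1)), 0.5)
  expect_equal(mse(1:5 + 0.3, 1:5 + 0.0), 0.09)
  expect_equal(mae(c(0.2, 0.9), c(0.5, 0.4)), 0.4)

  pred <- c(0.2, 0.9); truth <- c(0.1, 0.8); om <- c(0.5, 0.4)
  expect_equal(combined_retrain_loss(pred, truth, om, p = 0), mse(pred, truth))
  expect_equal(combined_retrain_loss(pred, truth, om, p = 2),
               mse(pred, truth) + 2 * exclusivity_loss(pred, om))
  expect_equal(combined_retrain_loss(pred, truth, om, p = 1.5, base = "l1"),
               mae(pred, truth) + 1.5 * exclusivity_loss(pred, om))
  expect_equal(combined_retrain_loss(truth, truth, truth, p = 3), 0)
  expect_error(combined_retrain_loss(pred, truth, om, p = 1, base = "huber"))
  expect_error(combined_retrain_loss(pred, truth, om, p = -1), ">= 0")
})

test_that("weight selection maximizes the exclusivity/MSE ratio with ties to small p", {
  expect_equal(select_weight(data.frame(p = 0:2, exclusivity = c(1, 1.5, 1.6),
                                        mse = c(1, 1.2, 1.6))), 1)
  expect_equal(select_weight(list(c(0.5, 2, 1))), 0.5)
  expect_equal(select_weight(data.frame(p = c(1, 2), exclusivity = c(2, 4),
                                        mse = c(1, 2))), 1)
  expect_error(select_weight(data.frame(p = numeric(), exclusivity = numeric(),
                                        mse = numeric())), "empty")
  expect_error(select_weight(data.frame(p = 1, exclusivity = 1, mse = 0)), "positive")
})

test_that("retraining order sorts by exclusivity with alphabetical ties", {
  v <- c(a = 0.4, b = 1.5, c = 1.1)
  expect_identical(retrain_order(v), c("b", "c", "a"))
  expect_identical(retrain_order(v, "increasing"), c("a", "c", "b"))
  expect_identical(retrain_order(c(z = 1)), "z")
  expect_identical(retrain_order(c(b = 1, a = 1, c = 2)), c("c", "a", "b"))
  expect_error(retrain_order(c(a = 1, b = NA)), "b")
})

test_that("exclusivity report tidiers expose all metrics", {
  rep_ <- exclusivity_report(example_image())
  td <- tidy(rep_)
  expect_true(all(c("overall", "organelle", "occupancy", "pairwise") %in% td$metric))
  expect_equal(td$value[td$metric == "overall"], 0.25)
  expect_equal(nrow(td[td$metric == "pairwise", ]), 6)
  gl <- glance(rep_)
  expect_identical(gl$n_undefined, 1L)
  expect_identical(gl$n_pixels, 2L)
})
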