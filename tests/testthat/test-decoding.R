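# small synthetic feature cube: trials x channels x bins at 10 ms spacing
fake_hg <- function(nt = 20, C = 4, t_range = c(-0.3, 0.3), seed = 1,
                    labels = rep(c("a", "b"), nt / 2),
                    effect = 0, effect_from = 0) {
  set.seed(seed)
  bt <- seq(t_range[1], t_range[2], by = 0.01)
  db <- array(rnorm(nt * C * length(bt)), dim = c(nt, C, length(bt)))
  if (effect != 0) {
    sel <- bt >= effect_from
    for (i in which(labels == "a"))
      db[i, 1:(C / 2), sel] <- db[i, 1:(C / 2), sel] + effect
    for (i in which(labels == "b"))
      db[i, (C / 2 + 1):C, sel] <- db[i, (C / 2 + 1):C, sel] + effect
  }
  list(db = db, bin_times_s = bt,
       trials = data.frame(trial = seq_len(nt), label = labels),
       included_channels = rep(TRUE, C))
}

test_that("causal windows have the right count, dimension and causality", {
  hg <- fake_hg(nt = 6, C = 3, t_range = c(-1.1, 1.0))
  w <- causal_windows(hg, t_range = c(-1, 1), step = 0.05)
  expect_length(w$times, 41)                    # -1.0 : 0.05 : 1.0
  expect_equal(ncol(w$features[[1]]), 3 * 10)   # channels x window bins
  # perturbing a bin later than t leaves features at t unchanged
  hg2 <- hg
  hg2$db[, , hg$bin_times_s > 0.02] <- 99
  w2 <- causal_windows(hg2, t_range = c(-1, 0), step = 0.05)
  w1 <- causal_windows(hg, t_range = c(-1, 0), step = 0.05)
  expect_equal(w1$features[[21]], w2$features[[21]])   # t = 0 unchanged
  expect_error(causal_windows(hg, t_range = c(-2, 1)), "window")
})

test_that("class balancing subsamples only past the 1.2 ratio", {
  lab <- c(rep("x", 30), rep("y", 24))          # ratio 1.25 > 1.2
  kept <- balance_classes(lab, seed = 1)
  expect_equal(as.vector(table(lab[kept])), c(24L, 24L))
  lab2 <- c(rep("x", 30), rep("y", 28))         # ratio ~1.07
  expect_equal(balance_classes(lab2, seed = 1), seq_along(lab2))
  lab3 <- rep(c("x", "y"), 10)
  expect_equal(balance_classes(lab3, seed = 5), seq_along(lab3))
  expect_identical(balance_classes(lab, seed = 2), balance_classes(lab, seed = 2))
  expect_error(balance_classes(rep("x", 5)), "two classes")
})

test_that("shuffled labels decode at chance; planted patterns decode well", {
  hg <- fake_hg(nt = 40, C = 6, effect = 3, effect_from = 0,
                labels = rep(c("a", "b"), each = 20), seed = 2)
  w <- causal_windows(hg, t_range = c(-0.1, 0.2), step = 0.1)
  tg <- temporal_generalization(w, hg$trials$label, seed = 3)
  expect_equal(tg$chance, 0.5)
  diag_acc <- diag(tg$accuracy)
  expect_gt(mean(diag_acc[w$times >= 0]), 0.9)  # separable classes
  # null: shuffle labels
  set.seed(4)
  accs <- replicate(8, {
    tgn <- temporal_generalization(w, sample(hg$trials$label),
                                   seed = NULL, diagonal_only = TRUE)
    mean(diag(tgn$accuracy))
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.05)
})

test_that("temporal generalization is causal and reproducible", {
  hg <- fake_hg(nt = 30, C = 4, effect = 4, effect_from = 0.1,
                labels = rep(c("a", "b"), 15), seed = 5)
  w <- causal_windows(hg, t_range = c(-0.2, 0.25), step = 0.05)
  tg1 <- temporal_generalization(w, hg$trials$label, seed = 6)
  tg2 <- temporal_generalization(w, hg$trials$label, seed = 6)
  expect_identical(tg1$accuracy, tg2$accuracy)
  # classifiers trained before the effect cannot decode above chance,
  # classifiers trained after it can
  pre <- w$times < 0
  post <- w$times >= 0.2
  expect_lt(mean(diag(tg1$accuracy)[pre]), 0.75)
  expect_gt(mean(diag(tg1$accuracy)[post]), 0.85)
  expect_error(temporal_generalization(w, rep("a", 20)), "two classes")
})

test_that("multi-class accuracy, AUC and confusion behave at k = 4", {
  set.seed(7)
  labs <- rep(c("a", "b", "c", "d"), each = 10)
  hg <- fake_hg(nt = 40, C = 8, labels = labs, seed = 7)
  # plant one channel pair per class
  bt <- hg$bin_times_s
  for (ci in 1:4) {
    sel <- which(labs == c("a", "b", "c", "d")[ci])
    hg$db[sel, (2 * ci - 1):(2 * ci), bt >= 0] <-
      hg$db[sel, (2 * ci - 1):(2 * ci), bt >= 0] + 4
  }
  w <- causal_windows(hg, t_range = c(0.1, 0.2), step = 0.1)
  tg <- temporal_generalization(w, labs, seed = 8)
  expect_equal(tg$chance, 0.25)
  expect_gt(diag(tg$accuracy)[2], 0.8)
  expect_true(all(tg$auc >= 0 & tg$auc <= 1, na.rm = TRUE))
  expect_equal(unname(rowSums(tg$confusion)), rep(1, 4), tolerance = 1e-9)
})

test_that("symmetric confusion averages mirrored entries", {
  cm <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, byrow = TRUE)
  sc <- symmetric_confusion(cm)
  expect_equal(sc[1, 2], 0.3)
  expect_equal(sc[2, 1], 0.3)
  expect_true(is.na(sc[1, 1]))
  # perfect classifier: zero off-diagonal rates
  expect_equal(symmetric_confusion(diag(3))[1, 2], 0)
  # symmetric input is unchanged off-diagonal
  sym <- matrix(c(0.7, 0.3, 0.3, 0.7), 2)
  expect_equal(symmetric_confusion(sym)[1, 2], 0.3)
  expect_error(symmetric_confusion(matrix(1, 2, 3)), "square")
})

test_that("encoding-decoding coupling interpolates with splines", {
  et <- seq(-0.5, 0.5, by = 0.05)
  ev <- exp(-((et - 0.1) / 0.2)^2)
  # identical series on identical grids
  cc <- encode_decode_coupling(et, ev, et, ev)
  expect_equal(cc$r, 1, tolerance = 1e-12)
  # negated series
  cc2 <- encode_decode_coupling(et, ev, et, -ev)
  expect_equal(cc2$r, -1, tolerance = 1e-12)
  # spline passes through the knots
  dt <- seq(-0.7, 0.7, by = 0.025)
  cc3 <- encode_decode_coupling(et, ev, dt, sin(dt))
  at_knots <- cc3$interpolated[match(round(et, 10), round(dt, 10))]
  expect_equal(at_knots, ev, tolerance = 1e-9)
  # outside the encoding range the interpolant is zero
  expect_true(all(cc3$interpolated[dt < -0.5 - 1e-6 | dt > 0.5 + 1e-6] == 0))
  const <- encode_decode_coupling(et, rep(0, length(et)), et, ev)
  expect_true(const$degenerate)
})
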