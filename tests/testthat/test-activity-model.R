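# small synthetic feature set with binary passthrough features, used to
# exercise the regression machinery without genome featurization
synth_features <- function(n = 1200, p = 40, seed = 1) {
  guidescreen:::with_seed(seed, {
    X <- matrix(rbinom(n * p, 1, 0.5), n, p)
    colnames(X) <- paste0("base_p", seq_len(p), "_A")
    fx <- as.data.frame(X)
    attr(fx, "kind") <- stats::setNames(rep("binary", p), colnames(fx))
    rownames(fx) <- paste0("sg", seq_len(n))
    fx
  })
}

test_that("bin_feature: fixed-width partition, value placement", {
  b <- bin_feature(0:10, width = 2, sparsity_min = 0)
  expect_equal(b$edges, c(0, 2, 4, 6, 8, 10))
  expect_false(b$degenerate)
  idx3 <- which(guidescreen:::bin_apply(3, b$edges)[1, ] == 1)
  expect_equal(unname(idx3), 2L)  # bin [2,4)
  # every row maps to exactly one bin
  expect_true(all(rowSums(b$indicators) == 1))
})

test_that("bin_feature: sparse edge bins merge inward", {
  v <- c(rep(1, 20), rep(3, 20), 9)  # single point in the top bin
  b <- bin_feature(v, width = 2, sparsity_min = 5)
  expect_true(all(rowSums(b$indicators) == 1))
  # the lone top value shares a bin with the 3s after merging
  top_bin <- which(guidescreen:::bin_apply(9, b$edges)[1, ] == 1)
  three_bin <- which(guidescreen:::bin_apply(3, b$edges)[1, ] == 1)
  expect_equal(top_bin, three_bin)
  # constant feature -> degenerate flag
  expect_true(bin_feature(rep(2, 10), width = 1)$degenerate)
  expect_error(bin_feature(1:10, width = 0), "width")
})

test_that("position curve: constant input, determinism, flat fallback", {
  d <- guidescreen:::with_seed(5, sample(-1000:1000, 400, replace = TRUE))
  y <- rep(0.5, 400)
  expect_warning(pm <- fit_position_svr(d, y, min_pairs = 100), "flat")
  expect_true(all(abs(predict(pm, -500:500) - 0.5) < 0.05))

  y2 <- guidescreen:::with_seed(6, 0.5 + 0.3 * sin(d / 100) + rnorm(400, 0, 0.05))
  pm1 <- fit_position_svr(d, y2, seed = 9, min_pairs = 100)
  pm2 <- fit_position_svr(d, y2, seed = 9, min_pairs = 100)
  expect_identical(predict(pm1, -300:300), predict(pm2, -300:300))
  expect_error(fit_position_svr(d[1:50], y2[1:50]), "training pairs")
})

test_that("gene-wise split never leaks genes and standardization is exact", {
  fx <- synth_features()
  act <- data.frame(sgrna = rownames(fx),
                    gene = paste0("G", rep(1:120, each = 10)),
                    activity = guidescreen:::with_seed(2, rnorm(1200)))
  mod <- fit_activity_model(fx, act, seed = 3)
  expect_length(intersect(mod$train_genes, mod$test_genes), 0)
  expect_setequal(c(mod$train_genes, mod$test_genes), unique(act$gene))
  expect_equal(length(mod$train_genes), 96L)  # 80% of 120 genes
  # training design matrix standardization: mean 0, sd 1 to 1e-9
  tr <- act$gene %in% mod$train_genes
  ftr <- fx[match(act$sgrna[tr], rownames(fx)), , drop = FALSE]
  attr(ftr, "kind") <- attr(fx, "kind")
  Z <- guidescreen:::model_design_matrix(mod, ftr)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-9))
})

test_that("prediction is a pure dot product and refuses foreign rosters", {
  # hand-computed three-feature toy model
  fx <- data.frame(base_p1_A = c(1, 0, 1), base_p2_A = c(0, 1, 1),
                   base_p3_A = c(1, 1, 0))
  attr(fx, "kind") <- stats::setNames(rep("binary", 3), names(fx))
  rownames(fx) <- paste0("s", 1:3)
  kind <- attr(fx, "kind")
  rh <- fnv1a_hash(paste(names(fx), kind, sep = ":"))
  mu <- c(0.5, 0.5, 0.5); sdev <- c(2, 4, 8)
  co <- c(base_p1_A = 1, base_p2_A = -2, base_p3_A = 0.5)
  mod <- structure(list(
    recipe = lapply(stats::setNames(names(fx), names(fx)), function(nm)
      list(type = "binary", category = "sequence")),
    column_category = stats::setNames(rep("sequence", 3), names(fx)),
    mean = stats::setNames(mu, names(fx)),
    sd = stats::setNames(sdev, names(fx)),
    keep = stats::setNames(rep(TRUE, 3), names(fx)),
    intercept = 0.25, coefficients = co,
    alpha = 0.5, lambda = 0.1, roster_hash = rh, roster = names(fx),
    train_genes = "A", test_genes = "B", seed = 1), class = "activity_model")
  pred <- predict_activity(mod, fx)
  manual <- 0.25 + as.matrix(sweep(sweep(fx, 2, mu), 2, sdev, "/")) %*% co
  expect_equal(unname(pred), as.numeric(manual))
  # duplicate rows give duplicate scores
  fx2 <- fx[c(1, 1, 2), ]; rownames(fx2) <- paste0("d", 1:3)
  attr(fx2, "kind") <- kind
  p2 <- predict_activity(mod, fx2)
  expect_equal(unname(p2[1]), unname(p2[2]))
  # increasing a positively-weighted feature raises the score
  fx3 <- fx[1, , drop = FALSE]; fx3$base_p1_A <- 0
  fx4 <- fx[1, , drop = FALSE]; fx4$base_p1_A <- 1
  attr(fx3, "kind") <- kind; attr(fx4, "kind") <- kind
  expect_gt(predict_activity(mod, fx4), predict_activity(mod, fx3))
  # roster mismatch errors instead of coercing
  bad <- fx; names(bad)[1] <- "base_p9_T"
  attr(bad, "kind") <- stats::setNames(rep("binary", 3), names(bad))
  expect_error(predict_activity(mod, bad), "roster")
})

test_that("evaluate_model: perfect ordering, single-class error", {
  fx <- synth_features(n = 200, p = 10, seed = 7)
  act <- data.frame(sgrna = rownames(fx),
                    gene = paste0("G", rep(1:20, each = 10)),
                    activity = guidescreen:::with_seed(8, rnorm(200)))
  mod <- fit_activity_model(fx, act, seed = 9, nfolds = 3)
  te <- act[act$gene %in% mod$test_genes, ]
  fte <- fx[match(te$sgrna, rownames(fx)), , drop = FALSE]
  attr(fte, "kind") <- attr(fx, "kind")
  expect_error(evaluate_model(mod, fte, rep(1, nrow(fte))), "single class")
  # scores that perfectly order the labels give AUC 1 (direct ROC check)
  expect_equal(roc_curve(1:10, c(rep(FALSE, 5), rep(TRUE, 5)))$auc, 1)
})

test_that("ROC/PR utilities match quadratic-time references", {
  for (seed in 1:5) {
    guidescreen:::with_seed(seed + 40, {
      n <- 150
      scores <- sample(seq_len(60), n, replace = TRUE)  # forces ties
      labels <- rbinom(n, 1, 0.4) == 1
      expect_equal(roc_curve(scores, labels)$auc, oracle_auc(scores, labels))
      pr <- pr_curve(scores, labels)
      opr <- oracle_pr(scores, labels)
      expect_equal(pr$precision, opr$precision)
      expect_equal(pr$recall, opr$recall)
    })
  }
  # random scores with balanced labels: AUC 0.5 +/- 0.03 at n = 2000
  guidescreen:::with_seed(77, {
    auc <- roc_curve(rnorm(2000), rep(c(TRUE, FALSE), 1000))$auc
    expect_lt(abs(auc - 0.5), 0.03)
  })
  # interpolated precision is monotone non-increasing as recall grows
  guidescreen:::with_seed(78, {
    pr <- pr_curve(rnorm(500), rbinom(500, 1, 0.3) == 1)
    expect_true(all(diff(pr$interpolated_precision) <= 1e-12))
  })
})

test_that("zero-coefficient categories contribute nothing", {
  fx <- synth_features(n = 300, p = 8, seed = 10)
  names(fx)[8] <- "chromatin_fake"
  kind <- stats::setNames(rep("binary", 8), names(fx))
  kind["chromatin_fake"] <- "binary"
  attr(fx, "kind") <- kind
  act <- data.frame(sgrna = rownames(fx),
                    gene = paste0("G", rep(1:30, each = 10)),
                    activity = guidescreen:::with_seed(11,
                      fx$base_p1_A + rnorm(300, 0, 0.1)))
  mod <- fit_activity_model(fx, act, seed = 12, nfolds = 3)
  mod$coefficients[grepl("^chromatin", names(mod$coefficients))] <- 0
  contrib <- feature_category_contribution(mod, fx)
  expect_equal(unname(contrib["chromatin"]), 0)
  expect_gt(unname(contrib["sequence"]), 0)
})

test_that("activity model JSON round trip preserves predictions", {
  ref <- toy_ref(); ann <- toy_annotation(); fz <- toy_featurized()
  act <- simulate_activity_dataset(fz$candidates, fz$features, seed = 21)
  suppressWarnings(
    mod <- fit_activity_model(fz$features, act, seed = 22, nfolds = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_activity_model(mod, path)
  back <- read_activity_model(path)
  sub <- fz$features[1:25, , drop = FALSE]
  attr(sub, "kind") <- attr(fz$features, "kind")
  attr(sub, "roster_hash") <- attr(fz$features, "roster_hash")
  expect_equal(predict_activity(back, sub), predict_activity(mod, sub),
               tolerance = 1e-10)
})
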