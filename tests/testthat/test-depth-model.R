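# Small synthetic regression task with a smooth, invertible feature-depth
# relation plus mild noise, used across algorithms.
make_task <- function(n_per_depth = 20, seed = 41) {
  set.seed(seed)
  depth <- rep(seq(2, 20, 2), each = n_per_depth)
  data.frame(
    depth = depth,
    Ct = exp(0.15 * depth) * (1 + rnorm(length(depth), 0, 0.02)),
    CtDelta = 0.5 * exp(0.12 * depth) * (1 + rnorm(length(depth), 0, 0.02)),
    RVD = 0.1 * depth + rnorm(length(depth), 0, 0.05))
}

test_that("all three algorithms learn an easy depth mapping", {
  df <- make_task()
  for (alg in c("svr", "knn", "pr")) {
    m <- depth_model(depth ~ Ct + CtDelta + RVD, df, algorithm = alg,
                     seed = 1)
    expect_s3_class(m, "depth_model")
    expect_gt(m$cv$r_squared, 0.95)
    expect_lt(m$cv$rmse, 1.5)
  }
})

test_that("the fit is reproducible given a seed", {
  df <- make_task()
  m1 <- depth_model(depth ~ Ct + RVD, df, algorithm = "svr", seed = 7)
  m2 <- depth_model(depth ~ Ct + RVD, df, algorithm = "svr", seed = 7)
  expect_identical(m1$cv$pred, m2$cv$pred)
  expect_identical(m1$cv$rmse, m2$cv$rmse)
})

test_that("predict works on new data and respects degeneracy flags", {
  df <- make_task()
  m <- depth_model(depth ~ Ct + CtDelta + RVD, df, algorithm = "knn",
                   seed = 2)
  nd <- make_task(n_per_depth = 3, seed = 99)
  p <- predict(m, nd)
  expect_length(p, nrow(nd))
  expect_lt(rmse(nd$depth, p), 2)
  nd$flag <- rep(c(TRUE, FALSE, FALSE), length.out = nrow(nd))
  p2 <- predict(m, nd)
  expect_true(all(is.na(p2[nd$flag])))
  expect_true(all(!is.na(p2[!nd$flag])))
})

test_that("flagged training records are dropped, with a 20% ceiling", {
  df <- make_task()
  df$flag <- FALSE
  df$flag[1:10] <- TRUE
  m <- depth_model(depth ~ Ct, df, algorithm = "pr", seed = 3)
  expect_equal(m$n, nrow(df) - 10)
  df$flag[seq_len(ceiling(0.3 * nrow(df)))] <- TRUE
  expect_error(depth_model(depth ~ Ct, df, algorithm = "pr"), "flagged")
})

test_that("standard S3 methods work", {
  df <- make_task()
  m <- depth_model(depth ~ Ct + RVD, df, algorithm = "pr", degree = 2,
                   seed = 4)
  expect_output(print(m), "PR")
  expect_output(print(summary(m)), "MAE")
  expect_true(is.numeric(coef(m)) && length(coef(m)) >= 3)
  expect_equal(residuals(m), m$y - fitted(m))
  expect_lt(max(abs(residuals(m))), 3)
  msvr <- depth_model(depth ~ Ct, df, algorithm = "svr", seed = 4)
  expect_message(cf <- coef(msvr), "polynomial")
  expect_null(cf)
  pdf(NULL); on.exit(dev.off(), add = TRUE)
  expect_invisible(plot(m))
})

test_that("mae_by_depth groups errors by true depth", {
  y <- c(2, 2, 4, 4)
  yhat <- c(2.5, 1.5, 4, 5)
  tab <- mae_by_depth(y, yhat)
  expect_equal(tab$depth, c(2, 4))
  expect_equal(tab$mae, c(0.5, 0.5))
  expect_equal(tab$n, c(2, 2))
})

test_that("preset wrapper builds the canonical formulas", {
  df <- make_task()
  # rename so the MD preset's features exist
  m <- depth_model_preset(df, "MD", algorithm = "pr", seed = 5)
  expect_equal(m$preset, "MD")
  expect_setequal(m$features, c("Ct", "CtDelta", "RVD"))
  expect_error(depth_model_preset(df, "Mp", algorithm = "pr"))
})

test_that("depth_model validates folds and features", {
  df <- make_task(2)
  expect_error(depth_model(depth ~ Ct, df, folds = 1), "fold")
  expect_error(depth_model(depth ~ 1, df), "empty feature")
})
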