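# Preprocessing, MLR training/prediction, leverage AD, JPDI protocol.

test_that("preprocessing behaves on the documented small cases", {
  p <- preprocess(data.frame(x = c(1, 2, 3)), scaling = "standardize")
  expect_equal(p$table$x, c(-1, 0, 1))  # sample sd = 1

  p2 <- preprocess(data.frame(k = c(5, 5, 5)), scaling = "minmax")
  expect_identical(p2$table$k, c(5, 5, 5))
  expect_identical(p2$transformer$constantColumns, "k")

  p3 <- preprocess(data.frame(x = c(1, NA, 3)), impute = "mean")
  expect_equal(p3$table$x, c(1, 2, 3))

  expect_error(preprocess(data.frame(x = c(NA_real_, NA_real_))),
               class = "enmkit_validation_error")
})

test_that("the transformer is fitted on training data and reapplied verbatim", {
  train <- data.frame(x = c(0, 10))
  tr <- fitTransformer(train, scaling = "minmax")
  applied <- applyTransformer(tr, data.frame(x = c(20)))
  expect_equal(applied$x, 2)  # training range, not query range
})

test_that("a noiseless linear law is recovered to machine precision", {
  set.seed(7)
  tab <- data.frame(x1 = rnorm(10), x2 = rnorm(10))
  tab$y <- 1 + 2 * tab$x1 - 3 * tab$x2
  b <- trainMLR(tab, "y")
  expect_equal(unname(b@coefficients), c(1, 2, -3), tolerance = 1e-10)
  expect_equal(b@stats$n, 10)
})

test_that("coefficients equal the closed-form normal-equations solution", {
  set.seed(8)
  tab <- data.frame(x1 = rnorm(30), x2 = runif(30), x3 = rnorm(30, 5))
  tab$y <- 2 - tab$x1 + 0.5 * tab$x2 + 0.1 * tab$x3 + rnorm(30, 0, 0.3)
  b <- trainMLR(tab, "y")
  ## independent small-matrix oracle: beta = (X'X)^-1 X'y
  X <- cbind(1, as.matrix(tab[, c("x1", "x2", "x3")]))
  beta <- solve(t(X) %*% X, t(X) %*% tab$y)
  expect_equal(unname(b@coefficients), as.numeric(beta), tolerance = 1e-9)
})

test_that("rank-deficient designs raise an error naming collinear columns", {
  set.seed(9)
  tab <- data.frame(x1 = rnorm(20))
  tab$x2 <- 2 * tab$x1
  tab$y <- tab$x1 + rnorm(20)
  err <- tryCatch(trainMLR(tab, "y"), error = identity)
  expect_s3_class(err, "enmkit_validation_error")
  expect_match(conditionMessage(err), "x2")
})

test_that("too few complete rows and missing targets are handled as documented", {
  tab <- data.frame(x1 = 1:4, x2 = c(2, 1, 4, 3), y = c(1, 2, NA, 4))
  expect_error(trainMLR(tab, "y"), "complete rows",
               class = "enmkit_validation_error")
  tab10 <- data.frame(x1 = rnorm(10), y = c(rnorm(8), NA, NA))
  b <- trainMLR(tab10, "y")
  expect_identical(b@stats$droppedMissingTarget, 2L)
  expect_identical(b@stats$n, 8L)
})

test_that("predicting the training set returns the fitted values; duplicates agree", {
  set.seed(10)
  tab <- data.frame(x1 = rnorm(15), x2 = rnorm(15))
  tab$y <- 1 + tab$x1 + 0.5 * tab$x2 + rnorm(15, 0, 0.1)
  b <- trainMLR(tab, "y")
  pred <- predict(b, tab)
  fit <- stats::lm(y ~ x1 + x2, tab)
  expect_equal(pred$prediction, unname(stats::fitted(fit)), tolerance = 1e-10)
  expect_equal(b@stats$r2, summary(fit)$r.squared, tolerance = 1e-12)

  one <- tab[3, c("x1", "x2")]
  three <- one[c(1, 1, 1), ]
  p3 <- predict(b, three)
  expect_identical(p3$prediction, rep(p3$prediction[1], 3))

  expect_error(predict(b, tab["x1"]), "x2",
               class = "enmkit_validation_error")
})

test_that("a reloaded model bundle predicts bit-identically", {
  set.seed(12)
  tab <- data.frame(x1 = rnorm(20), x2 = rnorm(20))
  tab$y <- 2 * tab$x1 - tab$x2 + rnorm(20, 0, 0.2)
  b <- trainMLR(tab, "y", scaling = "standardize", impute = "mean")
  path <- withr::local_tempfile(fileext = ".json")
  writeModelBundle(b, path)
  b2 <- readModelBundle(path)
  expect_identical(b2@payload, b@payload)
  expect_identical(predict(b2, tab), predict(b, tab))
  ## write -> read -> write round-trips the payload byte-identically
  path2 <- withr::local_tempfile(fileext = ".json")
  writeModelBundle(b2, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("leverage satisfies the hat-matrix identities on random designs", {
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(8:40, 1)
    k <- sample(1:4, 1)
    df <- as.data.frame(matrix(rnorm(n * k), n,
                               dimnames = list(NULL, paste0("f", 1:k))))
    ad <- fitAD(df)
    h <- leverage(ad, df)
    p <- k + 1
    expect_lt(abs(sum(h) - p), 1e-10)
    expect_equal(mean(h), p / n, tolerance = 1e-12)
    expect_true(all(h <= 1 + 1e-12))
    expect_true(max(h) >= p / n)
    expect_identical(ad@threshold, 3 * p / n)
  }
})

test_that("intercept-only designs give every training point leverage 1/n", {
  df <- data.frame()[1:5, , drop = FALSE]  # 5 rows, 0 columns
  ad <- fitAD(df, featureNames = character(0))
  h <- leverage(ad, df)
  expect_equal(unname(h), rep(0.2, 5))
  expect_identical(ad@threshold, 3 * 1 / 5)
})

test_that("a point far outside the training cloud is flagged out of domain", {
  set.seed(14)
  train <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  ad <- fitAD(train)
  far <- data.frame(x1 = 10 * stats::sd(train$x1) + mean(train$x1),
                    x2 = mean(train$x2))
  res <- inDomain(ad, far)
  expect_gt(res$leverage, ad@threshold)
  expect_false(res$inDomain)
  resTrain <- inDomain(ad, train)
  expect_true(mean(resTrain$inDomain) > 0.8)

  degenerate <- data.frame(x1 = rep(1, 10), x2 = rep(2, 10))
  expect_error(fitAD(degenerate), class = "enmkit_validation_error")
})

test_that("predictions carry AD flags when an AD model is attached", {
  set.seed(15)
  tab <- data.frame(x1 = rnorm(20))
  tab$y <- tab$x1 + rnorm(20, 0, 0.1)
  b <- trainMLR(tab, "y", ad = TRUE)
  pred <- predict(b, data.frame(x1 = c(0, 100)))
  expect_true(pred$inDomain[1])
  expect_false(pred$inDomain[2])
})

test_that("the registry supports register/get/patch/delete round-trips", {
  reg <- defaultRegistry()
  expect_setequal(listAlgorithms(reg), c("mlr", "pls", "svm", "rbf-network"))
  rec <- algorithmRecord("my-alg", function(x) "{}", function(x) "{}",
                         ontologyClass = "Clustering",
                         description = "test algorithm")
  registerAlgorithm(reg, rec)
  expect_identical(getAlgorithm(reg, "my-alg")$ontologyClass, "Clustering")
  expect_error(registerAlgorithm(reg, rec),
               class = "enmkit_validation_error")
  modifyAlgorithm(reg, "my-alg", list(description = "patched"))
  expect_identical(getAlgorithm(reg, "my-alg")$description, "patched")
  removeAlgorithm(reg, "my-alg")
  expect_error(getAlgorithm(reg, "my-alg"), class = "enmkit_notfound_error")

  expect_error(algorithmRecord("x", function(q) q, function(q) q,
                               ontologyClass = "Oracle"),
               class = "enmkit_validation_error")
  expect_error(trainViaJPDI(reg, "pls", data.frame(x = 1:9, y = 1:9), "y"),
               class = "enmkit_notimplemented_error")
})

test_that("the training request carries exactly dataset, prediction feature, parameters", {
  tab <- data.frame(x = 1:5, y = 2 * (1:5))
  req <- jsonlite::fromJSON(trainRequest(tab, "y", list(scaling = "none")),
                            simplifyVector = FALSE)
  expect_identical(sort(names(req)),
                   sort(c("dataset", "predictionFeature", "parameters")))
  expect_identical(req$predictionFeature, "y")
  expect_identical(unlist(req$dataset$features), c("x", "y"))
})

test_that("JPDI-wrapped MLR is output-identical to direct invocation", {
  set.seed(16)
  tab <- data.frame(x1 = rnorm(25), x2 = rnorm(25))
  tab$y <- 3 + tab$x1 - 2 * tab$x2 + rnorm(25, 0, 0.4)
  direct <- trainMLR(tab, "y")
  reg <- defaultRegistry()
  model <- trainViaJPDI(reg, "mlr", tab, "y")
  doc <- jsonlite::fromJSON(model$document)
  expect_identical(unlist(doc$coefficients)[names(direct@coefficients)],
                   direct@coefficients)
  pred <- predictViaJPDI(reg, model, tab)
  expect_identical(pred, predict(direct, tab)$prediction)

  ## a model document cannot be replayed against a different algorithm
  wrong <- model; wrong$algorithm <- "pls"
  expect_error(predictViaJPDI(reg, wrong, tab),
               class = "enmkit_validation_error")
})
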