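test_that("load_csv reads labelled numeric tables and validates input", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(iris_tbl(), path)
  d <- load_csv(path, "species")
  expect_equal(nrow(d), 150)
  expect_equal(setdiff(names(d), "species"),
               c("sepal_length", "sepal_width", "petal_length", "petal_width"))

  one <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(iris_tbl()[1, ], one)
  expect_equal(nrow(load_csv(one, "species")), 1)

  expect_error(load_csv(path, "not_a_column"), "label column")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,lab", "1,x,normal", "2,3,normal"), bad)
  expect_error(load_csv(bad, "lab"), "non-numeric")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b,lab", empty)
  expect_error(load_csv(empty, "lab"), "empty")
})

test_that("make_split reproduces the published split sizes on iris", {
  d <- iris_tbl()
  sp <- make_split(d, "species", "setosa", n_train = 17, seed = 1)
  expect_s3_class(sp, "cfa_split")
  expect_equal(nrow(sp$train_normal), 17)
  expect_equal(nrow(sp$test_normal), 33)
  expect_equal(nrow(sp$test_anomalous), 100)
  expect_true(all(sp$train_normal$species == "setosa"))
  expect_true(all(sp$test_anomalous$species != "setosa"))
  # rows partition the dataset
  expect_equal(nrow(sp$train_normal) + nrow(sp$test_normal) +
                 nrow(sp$test_anomalous), nrow(d))
})

test_that("make_split boundaries and determinism", {
  d <- iris_tbl()
  all_in <- make_split(d, "species", "setosa", n_train = 50, seed = 1)
  expect_equal(nrow(all_in$test_normal), 0)

  s1 <- make_split(d, "species", "setosa", 17, seed = 1)
  s2 <- make_split(d, "species", "setosa", 17, seed = 2)
  expect_false(identical(s1$train_normal, s2$train_normal))
  expect_equal(dim(s1$train_normal), dim(s2$train_normal))
  expect_identical(make_split(d, "species", "setosa", 17, seed = 1)$train_normal,
                   s1$train_normal)

  expect_error(make_split(d, "species", character(0), 10), "non-empty")
  expect_error(make_split(d, "species", "no_such_label", 10), "normal label")
  expect_error(make_split(d, "species", "setosa", 51), "exceeds")
})

test_that("replicate_features tiles by the smallest even k exceeding the threshold", {
  d4 <- iris_tbl() # 4 features
  r <- replicate_features(d4, "species", 32)
  expect_equal(ncol(r) - 1L, 40) # k = 10
  expect_identical(r$sepal_length_r2, r$sepal_length) # exact copies

  d60 <- tibble::as_tibble(matrix(rnorm(120), 2, 60,
                                  dimnames = list(NULL, paste0("f", 1:60))))
  d60$lab <- "a"
  expect_identical(replicate_features(d60, "lab", 32), d60)

  d32 <- tibble::as_tibble(matrix(rnorm(64), 2, 32,
                                  dimnames = list(NULL, paste0("f", 1:32))))
  d32$lab <- "a"
  expect_equal(ncol(replicate_features(d32, "lab", 32)) - 1L, 64) # k = 2
})

test_that("monte_carlo_folds resamples independently and reproducibly", {
  d <- iris_tbl()
  folds <- monte_carlo_folds(d, "species", "setosa", 17, k = 10, seed = 5)
  expect_length(folds, 10)
  sizes <- vapply(folds, function(f) nrow(f$train_normal), integer(1))
  expect_true(all(sizes == 17))
  memberships <- vapply(folds, function(f) {
    paste(sort(f$train_normal$sepal_length), collapse = ",")
  }, character(1))
  expect_gt(length(unique(memberships)), 1)

  again <- monte_carlo_folds(d, "species", "setosa", 17, k = 10, seed = 5)
  expect_identical(lapply(folds, `[[`, "train_normal"),
                   lapply(again, `[[`, "train_normal"))

  single <- monte_carlo_folds(d, "species", "setosa", 17, k = 1, seed = 5)
  expect_length(single, 1)
  expect_s3_class(single[[1]], "cfa_split")
})
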