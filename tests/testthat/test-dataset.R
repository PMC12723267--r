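test_that("split sizes follow the 85/10/5 rule", {
  s <- splitAssignment(10000)
  expect_equal(as.vector(table(s)), c(8500L, 1000L, 500L))
  s2 <- splitAssignment(600)
  expect_equal(as.vector(table(s2)), c(510L, 60L, 30L))
  expect_error(splitAssignment(5), "empty")
})

test_that("dataset generation is deterministic and round-trips bit-exactly", {
  ds1 <- generateDataset(n = 20, seed = 42)
  ds2 <- generateDataset(n = 20, seed = 42)
  expect_identical(ds1@inputs, ds2@inputs)
  expect_identical(ds1@targets, ds2@targets)
  expect_equal(dim(ds1@inputs), c(20L, 16L, 15L, 2L))
  expect_equal(dim(ds1@targets), c(20L, 64L, 64L, 2L))
  expect_true(all(is.finite(ds1@inputs)))
  d1 <- file.path(tempdir(), "dsA"); d2 <- file.path(tempdir(), "dsB")
  writeDataset(ds1, d1)
  writeDataset(ds2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "inputs.rds"))),
                   unname(tools::md5sum(file.path(d2, "inputs.rds"))))
  back <- readDataset(d1)
  expect_identical(back@inputs, ds1@inputs)
  expect_identical(back@targets, ds1@targets)
  expect_equal(back@split, ds1@split)
  expect_equal(back@stats, ds1@stats)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("target normalization maps the training split into [0,1] and inverts", {
  ds <- generateDataset(n = 20, seed = 3)
  tr <- splitIndices(ds, "train")
  yn <- normalizeTargets(ds@targets[tr, , , ], ds@stats)
  expect_gte(min(yn), 0)
  expect_lte(max(yn), 1)
  y <- ds@targets[5, , , ]
  expect_equal(denormalizeTargets(normalizeTargets(y, ds@stats), ds@stats), y,
               tolerance = 1e-12)
})
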