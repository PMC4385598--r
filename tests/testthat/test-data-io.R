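test_that("specimen CSV rows parse with values and order preserved", {
  d <- read_dataset(specimen_examples_path())
  expect_s3_class(d, "ccm_dataset")
  expect_equal(n_samples(d), 11L)
  # first specimen row
  expect_equal(unname(d$lab[1, ]), c(66.89667, -0.01, 14.92667))
  expect_equal(unname(d$recipe[1, ]), c(0.32, 0, 0, 0.08, 0))
  # all printed recipes obey the composition law
  expect_true(all(is_valid_recipe(d$recipe)))
})

test_that("read_dataset reports schema and parse errors precisely", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("L,a,b,A1,A4,B4,C4", p)   # D4 missing
  expect_error(read_dataset(p), "D4")

  writeLines(c("L,a,b,A1,A4,B4,C4,D4",
               "66.9,x,14.9,0.32,0,0,0.08,0"), p)
  expect_error(read_dataset(p), "row 1")

  writeLines("L,a,b,A1,A4,B4,C4,D4", p)  # header only
  expect_equal(n_samples(read_dataset(p)), 0L)
})

test_that("headerless files read via an explicit column order", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("0.32,0,0,0.08,0,66.9,-0.01,14.93", p)
  d <- read_dataset(p, columns = c("A1", "A4", "B4", "C4", "D4",
                                   "L", "a", "b"))
  expect_equal(unname(d$lab[1, ]), c(66.9, -0.01, 14.93))
  expect_equal(unname(d$recipe[1, 1]), 0.32)
  expect_error(read_dataset(p, columns = c("L", "a", "b")), "permutation")
})

test_that("write/read roundtrip preserves every field", {
  d <- generate_dataset(25, seed = 11)
  p <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, p)
  d2 <- read_dataset(p)
  expect_equal(d2$lab, d$lab, tolerance = 1e-9)
  expect_equal(d2$recipe, d$recipe, tolerance = 1e-9)
})

test_that("split sizes follow round(fraction * n) and the partition law", {
  d <- generate_dataset(119, seed = 5)
  parts <- split_dataset(d, 0.75, seed = 3)
  expect_equal(n_samples(parts$train), 89L)
  expect_equal(n_samples(parts$test), 30L)

  # partition law across sizes and seeds (property)
  for (n in c(2, 7, 30)) {
    for (seed in 1:3) {
      dd <- generate_dataset(n, seed = n + seed)
      pp <- split_dataset(dd, 0.6, seed = seed)
      all_rows <- rbind(cbind(pp$train$lab, pp$train$recipe),
                        cbind(pp$test$lab, pp$test$recipe))
      orig <- cbind(dd$lab, dd$recipe)
      expect_equal(n_samples(pp$train) + n_samples(pp$test), n)
      # same multiset of rows
      expect_equal(all_rows[do.call(order, as.data.frame(all_rows)), ],
                   orig[do.call(order, as.data.frame(orig)), ],
                   ignore_attr = TRUE)
    }
  }

  # determinism: same seed gives the identical split
  again <- split_dataset(d, 0.75, seed = 3)
  expect_identical(again$train$lab, parts$train$lab)
  expect_error(split_dataset(d, 1.2, seed = 1), "between 0 and 1")
})

test_that("normalizer maps endpoints affinely and inverts exactly", {
  d <- ccm_dataset(rbind(c(0, -1, 10), c(10, 1, 20), c(5, 0, 15)),
                   matrix(0.08, 3, 5))
  nrm <- fit_normalizer(d, lo = -1, hi = 1)
  z <- normalize_lab(nrm, d$lab)
  expect_equal(unname(z[, 1]), c(-1, 1, 0))

  # roundtrip identity, random datasets (property)
  for (seed in 1:5) {
    dd <- generate_dataset(20, seed = seed)
    nn <- fit_normalizer(dd, 0.1, 0.9)
    back <- denormalize_lab(nn, normalize_lab(nn, dd$lab))
    expect_equal(back, dd$lab, tolerance = 1e-12)
  }

  # hand-checked affine value from the example specimen table: the L*
  # column spans 63.86667..72.46333, so 66.89667 maps to ~0.35243 on [0,1]
  sp <- read_dataset(specimen_examples_path())
  nrm_l <- fit_normalizer(sp, 0, 1)
  z <- normalize_lab(nrm_l, sp$lab)
  expect_equal(unname(z[1, 1]),
               (66.89667 - 63.86667) / (72.46333 - 63.86667),
               tolerance = 1e-9)

  # constant dimension is rejected
  dc <- ccm_dataset(rbind(c(1, 5, 10), c(2, 5, 12)), matrix(0.08, 2, 5))
  expect_error(fit_normalizer(dc), "degenerate")
})
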