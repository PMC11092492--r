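test_that("problem enumeration covers the bounded arithmetic space", {
  probs <- enumerate_problems()
  expect_equal(nrow(probs), 380)
  expect_equal(sum(probs$operator == "add"), 190)
  expect_equal(sum(probs$operator == "sub"), 190)
  # result-0 problems: one addition (0+0), nineteen subtractions (a - a)
  expect_equal(sum(probs$result == 0 & probs$operator == "add"), 1)
  expect_equal(sum(probs$result == 0 & probs$operator == "sub"), 19)
  # every result represented in both operations
  counts <- table(probs$result, probs$operator)
  expect_true(all(counts >= 1))
  # invariants hold row-wise
  expect_true(all(probs$result >= 0 & probs$result <= 18))
  with(probs, {
    add <- operator == "add"
    expect_equal(result[add], (operand_a + operand_b)[add])
    expect_equal(result[!add], (operand_a - operand_b)[!add])
  })
})

test_that("canonical ordering puts additions first, sorted by result then operand", {
  probs <- enumerate_problems()
  expect_equal(unname(unlist(probs[1, c("operand_a", "operand_b")])), c(0, 0))
  expect_equal(probs$operator[191], "sub")       # first subtraction row
  expect_equal(probs$result[191], 0)
  expect_false(is.unsorted(probs$result[1:190]))
  expect_false(is.unsorted(probs$result[191:380]))
  # within (operator, result), ascending first operand
  by_block <- split(probs$operand_a, paste(probs$operator, probs$result))
  expect_true(all(vapply(by_block, function(x) !is.unsorted(x), logical(1))))
})

test_that("glyph rendering honors its construction rules", {
  src <- glyph_source("synthetic", "train", seed = 7, n_glyphs = 5)
  blank <- render_glyph("blank", src)
  expect_equal(blank, matrix(0, 28, 28))
  # seeded determinism
  g1 <- withr::with_seed(11, render_glyph("minus", src))
  g2 <- withr::with_seed(11, render_glyph("minus", src))
  expect_identical(g1, g2)
  # plus sign: central vertical and horizontal ink peaks
  plus <- withr::with_seed(3, render_glyph("plus", src))
  colsum <- colSums(plus); rowsum <- rowSums(plus)
  expect_gt(which.max(colsum), 9); expect_lt(which.max(colsum), 20)
  expect_gt(which.max(rowsum), 9); expect_lt(which.max(rowsum), 20)
  # all glyphs live in [0, 1]
  for (s in c(as.character(0:9), "plus", "minus")) {
    g <- withr::with_seed(5, render_glyph(s, src))
    expect_true(all(g >= 0 & g <= 1))
  }
  # empty pool errors
  src2 <- src; src2$pools[["3"]] <- list()
  expect_error(render_glyph("3", src2), "empty")
})

test_that("stimulus composition fills the five slots correctly", {
  src <- glyph_source("synthetic", "train", seed = 7, n_glyphs = 5)
  slot <- function(img, i) img[, ((i - 1) * 28 + 1):(i * 28), 1]
  p34 <- tibble::tibble(operand_a = 3, operand_b = 4, operator = "add")
  img <- withr::with_seed(1, compose_stimulus(p34, src))
  expect_equal(dim(img), c(28, 140, 3))
  expect_equal(slot(img, 1), matrix(0, 28, 28))    # tens of 3 blank
  expect_equal(slot(img, 4), matrix(0, 28, 28))    # tens of 4 blank
  expect_gt(sum(slot(img, 2)), 0)
  expect_gt(sum(slot(img, 3)), 0)
  # 10 - 2: tens slot of the first operand carries ink
  p102 <- tibble::tibble(operand_a = 10, operand_b = 2, operator = "sub")
  img2 <- withr::with_seed(1, compose_stimulus(p102, src))
  expect_gt(sum(slot(img2, 1)), 5)                 # the "1"
  expect_equal(slot(img2, 4), matrix(0, 28, 28))
  # channels identical (grayscale replicated) and range respected
  expect_identical(img[, , 1], img[, , 2])
  expect_identical(img[, , 1], img[, , 3])
  expect_true(min(img) >= 0 && max(img) <= 1)
})

test_that("dataset construction splits variants evenly and deterministically", {
  ds <- tiny_dataset()
  expect_equal(dim(ds$train_pixels)[4], 380)
  expect_equal(dim(ds$test_pixels)[4], 380)
  expect_equal(nrow(ds$train_meta), 380)
  # each problem appears equally often in both splits
  expect_true(all(table(ds$train_meta$problem_id) == 1))
  expect_true(all(table(ds$test_meta$problem_id) == 1))
  # identical seeds give identical datasets
  ds2 <- build_stimulus_dataset(2, seed = 42)
  expect_identical(ds$train_pixels, ds2$train_pixels)
  expect_identical(ds$test_pixels, ds2$test_pixels)
  # train and test renders differ (disjoint glyph sources)
  expect_false(identical(ds$train_pixels, ds$test_pixels))
  expect_error(build_stimulus_dataset(3, seed = 1), "even")
})

test_that("dataset archive round-trips and rejects corrupt files", {
  ds <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".rds")
  write_stimulus_dataset(ds, path)
  back <- read_stimulus_dataset(path)
  expect_identical(unclass(back), unclass(ds))
  expect_equal(back$variants_per_problem, 2L)
  # truncated file
  raw <- readBin(path, "raw", file.info(path)$size)
  bad <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw[1:100], bad)
  expect_error(read_stimulus_dataset(bad), "unreadable")
  # wrong content
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(read_stimulus_dataset(other), "format tag")
})

test_that("IDX reader parses images and labels written in MNIST format", {
  img_path <- withr::local_tempfile()
  lab_path <- withr::local_tempfile()
  imgs <- array(sample(0:255, 3 * 28 * 28, replace = TRUE), c(3, 28, 28))
  con <- file(img_path, "wb")
  writeBin(c(0x00000803L, 3L, 28L, 28L), con, size = 4, endian = "big")
  writeBin(as.integer(aperm(imgs, c(3, 2, 1))), con, size = 1)
  close(con)
  con <- file(lab_path, "wb")
  writeBin(c(0x00000801L, 3L), con, size = 4, endian = "big")
  writeBin(c(7L, 0L, 9L), con, size = 1)
  close(con)
  expect_equal(read_idx(img_path), imgs)
  expect_equal(read_idx(lab_path), c(7L, 0L, 9L))
  expect_error(read_idx(lab_path) -> labs, NA)
  # a non-IDX file is rejected
  junk <- withr::local_tempfile()
  writeBin(as.raw(1:64), junk)
  expect_error(read_idx(junk), "magic")
})

test_that("mnist-backend glyph sources pool images by digit label", {
  img_path <- withr::local_tempfile()
  lab_path <- withr::local_tempfile()
  n <- 20
  imgs <- array(sample(0:255, n * 28 * 28, replace = TRUE), c(n, 28, 28))
  labs <- rep(0:9, 2)
  con <- file(img_path, "wb")
  writeBin(as.integer(c(0x00000803L, n, 28L, 28L)), con, size = 4,
           endian = "big")
  writeBin(as.integer(aperm(imgs, c(3, 2, 1))), con, size = 1)
  close(con)
  con <- file(lab_path, "wb")
  writeBin(as.integer(c(0x00000801L, n)), con, size = 4, endian = "big")
  writeBin(as.integer(labs), con, size = 1)
  close(con)
  src <- glyph_source("mnist", "train", images = img_path, labels = lab_path)
  expect_equal(lengths(src$pools), setNames(rep(2L, 10), as.character(0:9)))
  expect_equal(src$pools[["7"]][[1]], imgs[8, , ] / 255)
})
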