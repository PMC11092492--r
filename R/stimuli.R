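# Stimulus composition: each problem is rendered as five 28x28 glyph slots
# T1 U1 S T2 U2 (tens/units of each operand around the operator), giving a
# 28x140 grayscale image replicated over 3 channels.

#' Compose one arithmetic stimulus image
#'
#' Fills the five glyph slots left to right: tens of the first operand
#' (blank below 10), its units, the operator, tens of the second operand,
#' its units. Glyph variants are drawn from `source` with the current RNG
#' stream.
#'
#' @param problem one-row data frame with `operand_a`, `operand_b`,
#'   `operator` (`"add"`/`"sub"`).
#' @param source a [glyph_source()].
#' @return a 28x140x3 array in \[0, 1\] (grayscale replicated across the
#'   three channels).
#' @export
compose_stimulus <- function(problem, source) {
  slot <- function(sym) render_glyph(sym, source)
  digit_slots <- function(v) {
    tens <- if (v >= 10) as.character(v %/% 10) else "blank"
    list(slot(tens), slot(as.character(v %% 10)))
  }
  a <- digit_slots(problem$operand_a)
  b <- digit_slots(problem$operand_b)
  op <- slot(if (problem$operator == "add") "plus" else "minus")
  plane <- cbind(a[[1]], a[[2]], op, b[[1]], b[[2]])
  array(plane, dim = c(GLYPH_SIZE, 5L * GLYPH_SIZE, 3L))
}

# symbols occupying the five glyph slots of one problem
slot_symbols <- function(problem) {
  tens <- function(v) if (v >= 10) as.character(v %/% 10) else "blank"
  c(tens(problem$operand_a), as.character(problem$operand_a %% 10),
    if (problem$operator == "add") "plus" else "minus",
    tens(problem$operand_b), as.character(problem$operand_b %% 10))
}

# per-slot number of distinct glyph choices ("plus" combines two strokes)
slot_pool_sizes <- function(symbols, source) {
  n1 <- length(source$pools[["1"]])
  vapply(symbols, function(s) switch(s,
    blank = 1L, minus = n1, plus = n1 * n1,
    {
      n <- length(source$pools[[s]])
      if (n == 0) abort(paste0("glyph pool for symbol '", s, "' is empty"))
      n
    }), integer(1))
}

glyph_from_code <- function(symbol, code, source) {
  n1 <- length(source$pools[["1"]])
  switch(symbol,
    blank = matrix(0, GLYPH_SIZE, GLYPH_SIZE),
    minus = rot90ccw(source$pools[["1"]][[code]]),
    plus = pmax(source$pools[["1"]][[(code - 1L) %/% n1 + 1L]],
                rot90ccw(source$pools[["1"]][[(code - 1L) %% n1 + 1L]])),
    source$pools[[symbol]][[code]])
}

# K distinct glyph-index tuples for one problem (rejection sampling)
sample_variant_tuples <- function(sizes, K) {
  if (prod(as.numeric(sizes)) < K)
    abort("glyph pools too small for the requested number of distinct variants")
  seen <- character(0)
  out <- matrix(0L, 0, length(sizes))
  while (nrow(out) < K) {
    draw <- vapply(sizes, function(n) sample.int(n, 1L), integer(1))
    key <- paste(draw, collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out <- rbind(out, draw)
    }
  }
  out
}

render_tuple <- function(symbols, tuple, source) {
  plane <- do.call(cbind, lapply(seq_along(symbols), function(i)
    glyph_from_code(symbols[i], tuple[i], source)))
  array(plane, dim = c(GLYPH_SIZE, 5L * GLYPH_SIZE, 3L))
}

#' Build a full stimulus dataset over the 380-problem space
#'
#' Renders `variants_per_problem` distinct variants of every problem (a
#' variant is a tuple of glyph choices for the five slots), assigning half
#' to the training split and half to the test split. With the default
#' synthetic backend both splits draw from one glyph pool and the variant
#' tuples are sampled without replacement, so the splits share no rendering;
#' with per-split sources (e.g. the MNIST train/test pools) the splits are
#' additionally disjoint at the glyph level.
#'
#' @param variants_per_problem even integer; total variants per problem.
#' @param source_train,source_test glyph sources for the two splits; by
#'   default one shared synthetic source derived from `seed`.
#' @param seed integer seed controlling all sampling.
#' @param problems problem table; defaults to [enumerate_problems()].
#' @param n_glyphs pool size per digit for the default synthetic source.
#' @return an object of class `stim_dataset`: pixel arrays
#'   (`28 x 140 x 3 x n`) and metadata tibbles per split, plus the problem
#'   table in canonical order.
#' @examples
#' ds <- build_stimulus_dataset(2, seed = 1)
#' dim(ds$train_pixels)   # 28 140 3 380
#' @export
build_stimulus_dataset <- function(variants_per_problem = 100L,
                                   source_train = NULL, source_test = NULL,
                                   seed = 1L,
                                   problems = enumerate_problems(),
                                   n_glyphs = 40L) {
  if (variants_per_problem %% 2 != 0 || variants_per_problem < 2)
    abort("`variants_per_problem` must be a positive even integer")
  check_problems(problems)
  seed <- as.integer(seed)
  if (is.null(source_train) && is.null(source_test)) {
    source_train <- source_test <-
      glyph_source("synthetic", "train", seed = seed + 1000L,
                   n_glyphs = n_glyphs)
  } else if (is.null(source_train) || is.null(source_test)) {
    abort("supply both glyph sources or neither")
  }
  shared_pool <- identical(source_train, source_test)
  half <- variants_per_problem %/% 2L
  np <- nrow(problems)
  # draw variant tuples: jointly without replacement when the pool is
  # shared, independently per split otherwise
  both <- withr::with_seed(seed + 11L, {
    lapply(seq_len(np), function(i) {
      sym <- slot_symbols(problems[i, ])
      if (shared_pool) {
        sizes <- slot_pool_sizes(sym, source_train)
        tup <- sample_variant_tuples(sizes, 2L * half)
        list(sym = sym, train = tup[seq_len(half), , drop = FALSE],
             test = tup[half + seq_len(half), , drop = FALSE])
      } else {
        list(sym = sym,
             train = sample_variant_tuples(
               slot_pool_sizes(sym, source_train), half),
             test = sample_variant_tuples(
               slot_pool_sizes(sym, source_test), half))
      }
    })
  })
  render_split <- function(which_split, source) {
    px <- array(0, dim = c(GLYPH_SIZE, 5L * GLYPH_SIZE, 3L, np * half))
    k <- 0L
    for (i in seq_len(np)) {
      tup <- both[[i]][[which_split]]
      for (v in seq_len(half)) {
        k <- k + 1L
        px[, , , k] <- render_tuple(both[[i]]$sym, tup[v, ], source)
      }
    }
    px
  }
  meta <- tibble(
    problem_id = rep(seq_len(np), each = half),
    operand_a = rep(problems$operand_a, each = half),
    operand_b = rep(problems$operand_b, each = half),
    operator = rep(problems$operator, each = half),
    result = rep(problems$result, each = half),
    variant_id = rep(seq_len(half), times = np)
  )
  structure(list(
    train_pixels = render_split("train", source_train),
    train_meta = meta,
    test_pixels = render_split("test", source_test),
    test_meta = mutate(meta, variant_id = .data$variant_id + half),
    problems = problems,
    variants_per_problem = as.integer(variants_per_problem),
    backend = source_train$backend,
    seed = seed
  ), class = "stim_dataset")
}

#' @export
print.stim_dataset <- function(x, ...) {
  cat("<stim_dataset> ", nrow(x$problems), " problems, ",
      dim(x$train_pixels)[4], " train + ", dim(x$test_pixels)[4],
      " test stimuli (", x$backend, " glyphs, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Persist a stimulus dataset
#'
#' Writes the dataset (pixels, labels, split membership and seed metadata)
#' to a single archive; [read_stimulus_dataset()] restores an identical
#' object.
#'
#' @param dataset a `stim_dataset`.
#' @param path file path.
#' @export
write_stimulus_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "stim_dataset"))
  saveRDS(c(list(.format = "gaintwin_stim_dataset", .version = 1L),
            unclass(dataset)), path)
  invisible(path)
}

#' @rdname write_stimulus_dataset
#' @return the restored `stim_dataset`.
#' @export
read_stimulus_dataset <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    abort(paste0("unreadable stimulus dataset archive: ", conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$.format, "gaintwin_stim_dataset"))
    abort("not a gaintwin stimulus dataset archive (missing format tag)")
  need <- c("train_pixels", "train_meta", "test_pixels", "test_meta",
            "problems", "variants_per_problem", "seed")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    abort(paste0("corrupt stimulus dataset archive; missing field: ",
                 paste(miss, collapse = ", ")))
  obj$.format <- NULL; obj$.version <- NULL
  structure(obj, class = "stim_dataset")
}
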