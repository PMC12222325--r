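# Internal helpers: seeded RNG scoping, validation, box conversions.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this so identical seeds give identical outputs.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  s <- utf8ToInt(as.character(stream))
  h <- sum(s * seq_along(s))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x)

# xywh (COCO) <-> xyxy conversions. Boxes are matrices with 4 columns.
xywh_to_xyxy <- function(b) {
  b <- as.matrix(b)
  cbind(b[, 1], b[, 2], b[, 1] + b[, 3], b[, 2] + b[, 4])
}

xyxy_to_xywh <- function(b) {
  b <- as.matrix(b)
  cbind(b[, 1], b[, 2], b[, 3] - b[, 1], b[, 4] - b[, 2])
}
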