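# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax
#' @param x numeric matrix; softmax is taken over each row.
#' @return matrix of the same shape with non-negative rows summing to 1.
#' @keywords internal
#' @noRd
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Glorot-uniform initializer, drawing from the *current* RNG stream so that
# callers control determinism with withr::with_seed().
glorot <- function(dim, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dim), -lim, lim), dim = dim)
}

zeros <- function(dim) array(0, dim = dim)

# Apply f to every numeric leaf of a nested list (used by Adam and the
# checkpoint round-trip checks); structure is preserved.
tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1L]]
  if (is.list(t1)) {
    nm <- names(t1)
    out <- lapply(seq_along(t1), function(i) {
      # align parallel trees by name where available (list order may differ)
      key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
      do.call(tree_map, c(list(f), lapply(trees, `[[`, key)))
    })
    names(out) <- nm
    out
  } else {
    do.call(f, trees)
  }
}

# Total number of scalar parameters in a nested parameter list.
tree_size <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_size, numeric(1))) else length(tree)
}

# Flatten a rank-4 (N, H, W, C) array into an (N*H*W) x C matrix without
# copying semantics beyond a dim change (layout is channel-last).
as_tokens <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

from_tokens <- function(x, d) {
  dim(x) <- d
  x
}
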