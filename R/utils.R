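#' Derive a reproducible child seed from a master seed and a key
#'
#' Stable polynomial hash of the master seed and any number of labels
#' (process name, realization, year). Used so that every stochastic process
#' in an ensemble run draws from its own named, reproducible stream, and so
#' that scenarios sharing a master seed are coupled by common random numbers.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master),
                 vapply(list(...), as.character, character(1))),
               collapse = "/")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h) + 1L
}

# out[i, j] <- m[i - di, j - dj], zero (or `fill`) outside the grid
shift_mat <- function(m, di, dj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr); ci <- seq_len(nc)
  dst_r <- ri[ri - di >= 1 & ri - di <= nr]
  dst_c <- ci[ci - dj >= 1 & ci - dj <= nc]
  if (length(dst_r) && length(dst_c))
    out[dst_r, dst_c] <- m[dst_r - di, dst_c - dj]
  out
}

# Chebyshev-ball offsets (Moore neighborhood of radius r), excluding (0, 0)
moore_offsets <- function(r = 1) {
  g <- expand.grid(di = -r:r, dj = -r:r)
  g[!(g$di == 0 & g$dj == 0), , drop = FALSE]
}

# sum of `mask` (numeric/logical matrix) over the Moore neighborhood
neighbor_sum <- function(mask, r = 1) {
  off <- moore_offsets(r)
  acc <- matrix(0, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off)))
    acc <- acc + shift_mat(mask + 0, off$di[k], off$dj[k])
  acc
}

# TRUE where any Moore neighbor of a TRUE cell in `mask` lies
neighbor_any <- function(mask, r = 1) neighbor_sum(mask, r) > 0

`%||%` <- function(a, b) if (is.null(a)) b else a
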