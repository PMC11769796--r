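# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip EBImage's Image class back to a plain matrix/array
as_plain <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else x
}

# reflect-pad a matrix by r rows/cols on every side (edge pixels mirrored,
# boundary row not duplicated: abc -> cb|abc|ba)
reflect_pad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(r < nr, r < nc)
  ri <- c((r + 1L):2L, 1L:nr, (nr - 1L):(nr - r))
  ci <- c((r + 1L):2L, 1L:nc, (nc - 1L):(nc - r))
  m[ri, ci, drop = FALSE]
}

# moving average over a w x w window with reflected borders, via integral image
box_mean <- function(m, w) {
  stopifnot(w %% 2L == 1L, w >= 3L)
  r <- (w - 1L) %/% 2L
  if (r >= nrow(m) || r >= ncol(m))
    stop("block_size larger than image")
  p <- reflect_pad(m, r)
  # summed-area table with a zero first row/col
  s <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  s[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  nr <- nrow(m); nc <- ncol(m)
  i1 <- 1L:nr; i2 <- i1 + w - 1L
  j1 <- 1L:nc; j2 <- j1 + w - 1L
  (s[i2 + 1L, j2 + 1L] - s[i1, j2 + 1L] - s[i2 + 1L, j1] + s[i1, j1]) / (w * w)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
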