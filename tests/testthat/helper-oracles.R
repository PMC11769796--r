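# Independent oracles, kept deliberately naive.

# queue-based flood fill; the reference for connected-component labeling
flood_fill_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  k <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    k <- k + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- k
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (d in seq_len(nrow(nb))) {
        ii <- p[1] + nb[d, 1]; jj <- p[2] + nb[d, 2]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- k
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# two-sided Mann-Whitney p by explicit enumeration of group labelings,
# with U computed by direct pair counting (no ranks)
mw_permutation_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (N - n1) / 2
  us <- apply(utils::combn(N, n1), 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# axis-aligned filled ellipse mask, semi-axes (a, b) px
ellipse_mask <- function(a, b, pad = 6L) {
  W <- 2L * ceiling(a) + 2L * pad
  H <- 2L * ceiling(b) + 2L * pad
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  xs <- ((seq_len(W) - cx) / a)^2
  ys <- ((seq_len(H) - cy) / b)^2
  outer(ys, xs, `+`) <= 1
}

# IoU of two logical masks
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

# small fast phantom used across tests
tiny_phantom_spec <- function(seed = 1L, ..., width = 160L, height = 160L,
                              n_sections = 12L, nuclei_density = 4,
                              noise_sd = 0.03) {
  phantom_spec(width = width, height = height, n_sections = n_sections,
               nuclei_density = nuclei_density, noise_sd = noise_sd,
               seed = seed, ...)
}
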