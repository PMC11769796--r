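#' Mann-Whitney U test with exact enumeration at small n
#'
#' Rank-sum comparison of two independent samples. The statistic is the
#' number of `(x_i, y_j)` pairs with `x_i > y_j` plus half the tied pairs
#' (so `0 <= U <= n1 * n2`, and `U = n1 * n2 / 2` for identical samples).
#' When `n1 + n2 <= exact_limit` the p-value is exact: the full permutation
#' distribution of U is enumerated over all `choose(n1 + n2, n1)` group
#' labelings (ties included, via midranks), and the two-sided p is the
#' probability of a U at least as far from `n1 * n2 / 2` as observed (the
#' permutation distribution of U is symmetric about that center). For
#' larger samples a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param x,y numeric samples, each non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger),
#'   or `"less"`.
#' @param exact_limit largest `n1 + n2` for which the exact enumeration is
#'   used (default 12).
#' @return object of class `mw_test`: `statistic` (U), `p_value`, `n1`,
#'   `n2`, `method` (`"exact"` or `"normal-approx"`), `alternative`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "greater",
                                                 "less"),
                           exact_limit = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))                       # midranks handle ties
  u_from_ranks <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u <- u_from_ranks(seq_len(n1))
  mu <- n1 * n2 / 2
  eps <- 1e-9

  if (N <= exact_limit) {
    combos <- combn(N, n1)
    us <- apply(combos, 2L, u_from_ranks)
    p <- switch(alternative,
      two.sided = mean(abs(us - mu) >= abs(u - mu) - eps),
      greater   = mean(us >= u - eps),
      less      = mean(us <= u + eps))
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {                     # all values tied
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      z <- u - mu
      p <- switch(alternative,
        two.sided = 2 * pnorm((abs(z) - 0.5) / sigma, lower.tail = FALSE),
        greater   = pnorm((z - 0.5) / sigma, lower.tail = FALSE),
        less      = pnorm((z + 0.5) / sigma))
      p <- min(1, max(p, .Machine$double.xmin))
    }
    method <- "normal-approx"
  }
  structure(list(statistic = u, p_value = p, n1 = n1, n2 = n2,
                 method = method, alternative = alternative),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p = %.4g [%s, %s]\n",
              x$statistic, x$n1, x$n2, x$p_value, x$method, x$alternative))
  invisible(x)
}

profile_matrix <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  reps <- unique(profiles$replicate_id)
  secs <- sort(unique(profiles$section))
  m <- matrix(NA_real_, length(reps), length(secs),
              dimnames = list(reps, secs))
  h <- rep(NA_real_, length(secs))
  for (i in seq_along(reps)) {
    d <- profiles[profiles$replicate_id == reps[i], ]
    j <- match(d$section, secs)
    m[i, j] <- d$coverage
    h[j] <- d$height_um
  }
  list(cov = m, sections = secs, heights = h)
}

# profile AUC by the trapezoidal rule over this replicate's non-missing
# sections; the scalar summary used as the independent unit per replicate
profile_auc <- function(heights, coverage) {
  ok <- !is.na(coverage)
  if (sum(ok) < 2L) return(NA_real_)
  pracma::trapz(heights[ok], coverage[ok])
}

#' Compare coverage profiles of two conditions, section by section
#'
#' For each optical section, a Mann-Whitney test of the replicate coverage
#' values of condition A against condition B; raw p-values are reported
#' alongside Holm-adjusted ones (adjusted across sections). The overall
#' across-sections test keeps replicates as the independent units: each
#' replicate's profile is collapsed to its area under the coverage-versus-
#' height curve (trapezoidal rule), and the per-replicate AUCs are compared
#' with the same Mann-Whitney test.
#'
#' @param profiles_a,profiles_b row-bound [coverage_profile()] tables, one
#'   profile per replicate; section grids must align.
#' @param partial `"skip"` (default) tests a section only when every
#'   replicate of both conditions has non-missing coverage there;
#'   `"allow"` tests whatever non-missing values exist (>= 1 per group).
#' @param alternative passed to [mann_whitney_u()].
#' @return data frame (class `section_comparison`): `level` (`"section"` or
#'   `"overall"`), `section`, `U`, `n1`, `n2`, `p`, `p_holm`, `method`.
#'   `p_holm` is `NA` for the overall row (a single test).
#' @export
per_section_comparison <- function(profiles_a, profiles_b,
                                   partial = c("skip", "allow"),
                                   alternative = "two.sided") {
  partial <- match.arg(partial)
  a <- profile_matrix(profiles_a)
  b <- profile_matrix(profiles_b)
  if (!identical(a$sections, b$sections))
    stop("section grids are misaligned between conditions")
  if (nrow(a$cov) < 2L || nrow(b$cov) < 2L)
    stop("need >= 2 replicates per condition for the overall test")

  secs <- a$sections
  rows <- lapply(seq_along(secs), function(j) {
    va <- a$cov[, j]; vb <- b$cov[, j]
    usable <- if (partial == "skip") !anyNA(c(va, vb)) else
      sum(!is.na(va)) >= 1L && sum(!is.na(vb)) >= 1L
    if (!usable) {
      return(data.frame(level = "section", section = secs[j], U = NA_real_,
                        n1 = NA_integer_, n2 = NA_integer_, p = NA_real_,
                        method = NA_character_, stringsAsFactors = FALSE))
    }
    t <- mann_whitney_u(va[!is.na(va)], vb[!is.na(vb)],
                        alternative = alternative)
    data.frame(level = "section", section = secs[j], U = t$statistic,
               n1 = t$n1, n2 = t$n2, p = t$p_value, method = t$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  ok <- !is.na(out$p)
  out$p_holm[ok] <- stats::p.adjust(out$p[ok], method = "holm")

  auc_a <- apply(a$cov, 1L, function(v) profile_auc(a$heights, v))
  auc_b <- apply(b$cov, 1L, function(v) profile_auc(b$heights, v))
  t <- mann_whitney_u(auc_a[!is.na(auc_a)], auc_b[!is.na(auc_b)],
                      alternative = alternative)
  out <- rbind(out,
               data.frame(level = "overall", section = NA_integer_,
                          U = t$statistic, n1 = t$n1, n2 = t$n2,
                          p = t$p_value, method = t$method,
                          p_holm = NA_real_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("section_comparison", class(out))
  out
}
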