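#' Bonferroni threshold for all pairwise comparisons
#'
#' With `n_groups` groups there are `m = n_groups * (n_groups - 1) / 2`
#' unordered comparisons and the family-wise per-comparison threshold is
#' `alpha / m`. The reported threshold is rounded to 3 significant figures
#' for display (8 groups at alpha 0.05 print as 0.00179, 4 groups as
#' 0.00833) but decisions always use the unrounded value.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_groups Number of groups (>= 2).
#' @return List: `m`, `threshold` (unrounded), `threshold_3sf`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_groups) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  n_groups <- as.integer(n_groups)
  if (is.na(n_groups) || n_groups < 2L) stop("`n_groups` must be >= 2", call. = FALSE)
  m <- n_groups * (n_groups - 1L) / 2
  thr <- alpha / m
  list(m = m, threshold = thr, threshold_3sf = signif(thr, 3))
}

welch_p <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      message("both groups constant with equal means: p = 1 by convention")
      return(1)
    }
    return(0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

student_p <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(1) else return(0)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

permutation_p <- function(x, y, n_perm = 10000L, seed = NULL,
                          exact_limit = 20000) {
  n1 <- length(x); n <- n1 + length(y)
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  n_assign <- choose(n, n1)
  if (n_assign <= exact_limit) {
    idx <- combn(n, n1)
    diffs <- apply(idx, 2L, function(i) {
      abs(mean(pooled[i]) - mean(pooled[-i]))
    })
    mean(diffs >= obs - 1e-12)
  } else {
    draw <- function() {
      hits <- vapply(seq_len(n_perm), function(j) {
        i <- sample.int(n, n1)
        abs(mean(pooled[i]) - mean(pooled[-i])) >= obs - 1e-12
      }, logical(1))
      (sum(hits) + 1) / (n_perm + 1)
    }
    if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
  }
}

#' Pairwise comparison matrix with two-tier significance flags
#'
#' Tests every unordered pair of groups for a difference in means and flags
#' each cell: `"double"` when the p-value clears the Bonferroni-corrected
#' threshold `alpha / m`, `"single"` when it is below `alpha` but not the
#' corrected threshold, `"ns"` otherwise. Groups with fewer than two values
#' are kept in the matrix and flagged `"insufficient-n"` rather than being
#' dropped silently.
#'
#' @param data Data frame of biological-replicate metrics.
#' @param value,group Column names (strings) of the metric values and group
#'   labels.
#' @param method `"welch"` (unequal-variance t, default), `"student"`, or
#'   `"permutation"` (exact enumeration when the number of group-label
#'   assignments is at most 20000, Monte Carlo with `seed` otherwise).
#' @param alpha Family-wise error rate.
#' @param n_perm,seed Monte Carlo permutation settings.
#' @return A `comparison_matrix`: list with `labels`, `p` (symmetric matrix,
#'   `NA` diagonal), `flags` (character matrix), `alpha`, `m`, `threshold`,
#'   `method`, `n` (per-group sizes).
#' @export
pairwise_compare <- function(data, value = "max_rate", group = "strain",
                             method = c("welch", "student", "permutation"),
                             alpha = 0.05, n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(value %in% names(data), group %in% names(data))
  vals <- split(data[[value]], as.character(data[[group]]))
  vals <- lapply(vals, function(v) v[is.finite(v)])
  labels <- names(vals)
  if (length(labels) < 2L) stop("need at least 2 groups", call. = FALSE)
  bt <- bonferroni_threshold(alpha, length(labels))
  p <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  flags <- matrix("ns", length(labels), length(labels),
                  dimnames = list(labels, labels))
  diag(flags) <- ""
  for (i in seq_along(labels)[-length(labels)]) {
    for (j in (i + 1L):length(labels)) {
      x <- vals[[i]]; y <- vals[[j]]
      if (length(x) < 2L || length(y) < 2L) {
        flags[i, j] <- flags[j, i] <- "insufficient-n"
        next
      }
      pv <- switch(method,
        welch = welch_p(x, y),
        student = student_p(x, y),
        permutation = permutation_p(x, y, n_perm = n_perm, seed = seed))
      p[i, j] <- p[j, i] <- pv
      fl <- if (pv < bt$threshold) "double" else if (pv < alpha) "single" else "ns"
      flags[i, j] <- flags[j, i] <- fl
    }
  }
  structure(list(labels = labels, p = p, flags = flags, alpha = alpha,
                 m = bt$m, threshold = bt$threshold, method = method,
                 n = vapply(vals, length, integer(1))),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix> %d groups, %d comparisons, %s test\n",
              length(x$labels), x$m, x$method))
  cat(sprintf("alpha = %g, Bonferroni-corrected threshold p < %g (3 s.f.)\n",
              x$alpha, signif(x$threshold, 3)))
  print(round(x$p, 5))
  cat("flags ('double' = significant after correction):\n")
  print(x$flags, quote = FALSE)
  invisible(x)
}

#' Empirical family-wise type-I error of the comparison stage
#'
#' Simulates all-null Gaussian groups, runs [pairwise_compare()] with
#' Bonferroni flagging, and reports the fraction of simulations producing at
#' least one `"double"` flag. For a valid correction this is at most
#' `alpha` (conservative for more than two groups).
#'
#' @param method Test method, as in [pairwise_compare()].
#' @param n_per_group,n_groups Simulated design.
#' @param n_sims Number of simulations (0 yields an empty report).
#' @param alpha Family-wise error rate.
#' @param seed Integer seed.
#' @return List: `rate` (observed family-wise error, `NA` when
#'   `n_sims = 0`), `n_sims`, `se` (binomial standard error).
#' @export
type_i_error_check <- function(method = "welch", n_per_group = 3L,
                               n_groups = 4L, n_sims = 2000L, alpha = 0.05,
                               seed = 1L) {
  if (n_sims <= 0) return(list(rate = NA_real_, n_sims = 0L, se = NA_real_))
  run <- function() {
    hits <- vapply(seq_len(n_sims), function(s) {
      df <- data.frame(
        strain = rep(paste0("g", seq_len(n_groups)), each = n_per_group),
        max_rate = rnorm(n_groups * n_per_group))
      cm <- pairwise_compare(df, method = method, alpha = alpha)
      any(cm$flags == "double")
    }, logical(1))
    mean(hits)
  }
  rate <- withr::with_seed(seed, run())
  list(rate = rate, n_sims = as.integer(n_sims),
       se = sqrt(rate * (1 - rate) / n_sims))
}
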