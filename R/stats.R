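# Two-group comparison with the normality-gated test choice: Lilliefors
# test on each sample (and on the paired differences), then Student's t
# when normality holds, otherwise Wilcoxon signed-rank / Mann-Whitney U.

# Cache of Monte-Carlo null distributions of the Lilliefors statistic,
# keyed by sample size (and replicate count).
.lilliefors_cache <- new.env(parent = emptyenv())

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- (x - mean(x)) / sd(x)
  u <- pnorm(sort(z))
  i <- seq_len(n)
  max(max(i / n - u), max(u - (i - 1) / n))
}

#' Lilliefors normality test with a Monte-Carlo null
#'
#' Kolmogorov-Smirnov test against a normal distribution with mean and
#' sd estimated from the data. Because the parameters are estimated, the
#' standard KS null does not apply; the null distribution of the
#' statistic is built by Monte-Carlo simulation (>= 10^4 standard-normal
#' samples of the same size, internally seeded and cached per sample
#' size, so results are deterministic and do not touch the caller's RNG
#' stream).
#'
#' @param x numeric sample, length >= 4, non-constant.
#' @param nsim Monte-Carlo replicates for the null distribution.
#' @return list with `statistic` and `p.value`.
#' @export
lilliefors_test <- function(x, nsim = 10000) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) abort("Lilliefors test needs at least 4 observations.")
  if (sd(x) == 0) abort("Lilliefors test is undefined for a constant sample.")
  key <- sprintf("n%d_s%d", n, nsim)
  if (is.null(.lilliefors_cache[[key]])) {
    .lilliefors_cache[[key]] <- with_local_seed(772210 + n, {
      vapply(seq_len(nsim), function(i) lilliefors_stat(rnorm(n)), double(1))
    })
  }
  d <- lilliefors_stat(x)
  null_d <- .lilliefors_cache[[key]]
  list(statistic = d, p.value = (1 + sum(null_d >= d)) / (nsim + 1))
}

#' Compare two samples with the normality-gated test choice
#'
#' Normality of each sample (and of the pairwise differences when
#' `paired`) is checked with [lilliefors_test()]. If every check passes
#' at `alpha_normality`, a Student's t test is used (paired or
#' unpaired, pooled variance); otherwise the Wilcoxon signed-rank test
#' (paired) or Mann-Whitney U test (unpaired). A zero-variance sample
#' forces the nonparametric branch, flagged in the output.
#'
#' @param x,y numeric samples, `n >= 3` each (equal lengths when
#'   paired).
#' @param paired are the samples paired (within-animal before/after)?
#' @param alpha_normality significance level of the normality gate.
#' @return one-row tibble of class `test_result`: `statistic`, `p`,
#'   `test_name` (`t_paired`, `t_unpaired`, `wilcoxon_signed_rank`,
#'   `mann_whitney_u`), `normality_p` (minimum across checks), `n_x`,
#'   `n_y`, `degenerate`.
#' @export
compare_groups <- function(x, y, paired = FALSE, alpha_normality = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) abort("each group needs at least 3 observations.")
  if (paired && length(x) != length(y)) abort("paired samples must have equal lengths.")

  degenerate <- sd(x) == 0 || sd(y) == 0 || (paired && sd(x - y) == 0)
  normality_p <- NA_real_
  normal <- FALSE
  if (!degenerate) {
    checks <- c(lilliefors_test(x)$p.value, lilliefors_test(y)$p.value)
    if (paired) checks <- c(checks, lilliefors_test(x - y)$p.value)
    normality_p <- min(checks)
    normal <- all(checks > alpha_normality)
  }

  if (normal) {
    ht <- t.test(x, y, paired = paired, var.equal = !paired)
    test_name <- if (paired) "t_paired" else "t_unpaired"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = paired, exact = FALSE))
    test_name <- if (paired) "wilcoxon_signed_rank" else "mann_whitney_u"
  }
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # fully degenerate data (e.g. x == y element-wise)
  out <- tibble::tibble(statistic = unname(ht$statistic), p = p,
                        test_name = test_name, normality_p = normality_p,
                        n_x = length(x), n_y = length(y),
                        degenerate = degenerate)
  class(out) <- c("test_result", class(out))
  out
}
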