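#' ROC curve and AUC by pair counting
#'
#' Receiver operating characteristic analysis oriented for a biomarker whose
#' \emph{low} values indicate the positive class (residual enzyme activity:
#' low activity = Hurler). The AUC is computed exactly by pair counting,
#'
#' \deqn{AUC = \frac{\#\{(i,j): x_i < y_j\} + 0.5\,\#\{x_i = y_j\}}{n_+ n_-}}
#'
#' over all positive/negative pairs, which for small samples is the exact
#' (trapezoidal) area under the empirical curve and equals the scaled
#' Mann-Whitney statistic. Curve points enumerate every distinct observed
#' value as a cut-off, with sensitivity = P(positive <= cut-off) and
#' specificity = P(negative > cut-off).
#'
#' @param values numeric vector of marker values.
#' @param labels parallel labels; `positive` (default `"H"`) is the positive
#'   class, everything else negative.
#' @param positive label of the positive class.
#' @return An object of class `"mpsi_roc"`: `auc`, `n_pos`, `n_neg`, and
#'   `points`, a data.frame with columns `cutoff`, `sensitivity`,
#'   `specificity` ordered by increasing cut-off.
#' @examples
#' coh <- mpsi_cohort()
#' keep <- !is.na(coh$idua_activity) & !is.na(coh$phenotype)
#' roc_auc(coh$idua_activity[keep], binary_phenotype(coh$phenotype[keep]))
#' @export
roc_auc <- function(values, labels, positive = "H") {
  stopifnot(length(values) == length(labels), all(is.finite(values)))
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("AUC undefined: need at least one sample in each class",
         call. = FALSE)
  }
  conc <- outer(pos, neg, "<")
  ties <- outer(pos, neg, "==")
  auc <- (sum(conc) + 0.5 * sum(ties)) / (length(pos) * length(neg))
  cutoffs <- sort(unique(values))
  points <- data.frame(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(c) mean(pos <= c), numeric(1)),
    specificity = vapply(cutoffs, function(c) mean(neg > c), numeric(1))
  )
  structure(list(auc = auc, n_pos = length(pos), n_neg = length(neg),
                 points = points), class = "mpsi_roc")
}

#' @export
print.mpsi_roc <- function(x, ...) {
  cat(sprintf("ROC (low value = positive): AUC = %.3f (%d positive vs %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.mpsi_roc <- function(x, ...) {
  fpr <- c(0, rev(1 - x$points$specificity), 1)
  tpr <- c(0, rev(x$points$sensitivity), 1)
  plot(fpr, tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("ROC curve (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Map phenotype labels to the H / non-H dichotomy
#'
#' Hurler-Scheie and Scheie both map to `"non-H"`: the dichotomy follows the
#' treatment indication (transplantation for Hurler, enzyme replacement
#' otherwise).
#'
#' @param phenotype character vector of `"H"`, `"HS"`, `"S"` (NA preserved).
#' @return Character vector of `"H"` / `"non-H"`.
#' @export
binary_phenotype <- function(phenotype) {
  binary_label(phenotype)
}

#' Two-sided Fisher's exact test by hypergeometric enumeration
#'
#' Probability-based two-sided exact test for a 2x2 table with fixed
#' margins: the p-value is the sum of hypergeometric probabilities of every
#' table (with the observed margins) whose probability does not exceed that
#' of the observed table, the comparison made with relative tolerance 1e-7
#' to absorb floating-point noise. This is the convention of standard
#' statistical packages.
#'
#' @param x a 2x2 integer matrix (rows = class, columns = feature
#'   present/absent), or the count `a` with `b`, `c`, `d` supplied.
#' @param b,c,d remaining cells when `x` is scalar `a`.
#' @return The two-sided p-value, clipped to the unit interval.
#' @examples
#' fisher_exact_two_sided(matrix(c(7, 2, 1, 9), 2, byrow = TRUE))  # 0.00548
#' @export
fisher_exact_two_sided <- function(x, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2L, 2L)))
    a <- x[1, 1]; b <- x[1, 2]; c <- x[2, 1]; d <- x[2, 2]
  } else {
    a <- x
    stopifnot(!is.null(b), !is.null(c), !is.null(d))
  }
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)), sum(cells) >= 1)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0L, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  log_obs <- logp[support == a]
  p <- sum(exp(logp)[logp <= log_obs + log1p(1e-7)])
  min(max(p, 0), 1)
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with the U statistic counted over all
#' cross-sample pairs (ties contribute 0.5). The reported `U` is the
#' conventional min(U1, U2); `U_less` counts pairs with `x < y` (plus half
#' ties), so that `U_less / (n_x n_y)` is the AUC of `x` as the low-valued
#' positive class. The two-sided p-value is exact — the probability, over
#' all equally likely assignments of the pooled values to the two groups, of
#' a U at least as far from its null mean `n_x n_y / 2` as observed —
#' computed by full enumeration of the null distribution (dynamic
#' programming over rank subsets) when there are no ties and
#' `min(n_x, n_y) <= 12`, and otherwise by seeded Monte-Carlo permutation.
#'
#' @param x,y numeric vectors.
#' @param n_perm number of permutations for the Monte-Carlo branch.
#' @return A list: `U`, `U_less`, `U_greater`, `p`, and `method`
#'   (`"exact"` or `"permutation"`).
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_exact <- function(x, y, n_perm = 1e5) {
  stopifnot(length(x) >= 1L, length(y) >= 1L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  u_less <- sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  u_greater <- n1 * n2 - u_less
  u_obs <- min(u_less, u_greater)
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0L

  if (!has_ties && min(n1, n2) <= 12L) {
    # null distribution of U_greater = (rank sum of x) - n1(n1+1)/2 over all
    # choose(n1+n2, n1) subsets; counts via DP over ranks
    dist <- u_null_distribution(n1, n2)
    mu <- n1 * n2 / 2
    dev <- abs(seq_along(dist) - 1 - mu)
    p <- sum(dist[dev >= abs(u_obs - mu) - 1e-9]) / sum(dist)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    r <- rank(pooled)
    dev_obs <- abs(u_obs - mu)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n1 + n2, n1)
      ug <- sum(r[idx]) - n1 * (n1 + 1) / 2
      if (abs(ug - mu) >= dev_obs - 1e-9) hits <- hits + 1L
    }
    p <- hits / n_perm
    method <- "permutation"
  }
  list(U = u_obs, U_less = u_less, U_greater = u_greater,
       p = min(p, 1), method = method)
}

# counts of subsets of ranks 1..(n1+n2) of size n1 by U value (0..n1*n2);
# recurrence over ranks taken one at a time, tracking subset size and rank sum
u_null_distribution <- function(n1, n2) {
  N <- n1 + n2
  max_sum <- sum((N - n1 + 1):N)
  # dp[k+1, s+1] = number of size-k subsets of ranks seen so far with sum s
  dp <- matrix(0, nrow = n1 + 1L, ncol = max_sum + 1L)
  dp[1, 1] <- 1
  for (r in seq_len(N)) {
    for (k in rev(seq_len(min(r, n1)))) {
      upto <- max_sum - r
      dp[k + 1L, (r + 1L):(upto + r + 1L)] <-
        dp[k + 1L, (r + 1L):(upto + r + 1L)] + dp[k, 1L:(upto + 1L)]
    }
  }
  sums <- dp[n1 + 1L, ]
  min_sum <- n1 * (n1 + 1) / 2
  # U_greater = ranksum - min_sum, support 0..n1*n2
  sums[(min_sum + 1L):(min_sum + n1 * n2 + 1L)]
}
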