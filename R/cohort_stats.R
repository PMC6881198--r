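# Repeated-measures cohort statistics: Pearson correlation with p value,
# the Friedman rank test (with an exact small-sample p value computed by
# dynamic programming over within-block rank permutations), and
# Bonferroni-corrected pairwise sign-permutation post hocs.

#' Paired cohort table
#'
#' One value per (patient, condition), e.g. flow behavior indices at 92,
#' 46, and 0 mm Hg. Friedman's test requires complete blocks.
#'
#' @param values Numeric matrix, rows = patients, columns = conditions;
#'   or a long data frame with columns `patient`, `condition`, `value`.
#' @return A numeric matrix of class `paired_cohort_table` with condition
#'   column names.
#' @export
paired_cohort_table <- function(values) {
  if (is.data.frame(values)) {
    need <- c("patient", "condition", "value")
    if (!all(need %in% names(values)))
      stop("long-format input needs columns patient, condition, value",
           call. = FALSE)
    m <- tapply(values$value, list(values$patient, values$condition),
                identity)
    values <- matrix(as.numeric(m), nrow(m), ncol(m),
                     dimnames = dimnames(m))
  }
  values <- as.matrix(values)
  if (anyNA(values))
    stop("table is incomplete: Friedman's test requires one value per ",
         "(patient, condition)", call. = FALSE)
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 patients and 2 conditions", call. = FALSE)
  structure(values, class = c("paired_cohort_table", "matrix"))
}

# Friedman chi-square statistic from within-block average ranks,
# with the standard tie correction.
friedman_statistic <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1, rank))
  cs <- colSums(R)
  stat <- 12 / (n * k * (k + 1)) * sum(cs^2) - 3 * n * (k + 1)
  ties <- apply(m, 1, function(r) {
    tt <- table(r); sum(tt^3 - tt)
  })
  corr <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (corr > 0) stat <- stat / corr
  stat
}

# Exact null distribution of sum of squared column rank sums for an
# (n blocks) x (k conditions) untied design, by dynamic-programming
# convolution over the k! equally likely rank orders per block.
# Returns list(ss = sorted unique sum-of-squares values, tail_p).
friedman_exact_dist <- function(n, k) {
  key <- paste0("f_", n, "_", k)
  cached <- .oxyrheo_cache[[key]]
  if (!is.null(cached)) return(cached)
  perms <- permutations_of(seq_len(k))      # k! x k matrix
  # state: column sums of the first k-1 columns (the k-th is determined)
  state <- matrix(0L, 1, k - 1)
  prob <- 1
  for (b in seq_len(n)) {
    ns <- state[rep(seq_len(nrow(state)), each = nrow(perms)), ,
                drop = FALSE] +
      perms[rep(seq_len(nrow(perms)), nrow(state)), -k, drop = FALSE]
    np <- rep(prob, each = nrow(perms)) / nrow(perms)
    keyv <- apply(ns, 1, paste, collapse = "_")
    agg <- rowsum(np, keyv)
    state <- do.call(rbind, lapply(strsplit(rownames(agg), "_"),
                                   as.integer))
    prob <- as.vector(agg)
  }
  tot <- n * k * (k + 1) / 2
  ss <- rowSums(state^2) + (tot - rowSums(state))^2
  ord <- order(ss)
  ss <- ss[ord]; prob <- prob[ord]
  agg <- rowsum(prob, ss)
  ssu <- as.numeric(rownames(agg))
  pu <- as.vector(agg)
  out <- list(ss = ssu, tail_p = rev(cumsum(rev(pu))))
  .oxyrheo_cache[[key]] <- out
  out
}

# All permutations of a vector (k <= 7 guard).
permutations_of <- function(x) {
  k <- length(x)
  if (k > 7) stop("permutation enumeration limited to k <= 7",
                  call. = FALSE)
  if (k == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_len(k)) {
    sub <- permutations_of(x[-i])
    out <- rbind(out, cbind(x[i], sub))
  }
  unname(out)
}

.oxyrheo_cache <- new.env(parent = emptyenv())

#' Friedman rank test for repeated measures
#'
#' Within-patient ranks (average ranks on ties) are summed per condition
#' and combined into the chi-square-distributed Friedman statistic with
#' k - 1 degrees of freedom. For untied tables of modest size the p value
#' is computed exactly from the permutation null distribution (all k!^n
#' equally likely within-block rank orders, enumerated by dynamic
#' programming over column rank sums); otherwise the asymptotic
#' chi-square approximation is used. At the 9-patient, 3-condition design
#' the exact test holds the 5% level closely while the asymptotic
#' approximation is slightly anti-conservative.
#'
#' @param table A [paired_cohort_table()] (or coercible matrix).
#' @param method `"auto"` (exact when untied and k <= 5, n <= 30),
#'   `"exact"`, or `"asymptotic"`.
#' @return List of class `friedman_result`: `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
friedman_test <- function(table, method = c("auto", "exact",
                                            "asymptotic")) {
  method <- match.arg(method)
  m <- paired_cohort_table(table)
  n <- nrow(m); k <- ncol(m)
  has_ties <- any(apply(m, 1, anyDuplicated) > 0)
  stat <- friedman_statistic(m)
  if (method == "auto")
    method <- if (!has_ties && k <= 5 && n <= 30) "exact" else "asymptotic"
  if (method == "exact") {
    if (has_ties)
      stop("exact Friedman p value requires untied blocks; ",
           "use method = 'asymptotic'", call. = FALSE)
    dist <- friedman_exact_dist(n, k)
    # invert the statistic to the sum of squared column rank sums
    ss_obs <- (stat + 3 * n * (k + 1)) * n * k * (k + 1) / 12
    p <- if (any(dist$ss >= ss_obs - 1e-9))
      dist$tail_p[which(dist$ss >= ss_obs - 1e-9)[1]] else 0
  } else {
    p <- stats::pchisq(stat, k - 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = k - 1, p_value = p,
                 method = method, n = n, k = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4g, df = %d, p = %.4g (%s, %d x %d)\n",
              x$statistic, x$df, x$p_value, x$method, x$n, x$k))
  invisible(x)
}

#' Pearson correlation with its two-sided p value
#'
#' Sample correlation with the p value from the t transform on n - 2
#' degrees of freedom, as used for the linearity of fractional velocity
#' change against hemoglobin fractions.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List: `r`, `p_value`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# Exact paired sign-permutation p value for the differences d (two-sided):
# the proportion of the 2^m sign assignments whose |sum| is at least the
# observed |sum|. Zero differences are dropped.
sign_permutation_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  if (m > 20)
    stop("exact sign-permutation test limited to 20 non-zero differences",
         call. = FALSE)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  sums <- abs(as.vector(signs %*% d))
  mean(sums >= abs(sum(d)) - 1e-12)
}

#' Bonferroni-corrected pairwise comparisons for a paired cohort table
#'
#' Every pair of conditions is compared with an exact paired
#' sign-permutation test on the within-patient differences (all 2^n sign
#' flips enumerated); raw p values are multiplied by the number of pairs
#' and capped at 1. A Wilcoxon signed-rank alternative is available.
#'
#' @param table A [paired_cohort_table()] (or coercible matrix).
#' @param alpha Family-wise significance level (default 0.05).
#' @param method `"sign_permutation"` (default, exact) or `"wilcoxon"`.
#' @return Data frame: `condition_a`, `condition_b`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
pairwise_bonferroni <- function(table, alpha = 0.05,
                                method = c("sign_permutation",
                                           "wilcoxon")) {
  method <- match.arg(method)
  m <- paired_cohort_table(table)
  k <- ncol(m)
  labs <- colnames(m)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- m[, a] - m[, b]
    p <- if (method == "sign_permutation") sign_permutation_p(d)
         else if (all(d == 0)) 1
         else suppressWarnings(
           stats::wilcox.test(d, exact = TRUE)$p.value)
    data.frame(condition_a = labs[a], condition_b = labs[b], p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * n_pairs)
  out$significant <- out$p_adj < alpha
  out
}
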