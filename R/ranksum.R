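#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test reporting the Wilcoxon statistic W (rank sum of
#' `x` using midranks). For small samples (`n1 + n2 <= exact_limit`) the
#' permutation distribution of W is enumerated exactly - ties included, which
#' is why this is done in-house; otherwise a normal approximation with tie
#' and continuity corrections is used. Two-sided p is
#' `Pr(|W - mu| >= |W_obs - mu|)`.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param exact_limit maximum pooled size for exact enumeration.
#' @return one-row tibble of class `ranksum_result`: `statistic`, `n1`, `n2`,
#'   `p_two_sided`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_limit = 20L) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (all(pooled == pooled[1])) {
    return(ranksum_result(W, n1, n2, 1,
                          if (n <= exact_limit) "exact" else "normal_approx"))
  }
  if (n <= exact_limit) {
    sel <- utils::combn(n, n1)
    Ws <- colSums(matrix(r[sel], nrow = n1))
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    return(ranksum_result(W, n1, n2, p, "exact"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(ranksum_result(W, n1, n2, 1, "normal_approx"))
  z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-max(0, z)))
  ranksum_result(W, n1, n2, p, "normal_approx")
}

ranksum_result <- function(W, n1, n2, p, method) {
  out <- tibble(statistic = W, n1 = n1, n2 = n2, p_two_sided = p,
                method = method)
  structure(out, class = c("ranksum_result", class(out)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy ranksum_result
tidy.ranksum_result <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_two_sided, method = x$method)
}

#' @export
#' @method glance ranksum_result
glance.ranksum_result <- function(x, ...) tidy.ranksum_result(x)
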