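#' Shapiro-Wilk normality check
#'
#' Used as a gate justifying the nonparametric comparison path (the
#' analysis never branches into a parametric ANOVA).
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop("insufficient data: Shapiro-Wilk needs n >= 3", call. = FALSE)
  }
  if (length(values) > 5000) stop("Shapiro-Wilk limited to n <= 5000",
                                  call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("Shapiro-Wilk undefined for constant input", call. = FALSE)
  }
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with df = k - 1. The default p-value uses the
#' chi-squared approximation (the convention for field data). For small
#' samples `p_method = "permutation"` enumerates all assignments of the
#' pooled observations to the group sizes and returns the exact
#' permutation tail probability of H.
#'
#' @param groups List of numeric vectors (>= 2 groups, each nonempty).
#' @param p_method `"chisq"` (default) or `"permutation"` (total n <= 9).
#' @return List with `H`, `df`, `p`, `n`, `p_method`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "permutation")) {
  p_method <- match.arg(p_method)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!vapply(groups, length, 1L))) {
    stop("each group must be nonempty", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups)

  if (stats::sd(x) == 0) {
    return(list(H = 0, df = k - 1L, p = 1, n = length(x),
                p_method = p_method))
  }
  ht <- stats::kruskal.test(x, g)
  H <- unname(ht$statistic)
  out <- list(H = H, df = k - 1L, p = ht$p.value, n = length(x),
              p_method = p_method)
  if (p_method == "permutation") {
    if (length(x) > 9) {
      stop("permutation p limited to total n <= 9", call. = FALSE)
    }
    sizes <- vapply(groups, length, 1L)
    Hs <- apply(all_permutations(length(x)), 1, function(idx) {
      kw_statistic(x[idx], sizes)
    })
    out$p <- mean(Hs >= H - 1e-9)
  }
  out
}

# Tie-corrected Kruskal-Wallis statistic for pooled values laid out in
# consecutive blocks of the given group sizes.
kw_statistic <- function(x, sizes) {
  n <- length(x)
  r <- rank(x)
  g <- rep(seq_along(sizes), sizes)
  rs <- tapply(r, g, sum)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (i in seq_len(n)) {
    # prepend i, shift sub-permutation values >= i up by one
    out[((i - 1L) * m + 1L):(i * m), ] <-
      cbind(rep(i, m), sub + (sub >= i))
  }
  out
}

#' Pairwise one-sided Wilcoxon rank-sum tests with BH adjustment
#'
#' Unpaired Wilcoxon (Mann-Whitney) test for every pair of groups, exact
#' when both groups have n <= 10 and the pooled values are tie-free,
#' otherwise the normal approximation with tie correction. Raw p-values
#' are adjusted over all pairs with the Benjamini-Hochberg step-up
#' procedure.
#'
#' @param groups Named list of numeric vectors.
#' @param alternative Either a single string (`"two.sided"`, `"greater"`,
#'   `"less"`) applied to every ordered pair (i, j), i < j, meaning group i
#'   versus group j; or a function `(name_i, name_j) -> alternative`
#'   allowing per-comparison directions (e.g. amended treatments tested
#'   one-sidedly against the reference).
#' @return List with matrices `p_raw` and `p_adjusted` (symmetric in
#'   labels; `[i, j]` and `[j, i]` carry the same comparison), the pair
#'   table `pairs`, and `method`.
#' @export
pairwise_wilcoxon_bh <- function(groups, alternative = "greater") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  nm <- names(groups)
  k <- length(groups)
  combos <- utils::combn(k, 2)
  alt_fun <- if (is.function(alternative)) alternative else {
    function(a, b) alternative
  }

  pairs <- data.frame(group1 = nm[combos[1, ]], group2 = nm[combos[2, ]],
                      alternative = NA_character_, n1 = NA_integer_,
                      n2 = NA_integer_, statistic = NA_real_,
                      p_raw = NA_real_, stringsAsFactors = FALSE)
  for (c_i in seq_len(ncol(combos))) {
    i <- combos[1, c_i]; j <- combos[2, c_i]
    gi <- groups[[i]]; gj <- groups[[j]]
    alt <- alt_fun(nm[i], nm[j])
    exact <- length(gi) <= 10 && length(gj) <= 10 &&
      !anyDuplicated(c(gi, gj))
    ht <- suppressWarnings(
      stats::wilcox.test(gi, gj, alternative = alt, exact = exact,
                         correct = !exact)
    )
    pairs$alternative[c_i] <- alt
    pairs$n1[c_i] <- length(gi); pairs$n2[c_i] <- length(gj)
    pairs$statistic[c_i] <- unname(ht$statistic)
    pairs$p_raw[c_i] <- ht$p.value
  }
  pairs$p_adjusted <- stats::p.adjust(pairs$p_raw, method = "BH")

  p_raw <- p_adj <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (c_i in seq_len(ncol(combos))) {
    i <- combos[1, c_i]; j <- combos[2, c_i]
    p_raw[i, j] <- p_raw[j, i] <- pairs$p_raw[c_i]
    p_adj[i, j] <- p_adj[j, i] <- pairs$p_adjusted[c_i]
  }
  list(p_raw = p_raw, p_adjusted = p_adj, pairs = pairs,
       method = "one/two-sided Wilcoxon rank-sum, Benjamini-Hochberg")
}

#' Spearman rank-correlation screen across parameter columns
#'
#' Rank correlation (average ranks on ties) for every pair of numeric
#' columns, using pairwise-complete observations; pairs with fewer than
#' `min_n` complete cases are reported as not estimable rather than
#' dropped silently. Censored measurements should enter as NA.
#'
#' @param table data.frame of aligned parameter columns.
#' @param min_n Minimum complete cases per pair (default 4).
#' @return data.frame with columns `param1`, `param2`, `n`, `rho`, `p`,
#'   `estimable`.
#' @export
spearman_screen <- function(table, min_n = 4) {
  num <- table[vapply(table, is.numeric, TRUE)]
  nm <- names(num)
  stopifnot(length(nm) >= 2)
  combos <- utils::combn(length(nm), 2)
  rows <- lapply(seq_len(ncol(combos)), function(c_i) {
    i <- combos[1, c_i]; j <- combos[2, c_i]
    ok <- stats::complete.cases(num[[i]], num[[j]])
    n <- sum(ok)
    if (n < min_n) {
      return(data.frame(param1 = nm[i], param2 = nm[j], n = n,
                        rho = NA_real_, p = NA_real_, estimable = FALSE,
                        stringsAsFactors = FALSE))
    }
    ht <- suppressWarnings(
      stats::cor.test(num[[i]][ok], num[[j]][ok], method = "spearman",
                      exact = FALSE)
    )
    data.frame(param1 = nm[i], param2 = nm[j], n = n,
               rho = unname(ht$estimate), p = ht$p.value, estimable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
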