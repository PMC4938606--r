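#' Agreement metrics between paired time-series measurements
#'
#' For two measurements `f(t)`, `g(t)` of the same quantity over a
#' maneuver of `T` frames, the absolute systematic error captures the
#' bias at full expiration,
#' `ASE = |f(T) - g(T)|`, and the mean absolute residual error the
#' remaining variation once that bias is removed,
#' `MARE = mean_t |(f(t) - g(t)) - (f(T) - g(T))|`.
#'
#' @param f,g numeric vectors of equal length (same units, e.g. mm).
#' @return scalar error in the input units.
#' @export
ase <- function(f, g) {
  if (length(f) != length(g)) stop("series lengths differ")
  Tn <- length(f)
  abs(f[Tn] - g[Tn])
}

#' @rdname ase
#' @export
mare <- function(f, g) {
  if (length(f) != length(g)) stop("series lengths differ")
  Tn <- length(f)
  bias <- f[Tn] - g[Tn]
  mean(abs((f - g) - bias))
}

#' Group comparison statistics for a feature table
#'
#' Per feature: group means and standard deviations, a two-sided Wilcoxon
#' rank-sum test (exact for group sizes up to `exact_max` without ties,
#' normal approximation with tie correction otherwise) with a 5%
#' significance flag, output sorted by descending p-value; plus the
#' Pearson correlation matrix over all feature pairs with nonsignificant
#' (p >= 0.05) entries masked as `NA`.
#'
#' @param features data.frame of numeric feature columns.
#' @param group factor/character vector (two levels) per row.
#' @param alpha significance level.
#' @param exact_max largest per-group size for the exact distribution.
#' @return list with `table` (data.frame: feature, means, sds, p,
#'   significant), `correlation` (masked matrix), `correlation_full`.
#' @export
group_stats <- function(features, group, alpha = 0.05, exact_max = 10L) {
  stopifnot(is.data.frame(features))
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("need exactly two groups")
  g1 <- levels(group)[1L]; g2 <- levels(group)[2L]
  if (min(table(group)) < 2L) stop("need >= 2 subjects per group")
  rows <- lapply(names(features), function(fn) {
    x <- features[[fn]][group == g1]
    y <- features[[fn]][group == g2]
    all_tied <- length(unique(c(x, y))) == 1L
    if (all_tied) {
      p <- 1
      flagged <- TRUE
    } else {
      exact <- max(length(x), length(y)) <= exact_max &&
        !any(duplicated(c(x, y)))
      p <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
      flagged <- FALSE
    }
    data.frame(feature = fn,
               mean_1 = mean(x), sd_1 = stats::sd(x),
               mean_2 = mean(y), sd_2 = stats::sd(y),
               p = p, significant = p < alpha, degenerate = flagged)
  })
  tab <- do.call(rbind, rows)
  names(tab)[2:5] <- c(paste0("mean_", g1), paste0("sd_", g1),
                       paste0("mean_", g2), paste0("sd_", g2))
  tab <- tab[order(-tab$p), ]
  rownames(tab) <- NULL
  fm <- as.matrix(features)
  cor_full <- suppressWarnings(stats::cor(fm))
  n <- ncol(fm)
  masked <- cor_full
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ct <- suppressWarnings(stats::cor.test(fm[, i], fm[, j]))
      if (!is.finite(ct$p.value) || ct$p.value >= alpha)
        masked[i, j] <- NA
    }
  }
  list(table = tab, correlation = masked, correlation_full = cor_full)
}

#' Exact two-sided rank-sum p-value by enumeration
#'
#' Reference implementation enumerating all assignments of ranks to the
#' smaller group; usable as an independent check of the rank-sum test for
#' small samples without ties.
#'
#' @param x,y numeric samples (no ties across the pooled sample).
#' @return two-sided p-value.
#' @export
rank_sum_exact <- function(x, y) {
  pooled <- c(x, y)
  if (any(duplicated(pooled))) stop("ties present: enumeration assumes none")
  r <- rank(pooled)
  n1 <- length(x)
  W_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  W_all <- colSums(matrix(rank(pooled)[combs], nrow = n1))
  mu <- n1 * (length(pooled) + 1) / 2
  p <- mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
  min(1, p)
}
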