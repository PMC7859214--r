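#' @name rank-tests
#' @title Nonparametric comparisons for perfusion parameter tables
#' @description Rank-based tests mirroring the analysis scheme used for the
#'   perfusion tables: Wilcoxon signed-rank for paired PWM-vs-RBM contrasts,
#'   Mann-Whitney U for the aortic-vs-segmental AIF SNR comparison, and
#'   Kruskal-Wallis with Dunn-Bonferroni post hoc across AIF kinds. All
#'   tests are two-sided. Exact p-values are computed by full enumeration
#'   whenever the sample is small (n <= 12 pairs, combined n <= 12, total
#'   N <= 12 respectively) — enumeration handles ties exactly — and
#'   tie-corrected normal / chi-square approximations are used otherwise.
NULL

new_comparison_report <- function(test, statistic, p_value, groups, n,
                                  pairwise = NULL, exact = NA,
                                  degenerate = FALSE) {
  structure(list(test = test, statistic = statistic,
                 p_value = min(max(p_value, 0), 1),
                 pairwise = pairwise, groups = groups, n = n,
                 exact = exact, degenerate = degenerate),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(x$test, ": statistic = ", signif(x$statistic, 5), ", p = ",
      signif(x$p_value, 4),
      if (isTRUE(x$exact)) " (exact)" else " (approximate)",
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  if (!is.null(x$pairwise)) print(x$pairwise, digits = 4)
  invisible(x)
}

#' Paired comparison (Wilcoxon signed-rank test)
#'
#' Two-sided Wilcoxon signed-rank test of paired samples. Zero differences
#' are dropped (the standard reduced-sample convention). For n <= 12
#' non-zero pairs the exact p-value is obtained by enumerating all `2^n`
#' sign assignments of the ranked absolute differences (valid under ties);
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b Paired numeric samples of equal length (>= 5 pairs).
#' @param exact_max Largest n for which enumeration is used (default 12).
#' @return A `comparison_report` with the V statistic (sum of positive
#'   ranks). If all differences are zero the report is flagged degenerate
#'   with p = 1.
#' @export
compare_paired <- function(a, b, exact_max = 12) {
  stopifnot(length(a) == length(b))
  if (length(a) < 5) stop("paired comparison needs at least 5 pairs")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(new_comparison_report("Wilcoxon signed rank", NA_real_, 1,
                                 c("a", "b"), length(a), degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # all 2^n sign assignments; V distribution by enumeration (tie-safe)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  new_comparison_report("Wilcoxon signed rank", v, p, c("a", "b"),
                        length(a), exact = exact)
}

#' Unpaired comparison (Mann-Whitney U test)
#'
#' Two-sided Mann-Whitney U test of two independent samples. For combined
#' n <= 12 the exact p-value is computed by enumerating all
#' `choose(n1+n2, n1)` group labelings of the pooled ranks (tie-safe);
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param a,b Independent numeric samples (>= 3 each).
#' @param exact_max Largest combined n for which enumeration is used.
#' @return A `comparison_report` with the U statistic for sample `a`.
#' @export
compare_unpaired <- function(a, b, exact_max = 12) {
  if (length(a) < 3 || length(b) < 3)
    stop("unpaired comparison needs at least 3 observations per group")
  n1 <- length(a); n2 <- length(b); nn <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (nn <= exact_max) {
    combs <- utils::combn(nn, n1)
    us <- apply(combs, 2L, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 *
      (nn + 1 - sum(ties^3 - ties) / (nn * (nn - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  new_comparison_report("Mann-Whitney U", u, p, c("a", "b"), c(n1, n2),
                        exact = exact)
}

kw_statistic <- function(r, g) {
  nn <- length(r)
  means <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  h <- 12 / (nn * (nn + 1)) * sum(ns * (means - (nn + 1) / 2)^2)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (nn^3 - nn)
  if (corr > 0) h <- h / corr
  h
}

# enumerate all assignments of positions to groups of fixed sizes
enumerate_assignments <- function(pos, sizes) {
  if (length(sizes) == 1L) return(list(list(pos)))
  out <- list()
  firsts <- utils::combn(pos, sizes[1], simplify = FALSE)
  for (f in firsts) {
    rest <- enumerate_assignments(setdiff(pos, f), sizes[-1])
    out <- c(out, lapply(rest, function(r) c(list(f), r)))
  }
  out
}

#' Multi-group comparison (Kruskal-Wallis with Dunn-Bonferroni post hoc)
#'
#' Omnibus Kruskal-Wallis test across three or more groups, followed by
#' pairwise Dunn z-tests with Bonferroni multiplication by the number of
#' pairs (capped at 1). With two groups, delegates to [compare_unpaired()].
#' For total N <= 12 the omnibus p is exact: `P(H >= H_obs)` over the full
#' permutation distribution of group assignments (tie-safe); otherwise the
#' tie-corrected chi-square approximation is used.
#'
#' @param groups List of numeric samples, each with n >= 2.
#' @param exact_max Largest total N for which enumeration is used.
#' @return A `comparison_report` with the H statistic and a `pairwise` data
#'   frame (`group1`, `group2`, `z`, `p_unadjusted`, `p_adjusted`).
#' @export
compare_groups <- function(groups, exact_max = 12) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(lengths(groups) < 2))
    stop("every group needs at least 2 observations")
  if (length(groups) == 2)
    return(compare_unpaired(groups[[1]], groups[[2]]))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  nn <- length(x)
  r <- rank(x)
  h <- kw_statistic(r, g)
  if (nn <= exact_max) {
    sizes <- lengths(groups)
    assigns <- enumerate_assignments(seq_len(nn), sizes)
    hs <- vapply(assigns, function(a) {
      gg <- integer(nn)
      for (i in seq_along(a)) gg[a[[i]]] <- i
      kw_statistic(r, factor(gg))
    }, numeric(1))
    p <- mean(hs >= h - 1e-9)
    exact <- TRUE
  } else {
    p <- stats::pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
    exact <- FALSE
  }
  # Dunn pairwise z-tests on mean ranks, Bonferroni-adjusted
  means <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (nn - 1))
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    se <- sqrt((nn * (nn + 1) / 12 - tie_term) *
                 (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    z <- (means[pr[1]] - means[pr[2]]) / se
    pu <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = pr[1], group2 = pr[2], z = as.numeric(z),
               p_unadjusted = pu,
               p_adjusted = min(1, length(pairs) * pu),
               row.names = NULL)
  }))
  new_comparison_report("Kruskal-Wallis", h, p, names(groups),
                        as.integer(lengths(groups)), pairwise = pw,
                        exact = exact)
}
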