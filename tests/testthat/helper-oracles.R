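# Independent brute-force oracles for the rank tests. These deliberately
# avoid the package's code paths: the signed-rank oracle enumerates sign
# vectors via bit masks, the Mann-Whitney oracle counts (a_i, b_j) pair
# orderings directly on the data, and the Kruskal-Wallis oracle reuses
# kruskal.test's statistic over explicitly enumerated group labelings.

oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.integer(intToBits(mask))[seq_len(n)]
    sum(r[signs == 1])
  }, numeric(1))
  min(1, 2 * min(mean(vs <= v_obs + 1e-9), mean(vs >= v_obs - 1e-9)))
}

# U counted directly from data pairs (not from ranks)
oracle_u_stat <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

oracle_mann_whitney_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_obs <- oracle_u_stat(a, b)
  labelings <- utils::combn(length(pooled), n1)
  us <- apply(labelings, 2, function(ix)
    oracle_u_stat(pooled[ix], pooled[-ix]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

oracle_kruskal_p <- function(groups) {
  x <- unlist(groups)
  sizes <- lengths(groups)
  h_of <- function(assign_list) {
    g <- factor(rep(seq_along(assign_list), lengths(assign_list)))
    xx <- unlist(lapply(assign_list, function(ix) x[ix]))
    unname(stats::kruskal.test(xx, g)$statistic)
  }
  h_obs <- unname(stats::kruskal.test(
    x, factor(rep(seq_along(groups), sizes)))$statistic)
  pos <- seq_along(x)
  # enumerate all splits of positions into groups of the given sizes
  splits <- list(list(pos = pos, chosen = list()))
  for (s in sizes[-length(sizes)]) {
    splits <- do.call(c, lapply(splits, function(st) {
      lapply(utils::combn(st$pos, s, simplify = FALSE), function(cc)
        list(pos = setdiff(st$pos, cc), chosen = c(st$chosen, list(cc))))
    }))
  }
  hs <- vapply(splits, function(st)
    h_of(c(st$chosen, list(st$pos))), numeric(1))
  mean(hs >= h_obs - 1e-9)
}
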