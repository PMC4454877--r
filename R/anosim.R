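# Analysis of similarities (ANOSIM): rank-based permutation test of
# between-group vs within-group dissimilarity.

#' ANOSIM permutation test
#'
#' All `N(N-1)/2` pairwise distances are ranked (midranks on ties) and
#' `R = (mean between-group rank - mean within-group rank) / (N(N-1)/4)`,
#' so `R` lies in `[-1, 1]`. The p-value uses the
#' `(1 + #\{permuted R >= observed R\}) / (1 + n_perm)` convention with
#' labels permuted uniformly at random (seeded), so `p > 0` always. With
#' `exact = TRUE` all distinct label arrangements are enumerated and
#' `p = #\{R >= observed\} / n_arrangements` (the observed arrangement
#' included).
#'
#' @param d symmetric distance matrix.
#' @param labels group assignment, one per sample (>= 2 groups, each with
#'   >= 1 member, and not all samples in one group).
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param exact exhaustively enumerate all distinct label arrangements
#'   (small designs only).
#' @return object of class `anosim_result`: list with `R`, `p`, `n_perm`,
#'   `groups`, and `exact`.
#' @export
anosim_test <- function(d, labels, n_perm = 999L, seed = 1L, exact = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) stop("`labels` must have one entry per sample")
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 groups")
  lower <- which(lower.tri(d), arr.ind = TRUE)
  pi_ <- lower[, 1L]
  pj <- lower[, 2L]
  r <- rank(d[lower])
  denom <- n * (n - 1) / 4
  r_stat <- function(gl) {
    w <- gl[pi_] == gl[pj]
    (mean(r[!w]) - mean(r[w])) / denom
  }
  if (!all(c(any(labels[pi_] == labels[pj]), any(labels[pi_] != labels[pj])))) {
    stop("grouping yields no within-group or no between-group pairs")
  }
  obs <- r_stat(labels)
  if (exact) {
    perms <- multiset_permutations(labels, limit = 1e5)
    stats <- vapply(perms, r_stat, numeric(1))
    p <- mean(stats >= obs - 1e-12)
    n_perm <- length(perms)
  } else {
    stats <- with_seed(substream_seed(seed, "anosim"),
                       vapply(seq_len(n_perm),
                              function(i) r_stat(sample(labels)), numeric(1)))
    p <- (1 + sum(stats >= obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(R = obs, p = p, n_perm = n_perm,
                 groups = names(tab), exact = exact),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s%d permutations; groups: %s)\n",
              x$R, x$p, if (x$exact) "exhaustive, " else "", x$n_perm,
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Pairwise ANOSIM over every group pair
#'
#' @inheritParams anosim_test
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `R`, `p`, `n_samples`.
#' @export
pairwise_anosim <- function(d, labels, n_perm = 999L, seed = 1L) {
  d <- as.matrix(d)
  labels <- as.character(labels)
  gs <- sort(unique(labels))
  combos <- utils::combn(gs, 2L)
  out <- lapply(seq_len(ncol(combos)), function(k) {
    g <- combos[, k]
    idx <- labels %in% g
    res <- anosim_test(d[idx, idx, drop = FALSE], labels[idx],
                       n_perm = n_perm,
                       seed = substream_seed(seed, paste(g, collapse = "~")))
    data.frame(group1 = g[1L], group2 = g[2L], R = res$R, p = res$p,
               n_samples = sum(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# All distinct arrangements of a label multiset (exhaustive enumeration for
# small designs; errors beyond `limit` arrangements).
multiset_permutations <- function(labels, limit = 1e5) {
  tab <- table(labels)
  total <- factorial(length(labels)) / prod(factorial(tab))
  if (total > limit) {
    stop("exhaustive enumeration would need ", format(total), " arrangements")
  }
  rec <- function(counts) {
    if (sum(counts) == 0L) return(list(character(0)))
    out <- list()
    for (g in names(counts)[counts > 0L]) {
      rest <- counts
      rest[g] <- rest[g] - 1L
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(g, tail)
    }
    out
  }
  rec(stats::setNames(as.integer(tab), names(tab)))
}
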