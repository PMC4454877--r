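# Chao1 nonparametric richness estimation.

#' Chao1 richness estimate for one sample
#'
#' With `F1` singletons, `F2` doubletons and `S_obs` observed OTUs:
#' `S_chao1 = S_obs + F1^2 / (2 F2)` when `F2 > 0`, otherwise the
#' bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`. The classical
#' variance formulas give the standard error.
#'
#' @param counts nonnegative integer vector of per-OTU counts for one sample
#'   (at least one nonzero entry).
#' @return list with `estimate`, `se`, `s_obs`, `f1`, `f2`.
#' @export
chao1 <- function(counts) {
  if (anyNA(counts) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("`counts` must be nonnegative integers")
  }
  if (!any(counts > 0)) stop("all counts are zero")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) {
    est <- s_obs + f1^2 / (2 * f2)
    rr <- f1 / f2
    v <- f2 * (rr^2 / 2 + rr^3 + rr^4 / 4)
  } else if (f1 > 0) {
    est <- s_obs + f1 * (f1 - 1) / 2
    v <- f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
  } else {
    est <- s_obs
    v <- 0
  }
  list(estimate = est, se = sqrt(max(v, 0)), s_obs = s_obs, f1 = f1, f2 = f2)
}

#' Chao1 richness per sample of an OTU table
#'
#' @param x an [otu_table].
#' @return data.frame with one row per sample: `sample_id`, `chao1`, `se`,
#'   `s_obs`, `f1`, `f2`.
#' @export
chao1_table <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  rows <- lapply(sample_ids(x), function(s) {
    est <- chao1(x$counts[, s])
    data.frame(sample_id = s, chao1 = est$estimate, se = est$se,
               s_obs = est$s_obs, f1 = est$f1, f2 = est$f2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
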