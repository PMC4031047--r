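# Binomial log-likelihood kernel on allele counts, without the binomial
# coefficient (constant across models, cancels in every comparison).
# Handles the boundary convention 0*log(0) = 0 so MLEs at p = 0 or 1 are finite.
binom_loglik <- function(k, n, p) {
  t1 <- ifelse(k > 0, k * log(p), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log1p(-p), 0)
  t1 + t2
}

# Draw per-replicate seeds from a master seed without disturbing the caller's
# RNG more than once; keeps parallel/partial reruns reproducible.
spawn_seeds <- function(master_seed, n) {
  if (!is.null(master_seed)) set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
    abort(paste0("`", name, "` must be a single non-negative integer"))
  }
}

# format "x (y%)" and "median (q1-q3)" strings for cohort summary tables
.fmt_count_pct <- function(k, n) {
  sprintf("%s (%.1f%%)", format(k, big.mark = ","), 100 * k / n)
}
.fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
}
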