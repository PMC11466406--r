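#' Rank highly variable genes by standardized variance (vst)
#'
#' Implements the variance-stabilizing-transform ranking used by standard
#' single-cell toolkits: fit a loess trend (span 0.3, degree 2) of
#' `log10(variance)` on `log10(mean)` over genes with positive variance,
#' standardize each gene's counts by the trend-predicted standard deviation,
#' clip the standardized values at `sqrt(n_cells)`, and rank genes by the
#' variance of the clipped values.
#'
#' @param counts a [count_matrix] (raw or smoothed counts).
#' @param n_top number of genes to return.
#' @return Character vector of up to `n_top` gene symbols, most variable
#'   first. If fewer genes have positive variance, all are returned with a
#'   warning. The full ranking statistics are attached as attribute `stats`
#'   (data.frame: gene, mean, variance, variance_std).
#' @export
select_variable_genes <- function(counts, n_top) {
  stopifnot(is_count_matrix(counts), n_top >= 1)
  x <- unclass(counts)
  n <- nrow(x)
  mu <- colMeans(x)
  v <- colVars_fast(x, mu)
  ok <- v > 0 & mu > 0
  vst_var <- numeric(ncol(x))
  if (sum(ok) >= 2L) {
    fit_df <- data.frame(lm = log10(mu[ok]), lv = log10(v[ok]))
    exp_sd <- rep(NA_real_, ncol(x))
    fitted_lv <- tryCatch({
      fit <- suppressWarnings(stats::loess(lv ~ lm, data = fit_df,
                                           span = 0.3, degree = 2))
      stats::predict(fit, fit_df$lm)
    }, error = function(e) NULL)
    if (is.null(fitted_lv) || anyNA(fitted_lv)) {
      # degenerate loess (too few distinct means): straight-line fallback
      fit <- stats::lm(lv ~ lm, data = fit_df)
      fitted_lv <- stats::predict(fit, fit_df)
    }
    exp_sd[ok] <- sqrt(10^fitted_lv)
    clipmax <- sqrt(n)
    z <- sweep(x[, ok, drop = FALSE], 2, mu[ok], "-")
    z <- sweep(z, 2, exp_sd[ok], "/")
    z[z > clipmax] <- clipmax
    z[z < -clipmax] <- -clipmax
    vst_var[ok] <- colVars_fast(z)
  } else if (sum(ok) == 1L) {
    vst_var[ok] <- 1
  }
  ord <- order(-vst_var, colnames(x))  # symbol order breaks exact ties
  n_avail <- sum(vst_var > 0)
  if (n_avail < n_top) {
    warning(sprintf("only %d genes with positive standardized variance (%d requested)",
                    n_avail, n_top))
  }
  top <- colnames(x)[ord[seq_len(min(n_top, ncol(x)))]]
  attr(top, "stats") <- data.frame(gene = colnames(x), mean = mu, variance = v,
                                   variance_std = vst_var,
                                   row.names = NULL)
  top
}

# column variances without building a centered copy per gene
colVars_fast <- function(x, mu = colMeans(x)) {
  n <- nrow(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}
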