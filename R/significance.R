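## Background removal: a per-RNA zero-truncated negative binomial model over
## the observed target bins. Only pairs that were seen at least once enter a
## pairs file, so the background is the NB conditioned on counts >= 1; each
## observed (RNA, bin) count is compared with that background, p-values are
## BH-adjusted genome-wide, and pairs with q <= 0.1 are called significant.

#' Zero-truncated negative binomial pmf
#'
#' `P(X = k | X >= 1)` for X ~ NB with mean `mu` and dispersion (size) `r`
#' (variance `mu + mu^2/r`).
#'
#' @param k counts (all >= 1).
#' @param mu NB mean (> 0).
#' @param r NB dispersion/size (> 0).
#' @return probabilities.
#' @export
dztnb <- function(k, mu, r) {
  assert_that(all(k >= 1), "zero-truncated pmf is undefined at k = 0")
  assert_that(all(mu > 0) && all(r > 0), "mu and r must be positive")
  dnbinom(k, size = r, mu = mu) / pnbinom(0, size = r, mu = mu,
                                          lower.tail = FALSE)
}

#' Upper-tail p-value under the zero-truncated negative binomial
#'
#' `p = P(X >= x | X >= 1)`; by construction `p = 1` exactly at `x = 1`.
#'
#' @param x observed counts (all >= 1).
#' @param mu,r background NB parameters.
#' @return p-values in (0, 1].
#' @export
pztnb_upper <- function(x, mu, r) {
  assert_that(all(x >= 1), "observed counts must be >= 1")
  p <- pnbinom(x - 1, size = r, mu = mu, lower.tail = FALSE) /
    pnbinom(0, size = r, mu = mu, lower.tail = FALSE)
  pmin(p, 1)
}

#' Draw from a zero-truncated negative binomial
#'
#' @param n number of draws.
#' @param mu,r NB parameters.
#' @return integer counts >= 1.
#' @export
rztnb <- function(n, mu, r) {
  p0 <- dnbinom(0, size = r, mu = mu)
  u <- runif(n, min = p0, max = 1)
  as.integer(qnbinom(u, size = r, mu = mu))
}

#' Zero-truncated NB log-likelihood (optionally right-conditioned)
#'
#' Log-likelihood of counts under NB(mu, r) conditioned on `1 <= X <= upper`.
#' With `upper = Inf` this is the plain zero-truncated likelihood.
#'
#' @param counts counts >= 1.
#' @param mu,r NB parameters.
#' @param upper right conditioning bound (default `Inf`).
#' @return scalar log-likelihood.
#' @export
ztnb_loglik <- function(counts, mu, r, upper = Inf) {
  denom <- if (is.finite(upper))
    pnbinom(upper, size = r, mu = mu) - dnbinom(0, size = r, mu = mu)
  else pnbinom(0, size = r, mu = mu, lower.tail = FALSE)
  if (denom <= 0) return(-Inf)
  sum(dnbinom(counts, size = r, mu = mu, log = TRUE)) -
    length(counts) * log(denom)
}

#' Fit a zero-truncated negative binomial background by maximum likelihood
#'
#' Fits (mu, r) to the nonzero counts of one RNA across its observed bins.
#' With `trim > 0` the upper `trim` fraction of counts is excluded and the
#' likelihood conditioned on `X <=` the trim threshold, so that genuine
#' signal bins do not inflate the background; the reported parameters still
#' describe the full (untrimmed) background law. Fits on fewer than
#' `min_bins` counts, on degenerate (all-equal) counts, or that fail to
#' converge are flagged for pooled fallback.
#'
#' @param counts nonzero counts for one RNA.
#' @param min_bins minimum number of observed bins for a direct fit.
#' @param trim upper-tail fraction excluded from the fit (default 0: plain
#'   zero-truncated ML).
#' @param upper optional fixed conditioning bound: the fit uses only counts
#'   `<= upper` with the likelihood conditioned on `1 <= X <= upper`
#'   (overrides `trim`).
#' @param r_bounds allowed dispersion range during optimisation.
#' @return list with `mu`, `r`, `loglik` (maximised conditional
#'   log-likelihood), `n_bins_used`, `fit_method` (`"ml"` or
#'   `"needs_fallback"`), `converged`.
#' @export
fit_ztnb <- function(counts, min_bins = 10L, trim = 0, upper = NULL,
                     r_bounds = c(1e-3, 1e6)) {
  assert_that(all(counts >= 1), "background fit requires nonzero counts")
  fail <- function(reason) list(mu = NA_real_, r = NA_real_,
                                loglik = NA_real_,
                                n_bins_used = length(counts),
                                fit_method = "needs_fallback",
                                converged = FALSE, reason = reason)
  if (length(counts) < min_bins) return(fail("too_few_bins"))
  if (!is.null(upper)) {
    kept <- counts[counts <= upper]
    if (!length(kept) || upper >= max(counts)) { upper <- Inf; kept <- counts }
  } else {
    upper <- Inf
    kept <- counts
    if (trim > 0) {
      upper <- as.numeric(quantile(counts, 1 - trim, type = 1))
      kept <- counts[counts <= upper]
      if (upper >= max(counts)) upper <- Inf  # nothing actually trimmed
    }
  }
  if (length(unique(kept)) == 1L) return(fail("degenerate_counts"))

  m <- mean(kept); v <- var(kept)
  r0 <- if (v > m) min(max(m^2 / (v - m), 0.05), 100) else 50
  obj <- function(th) {
    mu <- exp(th[1])
    r <- min(max(exp(th[2]), r_bounds[1]), r_bounds[2])
    -ztnb_loglik(kept, mu, r, upper = upper)
  }
  fit <- tryCatch(
    suppressWarnings(optim(c(log(m), log(r0)), obj, method = "Nelder-Mead",
                           control = list(maxit = 500))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(fail("no_convergence"))
  mu <- exp(fit$par[1])
  r <- min(max(exp(fit$par[2]), r_bounds[1]), r_bounds[2])
  list(mu = mu, r = r,
       loglik = ztnb_loglik(kept, mu, r, upper = upper),
       n_bins_used = length(counts),
       fit_method = "ml",
       converged = fit$convergence == 0, reason = NA_character_)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param p p-values in (0, 1].
#' @return q-values.
#' @export
bh_adjust <- function(p) {
  assert_that(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-RNA background mean at a fixed shared dispersion
#'
#' One-dimensional trimmed-conditional ML for the background mean of one RNA
#' when the dispersion is shared across RNAs. Unlike the joint (mu, r) fit,
#' this is well-posed even on small supports dominated by single counts.
#'
#' @param counts nonzero counts for one RNA.
#' @param r fixed NB dispersion.
#' @param upper conditioning bound: only counts `<= upper` enter the fit,
#'   with the likelihood conditioned on `1 <= X <= upper` (`Inf` = plain
#'   zero-truncated ML).
#' @return the fitted mean.
#' @export
fit_ztnb_mu <- function(counts, r, upper = Inf) {
  kept <- counts[counts <= upper]
  if (!length(kept) || upper >= max(counts)) { upper <- Inf; kept <- counts }
  opt <- optimize(function(lmu) -ztnb_loglik(kept, exp(lmu), r, upper = upper),
                  interval = log(c(1e-4, max(mean(counts) * 10, 1))))
  exp(opt$minimum)
}

#' Call significant RNA-DNA interactions against per-RNA backgrounds
#'
#' Builds a zero-truncated NB background for every RNA over its observed
#' bins, assigns each observed (gene, bin) count an upper-tail p-value,
#' applies a single genome-wide BH correction across all tested pairs, and
#' flags pairs with `q <= q_max`.
#'
#' The background mean is per-RNA; the dispersion is shared across RNAs (on
#' small per-RNA supports dominated by single counts the dispersion is not
#' identifiable, and a jointly fitted heavy-tailed background would mask
#' true signal). Both are estimated from the low-count bulk: only counts
#' `<= bulk_max` enter the fits, with the likelihood conditioned on
#' `1 <= X <= bulk_max`, so that genuine high-count interactions carry no
#' weight in the background. By default `bulk_max` is the larger of 3 and
#' the median observed count. RNAs with fewer than `min_bins` observed bins
#' fall back to a pooled background: genes are stratified into quartiles of
#' per-gene total count and one background is fitted per stratum.
#'
#' An optional `strata` vector (e.g. cis-distance deciles plus a trans
#' stratum from [distance_strata()]) splits each RNA's background into
#' per-stratum fits for sensitivity analysis.
#'
#' @param counts data.table with `gene_id`, `bin_id`, `count` (>= 1), e.g.
#'   from [build_pairs()].
#' @param q_max significance cutoff on the adjusted p-value (default 0.1).
#' @param min_bins minimum observed bins for a direct per-RNA fit.
#' @param bulk_max conditioning bound for background fits (`NULL` = larger
#'   of 3 and the median count; `Inf` = plain zero-truncated ML).
#' @param strata optional per-row stratum labels.
#' @return data.table with `gene_id`, `bin_id`, `count`, `mu`, `r`,
#'   `fit_method`, `p`, `q`, `significant`; attribute `fits` holds the
#'   per-background parameter table.
#' @export
call_significant <- function(counts, q_max = 0.1, min_bins = 10L,
                             bulk_max = NULL, strata = NULL) {
  counts <- as.data.table(counts)
  assert_that(all(counts$count >= 1), "pair counts must be >= 1")
  x <- copy(counts)
  x[, unit_ := if (is.null(strata)) gene_id else paste(gene_id, strata)]
  if (is.null(bulk_max))
    bulk_max <- max(3, as.numeric(quantile(x$count, 0.5, type = 1)))

  # shared dispersion from the pooled bulk-conditioned fit (large-n, stable)
  glob <- fit_ztnb(x$count, min_bins = 2L, upper = bulk_max)
  if (glob$fit_method != "ml")
    glob <- list(mu = max(mean(x$count) - 1, 0.01), r = 1e6)

  fits <- x[, {
    n <- .N
    if (n >= min_bins) {
      list(mu = fit_ztnb_mu(count, glob$r, upper = bulk_max), r = glob$r,
           n_bins_used = n, fit_method = "ml", total = sum(count))
    } else {
      list(mu = NA_real_, r = NA_real_, n_bins_used = n,
           fit_method = "needs_fallback", total = sum(count))
    }
  }, by = unit_]

  need <- fits[fit_method == "needs_fallback", unit_]
  if (length(need)) {
    # depth strata: quartiles of per-unit total count over all units
    qs <- unique(quantile(fits$total, c(0.25, 0.5, 0.75), type = 1))
    fits[, depth_stratum := findInterval(total, qs)]
    for (ds in unique(fits[unit_ %in% need, depth_stratum])) {
      units_ds <- fits[depth_stratum == ds, unit_]
      pooled_mu <- fit_ztnb_mu(x[unit_ %in% units_ds, count],
                               glob$r, upper = bulk_max)
      sel <- fits$unit_ %in% intersect(units_ds, need)
      fits[sel, `:=`(mu = pooled_mu, r = glob$r,
                     fit_method = "pooled_fallback")]
    }
    fits[, depth_stratum := NULL]
  }

  x <- merge(x, fits[, .(unit_, mu, r, fit_method)], by = "unit_",
             sort = FALSE)
  x[, p := pztnb_upper(count, mu, r)]
  x[, q := bh_adjust(p)]
  x[, significant := q <= q_max]
  x[, unit_ := NULL]
  setorder(x, gene_id, bin_id)
  setattr(x, "fits", fits[])
  x[]
}

#' Distance strata labels for sensitivity analysis
#'
#' Builds per-record stratum labels from annotated records: deciles of cis
#' distance plus one trans stratum.
#'
#' @param records interaction records with `distance` (NA for trans).
#' @param n_strata number of cis distance strata (default 10).
#' @return character vector of stratum labels aligned with `records`.
#' @export
distance_strata <- function(records, n_strata = 10L) {
  d <- records$distance
  lab <- rep("trans", length(d))
  cis <- !is.na(d)
  if (any(cis)) {
    br <- unique(quantile(d[cis], probs = seq(0, 1, length.out = n_strata + 1)))
    lab[cis] <- paste0("cis_q", findInterval(d[cis], br,
                                             rightmost.closed = TRUE))
  }
  lab
}
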