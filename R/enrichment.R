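## IP-vs-Input differential interaction analysis: per-RNA interaction counts
## across replicates, TMM scaling factors, a common NB dispersion, an exact
## NB test on equalised pseudo-counts, and the "Special" (unique + enriched)
## RNA set construction. The TMM + common-dispersion exact-test core is
## implemented here so the pipeline is self-contained; thresholds follow the
## adjusted-P <= 0.1, |log2FC| >= 0.5 convention.

#' Per-RNA interaction counts across replicates
#'
#' Counts interaction pairs per RNA (gene) in each replicate's record or
#' pair table.
#'
#' @param tables named list of interaction-record tables (or (gene,bin,count)
#'   tables with a `count` column), one per replicate.
#' @return integer matrix, genes x replicates.
#' @export
rna_count_matrix <- function(tables) {
  per <- lapply(tables, function(tb) {
    tb <- as.data.table(tb)
    if ("count" %in% names(tb)) tb[!is.na(gene_id), .(n = sum(count)), by = gene_id]
    else tb[!is.na(gene_id), .(n = .N), by = gene_id]
  })
  genes <- sort(unique(unlist(lapply(per, `[[`, "gene_id"))))
  m <- matrix(0L, nrow = length(genes), ncol = length(per),
              dimnames = list(genes, names(per)))
  for (j in seq_along(per))
    m[per[[j]]$gene_id, j] <- as.integer(per[[j]]$n)
  m
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values normalisation: for each library against a
#' reference library, M- and A-values over genes nonzero in both are doubly
#' trimmed (30% on M, 5% on A by default) and a precision-weighted mean
#' M-value gives the log2 scaling factor. Factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts genes x samples count matrix.
#' @param ref reference column index or name; `NULL` picks the library whose
#'   upper-quartile fraction is closest to the mean.
#' @param trim_M,trim_A two-sided trim fractions for M- and A-values.
#' @return numeric vector of per-sample scaling factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, ref = NULL, trim_M = 0.30, trim_A = 0.05) {
  counts <- as.matrix(counts)
  assert_that(ncol(counts) >= 2, "TMM needs at least two libraries")
  N <- colSums(counts)
  assert_that(all(N > 0), "TMM needs nonzero library sizes")
  if (is.null(ref)) {
    uq <- apply(counts, 2, function(y) quantile(y[y > 0], 0.75)) / N
    ref <- which.min(abs(uq - mean(uq)))
  }
  yr <- counts[, ref]; Nr <- N[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]; Nj <- N[j]
    keep <- y > 0 & yr > 0
    if (!any(keep)) {
      warning("library ", j, " shares no nonzero genes with the reference")
      return(1)
    }
    y <- y[keep]; r <- yr[keep]
    M <- log2((y / Nj) / (r / Nr))
    A <- 0.5 * log2((y / Nj) * (r / Nr))
    w <- 1 / ((Nj - y) / (Nj * y) + (Nr - r) / (Nr * r))
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (!length(M)) return(1)
    loM <- quantile(M, trim_M); hiM <- quantile(M, 1 - trim_M)
    loA <- quantile(A, trim_A); hiA <- quantile(A, 1 - trim_A)
    keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(keep2)) return(1)
    2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Common NB dispersion across genes
#'
#' Maximises the NB profile likelihood for one dispersion shared by all
#' genes, with per-gene per-condition means re-estimated at each candidate
#' dispersion under offsets `log(library size x TMM factor)` (offset-based
#' likelihood; recorded in the result).
#'
#' @param counts genes x samples count matrix.
#' @param condition factor/character of sample conditions.
#' @param factors TMM factors (default from [tmm_factors()]).
#' @param phi_fallback dispersion returned when no condition has
#'   replication.
#' @return list with `phi`, `method` (`"profile_ml"` or `"fallback"`).
#' @export
estimate_common_dispersion <- function(counts, condition, factors = NULL,
                                       phi_fallback = 0.1) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  if (max(table(condition)) < 2L) {
    warning("no replication in any condition: using fallback dispersion")
    return(list(phi = phi_fallback, method = "fallback"))
  }
  if (is.null(factors)) factors <- tmm_factors(counts)
  s <- colSums(counts) * factors
  groups <- split(seq_along(condition), condition)
  nll <- function(log_phi) {
    phi <- exp(log_phi); r <- 1 / phi
    ll <- 0
    for (g in seq_len(nrow(counts))) {
      for (idx in groups) {
        y <- counts[g, idx]; sj <- s[idx]
        if (all(y == 0)) next
        lam <- sum(y) / sum(sj)
        for (it in 1:5) lam <- sum(y / (r + sj * lam)) / sum(sj / (r + sj * lam))
        ll <- ll + sum(dnbinom(y, size = r, mu = sj * lam, log = TRUE))
      }
    }
    -ll
  }
  opt <- optimize(nll, interval = log(c(1e-4, 5)))
  list(phi = exp(opt$minimum), method = "profile_ml")
}

#' NB exact test for one gene
#'
#' Exact two-sided test for a condition difference under an NB model with a
#' common dispersion, applied to library-size-equalised pseudo-counts
#' (counts rescaled to the geometric-mean effective library size and
#' rounded). Conditional on the total, the group-A sum follows a ratio of NB
#' convolutions; the p-value sums all outcomes no more probable than the
#' observation.
#'
#' @param y counts for one gene across samples.
#' @param condition sample conditions (two levels).
#' @param s effective library sizes (library size x TMM factor).
#' @param phi common dispersion.
#' @param pair the two condition levels, `c(baseline, treatment)`; the
#'   returned log2FC is treatment over baseline.
#' @param prior prior count added to normalised means for the fold change.
#' @return list with `p` and `log2FC`.
#' @export
nb_exact_test <- function(y, condition, s, phi, pair, prior = 0.5) {
  condition <- as.character(condition)
  iA <- which(condition == pair[2])  # treatment
  iB <- which(condition == pair[1])  # baseline
  assert_that(length(iA) > 0 && length(iB) > 0, "both conditions need samples")
  s_geo <- exp(mean(log(s)))
  ps <- y * s_geo / s  # pseudo-counts at equal library size
  mA <- mean(ps[iA]); mB <- mean(ps[iB])
  lfc <- log2((mA + prior) / (mB + prior))
  a_obs <- round(sum(ps[iA])); S <- a_obs + round(sum(ps[iB]))
  if (S == 0) return(list(p = 1, log2FC = 0))
  nA <- length(iA); nB <- length(iB)
  r <- 1 / max(phi, 1e-8)
  m <- S / (nA + nB)
  k <- 0:S
  lp <- dnbinom(k, size = nA * r, mu = nA * m, log = TRUE) +
    dnbinom(S - k, size = nB * r, mu = nB * m, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  p <- sum(pr[pr <= pr[a_obs + 1] * (1 + 1e-8)])
  list(p = min(p, 1), log2FC = lfc)
}

#' Differential interaction analysis between IP and Input libraries
#'
#' TMM-normalises per-RNA interaction counts, estimates a common NB
#' dispersion, runs the per-gene exact test, BH-adjusts the p-values and
#' classifies each RNA as `IP_enriched`, `Input_enriched` or `ns` using the
#' `adjP <= adjp_max` and `|log2FC| >= lfc_min` cutoffs.
#'
#' @param counts genes x samples count matrix ([rna_count_matrix()]).
#' @param condition sample conditions; must contain the two `pair` levels.
#' @param pair `c(baseline, treatment)` condition names
#'   (default `c("input", "ip")`).
#' @param adjp_max adjusted-p cutoff (default 0.1).
#' @param lfc_min absolute log2 fold-change cutoff (default 0.5).
#' @param phi optional fixed common dispersion (estimated when `NULL`).
#' @param factors optional TMM factors (computed when `NULL`).
#' @return data.table with `gene_id`, `log2FC` (treatment vs baseline), `p`,
#'   `adjP`, `call`; attributes `factors`, `phi`, `dispersion_method`.
#' @export
differential_interactions <- function(counts, condition,
                                      pair = c("input", "ip"),
                                      adjp_max = 0.1, lfc_min = 0.5,
                                      phi = NULL, factors = NULL) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  assert_that(all(pair %in% condition), "pair levels missing from condition")
  if (is.null(factors)) factors <- tmm_factors(counts)
  disp_method <- "supplied"
  if (is.null(phi)) {
    d <- estimate_common_dispersion(counts, condition, factors)
    phi <- d$phi; disp_method <- d$method
  }
  s <- colSums(counts) * factors
  res <- lapply(seq_len(nrow(counts)), function(g)
    nb_exact_test(counts[g, ], condition, s, phi, pair))
  out <- data.table(gene_id = rownames(counts),
                    log2FC = vapply(res, `[[`, numeric(1), "log2FC"),
                    p = vapply(res, `[[`, numeric(1), "p"))
  out[, adjP := bh_adjust(p)]
  out[, call := fifelse(adjP <= adjp_max & log2FC >= lfc_min, "IP_enriched",
                 fifelse(adjP <= adjp_max & log2FC <= -lfc_min,
                         "Input_enriched", "ns"))]
  setattr(out, "factors", factors)
  setattr(out, "phi", phi)
  setattr(out, "dispersion_method", disp_method)
  out[]
}

#' Build "Special" (unique + enriched) RNA sets per condition
#'
#' An RNA is *unique* to a condition when captured only there, *enriched*
#' when the differential test calls it in that direction, and *Special* when
#' either holds.
#'
#' @param input_species,ip_species character vectors of RNA (gene) ids
#'   captured in each condition.
#' @param diff a [differential_interactions()] result (tested on the common
#'   RNAs).
#' @return list with elements `input` and `ip`, each a list of `unique`,
#'   `enriched` and `special` id vectors, plus `common` (ids captured in
#'   both conditions).
#' @export
build_special_sets <- function(input_species, ip_species, diff) {
  input_species <- unique(input_species); ip_species <- unique(ip_species)
  common <- intersect(input_species, ip_species)
  uniq_in <- setdiff(input_species, ip_species)
  uniq_ip <- setdiff(ip_species, input_species)
  enr_in <- diff[call == "Input_enriched", gene_id]
  enr_ip <- diff[call == "IP_enriched", gene_id]
  list(input = list(unique = uniq_in, enriched = enr_in,
                    special = union(uniq_in, enr_in)),
       ip = list(unique = uniq_ip, enriched = enr_ip,
                 special = union(uniq_ip, enr_ip)),
       common = common)
}
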