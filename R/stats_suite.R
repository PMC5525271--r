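# Comparative statistics: K-S determinant analysis, fold-change t-tests,
# Fisher enrichment, and k-means clustering of light-response profiles.

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |F_a - F_b|` over the pooled support, with the exact
#' permutation distribution of D when `n1 * n2 <= 100` and the asymptotic
#' two-sample approximation otherwise. D is invariant under any strictly
#' monotone transform applied to both samples, so comparisons of
#' abundances and ratios may be run on raw or log scale interchangeably.
#'
#' @param a,b Numeric samples.
#' @return List with `D`, `p_value`, `n1`, `n2`, `exact`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6))  # disjoint supports: D = 1
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  exact <- length(a) * length(b) <= 100
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(res$statistic), p_value = res$p.value,
       n1 = length(a), n2 = length(b), exact = exact)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by summation of hypergeometric point
#' probabilities at most the observed table's, the standard convention of
#' the exact test.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return The two-sided p-value.
#' @export
fisher_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0)) stop("negative entry in contingency table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins must be positive")
  }
  stats::fisher.test(table)$p.value
}

#' sRNA-to-target ratio determinant analysis
#'
#' For candidate sRNA-target pairs (predicted plus degradome-identified),
#' partitions pairs by degradome status — `plus` when a valid cleavage call
#' supports the pair, `minus` otherwise — and runs three two-sample K-S
#' comparisons between the strata: sRNA abundance, target abundance, and
#' the pairwise sRNA-to-target ratio. Ratios are defined only for expressed
#' targets (`target abundance > min_target_abundance`, default RPKM 0.01);
#' other pairs are dropped. Abundance snapshots are whatever the caller
#' passes: for the dark condition the W0 sRNA RPM and W0 mRNA RPKM, for
#' light the W3 sRNA RPM paired with the W4 mRNA RPKM of the companion
#' transcriptome's sampling grid.
#'
#' A `log10` column is exported for plotting; the K-S statistics are
#' computed on the untransformed values (rank-invariant, so equivalent).
#'
#' @param srna_abundance Named numeric vector of sRNA abundances (RPM).
#' @param target_abundance Named numeric vector of target mRNA abundances
#'   (RPKM).
#' @param pairs Data frame of candidate pairs: `srna_id`, `target_id`.
#' @param calls Cleavage-call data frame ([call_targets()]); a pair is
#'   `plus` when a row with `valid == TRUE` links its sRNA and target.
#' @param condition Label stored with the result (`"dark"` or `"light"`).
#' @param min_target_abundance Expression floor for targets (default 0.01).
#' @return List with `records` (per-pair data frame: ids, abundances,
#'   `ratio`, `log10_ratio`, `degradome_status`), `tests` (named list of
#'   [ks_two_sample()] results for `srna`, `target`, `ratio`; a comparison
#'   with an empty stratum is omitted with a warning), and `condition`.
#' @export
ratio_analysis <- function(srna_abundance, target_abundance, pairs, calls,
                           condition = c("dark", "light"),
                           min_target_abundance = 0.01) {
  condition <- match.arg(condition)
  stopifnot(all(c("srna_id", "target_id") %in% names(pairs)))
  valid_calls <- calls[calls$valid, , drop = FALSE]
  plus_key <- paste(valid_calls$srna_id, valid_calls$transcript_id)
  rec <- pairs
  rec$srna_abundance <- srna_abundance[rec$srna_id]
  rec$target_abundance <- target_abundance[rec$target_id]
  rec <- rec[!is.na(rec$srna_abundance) & !is.na(rec$target_abundance), , drop = FALSE]
  rec <- rec[rec$target_abundance > min_target_abundance, , drop = FALSE]
  rec$ratio <- rec$srna_abundance / rec$target_abundance
  rec$log10_ratio <- log10(rec$ratio)
  rec$degradome_status <- ifelse(paste(rec$srna_id, rec$target_id) %in% plus_key,
                                 "plus", "minus")
  rownames(rec) <- NULL
  plus <- rec[rec$degradome_status == "plus", , drop = FALSE]
  minus <- rec[rec$degradome_status == "minus", , drop = FALSE]
  tests <- list()
  if (nrow(plus) == 0L || nrow(minus) == 0L) {
    warning("a degradome stratum is empty; K-S comparisons omitted")
  } else {
    tests$srna <- ks_two_sample(plus$srna_abundance, minus$srna_abundance)
    tests$target <- ks_two_sample(plus$target_abundance, minus$target_abundance)
    tests$ratio <- ks_two_sample(plus$ratio, minus$ratio)
  }
  list(records = rec, tests = tests, condition = condition)
}

#' Compare light/dark fold changes between degradome strata
#'
#' Two-sided two-sample t-test between the `plus` and `minus` degradome
#' groups on log2 light/dark ratios — the comparison behind "targets with
#' cleavage evidence are preferentially down-regulated by light".
#'
#' @param light_over_dark Named numeric vector of per-feature light/dark
#'   ratios (linear scale unless `log_transform = FALSE`).
#' @param grouping Character vector (`"plus"`/`"minus"`), aligned with
#'   `light_over_dark`.
#' @param log_transform Take log2 before testing (default TRUE).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return List with `p_value`, group means (log2 scale) and sizes.
#' @export
fold_change_compare <- function(light_over_dark, grouping,
                                log_transform = TRUE, var_equal = FALSE) {
  stopifnot(length(light_over_dark) == length(grouping))
  x <- if (log_transform) log2(light_over_dark) else light_over_dark
  plus <- x[grouping == "plus"]
  minus <- x[grouping == "minus"]
  if (length(plus) < 2L || length(minus) < 2L) {
    stop("each degradome group needs at least 2 features")
  }
  list(p_value = .t_test_safe(plus, minus, var_equal),
       mean_plus = mean(plus), mean_minus = mean(minus),
       n_plus = length(plus), n_minus = length(minus))
}

#' Cluster light-response log2 fold-change profiles
#'
#' k-means with Euclidean distance on profiles anchored at W0 = 0, run with
#' `n_restarts` seeded random initializations keeping the best (lowest
#' within-cluster sum of squares) solution, so the result is deterministic
#' given `(seed, n_restarts)`. If the matrix has fewer distinct profiles
#' than `k`, the distinct profiles themselves are used as centers and the
#' effective k shrinks (degenerate input; inertia 0 when all profiles
#' coincide).
#'
#' @param log2fc_matrix Numeric matrix, features x time points.
#' @param k Number of clusters (default 3, the major light-response
#'   classes: induced-from-dark-silence, gradual up, gradual down; a
#'   4-cluster variant is obtained by passing `k = 4`).
#' @param n_restarts Random restarts (default 20).
#' @param seed Integer seed (default 1).
#' @return List with `cluster` (named integer labels), `k` (effective),
#'   `centroids`, `inertia`.
#' @export
cluster_profiles <- function(log2fc_matrix, k = 3L, n_restarts = 20L, seed = 1L) {
  stopifnot(is.matrix(log2fc_matrix), k >= 1L)
  if (k > nrow(log2fc_matrix)) stop("k exceeds the number of features")
  distinct <- unique(log2fc_matrix)
  k_eff <- min(k, nrow(distinct))
  fit <- .with_seed(seed, {
    if (k_eff < k) {
      stats::kmeans(log2fc_matrix, centers = distinct, iter.max = 100L)
    } else {
      stats::kmeans(log2fc_matrix, centers = k_eff, nstart = n_restarts,
                    iter.max = 100L)
    }
  })
  list(cluster = stats::setNames(fit$cluster, rownames(log2fc_matrix)),
       k = k_eff, centroids = fit$centers, inertia = fit$tot.withinss)
}

#' Published light-regulated miRNA profiles
#'
#' The packaged worked example for profile clustering: average log2 fold
#' changes (relative to dark, W0) of the 66 light-regulated miRNAs across
#' the de-etiolation time course, with their published cluster labels
#' (I: induced from near-silence in the dark, II: gradual up-regulation,
#' III: down-regulation under prolonged light).
#'
#' @return List with `log2fc` (66 x 6 matrix, miRNAs x time points) and
#'   `cluster` (named factor of printed labels).
#' @export
light_response_profiles <- function() {
  path <- system.file("extdata", "light_response_log2fc.tsv",
                      package = "deetiolR", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, TIME_POINTS])
  rownames(m) <- tab$mirna
  list(log2fc = m,
       cluster = stats::setNames(factor(tab$cluster), tab$mirna))
}

#' Published PHAS locus calls (worked examples)
#'
#' The packaged table of twelve expressed PHAS/TAS loci with their genomic
#' window bounds (1-based inclusive), trigger sRNA, distinct alignment
#' count `n`, phased count `k` and printed hypergeometric p-value — the
#' ground truth used to calibrate the phasing-statistic convention
#' ([calibrate_phasing_convention()]).
#'
#' @return Data frame with columns `locus`, `gene`, `chromosome`,
#'   `trigger`, `start`, `end`, `n`, `k`, `p_value`.
#' @export
phas_locus_table <- function() {
  path <- system.file("extdata", "phas_loci_observed.tsv",
                      package = "deetiolR", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
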