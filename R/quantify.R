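# Expression quantification and classification of sRNAs.
#
# Expression matrices are plain numeric matrices, features x libraries,
# with library columns named "<time>_<replicate>" (e.g. "W3_2") and
# attributes `unit` ("raw_count", "RPM" or "RPKM") and, for RPM matrices,
# `lib_sizes` (the per-library 20-24 nt mapped-read totals used for
# normalization).

#' Place reads on references by exact full-length matching
#'
#' A deliberately minimal exact-match aligner for synthetic references:
#' every full-length, mismatch-free occurrence of a read (or its reverse
#' complement) is reported. Reads placed at more than `max_hits` positions
#' across the whole reference set are discarded, mirroring the common
#' multi-mapping cap (`-m 5`) used for genome-scale sRNA mapping.
#'
#' @param reads Data frame with columns `read_id`, `sequence`, `count`
#'   (e.g. from [read_collapsed_reads()]).
#' @param references Transcriptome data frame from [read_fasta()].
#' @param max_hits Maximum number of placements before a read is dropped.
#' @return Data frame of aligned reads: `read_id`, `sequence`, `count`,
#'   `ref_id`, `start` (0-based), `end` (exclusive), `strand`. Rows are
#'   ordered by input read, then reference, start and strand, so the output
#'   is deterministic.
#' @export
map_exact <- function(reads, references, max_hits = 5L) {
  stopifnot(max_hits >= 1L, all(c("read_id", "sequence", "count") %in% names(reads)))
  refs <- Biostrings::DNAStringSet(references$sequence)
  names(refs) <- references$id
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    seq <- reads$sequence[i]
    len <- nchar(seq)
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else revcomp(seq)
      m <- Biostrings::vmatchPattern(pat, refs)
      starts <- Biostrings::startIndex(m)
      for (j in seq_along(starts)) {
        if (length(starts[[j]]) == 0L) next
        hits[[length(hits) + 1L]] <- data.frame(
          read_id = reads$read_id[i], sequence = seq, count = reads$count[i],
          ref_id = names(refs)[j], start = starts[[j]] - 1L,
          end = starts[[j]] - 1L + len, strand = strand)
      }
    }
    if (length(hits) == 0L) next
    hits <- do.call(rbind, hits)
    if (nrow(hits) > max_hits) next  # multi-mapper beyond the cap: discard
    out[[i]] <- hits[order(hits$ref_id, hits$start, hits$strand), ]
  }
  out <- do.call(rbind, c(out, list(data.frame(
    read_id = character(), sequence = character(), count = integer(),
    ref_id = character(), start = integer(), end = integer(),
    strand = character()))))
  rownames(out) <- NULL
  out
}

#' Normalize raw counts to reads per million mapped 20-24 nt reads
#'
#' Each library is normalized independently: `RPM = count / total * 1e6`,
#' where `total` is that library's number of mapped reads in the 20-24 nt
#' size range (not merely the reads assigned to quantified features).
#'
#' @param counts Numeric matrix, features x libraries, of raw counts.
#' @param totals Named numeric vector of per-library totals; names must
#'   match `colnames(counts)`. Defaults to the matrix's `lib_sizes`
#'   attribute when present.
#' @return RPM matrix with attributes `unit = "RPM"` and `lib_sizes`.
#' @examples
#' m <- matrix(c(8, 0), 1, 2, dimnames = list("x", c("W0_1", "W1_1")))
#' rpm_normalize(m, c(W0_1 = 2e6, W1_1 = 1e6))
#' @export
rpm_normalize <- function(counts, totals = attr(counts, "lib_sizes")) {
  stopifnot(is.matrix(counts))
  if (is.null(totals)) stop("per-library totals are required")
  if (is.null(names(totals))) stop("totals must be named by library")
  missing <- setdiff(colnames(counts), names(totals))
  if (length(missing) > 0L) {
    stop("no total for library: ", paste(missing, collapse = ", "))
  }
  totals <- totals[colnames(counts)]
  if (any(totals <= 0)) stop("library totals must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  out <- sweep(counts, 2L, totals, `/`) * 1e6
  attr(out, "unit") <- "RPM"
  attr(out, "lib_sizes") <- totals
  out
}

#' Split a multi-member family read count equally among members
#'
#' Reads matching several members of one sRNA family (near-identical mature
#' sequences from distinct loci, e.g. a miR166a-3p..g read) are weighted by
#' dividing the read count equally among the members hit, so total mass is
#' conserved.
#'
#' @param read_count Read count to distribute.
#' @param members_hit Character vector of member sRNA ids.
#' @return Named numeric vector of per-member assignments summing to
#'   `read_count`.
#' @export
weight_family_counts <- function(read_count, members_hit) {
  if (length(members_hit) == 0L) stop("members_hit must be non-empty")
  stopifnot(read_count >= 0)
  stats::setNames(rep(read_count / length(members_hit), length(members_hit)),
                  members_hit)
}

#' Expressed-sRNA criterion
#'
#' A feature is expressed when each of the three biological replicates has
#' a raw count of at least `min_count` in at least one time point. By
#' default the qualifying time point may differ between replicates (each
#' replicate qualifies on its own); set `same_time_point = TRUE` for the
#' stricter conjunctive reading in which one common time point must reach
#' the threshold in all replicates. Missing values count as zero. The
#' criterion is monotone: adding reads can never turn an expressed feature
#' into a non-expressed one.
#'
#' @param counts Numeric matrix of raw counts for one feature, time points
#'   in rows and replicates in columns.
#' @param min_count Count threshold (default 5).
#' @param same_time_point Require a single qualifying time point shared by
#'   all replicates.
#' @return Logical scalar.
#' @export
is_expressed <- function(counts, min_count = 5, same_time_point = FALSE) {
  stopifnot(is.matrix(counts))
  counts[is.na(counts)] <- 0
  hit <- counts >= min_count
  if (same_time_point) any(apply(hit, 1L, all)) else all(apply(hit, 2L, any))
}

#' Test one sRNA for light regulation against the dark sample
#'
#' Each light time point (W1..W24) is compared with the dark reference W0
#' by a two-sided two-sample t-test on replicate RPM values (Welch by
#' default; set `var_equal = TRUE` for the pooled-variance variant). The
#' feature is called light-regulated when any time point reaches
#' `p < alpha`. Log2 fold changes are computed from replicate-mean RPM with
#' W0 as reference, so the W0 entry is 0 by construction. A feature with
#' zero mean RPM in the dark ("barely detectable in the dark") has +Inf
#' fold changes; its detection time (first time point with positive mean)
#' is reported instead.
#'
#' If both groups have zero variance the test degenerates: equal means give
#' p = 1, different means p = 0.
#'
#' @param rpm Numeric matrix for one feature: rows = the six time points in
#'   [TIME_POINTS] order (row names optional), columns = replicates.
#' @param alpha Significance threshold (default 0.05).
#' @param var_equal Use the pooled-variance t-test.
#' @return List with `p_values` (named, W1..W24), `log2_fold_changes`
#'   (named, W0..W24), `light_regulated`, `min_p` and `detected_at`
#'   (NA unless the W0 mean is zero).
#' @export
light_regulation_test <- function(rpm, alpha = 0.05, var_equal = FALSE) {
  stopifnot(is.matrix(rpm), nrow(rpm) == length(TIME_POINTS), ncol(rpm) >= 2L)
  rownames(rpm) <- TIME_POINTS
  dark <- rpm["W0", ]
  light_tps <- TIME_POINTS[-1L]
  p <- vapply(light_tps, function(tp) .t_test_safe(rpm[tp, ], dark, var_equal),
              numeric(1L))
  means <- rowMeans(rpm)
  lfc <- log2(means / means[["W0"]])
  lfc[["W0"]] <- 0
  lfc[is.nan(lfc)] <- 0  # 0/0: never detected at either time point
  detected_at <- NA_character_
  if (means[["W0"]] == 0 && any(means > 0)) {
    detected_at <- TIME_POINTS[which(means > 0)[1L]]
  }
  list(p_values = p,
       log2_fold_changes = lfc,
       light_regulated = any(p < alpha),
       min_p = min(p),
       detected_at = detected_at)
}

#' Classify every feature of a time-course count matrix
#'
#' Applies the expressed-sRNA criterion to raw counts, RPM-normalizes, and
#' runs the light-regulation test on every expressed feature. Fold changes
#' are reported only for expressed features (light regulation implies
#' expression).
#'
#' @param counts Raw count matrix, features x libraries, with
#'   `<time>_<replicate>` column names and a `lib_sizes` attribute (or pass
#'   `totals`).
#' @param totals Optional named per-library totals for RPM normalization.
#' @param min_count,alpha,same_time_point,var_equal Passed through to
#'   [is_expressed()] and [light_regulation_test()].
#' @return Data frame with one row per feature: `srna_id`, `expressed`,
#'   `light_regulated`, `min_p`, and `lfc_W0` .. `lfc_W24`.
#' @export
classify_regulation <- function(counts, totals = attr(counts, "lib_sizes"),
                                min_count = 5, alpha = 0.05,
                                same_time_point = FALSE, var_equal = FALSE) {
  libs <- .parse_lib_names(colnames(counts))
  rpm <- rpm_normalize(counts, totals)
  reps <- sort(unique(libs$replicate))
  tp_matrix <- function(mat, feature) {
    m <- matrix(NA_real_, length(TIME_POINTS), length(reps),
                dimnames = list(TIME_POINTS, reps))
    for (j in seq_len(nrow(libs))) {
      m[libs$time_point[j], as.character(libs$replicate[j])] <- mat[feature, libs$lib[j]]
    }
    m
  }
  rows <- lapply(rownames(counts), function(f) {
    raw <- tp_matrix(counts, f)
    expressed <- is_expressed(raw, min_count, same_time_point)
    if (!expressed) {
      lfc <- stats::setNames(rep(NA_real_, length(TIME_POINTS)), TIME_POINTS)
      return(cbind(data.frame(srna_id = f, expressed = FALSE,
                              light_regulated = FALSE, min_p = NA_real_),
                   as.data.frame(t(lfc))))
    }
    res <- light_regulation_test(tp_matrix(rpm, f), alpha, var_equal)
    cbind(data.frame(srna_id = f, expressed = TRUE,
                     light_regulated = res$light_regulated, min_p = res$min_p),
          as.data.frame(t(res$log2_fold_changes)))
  })
  out <- do.call(rbind, rows)
  names(out) <- c("srna_id", "expressed", "light_regulated", "min_p",
                  paste0("lfc_", TIME_POINTS))
  rownames(out) <- NULL
  out
}
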