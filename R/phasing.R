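# PHAS/TAS locus detection.
#
# Phased siRNAs are diced in 21-nt steps from a double-stranded precursor,
# so their 5' ends fall into one of 21 residue classes ("registers") modulo
# the phase length. Within a sliding window, the number of distinct
# alignment positions n and the number k falling into the best register are
# scored with an upper-tail hypergeometric probability: drawing n occupied
# positions out of N possible positions, of which K lie in a register.

#' Parameters of the phasing scan
#'
#' Defaults encode the calibrated double-strand convention: a 251-nt
#' window, 21-nt phase length, `N = 2 * window_length` candidate positions
#' (both strands), `K = 2 * ceiling(W/L)` register positions, and no
#' register-selection multiplier (`register_multiplicity = 1`). This is the
#' member of the convention family that best reproduces the published
#' worked examples in [phas_locus_table()]; see
#' [calibrate_phasing_convention()] and the package vignette for the sweep
#' and its residual.
#'
#' Windows with fewer than `min_distinct_alignments` distinct alignments
#' are not tested: sparsely covered (in particular clipped) windows where
#' two or three reads share a register by chance are not meaningful phasing
#' evidence, and the published calls all have at least 10 distinct
#' alignments.
#'
#' @param window_length Window width in nt (default 251).
#' @param phase_length Phase (register) length in nt (default 21).
#' @param total_positions `N`, candidate positions per window; default
#'   `2 * window_length`.
#' @param phased_positions `K`, register positions per window; default
#'   `2 * ceiling(window_length / phase_length)`.
#' @param register_multiplicity Multiplier applied to the tail probability
#'   as a register-selection correction (capped at 1); default 1.
#' @param min_read_length,max_read_length Read lengths entering the scan
#'   (defaults 21, 21).
#' @param p_threshold Reporting threshold for [scan_phas()] (default 1e-4).
#' @param min_distinct_alignments Minimum `n` for a window to be tested
#'   (default 10).
#' @return An object of class `phasing_params`.
#' @export
phasing_params <- function(window_length = 251L,
                           phase_length = 21L,
                           total_positions = 2L * window_length,
                           phased_positions = 2L * ceiling(window_length / phase_length),
                           register_multiplicity = 1L,
                           min_read_length = 21L,
                           max_read_length = 21L,
                           p_threshold = 1e-4,
                           min_distinct_alignments = 10L) {
  stopifnot(window_length >= phase_length, phase_length >= 1L,
            phased_positions <= total_positions,
            register_multiplicity >= 1L,
            register_multiplicity <= phase_length,
            min_read_length <= max_read_length,
            p_threshold > 0, p_threshold <= 1)
  structure(list(window_length = as.integer(window_length),
                 phase_length = as.integer(phase_length),
                 total_positions = as.integer(total_positions),
                 phased_positions = as.integer(phased_positions),
                 register_multiplicity = as.integer(register_multiplicity),
                 min_read_length = as.integer(min_read_length),
                 max_read_length = as.integer(max_read_length),
                 p_threshold = p_threshold,
                 min_distinct_alignments = as.integer(min_distinct_alignments)),
            class = "phasing_params")
}

# Register coordinate of each alignment relative to a window start.
# Plus-strand reads phase by their 5' (= leftmost) position. Minus-strand
# reads phase by their 5' position minus 2: dicing leaves 2-nt 3'
# overhangs, so a phased minus-strand 5' end sits 2 nt 3' of the
# plus-strand register cut.
.phase_coord <- function(start, end, strand, window_start, phase_length) {
  five_prime <- ifelse(strand == "+", start, end - 1L)
  adj <- ifelse(strand == "+", five_prime, five_prime - 2L)
  (adj - window_start) %% phase_length
}

#' Count distinct and phased alignments in one window
#'
#' Restricts `alignments` to reads on `ref_id` whose length lies within the
#' configured bounds and whose (leftmost) start falls inside the window,
#' collapses them to distinct (start, strand) positions, and finds the
#' register holding the most positions.
#'
#' @param alignments Aligned-read data frame (see [map_exact()]).
#' @param ref_id Reference to examine.
#' @param window_start 0-based window start.
#' @param params A [phasing_params()] object.
#' @param ref_length Optional reference length; when supplied, a window
#'   extending past the reference end is clipped and flagged.
#' @return List with `n` (distinct alignments), `k` (alignments in the best
#'   register), `best_register` (0-based register coordinate; ties go to
#'   the smallest) and `clipped`.
#' @export
count_window <- function(alignments, ref_id, window_start, params = phasing_params(),
                         ref_length = NULL) {
  w_end <- window_start + params$window_length
  clipped <- FALSE
  if (!is.null(ref_length) && w_end > ref_length) {
    w_end <- ref_length
    clipped <- TRUE
  }
  a <- alignments[alignments$ref_id == ref_id, , drop = FALSE]
  len <- a$end - a$start
  a <- a[len >= params$min_read_length & len <= params$max_read_length &
           a$start >= window_start & a$start < w_end, , drop = FALSE]
  if (nrow(a) == 0L) {
    return(list(n = 0L, k = 0L, best_register = NA_integer_, clipped = clipped))
  }
  pos <- unique(a[, c("start", "end", "strand")])
  pos <- pos[!duplicated(pos[, c("start", "strand")]), , drop = FALSE]
  phases <- .phase_coord(pos$start, pos$end, pos$strand, window_start,
                         params$phase_length)
  tab <- tabulate(phases + 1L, nbins = params$phase_length)
  list(n = nrow(pos), k = max(tab), best_register = which.max(tab) - 1L,
       clipped = clipped)
}

#' Hypergeometric phasing p-value
#'
#' Upper-tail probability `P(X >= k)` that at least `k` of `n` occupied
#' positions fall on register positions when `n` positions are drawn
#' without replacement from `N` candidates containing `K` register
#' positions, multiplied by the register-selection correction and capped at
#' 1. Strictly decreasing in `k` at fixed `n`, and always in (0, 1].
#'
#' @param n Number of distinct alignments in the window.
#' @param k Number of phased alignments (best register).
#' @param params A [phasing_params()] object supplying `N`, `K` and the
#'   register multiplicity.
#' @return The p-value.
#' @examples
#' phasing_pvalue(12, 9)   # the TAS2-sized worked example
#' @export
phasing_pvalue <- function(n, k, params = phasing_params()) {
  N <- params$total_positions
  K <- params$phased_positions
  if (any(k > K)) stop("k exceeds the number of register positions K")
  if (any(n > N)) stop("n exceeds the number of candidate positions N")
  if (any(k > n) || any(k < 0) || any(n < 0)) stop("require 0 <= k <= n")
  p <- params$register_multiplicity *
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Scan references for phased-siRNA loci
#'
#' Slides windows of `window_length` in steps of one phase cycle over every
#' reference, tests each window holding at least `min_distinct_alignments`
#' distinct alignments with [phasing_pvalue()], merges runs of overlapping
#' significant windows (keeping the minimum p-value and its counts), and
#' returns calls below `p_threshold` sorted by p-value within each
#' reference. References shorter than one window are scanned as a single
#' clipped window.
#'
#' @param alignments Aligned-read data frame.
#' @param references Transcriptome data frame from [read_fasta()], or a
#'   named integer vector of reference lengths.
#' @param params A [phasing_params()] object.
#' @return Data frame of locus calls: `ref_id`, `start`, `end` (0-based
#'   half-open merged window bounds), `n`, `k`, `best_register`, `p_value`,
#'   `trigger` (NA; annotate from degradome calls when available).
#' @export
scan_phas <- function(alignments, references, params = phasing_params()) {
  if (is.data.frame(references)) {
    ref_lens <- stats::setNames(nchar(references$sequence), references$id)
  } else {
    ref_lens <- references
  }
  W <- params$window_length
  L <- params$phase_length
  empty <- data.frame(ref_id = character(), start = integer(), end = integer(),
                      n = integer(), k = integer(), best_register = integer(),
                      p_value = numeric(), trigger = character())
  len_ok <- (alignments$end - alignments$start) >= params$min_read_length &
    (alignments$end - alignments$start) <= params$max_read_length
  alignments <- alignments[len_ok, , drop = FALSE]
  out <- list()
  for (ref in names(ref_lens)) {
    a <- alignments[alignments$ref_id == ref, , drop = FALSE]
    if (nrow(a) == 0L) next
    pos <- a[!duplicated(a[, c("start", "strand")]), c("start", "end", "strand")]
    ord <- order(pos$start)
    pos <- pos[ord, , drop = FALSE]
    len <- ref_lens[[ref]]
    starts <- if (len >= W) seq.int(0L, len - W, by = L) else 0L
    # restrict to windows that can contain data
    starts <- starts[starts <= max(pos$start) & (starts + W) > min(pos$start)]
    hits <- list()
    for (ws in starts) {
      lo <- findInterval(ws - 1L, pos$start) + 1L
      hi <- findInterval(min(ws + W, len) - 1L, pos$start)
      if (hi < lo) next
      n <- hi - lo + 1L
      if (n < params$min_distinct_alignments) next
      ph <- .phase_coord(pos$start[lo:hi], pos$end[lo:hi], pos$strand[lo:hi],
                         ws, L)
      tab <- tabulate(ph + 1L, nbins = L)
      k <- max(tab)
      p <- phasing_pvalue(n, k, params)
      if (p < params$p_threshold) {
        hits[[length(hits) + 1L]] <- data.frame(
          ref_id = ref, start = ws, end = min(ws + W, len), n = n, k = k,
          best_register = which.max(tab) - 1L, p_value = p,
          trigger = NA_character_)
      }
    }
    if (length(hits) == 0L) next
    hits <- do.call(rbind, hits)
    # merge overlapping significant windows, keeping the minimum p
    merged <- hits[1L, , drop = FALSE]
    if (nrow(hits) > 1L) {
      for (i in 2L:nrow(hits)) {
        last <- nrow(merged)
        if (hits$start[i] < merged$end[last]) {
          keep <- if (hits$p_value[i] < merged$p_value[last]) hits[i, ] else merged[last, ]
          keep$start <- merged$start[last]
          keep$end <- max(merged$end[last], hits$end[i])
          merged[last, ] <- keep
        } else {
          merged <- rbind(merged, hits[i, ])
        }
      }
    }
    out[[ref]] <- merged[order(merged$p_value), , drop = FALSE]
  }
  out <- do.call(rbind, c(out, list(empty)))
  rownames(out) <- NULL
  out
}

#' Sweep phasing-statistic conventions against observed locus calls
#'
#' The published worked examples print, for each locus, the distinct
#' alignment count `n`, the phased count `k` and a hypergeometric p-value,
#' but not the convention (`N`, `K`, register correction) behind it. This
#' sweep evaluates the candidate family
#' `N in {W, 2W, L*ceiling(W/L), 2L*ceiling(W/L)}`,
#' `K in {ceiling(W/L), 2*ceiling(W/L)}` (members with `K < max(k)` are
#' infeasible and dropped), `m in {1, L}`, and ranks members by the worst
#' per-row log10 deviation from the printed p-values.
#'
#' @param observed Data frame with columns `n`, `k`, `p_value` (defaults to
#'   the packaged locus table, [phas_locus_table()]).
#' @param window_length,phase_length Window and phase length of the scan.
#' @return Data frame, one row per feasible convention, sorted best first:
#'   `total_positions`, `phased_positions`, `register_multiplicity`,
#'   `max_abs_log10_ratio`, `rank_agreement` (printed and computed p-values
#'   order identically), `all_2sf` (every row matches to 2 significant
#'   figures).
#' @export
calibrate_phasing_convention <- function(observed = phas_locus_table(),
                                         window_length = 251L,
                                         phase_length = 21L) {
  stopifnot(all(c("n", "k", "p_value") %in% names(observed)))
  W <- window_length
  L <- phase_length
  cyc <- ceiling(W / L)
  grid <- expand.grid(N = c(W, 2L * W, L * cyc, 2L * L * cyc),
                      K = c(cyc, 2L * cyc), m = c(1L, L))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    N <- grid$N[i]; K <- grid$K[i]; m <- grid$m[i]
    if (max(observed$k) > K || max(observed$n) > N) return(NULL)
    pars <- phasing_params(window_length = W, phase_length = L,
                           total_positions = N, phased_positions = K,
                           register_multiplicity = m)
    p <- phasing_pvalue(observed$n, observed$k, pars)
    ratio <- log10(p / observed$p_value)
    data.frame(total_positions = N, phased_positions = K,
               register_multiplicity = m,
               max_abs_log10_ratio = max(abs(ratio)),
               rank_agreement = identical(order(p), order(observed$p_value)),
               all_2sf = all(signif(p, 2) == signif(observed$p_value, 2)))
  })
  out <- do.call(rbind, rows)
  out[order(out$max_abs_log10_ratio), , drop = FALSE]
}
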