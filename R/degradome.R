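# Degradome (PARE) cleavage-event calling.
#
# A slicer-competent sRNA:target duplex leaves a diagnostic uncapped 5' end
# on the 3' cleavage fragment, opposite sRNA positions 10-11. Candidate
# duplexes are scored by complementarity penalties; the degradome signal at
# the expected cut is ranked against the rest of the transcript (category
# 0-4), and an empirical p-value is obtained from dinucleotide-preserving
# shuffles of the sRNA.

# Per-pair penalty: Watson-Crick 0, G:U wobble 0.5, anything else 1.
# Positions are sRNA coordinates counted from the sRNA 5' end; penalties
# double within the functionally critical region 2-13.
.PAIR_PENALTY <- local({
  p <- matrix(1, 4L, 4L, dimnames = list(names(.NT), names(.NT)))
  p["A", "T"] <- p["T", "A"] <- p["C", "G"] <- p["G", "C"] <- 0
  p["G", "T"] <- p["T", "G"] <- 0.5
  p
})

.position_weights <- function(len) {
  w <- rep(1, len)
  w[seq_len(len) >= 2 & seq_len(len) <= 13] <- 2
  w
}

#' Complementarity penalty score of an sRNA:target duplex
#'
#' Scores an anchored, equal-length duplex between an sRNA and the target
#' site written 5'->3' on the transcript (sense strand): sRNA position i
#' (from the sRNA 5' end) pairs with target position `len - i + 1`.
#' Penalties: mismatch 1, G:U wobble 0.5, bulge (a `-` in either strand,
#' treated as a single-position insertion) 1; every penalty doubles when
#' the sRNA position lies in 2-13. A perfect duplex scores 0.
#'
#' @param srna_sequence sRNA sequence, 5'->3' (ACGTU; U is read as T).
#' @param target_site_sequence Target site, 5'->3' on the transcript, same
#'   length as the sRNA.
#' @return List with `score` and `match_states` (per sRNA position:
#'   `"match"`, `"GU"`, `"mismatch"` or `"bulge"`).
#' @examples
#' allen_score("ACGUACGUACGUACGUACGUA", revcomp("ACGTACGTACGTACGTACGTA"))
#' @export
allen_score <- function(srna_sequence, target_site_sequence) {
  if (!nzchar(srna_sequence) || !nzchar(target_site_sequence)) {
    stop("empty sequence")
  }
  s <- strsplit(chartr("Uu", "Tt", toupper(srna_sequence)), "", fixed = TRUE)[[1L]]
  t <- strsplit(chartr("Uu", "Tt", toupper(target_site_sequence)), "", fixed = TRUE)[[1L]]
  if (length(s) != length(t)) stop("duplex strands must have equal length")
  len <- length(s)
  opp <- rev(t)  # opp[i] faces sRNA position i
  w <- .position_weights(len)
  states <- character(len)
  pen <- numeric(len)
  for (i in seq_len(len)) {
    if (s[i] == "-" || opp[i] == "-") {
      states[i] <- "bulge"; pen[i] <- 1
    } else {
      p <- .PAIR_PENALTY[s[i], opp[i]]
      states[i] <- if (p == 0) "match" else if (p == 0.5) "GU" else "mismatch"
      pen[i] <- p
    }
  }
  list(score = sum(pen * w), match_states = states)
}

# ---- vectorized scanning machinery -----------------------------------------

# A scan database concatenates all transcripts (separator code 5) so that
# every candidate window across the transcriptome is scored in one pass.
.scan_db <- function(transcripts) {
  codes <- lapply(transcripts$sequence, .encode_nt)
  lens <- lengths(codes)
  concat <- integer(sum(lens) + length(codes))
  offsets <- integer(length(codes))  # 0-based offset of transcript start in concat
  pos <- 0L
  for (i in seq_along(codes)) {
    offsets[i] <- pos
    concat[(pos + 1L):(pos + lens[i])] <- codes[[i]]
    pos <- pos + lens[i] + 1L
    concat[pos] <- 5L
  }
  list(concat = concat, ids = transcripts$id, lens = lens, offsets = offsets)
}

# Scores of all windows of width `len` in the concatenated database for a
# given sRNA (integer codes). Windows crossing a separator score Inf.
# score(w) = sum_i P[i, concat[w + len - i]]  (sRNA pos i pairs window pos
# len - i + 1), computed as `len` shifted vector lookups.
.scan_scores <- function(srna_codes, db) {
  len <- length(srna_codes)
  w <- .position_weights(len)
  nW <- length(db$concat) - len + 1L
  if (nW < 1L) return(numeric(0L))
  score <- numeric(nW)
  for (i in seq_along(srna_codes)) {
    lut <- c(.PAIR_PENALTY[names(.NT)[srna_codes[i]], ], Inf) * w[i]
    off <- len - i  # 0-based offset of the paired base within the window
    score <- score + lut[db$concat[(1L + off):(off + nW)]]
  }
  score
}

# Map 1-based concat window starts to (transcript index, 0-based local start).
.window_location <- function(window_starts, db) {
  idx <- findInterval(window_starts - 1L, db$offsets)
  data.frame(transcript = db$ids[idx],
             local_start = window_starts - 1L - db$offsets[idx])
}

#' Find candidate sRNA target sites on a transcript
#'
#' Scans every ungapped window of the transcript for duplexes with
#' [allen_score()] at most `max_score` (the `expectation = 3` style
#' complementarity cutoff). Overlapping candidate sites are deduplicated
#' keeping the minimum score. The expected cleavage position is the
#' transcript coordinate paired with sRNA position 10, i.e. the 5' end of
#' the downstream fragment left by slicing between positions 10 and 11.
#'
#' Target-site accessibility (an RNA-folding energy filter such as
#' `UPE = 25` in structure-aware predictors) is deliberately not computed:
#' candidate sites are ranked by complementarity only.
#'
#' @param srna Either an sRNA sequence or a one-row data frame with
#'   `srna_id` and `sequence`.
#' @param transcript One-row data frame with `id` and `sequence` (or a
#'   plain sequence).
#' @param max_score Penalty cutoff (default 3).
#' @return Data frame of target alignments: `srna_id`, `transcript_id`,
#'   `start` (0-based), `end`, `score`, `cleavage_pos` (1-based).
#' @export
find_candidate_sites <- function(srna, transcript, max_score = 3) {
  srna_id <- "sRNA"; srna_seq <- srna
  if (is.data.frame(srna)) { srna_id <- srna$srna_id[1L]; srna_seq <- srna$sequence[1L] }
  tx_id <- "transcript"; tx_seq <- transcript
  if (is.data.frame(transcript)) { tx_id <- transcript$id[1L]; tx_seq <- transcript$sequence[1L] }
  if (nchar(tx_seq) < nchar(srna_seq)) stop("transcript shorter than sRNA")
  db <- .scan_db(data.frame(id = tx_id, sequence = chartr("Uu", "Tt", toupper(tx_seq))))
  .candidates_from_scores(.encode_nt(chartr("Uu", "Tt", toupper(srna_seq))),
                          db, srna_id, max_score)
}

# Shared site extraction: score windows, keep those under the cutoff and
# deduplicate overlapping sites per transcript (best score wins; ties to
# the leftmost site).
.candidates_from_scores <- function(srna_codes, db, srna_id, max_score) {
  len <- length(srna_codes)
  scores <- .scan_scores(srna_codes, db)
  keep <- which(scores <= max_score)
  empty <- data.frame(srna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      cleavage_pos = integer())
  if (length(keep) == 0L) return(empty)
  loc <- .window_location(keep, db)
  cand <- data.frame(srna_id = srna_id, transcript_id = loc$transcript,
                     start = loc$local_start, end = loc$local_start + len,
                     score = scores[keep],
                     cleavage_pos = loc$local_start + len - 9L)
  cand <- cand[order(cand$transcript_id, cand$score, cand$start), , drop = FALSE]
  out <- list()
  for (tx in unique(cand$transcript_id)) {
    sub <- cand[cand$transcript_id == tx, , drop = FALSE]
    kept <- sub[0L, ]
    for (i in seq_len(nrow(sub))) {
      if (nrow(kept) == 0L ||
          all(sub$start[i] >= kept$end | sub$end[i] <= kept$start)) {
        kept <- rbind(kept, sub[i, ])
      }
    }
    out[[tx]] <- kept
  }
  out <- do.call(rbind, c(out, list(empty)))
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank-based degradome category of a cleavage site
#'
#' With `c` the 5'-end read count at `position` and the comparison set the
#' nonzero positions of the transcript profile: category 4 if `c == 1`;
#' 0 if `c > 1` and `c` is the unique maximum; 1 if `c > 1` and ties the
#' maximum; 2 if `c > 1`, above the median of nonzero counts but below the
#' maximum; 3 otherwise (`c > 1`, at or below the median). A site with no
#' reads has no category (`NA`).
#'
#' @param profile Integer vector of per-position 5'-end counts (1-based).
#' @param position 1-based transcript position of the expected cleavage
#'   site.
#' @return Integer category in 0..4, or `NA` for a read-free site.
#' @examples
#' categorize_site(c(0, 9, 2, 2, 0), 2)  # unique maximum: category 0
#' @export
categorize_site <- function(profile, position) {
  if (position < 1L || position > length(profile)) {
    stop("position outside transcript")
  }
  nz <- profile[profile > 0]
  if (length(nz) == 0L) stop("profile has no reads")
  c0 <- profile[position]
  if (c0 == 0) return(NA_integer_)
  if (c0 == 1) return(4L)
  mx <- max(nz)
  if (c0 == mx) {
    return(if (sum(nz == mx) == 1L) 0L else 1L)
  }
  if (c0 > stats::median(nz)) 2L else 3L
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffling: the sequence is viewed as an Eulerian walk
#' on the graph of dinucleotide transitions and a uniformly random Eulerian
#' walk with the same start and end letter is drawn, so mononucleotide and
#' dinucleotide counts are preserved exactly. Homopolymers (and any
#' sequence with a single possible walk) shuffle to themselves.
#'
#' @param sequence Nucleotide string.
#' @param n Number of shuffles.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return Character vector of `n` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(sequence, n = 1L, seed = NULL) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  len <- length(chars)
  if (len <= 2L) return(rep(sequence, n))
  .with_seed(seed, {
    verts <- unique(chars)
    from <- chars[-len]
    to <- chars[-1L]
    adj <- split(to, factor(from, levels = verts))
    last <- chars[len]
    one_shuffle <- function() {
      inner <- setdiff(verts, last)
      inner <- inner[vapply(adj[inner], length, integer(1L)) > 0L]
      repeat {
        # choose a random terminal edge for every non-final vertex and
        # accept when those edges form a tree into the final vertex
        pick <- vapply(inner, function(v) {
          out <- adj[[v]]
          out[[sample.int(length(out), 1L)]]
        }, character(1L))
        ok <- TRUE
        for (v in inner) {
          cur <- v
          steps <- 0L
          while (cur != last && steps <= length(verts)) {
            if (!cur %in% inner) break
            cur <- pick[[cur]]
            steps <- steps + 1L
          }
          if (cur != last) { ok <- FALSE; break }
        }
        if (ok) break
      }
      order_edges <- function(v) {
        out <- adj[[v]]
        if (length(out) == 0L) return(out)
        if (v %in% inner) {
          i <- which(out == pick[[v]])[1L]
          rest <- out[-i]
          c(if (length(rest) > 0L) rest[sample.int(length(rest))] else character(0L),
            out[i])
        } else {
          out[sample.int(length(out))]
        }
      }
      ordered <- lapply(stats::setNames(verts, verts), order_edges)
      used <- stats::setNames(integer(length(verts)), verts)
      res <- character(len)
      res[1L] <- chars[1L]
      cur <- chars[1L]
      for (i in 2L:len) {
        used[[cur]] <- used[[cur]] + 1L
        nxt <- ordered[[cur]][used[[cur]]]
        res[i] <- nxt
        cur <- nxt
      }
      paste(res, collapse = "")
    }
    vapply(seq_len(n), function(i) one_shuffle(), character(1L))
  })
}

#' Empirical p-value of a cleavage call
#'
#' Draws `n_shuffles` dinucleotide-preserving shuffles of the sRNA and
#' counts the number `b` that achieve, anywhere in the transcriptome, a
#' candidate site whose complementarity score is at most the observed score
#' *and* whose degradome category at the site's expected cleavage position
#' is at most the observed category. The p-value is `(1 + b) /
#' (n_shuffles + 1)`, so it is bounded below by `1 / (n_shuffles + 1)` and
#' adding shuffles refines but never invalidates the bound.
#'
#' @param call One-row data frame (or list) with at least `score` and
#'   `category`.
#' @param transcriptome Transcriptome data frame.
#' @param profiles Named list of degradome profiles (see
#'   [read_degradome_tsv()]).
#' @param srna_sequence The sRNA sequence behind the call.
#' @param n_shuffles Number of shuffles (default 100).
#' @param seed Optional seed.
#' @param max_score Site-candidacy cutoff used for the shuffled variants
#'   (default 3).
#' @param db Prebuilt scan database (internal reuse by [call_targets()]).
#' @return The empirical p-value.
#' @export
cleavage_pvalue <- function(call, transcriptome, profiles, srna_sequence,
                            n_shuffles = 100L, seed = NULL, max_score = 3,
                            db = NULL) {
  stopifnot(n_shuffles >= 1L)
  if (is.null(db)) db <- .scan_db(transcriptome)
  shuffles <- dinucleotide_shuffle(srna_sequence, n_shuffles, seed)
  b <- sum(vapply(shuffles, function(s) {
    .shuffle_qualifies(.encode_nt(s), db, profiles, call$score, call$category,
                       max_score)
  }, logical(1L)))
  (1 + b) / (n_shuffles + 1)
}

# Does a (shuffled) sRNA achieve score <= obs_score with category <=
# obs_category anywhere in the database?
.shuffle_qualifies <- function(codes, db, profiles, obs_score, obs_category,
                               max_score) {
  len <- length(codes)
  scores <- .scan_scores(codes, db)
  cand <- which(scores <= min(obs_score, max_score))
  if (length(cand) == 0L) return(FALSE)
  cand <- cand[order(scores[cand])]
  loc <- .window_location(cand, db)
  for (i in seq_along(cand)) {
    prof <- profiles[[loc$transcript[i]]]
    if (is.null(prof) || sum(prof) == 0L) next
    pos <- loc$local_start[i] + len - 9L
    if (pos < 1L || pos > length(prof)) next
    cat_i <- categorize_site(prof, pos)
    if (!is.na(cat_i) && cat_i <= obs_category) return(TRUE)
  }
  FALSE
}

#' Apply the cleavage-call validity filter
#'
#' A targeting event is reported as valid when its degradome category is
#' at most `max_category`, its empirical p-value at most `alpha`, and the
#' raw read count at the predicted cleavage site at least
#' `min_site_reads`. Calls with missing category or p-value are invalid.
#'
#' @param calls Data frame with columns `category`, `p_value`,
#'   `site_reads`.
#' @param min_site_reads,max_category,alpha Thresholds (defaults 5,
#'   category 2, p 0.05).
#' @return `calls` with the `valid` column (re)computed.
#' @export
validity_filter <- function(calls, min_site_reads = 5L, max_category = 2L,
                            alpha = 0.05) {
  stopifnot(all(c("category", "p_value", "site_reads") %in% names(calls)))
  calls$valid <- !is.na(calls$category) & calls$category <= max_category &
    !is.na(calls$p_value) & calls$p_value <= alpha &
    calls$site_reads >= min_site_reads
  calls
}

#' Call sRNA-guided cleavage events across a transcriptome
#'
#' The full degradome pipeline: candidate sites by complementarity
#' ([find_candidate_sites()] semantics over all transcripts at once), site
#' reads attributed within `site_tolerance` nt of the expected cleavage
#' position (absorbing 5'-end heterogeneity), rank category, empirical
#' p-value, and the validity filter `category <= 2 & p <= 0.05 &
#' site_reads >= 5`. Site reads are raw counts for the filter;
#' RPM-normalized site reads are reported alongside. Both valid and
#' invalid calls are returned, valid first.
#'
#' p-values are computed only for calls whose site holds at least one read
#' (read-free sites have no category and are invalid by definition).
#'
#' @param srnas Data frame with `srna_id`, `sequence` (a catalog of mature
#'   sRNAs).
#' @param transcriptome Transcriptome data frame.
#' @param profiles Degradome profile list with a `library_size` attribute.
#' @param max_score Complementarity cutoff (default 3).
#' @param site_tolerance Positional tolerance in nt when attributing
#'   degradome reads to the expected cleavage site (default 1).
#' @param n_shuffles,seed Passed to [cleavage_pvalue()].
#' @param min_site_reads,max_category,alpha The validity thresholds
#'   (defaults 5 reads, category 2, p 0.05).
#' @return Data frame of cleavage calls: `srna_id`, `transcript_id`,
#'   `site` (1-based attributed position), `score`, `site_reads`,
#'   `site_rpm`, `category`, `p_value`, `valid`.
#' @export
call_targets <- function(srnas, transcriptome, profiles,
                         max_score = 3, site_tolerance = 1L,
                         n_shuffles = 100L, seed = NULL,
                         min_site_reads = 5L, max_category = 2L,
                         alpha = 0.05) {
  db <- .scan_db(transcriptome)
  lib_size <- attr(profiles, "library_size")
  if (is.null(lib_size)) lib_size <- sum(vapply(profiles, sum, numeric(1L)))
  rows <- list()
  for (i in seq_len(nrow(srnas))) {
    codes <- .encode_nt(chartr("Uu", "Tt", toupper(srnas$sequence[i])))
    sites <- .candidates_from_scores(codes, db, srnas$srna_id[i], max_score)
    if (nrow(sites) == 0L) next
    for (j in seq_len(nrow(sites))) {
      prof <- profiles[[sites$transcript_id[j]]]
      if (is.null(prof)) next
      span <- max(1L, sites$cleavage_pos[j] - site_tolerance):
        min(length(prof), sites$cleavage_pos[j] + site_tolerance)
      site_pos <- span[which.max(prof[span])]
      site_reads <- prof[site_pos]
      category <- if (sum(prof) > 0L) categorize_site(prof, site_pos) else NA_integer_
      p <- NA_real_
      if (!is.na(category)) {
        p <- cleavage_pvalue(list(score = sites$score[j], category = category),
                             transcriptome, profiles, srnas$sequence[i],
                             n_shuffles = n_shuffles,
                             seed = if (is.null(seed)) NULL else seed + i,
                             max_score = max_score, db = db)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        srna_id = srnas$srna_id[i], transcript_id = sites$transcript_id[j],
        site = site_pos, score = sites$score[j],
        site_reads = as.integer(site_reads),
        site_rpm = site_reads / lib_size * 1e6,
        category = category, p_value = p)
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(
    srna_id = character(), transcript_id = character(), site = integer(),
    score = numeric(), site_reads = integer(), site_rpm = numeric(),
    category = integer(), p_value = numeric()))))
  out <- validity_filter(out, min_site_reads, max_category, alpha)
  out <- out[order(!out$valid, out$p_value, out$srna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position degradome series with called sites flagged (T-plot data)
#'
#' Exports the full per-position 5'-end count series of one transcript with
#' the positions of cleavage calls flagged — the data behind a degradome
#' T-plot, where flagged positions are the asterisked candidate cleavage
#' sites.
#'
#' @param profile Integer vector of per-position counts for one transcript.
#' @param calls Cleavage-call data frame ([call_targets()]) already
#'   restricted to, or carrying, this transcript via `transcript_id`;
#'   `site` positions are flagged.
#' @param transcript_id Optional transcript id to filter `calls`.
#' @return Data frame with `position`, `count`, `flagged`.
#' @export
tplot_data <- function(profile, calls, transcript_id = NULL) {
  if (length(profile) == 0L) stop("empty profile")
  sites <- calls$site
  if (!is.null(transcript_id) && "transcript_id" %in% names(calls)) {
    sites <- calls$site[calls$transcript_id == transcript_id]
  }
  data.frame(position = seq_along(profile),
             count = as.integer(profile),
             flagged = seq_along(profile) %in% sites)
}
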