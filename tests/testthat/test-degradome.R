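test_that("duplex scoring applies the penalty rules with seed doubling", {
  srna <- "ACGTACGTACGTACGTACGTA"
  perfect <- allen_score(srna, revcomp(srna))
  expect_equal(perfect$score, 0)
  expect_true(all(perfect$match_states == "match"))

  # one G:U wobble at sRNA position 20 (outside 2-13): 0.5
  s <- strsplit(srna, "")[[1]]
  site <- strsplit(revcomp(srna), "")[[1]]
  stopifnot(s[20] == "T")           # pairs site position 21 - 20 + 1 = 2
  site[2] <- "G"                    # U:A -> U:G wobble
  gu <- allen_score(srna, paste(site, collapse = ""))
  expect_equal(gu$score, 0.5)
  expect_equal(gu$match_states[20], "GU")

  # one mismatch at sRNA position 10 (inside 2-13): doubled to 2
  site <- strsplit(revcomp(srna), "")[[1]]
  opp10 <- 21 - 10 + 1
  site[opp10] <- "C"                # sRNA pos 10 is C; C opposite C mismatches
  mm <- allen_score(srna, paste(site, collapse = ""))
  expect_equal(mm$score, 2)
  expect_equal(mm$match_states[10], "mismatch")

  # a bulge in the seed region is penalized like a doubled mismatch
  site <- strsplit(revcomp(srna), "")[[1]]
  site[opp10] <- "-"
  expect_equal(allen_score(srna, paste(site, collapse = ""))$score, 2)

  expect_error(allen_score("", "ACGT"), "empty")
  expect_error(allen_score("ACGT", "ACGTA"), "equal length")
})

test_that("any sequence scores 0 against its own reverse complement", {
  set.seed(17)
  for (i in 1:20) {
    s <- random_dna(sample(20:24, 1))
    expect_equal(allen_score(s, revcomp(s))$score, 0)
  }
})

test_that("candidate-site scanning matches a naive window-by-window oracle", {
  set.seed(23)
  for (i in 1:10) {
    srna <- random_dna(21)
    tx <- random_dna(300)
    # plant a perfect site and a seed-mismatch site
    site <- revcomp(srna)
    substr(tx, 50, 70) <- site
    weak <- strsplit(site, "")[[1]]
    weak[12] <- setdiff(c("A", "C", "G", "T"), weak[12])[1]
    substr(tx, 150, 170) <- paste(weak, collapse = "")
    naive <- naive_site_scan(srna, tx, cutoff = 3)
    found <- find_candidate_sites(srna, data.frame(id = "t", sequence = tx),
                                  max_score = 3)
    # every naive hit is covered by a kept (deduplicated) site of equal or
    # better score, and all kept sites are naive hits
    idx <- match(found$start, naive$start)
    expect_false(anyNA(idx))
    expect_equal(found$score, naive$score[idx])
    expect_true(49 %in% found$start)
    expect_equal(found$score[found$start == 49], 0)
    expect_equal(found$cleavage_pos[found$start == 49], 49 + 21 - 9)
  }
})

test_that("site-cutoff behavior follows the expectation threshold", {
  srna <- "ACGTACGTACGTACGTACGTA"
  site <- strsplit(revcomp(srna), "")[[1]]
  site[21 - 10 + 1] <- "C"   # C opposite sRNA C: one seed mismatch, score 2
  tx <- paste0(strrep("T", 40), paste(site, collapse = ""), strrep("T", 40))
  hit3 <- find_candidate_sites(srna, tx, max_score = 3)
  expect_equal(nrow(hit3), 1L)
  expect_equal(hit3$score, 2)
  expect_equal(nrow(find_candidate_sites(srna, tx, max_score = 1)), 0L)
  expect_equal(nrow(find_candidate_sites(srna, strrep("A", 100))), 0L)
})

test_that("degradome categories partition sites by rank", {
  expect_equal(categorize_site(c(0, 9, 2, 2, 0), 2), 0L)  # unique maximum
  expect_equal(categorize_site(c(5, 5, 1), 1), 1L)        # tied maximum
  expect_equal(categorize_site(c(1, 0, 0), 1), 4L)        # single read
  # above the nonzero median but not maximal
  expect_equal(categorize_site(c(10, 4, 2, 2, 1), 2), 2L)
  # at or below the median
  expect_equal(categorize_site(c(10, 4, 2, 2, 1), 3), 3L)
  expect_true(is.na(categorize_site(c(1, 0, 3), 2)))      # read-free site
  expect_error(categorize_site(c(1, 2), 5), "outside")
  expect_error(categorize_site(c(0, 0), 1), "no reads")

  # partition property: every site with >= 1 read gets exactly one
  # category, agreeing with an independent restatement; category 0 implies
  # a strict maximum
  set.seed(31)
  for (i in 1:30) {
    prof <- rpois(20, 1.5)
    if (sum(prof) == 0) next
    for (pos in which(prof > 0)) {
      cat <- categorize_site(prof, pos)
      expect_true(cat %in% 0:4)
      expect_equal(cat, naive_category(prof, pos))
      if (cat == 0L) expect_true(all(prof[-pos] < prof[pos]))
    }
  }
})

test_that("dinucleotide shuffling preserves composition exactly", {
  set.seed(37)
  for (i in 1:15) {
    s <- random_dna(21)
    sh <- dinucleotide_shuffle(s, n = 5, seed = 100 + i)
    for (x in sh) {
      expect_equal(nchar(x), nchar(s))
      expect_equal(substr(x, 1, 1), substr(s, 1, 1))
      expect_equal(dinucleotide_counts(x), dinucleotide_counts(s))
    }
  }
  # homopolymers have a single Eulerian walk
  expect_equal(unique(dinucleotide_shuffle(strrep("A", 21), n = 10, seed = 1)),
               strrep("A", 21))
  # seeded draws are reproducible and do not disturb the caller's RNG
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- dinucleotide_shuffle("ACGTACGTACGTACGTACGTA", n = 3, seed = 7)
  b <- dinucleotide_shuffle("ACGTACGTACGTACGTACGTA", n = 3, seed = 7)
  expect_identical(a, b)
  expect_identical(runif(1), before)
})

test_that("the empirical cleavage p-value matches an independent recount", {
  set.seed(43)
  srna <- random_dna(21)
  tx1 <- random_dna(200); tx2 <- random_dna(200)
  substr(tx1, 60, 80) <- revcomp(srna)
  transcriptome <- data.frame(id = c("t1", "t2"), sequence = c(tx1, tx2),
                              biotype = "protein_coding")
  prof <- list(t1 = c(rpois(200, 0.3)), t2 = c(rpois(200, 0.3)))
  prof$t1[71] <- 25L   # strong peak at the expected cleavage position
  attr(prof, "library_size") <- sum(unlist(prof))
  obs <- list(score = 0, category = categorize_site(prof$t1, 71))

  n_sh <- 20L
  p <- cleavage_pvalue(obs, transcriptome, prof, srna,
                       n_shuffles = n_sh, seed = 99)
  # independent recount: regenerate the same shuffles, then qualify each
  # with the naive scanner and category restatement
  shuffles <- dinucleotide_shuffle(srna, n = n_sh, seed = 99)
  b <- 0L
  for (s in shuffles) {
    qual <- FALSE
    for (tx in c("t1", "t2")) {
      hits <- naive_site_scan(s, transcriptome$sequence[transcriptome$id == tx],
                              cutoff = obs$score)
      for (st in hits$start) {
        cat_i <- naive_category(prof[[tx]], st + 21 - 9)
        if (!is.na(cat_i) && cat_i <= obs$category) { qual <- TRUE; break }
      }
      if (qual) break
    }
    if (qual) b <- b + 1L
  }
  expect_equal(p, (1 + b) / (n_sh + 1))
  expect_gte(p, 1 / (n_sh + 1))

  # a homopolymer shuffles to itself, so every shuffle qualifies: p = 1
  homo <- strrep("A", 21)
  txh <- paste0(strrep("G", 60), strrep("T", 21), strrep("G", 60))
  profh <- list(th = integer(141)); profh$th[60 + 21 - 9] <- 10L
  attr(profh, "library_size") <- 10
  obs_h <- list(score = 0, category = 0L)
  expect_equal(cleavage_pvalue(obs_h, data.frame(id = "th", sequence = txh,
                                                 biotype = "protein_coding"),
                               profh, homo, n_shuffles = 10, seed = 5), 1)
})

test_that("call_targets applies the validity thresholds end to end", {
  set.seed(47)
  srna <- random_dna(21)
  tx <- random_dna(240)
  substr(tx, 101, 121) <- revcomp(srna)
  transcriptome <- data.frame(id = "tx", sequence = tx, biotype = "protein_coding")
  cleavage_at <- 100 + 21 - 9   # 1-based expected site
  mk_prof <- function(site_reads) {
    p <- list(tx = integer(240))
    p$tx[c(10, 50, 200)] <- c(2L, 1L, 3L)
    p$tx[cleavage_at] <- site_reads
    attr(p, "library_size") <- sum(unlist(p))
    p
  }
  srnas <- data.frame(srna_id = "q", sequence = srna, class = "miRNA",
                      family = "q")

  strong <- call_targets(srnas, transcriptome, mk_prof(10L),
                         n_shuffles = 30, seed = 7)
  expect_equal(nrow(strong), 1L)
  expect_true(strong$valid)
  expect_equal(strong$category, 0L)
  expect_equal(strong$site, cleavage_at)
  expect_equal(strong$site_reads, 10L)

  # identical event with only 4 site reads fails the >= 5 filter
  weak <- call_targets(srnas, transcriptome, mk_prof(4L),
                       n_shuffles = 30, seed = 7)
  expect_false(weak$valid)
  expect_equal(weak$category, 0L)

  # a below-median site (category 3) is invalid however significant
  buried <- mk_prof(2L)
  buried$tx[c(30, 60, 90, 140)] <- c(20L, 20L, 20L, 20L)
  bur <- call_targets(srnas, transcriptome, buried, n_shuffles = 30, seed = 7)
  expect_equal(bur$category, 3L)
  expect_false(bur$valid)
})

test_that("the validity rule itself is a pure threshold filter", {
  calls <- data.frame(category = c(0L, 2L, 3L, 0L, 1L, NA),
                      p_value = c(0.01, 0.05, 0.01, 0.051, NA, 0.01),
                      site_reads = c(5L, 5L, 50L, 10L, 10L, 10L))
  out <- validity_filter(calls)
  expect_equal(out$valid, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("T-plot export flags exactly the called sites", {
  prof <- c(0L, 3L, 0L, 9L, 1L)
  calls <- data.frame(transcript_id = c("t1", "t2"), site = c(4L, 2L))
  tp <- tplot_data(prof, calls, transcript_id = "t1")
  expect_equal(nrow(tp), 5L)
  expect_equal(tp$flagged, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(tp$count, prof)
  none <- tplot_data(prof, calls[0, ])
  expect_false(any(none$flagged))
  expect_error(tplot_data(integer(0), calls), "empty")
})
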