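# Seeded synthetic inputs with complete ground truth.
#
# The generator emulates the study design the pipeline targets: a
# de-etiolation time course (six time points W0..W24, three biological
# replicates), 21-nt phased read registers inside PHAS windows, degradome
# 5'-end peaks at canonical cleavage positions over sparse background
# decay, and the three light-response archetypes (induced from dark
# silence, gradual up, ~2-fold down by W24). Library sizes emulate ~20 M
# read libraries scaled down by `desk_scale` so tests run in seconds.

#' Configuration of the synthetic world
#'
#' @param seed Master seed; the three generator stages use `seed`,
#'   `seed + 1` and `seed + 2` so each stage is independently
#'   reproducible. Keep below 2^31 - 3.
#' @param n_transcripts Number of mRNA transcripts.
#' @param transcript_length Transcript length in nt.
#' @param n_mirnas Number of 21-nt miRNAs, each with one planted target
#'   site.
#' @param n_phas_loci Number of PHAS loci (each on its own noncoding
#'   reference).
#' @param phas_reference_length Length of each PHAS reference.
#' @param phase_fraction Fraction of locus read positions in the phased
#'   register (1 = perfect phasing, 1/21 ~ uniform).
#' @param reads_per_locus Distinct read positions per PHAS locus.
#' @param n_decoy_windows Unphased decoy references (251 nt each).
#' @param decoy_positions Distinct read positions per decoy window.
#' @param cluster_archetype_sizes Named counts of time-course features per
#'   light-response archetype `I` (induced from zero), `II` (gradual up),
#'   `III` (gradual down, ~2-fold by W24); defaults mirror the published
#'   66-miRNA set (1, 15, 50).
#' @param nb_dispersion Negative-binomial overdispersion of replicate
#'   counts (`variance = mu + dispersion * mu^2`); 0 gives noise-free
#'   rounded means.
#' @param degradome_signal Expected 5'-end reads at a planted cleavage
#'   site (Poisson mean).
#' @param degradome_noise Geometric background mean per transcript
#'   position.
#' @param n_light_only_events Planted cleavage events masked in the dark
#'   library (detectable only under light, like slicer-gene cleavage).
#' @param te_fraction Fraction of transcripts labeled transposable
#'   element.
#' @param desk_scale Library-size scale-down factor from ~20 M reads
#'   (default 1e4, i.e. ~2000-read libraries).
#' @param replicates Biological replicates per time point.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_transcripts = 30L,
                              transcript_length = 500L,
                              n_mirnas = 10L,
                              n_phas_loci = 5L,
                              phas_reference_length = 600L,
                              phase_fraction = 1.0,
                              reads_per_locus = 15L,
                              n_decoy_windows = 0L,
                              decoy_positions = 15L,
                              cluster_archetype_sizes = c(I = 1L, II = 15L, III = 50L),
                              nb_dispersion = 0.2,
                              degradome_signal = 10,
                              degradome_noise = 0.2,
                              n_light_only_events = 1L,
                              te_fraction = 0.15,
                              desk_scale = 1e4,
                              replicates = 3L) {
  stopifnot(phase_fraction >= 0, phase_fraction <= 1,
            n_transcripts >= 0, n_mirnas >= 0, n_phas_loci >= 0,
            nb_dispersion >= 0, degradome_signal >= 0, degradome_noise >= 0,
            te_fraction >= 0, te_fraction <= 1, replicates >= 1,
            all(cluster_archetype_sizes >= 0),
            all(c("I", "II", "III") %in% names(cluster_archetype_sizes)))
  structure(as.list(environment()), class = "simulation_config")
}

.random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

#' Generate the synthetic world: transcriptome, sRNA catalog, PHAS loci
#'
#' Builds random transcripts with planted miRNA target sites (exact
#' reverse complements, so the duplex scores 0 downstream), labels a
#' fraction as transposable elements, creates PHAS references carrying
#' 21-nt phased read registers at `phase_fraction` fidelity plus optional
#' unphased decoy windows, and groups the first six miRNAs into two
#' three-member families of identical sequence (the family-weighting
#' fixture). Every planted event is enumerated in the returned truth
#' tables. Byte-identical output for a fixed seed.
#'
#' @param config A [simulation_config()] object.
#' @return List with `transcripts`, `srnas`, `family_map`,
#'   `phas_references`, `decoy_references`, `alignments` (phased + decoy
#'   reads), `truth` (list of `targets`, `phas`, `decoys`) and `config`.
#' @export
simulate_world <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    margin <- 30L
    if (config$n_mirnas > 0L &&
        config$transcript_length < 21L + 2L * margin) {
      stop("transcript too short to place a target site")
    }
    transcripts <- data.frame(
      id = sprintf("TX%04d", seq_len(config$n_transcripts)),
      sequence = .random_seq(config$n_transcripts, config$transcript_length),
      biotype = rep("protein_coding", config$n_transcripts))
    n_te <- round(config$te_fraction * config$n_transcripts)
    if (n_te > 0L) {
      transcripts$biotype[sample.int(config$n_transcripts, n_te)] <-
        "transposable_element"
    }

    # miRNA catalog; first two triplets share a sequence (families)
    srnas <- data.frame(srna_id = character(), sequence = character(),
                        class = character(), family = character())
    if (config$n_mirnas > 0L) {
      seqs <- .random_seq(config$n_mirnas, 21L)
      fam <- sprintf("fam-%03d", seq_len(config$n_mirnas))
      if (config$n_mirnas >= 6L) {
        seqs[2:3] <- seqs[1L]; fam[1:3] <- "fam-001"
        seqs[5:6] <- seqs[4L]; fam[4:6] <- "fam-004"
      }
      srnas <- data.frame(srna_id = sprintf("syn-miR%03d", seq_len(config$n_mirnas)),
                          sequence = seqs, class = "miRNA", family = fam)
    }
    family_map <- split(srnas$srna_id, srnas$family)

    # plant one target site per miRNA, non-overlapping within a transcript
    targets <- data.frame(srna_id = character(), transcript_id = character(),
                          start = integer(), cleavage_pos = integer(),
                          light_only = logical())
    if (config$n_mirnas > 0L) {
      if (config$n_transcripts == 0L) stop("no transcripts to place sites on")
      tx_idx <- if (config$n_mirnas <= config$n_transcripts) {
        sample.int(config$n_transcripts, config$n_mirnas)
      } else {
        c(sample.int(config$n_transcripts, config$n_transcripts),
          sample.int(config$n_transcripts, config$n_mirnas - config$n_transcripts,
                     replace = TRUE))
      }
      occupied <- vector("list", config$n_transcripts)
      for (i in seq_len(config$n_mirnas)) {
        ti <- tx_idx[i]
        placed <- FALSE
        for (try in 1:50) {
          pos <- sample(margin:(config$transcript_length - 21L - margin), 1L)
          clash <- any(vapply(occupied[[ti]], function(iv) {
            pos < iv[2L] && (pos + 21L) > iv[1L]
          }, logical(1L)))
          if (!clash) { placed <- TRUE; break }
        }
        if (!placed) stop("transcript too short to place all target sites")
        occupied[[ti]] <- c(occupied[[ti]], list(c(pos, pos + 21L)))
        site <- revcomp(srnas$sequence[i])
        seq <- transcripts$sequence[ti]
        transcripts$sequence[ti] <- paste0(substr(seq, 1L, pos),
                                           site,
                                           substr(seq, pos + 22L, nchar(seq)))
        targets <- rbind(targets, data.frame(
          srna_id = srnas$srna_id[i], transcript_id = transcripts$id[ti],
          start = pos, cleavage_pos = pos + 12L,
          light_only = i <= config$n_light_only_events))
      }
    }

    # PHAS references with phased (and off-register) read positions
    phas_refs <- data.frame(id = character(), sequence = character(),
                            biotype = character())
    phas_truth <- data.frame(ref_id = character(), start = integer(),
                             end = integer(), register = integer())
    aln <- list()
    W <- 251L; L <- 21L
    add_reads <- function(ref_seq, ref_id, starts, strands) {
      counts <- sample(1:10, length(starts), replace = TRUE)
      data.frame(
        read_id = sprintf("%s_r%03d", ref_id, seq_along(starts)),
        sequence = vapply(seq_along(starts), function(j) {
          s <- substr(ref_seq, starts[j] + 1L, starts[j] + L)
          if (strands[j] == "-") revcomp(s) else s
        }, character(1L)),
        count = counts, ref_id = ref_id, start = starts,
        end = starts + L, strand = strands)
    }
    if (config$n_phas_loci > 0L) {
      stopifnot(config$phas_reference_length >= W + 2L * L)
      max_cycle <- (config$phas_reference_length - W) %/% L
      for (i in seq_len(config$n_phas_loci)) {
        ref_id <- sprintf("PHAS%03d", i)
        ref_seq <- .random_seq(1L, config$phas_reference_length)
        locus_start <- L * sample(2:max_cycle, 1L)
        # candidate register positions: plus-strand cuts at every cycle,
        # minus-strand 5' ends 2 nt 3' of the cut (read start = cut - 18)
        plus_starts <- locus_start + L * (0:11)
        minus_starts <- locus_start + L * (1:11) - 18L
        cand <- data.frame(start = c(plus_starts, minus_starts),
                           strand = rep(c("+", "-"), c(12L, 11L)))
        n_reads <- config$reads_per_locus
        n_in <- min(nrow(cand), round(config$phase_fraction * n_reads))
        sel <- cand[sample.int(nrow(cand), n_in), , drop = FALSE]
        n_off <- n_reads - n_in
        while (n_off > 0L) {
          st <- locus_start + sample.int(W - L, 1L) - 1L
          strand <- sample(c("+", "-"), 1L)
          ph <- .phase_coord(st, st + L, strand, locus_start, L)
          if (ph == 0L) next  # would land in the planted register
          if (any(sel$start == st & sel$strand == strand)) next
          sel <- rbind(sel, data.frame(start = st, strand = strand))
          n_off <- n_off - 1L
        }
        phas_refs <- rbind(phas_refs, data.frame(
          id = ref_id, sequence = ref_seq, biotype = "TAS_noncoding"))
        phas_truth <- rbind(phas_truth, data.frame(
          ref_id = ref_id, start = locus_start, end = locus_start + W,
          register = 0L))
        aln[[length(aln) + 1L]] <- add_reads(ref_seq, ref_id, sel$start, sel$strand)
      }
    }

    decoy_refs <- data.frame(id = character(), sequence = character(),
                             biotype = character())
    if (config$n_decoy_windows > 0L) {
      for (i in seq_len(config$n_decoy_windows)) {
        ref_id <- sprintf("DECOY%03d", i)
        ref_seq <- .random_seq(1L, W)
        starts <- sample.int(W - L, config$decoy_positions) - 1L
        strands <- sample(c("+", "-"), config$decoy_positions, replace = TRUE)
        decoy_refs <- rbind(decoy_refs, data.frame(
          id = ref_id, sequence = ref_seq, biotype = "other"))
        aln[[length(aln) + 1L]] <- add_reads(ref_seq, ref_id, starts, strands)
      }
    }

    alignments <- do.call(rbind, c(aln, list(data.frame(
      read_id = character(), sequence = character(), count = integer(),
      ref_id = character(), start = integer(), end = integer(),
      strand = character()))))
    rownames(alignments) <- NULL

    list(transcripts = transcripts,
         srnas = srnas,
         family_map = family_map,
         phas_references = phas_refs,
         decoy_references = decoy_refs,
         alignments = alignments,
         truth = list(targets = targets, phas = phas_truth,
                      decoys = decoy_refs$id),
         config = config)
  })
}

#' Simulate time-course replicate counts for the archetype features
#'
#' Counts are negative-binomial around archetype mean trajectories:
#' archetype I rises from a zero dark mean ("barely detectable in the
#' dark"), II climbs gradually, III declines to about half its dark level
#' by W24. Per-feature baselines are log-normal around the archetype base
#' mean. In the `nb_dispersion -> 0` limit, counts equal the rounded
#' means. Per-library totals (the 20-24 nt mapped totals used for RPM) are
#' the feature sums plus a Poisson background of unquantified mapped
#' reads.
#'
#' @param config A [simulation_config()] object.
#' @return List with `counts` (features x libraries raw-count matrix with
#'   `unit`, `lib_sizes` attributes; columns `W0_1` .. `W24_3`) and
#'   `truth` (per-feature archetype labels and the mean-trajectory
#'   matrix).
#' @export
simulate_timecourse_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed + 1L, {
    sizes <- config$cluster_archetype_sizes
    arch <- rep(c("I", "II", "III"), sizes[c("I", "II", "III")])
    n_feat <- length(arch)
    ids <- sprintf("mir-%s-%02d", arch, unlist(lapply(sizes[c("I", "II", "III")],
                                                      seq_len)))
    traj <- list(I = c(0, 0.3, 1.0, 1.6, 1.5, 2.0),
                 II = 2^c(0, 0.10, 0.25, 0.40, 0.60, 0.90),
                 III = 2^c(0, -0.10, -0.30, -0.50, -0.80, -1.00))
    base_mean <- c(I = 60, II = 50, III = 100)
    base <- base_mean[arch] * stats::rlnorm(n_feat, 0, 0.4)
    mu <- t(vapply(seq_len(n_feat), function(i) base[i] * traj[[arch[i]]],
                   numeric(length(TIME_POINTS))))
    dimnames(mu) <- list(ids, TIME_POINTS)
    libs <- as.vector(t(outer(TIME_POINTS, seq_len(config$replicates),
                              function(tp, r) paste0(tp, "_", r))))
    counts <- matrix(0L, n_feat, length(libs), dimnames = list(ids, libs))
    for (j in seq_along(libs)) {
      tp <- sub("_[0-9]+$", "", libs[j])
      m <- mu[, tp]
      counts[, j] <- if (config$nb_dispersion <= 0) {
        as.integer(round(m))
      } else {
        stats::rnbinom(n_feat, mu = m, size = 1 / config$nb_dispersion)
      }
    }
    background <- stats::rpois(length(libs), 20e6 / config$desk_scale)
    attr(counts, "unit") <- "raw_count"
    attr(counts, "lib_sizes") <- stats::setNames(colSums(counts) + background,
                                                 libs)
    list(counts = counts,
         truth = list(archetype = stats::setNames(arch, ids), mu = mu))
  })
}

#' Simulate dark and light degradome libraries
#'
#' Each transcript position receives geometric background reads (mean
#' `degradome_noise`); every planted cleavage event adds Poisson
#' (`degradome_signal`) reads at the position opposite sRNA position 10.
#' Events flagged `light_only` in the truth table contribute to the light
#' library only, emulating cleavage signatures detectable only after
#' irradiation.
#'
#' @param config A [simulation_config()] object.
#' @param world The matching [simulate_world()] result.
#' @return List with `dark` and `light` degradome profile lists (each a
#'   named list of per-position integer vectors with a `library_size`
#'   attribute).
#' @export
simulate_degradome <- function(config, world) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed + 2L, {
    targets <- world$truth$targets
    lens <- stats::setNames(nchar(world$transcripts$sequence),
                            world$transcripts$id)
    one_library <- function(mask_light_only) {
      profiles <- lapply(lens, function(len) {
        if (config$degradome_noise > 0) {
          stats::rgeom(len, prob = 1 / (1 + config$degradome_noise))
        } else {
          integer(len)
        }
      })
      for (i in seq_len(nrow(targets))) {
        if (mask_light_only && targets$light_only[i]) next
        id <- targets$transcript_id[i]
        pos <- targets$cleavage_pos[i]
        profiles[[id]][pos] <- profiles[[id]][pos] +
          stats::rpois(1L, config$degradome_signal)
      }
      attr(profiles, "library_size") <- sum(vapply(profiles, sum, numeric(1L)))
      profiles
    }
    list(dark = one_library(mask_light_only = TRUE),
         light = one_library(mask_light_only = FALSE))
  })
}
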