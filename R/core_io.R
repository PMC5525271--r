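# Readers and writers for every external format the pipeline touches.
#
# Coordinate convention: every interval held in memory is 0-based half-open
# [start, end); everything emitted as GFF3 is 1-based inclusive. Sequences
# are stored DNA-style (U -> T) and upper case.

#' Read a transcriptome FASTA
#'
#' Records are returned in file order with `U` bases normalized to `T` and
#' sequences upper-cased. The transcript biotype may be annotated in the
#' description line as a `biotype=<value>` token (one of `protein_coding`,
#' `TAS_noncoding`, `transposable_element`, `other`); records without the
#' token default to `protein_coding`, the usual case for a cDNA set.
#'
#' @param path Path to a FASTA file (gzip accepted).
#' @return A data frame with columns `id`, `sequence`, `biotype`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      biotype = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("Uu", "Tt", toupper(as.character(set)))
  if (any(!nzchar(seqs))) stop("empty sequence for id: ", ids[!nzchar(seqs)][1L])
  bio <- rep("protein_coding", length(ids))
  m <- regmatches(headers, regexpr("biotype=[A-Za-z_]+", headers))
  has <- grepl("biotype=", headers)
  bio[has] <- sub("^biotype=", "", m)
  bad <- !bio %in% c("protein_coding", "TAS_noncoding", "transposable_element", "other")
  if (any(bad)) stop("unknown biotype: ", paste(unique(bio[bad]), collapse = ", "))
  data.frame(id = ids, sequence = unname(seqs), biotype = bio)
}

#' Write transcripts to FASTA
#'
#' The biotype is carried in the description as a `biotype=` token so that
#' [read_fasta()] round-trips it.
#'
#' @param transcripts Data frame with columns `id`, `sequence` and
#'   optionally `biotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  stopifnot(all(c("id", "sequence") %in% names(transcripts)))
  set <- Biostrings::BStringSet(transcripts$sequence)
  names(set) <- if ("biotype" %in% names(transcripts)) {
    paste0(transcripts$id, " biotype=", transcripts$biotype)
  } else {
    transcripts$id
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a collapsed small-RNA read library
#'
#' The collapsed-FASTA dialect stores the read multiplicity as an integer
#' suffix on the header, `>name_<count>`. Sequences are upper-cased and
#' `U` normalized to `T`.
#'
#' @param path Path to a collapsed FASTA file.
#' @return Data frame with columns `read_id` (full header name), `sequence`,
#'   `count`.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">r1_17", "TTGACAGAAGATAGAGAGCAC"), f)
#' read_collapsed_reads(f)
#' @export
read_collapsed_reads <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      count = integer()))
  }
  ids <- sub("\\s.*$", "", names(set))
  m <- regmatches(ids, regexec("^(.*)_([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad)) {
    stop("collapsed-read header without integer count suffix: ",
         paste(ids[bad], collapse = ", "))
  }
  counts <- as.integer(vapply(m, `[`, character(1L), 3L))
  if (any(counts < 1L)) stop("collapsed-read count must be >= 1")
  data.frame(read_id = ids,
             sequence = chartr("Uu", "Tt", toupper(unname(as.character(set)))),
             count = counts)
}

#' Write a collapsed small-RNA read library
#'
#' @param reads Data frame with columns `sequence` and `count` (and
#'   optionally `read_id`; ids are regenerated to keep the `_count` suffix
#'   consistent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_reads <- function(reads, path) {
  stopifnot(all(c("sequence", "count") %in% names(reads)))
  base <- if ("read_id" %in% names(reads)) {
    sub("_[0-9]+$", "", reads$read_id)
  } else {
    sprintf("r%d", seq_len(nrow(reads)))
  }
  set <- Biostrings::BStringSet(reads$sequence)
  names(set) <- sprintf("%s_%d", base, as.integer(reads$count))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Collapse a FASTQ library to (sequence, count) records
#'
#' Plain FASTQ input is accepted and collapsed on load: identical read
#' sequences are merged and their multiplicity recorded, giving the same
#' shape as [read_collapsed_reads()]. Records are ordered by decreasing
#' count, ties broken alphabetically, so the result is deterministic.
#'
#' @param path Path to a FASTQ file.
#' @return Data frame with columns `read_id`, `sequence`, `count`.
#' @export
read_fastq_collapsed <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  if (length(set) == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      count = integer()))
  }
  tab <- table(as.character(set))
  ord <- order(-as.integer(tab), names(tab))
  seqs <- names(tab)[ord]
  counts <- as.integer(tab)[ord]
  data.frame(read_id = sprintf("r%d_%d", seq_along(seqs), counts),
             sequence = seqs, count = counts)
}

#' Write PHAS locus calls as GFF3
#'
#' Internal 0-based half-open window bounds become 1-based inclusive GFF3
#' columns 4 and 5. The hypergeometric p-value is carried in the attribute
#' column as `pvalue=` (C-style `%g` formatting, e.g. `3.4e-07`), together
#' with the distinct (`n`) and phased (`k`) alignment counts and, when
#' known, the trigger sRNA.
#'
#' @param calls Data frame as returned by [scan_phas()] (columns `ref_id`,
#'   `start`, `end`, `n`, `k`, `p_value`, optionally `trigger`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_gff3 <- function(calls, path) {
  lines <- "##gff-version 3"
  if (nrow(calls) > 0L) {
    stopifnot(all(c("ref_id", "start", "end", "n", "k", "p_value") %in% names(calls)))
    trigger <- if ("trigger" %in% names(calls)) calls$trigger else rep(NA_character_, nrow(calls))
    attrs <- sprintf("ID=phas_%04d;n=%d;k=%d;pvalue=%s",
                     seq_len(nrow(calls)), as.integer(calls$n),
                     as.integer(calls$k), sprintf("%g", calls$p_value))
    has_trig <- !is.na(trigger) & nzchar(trigger)
    attrs[has_trig] <- paste0(attrs[has_trig], ";trigger=", trigger[has_trig])
    lines <- c(lines, sprintf("%s\tdeetiolR\tsiRNA_locus\t%d\t%d\t.\t.\t.\t%s",
                              calls$ref_id, as.integer(calls$start) + 1L,
                              as.integer(calls$end), attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read degradome 5'-end profiles from a per-position TSV
#'
#' The TSV has a header row and three columns: `transcript_id`, `position`
#' (1-based transcript coordinate of an uncapped 5' end) and `count`.
#' Positions absent from the file hold zero reads. Every transcript in
#' `transcripts` receives a profile (possibly all-zero) whose length equals
#' the transcript length; the summed count is stored as the library size
#' used for RPM reporting.
#'
#' @param path Path to the TSV.
#' @param transcripts Transcriptome data frame from [read_fasta()].
#' @return A named list of integer vectors (one per transcript, 1-based
#'   positions) with attribute `library_size`.
#' @seealso [write_degradome_tsv()]
#' @export
read_degradome_tsv <- function(path, transcripts) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "position", "count") %in% names(tab)))
  lens <- nchar(transcripts$sequence)
  names(lens) <- transcripts$id
  unknown <- setdiff(tab$transcript_id, transcripts$id)
  if (length(unknown) > 0L) {
    stop("degradome rows for unknown transcript(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  if (any(tab$count < 0)) stop("degradome counts must be non-negative")
  profiles <- lapply(transcripts$id, function(id) integer(lens[[id]]))
  names(profiles) <- transcripts$id
  for (i in seq_len(nrow(tab))) {
    id <- tab$transcript_id[i]
    pos <- tab$position[i]
    if (pos < 1L || pos > lens[[id]]) {
      stop("position ", pos, " outside transcript ", id)
    }
    profiles[[id]][pos] <- profiles[[id]][pos] + as.integer(tab$count[i])
  }
  attr(profiles, "library_size") <- sum(tab$count)
  profiles
}

#' Write degradome profiles as a per-position TSV
#'
#' Only positions with nonzero counts are written; [read_degradome_tsv()]
#' restores the zero positions, so the pair round-trips exactly.
#'
#' @param profiles Named list of per-position count vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_degradome_tsv <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    nz <- which(profiles[[id]] > 0L)
    if (length(nz) == 0L) return(NULL)
    data.frame(transcript_id = id, position = nz, count = profiles[[id]][nz])
  })
  tab <- do.call(rbind, c(rows, list(data.frame(transcript_id = character(),
                                                position = integer(),
                                                count = integer()))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
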