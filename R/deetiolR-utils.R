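# Internal helpers shared across modules.

# Integer encoding of nucleotides; 5 marks a scan separator that can never
# pair (used to keep sliding windows from crossing transcript boundaries).
.NT <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.encode_nt <- function(seq) {
  x <- .NT[strsplit(toupper(seq), "", fixed = TRUE)[[1L]]]
  if (anyNA(x)) stop("sequence contains non-ACGT characters")
  unname(x)
}

#' Reverse complement of a DNA string
#'
#' Convenience wrapper for plain character vectors; `U` is treated as `T`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- chartr("Uu", "Tt", s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards so seeded package functions
# do not disturb user-level random streams. seed = NULL uses the current
# stream untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Two-sample two-sided t-test robust to degenerate (zero-variance) inputs:
# both groups constant and equal -> p = 1; constant but different -> p = 0.
.t_test_safe <- function(x, y, var_equal = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

# Split expression-matrix library names "W3_2" into time point / replicate.
.parse_lib_names <- function(libs) {
  m <- regmatches(libs, regexec("^(W[0-9]+)_([0-9]+)$", libs))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad)) {
    stop("library names must look like '<time>_<replicate>', e.g. 'W3_2'; bad: ",
         paste(libs[bad], collapse = ", "))
  }
  data.frame(lib = libs,
             time_point = vapply(m, `[`, character(1L), 2L),
             replicate = as.integer(vapply(m, `[`, character(1L), 3L)))
}
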