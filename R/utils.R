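# Internal sequence helpers shared across modules. Sequences are plain
# upper-case character scalars internally; Biostrings objects are used at
# the I/O boundary and for pattern matching.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# vectorised character-level accessor
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# run-length decomposition of a DNA string into alternating A-runs and
# non-A chunks; returns data.frame(start, end, a_run, string)
chunk_a_runs <- function(x) {
  if (nchar(x) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      a_run = logical(), string = character(),
                      stringsAsFactors = FALSE))
  }
  ch <- seq_chars(x)
  is_a <- ch == "A"
  r <- rle(is_a)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(
    start = start, end = end, a_run = r$values,
    string = vapply(seq_along(start),
                    function(i) substr(x, start[i], end[i]), ""),
    stringsAsFactors = FALSE
  )
}

# Hamming distance between equal-length strings (Inf if lengths differ)
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(seq_chars(a) != seq_chars(b))
}

# longest k <= max_len such that the length-k suffix of `left` equals the
# length-k prefix of `right` (the two junction-anchored copies of a direct
# repeat); substring equality must be rechecked per k because the character
# alignment shifts with the candidate length
anchored_repeat_len <- function(left, right, max_len) {
  kmax <- min(nchar(left), nchar(right), max_len)
  if (kmax < 1L) return(0L)
  nl <- nchar(left)
  for (k in kmax:1) {
    if (substr(left, nl - k + 1L, nl) == substr(right, 1L, k))
      return(as.integer(k))
  }
  0L
}

# length of the leading A-run of a string
leading_a <- function(x) {
  m <- regmatches(x, regexpr("^A*", x))
  nchar(m)
}

trailing_a <- function(x) {
  m <- regmatches(x, regexpr("A*$", x))
  nchar(m)
}

# sample n bases at a GC fraction
random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

random_seq <- function(n, gc) paste(random_bases(n, gc), collapse = "")

# write a named character vector of sequences as FASTA
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

# seed-stamped header comment for tabular outputs
output_header <- function(seed, what) {
  sprintf("# tailslip %s | %s | seed=%s",
          as.character(utils::packageVersion("tailslip")), what,
          if (is.null(seed)) "NA" else as.character(seed))
}

write_tsv_with_header <- function(df, path, seed = NULL, what = "table") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, what), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
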