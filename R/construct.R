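# Tagged-construct model: disruption-tagged A-tail templates and the
# construct reference (SINE body + tail + optional unique 3' region).

#' Create a disruption-tagged A-tail template
#'
#' A tail template describes the parental A-tail of a tagged SINE rescue
#' construct: an ordered run of polyA segments separated by short non-A
#' "disruption" strings. The disruptions act as sequence landmarks that make
#' TPRT priming location and reverse-transcription slippage observable in
#' recovered inserts.
#'
#' @param name label for the template (e.g. \code{"A70D"}).
#' @param segments integer vector of polyA segment lengths (nt), 5' to 3'.
#' @param disruptions character vector of non-A strings placed between
#'   consecutive segments; must have \code{length(segments) - 1} elements
#'   (or 0 for a single-segment homopolymer template).
#' @return an object of class \code{tail_template}.
#' @examples
#' tail_template("A30D", c(10, 10, 10), c("CT", "TAC"))
#' @export
tail_template <- function(name, segments, disruptions = character()) {
  segments <- as.integer(segments)
  disruptions <- toupper(as.character(disruptions))
  if (length(segments) < 1L || any(is.na(segments)) || any(segments < 0L))
    stop("`segments` must be non-negative integers")
  if (length(disruptions) != length(segments) - 1L)
    stop("need exactly length(segments) - 1 disruptions")
  if (length(disruptions)) {
    if (any(nchar(disruptions) == 0L))
      stop("disruptions must be non-empty")
    if (any(grepl("A{4,}", disruptions)))
      stop("disruptions must not contain runs of >= 4 A's")
    if (any(grepl("^A|A$", disruptions)))
      stop("disruptions must not start or end with A (flanking A's are ",
           "indistinguishable from segment adenosines)")
    if (any(grepl("[^ACGT]", disruptions)))
      stop("disruptions must be DNA over A/C/G/T")
  }
  structure(
    list(name = as.character(name), segments = segments,
         disruptions = disruptions),
    class = "tail_template"
  )
}

#' @export
print.tail_template <- function(x, ...) {
  cat(sprintf("<tail_template %s> %d segments [%s]",
              x$name, length(x$segments),
              paste(x$segments, collapse = ",")))
  if (length(x$disruptions))
    cat(sprintf(" disruptions {%s}", paste(x$disruptions, collapse = ",")))
  cat(sprintf(" rendered %d nt\n", rendered_length(x)))
  invisible(x)
}

rendered_length <- function(template) {
  sum(template$segments) + sum(nchar(template$disruptions))
}

#' Built-in tail templates
#'
#' \code{"A70D"} is the long construct tail: four polyA segments of 17 or 18
#' adenosines (default order 17, 18, 17, 18; 70 A total) separated by the
#' disruptions CATTAC, G and CACAC, rendering to 82 nt. \code{"A30D"} is the
#' short tail: three segments of 10 adenosines separated by CT and TAC,
#' rendering to 35 nt. The per-segment order of 17 vs 18 in A70D is not fixed
#' by the published composition (only the per-segment range and the 82-nt
#' total are); pass \code{a70d_order} to permute it.
#'
#' @param name one of \code{"A70D"}, \code{"A30D"}.
#' @param a70d_order integer vector of four segment lengths summing to 70,
#'   each 17 or 18; only used for \code{"A70D"}.
#' @return a \code{\link{tail_template}}.
#' @examples
#' nchar(render_tail(builtin_template("A70D")))  # 82
#' nchar(render_tail(builtin_template("A30D")))  # 35
#' @export
builtin_template <- function(name, a70d_order = c(17L, 18L, 17L, 18L)) {
  switch(
    name,
    A70D = {
      a70d_order <- as.integer(a70d_order)
      if (length(a70d_order) != 4L || !all(a70d_order %in% c(17L, 18L)) ||
          sum(a70d_order) != 70L)
        stop("a70d_order must be four values of 17 or 18 summing to 70")
      tail_template("A70D", a70d_order, c("CATTAC", "G", "CACAC"))
    },
    A30D = tail_template("A30D", c(10L, 10L, 10L), c("CT", "TAC")),
    stop(sprintf("unknown tail template '%s'", name))
  )
}

#' Render a tail template to its nucleotide sequence
#'
#' Concatenates \code{A^s1 + d1 + A^s2 + ...}; the rendered length is
#' \code{sum(segments) + sum(nchar(disruptions))}.
#'
#' @param template a \code{\link{tail_template}}.
#' @return character scalar DNA sequence.
#' @export
render_tail <- function(template) {
  stopifnot(inherits(template, "tail_template"))
  n <- length(template$segments)
  parts <- character(2L * n - 1L)
  parts[seq(1L, 2L * n - 1L, by = 2L)] <-
    vapply(template$segments, function(s) strrep("A", s), "")
  if (n > 1L)
    parts[seq(2L, 2L * n - 2L, by = 2L)] <- template$disruptions
  paste(parts, collapse = "")
}

#' Read a tail template from a YAML definition file
#'
#' The file carries \code{name}, \code{segments} and \code{disruptions}
#' keys, so that tails of other tagged SINEs (e.g. B2, BC1 constructs) can
#' be analyzed with the same machinery.
#'
#' @param path path to a YAML file.
#' @return a \code{\link{tail_template}}.
#' @export
read_tail_template <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$segments))
    stop("template file must define `name` and `segments`")
  tail_template(y$name, unlist(y$segments),
                unlist(y$disruptions) %||% character())
}

#' Write a tail template to a YAML definition file
#' @param template a \code{\link{tail_template}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tail_template <- function(template, path) {
  yaml::write_yaml(
    list(name = template$name,
         segments = as.integer(template$segments),
         disruptions = as.list(template$disruptions)),
    path)
  invisible(path)
}

# Fixed synthetic SINE body used by the default construct: 286 nt with a
# single internal A-rich run (positions 137-144) standing in for the A-rich
# linker of a left+right Alu monomer pair. Free of TTTTAA/TTAAAA and of
# terminal A's so body/tail and junction boundaries stay unambiguous.
TAILSLIP_BODY <- paste0(
  "GGCCGGTAGTTGTGCTAACTTGCGCAATGGACTTCCGAAAGGTAGGGGCGCAAAATTACCGCCTGGCGCT",
  "AAAGAGGCGGGCCATGTCCGTGGTGTTTCACTCCAGGCGTGTCCCTTTCCTACTGAGTCCTACTCGAAAA",
  "AAAACGCTGGTGGCGGAGTGCAAGGCCGAGCATCTCAGACACGGTCCACTTACCCCTTGGACCTGCATAG",
  "AGATGCCAGTATCACGGCCGCCCCGAGACTGTCCCAGGAGACGGCGGATCGATCACGTTCGTGATAGACA",
  "CAGTCG")

#' Locate the A-rich middle of a SINE body
#'
#' Returns the longest internal run of at least \code{min_run} consecutive
#' A's, as a 1-based inclusive \code{c(start, end)} interval. This region is
#' masked in body mismatch scans because its length is unstable through
#' cloning and alignment there is unreliable.
#'
#' @param body character scalar DNA sequence.
#' @param min_run minimum run length considered A-rich (default 6).
#' @return integer vector \code{c(start, end)}, or \code{NULL} if no
#'   qualifying run exists.
#' @export
find_a_rich_middle <- function(body, min_run = 6L) {
  m <- gregexpr(sprintf("A{%d,}", min_run), body)[[1]]
  if (m[1] == -1L) return(NULL)
  len <- attr(m, "match.length")
  i <- which.max(len)
  c(as.integer(m[i]), as.integer(m[i]) + len[i] - 1L)
}

#' Create a construct reference
#'
#' Bundles the tagged SINE body (everything 5' of the A-tail), the parental
#' tail template, an optional unique region 3' of the tail (such as the BC1
#' "u" region used for 3' RACE priming), and the A-rich middle interval of
#' the body that mismatch scans exclude.
#'
#' @param body DNA sequence of the tagged SINE upstream of the tail.
#' @param tail a \code{\link{tail_template}}.
#' @param unique_3p optional DNA sequence placed 3' of the tail.
#' @param a_rich_middle optional \code{c(start, end)} 1-based interval in
#'   the body to mask; defaults to the longest internal run of >= 6 A's.
#' @return an object of class \code{construct_reference}.
#' @export
construct_reference <- function(body, tail, unique_3p = NULL,
                                a_rich_middle = NULL) {
  stopifnot(inherits(tail, "tail_template"))
  body <- toupper(body)
  if (nchar(body) == 0L) stop("body must be non-empty")
  if (is.null(a_rich_middle)) a_rich_middle <- find_a_rich_middle(body)
  if (!is.null(a_rich_middle)) {
    a_rich_middle <- as.integer(a_rich_middle)
    if (length(a_rich_middle) != 2L || a_rich_middle[1] < 1L ||
        a_rich_middle[2] > nchar(body) ||
        a_rich_middle[1] > a_rich_middle[2])
      stop("a_rich_middle must lie within body bounds")
  }
  structure(
    list(body = body, tail = tail,
         unique_3p = if (is.null(unique_3p)) NULL else toupper(unique_3p),
         a_rich_middle = a_rich_middle),
    class = "construct_reference"
  )
}

#' Default tagged-construct reference
#'
#' A synthetic 286-nt SINE body joined to a built-in tail template. The body
#' sequence is a fixed pseudo-SINE (not a natural Alu) with one internal
#' A-rich run; it plays the role of the tagged element for simulation and
#' round-trip testing.
#'
#' @param template_name \code{"A70D"} (default) or \code{"A30D"}.
#' @return a \code{\link{construct_reference}}.
#' @export
default_construct <- function(template_name = "A70D") {
  construct_reference(TAILSLIP_BODY, builtin_template(template_name))
}

#' Full element sequence of a construct
#'
#' @param construct a \code{\link{construct_reference}}.
#' @return body + rendered tail (+ unique 3' region if present).
#' @export
construct_sequence <- function(construct) {
  stopifnot(inherits(construct, "construct_reference"))
  paste0(construct$body, render_tail(construct$tail),
         construct$unique_3p %||% "")
}
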