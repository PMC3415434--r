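# TPRT insertion simulator: endonuclease target-site choice, priming-offset
# selection, slippage-prone reverse transcription of the A-tail, target-site
# duplication formation, and the two atypical resolution modes (chimeric
# recombination, endonuclease-independent insertion).

#' Slippage-model parameters
#'
#' Parameters of the replication-slippage model of reverse transcription
#' over the homopolymeric A-tail. Priming is disallowed within the first
#' \code{min_prime_offset} nt of the tail (5' coordinate). Before each
#' incorporated nucleotide the nascent cDNA dissociates with probability
#' \code{p_dissoc0 * exp(-L / decay_scale)} where L is the current cDNA
#' length: slippage is frequent early and vanishes as base pairing
#' stabilizes the duplex. A dissociation re-anneals 3'-ward on the RNA with
#' probability \code{p_duplicate} (re-copying, i.e. duplicating, template
#' positions) and 5'-ward otherwise (deleting them); the re-anneal span is
#' drawn from a truncated geometric distribution.
#'
#' @param min_prime_offset nt from the tail 5' end below which priming is
#'   disallowed (default 20).
#' @param p_dissoc0 per-nucleotide dissociation probability at cDNA length
#'   0 (default 0.7).
#' @param decay_scale cDNA-length scale (nt) of the exponential decay of
#'   the dissociation probability (default 40).
#' @param p_duplicate probability that a slip re-anneals 3'-ward,
#'   duplicating template positions (default 0.9).
#' @param slip_span_mean mean of the geometric re-anneal span (default 3).
#' @param slip_span_max truncation of the span distribution (default 10).
#' @param p_cross_disruption probability that a slip whose span crosses a
#'   non-A template position completes (default 0.05). Re-annealing pairs
#'   the nascent poly-T cDNA with the polyA tract; a register shift across
#'   a disruption requires fortuitous base pairing, so disruptions anchor
#'   the register and duplicated disruptions stay rare even under strong
#'   within-run expansion.
#' @return list of class \code{slippage_params}.
#' @export
slippage_params <- function(min_prime_offset = 20L, p_dissoc0 = 0.7,
                            decay_scale = 40, p_duplicate = 0.9,
                            slip_span_mean = 3, slip_span_max = 10L,
                            p_cross_disruption = 0.05) {
  stopifnot(min_prime_offset >= 0L, p_dissoc0 >= 0, p_dissoc0 <= 1,
            decay_scale > 0, p_duplicate >= 0, p_duplicate <= 1,
            slip_span_mean > 0, slip_span_max >= 1L,
            p_cross_disruption >= 0, p_cross_disruption <= 1)
  structure(list(min_prime_offset = as.integer(min_prime_offset),
                 p_dissoc0 = p_dissoc0, decay_scale = decay_scale,
                 p_duplicate = p_duplicate,
                 slip_span_mean = slip_span_mean,
                 slip_span_max = as.integer(slip_span_max),
                 p_cross_disruption = p_cross_disruption),
            class = "slippage_params")
}

draw_slip_span <- function(params) {
  # geometric with the requested mean, truncated at slip_span_max
  p <- 1 / params$slip_span_mean
  s <- stats::rgeom(1L, p) + 1L
  min(s, params$slip_span_max)
}

# endonuclease consensus match scores for an insertion gap immediately
# before 1-based position i of a top-strand sequence:
#   plus strand (element sense = top): bottom-strand hexamer spanning the
#     nick is revcomp(top[i-2 .. i+3]); matches to TTTTAA equal positionwise
#     matches of top[i-2 .. i+3] to TTAAAA
#   minus strand: the nicked strand is the top strand, window
#     top[i-4 .. i+1] scored against TTTTAA directly
en_site_scores <- function(chrom_seq) {
  ch <- seq_chars(chrom_seq)
  n <- length(ch)
  score_window <- function(offsets, target) {
    s <- integer(n)
    for (k in seq_along(offsets)) {
      idx <- seq_len(n) + offsets[k]
      ok <- idx >= 1L & idx <= n
      v <- logical(n)
      v[ok] <- ch[idx[ok]] == target[k]
      s <- s + v
    }
    s
  }
  list(plus = score_window(-2:3, c("T", "T", "A", "A", "A", "A")),
       minus = score_window(-4:1, c("T", "T", "T", "T", "A", "A")))
}

#' Select an endonuclease target site
#'
#' Scans both orientations of every chromosome for windows resembling the
#' L1 endonuclease consensus 5'-TTTT/AA-3' (cleavage between T4 and A1 on
#' the nicked strand) and samples one insertion point, weighted by
#' consensus match score among sites scoring at least \code{min_score} of
#' 6. The returned position is the base 5' of the insertion gap on the top
#' strand; strand is the element orientation implied by the better-scoring
#' window.
#'
#' @param genome a \code{\link{generate_genome}} result or a named
#'   character vector of chromosome sequences.
#' @param min_score minimum consensus matches (of 6) for a candidate site
#'   (default 6: perfect sites only).
#' @param n number of sites to draw (without replacement; default 1).
#' @param edge_margin bases excluded at chromosome ends so flanks fit.
#' @param seed optional integer seed.
#' @return data.frame with columns chrom, pos (1-based base 5' of the
#'   insertion gap), strand, score.
#' @export
select_target_site <- function(genome, min_score = 6L, n = 1L,
                               edge_margin = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- if (inherits(genome, "synthetic_genome"))
    genome$chromosomes else genome
  cand <- list()
  for (cn in names(chroms)) {
    sc <- en_site_scores(chroms[[cn]])
    L <- nchar(chroms[[cn]])
    ok_range <- function(i) i > edge_margin & i <= L - edge_margin
    for (str in c("plus", "minus")) {
      idx <- which(sc[[str]] >= min_score)
      idx <- idx[ok_range(idx)]
      if (length(idx))
        cand[[length(cand) + 1L]] <- data.frame(
          chrom = cn, pos = idx - 1L,  # gap before idx = after pos idx-1
          strand = if (str == "plus") "+" else "-",
          score = sc[[str]][idx], stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    stop("no endonuclease site above threshold in the genome")
  cand <- do.call(rbind, cand)
  # a gap can qualify on both strands; keep the better-scoring orientation
  key <- paste(cand$chrom, cand$pos)
  cand <- cand[order(key, -cand$score), ]
  cand <- cand[!duplicated(paste(cand$chrom, cand$pos)), ]
  if (n > nrow(cand))
    stop(sprintf("requested %d sites but only %d available", n, nrow(cand)))
  w <- cand$score - min(cand$score) + 1
  take <- sample.int(nrow(cand), n, prob = w)
  out <- cand[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reverse-transcribe a tail template with slippage
#'
#' Draws a priming position uniformly over the tail's adenosine positions
#' greater than \code{min_prime_offset} (so priming uses only the 3'
#' portion of the tail), then copies the template 3'->5' from that
#' position. Before each
#' incorporated nucleotide a slip occurs with probability
#' \code{p_dissoc0 * exp(-L/decay_scale)}; a slip re-positions the
#' polymerase 3'-ward (duplicating already-copied template positions, with
#' probability \code{p_duplicate}) or 5'-ward (deleting positions). With
#' \code{p_dissoc0 = 0} the realized tail is exactly the template prefix
#' up to the priming position.
#'
#' @param template a \code{\link{tail_template}}.
#' @param params a \code{\link{slippage_params}}.
#' @param primed_position optional fixed priming position (1-based nt from
#'   the tail 5' end); drawn if \code{NULL}.
#' @param seed optional integer seed.
#' @return list with \code{realized_tail}, \code{primed_position},
#'   \code{slip_events} (data.frame: cdna_len, kind, span, substring).
#' @export
reverse_transcribe_tail <- function(template, params = slippage_params(),
                                    primed_position = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(template, "tail_template"),
            inherits(params, "slippage_params"))
  rendered <- render_tail(template)
  L <- nchar(rendered)
  if (L <= params$min_prime_offset)
    stop("rendered template length must exceed min_prime_offset")
  if (is.null(primed_position)) {
    # priming anneals the T-rich primer to the polyA tract, so only
    # adenosines inside polyA segments (not disruption-internal A's)
    # beyond the excluded 5' prefix are eligible
    segs <- template$segments
    d_len <- nchar(template$disruptions)
    seg_start <- cumsum(c(0L, segs[-length(segs)] + d_len)) + 1L
    eligible <- unlist(Map(function(s, w) seq(s, length.out = w),
                           seg_start, segs))
    eligible <- eligible[eligible > params$min_prime_offset]
    if (!length(eligible))
      stop("no eligible priming position beyond min_prime_offset")
    primed_position <- if (length(eligible) == 1L) eligible
                       else sample(eligible, 1L)
  }
  x <- as.integer(primed_position)
  stopifnot(x >= 1L, x <= L)

  tmpl <- seq_chars(rendered)
  visited <- integer(0)
  events <- list()
  p <- x
  cdna <- 0L
  while (p >= 1L) {
    pr <- params$p_dissoc0 * exp(-cdna / params$decay_scale)
    if (pr > 0 && stats::runif(1) < pr) {
      span <- draw_slip_span(params)
      # a slip crossing a non-A template position loses the poly-T/polyA
      # register and usually aborts
      crosses <- function(a, b) any(tmpl[a:b] != "A")
      if (stats::runif(1) < params$p_duplicate) {
        p2 <- min(x, p + span)
        ok <- p2 > p && (!crosses(p + 1L, p2) ||
                           stats::runif(1) < params$p_cross_disruption)
        if (ok) {
          events[[length(events) + 1L]] <- data.frame(
            cdna_len = cdna, kind = "duplication", span = p2 - p,
            substring = paste(tmpl[(p + 1L):p2], collapse = ""),
            stringsAsFactors = FALSE)
          p <- p2
        }
      } else {
        p2 <- max(1L, p - span)
        ok <- p2 < p && (!crosses(p2, p - 1L) ||
                           stats::runif(1) < params$p_cross_disruption)
        if (ok) {
          events[[length(events) + 1L]] <- data.frame(
            cdna_len = cdna, kind = "deletion", span = p - p2,
            substring = paste(tmpl[(p2 + 1L):p], collapse = ""),
            stringsAsFactors = FALSE)
          p <- p2
        }
      }
    }
    visited <- c(visited, p)
    p <- p - 1L
    cdna <- cdna + 1L
  }
  realized <- paste(tmpl[rev(visited)], collapse = "")
  list(realized_tail = realized, primed_position = x,
       slip_events = if (length(events)) do.call(rbind, events)
                     else data.frame(cdna_len = integer(),
                                     kind = character(), span = integer(),
                                     substring = character(),
                                     stringsAsFactors = FALSE))
}

#' Replay recorded slip events on a template
#'
#' Deterministically reproduces the realized tail from the template, the
#' priming position and the slip-event list (slippage conservation: the
#' realized tail is fully determined by the events).
#'
#' @param template a \code{\link{tail_template}}.
#' @param primed_position priming position used.
#' @param slip_events the event data.frame from
#'   \code{\link{reverse_transcribe_tail}}.
#' @return character scalar, the reconstructed realized tail.
#' @export
replay_slippage <- function(template, primed_position, slip_events) {
  tmpl <- seq_chars(render_tail(template))
  x <- as.integer(primed_position)
  visited <- integer(0)
  p <- x
  cdna <- 0L
  ev <- slip_events
  ei <- 1L
  while (p >= 1L) {
    if (ei <= nrow(ev) && ev$cdna_len[ei] == cdna) {
      if (ev$kind[ei] == "duplication") p <- min(x, p + ev$span[ei])
      else p <- max(0L, p - ev$span[ei])
      ei <- ei + 1L
      if (p < 1L) break
    }
    visited <- c(visited, p)
    p <- p - 1L
    cdna <- cdna + 1L
  }
  paste(tmpl[rev(visited)], collapse = "")
}

# Clean-junction edits on the local pre/post flanks so that junction
# boundaries are unambiguous regardless of TSD-assignment policy:
#  - the base immediately 3' of the duplicated target (rest[1]) must not be
#    'A' (else the tail would absorb it) and must differ from the last base
#    of the 5' flank (else the anchored repeat would extend by chance)
#  - the last base of the 5' flank must not be 'A'
clean_junction_flanks <- function(flank5, flank3, tsd_len) {
  f5 <- seq_chars(flank5)
  f3 <- seq_chars(flank3)
  # an 'A' at the 5' junction would be claimed by tail/TSD boundary logic
  if (length(f5) && f5[length(f5)] == "A") f5[length(f5)] <- "C"
  ri <- tsd_len + 1L
  if (ri <= length(f3)) {
    if (f3[ri] == "A") f3[ri] <- "G"
    if (length(f5) && f3[ri] == f5[length(f5)])
      f3[ri] <- setdiff(c("C", "G", "T"), f5[length(f5)])[1L]
  }
  list(flank5 = paste(f5, collapse = ""), flank3 = paste(f3, collapse = ""))
}

#' Integrate a reverse-transcribed element at a target site
#'
#' Builds the post-insertion locus
#' \code{5'flank + TSD + body(5'-truncated if drawn) + realized_tail + TSD
#' + 3'flank}, with the target-site duplication taken from the sequence 3'
#' of the cleavage point. For minus-strand insertions the element (body +
#' tail) is reverse-complemented before insertion. Junction-adjacent bases
#' of the local flank copies are edited (\code{clean_junctions}) so that
#' TSD and tail boundaries are exactly recoverable; the genome itself is
#' never modified.
#'
#' @param genome a \code{synthetic_genome} or named character vector.
#' @param site one row of \code{\link{select_target_site}} output.
#' @param construct a \code{\link{construct_reference}}.
#' @param realized_tail tail sequence from
#'   \code{\link{reverse_transcribe_tail}}.
#' @param tsd_len target-site duplication length (nt).
#' @param truncation_5p nt removed from the body 5' end (default 0).
#' @param flank nt of genomic flank kept on each side (default 500).
#' @param clean_junctions edit junction-adjacent flank bases for exact
#'   recoverability (default TRUE).
#' @param a_policy junction A-assignment convention used for the recorded
#'   ground truth: \code{"tail"} (junction-adjacent A's belong to the
#'   tail; default) or \code{"tsd"}.
#' @return list with \code{pre_locus}, \code{post_locus}, and a
#'   \code{truth} list (canonical tsd_len/tsd_seq under \code{a_policy},
#'   drawn tsd_len, truncation, strand, terminal_extra_a, tail_seq).
#' @export
integrate_insertion <- function(genome, site, construct, realized_tail,
                                tsd_len, truncation_5p = 0L, flank = 500L,
                                clean_junctions = TRUE,
                                a_policy = c("tail", "tsd")) {
  a_policy <- match.arg(a_policy)
  stopifnot(inherits(construct, "construct_reference"))
  chroms <- if (inherits(genome, "synthetic_genome"))
    genome$chromosomes else genome
  seqc <- chroms[[site$chrom]]
  pos <- site$pos
  tsd_len <- as.integer(tsd_len)
  flank5 <- substr(seqc, max(1L, pos - flank + 1L), pos)
  flank3 <- substr(seqc, pos + 1L, min(nchar(seqc), pos + flank))
  if (nchar(flank3) < tsd_len) stop("3' flank shorter than TSD length")
  if (clean_junctions) {
    cj <- clean_junction_flanks(flank5, flank3, tsd_len)
    flank5 <- cj$flank5; flank3 <- cj$flank3
  }
  tsd <- substr(flank3, 1L, tsd_len)
  body <- construct$body
  if (truncation_5p >= nchar(body) - 30L)
    stop("truncation leaves too little body to anchor")
  insert_elem <- paste0(substr(body, truncation_5p + 1L, nchar(body)),
                        realized_tail, construct$unique_3p %||% "")
  oriented <- if (site$strand == "-") revcomp(insert_elem) else insert_elem
  post <- paste0(flank5, tsd, oriented, flank3)
  pre <- paste0(flank5, flank3)

  # canonical ground truth in element orientation: junction A-absorption
  # applies to the sequence immediately 3' of the element's tail
  after_elem <- if (site$strand == "-") revcomp(paste0(flank5, tsd))
                else flank3
  extra_a <- if (a_policy == "tail") leading_a(substr(after_elem, 1L,
                                                      tsd_len + 50L)) else 0L
  # the absorbed A's are a prefix of the (oriented) TSD copy
  tsd_elem <- if (site$strand == "-") revcomp(tsd) else tsd
  extra_a <- min(extra_a, nchar(tsd_elem))
  truth <- list(
    tsd_len_drawn = tsd_len,
    tsd_len = tsd_len - extra_a,
    tsd_seq = substr(tsd_elem, extra_a + 1L, nchar(tsd_elem)),
    terminal_extra_a = extra_a,
    tail_seq = paste0(realized_tail, strrep("A", extra_a)),
    truncation_5p = as.integer(truncation_5p),
    strand = site$strand, chrom = site$chrom, pos = pos,
    en_score = site$score)
  list(pre_locus = pre, post_locus = post, truth = truth)
}

#' Simulate an atypical insertion
#'
#' \code{chimeric}: the integrated element's 5' part is a (diverged) copy
#' of the genomic repeat-library Alu fused to the 3' part of the tagged
#' construct; no target-site duplication is formed and a genomic deletion
#' of \code{deletion} nt follows the insertion point.
#' \code{endonuclease_independent}: blunt insertion of the element at a
#' site scoring below the consensus threshold, with no duplication.
#'
#' @param genome a \code{synthetic_genome} (chimeric mode needs its planted
#'   Alu repeat library).
#' @param construct a \code{\link{construct_reference}}.
#' @param mode \code{"chimeric"} or \code{"endonuclease_independent"}.
#' @param realized_tail tail sequence carried by the insert.
#' @param deletion genomic nt deleted 3' of the breakpoint (chimeric mode;
#'   default 200).
#' @param alu_part nt of genomic Alu forming the insert 5' part (default
#'   150).
#' @param body_cut body position at which the construct-derived 3' part
#'   starts (default half the body).
#' @param flank flank length kept on each side.
#' @param max_site_score maximum endonuclease score (both orientations) at
#'   an acceptable ENi site (default 3).
#' @param seed optional integer seed.
#' @return list with \code{pre_locus}, \code{post_locus}, \code{truth}.
#' @export
make_atypical <- function(genome, construct,
                          mode = c("chimeric", "endonuclease_independent"),
                          realized_tail, deletion = 200L, alu_part = 150L,
                          body_cut = NULL, flank = 500L,
                          max_site_score = 3L, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(genome, "synthetic_genome"))
  body <- construct$body
  if (is.null(body_cut)) body_cut <- nchar(body) %/% 2L

  # random interior position with a low endonuclease score on both strands
  pick_low_score_pos <- function(cn) {
    seqc <- genome$chromosomes[[cn]]
    sc <- en_site_scores(seqc)
    L <- nchar(seqc)
    ok <- which(pmax(sc$plus, sc$minus) <= max_site_score)
    ok <- ok[ok > flank + deletion & ok <= L - flank - deletion]
    if (!length(ok)) stop("no low-score site available")
    sample(ok, 1L) - 1L
  }

  cn <- sample(names(genome$chromosomes), 1L)
  pos <- pick_low_score_pos(cn)
  seqc <- genome$chromosomes[[cn]]
  flank5 <- substr(seqc, max(1L, pos - flank + 1L), pos)

  if (mode == "chimeric") {
    alu <- genome$repeat_library[["Alu"]]
    if (is.null(alu)) stop("chimeric mode requires a genomic Alu library")
    if (!any(genome$annotations$type == "repeat" &
             genome$annotations$class == "Alu"))
      stop("chimeric mode requires planted genomic Alu elements")
    alu5 <- mutate_seq(substr(alu, 1L, alu_part), 0.02)
    insert <- paste0(alu5, substr(body, body_cut + 1L, nchar(body)),
                     realized_tail)
    flank3 <- substr(seqc, pos + 1L + deletion,
                     min(nchar(seqc), pos + deletion + flank))
    truth <- list(class = "chimeric_recombination", chrom = cn, pos = pos,
                  strand = "+", tsd_len = 0L, deletion = as.integer(deletion),
                  alu_part = as.integer(alu_part),
                  body_cut = as.integer(body_cut),
                  tail_seq = realized_tail)
  } else {
    insert <- paste0(body, realized_tail)
    flank3 <- substr(seqc, pos + 1L, min(nchar(seqc), pos + flank))
    truth <- list(class = "endonuclease_independent", chrom = cn, pos = pos,
                  strand = "+", tsd_len = 0L, deletion = 0L,
                  tail_seq = realized_tail)
  }
  # keep the post-insert junction free of A's so the tail boundary is exact
  f3 <- seq_chars(flank3)
  if (length(f3) && f3[1L] == "A") f3[1L] <- "G"
  flank3 <- paste(f3, collapse = "")
  pre3 <- substr(seqc, pos + 1L, min(nchar(seqc), pos + flank))
  list(pre_locus = paste0(flank5, pre3),
       post_locus = paste0(flank5, insert, flank3),
       truth = truth)
}
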