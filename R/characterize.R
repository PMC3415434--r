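# Insert characterizer: anchors the tagged construct inside a recovered
# post-insertion locus, recovers the target-site duplication, scores the
# endonuclease site, measures 5' truncation, scans body mismatches, and
# classifies the event (typical TPRT / chimeric recombination /
# endonuclease-independent).

# longest common prefix length of two strings
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- seq_chars(substr(a, 1L, n))
  cb <- seq_chars(substr(b, 1L, n))
  d <- which(ca != cb)
  if (!length(d)) n else d[1L] - 1L
}

# Anchor the construct body in a post-insertion locus. The 3'-terminal
# 20-mer of the body is the primary seed (5' truncations never remove it);
# earlier 20-mers are fallbacks. The body 5' extent is then recovered with
# a gap-free score walk (+1 match, -2 mismatch) whose argmax separates body
# from flank/TSD sequence even in the presence of rare point mutations.
locate_insert <- function(post_locus, construct, seed_len = 20L) {
  body <- construct$body
  B <- nchar(body)
  stopifnot(B > seed_len)
  seeds_at <- c(B - seed_len + 1L,
                rev(seq(1L, B - seed_len, by = 50L)))
  try_orient <- function(work) {
    for (sa in seeds_at) {
      seed <- substr(body, sa, sa + seed_len - 1L)
      m <- regexpr(seed, work, fixed = TRUE)
      if (m[1] != -1L)
        return(list(work = work, seed_start = as.integer(m[1]),
                    body_seed_start = sa))
    }
    NULL
  }
  hit <- try_orient(post_locus)
  strand <- "+"
  if (is.null(hit)) {
    hit <- try_orient(revcomp(post_locus))
    strand <- "-"
  }
  if (is.null(hit))
    return(list(found = FALSE, strand = NA_character_))
  work <- hit$work

  # align forward from the seed to the body 3' end (tolerating mismatches)
  n_fwd <- B - (hit$body_seed_start + seed_len - 1L)
  body_end <- hit$seed_start + seed_len - 1L
  if (n_fwd > 0L)
    body_end <- body_end + min(n_fwd, nchar(work) - body_end)

  # score walk 5' of the seed
  i0 <- hit$seed_start - 1L
  b0 <- hit$body_seed_start - 1L
  kmax <- min(i0, b0)
  ext <- 0L
  mism_ext <- integer()
  if (kmax > 0L) {
    wch <- seq_chars(substr(work, i0 - kmax + 1L, i0))
    bch <- seq_chars(substr(body, b0 - kmax + 1L, b0))
    sc <- ifelse(rev(wch) == rev(bch), 1, -2)  # walking outward from seed
    cum <- cumsum(sc)
    best <- which.max(cum)
    if (cum[best] > 0) {
      ext <- best
      mism_ext <- b0 - (which(rev(wch)[1:best] != rev(bch)[1:best])) + 1L
    }
  }
  body_start <- hit$seed_start - ext
  body_offset <- b0 - ext + 1L        # first body position present
  truncation <- body_offset - 1L

  # mismatches across the whole aligned body region (body coordinates)
  aln_len <- body_end - body_start + 1L
  wch <- seq_chars(substr(work, body_start, body_end))
  bch <- seq_chars(substr(body, body_offset, body_offset + aln_len - 1L))
  mismatch_pos <- body_offset + which(wch != bch) - 1L

  list(found = TRUE, strand = strand, work = work,
       body_start = body_start, body_end = body_end,
       body_offset = body_offset, truncation = truncation,
       mismatch_pos = mismatch_pos)
}

# Tail/TSD boundary resolution 3' of the anchored body. The region after
# the body is tokenized (A-runs, disruptions, duplications, unparseable
# chunks); the tail cannot be delimited greedily because target-site
# sequence can mimic disruption tokens and slippage fragments can look
# unparseable. Candidate boundaries are therefore the A-run token ends;
# the boundary whose following sequence forms the longest direct repeat
# with the sequence 5' of the insert (>= min_tsd) wins. When no candidate
# yields a qualifying repeat (atypical events), the strict greedy end --
# tokens up to the first unparseable chunk -- is used. Junction-adjacent
# A's 3' of the chosen boundary are then absorbed into the tail
# ("tail-first" A assignment; \code{find_tsd} can undo this for the
# "tsd" policy).
extract_tail <- function(work, body_end, template, left_context,
                         max_disruption_mismatch = 1L, max_tsd = 50L,
                         min_tsd = 5L, scan_limit = 800L) {
  region <- substr(work, body_end + 1L,
                   min(nchar(work), body_end + scan_limit))
  if (nchar(region) == 0L)
    return(list(tail_seq = "", tail_end = body_end))
  sc <- scan_tail_tokens(region, template, max_disruption_mismatch)
  toks <- sc$tokens
  kinds <- vapply(toks, `[[`, "", "kind")
  ends <- vapply(toks, `[[`, 0L, "end")
  lens <- vapply(toks, function(t) nchar(t$string), 0L)

  # strict greedy end: everything before the first unparseable token
  first_bad <- which(kinds == "unparseable")[1]
  strict_end <- if (is.na(first_bad)) {
    if (length(ends)) ends[length(ends)] else 0L
  } else if (first_bad == 1L) 0L else ends[first_bad - 1L]

  # candidate boundaries may pass short unparseable chunks (slippage
  # fragments), but flanking genomic sequence accumulates unparseable
  # content quickly -- cap the search there so homologous repeats deeper
  # in the flank cannot masquerade as the tail/TSD junction
  un_len <- cumsum(ifelse(kinds == "unparseable", lens, 0L))
  un_cnt <- cumsum(kinds == "unparseable")
  ok_tok <- un_len <= 12L & un_cnt <= 4L
  cand <- unique(c(0L, ends[kinds == "run" & ok_tok]))
  rep_len <- vapply(cand, function(e)
    anchored_repeat_len(left_context,
                        substr(work, body_end + e + 1L, nchar(work)),
                        max_tsd), 0L)
  qual <- rep_len >= min_tsd
  if (any(qual)) {
    best <- which(qual & rep_len == max(rep_len[qual]))
    e <- max(cand[best])
  } else {
    e <- strict_end
  }
  # absorb junction-adjacent A's (tail-first policy)
  extra <- leading_a(substr(work, body_end + e + 1L, nchar(work)))
  e <- e + extra
  list(tail_seq = substr(region, 1L, e), tail_end = body_end + e)
}

#' Find the target-site duplication of a recovered insert
#'
#' Anchors the construct body in the post-insertion locus (both strands),
#' extracts the observed tail, and reports the longest exact repeat (up to
#' \code{max_len} nt) anchored immediately 5' of the insert's 5' junction
#' and immediately 3' of its 3' junction. Junction-adjacent shared A's are
#' assigned to the tail first (\code{a_policy = "tail"}, the default) or
#' reclaimed into the duplication (\code{a_policy = "tsd"}: the tail/TSD
#' boundary is shifted left over trailing tail A's to the position
#' maximizing the anchored repeat).
#'
#' @param pre_locus pre-insertion locus sequence.
#' @param post_locus post-insertion locus sequence.
#' @param construct a \code{\link{construct_reference}}.
#' @param max_len maximum duplication length considered (default 50).
#' @param a_policy junction A-assignment convention.
#' @return list with \code{found}, \code{tsd_seq}, \code{tsd_len},
#'   \code{strand}, \code{truncation}, \code{tail_seq}, insert junctions
#'   \code{j5}/\code{j3} (element-oriented coordinates) and the anchor
#'   details. \code{found = FALSE} flags an unresolvable record (construct
#'   body absent).
#' @export
find_tsd <- function(pre_locus, post_locus, construct, max_len = 50L,
                     a_policy = c("tail", "tsd")) {
  a_policy <- match.arg(a_policy)
  loc <- locate_insert(post_locus, construct)
  if (!loc$found) return(list(found = FALSE))
  work <- loc$work
  j5 <- loc$body_start
  left <- substr(work, 1L, j5 - 1L)
  tl <- extract_tail(work, loc$body_end, construct$tail,
                     left_context = left, max_tsd = max_len)
  j3 <- tl$tail_end
  tail_seq <- tl$tail_seq
  if (a_policy == "tail") {
    k <- anchored_repeat_len(left, substr(work, j3 + 1L, nchar(work)),
                             max_len)
  } else {
    give_max <- trailing_a(tail_seq)
    best_k <- -1L; best_m <- 0L
    for (m in 0:give_max) {
      k_m <- anchored_repeat_len(left,
                                 substr(work, j3 - m + 1L, nchar(work)),
                                 max_len)
      if (k_m > best_k) { best_k <- k_m; best_m <- m }
    }
    j3 <- j3 - best_m
    tail_seq <- substr(tail_seq, 1L, nchar(tail_seq) - best_m)
    k <- best_k
  }
  list(found = TRUE,
       tsd_seq = if (k > 0L) substr(work, j5 - k, j5 - 1L) else "",
       tsd_len = k, strand = loc$strand, truncation = loc$truncation,
       tail_seq = tail_seq, j5 = j5, j3 = j3, anchor = loc)
}

#' Score an endonuclease site at a cleavage point
#'
#' Counts matches to the L1 endonuclease consensus (default
#' \code{TTTTAA}, read 5'-TTTT/AA-3' on the nicked strand with cleavage
#' between T4 and A1) across the 6 positions spanning the cleavage point.
#' Both orientations are scanned and the better-scoring one reported: for
#' a plus-strand element the nicked (bottom) strand window is the reverse
#' complement of \code{pre_locus[t-2 .. t+3]}; for a minus-strand element
#' the top strand itself is nicked and \code{pre_locus[t-4 .. t+1]} is
#' scored directly.
#'
#' @param pre_locus pre-insertion locus sequence.
#' @param cleavage_point 1-based position of the first base 3' of the nick
#'   (the start of the duplicated target).
#' @param consensus 6-mer consensus (default \code{"TTTTAA"}).
#' @return list with \code{score} (0-6), \code{strand} of the better
#'   orientation, \code{window} (the nicked-strand hexamer), and
#'   \code{clipped} (TRUE when the window ran off the sequence end).
#' @export
score_en_site <- function(pre_locus, cleavage_point,
                          consensus = "TTTTAA") {
  stopifnot(nchar(consensus) == 6L)
  t <- as.integer(cleavage_point)
  L <- nchar(pre_locus)
  cons <- seq_chars(consensus)
  target_plus <- seq_chars(revcomp(consensus))  # positionwise on top strand
  win_score <- function(from, to, target) {
    idx <- from:to
    ok <- idx >= 1L & idx <= L
    ch <- rep("-", 6L)
    ch[ok] <- seq_chars(substr(pre_locus, max(1L, from), min(L, to)))
    list(score = sum(ch == target), clipped = !all(ok),
         seq = paste(ch, collapse = ""))
  }
  p <- win_score(t - 2L, t + 3L, target_plus)
  m <- win_score(t - 4L, t + 1L, cons)
  if (p$score >= m$score) {
    list(score = p$score, strand = "+",
         window = revcomp(gsub("-", "N", p$seq)), clipped = p$clipped)
  } else {
    list(score = m$score, strand = "-",
         window = gsub("-", "N", m$seq), clipped = m$clipped)
  }
}

#' Build a position frequency matrix of pre-integration windows
#'
#' @param windows character vector of equal-length aligned sequences
#'   (e.g. nicked-strand hexamers aligned on the cleavage point).
#' @return numeric matrix, one row per position and columns A/C/G/T; rows
#'   sum to 1. The consensus string is attached as attribute
#'   \code{"consensus"}.
#' @export
build_target_pfm <- function(windows) {
  if (!length(windows)) stop("no windows supplied")
  n <- unique(nchar(windows))
  if (length(n) != 1L) stop("windows must be equal length")
  mat <- matrix(0, nrow = n, ncol = 4L,
                dimnames = list(seq_len(n), c("A", "C", "G", "T")))
  for (w in windows) {
    ch <- seq_chars(w)
    for (i in seq_len(n)) {
      if (ch[i] %in% colnames(mat))
        mat[i, ch[i]] <- mat[i, ch[i]] + 1
    }
  }
  rs <- rowSums(mat)
  rs[rs == 0] <- 1
  mat <- mat / rs
  attr(mat, "consensus") <- paste(colnames(mat)[apply(mat, 1L, which.max)],
                                  collapse = "")
  mat
}

#' Scan construct-body mismatches of an anchored insert
#'
#' Compares the aligned body region of the insert to the construct body,
#' excluding the A-rich middle interval (whose length is unstable through
#' cloning) and any 5'-truncated positions.
#'
#' @param tsd_result a \code{\link{find_tsd}} result with \code{found =
#'   TRUE}.
#' @param construct the \code{\link{construct_reference}}.
#' @return list with \code{mismatches} (count), \code{positions} (body
#'   coordinates), \code{analyzed_bp}, \code{rate}.
#' @export
scan_body_mismatches <- function(tsd_result, construct) {
  stopifnot(isTRUE(tsd_result$found))
  loc <- tsd_result$anchor
  mask <- construct$a_rich_middle
  pos <- loc$mismatch_pos
  lo <- loc$body_offset
  hi <- loc$body_offset +
    (loc$body_end - loc$body_start)
  analyzed <- hi - lo + 1L
  if (!is.null(mask)) {
    masked <- pos >= mask[1] & pos <= mask[2]
    pos <- pos[!masked]
    overlap <- max(0L, min(hi, mask[2]) - max(lo, mask[1]) + 1L)
    analyzed <- analyzed - overlap
  }
  list(mismatches = length(pos), positions = pos,
       analyzed_bp = analyzed,
       rate = if (analyzed > 0) length(pos) / analyzed else NA_real_)
}

# local-alignment identity of the insert 5' extra region against candidate
# repeat sequences
chimeric_5p_match <- function(extra, repeats, min_identity = 0.9,
                              min_len = 30L) {
  if (nchar(extra) < min_len || !length(repeats)) return(FALSE)
  for (r in repeats) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(extra), Biostrings::DNAString(r),
      type = "local")
    if (Biostrings::nchar(al) >= min_len &&
        Biostrings::pid(al) / 100 >= min_identity)
      return(TRUE)
  }
  FALSE
}

#' Classify an insertion event
#'
#' \code{TPRT_typical}: duplication of at least \code{min_tsd} nt and an
#' endonuclease score of at least \code{en_threshold}.
#' \code{chimeric_recombination}: no qualifying duplication and an insert
#' 5' region that diverges from the construct but matches an annotated
#' genomic Alu (at least \code{min_identity} over \code{min_len} nt).
#' \code{endonuclease_independent}: no duplication, no chimerism, and a
#' sub-threshold endonuclease score. Anything else is \code{ambiguous},
#' with reasons attached.
#'
#' @param tsd_len recovered duplication length.
#' @param en_score endonuclease consensus score (0-6).
#' @param extra_5p insert sequence 5' of the anchored construct body
#'   (empty for non-chimeric events).
#' @param repeats character vector of candidate genomic repeat sequences
#'   (e.g. the planted Alu library), or \code{NULL}.
#' @param min_tsd minimum duplication length for a typical call (default
#'   5).
#' @param en_threshold minimum endonuclease score for a canonical site
#'   (default 4 of 6).
#' @param min_identity,min_len chimeric-match thresholds (default 90\%
#'   over 30 nt).
#' @return character scalar class label; attribute \code{"reasons"} set
#'   for ambiguous calls.
#' @export
classify_insertion <- function(tsd_len, en_score, extra_5p = "",
                               repeats = NULL, min_tsd = 5L,
                               en_threshold = 4L, min_identity = 0.9,
                               min_len = 30L) {
  has_tsd <- tsd_len >= min_tsd
  canonical <- en_score >= en_threshold
  chim <- !has_tsd && chimeric_5p_match(extra_5p, repeats,
                                        min_identity, min_len)
  if (has_tsd && canonical) return("TPRT_typical")
  if (chim) return("chimeric_recombination")
  if (!has_tsd && !canonical) return("endonuclease_independent")
  structure("ambiguous",
            reasons = sprintf("tsd_len=%d en_score=%d chimeric=%s",
                              tsd_len, en_score, chim))
}

#' Characterize one recovered insert
#'
#' Runs the full per-insert hallmark recovery: body anchoring, target-site
#' duplication, endonuclease-site score, 5' truncation, body mismatch scan
#' and event classification.
#'
#' @param pre_locus,post_locus the paired locus sequences.
#' @param construct the \code{\link{construct_reference}}.
#' @param repeats optional candidate genomic repeat sequences for the
#'   chimeric test.
#' @param max_tsd,a_policy,min_tsd,en_threshold see
#'   \code{\link{find_tsd}} and \code{\link{classify_insertion}}.
#' @return one-row data.frame (columns: found, strand, tsd_len, tsd_seq,
#'   en_score, en_strand, en_window, truncation_5p, insertion_class,
#'   body_mismatches, analyzed_bp, tail_seq, extra_5p_len, cleavage).
#' @export
characterize_insert <- function(pre_locus, post_locus, construct,
                                repeats = NULL, max_tsd = 50L,
                                a_policy = c("tail", "tsd"),
                                min_tsd = 5L, en_threshold = 4L) {
  a_policy <- match.arg(a_policy)
  res <- find_tsd(pre_locus, post_locus, construct, max_len = max_tsd,
                  a_policy = a_policy)
  if (!isTRUE(res$found)) {
    return(data.frame(found = FALSE, strand = NA_character_,
                      tsd_len = NA_integer_, tsd_seq = NA_character_,
                      en_score = NA_integer_, en_strand = NA_character_,
                      en_window = NA_character_,
                      truncation_5p = NA_integer_,
                      insertion_class = "unresolvable",
                      body_mismatches = NA_integer_,
                      analyzed_bp = NA_integer_, tail_seq = NA_character_,
                      extra_5p_len = NA_integer_, cleavage = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  pre_work <- if (res$strand == "-") revcomp(pre_locus) else pre_locus
  # insert 5' region between pre/post divergence and the body anchor
  dv <- lcp_len(pre_work, res$anchor$work)
  extra_5p <- if (res$tsd_len < min_tsd && res$j5 - 1L > dv)
    substr(res$anchor$work, dv + 1L, res$j5 - 1L) else ""
  # cleavage point = start of the full duplicated target in the original
  # (genomic top strand) orientation of pre_locus. Under the tail-first
  # policy the target's leading A's were absorbed into the tail, so the
  # element-oriented target start is j5 - tsd_len minus the A-run
  # immediately 5' of the recovered duplication copy; for minus-strand
  # elements the original-orientation start maps to Lp - j5 + 2.
  Lp <- nchar(pre_locus)
  cleavage <- if (res$tsd_len >= min_tsd) {
    raw5 <- res$j5 - res$tsd_len
    m <- min(10L, trailing_a(substr(res$anchor$work, 1L, raw5 - 1L)))
    if (res$strand == "-") Lp - res$j5 + 2L else raw5 - m
  } else {
    if (res$strand == "-") max(1L, Lp - dv + 1L) else min(dv + 1L, Lp)
  }
  en <- score_en_site(pre_locus, cleavage)
  mm <- scan_body_mismatches(res, construct)
  cls <- classify_insertion(res$tsd_len, en$score, extra_5p, repeats,
                            min_tsd = min_tsd, en_threshold = en_threshold)
  data.frame(found = TRUE, strand = res$strand, tsd_len = res$tsd_len,
             tsd_seq = res$tsd_seq, en_score = en$score,
             en_strand = en$strand, en_window = en$window,
             truncation_5p = res$truncation,
             insertion_class = as.character(cls),
             body_mismatches = mm$mismatches, analyzed_bp = mm$analyzed_bp,
             tail_seq = res$tail_seq,
             extra_5p_len = nchar(extra_5p), cleavage = cleavage,
             stringsAsFactors = FALSE)
}

#' Characterize a cohort of recovered inserts
#'
#' @param records data.frame with columns \code{id}, \code{pre_locus},
#'   \code{post_locus} (and optionally \code{driver}).
#' @param construct the \code{\link{construct_reference}}.
#' @param repeats optional repeat library for the chimeric test.
#' @param ... passed to \code{\link{characterize_insert}}.
#' @return data.frame, one row per record, id (and driver) prepended.
#' @export
characterize_cohort <- function(records, construct, repeats = NULL, ...) {
  stopifnot(all(c("id", "pre_locus", "post_locus") %in% names(records)))
  rows <- lapply(seq_len(nrow(records)), function(i)
    characterize_insert(records$pre_locus[i], records$post_locus[i],
                        construct, repeats = repeats, ...))
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(id = records$id, stringsAsFactors = FALSE), out)
  if ("driver" %in% names(records)) out$driver <- records$driver
  out
}

#' Summarize a characterization table
#'
#' Cohort-level summaries mirroring the published per-cohort statistics:
#' class counts and fractions, direct-repeat length mean/sd/median/range
#' (over rows with a measured duplication), 5'-truncation fraction, body
#' mismatch totals and rate, and the target-site position frequency
#' matrix built from the endonuclease windows of typical events.
#'
#' @param chr data.frame from \code{\link{characterize_cohort}} (or an
#'   equivalent per-insert table with columns \code{insertion_class},
#'   \code{tsd_len}, \code{truncation_5p}, and optionally
#'   \code{body_mismatches}, \code{analyzed_bp}, \code{en_window}).
#' @return list of cohort summaries.
#' @export
summarize_characterization <- function(chr) {
  n <- nrow(chr)
  cls <- table(chr$insertion_class)
  dr <- chr$tsd_len[!is.na(chr$tsd_len) & chr$tsd_len > 0]
  trunc_n <- sum(chr$truncation_5p > 0, na.rm = TRUE)
  mm_tot <- if ("body_mismatches" %in% names(chr))
    sum(chr$body_mismatches, na.rm = TRUE) else NA_integer_
  bp_tot <- if ("analyzed_bp" %in% names(chr))
    sum(chr$analyzed_bp, na.rm = TRUE) else NA_integer_
  pfm <- NULL
  if ("en_window" %in% names(chr)) {
    w <- chr$en_window[chr$insertion_class == "TPRT_typical" &
                         !is.na(chr$en_window)]
    w <- w[!grepl("N", w)]
    if (length(w)) pfm <- build_target_pfm(w)
  }
  list(
    n = n,
    class_counts = cls,
    class_fractions = cls / n,
    dr_n = length(dr),
    dr_mean = if (length(dr)) mean(dr) else NA_real_,
    dr_sd = if (length(dr)) stats::sd(dr) else NA_real_,
    dr_median = if (length(dr)) stats::median(dr) else NA_real_,
    dr_range = if (length(dr)) range(dr) else c(NA_real_, NA_real_),
    truncated_n = trunc_n,
    truncated_fraction = trunc_n / n,
    body_mismatches = mm_tot,
    analyzed_bp = bp_tot,
    mismatch_rate = if (!is.na(mm_tot) && !is.na(bp_tot) && bp_tot > 0)
      mm_tot / bp_tot else NA_real_,
    pfm = pfm)
}

#' Classify genic context of insertion positions
#'
#' Deterministic interval classification against gene models: positions in
#' no gene are intergenic; positions inside a gene take the most specific
#' overlapping substructure (CDS > UTR > intron) and a sense/antisense
#' orientation call (sense = insert strand equals gene strand). At cohort
#' level a two-sided binomial test of the genic sense fraction against
#' \code{null_sense} is reported.
#'
#' @param positions data.frame with columns \code{chrom}, \code{pos},
#'   \code{strand}.
#' @param annotations a \code{GRanges} annotation track with \code{type}
#'   (\code{"gene"}, \code{"CDS"}, \code{"UTR"}, \code{"intron"}) and
#'   \code{gene_id} metadata (as built by \code{\link{generate_genome}}).
#' @param null_sense null sense fraction for the binomial test (default
#'   0.5; 0.45 approximates the genomic intronic background).
#' @return list with per-position data.frame (\code{context},
#'   \code{orientation}, \code{gene_id}) and the cohort \code{sense_test}.
#' @export
classify_genic_context <- function(positions, annotations,
                                   null_sense = 0.5) {
  pts <- GenomicRanges::GRanges(
    positions$chrom, IRanges::IRanges(positions$pos, positions$pos))
  prec <- c(CDS = 3L, UTR = 2L, intron = 1L)
  ann <- annotations[annotations$type %in% c("gene", "CDS", "UTR",
                                             "intron")]
  ov <- GenomicRanges::findOverlaps(pts, ann, ignore.strand = TRUE)
  context <- rep("intergenic", nrow(positions))
  orientation <- rep(NA_character_, nrow(positions))
  gene_id <- rep(NA_character_, nrow(positions))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    for (q in unique(qh)) {
      hits <- sh[qh == q]
      types <- ann$type[hits]
      sub <- hits[types != "gene"]
      if (length(sub)) {
        best <- sub[which.max(prec[ann$type[sub]])]
        context[q] <- ann$type[best]
      } else {
        context[q] <- "intron"  # inside a gene but no substructure row
      }
      gh <- hits[types == "gene"][1]
      if (!is.na(gh)) {
        gene_id[q] <- ann$gene_id[gh]
        gs <- as.character(GenomicRanges::strand(ann[gh]))
        orientation[q] <- if (gs %in% c("+", "-") &&
                              positions$strand[q] %in% c("+", "-")) {
          if (gs == positions$strand[q]) "sense" else "antisense"
        } else NA_character_
      }
    }
  }
  genic <- context != "intergenic"
  n_sense <- sum(orientation == "sense", na.rm = TRUE)
  n_orient <- sum(!is.na(orientation))
  sense_test <- if (n_orient > 0)
    stats::binom.test(n_sense, n_orient, p = null_sense)$p.value
  else NA_real_
  list(
    per_position = data.frame(
      chrom = positions$chrom, pos = positions$pos,
      strand = positions$strand, context = context,
      orientation = orientation, gene_id = gene_id,
      stringsAsFactors = FALSE),
    n_genic = sum(genic), n_intergenic = sum(!genic),
    n_sense = n_sense, n_antisense = sum(orientation == "antisense",
                                         na.rm = TRUE),
    sense_test_p = sense_test)
}
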