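# A-tail analyzer: segments observed insert tails against the parental
# disruption-tagged template, infers TPRT priming location, types inserts,
# quantifies per-segment expansion/contraction, detects duplicated
# disruptions, and computes cohort statistics.

# disruption matching rule shared by the parser and the tail extractor:
# substitutions only (no indels), at most `max_mm` of them, and never more
# than length-2 mismatches so that 1-2 nt disruptions require exact matches
disruption_match <- function(s, d, max_mm = 1L) {
  hamming(s, d) <= min(max_mm, max(0L, nchar(d) - 2L))
}

# Position-wise tail scanner shared by the parser and the characterizer's
# tail extractor. Disruptions may contain internal A's (e.g. CATTAC), so
# matching is anchored at each non-A position: the candidate disruption
# must fit the substring there (within tolerance) and be followed by an
# adenosine (or the string end). Match preference: exact match of the next
# expected disruption, then an exact lookahead match of a later disruption
# (a lost disruption implies a deletion slip, so a fuzzy lookahead would
# over-trigger), then an exact-or-fuzzy duplication of an already-seen
# disruption, then a fuzzy match of the next expected disruption. Unmatched
# non-A chunks are recorded as unparseable and the scan continues; each
# token carries its end offset so callers can resolve the tail boundary.
scan_tail_tokens <- function(observed, template,
                             max_disruption_mismatch = 1L) {
  ch <- seq_chars(observed)
  n <- length(ch)
  dis <- template$disruptions
  n_d <- length(dis)
  next_d <- 1L
  seen <- integer()
  skipped <- integer()
  tokens <- list()
  i <- 1L
  push <- function(kind, index, string, end) {
    tokens[[length(tokens) + 1L]] <<-
      list(kind = kind, index = index, string = string, end = end)
  }
  while (i <= n) {
    if (ch[i] == "A") {
      j <- i
      while (j < n && ch[j + 1L] == "A") j <- j + 1L
      push("run", NA_integer_, substr(observed, i, j), j)
      i <- j + 1L
      next
    }
    try_match <- function(d_idx, exact_only) {
      d <- dis[d_idx]
      len <- nchar(d)
      if (i + len - 1L > n) return(NULL)
      sub <- substr(observed, i, i + len - 1L)
      if (i + len <= n && ch[i + len] != "A") return(NULL)
      ok <- if (exact_only) sub == d
            else disruption_match(sub, d, max_disruption_mismatch)
      if (ok) sub else NULL
    }
    hit <- NA_integer_
    hit_sub <- NULL
    if (next_d <= n_d) {               # exact next
      m <- try_match(next_d, TRUE)
      if (!is.null(m)) { hit <- next_d; hit_sub <- m }
    }
    if (is.na(hit) && next_d < n_d) {  # exact lookahead (lost disruption)
      for (j in (next_d + 1L):n_d) {
        m <- try_match(j, TRUE)
        if (!is.null(m)) { hit <- j; hit_sub <- m; break }
      }
    }
    if (is.na(hit) && length(seen)) {  # duplication (slippage re-copy)
      for (j in rev(seen)) {
        m <- try_match(j, FALSE)
        if (!is.null(m)) { hit <- -j; hit_sub <- m; break }
      }
    }
    if (is.na(hit) && next_d <= n_d) { # fuzzy next (point mutation)
      m <- try_match(next_d, FALSE)
      if (!is.null(m)) { hit <- next_d; hit_sub <- m }
    }
    if (is.na(hit)) {
      j <- i
      while (j < n && ch[j + 1L] != "A") j <- j + 1L
      push("unparseable", NA_integer_, substr(observed, i, j), j)
      i <- j + 1L
      next
    }
    if (hit > 0L) {
      if (hit > next_d) skipped <- c(skipped, next_d:(hit - 1L))
      push("disruption", hit, hit_sub, i + nchar(hit_sub) - 1L)
      seen <- c(seen, hit)
      next_d <- hit + 1L
    } else {
      push("duplication", -hit, hit_sub, i + nchar(hit_sub) - 1L)
    }
    i <- i + nchar(hit_sub)
  }
  list(tokens = tokens, skipped = skipped)
}

#' Segment an observed A-tail against its parental template
#'
#' Greedy left-to-right parse. Maximal A-runs become polyA segments;
#' intervening non-A strings are matched to the template disruptions in
#' order, allowing up to \code{max_disruption_mismatch} substitutions
#' (no indels). A non-A string that instead re-matches an
#' already-seen disruption is recorded as a duplication event (the
#' signature of replication slippage re-copying template positions);
#' its flanking A-runs are accumulated into the current segment. A
#' non-A string matching a later disruption implies the intervening
#' disruption(s) were lost (recorded in \code{skipped}); one matching
#' nothing is flagged unparseable and the parse continues.
#'
#' The template index of the last observed polyA segment is the inferred
#' TPRT priming segment: reverse transcription starts at the priming
#' position and copies the RNA 3'->5', so the insert retains the template
#' prefix up to that position and every disruption 5' of it. A terminal
#' segment shorter than its parental length indicates internal priming
#' within that segment.
#'
#' @param observed_tail DNA sequence of the insert's tail (between the
#'   construct body 3' end and the 3' target-site duplication / flank).
#' @param template the parental \code{\link{tail_template}}.
#' @param max_disruption_mismatch maximum substitutions tolerated when
#'   matching a disruption (default 1; the assay's point-mutation rate is
#'   of order 1e-4 so exact-only matching would occasionally misparse).
#' @return an object of class \code{tail_parse} with components
#'   \code{segments} (data.frame of template_index, observed_a, parental,
#'   expansion), \code{disruptions}, \code{duplications}, \code{skipped},
#'   \code{unparseable}, \code{insert_type}, \code{priming_segment},
#'   \code{terminal_index}, \code{internal_priming},
#'   \code{priming_offset_estimate} and the token stream used for exact
#'   reconstruction.
#' @export
segment_tail <- function(observed_tail, template,
                         max_disruption_mismatch = 1L) {
  stopifnot(inherits(template, "tail_template"))
  observed_tail <- toupper(observed_tail)
  if (grepl("[^ACGT]", observed_tail))
    stop("observed_tail must be DNA over A/C/G/T")
  n_seg <- length(template$segments)

  sc <- scan_tail_tokens(observed_tail, template, max_disruption_mismatch)
  counts <- rep(NA_integer_, n_seg)
  cur_seg <- 1L
  counts[1L] <- 0L
  matched <- data.frame(template_index = integer(), observed = character(),
                        exact = logical(), stringsAsFactors = FALSE)
  dups <- data.frame(template_index = integer(), observed = character(),
                     a_before = integer(), a_after = integer(),
                     stringsAsFactors = FALSE)
  unparseable <- character()
  tokens <- list()

  toks <- sc$tokens
  for (k in seq_along(toks)) {
    tk <- toks[[k]]
    if (tk$kind == "run") {
      counts[cur_seg] <- counts[cur_seg] + nchar(tk$string)
      tokens[[length(tokens) + 1L]] <-
        list(kind = "segment", index = cur_seg, string = tk$string)
    } else if (tk$kind == "disruption") {
      matched <- rbind(matched, data.frame(
        template_index = tk$index, observed = tk$string,
        exact = identical(tk$string, template$disruptions[tk$index]),
        stringsAsFactors = FALSE))
      tokens[[length(tokens) + 1L]] <-
        list(kind = "disruption", index = tk$index, string = tk$string)
      cur_seg <- tk$index + 1L
      if (is.na(counts[cur_seg])) counts[cur_seg] <- 0L
    } else if (tk$kind == "duplication") {
      run_len <- function(kk) {
        if (kk >= 1L && kk <= length(toks) && toks[[kk]]$kind == "run")
          nchar(toks[[kk]]$string) else 0L
      }
      dups <- rbind(dups, data.frame(
        template_index = tk$index, observed = tk$string,
        a_before = run_len(k - 1L), a_after = run_len(k + 1L),
        stringsAsFactors = FALSE))
      tokens[[length(tokens) + 1L]] <-
        list(kind = "duplication", index = tk$index, string = tk$string)
    } else {
      unparseable <- c(unparseable, tk$string)
      tokens[[length(tokens) + 1L]] <-
        list(kind = "unparseable", index = NA_integer_, string = tk$string)
    }
  }
  skipped <- sc$skipped

  # drop a trailing empty segment entered by a terminal disruption
  if (counts[cur_seg] == 0L && cur_seg > 1L) {
    counts[cur_seg] <- NA_integer_
    cur_seg <- max(which(!is.na(counts)))
  }

  obs_idx <- which(!is.na(counts))
  seg_df <- data.frame(
    template_index = obs_idx,
    observed_a = counts[obs_idx],
    parental = template$segments[obs_idx],
    stringsAsFactors = FALSE)
  seg_df$expansion <- seg_df$observed_a - seg_df$parental

  terminal_index <- max(obs_idx)
  internal_priming <- counts[terminal_index] <
    template$segments[terminal_index]
  # tail-coordinate offset of the last copied template position, assuming
  # no net slippage in the terminal segment (an estimate, not a certainty)
  prior <- seq_len(terminal_index - 1L)
  offset_est <- sum(template$segments[prior]) +
    sum(nchar(template$disruptions[seq_len(terminal_index - 1L)])) +
    min(counts[terminal_index], template$segments[terminal_index])

  parse <- structure(
    list(template = template, observed_tail = observed_tail,
         segments = seg_df, disruptions = matched, duplications = dups,
         skipped = skipped, unparseable = unparseable,
         priming_segment = terminal_index, terminal_index = terminal_index,
         internal_priming = internal_priming,
         priming_offset_estimate = offset_est,
         tokens = tokens),
    class = "tail_parse")
  parse$insert_type <- classify_tail_type(parse)
  parse
}

#' Reconstruct the observed tail from a parse
#'
#' Concatenates the parsed token stream (A-runs, matched disruptions,
#' duplications, unparseable strings) in order; equals the input tail
#' exactly.
#'
#' @param parse a \code{tail_parse}.
#' @return character scalar.
#' @export
reconstruct_tail <- function(parse) {
  stopifnot(inherits(parse, "tail_parse"))
  paste(vapply(parse$tokens, `[[`, "", "string"), collapse = "")
}

#' Classify an insert tail into types A, B, C, ...
#'
#' Type is set by the highest-index template disruption retained in the
#' insert: with the three-disruption A70D template, all three present gives
#' type A, the first two B, the first only C, and a pure homopolymer
#' (no disruptions) D. The scheme generalizes to any n-disruption template:
#' the (n+1) classes run from A (all disruptions) to the letter for a
#' homopolymeric tail.
#'
#' @param parse a \code{tail_parse}.
#' @return single letter character.
#' @export
classify_tail_type <- function(parse) {
  stopifnot(inherits(parse, "tail_parse"))
  n_d <- length(parse$template$disruptions)
  h <- if (nrow(parse$disruptions)) max(parse$disruptions$template_index)
       else 0L
  LETTERS[n_d - h + 1L]
}

#' Duplicated-disruption events of a parse
#'
#' One event per occurrence of a template disruption string (exact or
#' within the parse's mismatch tolerance) beyond its single expected copy,
#' with the A-run lengths flanking the duplicate. Duplicated disruptions
#' are the direct sequence signature of slippage re-copying template
#' positions during reverse transcription.
#'
#' @param parse a \code{tail_parse}.
#' @return data.frame with columns template_index, observed, a_before,
#'   a_after.
#' @export
detect_duplicated_disruptions <- function(parse) {
  stopifnot(inherits(parse, "tail_parse"))
  parse$duplications
}

#' @export
print.tail_parse <- function(x, ...) {
  cat(sprintf(
    "<tail_parse> type %s, priming segment %d%s, segments [%s]\n",
    x$insert_type, x$priming_segment,
    if (x$internal_priming) " (internal priming)" else "",
    paste(x$segments$observed_a, collapse = ",")))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midranks for ties. For small problems
#' (\code{length(x) + length(y) <= exact_limit}) the null distribution is
#' enumerated exactly over all group labelings of the pooled values;
#' otherwise the normal approximation with tie-corrected variance and a
#' 0.5 continuity correction is used. U counts pairs where an \code{x}
#' value exceeds a \code{y} value (ties count one half), so
#' \code{alternative = "greater"} tests whether \code{x} is shifted right
#' of \code{y}.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @param exact_limit pooled-size threshold at or below which the exact
#'   enumeration is used (default 10).
#' @return list with \code{U}, \code{Z}, \code{p.value}, \code{method},
#'   \code{n1}, \code{n2}.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           exact_limit = 10L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (N <= exact_limit) {
    combs <- utils::combn(N, n1)
    u_all <- apply(combs, 2L, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    eps <- 1e-9
    p <- switch(alternative,
      less = mean(u_all <= U + eps),
      greater = mean(u_all >= U - eps),
      two.sided = mean(abs(u_all - mu) >= abs(U - mu) - eps))
    return(list(U = U, Z = NA_real_, p.value = p, method = "exact",
                n1 = n1, n2 = n2))
  }

  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(U = U, Z = 0, p.value = 1, method = "normal",
                n1 = n1, n2 = n2))
  }
  sd0 <- sqrt(sigma2)
  # continuity correction toward the null mean
  cc <- function(u) sign(u - mu) * pmin(0.5, abs(u - mu))
  Z <- (U - mu - cc(U)) / sd0
  p <- switch(alternative,
    less = stats::pnorm((U - mu + 0.5) / sd0),
    greater = stats::pnorm((U - mu - 0.5) / sd0, lower.tail = FALSE),
    two.sided = min(1, 2 * stats::pnorm(-abs(Z))))
  list(U = U, Z = Z, p.value = p, method = "normal", n1 = n1, n2 = n2)
}

# per-segment eligible parental A positions for the priming null, after
# excluding the first `excl` tail positions (5' coordinate)
eligible_segment_lengths <- function(template, excl = 0L) {
  segs <- template$segments
  d_len <- nchar(template$disruptions)
  start <- cumsum(c(0L, segs[-length(segs)] + d_len)) + 1L
  end <- start + segs - 1L
  pmax(0L, end - pmax(start, excl + 1L) + 1L)
}

#' Summarize a cohort of tail parses
#'
#' Computes the cohort-level tail statistics: median/quartiles and counts
#' of internal vs terminal segment lengths, per-segment priming histogram,
#' contracted-terminal count, expansion fractions, insert-type counts,
#' duplication events, a two-sided Mann-Whitney U test comparing internal
#' against terminal segment lengths, and a chi-square goodness-of-fit test
#' of the priming-segment counts against a null of priming positions
#' uniform over the A-tail's adenosines (expected counts proportional to
#' eligible parental segment lengths).
#'
#' The terminal expansion fraction is computed over end-primed terminal
#' segments only (observed length >= parental): a contracted terminal
#' implies internal priming, in which case the copied template extent, and
#' hence its expansion, is not observable. Internal segments cannot
#' contract, so their fraction is over all internal segments.
#'
#' @param parses list of \code{tail_parse} objects (>= 2).
#' @param template the shared parental template.
#' @param expansion_threshold adenosines of net gain that count as an
#'   expansion (default 4).
#' @param expansion_marker_frac alternate marker: fraction of parental
#'   length by which a segment must exceed parental to be flagged
#'   (default 0.4, i.e. at least 40\% longer).
#' @param prime_offset_excluded tail positions from the 5' end removed from
#'   the eligible length of the goodness-of-fit null (default 0: priming
#'   uniform over all A positions). If the exclusion zeroes a segment that
#'   nevertheless has observed priming events, the unrestricted null is
#'   used with a warning.
#' @return list of class \code{tail_cohort_summary}.
#' @export
summarize_tail_cohort <- function(parses, template,
                                  expansion_threshold = 4L,
                                  expansion_marker_frac = 0.4,
                                  prime_offset_excluded = 0L) {
  stopifnot(length(parses) >= 2L,
            all(vapply(parses, inherits, TRUE, "tail_parse")))
  n_seg <- length(template$segments)

  term_len <- vapply(parses, function(p)
    p$segments$observed_a[p$segments$template_index == p$terminal_index], 0L)
  term_idx <- vapply(parses, `[[`, 0L, "terminal_index")
  term_parental <- template$segments[term_idx]

  int_len <- integer(); int_idx <- integer()
  for (p in parses) {
    keep <- p$segments$template_index != p$terminal_index
    int_len <- c(int_len, p$segments$observed_a[keep])
    int_idx <- c(int_idx, p$segments$template_index[keep])
  }
  int_parental <- template$segments[int_idx]

  priming_counts <- tabulate(term_idx, nbins = n_seg)
  contracted <- sum(term_len < term_parental)

  end_primed <- term_len >= term_parental
  frac_term_exp <- if (any(end_primed))
    mean((term_len - term_parental)[end_primed] >= expansion_threshold)
  else NA_real_
  frac_int_exp <- if (length(int_len))
    mean(int_len - int_parental >= expansion_threshold) else NA_real_
  frac_term_marker <- if (any(end_primed))
    mean(term_len[end_primed] >=
           (1 + expansion_marker_frac) * term_parental[end_primed])
  else NA_real_
  frac_int_marker <- if (length(int_len))
    mean(int_len >= (1 + expansion_marker_frac) * int_parental)
  else NA_real_

  mw <- if (length(int_len) && length(term_len)) {
    mann_whitney_u(int_len, term_len, alternative = "two.sided")
  } else {
    warning("all segments in one class; Mann-Whitney test skipped")
    NULL
  }

  elig <- eligible_segment_lengths(template, prime_offset_excluded)
  if (any(elig == 0L & priming_counts > 0L)) {
    warning("priming observed in a segment with zero eligible length; ",
            "using the unrestricted priming null")
    elig <- template$segments
  }
  keep <- elig > 0L
  gof <- suppressWarnings(
    stats::chisq.test(priming_counts[keep],
                      p = elig[keep] / sum(elig[keep])))

  types <- vapply(parses, `[[`, "", "insert_type")
  type_counts <- table(factor(types, levels = LETTERS[seq_len(
    length(template$disruptions) + 1L)]))
  # "complete" tails: all disruptions present (== type A); also count
  # parses where additionally every polyA segment was observed
  n_type_a <- sum(types == "A")
  n_complete <- sum(vapply(parses, function(p)
    p$insert_type == "A" && nrow(p$segments) == n_seg, TRUE))

  dup_events <- sum(vapply(parses, function(p) nrow(p$duplications), 0L))

  structure(list(
    n = length(parses),
    n_internal = length(int_len), n_terminal = length(term_len),
    internal_median = stats::median(int_len),
    internal_quartiles = stats::quantile(int_len, c(0.25, 0.75),
                                         names = FALSE),
    terminal_median = stats::median(term_len),
    terminal_quartiles = stats::quantile(term_len, c(0.25, 0.75),
                                         names = FALSE),
    priming_counts = priming_counts,
    contracted_terminal = contracted,
    frac_terminal_expanded = frac_term_exp,
    frac_internal_expanded = frac_int_exp,
    frac_terminal_marker = frac_term_marker,
    frac_internal_marker = frac_int_marker,
    mann_whitney = mw,
    priming_gof = list(statistic = unname(gof$statistic),
                       df = unname(gof$parameter),
                       p.value = gof$p.value),
    type_counts = type_counts,
    n_type_a = n_type_a, n_complete = n_complete,
    duplication_events = dup_events,
    internal_lengths = int_len, internal_indices = int_idx,
    terminal_lengths = term_len, terminal_indices = term_idx),
    class = "tail_cohort_summary")
}

#' @export
print.tail_cohort_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<tail_cohort_summary> n=%d | internal n=%d median=%.1f | ",
           "terminal n=%d median=%.1f | contracted=%d | dup events=%d\n"),
    x$n, x$n_internal, x$internal_median, x$n_terminal,
    x$terminal_median, x$contracted_terminal, x$duplication_events))
  if (!is.null(x$mann_whitney))
    cat(sprintf("  internal vs terminal: U=%.1f p=%.3g\n",
                x$mann_whitney$U, x$mann_whitney$p.value))
  cat(sprintf("  priming counts: %s | GOF X2=%.2f p=%.3g\n",
              paste(x$priming_counts, collapse = "/"),
              x$priming_gof$statistic, x$priming_gof$p.value))
  invisible(x)
}
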