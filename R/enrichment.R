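# Genomic-window enrichment testing: assign inserts to non-overlapping
# windows, compare feature distributions between insert-containing and
# insert-free windows with the Mann-Whitney-Wilcoxon statistic, calibrate
# p-values by label permutation, and apply a Bonferroni correction.

#' Assign insertion positions to windows
#'
#' A window is labelled insert-containing when at least one position maps
#' inside it (windows hosting several inserts count once); positions
#' falling in no window are reported as unassigned.
#'
#' @param positions data.frame with \code{chrom}, \code{pos}.
#' @param windows data.frame with \code{window_id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive; e.g. from
#'   \code{\link{generate_feature_windows}}).
#' @return list with \code{insert_count} (per window, in window order),
#'   \code{containing} (logical), \code{n_containing},
#'   \code{n_unassigned}.
#' @export
assign_windows <- function(positions, windows) {
  w <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start, windows$end))
  p <- GenomicRanges::GRanges(positions$chrom,
                              IRanges::IRanges(positions$pos,
                                               positions$pos))
  ov <- GenomicRanges::findOverlaps(p, w, ignore.strand = TRUE)
  counts <- tabulate(S4Vectors::subjectHits(ov), nbins = length(w))
  list(insert_count = counts,
       containing = counts > 0L,
       n_containing = sum(counts > 0L),
       n_unassigned = nrow(positions) -
         length(unique(S4Vectors::queryHits(ov))))
}

#' Permutation-calibrated Mann-Whitney test of one feature
#'
#' Computes the Mann-Whitney U statistic contrasting feature values of
#' label-TRUE windows (insert-containing) against label-FALSE windows,
#' then reshuffles the labels \code{n_perm} times preserving class sizes
#' and benchmarks the observed statistic against the permutation null.
#' Empirical p-values use add-one smoothing,
#' \code{(1 + #extreme) / (1 + n_perm)}; "as or more extreme" is defined
#' on the U statistic centered at its null mean, with ties counted as
#' extreme. All three alternatives are computed from the same null
#' sample: right-sided tests whether containing windows are shifted
#' toward higher values.
#'
#' @param values numeric feature vector, one per window.
#' @param labels logical vector (TRUE = insert-containing).
#' @param n_perm number of permutations (default 10000; fewer than 100
#'   triggers a warning).
#' @param seed optional integer seed.
#' @return list with \code{U}, \code{Z}, \code{p_two}, \code{p_left},
#'   \code{p_right}, \code{n_perm}, \code{median_in}, \code{median_out}.
#' @export
permutation_test <- function(values, labels, n_perm = 10000L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(values) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels); N <- n1 + n0
  if (n1 == 0L || n0 == 0L) stop("both label classes must be non-empty")
  if (n_perm < 100L) warning("fewer than 100 permutations")
  r <- rank(values)
  const <- n1 * (n1 + 1) / 2
  U_obs <- sum(r[labels]) - const
  mu <- n1 * n0 / 2
  u_null <- vapply(seq_len(n_perm), function(b)
    sum(r[sample.int(N, n1)]) - const, 0)
  eps <- 1e-9
  p_right <- (1 + sum(u_null >= U_obs - eps)) / (1 + n_perm)
  p_left <- (1 + sum(u_null <= U_obs + eps)) / (1 + n_perm)
  p_two <- (1 + sum(abs(u_null - mu) >= abs(U_obs - mu) - eps)) /
    (1 + n_perm)
  z <- mann_whitney_u(values[labels], values[!labels],
                      alternative = "two.sided", exact_limit = 0L)$Z
  list(U = U_obs, Z = z, p_two = p_two, p_left = p_left,
       p_right = p_right, n_perm = n_perm,
       median_in = stats::median(values[labels]),
       median_out = stats::median(values[!labels]))
}

#' Bonferroni adjustment
#'
#' @param p numeric p-values in [0, 1].
#' @param m number of tests (default \code{length(p)}).
#' @return \code{pmin(1, m * p)}.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  if (m < 1L) stop("m must be >= 1")
  pmin(1, m * p)
}

#' Count a degenerate motif in a sequence
#'
#' Counts possibly-overlapping matches of a motif over \code{A/C/G/T/N}
#' (N matches any base). By default both strands are scanned and the total
#' reported, as appropriate for the strand-symmetric recombination-hotspot
#' 13-mer \code{CCNCCNTNNCCNC}.
#'
#' @param sequence DNA string.
#' @param motif motif string (IUPAC ambiguity codes allowed).
#' @param both_strands add the reverse-complement strand count (default
#'   TRUE).
#' @return integer count.
#' @export
count_motif <- function(sequence, motif = "CCNCCNTNNCCNC",
                        both_strands = TRUE) {
  subj <- Biostrings::DNAString(sequence)
  n <- Biostrings::countPattern(motif, subj, fixed = "subject")
  if (both_strands)
    n <- n + Biostrings::countPattern(
      motif, Biostrings::reverseComplement(subj), fixed = "subject")
  as.integer(n)
}

#' Feature enrichment of insert-containing windows
#'
#' Runs \code{\link{permutation_test}} for each feature column of a window
#' table, contrasting insert-containing against insert-free windows, and
#' returns a table with per-feature medians, the absolute difference in
#' medians, U, Z, the requested empirical p-value and its Bonferroni
#' adjustment (m = number of features tested).
#'
#' @param window_table data.frame from
#'   \code{\link{generate_feature_windows}} (or any table with window
#'   coordinates plus numeric feature columns).
#' @param positions insertion positions (\code{chrom}, \code{pos}).
#' @param features feature column names (default: all numeric columns
#'   other than coordinates).
#' @param n_perm permutations per feature.
#' @param alternative \code{"two"}, \code{"left"} or \code{"right"}
#'   (default \code{"right"}: containing windows shifted to higher
#'   values).
#' @param seed optional integer seed.
#' @return data.frame, one row per feature: median_in, median_out,
#'   abs_median_diff, U, Z, p_two, p_left, p_right, p (selected
#'   alternative), p_adjusted.
#' @export
enrichment_table <- function(window_table, positions, features = NULL,
                             n_perm = 10000L,
                             alternative = c("right", "left", "two"),
                             seed = NULL) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  asg <- assign_windows(positions, window_table)
  if (asg$n_containing == 0L ||
      asg$n_containing == nrow(window_table))
    stop("need both insert-containing and insert-free windows")
  if (is.null(features)) {
    skip <- c("window_id", "chrom", "start", "end", "insert_count")
    features <- setdiff(names(window_table)[vapply(window_table,
                                                   is.numeric, TRUE)],
                        skip)
  }
  rows <- lapply(features, function(f) {
    pt <- permutation_test(window_table[[f]], asg$containing,
                           n_perm = n_perm)
    data.frame(feature = f, median_in = pt$median_in,
               median_out = pt$median_out,
               abs_median_diff = abs(pt$median_in - pt$median_out),
               U = pt$U, Z = pt$Z, p_two = pt$p_two, p_left = pt$p_left,
               p_right = pt$p_right,
               p = switch(alternative, two = pt$p_two, left = pt$p_left,
                          right = pt$p_right),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni_adjust(out$p, m = length(features))
  attr(out, "n_containing") <- asg$n_containing
  attr(out, "n_unassigned") <- asg$n_unassigned
  out
}
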