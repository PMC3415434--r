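a70 <- builtin_template("A70D")
a30 <- builtin_template("A30D")

test_that("segmenting a rendered template is the identity parse", {
  p <- segment_tail(render_tail(a70), a70)
  expect_equal(p$insert_type, "A")
  expect_equal(p$priming_segment, 4L)
  expect_equal(p$segments$observed_a, a70$segments)
  expect_true(all(p$segments$expansion == 0L))
  expect_equal(nrow(p$duplications), 0L)
  expect_false(p$internal_priming)
  expect_equal(reconstruct_tail(p), render_tail(a70))
})

test_that("hand-built tails parse per the template rules", {
  # priming in segment 2 with terminal expansion
  p <- segment_tail(paste0(strrep("A", 30), "CT", strrep("A", 50)), a30)
  expect_equal(p$segments$template_index, c(1L, 2L))
  expect_equal(p$segments$observed_a, c(30L, 50L))
  expect_equal(p$priming_segment, 2L)
  expect_equal(p$disruptions$template_index, 1L)

  # homopolymer: type D for the three-disruption template
  p2 <- segment_tail(strrep("A", 40), a70)
  expect_equal(p2$insert_type, "D")
  expect_equal(nrow(p2$segments), 1L)
  expect_equal(p2$segments$observed_a, 40L)

  # internal priming within the terminal segment
  p3 <- segment_tail(paste0(strrep("A", 17), "CATTAC", strrep("A", 7)),
                     a70)
  expect_true(p3$internal_priming)
  expect_equal(p3$priming_segment, 2L)
  expect_equal(p3$priming_offset_estimate, 17L + 6L + 7L)
})

test_that("insert types follow the highest retained disruption", {
  mk <- function(...) segment_tail(paste0(...), a70)
  expect_equal(mk(strrep("A", 20), "CATTAC", strrep("A", 20), "G",
                  strrep("A", 20), "CACAC", strrep("A", 30))$insert_type,
               "A")
  expect_equal(mk(strrep("A", 20), "CATTAC", strrep("A", 20), "G",
                  strrep("A", 30))$insert_type, "B")
  expect_equal(mk(strrep("A", 20), "CATTAC", strrep("A", 40))$insert_type,
               "C")
  expect_equal(mk(strrep("A", 25))$insert_type, "D")
})

test_that("duplicated disruptions are detected with flanking A counts", {
  tail <- paste0(strrep("A", 20), "CATTAC", strrep("A", 5), "CATTAC",
                 strrep("A", 30), "G", strrep("A", 20))
  p <- segment_tail(tail, a70)
  dups <- detect_duplicated_disruptions(p)
  expect_equal(nrow(dups), 1L)
  expect_equal(dups$template_index, 1L)
  expect_equal(dups$a_before, 5L)
  expect_equal(dups$a_after, 30L)
  # duplicate A's accrue to the segment after the first copy
  expect_equal(p$segments$observed_a, c(20L, 35L, 20L))
  expect_equal(p$insert_type, "B")
  expect_equal(reconstruct_tail(p), tail)
  expect_equal(nrow(segment_tail(render_tail(a70), a70)$duplications), 0L)
})

test_that("mutated disruptions are tolerated and flagged non-exact", {
  tail <- paste0(strrep("A", 18), "CGTTAC", strrep("A", 25))
  p <- segment_tail(tail, a70)
  expect_equal(p$disruptions$template_index, 1L)
  expect_false(p$disruptions$exact)
  expect_equal(p$priming_segment, 2L)
  expect_equal(reconstruct_tail(p), tail)
  # 1-2 nt disruptions require exact matches: a stray "C" is unparseable,
  # not a mutated "G"
  p2 <- segment_tail(paste0(strrep("A", 18), "C", strrep("A", 25)), a70)
  expect_equal(length(p2$unparseable), 1L)
  expect_equal(nrow(p2$disruptions), 0L)
  expect_equal(reconstruct_tail(p2),
               paste0(strrep("A", 18), "C", strrep("A", 25)))
})

test_that("round-trip parse reproduces random templates exactly", {
  set.seed(303)
  for (i in 1:300) {
    tt <- random_template()
    if (sum(tt$segments) == 0) next
    p <- segment_tail(render_tail(tt), tt)
    expect_equal(p$segments$observed_a, tt$segments)
    expect_true(all(p$segments$expansion == 0L))
    if (length(tt$disruptions))
      expect_equal(p$disruptions$observed, tt$disruptions)
    expect_equal(reconstruct_tail(p), render_tail(tt))
    expect_equal(p$insert_type, "A")
  }
})

test_that("Mann-Whitney U matches hand results and the exact tail", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 1 / 20)
  expect_equal(r$method, "exact")

  # identical multisets: symmetric, Z ~ 0, p ~ 1
  r2 <- mann_whitney_u(rep(c(1, 5, 9), 8), rep(c(1, 5, 9), 8))
  expect_lt(abs(r2$Z), 1e-8)
  expect_equal(r2$p.value, 1)

  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p equals the enumeration oracle", {
  set.seed(11)
  for (rep in 1:40) {
    n1 <- sample(1:5, 1)
    n2 <- sample(1:(10 - n1), 1)
    vals <- sample(1:6, n1 + n2, replace = TRUE)  # ties likely
    x <- vals[seq_len(n1)]
    y <- vals[-seq_len(n1)]
    for (alt in c("two.sided", "less", "greater")) {
      got <- mann_whitney_u(x, y, alternative = alt)
      ora <- mw_enum_oracle(x, y, alternative = alt)
      expect_equal(got$U, ora$U)
      expect_equal(got$p.value, ora$p, tolerance = 1e-12)
    }
  }
})

test_that("normal-approximation p agrees with wilcox.test", {
  set.seed(21)
  x <- rnorm(25)
  y <- rnorm(30, 0.4)
  got <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  # with ties
  xt <- sample(1:8, 25, replace = TRUE)
  yt <- sample(2:9, 30, replace = TRUE)
  expect_equal(mann_whitney_u(xt, yt)$p.value,
               stats::wilcox.test(xt, yt, correct = TRUE,
                                  exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("cohort summary handles the all-parental degenerate case", {
  parses <- lapply(1:5, function(i) segment_tail(render_tail(a70), a70))
  s <- suppressWarnings(summarize_tail_cohort(parses, a70))
  expect_equal(s$n_terminal, 5L)
  expect_equal(s$n_internal, 15L)
  expect_equal(s$contracted_terminal, 0L)
  expect_equal(s$frac_terminal_expanded, 0)
  expect_equal(s$frac_internal_expanded, 0)
  expect_equal(s$duplication_events, 0L)
  expect_equal(sum(s$type_counts), 5L)
})

test_that("priming GOF is null when counts match eligible lengths", {
  eq <- tail_template("EQ", c(15L, 15L, 15L, 15L),
                      c("CAT", "G", "CGC"))
  parses <- lapply(c(1, 2, 3, 4), function(p) {
    segs <- eq$segments[seq_len(p)]
    parts <- character(0)
    for (s in seq_len(p)) {
      parts <- c(parts, strrep("A", segs[s]))
      if (s < p) parts <- c(parts, eq$disruptions[s])
    }
    segment_tail(paste(parts, collapse = ""), eq)
  })
  s <- suppressWarnings(summarize_tail_cohort(parses, eq))
  expect_equal(s$priming_counts, rep(1L, 4))
  expect_equal(s$priming_gof$statistic, 0, tolerance = 1e-12)
  expect_equal(s$priming_gof$p.value, 1)
})

test_that("contraction arises only in terminal segments without deletion", {
  set.seed(55)
  sp <- slippage_params(p_duplicate = 1)  # deletion slips disabled
  for (i in 1:200) {
    rt <- reverse_transcribe_tail(a70, sp)
    p <- segment_tail(rt$realized_tail, a70)
    internal <- p$segments[p$segments$template_index != p$terminal_index, ]
    expect_true(all(internal$observed_a >= internal$parental))
  }
})
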