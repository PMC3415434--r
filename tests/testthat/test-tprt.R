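a70 <- builtin_template("A70D")

test_that("endonuclease site selection honours planted consensus sites", {
  # one perfect bottom-strand site in an otherwise site-free sequence:
  # top strand TTAAAA <=> bottom 5'-TTTT/AA-3'
  g1 <- c(chrX = paste0(strrep("G", 60), "TTAAAA", strrep("G", 60)))
  s <- select_target_site(g1, edge_margin = 5L, seed = 1)
  expect_equal(s$pos, 62L)  # insertion gap between TT and AAAA
  expect_equal(s$strand, "+")
  expect_equal(s$score, 6L)

  expect_error(select_target_site(c(chrX = strrep("G", 200)),
                                  edge_margin = 5L),
               "no endonuclease site")

  # two perfect sites: close to 50/50 over repeated draws
  g2 <- c(chrX = paste0(strrep("G", 50), "TTAAAA", strrep("G", 100),
                        "TTAAAA", strrep("G", 50)))
  set.seed(42)
  picks <- replicate(2000, select_target_site(g2, edge_margin = 5L)$pos)
  share <- mean(picks == 52L)
  ci <- qbinom(c(0.0005, 0.9995), 2000, 0.5) / 2000  # 99.9% band
  expect_gte(share, ci[1])
  expect_lte(share, ci[2])
})

test_that("minus-strand consensus sites are found and oriented", {
  g <- c(chrX = paste0(strrep("C", 60), "TTTTAA", strrep("C", 60)))
  s <- select_target_site(g, edge_margin = 5L, seed = 3)
  expect_equal(s$strand, "-")
  expect_equal(s$score, 6L)
  expect_equal(s$pos, 64L)  # gap between TTTT and AA on the nicked strand
})

test_that("reverse transcription without slippage copies a template prefix", {
  L <- nchar(render_tail(a70))
  rt <- reverse_transcribe_tail(a70, slippage_params(p_dissoc0 = 0),
                                primed_position = L)
  expect_equal(rt$realized_tail, render_tail(a70))
  expect_equal(nrow(rt$slip_events), 0L)

  rt2 <- reverse_transcribe_tail(a70, slippage_params(p_dissoc0 = 0),
                                 primed_position = 30L)
  expect_equal(rt2$realized_tail, substr(render_tail(a70), 1, 30))

  set.seed(9)
  for (i in 1:25) {
    rt3 <- reverse_transcribe_tail(a70, slippage_params(p_dissoc0 = 0))
    expect_gt(rt3$primed_position, 20L)
    expect_equal(rt3$realized_tail,
                 substr(render_tail(a70), 1, rt3$primed_position))
  }
  expect_error(
    reverse_transcribe_tail(tail_template("short", 10L),
                            slippage_params()),
    "min_prime_offset")
})

test_that("replaying slip events reconstructs the realized tail", {
  set.seed(13)
  for (i in 1:150) {
    rt <- reverse_transcribe_tail(a70, slippage_params())
    expect_equal(replay_slippage(a70, rt$primed_position, rt$slip_events),
                 rt$realized_tail)
  }
})

test_that("duplication slips crossing a disruption copy its sequence", {
  set.seed(31)
  sp <- slippage_params(p_dissoc0 = 0.9, decay_scale = 60,
                        p_duplicate = 1, slip_span_mean = 8,
                        slip_span_max = 10L, p_cross_disruption = 1)
  hits <- 0L
  intact <- 0L
  for (i in 1:200) {
    rt <- reverse_transcribe_tail(a70, sp, primed_position = 82L)
    full_dup <- any(grepl("CATTAC", rt$slip_events$substring,
                          fixed = TRUE) &
                      rt$slip_events$kind == "duplication")
    if (full_dup) hits <- hits + 1L
    # a later slip can fragment a re-copied disruption, so intact second
    # copies are a subset of the crossing duplications
    if (lengths(gregexpr("CATTAC", rt$realized_tail, fixed = TRUE)) >= 2L)
      intact <- intact + 1L
  }
  expect_gte(hits, 3L)
  expect_gte(intact, 1L)
  # and with crossing disabled, duplicated disruptions are impossible
  sp0 <- slippage_params(p_dissoc0 = 0.9, decay_scale = 60,
                         p_duplicate = 1, slip_span_mean = 8,
                         p_cross_disruption = 0)
  set.seed(32)
  for (i in 1:50) {
    rt <- reverse_transcribe_tail(a70, sp0, primed_position = 82L)
    expect_lte(lengths(gregexpr("CATTAC", rt$realized_tail,
                                fixed = TRUE)), 1L)
  }
})

test_that("mean realized tail length is monotone in p_duplicate", {
  mean_len <- function(p_dup) {
    set.seed(71)
    mean(vapply(1:300, function(i)
      nchar(reverse_transcribe_tail(
        a70, slippage_params(p_duplicate = p_dup),
        primed_position = 82L)$realized_tail), 0))
  }
  lens <- vapply(c(0.1, 0.5, 0.9), mean_len, 0)
  expect_true(all(diff(lens) >= 0))
})

test_that("terminal segments expand more than internal segments", {
  set.seed(83)
  parses <- lapply(1:400, function(i) {
    rt <- reverse_transcribe_tail(a70, slippage_params())
    segment_tail(rt$realized_tail, a70)
  })
  s <- suppressWarnings(summarize_tail_cohort(parses, a70))
  expect_gt(s$terminal_median, s$internal_median)
  expect_lt(s$mann_whitney$p.value, 1e-4)
  # per-segment expectation is non-increasing from terminal toward the
  # 5' end: pool expansions by distance from the terminal segment
  expansions <- list()
  for (p in parses) {
    d <- p$terminal_index - p$segments$template_index
    for (k in seq_along(d)) {
      key <- as.character(d[k])
      expansions[[key]] <- c(expansions[[key]], p$segments$expansion[k])
    }
  }
  ord <- as.character(0:2)
  means <- vapply(ord, function(k) mean(expansions[[k]]), 0)
  expect_true(all(diff(means) <= 0))
})

test_that("integration builds a TPRT locus with identical repeat copies", {
  genome <- fixture_genome()
  cons <- default_construct("A70D")
  site <- select_target_site(genome, n = 1L, edge_margin = 600L, seed = 5)
  site$strand <- "+"
  rt <- reverse_transcribe_tail(cons$tail,
                                slippage_params(p_dissoc0 = 0),
                                primed_position = 82L)
  ins <- integrate_insertion(genome, site, cons, rt$realized_tail,
                             tsd_len = 14L)
  post <- ins$post_locus
  # drawn copies flank the insert identically
  f5 <- 500L
  copy1 <- substr(post, f5 + 1L, f5 + 14L)
  elem_len <- nchar(cons$body) + nchar(rt$realized_tail)
  copy2 <- substr(post, f5 + 15L + elem_len, f5 + 28L + elem_len)
  expect_equal(copy1, copy2)
  expect_equal(nchar(copy1), 14L)
  expect_true(grepl(cons$body, post, fixed = TRUE))
  # truncation guard
  expect_error(
    integrate_insertion(genome, site, cons, rt$realized_tail, 14L,
                        truncation_5p = nchar(cons$body) - 10L),
    "too little body")
})

test_that("atypical events lack duplications and consensus sites", {
  genome <- fixture_genome()
  cons <- default_construct("A70D")
  tail <- substr(render_tail(cons$tail), 1, 40)
  set.seed(61)
  chim <- make_atypical(genome, cons, "chimeric", realized_tail = tail,
                        deletion = 2000L)
  res <- characterize_insert(chim$pre_locus, chim$post_locus, cons,
                             repeats = genome$repeat_library["Alu"])
  expect_lt(res$tsd_len, 5L)
  expect_equal(res$insertion_class, "chimeric_recombination")
  # post locus layout: flanks + genomic-Alu 5' part + construct 3' part
  # + tail; the 3' flank starts `deletion` bases downstream of the
  # breakpoint, so the deletion is visible as pre/post flank offset
  expect_equal(
    nchar(chim$post_locus),
    1000L + 150L + (nchar(cons$body) - nchar(cons$body) %/% 2L) +
      nchar(tail))
  del_flank <- substr(chim$post_locus, nchar(chim$post_locus) - 499L,
                      nchar(chim$post_locus))
  expect_false(substr(chim$pre_locus, 501L, 520L) ==
                 substr(del_flank, 1L, 20L))

  eni <- make_atypical(genome, cons, "endonuclease_independent",
                       realized_tail = tail)
  res2 <- characterize_insert(eni$pre_locus, eni$post_locus, cons,
                              repeats = genome$repeat_library["Alu"])
  expect_lt(res2$tsd_len, 5L)
  expect_lt(res2$en_score, 4L)
  expect_equal(res2$insertion_class, "endonuclease_independent")
})
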