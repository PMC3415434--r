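cons70 <- default_construct("A70D")

# hand-built locus: flank5 + D + body + tail + D + flank3
hand_locus <- function(tsd = "GATCGTTACGCTAG", tail_len = 82L,
                       trunc = 0L) {
  set.seed(nchar(tsd) * 1000L + tail_len + trunc)
  f5 <- paste0(random_seq(200, 0.45), "C")  # non-A junction
  rest <- paste0("G", random_seq(200, 0.45))
  body <- substr(cons70$body, trunc + 1L, nchar(cons70$body))
  tail <- substr(render_tail(cons70$tail), 1L, tail_len)
  list(pre = paste0(f5, tsd, rest),
       post = paste0(f5, tsd, body, tail, tsd, rest),
       f5_len = nchar(f5))
}

test_that("find_tsd recovers a constructed duplication exactly", {
  h <- hand_locus()
  res <- find_tsd(h$pre, h$post, cons70)
  expect_true(res$found)
  expect_equal(res$tsd_seq, "GATCGTTACGCTAG")
  expect_equal(res$tsd_len, 14L)
  expect_equal(res$strand, "+")
  expect_equal(res$truncation, 0L)
  expect_equal(res$tail_seq, render_tail(cons70$tail))

  # unresolvable when the body is absent
  res2 <- find_tsd(h$pre, paste0(h$pre, "TTTT"), cons70)
  expect_false(res2$found)
})

test_that("junction A-assignment policies split an A-leading duplication", {
  h <- hand_locus(tsd = "AAAAGTCGTGCTTG")
  tailp <- find_tsd(h$pre, h$post, cons70, a_policy = "tail")
  expect_equal(tailp$tsd_len, 10L)
  expect_equal(tailp$tsd_seq, "GTCGTGCTTG")
  expect_equal(tailp$tail_seq,
               paste0(render_tail(cons70$tail), "AAAA"))
  tsdp <- find_tsd(h$pre, h$post, cons70, a_policy = "tsd")
  expect_equal(tsdp$tsd_len, 14L)
  expect_equal(tsdp$tsd_seq, "AAAAGTCGTGCTTG")
  expect_equal(tsdp$tail_seq, render_tail(cons70$tail))
})

test_that("5' truncations are measured from the anchored body", {
  # TSD ending in T: body position 50 is G, so the alignment cannot
  # extend ambiguously across the junction
  h <- hand_locus(tsd = "GATCGTTACGCTAT", trunc = 50L)
  res <- find_tsd(h$pre, h$post, cons70)
  expect_equal(res$truncation, 50L)
  expect_equal(res$tsd_len, 14L)
  h0 <- hand_locus(trunc = 0L)
  expect_equal(find_tsd(h0$pre, h0$post, cons70)$truncation, 0L)
})

test_that("find_tsd agrees with a junction-anchored brute-force oracle", {
  g <- fixture_genome()
  co <- fixture_clean_cohort()
  typ <- co$truth$class == "typical"
  # oracle: with known junctions (element-oriented), the duplication is
  # the longest k with post[j5-k..j5-1] == post[j3+1..j3+k], scanned by
  # direct string comparison from k = 50 down
  oracle_k <- function(post, j5, j3, max_len = 50L) {
    for (k in seq(min(max_len, j5 - 1L, nchar(post) - j3), 1L)) {
      if (substr(post, j5 - k, j5 - 1L) ==
          substr(post, j3 + 1L, j3 + k)) return(k)
    }
    0L
  }
  n_checked <- 0L
  for (i in which(typ)[1:40]) {
    res <- find_tsd(co$records$pre_locus[i], co$records$post_locus[i],
                    default_construct("A70D"))
    work <- if (res$strand == "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(co$records$post_locus[i])))
    } else co$records$post_locus[i]
    expect_equal(oracle_k(work, res$j5, res$j3), res$tsd_len)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 40L)
})

test_that("endonuclease windows are scored on the nicked strand", {
  # plus-strand element: top strand reads TT|AAAA at the cleavage
  pre <- paste0(strrep("C", 50), "TTAAAA", strrep("C", 50))
  r <- score_en_site(pre, 53L)
  expect_equal(r$score, 6L)
  expect_equal(r$strand, "+")
  expect_equal(r$window, "TTTTAA")
  # one mismatch on the nicked strand: bottom TTTCAA <=> top TTGAAA
  pre2 <- paste0(strrep("C", 50), "TTGAAA", strrep("C", 50))
  expect_equal(score_en_site(pre2, 53L)$score, 5L)
  # no consensus at all
  expect_equal(score_en_site(strrep("G", 100), 50L)$score, 0L)
  # minus orientation: top strand itself reads TTTT|AA
  pre3 <- paste0(strrep("C", 50), "TTTTAA", strrep("C", 50))
  r3 <- score_en_site(pre3, 55L)
  expect_equal(r3$score, 6L)
  expect_equal(r3$strand, "-")
  # clipped when the better window runs off the sequence edge
  expect_true(score_en_site("TTAA", 3L)$clipped)
})

test_that("target PFMs summarize aligned windows", {
  pfm <- build_target_pfm(rep("TTTTAA", 10))
  expect_equal(dim(pfm), c(6L, 4L))
  expect_true(all(abs(rowSums(pfm) - 1) < 1e-12))
  expect_equal(attr(pfm, "consensus"), "TTTTAA")
  expect_equal(unname(pfm[1, "T"]), 1)

  pfm2 <- build_target_pfm(c("TTTTAA", "CTTTAA"))
  expect_equal(unname(pfm2[1, "T"]), 0.5)
  expect_equal(unname(pfm2[1, "C"]), 0.5)
  expect_error(build_target_pfm(character()), "no windows")
  expect_error(build_target_pfm(c("AA", "AAA")), "equal length")
})

test_that("body mismatch scan excludes the A-rich middle", {
  h <- hand_locus()
  res <- find_tsd(h$pre, h$post, cons70)
  mm0 <- scan_body_mismatches(res, cons70)
  expect_equal(mm0$mismatches, 0L)
  expect_equal(mm0$analyzed_bp,
               nchar(cons70$body) -
                 (cons70$a_rich_middle[2] - cons70$a_rich_middle[1] + 1L))

  # plant two substitutions outside the mask and one inside
  post <- h$post
  poke <- function(s, body_pos) {
    cur <- substr(cons70$body, body_pos, body_pos)
    substr(s, h$f5_len + 14L + body_pos, h$f5_len + 14L + body_pos) <-
      setdiff(c("C", "G", "T"), cur)[1]
    s
  }
  post <- poke(post, 10L)
  post <- poke(post, 200L)
  mid <- cons70$a_rich_middle[1] + 2L
  post <- poke(post, mid)                 # inside the A-rich mask
  res2 <- find_tsd(h$pre, post, cons70)
  mm <- scan_body_mismatches(res2, cons70)
  expect_equal(mm$mismatches, 2L)
  expect_setequal(mm$positions, c(10L, 200L))
  expect_equal(mm$rate, 2 / mm0$analyzed_bp)
})

test_that("classification follows the hallmark rule table", {
  expect_equal(classify_insertion(14L, 6L), "TPRT_typical")
  expect_equal(classify_insertion(5L, 4L), "TPRT_typical")
  expect_equal(classify_insertion(0L, 2L), "endonuclease_independent")
  amb <- classify_insertion(14L, 2L)
  expect_equal(as.character(amb), "ambiguous")
  expect_match(attr(amb, "reasons"), "en_score=2")
  # chimeric requires a matching repeat for the 5' extra region
  alu <- fixture_genome()$repeat_library[["Alu"]]
  extra <- substr(alu, 11, 150)
  expect_equal(classify_insertion(0L, 5L, extra, list(alu)),
               "chimeric_recombination")
  expect_equal(as.character(classify_insertion(0L, 5L, "", list(alu))),
               "ambiguous")
})

test_that("hallmarks are recovered exactly on a slippage-free cohort", {
  g <- fixture_genome()
  co <- fixture_clean_cohort()
  cons <- default_construct("A70D")
  ch <- characterize_cohort(co$records, cons,
                            repeats = g$repeat_library["Alu"])
  typ <- co$truth$class == "typical"
  expect_equal(ch$insertion_class[typ],
               rep("TPRT_typical", sum(typ)))
  expect_equal(ch$tsd_len[typ], co$truth$tsd_len[typ])
  expect_equal(ch$tsd_seq[typ], co$truth$tsd_seq[typ])
  expect_equal(ch$truncation_5p[typ], co$truth$truncation_5p[typ])
  expect_equal(ch$strand, co$truth$strand)
  expect_equal(ch$tail_seq[typ], co$truth$tail_seq[typ])
  expect_true(all(ch$body_mismatches[typ] == 0L))
  # priming offsets and segments through the tail parser
  parses <- lapply(ch$tail_seq[typ], segment_tail,
                   template = cons$tail)
  expect_equal(vapply(parses, `[[`, 0L, "priming_segment"),
               co$truth$priming_segment[typ])
  expect_equal(vapply(parses, `[[`, 0L, "priming_offset_estimate"),
               co$truth$primed_position_obs[typ])
  # the pre-integration consensus of typical events is the canonical site
  s <- summarize_characterization(ch[typ, ])
  expect_equal(attr(s$pfm, "consensus"), "TTTTAA")
  expect_equal(s$dr_mean, mean(co$truth$tsd_len[typ]))
})

test_that("genic context classification is deterministic and stranded", {
  g <- fixture_genome()
  ann <- g$annotations
  genes <- ann[ann$type == "gene"]
  minus <- genes[as.character(GenomicRanges::strand(genes)) == "-"][1]
  intron <- ann[ann$type == "intron" &
                  ann$gene_id == minus$gene_id]
  pos_in <- GenomicRanges::start(intron) + 5L
  cds <- ann[ann$type == "CDS" & ann$gene_id == minus$gene_id][1]
  positions <- data.frame(
    chrom = rep(as.character(GenomicRanges::seqnames(minus)), 3),
    pos = c(pos_in, GenomicRanges::start(cds) + 2L, 1L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  res <- classify_genic_context(positions, ann)
  expect_equal(res$per_position$context,
               c("intron", "CDS", "intergenic"))
  expect_equal(res$per_position$orientation[1:2],
               c("antisense", "sense"))
  expect_equal(res$n_genic, 2L)

  # cohort-scale sense/antisense binomial test: 47 sense of 130 genic
  p_expected <- stats::binom.test(47, 130, 0.5)$p.value
  expect_equal(round(p_expected, 3), 0.002)
})
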