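test_that("genome generation is deterministic under a fixed seed", {
  g1 <- generate_genome(c(chrA = 20000L), seed = 7)
  g2 <- generate_genome(c(chrA = 20000L), seed = 7)
  expect_identical(g1$chromosomes, g2$chromosomes)
  expect_identical(as.data.frame(g1$annotations),
                   as.data.frame(g2$annotations))
  g3 <- generate_genome(c(chrA = 20000L), seed = 8)
  expect_false(identical(g1$chromosomes, g3$chromosomes))
})

test_that("annotation densities follow the requested parameters", {
  g <- generate_genome(c(chrA = 50000L), repeat_density = c(Alu = 0),
                       gene_density = 0.2, seed = 3)
  expect_equal(sum(g$annotations$type == "repeat"), 0L)

  g2 <- fixture_genome()
  ann <- g2$annotations
  expect_setequal(unique(ann$type[ann$type == "repeat"]), "repeat")
  alu_bp <- sum(IRanges::width(ann[ann$type == "repeat" &
                                     ann$class == "Alu"]))
  expect_equal(alu_bp / 140000, 0.10, tolerance = 0.05)
  # intervals lie within chromosome bounds and gene substructure nests
  expect_true(all(GenomicRanges::start(ann) >= 1))
  genes <- ann[ann$type == "gene"]
  subs <- ann[ann$type %in% c("UTR", "CDS", "intron")]
  ov <- GenomicRanges::findOverlaps(subs, genes, type = "within",
                                    ignore.strand = TRUE)
  expect_equal(length(unique(S4Vectors::queryHits(ov))), length(subs))
})

test_that("background GC tracks the target within the sampling bound", {
  g <- generate_genome(c(chrA = 100000L),
                       repeat_density = c(Alu = 0), gene_density = 0,
                       conserved_density = 0, en_site_per_kb = 0,
                       gc = 0.41, seed = 5)
  gc <- Biostrings::letterFrequency(
    Biostrings::DNAString(g$chromosomes[[1]]), "GC", as.prob = TRUE)
  expect_equal(unname(gc), 0.41, tolerance = 0.02 / 0.41)
})

test_that("feature windows tile the genome with brute-force motif counts", {
  g <- fixture_genome()
  fw <- generate_feature_windows(g, 10000L)
  expect_equal(sum(fw$end - fw$start + 1L), 140000L)
  # non-overlapping per chromosome
  for (cn in unique(fw$chrom)) {
    w <- fw[fw$chrom == cn, ]
    expect_true(all(w$start[-1] == w$end[-nrow(w)] + 1L))
  }
  expect_true(all(fw$gene_content >= 0 & fw$gene_content <= 1))
  # sliding-window motif oracle on every window
  motif <- "CCNCCNTNNCCNC"
  mlen <- nchar(motif)
  fixed <- strsplit(motif, "")[[1]] != "N"
  mref <- strsplit(motif, "")[[1]]
  brute <- function(s) {
    ch <- strsplit(s, "")[[1]]
    rc <- strsplit(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s))), "")[[1]]
    cnt <- 0L
    for (v in list(ch, rc)) {
      if (length(v) < mlen) next
      for (i in 1:(length(v) - mlen + 1L)) {
        if (all(v[i:(i + mlen - 1L)][fixed] == mref[fixed]))
          cnt <- cnt + 1L
      }
    }
    cnt
  }
  seqs <- vapply(seq_len(nrow(fw)), function(i)
    genome_subseq(g, fw$chrom[i], fw$start[i], fw$end[i]), "")
  expect_equal(fw$motif_count, vapply(seqs, brute, 0L, USE.NAMES = FALSE))
})

test_that("cohort generation respects the class mix by construction", {
  g <- fixture_genome()
  cons <- default_construct("A70D")
  co_t <- generate_cohort(g, cons, n = 10,
                          class_mix = c(typical = 1, chimeric = 0,
                                        endonuclease_independent = 0),
                          seed = 21)
  expect_true(all(co_t$truth$class == "typical"))
  expect_true(all(co_t$truth$tsd_len >= 5L))

  co_c <- generate_cohort(g, cons, n = 6,
                          class_mix = c(typical = 0, chimeric = 1,
                                        endonuclease_independent = 0),
                          seed = 22)
  ch <- characterize_cohort(co_c$records, cons,
                            repeats = g$repeat_library["Alu"])
  expect_true(all(ch$tsd_len < 5L))
  expect_error(
    generate_cohort(g, cons, n = 5, class_mix = c(typical = 0.7,
                                                  chimeric = 0.2,
                                                  endonuclease_independent
                                                  = 0.2), seed = 1),
    "sum to 1")
})

test_that("cohorts are byte-identical under a fixed seed", {
  g <- fixture_genome()
  cons <- default_construct("A30D")
  co1 <- generate_cohort(g, cons, n = 12, seed = 99)
  co2 <- generate_cohort(g, cons, n = 12, seed = 99)
  expect_identical(co1$records, co2$records)
  expect_identical(co1$truth, co2$truth)
})

test_that("genome and cohort fixtures round-trip through disk formats", {
  dir <- withr::local_tempdir()
  g <- generate_genome(c(chrA = 20000L), seed = 12)
  paths <- write_genome(g, dir)
  expect_true(all(file.exists(paths)))
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(as.character(fa[["chrA"]]), g$chromosomes[["chrA"]])
  bed <- read.delim(paths[["bed"]], header = FALSE)
  expect_equal(nrow(bed), length(g$annotations))
  expect_true(all(bed$V2 >= 0))
  expect_true(all(bed$V3 > bed$V2))

  co <- generate_cohort(fixture_genome(), default_construct("A70D"),
                        n = 8, seed = 31)
  write_cohort(co, dir, seed = 31)
  back <- read_cohort(dir)
  expect_equal(back$records$post_locus, co$records$post_locus)
  expect_equal(back$records$id, co$records$id)
  expect_equal(nrow(back$truth), 8L)
})
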