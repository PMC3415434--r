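toy_windows <- function(n, width = 1000L) {
  data.frame(window_id = sprintf("w%03d", seq_len(n)), chrom = "chrT",
             start = (seq_len(n) - 1L) * width + 1L,
             end = seq_len(n) * width, stringsAsFactors = FALSE)
}

test_that("window assignment counts containing windows once", {
  w <- toy_windows(300L)
  # 217 inserts, 14 windows carrying two each -> 203 containing windows
  doubles <- rep(1:14, each = 2L)
  singles <- 15:203
  pos <- data.frame(chrom = "chrT",
                    pos = c(doubles, singles) * 1000L - 500L)
  asg <- assign_windows(pos, w)
  expect_equal(asg$n_containing, 203L)
  expect_equal(sum(asg$insert_count), 217L)
  expect_equal(sum(asg$insert_count == 2L), 14L)
  expect_equal(asg$n_unassigned, 0L)

  expect_equal(assign_windows(pos[0, ], w)$n_containing, 0L)
  off <- data.frame(chrom = "chrT", pos = 300L * 1000L + 50L)
  expect_equal(assign_windows(off, w)$n_unassigned, 1L)
})

test_that("permutation p-values obey the add-one smoothing floor", {
  set.seed(5)
  values <- c(rnorm(20, 10), rnorm(180, 0))  # grossly separated
  labels <- c(rep(TRUE, 20), rep(FALSE, 180))
  pt <- permutation_test(values, labels, n_perm = 999L, seed = 8)
  expect_equal(pt$p_right, 1 / 1000)
  expect_equal(pt$p_two, 1 / 1000)
  expect_gt(pt$p_left, 0.99)
  expect_error(permutation_test(values, rep(TRUE, 200)), "non-empty")
  expect_warning(permutation_test(values, labels, n_perm = 50L),
                 "fewer than 100")
})

test_that("empirical p matches the exhaustive labeling oracle on a toy", {
  values <- c(3.2, 1.1, 4.8, 0.7, 2.9, 5.5, 1.8, 4.1)
  labels <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  # exhaustive: all C(8,3) labelings of the same values
  r <- rank(values)
  n1 <- 3L
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_all <- apply(utils::combn(8L, n1), 2, u_of)
  U_obs <- u_of(which(labels))
  mu <- n1 * 5L / 2
  exact_two <- mean(abs(u_all - mu) >= abs(U_obs - mu) - 1e-9)
  pt <- permutation_test(values, labels, n_perm = 4000L, seed = 77)
  expect_equal(pt$U, U_obs)
  expect_equal(pt$p_two, exact_two, tolerance = 0.05)
})

test_that("permutation p is invariant to monotone feature transforms", {
  set.seed(19)
  values <- rnorm(120)
  labels <- seq_along(values) %in% sample(120, 25)
  p1 <- permutation_test(values, labels, n_perm = 500L, seed = 4)
  p2 <- permutation_test(exp(values), labels, n_perm = 500L, seed = 4)
  expect_equal(p1$p_two, p2$p_two)
  expect_equal(p1$U, p2$U)
})

test_that("permutation p converges to the normal approximation", {
  set.seed(29)
  values <- rnorm(400)
  labels <- c(rep(TRUE, 200), rep(FALSE, 200))
  pt <- permutation_test(values, labels, n_perm = 4000L, seed = 6)
  ref <- mann_whitney_u(values[labels], values[!labels])$p.value
  expect_equal(pt$p_two, ref, tolerance = 0.02 / max(ref, 0.05))
})

test_that("Bonferroni adjustment is the capped product", {
  expect_equal(bonferroni_adjust(0.004, m = 9), 0.036)
  expect_equal(bonferroni_adjust(0.5, m = 9), 1)
  expect_equal(bonferroni_adjust(c(0.01, 0.2), m = 1), c(0.01, 0.2))
  p <- c(0.001, 0.04, 0.7)
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_error(bonferroni_adjust(1.2), "in \\[0, 1\\]")
})

test_that("degenerate motif counting handles overlap and strand", {
  expect_equal(count_motif("CCACCATAACCAC", both_strands = FALSE), 1L)
  expect_equal(count_motif(strrep("A", 100), both_strands = FALSE), 0L)
  expect_equal(count_motif("CCACCATAACCACCCACCATAACCAC",
                           both_strands = FALSE), 2L)
  # reverse-complement occurrences are picked up in both-strand mode
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("CCACCATAACCAC")))
  expect_equal(count_motif(rc, both_strands = FALSE), 0L)
  expect_equal(count_motif(rc), 1L)
})

test_that("enrichment detects planted feature shifts and not null ones", {
  set.seed(91)
  w <- toy_windows(200L)
  w$sine_count <- rpois(200L, 8)
  w$gc_content <- rnorm(200L, 0.41, 0.02)
  containing <- sample(200L, 40L)
  # plant a 2x SINE enrichment in containing windows
  w$sine_count[containing] <- rpois(40L, 16)
  pos <- data.frame(chrom = "chrT", pos = containing * 1000L - 500L)
  et <- enrichment_table(w, pos, n_perm = 2000L, seed = 13)
  expect_equal(nrow(et), 2L)
  sine <- et[et$feature == "sine_count", ]
  gc <- et[et$feature == "gc_content", ]
  expect_lt(sine$p_adjusted, 0.05)
  expect_gt(gc$p_adjusted, 0.05)
  expect_equal(sine$abs_median_diff,
               abs(sine$median_in - sine$median_out))
  # determinism under the seed
  et2 <- enrichment_table(w, pos, n_perm = 2000L, seed = 13)
  expect_identical(et$p, et2$p)
})
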