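# Shared fixtures, built once per test run. The fixture genome is small
# enough to build in a few seconds but carries every annotation class and
# plenty of perfect endonuclease sites.

fixture_env <- new.env(parent = emptyenv())

fixture_genome <- function() {
  if (is.null(fixture_env$genome)) {
    fixture_env$genome <- generate_genome(
      chrom_sizes = c(chr1 = 80000L, chr2 = 60000L),
      en_site_per_kb = 1, seed = 424242)
  }
  fixture_env$genome
}

# deterministic cohort with slippage disabled: every hallmark is exactly
# recoverable, so it backs the parameter-recovery tests
fixture_clean_cohort <- function() {
  if (is.null(fixture_env$clean)) {
    fixture_env$clean <- generate_cohort(
      fixture_genome(), default_construct("A70D"), n = 80,
      slippage = slippage_params(p_dissoc0 = 0), seed = 777)
  }
  fixture_env$clean
}

# random valid tail template (disruptions never start/end with A and
# contain no long A runs)
random_template <- function() {
  n_seg <- sample(1:5, 1)
  segs <- sample(5:25, n_seg, replace = TRUE)
  dis <- character(max(0, n_seg - 1))
  if (n_seg > 1) {
    for (i in seq_len(n_seg - 1)) {
      len <- sample(1:6, 1)
      repeat {
        d <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                          prob = c(0.2, 0.3, 0.2, 0.3)), collapse = "")
        if (!grepl("^A|A$", d) && !grepl("A{4,}", d)) break
      }
      dis[i] <- d
    }
  }
  tail_template(sprintf("rnd%d", sample.int(1e6, 1)), segs, dis)
}

# pairwise-comparison Mann-Whitney oracle: U from direct x>y counts and an
# exact p from enumerating every group labeling of the pooled values
mw_enum_oracle <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U_obs <- u_of(x, y)
  combs <- utils::combn(N, n1)
  u_all <- apply(combs, 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  mu <- n1 * (N - n1) / 2
  eps <- 1e-9
  p <- switch(alternative,
    less = mean(u_all <= U_obs + eps),
    greater = mean(u_all >= U_obs - eps),
    two.sided = mean(abs(u_all - mu) >= abs(U_obs - mu) - eps))
  list(U = U_obs, p = p)
}
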