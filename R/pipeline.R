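# Pipeline orchestration: file-based subcommand equivalents (simulate /
# characterize / tails / enrich) tying the modules into reproducible,
# seed-stamped runs. Each step reads the previous step's outputs from the
# run directory.

#' Default pipeline configuration
#'
#' @param seed integer seed used for every stochastic step.
#' @param outdir run directory.
#' @param n cohort size.
#' @param template_name built-in tail template name.
#' @param chrom_sizes fixture genome dimensions.
#' @param window_size feature-window width (nt).
#' @param n_perm permutations for enrichment testing.
#' @return named list of settings.
#' @export
pipeline_config <- function(seed = 1L, outdir = "tailslip_run",
                            n = 226L, template_name = "A70D",
                            chrom_sizes = c(chr1 = 200000L,
                                            chr2 = 150000L),
                            window_size = 2000L, n_perm = 2000L) {
  list(seed = as.integer(seed), outdir = outdir, n = as.integer(n),
       template_name = template_name, chrom_sizes = chrom_sizes,
       window_size = as.integer(window_size),
       n_perm = as.integer(n_perm))
}

#' Simulate pipeline fixtures
#'
#' Generates the fixture genome (FASTA + BED + GFF3), a uniform karyotype
#' table, the feature-window table and a simulated cohort with ground
#' truth, all under \code{config$outdir}. Idempotent under a fixed seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return named vector of written paths, invisibly.
#' @export
pipeline_simulate <- function(config = pipeline_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  genome <- generate_genome(chrom_sizes = config$chrom_sizes)
  paths <- write_genome(genome, config$outdir)

  kt <- uniform_karyotype(genome)
  kt_path <- file.path(config$outdir, "karyotype.tsv")
  write_tsv_with_header(as.data.frame(kt), kt_path, config$seed,
                        "karyotype profile")

  fw <- generate_feature_windows(genome, config$window_size)
  fw_path <- file.path(config$outdir, "feature_windows.tsv")
  write_tsv_with_header(fw, fw_path, config$seed, "feature windows")

  construct <- default_construct(config$template_name)
  cohort <- generate_cohort(genome, construct, n = config$n)
  cpaths <- write_cohort(cohort, config$outdir, config$seed)

  invisible(c(paths, karyotype = kt_path, windows = fw_path, cpaths))
}

#' Characterize a simulated (or user-supplied) cohort
#'
#' Reads the cohort FASTA pair from the run directory, characterizes every
#' insert and writes the per-insert TSV plus a cohort summary JSON
#' (class counts, direct-repeat statistics, truncation fraction, mismatch
#' totals, target-site consensus).
#'
#' @param config a \code{\link{pipeline_config}} whose \code{outdir}
#'   holds \code{\link{pipeline_simulate}} output.
#' @return path of the characterization TSV, invisibly.
#' @export
pipeline_characterize <- function(config = pipeline_config()) {
  cohort <- read_cohort(config$outdir)
  construct <- default_construct(config$template_name)
  # repeat library for the chimeric test: the genome build is
  # deterministic under the run seed, so regenerate it
  set.seed(config$seed)
  genome <- generate_genome(chrom_sizes = config$chrom_sizes)
  chr <- characterize_cohort(cohort$records, construct,
                             repeats = genome$repeat_library["Alu"])
  out <- file.path(config$outdir, "characterization.tsv")
  write_tsv_with_header(chr, out, config$seed, "insert characterization")
  s <- summarize_characterization(chr)
  s$pfm <- if (!is.null(s$pfm))
    list(matrix = unclass(s$pfm), consensus = attr(s$pfm, "consensus"))
  else NULL
  jsonlite::write_json(
    c(list(seed = config$seed), s),
    file.path(config$outdir, "characterization_summary.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}

#' Parse and summarize cohort A-tails
#'
#' Reads the characterization TSV (tail_seq column), segments every tail
#' against the template, and writes the per-insert parse TSV plus the
#' cohort tail summary JSON.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return path of the parse TSV, invisibly.
#' @export
pipeline_tails <- function(config = pipeline_config()) {
  chr <- read_tsv_table(file.path(config$outdir, "characterization.tsv"))
  template <- builtin_template(config$template_name)
  keep <- !is.na(chr$tail_seq) & nchar(chr$tail_seq) > 0
  parses <- lapply(chr$tail_seq[keep], segment_tail, template = template)
  parse_df <- data.frame(
    id = chr$id[keep],
    insert_type = vapply(parses, `[[`, "", "insert_type"),
    priming_segment = vapply(parses, `[[`, 0L, "priming_segment"),
    internal_priming = vapply(parses, `[[`, TRUE, "internal_priming"),
    segments = vapply(parses, function(p)
      paste(p$segments$observed_a, collapse = ","), ""),
    expansions = vapply(parses, function(p)
      paste(p$segments$expansion, collapse = ","), ""),
    duplications = vapply(parses, function(p) nrow(p$duplications), 0L),
    unparseable = vapply(parses, function(p)
      length(p$unparseable) > 0L, TRUE),
    stringsAsFactors = FALSE)
  out <- file.path(config$outdir, "tail_parses.tsv")
  write_tsv_with_header(parse_df, out, config$seed, "tail parses")
  s <- summarize_tail_cohort(parses, template)
  js <- list(
    seed = config$seed, n = s$n,
    n_internal = s$n_internal, n_terminal = s$n_terminal,
    internal_median = s$internal_median,
    terminal_median = s$terminal_median,
    priming_counts = s$priming_counts,
    contracted_terminal = s$contracted_terminal,
    frac_terminal_expanded = s$frac_terminal_expanded,
    frac_internal_expanded = s$frac_internal_expanded,
    type_counts = as.list(s$type_counts),
    duplication_events = s$duplication_events,
    mann_whitney_p = if (!is.null(s$mann_whitney))
      s$mann_whitney$p.value else NA,
    priming_gof_p = s$priming_gof$p.value)
  jsonlite::write_json(js, file.path(config$outdir, "tail_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Window-enrichment testing of cohort insertion positions
#'
#' Reads the feature-window table and ground-truth insertion positions and
#' writes the per-feature enrichment table (medians, absolute difference,
#' U, Z, empirical and Bonferroni-adjusted p-values).
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param alternative \code{"right"}, \code{"left"} or \code{"two"}.
#' @return path of the enrichment TSV, invisibly.
#' @export
pipeline_enrich <- function(config = pipeline_config(),
                            alternative = "right") {
  fw <- read_tsv_table(file.path(config$outdir, "feature_windows.tsv"))
  truth <- read_tsv_table(file.path(config$outdir, "ground_truth.tsv"))
  et <- enrichment_table(fw, truth[, c("chrom", "pos")],
                         n_perm = config$n_perm,
                         alternative = alternative, seed = config$seed)
  out <- file.path(config$outdir, "enrichment.tsv")
  write_tsv_with_header(et, out, config$seed, "window enrichment")
  invisible(out)
}

#' Run the full pipeline
#' @param config a \code{\link{pipeline_config}}.
#' @return the run directory, invisibly.
#' @export
pipeline_all <- function(config = pipeline_config()) {
  pipeline_simulate(config)
  pipeline_characterize(config)
  pipeline_tails(config)
  pipeline_enrich(config)
  invisible(config$outdir)
}
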