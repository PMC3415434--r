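# Simulated insertion cohorts with full ground truth: typical TPRT events
# (target-site duplication, endonuclease-consensus site, slippage-expanded
# tail, occasional 5' truncation) plus minority chimeric and
# endonuclease-independent events, as paired pre-/post-insertion loci.

#' Generate a simulated insertion cohort
#'
#' Draws an event class per insert, simulates each event with
#' \code{\link{reverse_transcribe_tail}} /
#' \code{\link{integrate_insertion}} / \code{\link{make_atypical}}, and
#' returns paired pre-/post-insertion loci together with a ground-truth
#' table. Typical events are placed at distinct perfect endonuclease
#' consensus sites (generation fails if the genome offers too few),
#' carry duplications drawn from \code{tsd_range}, and are 5'-truncated
#' with probability \code{truncation_prob}. Each typical record is
#' verified to be exactly recoverable by the characterizer under
#' \code{a_policy}; the rare record whose flank coincidentally mimics
#' tail or duplication sequence is re-placed at a spare site.
#'
#' @param genome a \code{\link{generate_genome}} result.
#' @param construct a \code{\link{construct_reference}}.
#' @param n cohort size.
#' @param class_mix named proportions over \code{typical},
#'   \code{chimeric}, \code{endonuclease_independent}; must sum to 1.
#'   Defaults to the observed 96.5 / 2.7 / 0.8 percent mix.
#' @param slippage a \code{\link{slippage_params}}.
#' @param tsd_range duplication length range (default 5-27, drawn
#'   uniformly).
#' @param truncation_prob probability of a 5' truncation (default 0.035).
#' @param driver_mix named proportions for the driver label (default the
#'   178:48 ORF2:L1 recovery mix).
#' @param minus_strand_prob probability an element integrates on the
#'   minus strand (default 0.5).
#' @param flank genomic flank kept on each side of a locus (default 500).
#' @param a_policy junction A-assignment convention for ground truth.
#' @param seed optional integer seed; fixed seed gives identical output.
#' @return list with \code{records} (data.frame: id, driver, class,
#'   pre_locus, post_locus) and \code{truth} (per-insert ground truth).
#' @export
generate_cohort <- function(genome, construct, n,
                            class_mix = c(typical = 0.965,
                                          chimeric = 0.027,
                                          endonuclease_independent = 0.008),
                            slippage = slippage_params(),
                            tsd_range = c(5L, 27L),
                            truncation_prob = 0.035,
                            driver_mix = c(ORF2 = 178, L1 = 48) / 226,
                            minus_strand_prob = 0.5,
                            flank = 500L,
                            a_policy = c("tail", "tsd"),
                            seed = NULL) {
  a_policy <- match.arg(a_policy)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(genome, "synthetic_genome"), n >= 1L)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  classes <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
  drivers <- sample(names(driver_mix), n, replace = TRUE,
                    prob = driver_mix)

  n_typ <- sum(classes == "typical")
  spare <- 50L
  sites <- if (n_typ > 0L)
    select_target_site(genome, min_score = 6L, n = n_typ + spare,
                       edge_margin = flank + 10L)
  else NULL
  # elements integrate on the drawn strand; overwrite the site-scan strand
  if (n_typ > 0L)
    sites$strand <- ifelse(stats::runif(nrow(sites)) < minus_strand_prob,
                           "-", "+")

  records <- list()
  truth <- list()
  site_i <- 0L
  for (i in seq_len(n)) {
    id <- sprintf("ins%04d", i)
    rt <- reverse_transcribe_tail(construct$tail, slippage)
    if (classes[i] == "typical") {
      tsd_target <- sample(seq(tsd_range[1], tsd_range[2]), 1L)
      trunc <- if (stats::runif(1) < truncation_prob)
        sample(30:150, 1L) else 0L
      ok <- FALSE
      for (try in 1:10) {
        site_i <- site_i + 1L
        if (site_i > nrow(sites))
          stop("ran out of target sites; increase genome size or density")
        site <- sites[site_i, ]
        # the drawn range describes the *recoverable* duplication length;
        # under the tail-first convention the target's junction A-run is
        # absorbed into the tail, so extend the generative length by it
        tsd_len <- tsd_target +
          if (a_policy == "tail")
            junction_a_run(genome, site, tsd_target) else 0L
        ins <- integrate_insertion(genome, site, construct,
                                   rt$realized_tail, tsd_len,
                                   truncation_5p = trunc, flank = flank,
                                   a_policy = a_policy)
        chk <- find_tsd(ins$pre_locus, ins$post_locus, construct,
                        a_policy = a_policy)
        if (isTRUE(chk$found) &&
            ins$truth$tsd_len >= tsd_range[1] &&
            chk$tsd_len == ins$truth$tsd_len &&
            chk$tail_seq == ins$truth$tail_seq &&
            chk$truncation == ins$truth$truncation_5p &&
            chk$strand == site$strand) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place a cleanly recoverable typical event")
      tr <- ins$truth
      records[[i]] <- data.frame(
        id = id, driver = drivers[i], class = "typical",
        pre_locus = ins$pre_locus, post_locus = ins$post_locus,
        stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        id = id, class = "typical", driver = drivers[i],
        chrom = tr$chrom, pos = tr$pos, strand = tr$strand,
        tsd_len_drawn = tr$tsd_len_drawn, tsd_len = tr$tsd_len,
        tsd_seq = tr$tsd_seq, truncation_5p = tr$truncation_5p,
        primed_position = rt$primed_position,
        # offset as observable after junction A-absorption: the absorbed
        # A's read as terminal-segment adenosines, and an apparent
        # terminal at or beyond parental length reads as end-priming
        # (capped at the priming segment's 3' end)
        primed_position_obs = min(
          rt$primed_position + tr$terminal_extra_a,
          segment_end_position(construct$tail,
                               position_to_segment(construct$tail,
                                                   rt$primed_position))),
        priming_segment = position_to_segment(construct$tail,
                                              rt$primed_position),
        terminal_extra_a = tr$terminal_extra_a,
        tail_seq = tr$tail_seq,
        n_slips = nrow(rt$slip_events),
        n_dup_slips = sum(rt$slip_events$kind == "duplication"),
        en_score = tr$en_score, stringsAsFactors = FALSE)
    } else {
      mode <- if (classes[i] == "chimeric") "chimeric"
              else "endonuclease_independent"
      at <- make_atypical(genome, construct, mode = mode,
                          realized_tail = rt$realized_tail, flank = flank)
      records[[i]] <- data.frame(
        id = id, driver = drivers[i], class = classes[i],
        pre_locus = at$pre_locus, post_locus = at$post_locus,
        stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(
        id = id, class = classes[i], driver = drivers[i],
        chrom = at$truth$chrom, pos = at$truth$pos,
        strand = at$truth$strand,
        tsd_len_drawn = 0L, tsd_len = 0L, tsd_seq = "",
        truncation_5p = NA_integer_,
        primed_position = rt$primed_position,
        primed_position_obs = rt$primed_position,
        priming_segment = position_to_segment(construct$tail,
                                              rt$primed_position),
        terminal_extra_a = 0L, tail_seq = at$truth$tail_seq,
        n_slips = nrow(rt$slip_events),
        n_dup_slips = sum(rt$slip_events$kind == "duplication"),
        en_score = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, records), truth = do.call(rbind, truth))
}

# Junction A-run absorbed into the tail at a target site: for plus-strand
# elements the leading A's of the duplicated target, for minus-strand
# elements the leading A's of its reverse complement (= trailing T-run).
# The trailing run depends on the duplication length, so iterate briefly.
junction_a_run <- function(genome, site, tsd_target) {
  f3 <- genome_subseq(genome, site$chrom, site$pos + 1L, site$pos + 90L)
  if (site$strand == "+") return(leading_a(f3))
  # smallest extension m such that the duplication minus its trailing
  # T-run is at least the target length (the run depends on where the
  # duplication ends, so scan forward)
  for (m in 0:40) {
    tsd <- substr(f3, 1L, tsd_target + m)
    if (nchar(tsd) - trailing_a(chartr("ACGT", "TGCA", tsd)) >=
        tsd_target) return(m)
  }
  0L
}

# 1-based tail coordinate of the last adenosine of a template segment
segment_end_position <- function(template, seg) {
  segs <- template$segments
  d_len <- nchar(template$disruptions)
  sum(segs[seq_len(seg)]) + sum(d_len[seq_len(seg - 1L)])
}

# template segment index containing a 1-based tail position (positions
# inside a disruption map to the preceding segment)
position_to_segment <- function(template, pos) {
  segs <- template$segments
  d_len <- nchar(template$disruptions)
  seg_end <- cumsum(segs + c(d_len, 0L))
  findInterval(pos - 1L, c(0L, seg_end)) |>
    min(length(segs))
}

#' Write a cohort to disk
#'
#' Emits paired FASTA files (\code{cohort_pre.fasta},
#' \code{cohort_post.fasta}, records named \code{<id>_pre} /
#' \code{<id>_post}), the ground-truth TSV and a manifest TSV.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param dir output directory.
#' @param seed seed recorded in the TSV headers.
#' @return named vector of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pre <- stats::setNames(cohort$records$pre_locus,
                         paste0(cohort$records$id, "_pre"))
  post <- stats::setNames(cohort$records$post_locus,
                          paste0(cohort$records$id, "_post"))
  p1 <- file.path(dir, "cohort_pre.fasta")
  p2 <- file.path(dir, "cohort_post.fasta")
  write_fasta(pre, p1)
  write_fasta(post, p2)
  p3 <- file.path(dir, "ground_truth.tsv")
  write_tsv_with_header(cohort$truth, p3, seed, "cohort ground truth")
  manifest <- cohort$records[, c("id", "driver", "class")]
  p4 <- file.path(dir, "manifest.tsv")
  write_tsv_with_header(manifest, p4, seed, "cohort manifest")
  invisible(c(pre = p1, post = p2, truth = p3, manifest = p4))
}

#' Read a cohort written by \code{\link{write_cohort}}
#' @param dir directory holding the cohort files.
#' @return list with \code{records} and \code{truth} data.frames.
#' @export
read_cohort <- function(dir) {
  pre <- read_fasta(file.path(dir, "cohort_pre.fasta"))
  post <- read_fasta(file.path(dir, "cohort_post.fasta"))
  manifest <- read_tsv_table(file.path(dir, "manifest.tsv"))
  ids <- manifest$id
  records <- data.frame(
    id = ids, driver = manifest$driver, class = manifest$class,
    pre_locus = unname(pre[paste0(ids, "_pre")]),
    post_locus = unname(post[paste0(ids, "_post")]),
    stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "ground_truth.tsv")
  truth <- if (file.exists(truth_path)) read_tsv_table(truth_path)
           else NULL
  list(records = records, truth = truth)
}
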