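# Karyotype-weighted random insertion placement: the genome is mapped to
# consecutive integer space with each region's allocation proportional to
# its copy number, positions are drawn uniformly over the integers, and
# flank G+C / repeat-class content is summarized for the sampled cohort.

#' Create and validate a karyotype copy-number profile
#'
#' @param regions data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive), \code{copy_number} (non-negative
#'   integer). Regions must tile each chromosome without overlap.
#' @param seqlengths optional named chromosome lengths; when given, full
#'   tiling is enforced.
#' @return data.frame of class \code{karyotype_profile}.
#' @export
karyotype_profile <- function(regions, seqlengths = NULL) {
  need <- c("chrom", "start", "end", "copy_number")
  stopifnot(all(need %in% names(regions)))
  regions <- regions[order(regions$chrom, regions$start), need]
  if (any(regions$copy_number < 0)) stop("copy_number must be >= 0")
  if (any(regions$end < regions$start)) stop("malformed region")
  for (cn in unique(regions$chrom)) {
    r <- regions[regions$chrom == cn, ]
    if (nrow(r) > 1L && any(r$start[-1L] <= r$end[-nrow(r)]))
      stop("overlapping karyotype regions on ", cn)
    if (!is.null(seqlengths)) {
      if (r$start[1L] != 1L || r$end[nrow(r)] != seqlengths[[cn]] ||
          (nrow(r) > 1L && any(r$start[-1L] != r$end[-nrow(r)] + 1L)))
        stop("karyotype must tile chromosome ", cn)
    }
  }
  class(regions) <- c("karyotype_profile", "data.frame")
  regions
}

#' Uniform karyotype over a genome
#' @param genome a \code{synthetic_genome} or named lengths vector.
#' @param copy_number copy number applied to every chromosome (default 2).
#' @return a \code{\link{karyotype_profile}}.
#' @export
uniform_karyotype <- function(genome, copy_number = 2L) {
  sl <- if (inherits(genome, "synthetic_genome")) genome_seqlengths(genome)
        else genome
  karyotype_profile(data.frame(
    chrom = names(sl), start = 1L, end = as.integer(sl),
    copy_number = as.integer(copy_number), stringsAsFactors = FALSE),
    seqlengths = sl)
}

#' Map a genome to copy-number-weighted integer space
#'
#' Each karyotype region of width w and copy number c receives w * c
#' consecutive integers (regions with copy number 0 receive none), so a
#' uniform draw over the integer space visits each genomic base with
#' probability proportional to its copy number. Only relative weights
#' matter, so the copy number itself (not copy number / 2) is used.
#'
#' @param genome a \code{synthetic_genome} or named chromosome-length
#'   vector.
#' @param karyotype a \code{\link{karyotype_profile}}.
#' @return data.frame of class \code{integer_map} with columns chrom,
#'   start, end, copy_number, int_start, int_end (0-based half-open
#'   integer spans) and attribute \code{total}.
#' @export
build_integer_map <- function(genome, karyotype) {
  sl <- if (inherits(genome, "synthetic_genome")) genome_seqlengths(genome)
        else genome
  karyotype <- karyotype_profile(karyotype, seqlengths = sl)
  k <- karyotype[karyotype$copy_number > 0, ]
  if (!nrow(k)) stop("karyotype allocates no integer space")
  w <- (k$end - k$start + 1) * k$copy_number
  int_end <- cumsum(as.numeric(w))
  k$int_start <- c(0, int_end[-length(int_end)])
  k$int_end <- int_end
  attr(k, "total") <- int_end[length(int_end)]
  class(k) <- c("integer_map", "data.frame")
  k
}

#' Sample insertion positions uniformly over integer space
#'
#' Each draw selects one integer uniformly, maps it back to its genomic
#' base (each base owns \code{copy_number} consecutive integers), and
#' records the insertion as occurring between that base and the next.
#'
#' @param map an \code{\link{build_integer_map}} result.
#' @param n number of positions to draw.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{chrom}, \code{pos} (1-based base
#'   5' of the insertion gap).
#' @export
sample_insertions <- function(map, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(map, "integer_map"), n >= 1L)
  total <- attr(map, "total")
  u <- floor(stats::runif(n) * total)
  u[u >= total] <- total - 1  # guard the runif(1) == 1 edge
  span <- findInterval(u, map$int_start)
  off <- u - map$int_start[span]
  base_idx <- floor(off / map$copy_number[span])
  data.frame(chrom = map$chrom[span],
             pos = as.integer(map$start[span] + base_idx),
             stringsAsFactors = FALSE)
}

#' Map an integer back to its genomic position
#' @param map an \code{integer_map}.
#' @param u integer(s) in [0, total).
#' @return data.frame chrom/pos as in \code{\link{sample_insertions}}.
#' @export
integer_to_position <- function(map, u) {
  span <- findInterval(u, map$int_start)
  off <- u - map$int_start[span]
  data.frame(chrom = map$chrom[span],
             pos = as.integer(map$start[span] +
                                floor(off / map$copy_number[span])),
             stringsAsFactors = FALSE)
}

#' Summarize flank G+C and repeat content of insertion positions
#'
#' For each position, takes \code{flank_total / 2} nt on each side
#' (clipped at chromosome ends; denominators use the realized flank
#' length) and reports the cohort mean percent G+C and the percent of
#' flank covered by each repeat class, computed by interval intersection
#' against the annotation track.
#'
#' @param positions data.frame with \code{chrom}, \code{pos}.
#' @param genome a \code{synthetic_genome}.
#' @param annotations annotation \code{GRanges} (defaults to the genome's
#'   own track).
#' @param flank_total total flank per insertion in nt (default 20000,
#'   i.e. 10 kb each side).
#' @param classes repeat classes to report.
#' @return one-row data.frame: \code{n}, \code{flank_bp}, \code{gc_pct},
#'   then one \code{pct_<class>} column per repeat class.
#' @export
summarize_flanks <- function(positions, genome, annotations = NULL,
                             flank_total = 20000L,
                             classes = REPEAT_CLASSES) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (is.null(annotations)) annotations <- genome$annotations
  half <- as.integer(flank_total / 2L)
  sl <- genome_seqlengths(genome)
  starts <- pmax(1L, positions$pos - half + 1L)
  ends <- pmin(sl[positions$chrom], positions$pos + half)
  fl <- GenomicRanges::GRanges(positions$chrom,
                               IRanges::IRanges(starts, ends))
  total_bp <- sum(IRanges::width(fl))

  gc_bp <- 0
  for (i in seq_along(fl)) {
    s <- genome_subseq(genome, positions$chrom[i], starts[i], ends[i])
    gc_bp <- gc_bp +
      sum(Biostrings::letterFrequency(Biostrings::DNAString(s), "GC"))
  }

  rep_ann <- annotations[annotations$type == "repeat"]
  out <- data.frame(n = nrow(positions), flank_bp = total_bp,
                    gc_pct = 100 * gc_bp / total_bp)
  for (cls in classes) {
    cls_ann <- GenomicRanges::reduce(rep_ann[rep_ann$class == cls],
                                     ignore.strand = TRUE)
    # per-flank overlap sums (overlapping flanks each count their bases)
    hit <- GenomicRanges::findOverlaps(fl, cls_ann, ignore.strand = TRUE)
    bp <- 0
    if (length(hit)) {
      q <- S4Vectors::queryHits(hit); sj <- S4Vectors::subjectHits(hit)
      bp <- sum(pmin(IRanges::end(fl)[q], IRanges::end(cls_ann)[sj]) -
                  pmax(IRanges::start(fl)[q],
                       IRanges::start(cls_ann)[sj]) + 1)
    }
    out[[paste0("pct_", cls)]] <- 100 * bp / total_bp
  }
  out
}
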