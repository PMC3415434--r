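# Synthetic annotated genome: a small multi-chromosome fixture with planted
# repeat/gene/conserved intervals and endonuclease consensus sites, standing
# in for a reference assembly plus its annotation tracks so that every
# downstream stage runs without external downloads.

REPEAT_CLASSES <- c("Alu", "L1", "L2", "MIR", "MaLR")
# class-typical consensus lengths for planted copies (nt)
REPEAT_CONSENSUS_LEN <- c(Alu = 300L, L1 = 1000L, L2 = 300L, MIR = 260L,
                          MaLR = 350L)

# sample non-overlapping intervals of the given widths inside [1, size],
# avoiding already-occupied ranges: each interval is placed uniformly over
# the free gaps that can host it (gap chosen with probability proportional
# to the number of admissible start positions), so placement succeeds
# whenever room exists
place_intervals <- function(size, widths, occupied) {
  out <- matrix(0L, nrow = length(widths), ncol = 2L)
  gaps <- if (length(occupied))
    IRanges::setdiff(IRanges::IRanges(1L, size), occupied)
  else IRanges::IRanges(1L, size)
  for (k in seq_along(widths)) {
    w <- widths[k]
    fit <- gaps[IRanges::width(gaps) >= w]
    if (!length(fit))
      stop("could not place requested intervals; densities too high")
    slots <- IRanges::width(fit) - w + 1L
    g <- sample.int(length(fit), 1L, prob = slots)
    s <- IRanges::start(fit)[g] + sample.int(slots[g], 1L) - 1L
    iv <- IRanges::IRanges(s, s + w - 1L)
    out[k, ] <- c(s, s + w - 1L)
    gaps <- IRanges::setdiff(gaps, iv)
  }
  occupied <- IRanges::setdiff(IRanges::IRanges(1L, size), gaps)
  list(intervals = data.frame(start = out[, 1L], end = out[, 2L]),
       occupied = occupied)
}

mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  ch <- seq_chars(x)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic annotated genome
#'
#' Builds random background sequence at a target GC fraction, then plants
#' repeat-element copies (classes Alu, L1, L2, MIR, MaLR, each copied with
#' small divergence from a fixed per-class consensus), gene models with
#' UTR/CDS/intron substructure on random strands, conserved elements, and
#' extra top-strand \code{TTAAAA} hexamers (a perfect L1 endonuclease
#' consensus site on the bottom strand) at a controllable density. Planted
#' intervals are recorded in the annotation track, which is the ground
#' truth: repeats are planted, not discovered.
#'
#' @param chrom_sizes named integer vector of chromosome lengths (>= 10 kb
#'   each).
#' @param gc target GC fraction of the background sequence in [0, 1].
#' @param repeat_density named numeric vector, fraction of each chromosome
#'   covered by each repeat class (names from
#'   \code{c("Alu","L1","L2","MIR","MaLR")}); total must leave room for
#'   genes.
#' @param gene_density fraction covered by gene models.
#' @param conserved_density fraction covered by conserved elements.
#' @param en_site_per_kb planted perfect endonuclease sites per kb (placed
#'   outside repeats so planted copies stay intact).
#' @param divergence per-base substitution rate applied to planted repeat
#'   copies (default 0.02).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return object of class \code{synthetic_genome}: \code{chromosomes}
#'   (named character), \code{annotations}
#'   (\code{\link[GenomicRanges]{GRanges}} with \code{type}, \code{class},
#'   \code{gene_id} metadata), \code{repeat_library} (per-class consensus
#'   sequences), \code{params}.
#' @export
generate_genome <- function(chrom_sizes = c(chr1 = 200000L, chr2 = 150000L),
                            gc = 0.41,
                            repeat_density = c(Alu = 0.10, L1 = 0.164,
                                               L2 = 0.032, MIR = 0.029,
                                               MaLR = 0.038),
                            gene_density = 0.3,
                            conserved_density = 0.02,
                            en_site_per_kb = 0.5,
                            divergence = 0.02,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom_sizes <- vapply(chrom_sizes, as.integer, 0L)
  if (any(chrom_sizes < 10000L)) stop("chromosomes must be >= 10 kb")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  repeat_density <- repeat_density[repeat_density > 0]
  if (length(repeat_density) &&
      !all(names(repeat_density) %in% REPEAT_CLASSES))
    stop("repeat_density names must be repeat classes")
  dens_total <- sum(repeat_density) + gene_density + conserved_density
  if (any(c(repeat_density, gene_density, conserved_density) < 0) ||
      dens_total > 0.95)
    stop("densities must be in [0,1] and jointly tileable")

  repeat_library <- lapply(REPEAT_CONSENSUS_LEN, function(n)
    random_seq(n, 0.5))

  chroms <- list()
  ann <- list()
  for (cn in names(chrom_sizes)) {
    size <- chrom_sizes[[cn]]
    ch <- random_bases(size, gc)

    # build all placement requests first and place them largest-first in
    # one pass, so big gene intervals are not starved by fragmentation
    req <- list()
    for (cls in names(repeat_density)) {
      cons <- repeat_library[[cls]]
      clen <- nchar(cons)
      total <- round(repeat_density[[cls]] * size)
      while (total > 0) {
        w <- if (stats::runif(1) < 0.3)
          sample(seq(50L, clen), 1L) else clen  # some truncated copies
        req[[length(req) + 1L]] <- list(kind = "repeat", class = cls,
                                        width = w)
        total <- total - w
      }
    }
    if (gene_density > 0) {
      total <- round(gene_density * size)
      while (total > 0) {
        w <- sample(seq(1500L, 6000L), 1L)
        req[[length(req) + 1L]] <- list(kind = "gene", class = NA, width = w)
        total <- total - w
      }
    }
    if (conserved_density > 0) {
      total <- round(conserved_density * size)
      while (total > 0) {
        w <- sample(seq(100L, 300L), 1L)
        req[[length(req) + 1L]] <- list(kind = "conserved", class = NA,
                                        width = w)
        total <- total - w
      }
    }
    n_en <- round(en_site_per_kb * size / 1000)
    for (k in seq_len(n_en))
      req[[length(req) + 1L]] <- list(kind = "en_site", class = NA,
                                      width = 6L)

    widths <- vapply(req, `[[`, 0L, "width")
    ord <- order(widths, decreasing = TRUE)
    pl <- place_intervals(size, widths[ord], IRanges::IRanges())
    iv_all <- pl$intervals[order(ord), ]  # back to request order

    gene_no <- 0L
    for (k in seq_along(req)) {
      r <- req[[k]]
      s <- iv_all$start[k]; e <- iv_all$end[k]
      if (r$kind == "repeat") {
        cons <- repeat_library[[r$class]]
        clen <- nchar(cons)
        w <- e - s + 1L
        copy <- mutate_seq(substr(cons, clen - w + 1L, clen), divergence)
        ch[s:e] <- seq_chars(copy)
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = cn, start = s, end = e, type = "repeat",
          class = r$class, gene_id = NA_character_, strand = "*",
          stringsAsFactors = FALSE)
      } else if (r$kind == "gene") {
        gene_no <- gene_no + 1L
        strand <- sample(c("+", "-"), 1L)
        gid <- sprintf("%s_g%03d", cn, gene_no)
        utr5 <- c(s, s + 99L)
        cds1 <- c(utr5[2] + 1L, utr5[2] + 200L)
        utr3 <- c(e - 99L, e)
        cds2 <- c(utr3[1] - 200L, utr3[1] - 1L)
        intr <- c(cds1[2] + 1L, cds2[1] - 1L)
        # substructure coordinates are laid out left-to-right regardless
        # of strand; extents (not reading frames) are what the fixture
        # needs
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = cn,
          start = c(s, utr5[1], cds1[1], intr[1], cds2[1], utr3[1]),
          end = c(e, utr5[2], cds1[2], intr[2], cds2[2], utr3[2]),
          type = c("gene", "UTR", "CDS", "intron", "CDS", "UTR"),
          class = NA_character_, gene_id = gid, strand = strand,
          stringsAsFactors = FALSE)
      } else if (r$kind == "conserved") {
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = cn, start = s, end = e, type = "conserved",
          class = NA_character_, gene_id = NA_character_, strand = "*",
          stringsAsFactors = FALSE)
      } else {
        ch[s:(s + 5L)] <- c("T", "T", "A", "A", "A", "A")
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = cn, start = s, end = e, type = "en_site",
          class = NA_character_, gene_id = NA_character_, strand = "+",
          stringsAsFactors = FALSE)
      }
    }

    chroms[[cn]] <- paste(ch, collapse = "")
  }

  ann_df <- do.call(rbind, ann)
  gr <- GenomicRanges::GRanges(
    seqnames = ann_df$chrom,
    ranges = IRanges::IRanges(ann_df$start, ann_df$end),
    strand = ann_df$strand,
    type = ann_df$type, class = ann_df$class, gene_id = ann_df$gene_id,
    seqlengths = chrom_sizes)

  structure(
    list(chromosomes = unlist(chroms), annotations = gr,
         repeat_library = lapply(repeat_library, identity),
         params = list(chrom_sizes = chrom_sizes, gc = gc,
                       repeat_density = repeat_density,
                       gene_density = gene_density,
                       conserved_density = conserved_density,
                       en_site_per_kb = en_site_per_kb,
                       divergence = divergence, seed = seed)),
    class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d chromosome(s), %s nt, %d annotations\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              length(x$annotations)))
  invisible(x)
}

genome_seqlengths <- function(genome) {
  stats::setNames(nchar(genome$chromosomes), names(genome$chromosomes))
}

#' Extract a subsequence from a synthetic genome, clipped at bounds
#' @param genome a \code{synthetic_genome}.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates (clipped to the
#'   chromosome).
#' @return character scalar.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  L <- nchar(genome$chromosomes[[chrom]])
  substr(genome$chromosomes[[chrom]], max(1L, start), min(L, end))
}

#' Tile a genome into feature windows
#'
#' Tiles each chromosome into non-overlapping windows (the last window of a
#' chromosome may be shorter) and computes, per window: gene content
#' (fraction of the window covered by gene intervals), SINE count (planted
#' Alu + MIR intervals overlapping the window), GC content, conserved
#' element count and counts of a degenerate motif (both strands). These are
#' the fixture-scale analogues of the 1-Mb genomic feature windows used
#' for insertion-enrichment testing.
#'
#' @param genome a \code{\link{generate_genome}} result.
#' @param window_size window width in nt (<= shortest chromosome).
#' @param motif degenerate motif over A/C/G/T/N counted per window
#'   (default the recombination-hotspot 13-mer \code{CCNCCNTNNCCNC}).
#' @return data.frame with window id, coordinates and feature columns
#'   \code{gene_content}, \code{sine_count}, \code{gc_content},
#'   \code{conserved_count}, \code{motif_count}.
#' @export
generate_feature_windows <- function(genome, window_size = 10000L,
                                     motif = "CCNCCNTNNCCNC") {
  stopifnot(inherits(genome, "synthetic_genome"))
  sl <- genome_seqlengths(genome)
  if (window_size > min(sl)) stop("window_size exceeds a chromosome length")
  tiles <- GenomicRanges::tileGenome(sl, tilewidth = window_size,
                                     cut.last.tile.in.chrom = TRUE)
  ann <- genome$annotations
  genes <- ann[ann$type == "gene"]
  sines <- ann[ann$type == "repeat" & ann$class %in% c("Alu", "MIR")]
  cons <- ann[ann$type == "conserved"]

  gene_cov <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(tiles, gene_cov,
                                     ignore.strand = TRUE)
  covered <- rep(0, length(tiles))
  if (length(hit)) {
    pieces <- GenomicRanges::pintersect(
      tiles[S4Vectors::queryHits(hit)],
      gene_cov[S4Vectors::subjectHits(hit)])
    w <- tapply(IRanges::width(pieces), S4Vectors::queryHits(hit), sum)
    covered[as.integer(names(w))] <- w
  }

  seqs <- vapply(seq_along(tiles), function(i) {
    genome_subseq(genome,
                  as.character(GenomicRanges::seqnames(tiles)[i]),
                  GenomicRanges::start(tiles)[i],
                  GenomicRanges::end(tiles)[i])
  }, "")
  gc <- vapply(seqs, function(s) {
    f <- Biostrings::letterFrequency(Biostrings::DNAString(s), "GC")
    n <- nchar(s) - Biostrings::letterFrequency(Biostrings::DNAString(s),
                                                "N")
    if (n == 0) 0 else unname(f / n)
  }, 0)

  data.frame(
    window_id = sprintf("w%04d", seq_along(tiles)),
    chrom = as.character(GenomicRanges::seqnames(tiles)),
    start = GenomicRanges::start(tiles),
    end = GenomicRanges::end(tiles),
    gene_content = covered / IRanges::width(tiles),
    sine_count = GenomicRanges::countOverlaps(tiles, sines,
                                              ignore.strand = TRUE),
    gc_content = unname(gc),
    conserved_count = GenomicRanges::countOverlaps(tiles, cons,
                                                   ignore.strand = TRUE),
    motif_count = vapply(seqs, count_motif, 0L, motif = motif,
                         USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Write genome fixtures to disk
#'
#' Emits the genome FASTA, a 6-column BED of all annotations (0-based
#' half-open, class in the name field) and a GFF3 of gene models.
#'
#' @param genome a \code{synthetic_genome}.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fasta")
  write_fasta(genome$chromosomes, fa)

  ann <- genome$annotations
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ann)),
    start = GenomicRanges::start(ann) - 1L,
    end = GenomicRanges::end(ann),
    name = ifelse(is.na(ann$class),
                  ifelse(is.na(ann$gene_id), ann$type,
                         paste(ann$type, ann$gene_id, sep = ":")),
                  paste(ann$type, ann$class, sep = ":")),
    score = 0L,
    strand = as.character(GenomicRanges::strand(ann)),
    stringsAsFactors = FALSE)
  bed$strand[bed$strand == "*"] <- "."
  bed_path <- file.path(dir, "annotations.bed")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  gidx <- which(ann$type %in% c("gene", "UTR", "CDS", "intron"))
  g <- ann[gidx]
  gff <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(g)),
    source = "tailslip",
    type = ifelse(g$type == "UTR", "UTR",
                  ifelse(g$type == "CDS", "CDS",
                         ifelse(g$type == "intron", "intron", "gene"))),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    score = ".", strand = as.character(GenomicRanges::strand(g)),
    phase = ".",
    attributes = ifelse(g$type == "gene",
                        sprintf("ID=%s", g$gene_id),
                        sprintf("Parent=%s", g$gene_id)),
    stringsAsFactors = FALSE)
  gff_path <- file.path(dir, "genes.gff3")
  con <- file(gff_path, "w")
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)

  invisible(c(fasta = fa, bed = bed_path, gff3 = gff_path))
}
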