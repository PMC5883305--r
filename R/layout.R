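#' Construct a toy diploid genome layout
#'
#' Defines the coordinate system of the simulated genome: chromosomes, CpG
#' dyad positions (0-based position of the plus-strand C; the dyad occupies
#' `[pos, pos + 2)`), and named interval annotations. Annotations include
#' LINE-1-like elements (`"L1"`, candidate loci for coherent
#' hemimethylation), CpG islands (`"CGI"`, kept unmethylated by default),
#' and generic gene-model classes used by feature aggregation.
#'
#' @param n_chrom number of chromosomes.
#' @param cpgs_per_chrom CpG dyads per chromosome.
#' @param spacing distance in bp between consecutive CpG positions.
#' @param l1_per_chrom number of L1-like element loci per chromosome.
#' @param l1_cpgs CpGs per L1-like element.
#' @param cgi_per_chrom number of CpG islands per chromosome.
#' @param cgi_cpgs CpGs per island.
#' @param seed optional integer seed for placement of elements.
#'
#' @return An object of class `meth_layout`: a list with `cpgs`
#'   (data.frame `chrom`, `pos`), `chrom_lengths` (named integer), and
#'   `annotation` (named list of interval data.frames `chrom`, `start`,
#'   `end`, 0-based half-open).
#' @export
sim_layout <- function(n_chrom = 4, cpgs_per_chrom = 4000, spacing = 200L,
                       l1_per_chrom = 10, l1_cpgs = 7,
                       cgi_per_chrom = 5, cgi_cpgs = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_chrom < 1 || cpgs_per_chrom < 1) mm_stop("need at least one chromosome and one CpG")
  chroms <- paste0("chr", seq_len(n_chrom))
  pos <- as.integer((seq_len(cpgs_per_chrom) - 1L) * spacing)
  cpgs <- data.frame(
    chrom = rep(chroms, each = cpgs_per_chrom),
    pos = rep(pos, n_chrom),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(cpgs)) mm_stop("overlapping CpG coordinates in layout")
  chrom_len <- stats::setNames(rep(cpgs_per_chrom * spacing, n_chrom), chroms)

  place <- function(n_per_chrom, n_cpg_in_feat) {
    if (n_per_chrom == 0) {
      return(data.frame(chrom = character(), start = integer(), end = integer()))
    }
    out <- lapply(chroms, function(ch) {
      ## features occupy runs of consecutive CpGs, non-overlapping
      max_start <- cpgs_per_chrom - n_cpg_in_feat
      slots <- floor(seq(1, max_start, length.out = n_per_chrom + 2))[-c(1, n_per_chrom + 2)]
      jitter <- sample.int(max(1L, spacing %/% 2L), n_per_chrom, replace = TRUE)
      i0 <- pmax(1L, pmin(max_start, slots + (jitter %% 3L)))
      data.frame(
        chrom = ch,
        start = pos[i0],
        end = pos[i0 + n_cpg_in_feat - 1L] + 2L
      )
    })
    do.call(rbind, out)
  }

  l1 <- place(l1_per_chrom, l1_cpgs)
  cgi <- place(cgi_per_chrom, cgi_cpgs)

  ## simple gene models tiled along each chromosome; promoters are
  ## TSS +/- 1 kb, strand-conscious (see promoter_intervals)
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    n_gene <- max(2L, n_chrom + 3L)
    len <- chrom_len[[ch]]
    starts <- floor(seq(0.05, 0.8, length.out = n_gene) * len)
    data.frame(
      chrom = ch, start = as.integer(starts),
      end = as.integer(starts + floor(0.1 * len)),
      strand = rep(c("+", "-"), length.out = n_gene),
      stringsAsFactors = FALSE
    )
  }))
  exons <- transform(genes[, c("chrom", "start", "end")],
                     end = start + as.integer((end - start) %/% 4L))
  introns <- transform(genes[, c("chrom", "start", "end")],
                       start = start + as.integer((end - start) %/% 4L))
  intergenic <- do.call(rbind, lapply(chroms, function(ch) {
    g <- genes[genes$chrom == ch, ]
    bounds <- sort(unique(c(0L, g$start, g$end, chrom_len[[ch]])))
    gaps <- data.frame(chrom = ch, start = head(bounds, -1), end = bounds[-1])
    covered <- vapply(seq_len(nrow(gaps)), function(i) {
      any(g$start < gaps$end[i] & g$end > gaps$start[i])
    }, logical(1))
    gaps[!covered & gaps$end > gaps$start, ]
  }))

  structure(list(
    cpgs = cpgs,
    chrom_lengths = chrom_len,
    annotation = list(
      L1 = l1, CGI = cgi,
      gene = genes, exon = exons, intron = introns, intergenic = intergenic
    )
  ), class = "meth_layout")
}

#' @export
print.meth_layout <- function(x, ...) {
  cat(sprintf(
    "meth_layout: %d CpG dyads on %d chromosome(s); annotations: %s\n",
    nrow(x$cpgs), length(x$chrom_lengths),
    paste(names(x$annotation), collapse = ", ")
  ))
  invisible(x)
}

#' Strand-conscious promoter intervals
#'
#' Promoters are taken as TSS +/- `flank` bp, where the TSS is `start` for
#' plus-strand genes and `end` for minus-strand genes.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open intervals).
#' @param flank bp on each side of the TSS (default 1000).
#' @return data.frame of promoter intervals (`chrom`, `start`, `end`,
#'   `strand`), clipped at 0.
#' @export
promoter_intervals <- function(genes, flank = 1000L) {
  if (!all(c("chrom", "start", "end", "strand") %in% names(genes))) {
    mm_stop("genes must have chrom, start, end, strand")
  }
  tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  data.frame(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(tss - flank)),
    end = as.integer(tss + flank),
    strand = genes$strand,
    stringsAsFactors = FALSE
  )
}

#' Imprinted differentially methylated region annotation
#'
#' Places synthetic stand-ins for the gametic imprinted DMRs commonly used
#' in mouse methylome studies: 11 maternal and 3 paternal loci. Maternal
#' DMRs are flagged so the genome generator can start them unmethylated
#' (the expected state on the paternal germline genome), paternal DMRs
#' methylated.
#'
#' @param layout a `meth_layout`.
#' @param n_cpgs CpGs per DMR interval.
#' @return named list of two interval data.frames, `DMR_maternal` and
#'   `DMR_paternal`.
#' @export
imprinted_dmr_annotation <- function(layout, n_cpgs = 15L) {
  maternal <- c("Grb10", "Igf2r", "Impact", "Kcnq1ot1", "Mest", "Nespas-Gnasxl",
                "Peg10", "Peg3", "Snrpn", "U2af1-rs1", "Zac1")
  paternal <- c("H19", "Dlk1-Gtl2", "Rasgrf1")
  cp <- layout$cpgs
  n_tot <- length(maternal) + length(paternal)
  idx <- floor(seq(1, nrow(cp) - n_cpgs, length.out = n_tot + 2))[-c(1, n_tot + 2)]
  ## keep each DMR on one chromosome
  idx <- vapply(idx, function(i) {
    ch <- cp$chrom[i]
    if (cp$chrom[i + n_cpgs - 1] != ch) i - n_cpgs else i
  }, numeric(1))
  mk <- function(ii, nm) {
    data.frame(
      chrom = cp$chrom[ii], start = cp$pos[ii],
      end = cp$pos[ii + n_cpgs - 1L] + 2L, name = nm,
      stringsAsFactors = FALSE
    )
  }
  list(
    DMR_maternal = mk(idx[seq_along(maternal)], maternal),
    DMR_paternal = mk(idx[length(maternal) + seq_along(paternal)], paternal)
  )
}

#' Build a replication-timing track over a layout
#'
#' Tiles each chromosome with alternating early/late replication-timing
#' domains covering every CpG exactly once. Higher `rt_value` means
#' earlier replication, following the convention of Repli-seq log-ratio
#' tracks.
#'
#' @param layout a `meth_layout`.
#' @param domain_cpgs CpGs per domain.
#' @param early_mean,late_mean,sd normal parameters of domain `rt_value`.
#' @param seed optional integer seed.
#' @return data.frame (`chrom`, `start`, `end`, `rt_value`), class
#'   `rt_track`; 0-based half-open, sorted, non-overlapping.
#' @export
sim_rt_track <- function(layout, domain_cpgs = 1000L,
                         early_mean = 1.5, late_mean = -1.5, sd = 0.3,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cp <- layout$cpgs
  out <- lapply(names(layout$chrom_lengths), function(ch) {
    p <- cp$pos[cp$chrom == ch]
    n <- length(p)
    n_dom <- max(1L, ceiling(n / domain_cpgs))
    i0 <- as.integer(floor(seq(1, n + 1, length.out = n_dom + 1)))
    starts <- p[i0[-length(i0)]]
    ends <- c(p[i0[-1][-n_dom]], layout$chrom_lengths[[ch]])
    early <- rep(c(TRUE, FALSE), length.out = n_dom)
    data.frame(
      chrom = ch, start = starts, end = ends,
      rt_value = ifelse(early, stats::rnorm(n_dom, early_mean, sd),
                        stats::rnorm(n_dom, late_mean, sd)),
      stringsAsFactors = FALSE
    )
  })
  rt <- do.call(rbind, out)
  rownames(rt) <- NULL
  validate_rt_track(rt, layout)
  class(rt) <- c("rt_track", "data.frame")
  rt
}

validate_rt_track <- function(rt, layout = NULL) {
  if (!all(c("chrom", "start", "end", "rt_value") %in% names(rt))) {
    mm_stop("rt track needs chrom, start, end, rt_value")
  }
  if (any(rt$end <= rt$start)) mm_stop("rt track has empty or inverted intervals")
  for (ch in unique(rt$chrom)) {
    d <- rt[rt$chrom == ch, ]
    d <- d[order(d$start), ]
    if (any(d$start[-1] < d$end[-nrow(d)])) mm_stop("rt track intervals overlap")
  }
  if (!is.null(layout)) {
    hit <- interval_index(layout$cpgs$chrom, layout$cpgs$pos, rt)
    if (anyNA(hit)) mm_stop("rt track does not cover every CpG in the layout")
  }
  invisible(rt)
}

## index of the interval (row of `iv`) containing each point; NA if none
interval_index <- function(chrom, pos, iv) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  s <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  as.integer(hit)
}

#' Read / write a replication-timing track as bedGraph
#'
#' Thin wrappers over `rtracklayer` import/export;
#' coordinates are converted between the 1-based GRanges representation
#' and the 0-based half-open data.frame used internally.
#'
#' @param path file path.
#' @rdname rt_bedgraph
#' @return `read_rt_bedgraph` returns an `rt_track` data.frame.
#' @export
read_rt_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  rt <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    rt_value = gr$score,
    stringsAsFactors = FALSE
  )
  validate_rt_track(rt)
  class(rt) <- c("rt_track", "data.frame")
  rt
}

#' @param rt an `rt_track` data.frame.
#' @rdname rt_bedgraph
#' @export
write_rt_bedgraph <- function(rt, path) {
  gr <- GenomicRanges::GRanges(
    rt$chrom, IRanges::IRanges(rt$start + 1L, rt$end), score = rt$rt_value
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
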