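#' The L1MdTf 5' promoter consensus
#'
#' The 5'-end consensus of the young, potentially active mouse LINE-1
#' L1MdTf family used as the hairpin-bisulfite amplicon target. CpG
#' positions are always derived by scanning the sequence, never stored.
#'
#' @param sequence consensus DNA string; defaults to the L1MdTf 5'
#'   consensus beginning at the BspEI site (TCCGGA).
#' @return object of class `l1_consensus`: list with `sequence`
#'   (uppercase) and `cpg_pos` (0-based positions of the CpG C on the
#'   given strand).
#' @export
l1_consensus <- function(sequence = NULL) {
  if (is.null(sequence)) {
    sequence <- paste0(
      "tccggaccggaggacaggtgcccacccggctggggaggcggcctaagccacagcagcagcggtcgcc",
      "atcttggtcccgggactccaaggaacttaggaatttagtctgcttaagtgagagtctgtaccacctg",
      "ggaactgccaaagcaacacagtgtctgagaaaggtcctgttttgg"
    )
  }
  seq <- toupper(sequence)
  if (grepl("[^ACGT]", seq)) mm_stop("consensus must be plain ACGT")
  structure(list(sequence = seq, cpg_pos = scan_cpg(seq)), class = "l1_consensus")
}

#' 0-based CpG C positions of a sequence
#' @param seq DNA string.
#' @return integer vector (possibly empty).
#' @export
scan_cpg <- function(seq) {
  hits <- gregexpr("(?=CG)", toupper(seq), perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits - 1L)
}

#' Read a consensus from FASTA
#' @param path FASTA path (first record used).
#' @return an `l1_consensus`.
#' @export
read_consensus_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  l1_consensus(as.character(ss[[1]]))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a population of L1 duplex molecules
#'
#' Molecules carry per-dyad top/bottom methylation states at the
#' consensus CpG positions. A fraction is strand-coherently
#' hemimethylated (top methylated, bottom not, at every dyad) — the
#' incompletely methylated spermatogonial L1 class — and the remainder
#' have each dyad fully methylated with probability `meth_level`.
#'
#' @param n_molecules number of duplex molecules.
#' @param consensus an [l1_consensus()].
#' @param hemi_frac fraction of coherently hemimethylated molecules.
#' @param meth_level probability a dyad of a non-hemi molecule is `MM`.
#' @param seed integer seed.
#' @return list of class `l1_molecules`: logical matrices `top`, `bottom`
#'   (molecules x dyads), the `consensus`, and `is_hemi` flags.
#' @export
make_l1_population <- function(n_molecules, consensus = l1_consensus(),
                               hemi_frac = 0.04, meth_level = 1, seed = 1L) {
  check_prob(hemi_frac, "hemi_frac"); check_prob(meth_level, "meth_level")
  set.seed(seed)
  nd <- length(consensus$cpg_pos)
  n_hemi <- round(hemi_frac * n_molecules)
  is_hemi <- seq_len(n_molecules) <= n_hemi  # deterministic count; order is immaterial
  mm <- matrix(stats::runif(n_molecules * nd) < meth_level, n_molecules, nd)
  top <- mm; bottom <- mm
  top[is_hemi, ] <- TRUE
  bottom[is_hemi, ] <- FALSE
  structure(list(top = top, bottom = bottom, consensus = consensus,
                 is_hemi = is_hemi, seed = seed),
            class = "l1_molecules")
}

#' One round of semiconservative replication of L1 duplex molecules
#'
#' Each duplex yields two daughters: one keeps the top strand (new bottom
#' methylated with probability `m` where the top is methylated), the other
#' keeps the bottom strand likewise. The result has twice the molecules.
#'
#' @param mols an `l1_molecules` set.
#' @param m maintenance-methylation efficiency.
#' @param seed integer seed.
#' @return an `l1_molecules` set of `2 * n` molecules; `parent` records
#'   the source molecule of each daughter.
#' @export
replicate_l1_population <- function(mols, m = 0, seed = mols$seed + 1L) {
  check_prob(m, "m")
  set.seed(seed)
  top <- mols$top; bot <- mols$bottom
  n <- nrow(top); nd <- ncol(top)
  d1_bot <- top & (matrix(stats::runif(n * nd), n, nd) < m)
  d2_top <- bot & (matrix(stats::runif(n * nd), n, nd) < m)
  structure(list(
    top = rbind(top, d2_top),
    bottom = rbind(d1_bot, bot),
    consensus = mols$consensus,
    is_hemi = rep(mols$is_hemi, 2),
    parent = rep(seq_len(n), 2),
    seed = seed
  ), class = "l1_molecules")
}

#' Fold duplex molecules into hairpin constructs
#'
#' Mimics the wet protocol: the duplex is cut at the restriction site
#' (default BspEI, TCCGGA) and the two strands are joined by a hairpin
#' linker, yielding one single-stranded molecule
#' `top arm + linker + reverse complement of the top arm` whose two arms
#' carry independent methylation flags (that independence is what makes
#' hemimethylation observable). Elements whose sequence lacks the site
#' are excluded and counted, signaling digest failure.
#'
#' @param element_seq duplex element sequence (top strand).
#' @param top,bottom logical matrices (molecules x dyads) of methylation
#'   at the element's CpG dyads (scanned from `element_seq`).
#' @param enzyme_site recognition motif that must occur in the element.
#' @param linker hairpin linker sequence (cytosines treated unmethylated).
#' @return object of class `hairpin_set`: the arm sequence (from the cut
#'   site on), linker, per-molecule arm methylation matrices, dyad
#'   positions in arm coordinates, and `n_excluded`.
#' @export
build_hairpin <- function(element_seq, top, bottom,
                          enzyme_site = "TCCGGA",
                          linker = "CCGGGGGCCTATATAGTATAGGCCC") {
  seq <- toupper(element_seq)
  cut <- regexpr(toupper(enzyme_site), seq, fixed = TRUE)
  if (cut == -1) {
    return(structure(list(arm = NULL, n_excluded = nrow(top)),
                     class = "hairpin_set"))
  }
  arm <- substr(seq, cut, nchar(seq))  # anchored at the cut site
  offset <- as.integer(cut) - 1L
  element_cpg <- scan_cpg(seq)
  keep <- element_cpg >= offset
  if (ncol(top) != length(element_cpg)) {
    mm_stop("dyad state matrices must have one column per element CpG")
  }
  structure(list(
    arm = arm, linker = toupper(linker),
    cpg_pos = element_cpg[keep] - offset,  # arm coordinates
    top = top[, keep, drop = FALSE],
    bottom = bottom[, keep, drop = FALSE],
    n_excluded = 0L
  ), class = "hairpin_set")
}

#' In-silico bisulfite conversion of one sequence
#'
#' Each unmethylated C becomes T with probability `conv`; methylated Cs
#' and non-C bases are untouched.
#'
#' @param seq DNA string.
#' @param meth logical vector, one flag per base (recycled; `TRUE` =
#'   methylated, only meaningful at C) or integer vector of 0-based
#'   methylated-C positions.
#' @param conv conversion rate in `[0,1]`.
#' @param seed optional integer seed.
#' @return converted DNA string.
#' @export
bisulfite_convert <- function(seq, meth = FALSE, conv = 1, seed = NULL) {
  check_prob(conv, "conv")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  flags <- if (is.logical(meth)) rep_len(meth, length(chars)) else {
    f <- rep(FALSE, length(chars)); f[meth + 1L] <- TRUE; f
  }
  target <- chars == "C" & !flags
  target[target] <- stats::runif(sum(target)) < conv
  chars[target] <- "T"
  paste(chars, collapse = "")
}

## converted full hairpin strands for all molecules (vectorized):
## S = arm + linker + revcomp(arm); returns character vector, one per molecule
convert_hairpins <- function(hp, conv = 1, seed = 1L) {
  check_prob(conv, "conv")
  set.seed(seed)
  arm_chars <- strsplit(hp$arm, "")[[1]]
  linker_chars <- strsplit(hp$linker, "")[[1]]
  rc_chars <- strsplit(revcomp(hp$arm), "")[[1]]
  La <- length(arm_chars); Ll <- length(linker_chars)
  S <- c(arm_chars, linker_chars, rc_chars)
  Ls <- length(S)
  n <- nrow(hp$top)

  c_pos <- which(S == "C")  # 1-based in S
  ## classify each C: top-arm dyad C, bottom-arm dyad C, or always-unmethylated
  top_c <- hp$cpg_pos + 1L                       # arm coords, 1-based in S
  ## bottom-strand C of dyad at arm pos p pairs with top G at p+1;
  ## in the reverse-complement arm its index is La - (p + 1), 1-based:
  bot_c <- La + Ll + (La - hp$cpg_pos - 1L)
  meth <- matrix(FALSE, n, length(c_pos))
  i_top <- match(top_c, c_pos)
  i_bot <- match(bot_c, c_pos)
  stopifnot(!anyNA(i_top), !anyNA(i_bot))
  meth[, i_top] <- hp$top
  meth[, i_bot] <- hp$bottom

  conv_mask <- !meth & (matrix(stats::runif(n * length(c_pos)), n) < conv)
  out_cols <- vector("list", Ls)
  for (j in seq_len(Ls)) out_cols[[j]] <- rep(S[j], n)
  for (k in seq_along(c_pos)) {
    cc <- out_cols[[c_pos[k]]]
    cc[conv_mask[, k]] <- "T"
    out_cols[[c_pos[k]]] <- cc
  }
  do.call(paste0, out_cols)
}

#' Simulate paired-end reads from hairpin-bisulfite amplicons
#'
#' Each read pair samples one molecule's converted, PCR-amplified hairpin.
#' Read 1 covers one end of the amplicon and read 2 the other (reverse
#' complement), with the sequenced strand of the PCR duplex chosen at
#' random, so pairs fall in the {OT, CTOB} or {CTOT, OB} bisulfite strand
#' classes. Per-base substitution errors are applied at rate `err`. The
#' source molecule index and orientation are recorded in read names so
#' simulator truth can be recovered in oracle tests.
#'
#' @param hp a `hairpin_set` (from [build_hairpin()]).
#' @param n_pairs number of read pairs (> 0).
#' @param read_len read length in nt (must not exceed amplicon length).
#' @param conv bisulfite conversion rate.
#' @param err per-base substitution error rate.
#' @param seed integer seed.
#' @return list of class `hairpin_reads`: `id`, `read1`, `read2`
#'   character vectors, `molecule` index, `flipped` orientation flag, and
#'   `truth` (the molecule dyad-state code matrix, rows = pairs).
#' @export
simulate_read_pairs <- function(hp, n_pairs, read_len = 150L, conv = 1,
                                err = 0, seed = 1L) {
  if (n_pairs <= 0) mm_stop("n_pairs must be positive")
  check_prob(err, "err")
  set.seed(seed)
  strands <- convert_hairpins(hp, conv = conv, seed = seed + 1L)
  Ls <- nchar(strands[1])
  if (read_len > Ls) mm_stop("read_len exceeds amplicon length")

  mol <- sample.int(length(strands), n_pairs, replace = TRUE)
  A <- strands[mol]
  r1 <- substr(A, 1L, read_len)
  r2_rc <- substr(A, Ls - read_len + 1L, Ls)
  r2 <- revcomp(r2_rc)
  flip <- stats::runif(n_pairs) < 0.5  # which PCR strand is read 1
  read1 <- ifelse(flip, r2, r1)
  read2 <- ifelse(flip, r1, r2)

  if (err > 0) {
    read1 <- add_substitutions(read1, err)
    read2 <- add_substitutions(read2, err)
  }

  truth <- dyad_code(hp$top[mol, , drop = FALSE], hp$bottom[mol, , drop = FALSE])
  structure(list(
    id = sprintf("hp:%d:%d:%s", seq_len(n_pairs), mol, ifelse(flip, "F", "R")),
    read1 = read1, read2 = read2,
    molecule = mol, flipped = flip, truth = truth,
    cpg_pos = hp$cpg_pos, seed = seed, conv = conv, err = err
  ), class = "hairpin_reads")
}

## per-base substitution errors at rate err (uniform over the 3 other bases)
add_substitutions <- function(reads, err) {
  n <- length(reads)
  rl <- nchar(reads)
  n_err <- stats::rbinom(n, rl, err)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(rl[i], n_err[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  reads
}

## MM / MU / UM / UU code matrix from logical strand matrices
dyad_code <- function(top, bottom) {
  out <- matrix("UU", nrow(top), ncol(top))
  out[top & bottom] <- "MM"
  out[top & !bottom] <- "MU"
  out[!top & bottom] <- "UM"
  out
}

#' Write simulated hairpin read pairs as FASTQ
#'
#' @param reads a `hairpin_reads` object.
#' @param path1,path2 output FASTQ paths for read 1 / read 2.
#' @export
write_hairpin_fastq <- function(reads, path1, path2) {
  wr <- function(seqs, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- reads$id
    Biostrings::writeXStringSet(
      ss, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs)))
    )
  }
  wr(reads$read1, path1)
  wr(reads$read2, path2)
  invisible(c(path1, path2))
}

#' Read paired FASTQ into the caller's input form
#' @param path1,path2 FASTQ paths.
#' @return list with `id`, `read1`, `read2`.
#' @export
read_hairpin_fastq <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(s1) != length(s2)) mm_stop("read 1 / read 2 files differ in length")
  list(id = sub(" .*", "", names(s1)),
       read1 = unname(as.character(s1)), read2 = unname(as.character(s2)))
}
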