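#' Canonical CpG island thresholds
#'
#' The canonical CpG island definition: length at least 200 bp, GC content at
#' least 50%, and a ratio of observed over expected CpG dinucleotides of at
#' least 0.6 (Gardiner-Garden and Frommer criteria).
#'
#' @param min_length minimum island length in bp.
#' @param min_gc minimum GC fraction.
#' @param min_oe minimum observed/expected CpG ratio.
#' @return A `cgi_params` list.
#' @export
cgi_params <- function(min_length = 200, min_gc = 0.5, min_oe = 0.6) {
  stop_if(min_length <= 0 || min_gc <= 0 || min_oe <= 0,
          "all CGI thresholds must be strictly positive")
  structure(list(min_length = min_length, min_gc = min_gc, min_oe = min_oe),
            class = "cgi_params")
}

# Repeat-masked genomes drive CGI identification: soft-masked (lowercase)
# bases are normalized to N before any computation, so masked sequence can
# neither form CpGs nor contribute to base counts.
normalize_seq <- function(seq) {
  chartr("acgtnRYSWKMBDHVryswkmbdhv",
         paste(rep("N", 25), collapse = ""), seq)
}

#' Find CpG dinucleotide positions
#'
#' Returns the 0-based positions i where the uppercase-normalized sequence has
#' C at i and G at i+1. Soft-masked (lowercase) and N bases never form a CpG.
#'
#' @param seq nucleotide string (A/C/G/T/N, either case).
#' @return Integer vector of 0-based positions.
#' @export
find_cpgs <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- normalize_seq(seq)
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

#' Sequence statistics for an interval
#'
#' Over the uppercase-normalized subsequence with N excluded from the base
#' counts: `gc_fraction` = (#C + #G) / (#A + #C + #G + #T); `cpg_count` =
#' number of CpG dinucleotides fully inside the interval; `obs_exp_ratio` =
#' cpg_count * L / (#C * #G) where L is the interval length
#' (Gardiner-Garden--Frommer expected count), defined as 0 when #C * #G = 0.
#'
#' @param seq nucleotide string.
#' @param start,end 0-based half-open interval within the sequence.
#' @return List with `gc_fraction`, `cpg_count`, `obs_exp_ratio`.
#' @export
cgi_stats <- function(seq, start, end) {
  stopifnot(is.character(seq), length(seq) == 1)
  n <- nchar(seq)
  stop_if(start < 0 || end > n || start >= end,
          "interval [%d,%d) outside sequence of length %d", start, end, n)
  sub <- normalize_seq(substr(seq, start + 1, end))
  r <- charToRaw(sub)
  nC <- sum(r == charToRaw("C"))
  nG <- sum(r == charToRaw("G"))
  nAT <- sum(r == charToRaw("A")) + sum(r == charToRaw("T"))
  denom <- nC + nG + nAT
  gc <- if (denom > 0) (nC + nG) / denom else 0
  m <- gregexpr("CG", sub, fixed = TRUE)[[1]]
  cpg <- if (m[1] == -1) 0L else length(m)
  L <- end - start
  oe <- if (nC * nG > 0) cpg * L / (nC * nG) else 0
  list(gc_fraction = gc, cpg_count = cpg, obs_exp_ratio = oe)
}

#' Segment CpG islands by the CpG-windowing procedure
#'
#' Left-to-right scan over CpG positions. A candidate island is anchored at a
#' CpG and extended one downstream CpG at a time; the candidate interval runs
#' from the first CpG's C to the last CpG's G (end = position + 2). When the
#' span first reaches `min_length` the GC and observed/expected criteria are
#' tested. On a pass the candidate keeps growing (adding the next CpG and
#' re-testing); at the first subsequent failure, or at sequence end, the last
#' passing interval is emitted and the scan resumes at the first CpG after
#' it. When the initial test fails the anchor CpG is dropped and extension
#' continues. Every emitted call satisfies all three thresholds.
#'
#' Candidate islands never span a masked gap: runs of N (hard-masked or
#' normalized soft-masked sequence) of at least `mask_break_bp` bases act
#' as scan breaks, since sequence unavailable to the caller cannot be
#' island interior. Without this, a candidate bridging a masked block
#' would have its length inflated by bases excluded from the counts,
#' producing spurious high observed/expected ratios.
#'
#' @param seq nucleotide string (soft-masked bases are treated as N).
#' @param chrom chromosome name for the emitted calls.
#' @param params a [cgi_params()] object.
#' @param mask_break_bp minimum N-run length acting as a scan break.
#' @return Data frame of calls: chrom, start, end, name, length_bp,
#'   gc_fraction, cpg_count, obs_exp_ratio; sorted, non-overlapping.
#' @export
segment_cgis <- function(seq, chrom = "chr1", params = cgi_params(),
                         mask_break_bp = 50) {
  stopifnot(inherits(params, "cgi_params"))
  s <- normalize_seq(seq)
  n <- nchar(s)
  P <- find_cpgs(s)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      length_bp = numeric(), gc_fraction = numeric(),
                      cpg_count = numeric(), obs_exp_ratio = numeric(),
                      stringsAsFactors = FALSE)
  if (length(P) < 1) return(empty)

  r <- charToRaw(s)
  cumC <- c(0L, cumsum(r == charToRaw("C")))
  cumG <- c(0L, cumsum(r == charToRaw("G")))
  cumN <- c(0L, cumsum(r == charToRaw("N")))
  # stats of the 0-based interval [a, b) with k CpGs, via cumulative counts
  test_iv <- function(a, b, k) {
    nC <- cumC[b + 1L] - cumC[a + 1L]
    nG <- cumG[b + 1L] - cumG[a + 1L]
    nN <- cumN[b + 1L] - cumN[a + 1L]
    L <- b - a
    denom <- L - nN
    gc <- if (denom > 0) (nC + nG) / denom else 0
    oe <- if (nC * nG > 0) k * L / (nC * nG) else 0
    gc >= params$min_gc && oe >= params$min_oe
  }

  # partition CpGs at long N runs so no candidate spans a masked gap
  br <- gregexpr(sprintf("N{%d,}", mask_break_bp), s)[[1]]
  group <- if (br[1] == -1) rep(1L, length(P))
           else findInterval(P, as.integer(br) - 1L) + 1L

  scan_group <- function(Pg) {
    m <- length(Pg)
    starts <- numeric(0); ends <- numeric(0)
    i <- 1L; j <- 1L
    passing <- FALSE
    last_i <- NA_integer_; last_j <- NA_integer_
    while (i <= m) {
      if (j < i) j <- i
      span <- Pg[j] + 2L - Pg[i]
      if (span < params$min_length) {
        if (j < m) { j <- j + 1L; next }
        # sequence end before reaching min length
        if (passing) {
          starts <- c(starts, Pg[last_i]); ends <- c(ends, Pg[last_j] + 2L)
        }
        break
      }
      ok <- test_iv(Pg[i], Pg[j] + 2L, j - i + 1L)
      if (ok) {
        passing <- TRUE; last_i <- i; last_j <- j
        if (j < m) { j <- j + 1L; next }
        starts <- c(starts, Pg[i]); ends <- c(ends, Pg[j] + 2L)
        break
      }
      if (passing) {
        # first failure after a pass: emit the last passing interval
        starts <- c(starts, Pg[last_i]); ends <- c(ends, Pg[last_j] + 2L)
        passing <- FALSE
        i <- findInterval(ends[length(ends)] - 1L, Pg) + 1L  # first CpG at/after end
        if (i > m) break
        j <- i
      } else {
        # initial test failed: drop the anchor CpG
        i <- i + 1L
      }
    }
    list(starts = starts, ends = ends)
  }

  res <- lapply(split(P, group), scan_group)
  starts <- unlist(lapply(res, `[[`, "starts"), use.names = FALSE)
  ends <- unlist(lapply(res, `[[`, "ends"), use.names = FALSE)
  if (!length(starts)) return(empty)
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  stats <- lapply(seq_along(starts),
                  function(k) cgi_stats(s, starts[k], ends[k]))
  data.frame(chrom = chrom, start = starts, end = ends,
             name = sprintf("CGI_%d", seq_along(starts)),
             length_bp = ends - starts,
             gc_fraction = vapply(stats, `[[`, 0, "gc_fraction"),
             cpg_count = vapply(stats, `[[`, 0, "cpg_count"),
             obs_exp_ratio = vapply(stats, `[[`, 0, "obs_exp_ratio"),
             stringsAsFactors = FALSE)
}

#' Call CpG islands over a multi-sequence genome
#'
#' @param genome named character vector of chromosome sequences, or a path to
#'   a FASTA file.
#' @param params a [cgi_params()] object.
#' @return Combined call data frame across chromosomes (names made unique
#'   genome-wide).
#' @export
call_cgis <- function(genome, params = cgi_params()) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  stop_if(is.null(names(genome)), "genome sequences must be named")
  calls <- do.call(rbind, lapply(names(genome), function(ch) {
    segment_cgis(genome[[ch]], chrom = ch, params = params)
  }))
  if (!is.null(calls) && nrow(calls)) {
    calls$name <- sprintf("CGI_%d", seq_len(nrow(calls)))
  }
  calls
}

#' Read / write genome FASTA
#'
#' Thin wrappers around Biostrings keeping the package's plain character
#' representation (one string per chromosome, case preserved so soft-masking
#' survives a round trip).
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_genome_fasta
#' @param genome named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(genome), path)
  invisible(path)
}
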