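#' Scanner parameters for G-quadruplex motif search
#'
#' Parameters controlling the G3N1-7 motif scan: minimum G-tract length,
#' loop-length bounds, strand handling and the overlap policy.
#'
#' @param min_g_tract_length Minimum number of consecutive guanines per
#'   G-tract (default 3, the canonical G3 requirement).
#' @param min_loop_length Minimum loop length in nucleotides (default 1).
#' @param max_loop_length Maximum loop length in nucleotides (default 7).
#' @param scan_both_strands Scan the reverse complement as well and report
#'   minus-strand motifs in forward-strand coordinates (default TRUE).
#' @param overlap_policy `"all_maximal"` enumerates every valid
#'   tract/loop decomposition (including decompositions that shorten a
#'   longer G-run to feed a loop); `"greedy_nonoverlapping"` reports the
#'   leftmost motif on each strand and resumes scanning past its end.
#' @return An object of class `gq_scan_params`.
#' @export
scan_params <- function(min_g_tract_length = 3L,
                        min_loop_length = 1L,
                        max_loop_length = 7L,
                        scan_both_strands = TRUE,
                        overlap_policy = c("all_maximal", "greedy_nonoverlapping")) {
  overlap_policy <- match.arg(overlap_policy)
  min_g_tract_length <- as.integer(min_g_tract_length)
  min_loop_length <- as.integer(min_loop_length)
  max_loop_length <- as.integer(max_loop_length)
  if (is.na(min_g_tract_length) || min_g_tract_length < 2L)
    stop("min_g_tract_length must be an integer >= 2")
  if (is.na(min_loop_length) || min_loop_length < 1L)
    stop("min_loop_length must be an integer >= 1")
  if (is.na(max_loop_length) || max_loop_length < min_loop_length)
    stop("max_loop_length must be >= min_loop_length")
  structure(list(min_g_tract_length = min_g_tract_length,
                 min_loop_length = min_loop_length,
                 max_loop_length = max_loop_length,
                 scan_both_strands = isTRUE(scan_both_strands),
                 overlap_policy = overlap_policy),
            class = "gq_scan_params")
}

.empty_motifs <- function() {
  data.frame(sequence_id = character(0),
             start = integer(0), end = integer(0),
             strand = character(0), motif_length = integer(0),
             t1_start = integer(0), t2_start = integer(0),
             t3_start = integer(0), t4_start = integer(0),
             t1_len = integer(0), t2_len = integer(0),
             t3_len = integer(0), t4_len = integer(0),
             loop1_len = integer(0), loop2_len = integer(0),
             loop3_len = integer(0),
             loop1_seq = character(0), loop2_seq = character(0),
             loop3_seq = character(0),
             loop_profile = character(0),
             stringsAsFactors = FALSE)
}

## All (start, length) substrings consisting solely of G, length >= min_len.
## 1-based start coordinates on the supplied string.
.g_tract_candidates <- function(chars, min_len) {
  runs <- rle(chars == "G")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_len
  out_s <- integer(0); out_l <- integer(0)
  for (i in which(keep)) {
    p <- starts[i]; L <- runs$lengths[i]
    for (s in p:(p + L - min_len)) {
      for (l in min_len:(p + L - s)) {
        out_s <- c(out_s, s); out_l <- c(out_l, l)
      }
    }
  }
  data.frame(start = out_s, len = out_l, end = out_s + out_l)
}

## Scan one strand (string as given); returns motif table in 1-based
## coordinates local to the string, loops read 5'->3'.
.scan_strand <- function(s, params) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  cand <- .g_tract_candidates(chars, params$min_g_tract_length)
  if (nrow(cand) == 0L) return(NULL)
  minL <- params$min_loop_length; maxL <- params$max_loop_length
  ## index candidates by start position for the chained lookup
  by_start <- split(seq_len(nrow(cand)), cand$start)
  next_tracts <- function(end_prev) {
    lo <- end_prev + minL; hi <- end_prev + maxL
    idx <- unlist(by_start[as.character(lo:hi)], use.names = FALSE)
    idx[!is.na(idx)]
  }
  rows <- list(); n <- 0L
  for (i1 in seq_len(nrow(cand))) {
    for (i2 in next_tracts(cand$end[i1])) {
      for (i3 in next_tracts(cand$end[i2])) {
        for (i4 in next_tracts(cand$end[i3])) {
          n <- n + 1L
          rows[[n]] <- c(cand$start[i1], cand$start[i2], cand$start[i3],
                         cand$start[i4], cand$len[i1], cand$len[i2],
                         cand$len[i3], cand$len[i4])
        }
      }
    }
  }
  if (n == 0L) return(NULL)
  m <- do.call(rbind, rows)
  colnames(m) <- c("t1_start", "t2_start", "t3_start", "t4_start",
                   "t1_len", "t2_len", "t3_len", "t4_len")
  df <- as.data.frame(m)
  df$start <- df$t1_start
  df$end <- df$t4_start + df$t4_len
  df$loop1_len <- df$t2_start - (df$t1_start + df$t1_len)
  df$loop2_len <- df$t3_start - (df$t2_start + df$t2_len)
  df$loop3_len <- df$t4_start - (df$t3_start + df$t3_len)
  df$loop1_seq <- substring(s, df$t1_start + df$t1_len, df$t2_start - 1L)
  df$loop2_seq <- substring(s, df$t2_start + df$t2_len, df$t3_start - 1L)
  df$loop3_seq <- substring(s, df$t3_start + df$t3_len, df$t4_start - 1L)
  if (params$overlap_policy == "greedy_nonoverlapping") {
    ord <- order(df$start, df$end, df$t2_start, df$t3_start, df$t4_start)
    df <- df[ord, , drop = FALSE]
    keep <- logical(nrow(df)); cursor <- 0L
    for (i in seq_len(nrow(df))) {
      if (df$start[i] > cursor) {  # 1-based: start > cursor means no overlap
        keep[i] <- TRUE
        cursor <- df$end[i] - 1L   # last base used
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  df
}

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

#' Scan a DNA sequence for G-quadruplex motifs
#'
#' Finds every occurrence of the quadruplex pattern
#' G(3+) N(1-7) G(3+) N(1-7) G(3+) N(1-7) G(3+): four runs of at least
#' `min_g_tract_length` guanines separated by three loops whose lengths lie
#' within the configured bounds. The reverse strand is searched by scanning
#' the reverse complement; minus-strand motifs are reported in
#' forward-strand coordinates with tract coordinates in motif (5' to 3' on
#' the motif strand) order and loop sequences read on the motif strand.
#'
#' @param sequence A single DNA string over A, C, G, T, N
#'   (case-insensitive; N never counts as G).
#' @param params A [scan_params()] object.
#' @param sequence_id Identifier recorded in the output (default "seq").
#' @return A data frame of class `gq_motifs`, one row per motif, with
#'   0-based half-open `start`/`end` forward-strand coordinates, `strand`,
#'   per-tract starts/lengths, loop lengths and sequences, and the loop
#'   profile string (e.g. "1-4-4"). Sorted by (start, strand).
#' @examples
#' scan_g_quadruplex("GGGTTAGGGTTAGGGTTAGGG")
#' @export
scan_g_quadruplex <- function(sequence, params = scan_params(),
                              sequence_id = "seq") {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single character string")
  if (!inherits(params, "gq_scan_params")) stop("params must come from scan_params()")
  s <- toupper(sequence)
  if (nchar(s) == 0L) return(.empty_motifs())
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside the A/C/G/T/N alphabet")
  L <- nchar(s)

  finalize <- function(df, strand, on_revcomp) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    out <- df
    if (!on_revcomp) {
      out$fstart <- df$start - 1L          # to 0-based half-open
      out$fend <- df$end - 1L
      ts <- df[, c("t1_start", "t2_start", "t3_start", "t4_start")] - 1L
    } else {
      ## [a,b) on revcomp (1-based a, b exclusive end+? here end = last+1)
      out$fstart <- L - (df$end - 1L)
      out$fend <- L - df$start + 1L
      ## tract at 1-based [s, s+l-1] on revcomp -> forward 0-based start
      ## L - s - l + 1
      ts <- data.frame(
        t1 = L - df$t1_start - df$t1_len + 1L,
        t2 = L - df$t2_start - df$t2_len + 1L,
        t3 = L - df$t3_start - df$t3_len + 1L,
        t4 = L - df$t4_start - df$t4_len + 1L)
    }
    data.frame(sequence_id = sequence_id,
               start = as.integer(out$fstart),
               end = as.integer(out$fend),
               strand = strand,
               motif_length = as.integer(out$fend - out$fstart),
               t1_start = as.integer(ts[[1]]), t2_start = as.integer(ts[[2]]),
               t3_start = as.integer(ts[[3]]), t4_start = as.integer(ts[[4]]),
               t1_len = as.integer(df$t1_len), t2_len = as.integer(df$t2_len),
               t3_len = as.integer(df$t3_len), t4_len = as.integer(df$t4_len),
               loop1_len = as.integer(df$loop1_len),
               loop2_len = as.integer(df$loop2_len),
               loop3_len = as.integer(df$loop3_len),
               loop1_seq = df$loop1_seq, loop2_seq = df$loop2_seq,
               loop3_seq = df$loop3_seq,
               loop_profile = paste(df$loop1_len, df$loop2_len, df$loop3_len,
                                    sep = "-"),
               stringsAsFactors = FALSE)
  }

  plus <- finalize(.scan_strand(s, params), "+", FALSE)
  minus <- NULL
  if (params$scan_both_strands)
    minus <- finalize(.scan_strand(.revcomp(s), params), "-", TRUE)
  res <- rbind(plus, minus)
  if (is.null(res) || nrow(res) == 0L) return(.empty_motifs())
  res <- res[order(res$start, res$strand, res$end,
                   res$t2_start, res$t3_start, res$t4_start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("gq_motifs", "data.frame")
  res
}
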