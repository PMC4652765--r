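# Independent oracles and fixture builders shared across test files.

# Brute-force G3N1-7 enumerator: tries every (tract-start, tract-length,
# loop-length) combination by direct nested loops over the character
# vector. Returns the same flat columns as scan_g_quadruplex, one strand,
# 1-based start converted to 0-based half-open at the end.
brute_force_scan_strand <- function(s, min_tract = 3L, min_loop = 1L,
                                    max_loop = 7L) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- length(chars)
  isG <- chars == "G"
  cand <- list()
  for (st in seq_len(n)) {
    len <- 0L
    while (st + len <= n && isG[st + len]) len <- len + 1L
    if (len >= min_tract)
      for (l in min_tract:len) cand[[length(cand) + 1L]] <- c(st, l)
  }
  if (length(cand) == 0L) return(NULL)
  cand <- do.call(rbind, cand)
  rows <- list()
  nr <- 0L
  nc <- nrow(cand)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    s1 <- cand[i, 1]; l1 <- cand[i, 2]
    s2 <- cand[j, 1]; l2 <- cand[j, 2]
    g1 <- s2 - (s1 + l1)
    if (g1 < min_loop || g1 > max_loop) next
    for (k in seq_len(nc)) {
      s3 <- cand[k, 1]; l3 <- cand[k, 2]
      g2 <- s3 - (s2 + l2)
      if (g2 < min_loop || g2 > max_loop) next
      for (m in seq_len(nc)) {
        s4 <- cand[m, 1]; l4 <- cand[m, 2]
        g3 <- s4 - (s3 + l3)
        if (g3 < min_loop || g3 > max_loop) next
        nr <- nr + 1L
        rows[[nr]] <- c(s1 - 1L, s4 + l4 - 1L, s1 - 1L, s2 - 1L,
                        s3 - 1L, s4 - 1L, l1, l2, l3, l4, g1, g2, g3)
      }
    }
  }
  if (nr == 0L) return(NULL)
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("start", "end", "t1_start", "t2_start", "t3_start",
                  "t4_start", "t1_len", "t2_len", "t3_len", "t4_len",
                  "loop1_len", "loop2_len", "loop3_len")
  out
}

# Canonical ordering so scanner and oracle outputs can be compared row-wise.
canonical_motifs <- function(df) {
  cols <- c("start", "end", "t1_start", "t2_start", "t3_start", "t4_start",
            "t1_len", "t2_len", "t3_len", "t4_len",
            "loop1_len", "loop2_len", "loop3_len")
  df <- as.data.frame(df)[, cols, drop = FALSE]
  class(df) <- "data.frame"
  df[] <- lapply(df, as.integer)
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_dna <- function(n, gc_bias = c(0.3, 0.2, 0.3, 0.2)) {
  paste(sample(c("G", "A", "C", "T"), n, replace = TRUE, prob = gc_bias),
        collapse = "")
}

# Builds a GQ construct string from a loop-length triplet using T loops.
construct_from_loops <- function(loops, tract = "GGG") {
  paste0(tract, strrep("T", loops[1]), tract, strrep("T", loops[2]),
         tract, strrep("T", loops[3]), tract)
}

# Noiseless simulator configuration for exactness tests; any default here
# can be overridden by the caller.
noiseless_config <- function(...) {
  base <- list(total_intensity_sd = 0, channel_noise_sd = 0,
               background_mean = 0, donor_only_fraction = 0,
               dynamic_fraction = 0,
               donor_bleach_mean_s = Inf, acceptor_bleach_mean_s = Inf)
  do.call(trace_sim_config, utils::modifyList(base, list(...)))
}
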