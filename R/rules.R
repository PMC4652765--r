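#' Conformation rule table for GQ loop profiles
#'
#' Builds the ordered rule table mapping a motif's loop-length triplet and
#' strandedness context (single- vs double-stranded DNA) to a predicted
#' conformation and folding-propensity class, plus the calibration map from
#' loop triplets to measured double-stranded folded percentages. Rules
#' encode the empirical picture that a single-nucleotide loop drives
#' parallel folding, that longer loops in single strands shift folding
#' towards antiparallel and then unfolded states, and that in duplex DNA
#' only parallel folding is ever observed.
#'
#' The first matching rule wins and a catch-all "unfolded" row makes each
#' context exhaustive. All thresholds are configurable; defaults reflect
#' the measured behaviour of the calibration constructs.
#'
#' @param ss_parallel_any_loop_le In ssDNA, a motif with any loop of at most
#'   this length is called parallel / high propensity (default 1).
#' @param ss_antiparallel_all_loops_le In ssDNA, a motif whose loops are all
#'   at most this length (and which did not match the parallel rule) is
#'   called antiparallel / intermediate (default 3).
#' @param ds_parallel_all_loops_le In dsDNA, all loops at most this length
#'   gives parallel / high (default 2).
#' @param ds_intermediate_single_loop_len In dsDNA, exactly one loop of this
#'   length with the other loops at most `ds_intermediate_other_loops_le`
#'   gives parallel / intermediate (defaults 1 and 5).
#' @param ds_intermediate_other_loops_le See above.
#' @param calibration Data frame with columns `l1`, `l2`, `l3` (a sorted
#'   loop triplet) and `folded_percent`, the measured high-FRET percentage
#'   for that construct in dsDNA.
#' @return An object of class `gq_rule_table` with elements `ss`, `ds`
#'   (ordered lists of rule rows, each with `id`, `conformation`,
#'   `propensity_class` and a predicate over the loop triplet) and
#'   `calibration`.
#' @export
gq_rule_table <- function(ss_parallel_any_loop_le = 1L,
                          ss_antiparallel_all_loops_le = 3L,
                          ds_parallel_all_loops_le = 2L,
                          ds_intermediate_single_loop_len = 1L,
                          ds_intermediate_other_loops_le = 5L,
                          calibration = default_ds_calibration()) {
  if (!is.data.frame(calibration) ||
      !all(c("l1", "l2", "l3", "folded_percent") %in% names(calibration)))
    stop("calibration must have columns l1, l2, l3, folded_percent")
  if (nrow(calibration) == 0L)
    stop("calibration table is empty")
  srt <- t(apply(calibration[, c("l1", "l2", "l3")], 1L, sort))
  if (!all(srt == as.matrix(calibration[, c("l1", "l2", "l3")])))
    stop("calibration loop triplets must be sorted ascending")
  rule <- function(id, conformation, propensity_class, pred)
    list(id = id, conformation = conformation,
         propensity_class = propensity_class, pred = pred)
  a <- ss_parallel_any_loop_le
  b <- ss_antiparallel_all_loops_le
  d1 <- ds_parallel_all_loops_le
  d2 <- ds_intermediate_single_loop_len
  d3 <- ds_intermediate_other_loops_le
  ss <- list(
    rule("ss.single_nt_loop", "parallel", "high",
         function(l) any(l <= a)),
    rule("ss.all_loops_short", "antiparallel", "intermediate",
         function(l) all(l <= b)),
    rule("ss.default_unfolded", "unfolded", "none",
         function(l) TRUE))
  ds <- list(
    rule("ds.all_loops_minimal", "parallel", "high",
         function(l) all(l <= d1)),
    rule("ds.one_single_nt_loop", "parallel", "intermediate",
         function(l) sum(l == d2) == 1L && all(l[l != d2] <= d3)),
    rule("ds.default_unfolded", "unfolded", "none",
         function(l) TRUE))
  for (ctx in list(ss, ds))
    if (!isTRUE(ctx[[length(ctx)]]$pred(c(7L, 7L, 7L))))
      stop("rule table is not exhaustive: final default row must match any triplet")
  structure(list(ss = ss, ds = ds, calibration = calibration,
                 thresholds = list(
                   ss_parallel_any_loop_le = a,
                   ss_antiparallel_all_loops_le = b,
                   ds_parallel_all_loops_le = d1,
                   ds_intermediate_single_loop_len = d2,
                   ds_intermediate_other_loops_le = d3)),
            class = "gq_rule_table")
}

#' Measured dsDNA folded percentages for the calibration constructs
#'
#' High-FRET (folded) percentages measured by smFRET for GQ constructs
#' annealed into duplex DNA, keyed by the sorted loop-length triplet.
#' The (1,1,2) row is the CMYC promoter quadruplex (loop profile 1-2-1).
#'
#' @return Data frame with columns `l1`, `l2`, `l3`, `folded_percent`,
#'   and a `construct` label.
#' @export
default_ds_calibration <- function() {
  data.frame(
    construct = c("CMYC", "1-3-3", "1-4-4", "1-5-5", "(TTA)3"),
    l1 = c(1L, 1L, 1L, 1L, 3L),
    l2 = c(1L, 3L, 4L, 5L, 3L),
    l3 = c(2L, 3L, 4L, 5L, 3L),
    folded_percent = c(92, 86, 66, 58, 0),
    stringsAsFactors = FALSE)
}

#' Default conformation rule table
#'
#' @return The [gq_rule_table()] built with default thresholds and the
#'   packaged dsDNA calibration map.
#' @export
default_rule_table <- function() gq_rule_table()

#' Read a rule table from a YAML file
#'
#' The file may set any of the threshold arguments of [gq_rule_table()]
#' (keys `ss`/`ds` blocks mirroring the argument names without prefix) and
#' a `calibration` list of `{loops: [l1,l2,l3], folded_percent: x}`
#' entries. Missing entries keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `gq_rule_table`.
#' @export
read_rule_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$ss)) {
    if (!is.null(cfg$ss$parallel_any_loop_le))
      args$ss_parallel_any_loop_le <- cfg$ss$parallel_any_loop_le
    if (!is.null(cfg$ss$antiparallel_all_loops_le))
      args$ss_antiparallel_all_loops_le <- cfg$ss$antiparallel_all_loops_le
  }
  if (!is.null(cfg$ds)) {
    if (!is.null(cfg$ds$parallel_all_loops_le))
      args$ds_parallel_all_loops_le <- cfg$ds$parallel_all_loops_le
    if (!is.null(cfg$ds$intermediate_single_loop_len))
      args$ds_intermediate_single_loop_len <- cfg$ds$intermediate_single_loop_len
    if (!is.null(cfg$ds$intermediate_other_loops_le))
      args$ds_intermediate_other_loops_le <- cfg$ds$intermediate_other_loops_le
  }
  if (!is.null(cfg$calibration)) {
    rows <- lapply(cfg$calibration, function(e) {
      l <- sort(as.integer(e$loops))
      data.frame(construct = if (is.null(e$construct)) paste(l, collapse = "-")
                 else e$construct,
                 l1 = l[1], l2 = l[2], l3 = l[3],
                 folded_percent = as.numeric(e$folded_percent),
                 stringsAsFactors = FALSE)
    })
    args$calibration <- do.call(rbind, rows)
  }
  do.call(gq_rule_table, args)
}

.loops_from <- function(motif) {
  if (is.numeric(motif) && length(motif) == 3L) return(as.integer(motif))
  if (is.data.frame(motif) && nrow(motif) == 1L &&
      all(c("loop1_len", "loop2_len", "loop3_len") %in% names(motif)))
    return(as.integer(c(motif$loop1_len, motif$loop2_len, motif$loop3_len)))
  stop("motif must be a loop-length triplet or a single gq_motifs row")
}

.classify_loops <- function(loops, context, rules) {
  rows <- if (context == "ss") rules$ss else rules$ds
  for (r in rows) {
    if (isTRUE(r$pred(loops))) {
      pct <- if (context == "ds")
        .predict_ds_percent(loops, rules) else NA_real_
      return(list(context = context,
                  conformation = r$conformation,
                  propensity_class = r$propensity_class,
                  predicted_folded_percent = pct,
                  rule_id = r$id))
    }
  }
  stop("rule table is not exhaustive for loops ", paste(loops, collapse = "-"))
}

#' Classify the predicted conformation of a GQ motif
#'
#' Applies the ordered rule table for the given strandedness context to the
#' motif's loop-length triplet; the first matching rule wins. In the
#' double-stranded context the predicted folded percentage from the
#' calibration map is attached; antiparallel calls never occur in the ds
#' context.
#'
#' @param motif A single row of a [scan_g_quadruplex()] result, or a
#'   numeric loop-length triplet.
#' @param context `"ss"` or `"ds"`.
#' @param rules A [gq_rule_table()].
#' @return A one-row data frame with `context`, `conformation`
#'   (parallel/antiparallel/unfolded), `propensity_class`
#'   (high/intermediate/none), `predicted_folded_percent` (NA in ss
#'   context) and `rule_id`.
#' @examples
#' classify_conformation(c(1, 4, 4), "ss")
#' classify_conformation(c(3, 3, 3), "ds")
#' @export
classify_conformation <- function(motif, context = c("ss", "ds"),
                                  rules = default_rule_table()) {
  context <- match.arg(context)
  if (!inherits(rules, "gq_rule_table")) stop("rules must be a gq_rule_table")
  loops <- .loops_from(motif)
  if (any(loops < 1L)) stop("loop lengths must be positive")
  res <- .classify_loops(loops, context, rules)
  if (context == "ds" && res$conformation == "antiparallel")
    stop("internal error: antiparallel conformation emitted in ds context")
  if (res$propensity_class == "none" && res$conformation != "unfolded")
    stop("internal error: propensity 'none' must imply unfolded")
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Classify every motif in a scan result
#'
#' @param motifs A `gq_motifs` data frame.
#' @inheritParams classify_conformation
#' @return `motifs` with the classification columns appended.
#' @export
classify_motifs <- function(motifs, context = c("ss", "ds"),
                            rules = default_rule_table()) {
  context <- match.arg(context)
  if (nrow(motifs) == 0L) {
    out <- cbind(motifs, classify_conformation(c(1, 1, 1), context, rules)[0, ])
    return(out)
  }
  calls <- do.call(rbind, lapply(seq_len(nrow(motifs)), function(i)
    classify_conformation(motifs[i, , drop = FALSE], context, rules)))
  cbind(motifs, calls)
}

.predict_ds_percent <- function(loops, rules) {
  ## triplets the ds rules call unfolded fold at 0%
  for (r in rules$ds) {
    if (isTRUE(r$pred(loops))) {
      if (r$propensity_class == "none") return(0)
      break
    }
  }
  key <- sort(loops)
  cal <- rules$calibration
  hit <- which(cal$l1 == key[1] & cal$l2 == key[2] & cal$l3 == key[3])
  if (length(hit) == 1L) return(cal$folded_percent[hit])
  d <- abs(cal$l1 - key[1]) + abs(cal$l2 - key[2]) + abs(cal$l3 - key[3])
  best <- which(d == min(d))
  if (length(best) > 1L) {
    tot <- cal$l1[best] + cal$l2[best] + cal$l3[best]
    best <- best[tot == min(tot)]
    best <- best[1L]  # residual ties: first (lexicographically smallest) key
  }
  cal$folded_percent[best]
}

#' Predict the folded percentage of a motif in duplex DNA
#'
#' Looks the motif's sorted loop triplet up in the calibration map of
#' measured dsDNA folded percentages. Triplets the ds rules classify as
#' non-folding return 0; a triplet absent from the map falls back to the
#' nearest calibrated triplet by L1 distance on sorted triplets, ties
#' broken towards the smaller total loop length.
#'
#' @inheritParams classify_conformation
#' @return A folded percentage in \[0, 100\].
#' @examples
#' predict_ds_folded_fraction(c(1, 4, 4))  # 66
#' predict_ds_folded_fraction(c(3, 3, 3))  # 0
#' @export
predict_ds_folded_fraction <- function(motif, rules = default_rule_table()) {
  if (!inherits(rules, "gq_rule_table")) stop("rules must be a gq_rule_table")
  loops <- .loops_from(motif)
  .predict_ds_percent(loops, rules)
}
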