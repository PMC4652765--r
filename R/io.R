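#' Read a multi-record FASTA file
#'
#' @param path Path to a FASTA file. Sequences are uppercased; CRLF line
#'   endings are tolerated; an empty file yields an empty result.
#' @return Data frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("malformed FASTA: line ", nonblank[1],
         " is sequence data before any '>' header")
  set <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(set),
             sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with `id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write GQ motifs as BED6
#'
#' Writes one line per motif: sequence id, 0-based half-open start/end,
#' the loop profile string as the feature name, the rounded predicted
#' dsDNA folded percentage as the score, and the strand.
#'
#' @param motifs A `gq_motifs` data frame.
#' @param path Output path.
#' @param rules Rule table used for the score column.
#' @export
write_bed <- function(motifs, path, rules = default_rule_table()) {
  if (nrow(motifs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- vapply(seq_len(nrow(motifs)), function(i)
    round(predict_ds_folded_fraction(motifs[i, , drop = FALSE], rules)),
    numeric(1))
  bed <- data.frame(chrom = motifs$sequence_id,
                    start = motifs$start, end = motifs$end,
                    name = motifs$loop_profile,
                    score = as.integer(score),
                    strand = motifs$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path Path to a BED file written by [write_bed()].
#' @return Data frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`; empty files yield an empty frame.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  if (file.size(path) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(out) <- cols[seq_len(ncol(out))]
  out
}

#' Write an emission spectrum as CSV
#'
#' Two-column CSV with header `wavelength_nm,intensity`.
#'
#' @param spectrum An [emission_spectrum()] or [cd_spectrum()] (CD spectra
#'   use the `ellipticity` field as the intensity column).
#' @param path Output path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  y <- if (inherits(spectrum, "cd_spectrum")) spectrum$ellipticity
  else spectrum$intensity
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelength_nm,
                              intensity = y),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an emission spectrum from CSV
#'
#' @param path CSV with header `wavelength_nm,intensity`.
#' @param ligand,excitation_nm,sample_id,metadata Metadata attached to the
#'   spectrum (usually from the manifest).
#' @return An [emission_spectrum()].
#' @export
read_spectrum_csv <- function(path, ligand = "none",
                              excitation_nm = NA_real_, sample_id = "",
                              metadata = list()) {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(d)))
    stop("spectrum CSV must have columns wavelength_nm, intensity: ", path)
  emission_spectrum(d$wavelength_nm, d$intensity, ligand = ligand,
                    excitation_nm = excitation_nm, sample_id = sample_id,
                    metadata = metadata)
}

#' Read a spectra manifest
#'
#' The manifest is a CSV with columns `sample_id`, `ligand`,
#' `excitation_nm`, `file` (paths relative to the manifest's directory).
#'
#' @param path Manifest CSV path.
#' @return List of [emission_spectrum()] objects.
#' @export
read_spectra_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "ligand", "excitation_nm", "file")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, man$file[i])
    read_spectrum_csv(f, ligand = man$ligand[i],
                      excitation_nm = man$excitation_nm[i],
                      sample_id = man$sample_id[i])
  })
}

#' Write a simulated dataset as a plain-text trace store
#'
#' One tab-separated file per imaging field (`field_###.tsv` with columns
#' `molecule_id`, `frame`, `time_s`, `donor`, `acceptor`) plus a
#' `manifest.json` sidecar holding the simulation config, the per-molecule
#' truth labels and the red-pulse marker series.
#'
#' @param dataset A `fret_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_trace_store <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in sort(unique(dataset$field))) {
    idx <- which(dataset$field == f)
    tabs <- lapply(idx, function(i) {
      tr <- dataset$traces[[i]]
      data.table::data.table(molecule_id = tr$molecule_id,
                             frame = seq_along(tr$time),
                             time_s = tr$time,
                             donor = tr$donor, acceptor = tr$acceptor)
    })
    data.table::fwrite(data.table::rbindlist(tabs),
                       file.path(dir, sprintf("field_%03d.tsv", f)),
                       sep = "\t")
  }
  truth <- lapply(dataset$traces, function(tr) {
    tt <- tr$truth
    list(molecule_id = tr$molecule_id, class = tt$class,
         state_path = tt$state_path,
         donor_bleach_frame = tt$donor_bleach_frame,
         acceptor_bleach_frame = tt$acceptor_bleach_frame,
         total_intensity = tt$total_intensity,
         red_pulse_acceptor = tr$red_pulse_acceptor)
  })
  side <- list(config = unclass(dataset$config),
               field = dataset$field,
               truth = truth)
  jsonlite::write_json(side, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Read a trace store back into a dataset
#'
#' @param dir Directory written by [write_trace_store()].
#' @return A `fret_dataset`.
#' @export
read_trace_store <- function(dir) {
  if (!dir.exists(dir)) stop("trace store directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "^field_[0-9]+\\.tsv$",
                           full.names = TRUE))
  manifest_path <- file.path(dir, "manifest.json")
  if (length(files) == 0L) stop("no field files in trace store: ", dir)
  if (!file.exists(manifest_path))
    stop("trace store sidecar manifest.json missing in ", dir)
  side <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- side$config
  cfg$molecules_per_field <- as.integer(cfg$molecules_per_field)
  config <- do.call(trace_sim_config, cfg)
  tab <- data.table::rbindlist(lapply(files, data.table::fread))
  tab <- tab[order(tab$molecule_id, tab$frame), ]
  ids <- unique(tab$molecule_id)
  truth <- side$truth
  truth_ids <- vapply(seq_len(nrow(truth)), function(i)
    as.integer(truth$molecule_id[i]), integer(1))
  traces <- lapply(ids, function(id) {
    sub <- tab[tab$molecule_id == id, ]
    ti <- match(id, truth_ids)
    structure(list(molecule_id = as.integer(id),
                   time = sub$time_s,
                   donor = sub$donor, acceptor = sub$acceptor,
                   red_pulse_acceptor =
                     unlist(truth$red_pulse_acceptor[ti]),
                   truth = list(
                     class = truth$class[ti],
                     state_path = unlist(truth$state_path[ti]),
                     donor_bleach_frame =
                       .null_na_int(truth$donor_bleach_frame[ti]),
                     acceptor_bleach_frame =
                       .null_na_int(truth$acceptor_bleach_frame[ti]),
                     total_intensity = truth$total_intensity[ti])),
              class = "fret_trace_raw")
  })
  field <- as.integer(side$field)
  manifest <- data.frame(
    molecule_id = as.integer(ids),
    field = field[match(ids, truth_ids)],
    class = vapply(traces, function(t) t$truth$class, character(1)),
    stringsAsFactors = FALSE)
  structure(list(traces = traces, config = config, field = field,
                 manifest = manifest),
            class = "fret_dataset")
}

.null_na_int <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) NA_integer_
  else as.integer(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report A `fret_report` from [analyze_dataset()], or any list.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass_recursive(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Write a FRET histogram (with fitted curve) as CSV
#'
#' @param hist A `fret_histogram`.
#' @param fit Optional `folded_fraction_result`; when given, a
#'   `fit_curve` column with the fitted Gaussian model evaluated at the
#'   bin centers is added.
#' @param path Output path.
#' @export
write_histogram_csv <- function(hist, path, fit = NULL) {
  d <- data.frame(bin_center = hist$bin_centers, count = hist$counts)
  if (!is.null(fit)) {
    f <- fit$fit
    curve <- numeric(length(hist$bin_centers))
    if (!is.na(f$mean_low) && f$area_low > 0)
      curve <- curve + .gauss(hist$bin_centers,
                              f$area_low / (f$sd_low * sqrt(2 * pi)),
                              f$mean_low, f$sd_low)
    if (!is.na(f$mean_high) && f$area_high > 0)
      curve <- curve + .gauss(hist$bin_centers,
                              f$area_high / (f$sd_high * sqrt(2 * pi)),
                              f$mean_high, f$sd_high)
    d$fit_curve <- curve
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
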