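# TSV readers/writers for elastic scans and HDX peak lists, plus ground
# truth serialisation. All outputs are re-readable by these readers.

#' Write elastic scans to a TSV file
#'
#' Columns: `temperature_K`, `Q_invA`, `intensity`, `sigma`.
#'
#' @param scans List of [elastic_scan()]s (or an `elastic_dataset`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scans, path) {
  if (inherits(scans, "elastic_dataset")) scans <- scans$scans
  rows <- lapply(scans, function(sc) {
    data.frame(temperature_K = scan_temperature(sc), Q_invA = sc$q,
               intensity = sc$intensity, sigma = sc$sigma)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv_checked <- function(path, required) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = NA, comment.char = "")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (col in required) {
    if (col %in% c("peptide_id")) next
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value in column '%s' at data line %d",
                   path, col, bad[1]))
    }
    tab[[col]] <- v
  }
  tab
}

#' Read elastic scans from a TSV file
#'
#' Expects the schema written by [write_scan_table()]; rows are grouped by
#' temperature and sorted by Q, so row order in the file does not matter.
#'
#' @param path Input path.
#' @return List of [elastic_scan()]s ordered by temperature.
#' @export
read_scan_table <- function(path) {
  tab <- .read_tsv_checked(path, c("temperature_K", "Q_invA", "intensity",
                                   "sigma"))
  temps <- sort(unique(tab$temperature_K))
  lapply(temps, function(tt) {
    sub <- tab[tab$temperature_K == tt, , drop = FALSE]
    elastic_scan(tt, sub$Q_invA, sub$intensity, sub$sigma)
  })
}

#' Write an MSD series to TSV
#'
#' Columns: `temperature_K`, `msd_A2`, `sigma_A2`, `valid_fraction`.
#' @param series An `msd_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msd_table <- function(series, path) {
  tab <- data.frame(temperature_K = series$temperature, msd_A2 = series$msd,
                    sigma_A2 = series$msd_sigma,
                    valid_fraction = series$valid_fraction)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write HDX envelopes to a TSV peak list
#'
#' Columns: `peptide_id`, `start`, `end`, `charge`, `time_s`, `mz`,
#' `intensity`; controls use `time_s = -1` (0%) and `-2` (80%).
#'
#' @param envelopes List of [hdx_envelope()]s (or an `hdx_dataset`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(envelopes, path) {
  if (inherits(envelopes, "hdx_dataset")) envelopes <- envelopes$envelopes
  rows <- lapply(envelopes, function(env) {
    data.frame(peptide_id = attr(env, "peptide_id"),
               start = attr(env, "start"), end = attr(env, "end"),
               charge = attr(env, "charge"), time_s = attr(env, "time"),
               mz = env$mz, intensity = env$intensity)
  })
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) format(v, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read HDX envelopes from a TSV peak list
#'
#' Groups rows by (peptide, charge, time); duplicate
#' (peptide, time, mz) rows have their intensities summed (documented merge
#' rule). Every peptide must carry a 0% control (`time_s = -1`); a missing
#' 80% control only disables back-exchange correction downstream, with a
#' warning here.
#'
#' @param path Input path.
#' @return List of [hdx_envelope()]s.
#' @export
read_peak_table <- function(path) {
  tab <- .read_tsv_checked(path, c("peptide_id", "start", "end", "charge",
                                   "time_s", "mz", "intensity"))
  key <- interaction(tab$peptide_id, tab$charge, tab$time_s, drop = TRUE)
  envs <- lapply(split(tab, key), function(sub) {
    grp <- factor(sub$mz)
    peaks <- data.frame(
      mz = as.numeric(levels(grp)),
      intensity = as.numeric(tapply(sub$intensity, grp, sum))
    )
    hdx_envelope(peaks, sub$peptide_id[1], sub$start[1], sub$end[1],
                 sub$charge[1], sub$time_s[1])
  })
  names(envs) <- NULL
  ids <- vapply(envs, function(e) attr(e, "peptide_id"), character(1))
  times <- vapply(envs, function(e) attr(e, "time"), numeric(1))
  for (id in unique(ids)) {
    tt <- times[ids == id]
    if (!any(tt == -1)) stop(sprintf("peptide %s has no 0%% control", id))
    if (!any(tt == -2)) {
      warning(sprintf(
        "peptide %s has no 80%% control; back-exchange correction disabled", id))
    }
  }
  envs
}

#' Write HDX ground truth to YAML
#'
#' @param truth An [hdx_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  obj <- list(
    sequence = truth$sequence,
    peptides = lapply(truth$peptides, function(p) {
      list(id = p$id, start = p$start, end = p$end, charge = p$charge)
    }),
    pf_dimer = truth$pf$dimer,
    pf_monomer = truth$pf$monomer,
    mixture_weights = lapply(truth$mixture_weights, as.numeric),
    conditions = list(pD = truth$conditions$pD,
                      temperature_K = truth$conditions$temperature,
                      d_fraction = truth$conditions$d_fraction),
    times_s = truth$times,
    back_exchange = truth$back_exchange,
    seed = truth$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}
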