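#' Peptide record
#'
#' A digested peptide mapped onto its parent protein.
#'
#' @param sequence Amino-acid string (one-letter codes).
#' @param start,end 1-based residue span on the parent protein (inclusive).
#' @param charge Charge state of the observed ion; `>= 1`.
#' @param id Optional identifier; defaults to `"start-end"`.
#' @return Object of class `peptide_record`.
#' @export
peptide_record <- function(sequence, start = 1L, end = start + nchar(sequence) - 1L,
                           charge = 2L, id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]], rownames(RESIDUE_FORMULAS))
  if (length(bad)) {
    stop(sprintf("unknown residue code(s): %s", paste(unique(bad), collapse = ", ")))
  }
  if (end - start + 1L != nchar(sequence)) {
    stop("span length does not match sequence length")
  }
  if (charge < 1L) stop("charge must be >= 1")
  structure(
    list(sequence = sequence, start = as.integer(start), end = as.integer(end),
         charge = as.integer(charge),
         id = if (is.null(id)) sprintf("%d-%d", start, end) else id),
    class = "peptide_record"
  )
}

#' @export
print.peptide_record <- function(x, ...) {
  cat(sprintf("Peptide %s (%d-%d, z = %d): %s  [N_exch = %d]\n",
              x$id, x$start, x$end, x$charge, x$sequence,
              count_exchangeable(x)))
  invisible(x)
}

#' Number of observable exchangeable backbone amides in a peptide
#'
#' Prolines carry no backbone amide hydrogen, and the first
#' `n_term_excluded` residues of a digested peptide are not counted: residue
#' 1 has no amide proper (free amine after digestion) and the residue-2 amide
#' back-exchanges faster than the earliest measurable time point.
#'
#' @param peptide A [peptide_record()] or amino-acid string.
#' @param n_term_excluded Number of N-terminal residues excluded (default 2).
#' @return Integer count of exchangeable amides.
#' @export
count_exchangeable <- function(peptide, n_term_excluded = 2L) {
  seq <- if (inherits(peptide, "peptide_record")) peptide$sequence else
    toupper(peptide)
  n <- nchar(seq)
  if (n < n_term_excluded) stop("sequence shorter than n_term_excluded")
  res <- strsplit(seq, "")[[1]]
  pos <- seq_len(n)
  sum(pos > n_term_excluded & res != "P")
}

#' Positions of exchangeable amides within a peptide
#'
#' @inheritParams count_exchangeable
#' @return Integer vector of 1-based positions within the peptide.
#' @export
exchangeable_positions <- function(peptide, n_term_excluded = 2L) {
  seq <- if (inherits(peptide, "peptide_record")) peptide$sequence else
    toupper(peptide)
  res <- strsplit(seq, "")[[1]]
  pos <- seq_along(res)
  pos[pos > n_term_excluded & res != "P"]
}

#' Read a single protein sequence from a FASTA file
#'
#' @param path Path to a FASTA file; the first record is used.
#' @return Upper-case amino-acid string.
#' @export
read_protein_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[[1]], ">")) {
    stop("not a FASTA file: ", path)
  }
  headers <- grep("^>", lines)
  first_end <- if (length(headers) > 1L) headers[2L] - 1L else length(lines)
  toupper(paste(gsub("\\s", "", lines[(headers[1L] + 1L):first_end]),
                collapse = ""))
}

#' Bundled mature human apoA-I sequence (243 residues)
#'
#' The standard mature apolipoprotein A-I sequence used as the worked-example
#' protein throughout the package; any FASTA can be substituted.
#'
#' @return Amino-acid string of length 243.
#' @export
apoa1_sequence <- function() {
  read_protein_fasta(system.file("extdata", "apoa1.fasta",
                                 package = "einshdx", mustWork = TRUE))
}
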