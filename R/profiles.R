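#' Per-residue dynamics profile
#'
#' Container for per-residue probability profiles of a protein sequence, as
#' produced by external disorder/phase-separation predictors: `p_d`
#' (structural disorder in the free state), `p_dd` (disordered, "fuzzy"
#' binding), `p_dp` (droplet-promoting propensity), and an optional per-residue
#' multiplicity-of-binding-modes (MBM) flag marking regions able to switch
#' between ordered and disordered binding.
#'
#' @param sequence single amino-acid string or character vector of one-letter
#'   codes; length must equal the number of positions.
#' @param positions integer residue indices (1-based, full-protein numbering),
#'   strictly increasing. Defaults to `1:n`.
#' @param p_d,p_dd,p_dp numeric vectors in \[0, 1\], one value per residue.
#' @param mbm_flag optional logical vector flagging MBM residues.
#' @param p_llps optional scalar whole-protein droplet probability in \[0, 1\].
#' @return An object of class `residue_profile`.
#' @examples
#' pr <- residue_profile("ACDEFGH", p_d = seq(0.1, 0.7, by = 0.1))
#' pr
#' @export
residue_profile <- function(sequence, positions = NULL, p_d = NULL,
                            p_dd = NULL, p_dp = NULL, mbm_flag = NULL,
                            p_llps = NULL) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  n <- length(sequence)
  if (is.null(positions)) positions <- seq_len(n)
  positions <- as.integer(positions)
  if (length(positions) != n)
    stop("sequence length (", n, ") != number of positions (",
         length(positions), ")")
  if (n > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  chk <- function(p, name) {
    if (is.null(p)) return(rep(NA_real_, n))
    p <- as.numeric(p)
    if (length(p) != n)
      stop(name, " must have one value per residue")
    if (any(!is.na(p) & (p < 0 | p > 1)))
      stop(name, " values must lie in [0, 1]")
    p
  }
  if (!is.null(p_llps) && (p_llps < 0 || p_llps > 1))
    stop("p_llps must lie in [0, 1]")
  structure(list(
    sequence = sequence, positions = positions,
    p_d = chk(p_d, "p_d"), p_dd = chk(p_dd, "p_dd"), p_dp = chk(p_dp, "p_dp"),
    mbm_flag = if (is.null(mbm_flag)) rep(FALSE, n) else as.logical(mbm_flag),
    p_llps = p_llps
  ), class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  cat("residue_profile:", length(x$sequence), "residues,",
      "positions", x$positions[1], "-", x$positions[length(x$positions)], "\n")
  cat("  sequence:", paste(utils::head(x$sequence, 40), collapse = ""),
      if (length(x$sequence) > 40) "...\n" else "\n")
  for (f in c("p_d", "p_dd", "p_dp")) {
    v <- x[[f]]
    if (all(is.na(v))) next
    cat(sprintf("  %-4s mean %.3f  range [%.3f, %.3f]\n", f,
                mean(v, na.rm = TRUE), min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  }
  if (any(x$mbm_flag)) cat("  MBM residues:", sum(x$mbm_flag), "\n")
  invisible(x)
}

#' @export
length.residue_profile <- function(x) length(x$sequence)

#' Read a per-residue profile table
#'
#' Reads a tab-separated table with columns `position`, `residue`, `p_d`,
#' `p_dd`, `p_dp` and optional `mbm_flag` into a [residue_profile].
#'
#' @param path path to a TSV file.
#' @return A [residue_profile].
#' @export
read_profile_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "residue", "p_d", "p_dd", "p_dp")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("profile table is missing columns: ", paste(miss, collapse = ", "))
  residue_profile(
    sequence = tab$residue, positions = tab$position,
    p_d = tab$p_d, p_dd = tab$p_dd, p_dp = tab$p_dp,
    mbm_flag = if ("mbm_flag" %in% names(tab)) tab$mbm_flag > 0 else NULL
  )
}

#' Write a profile to a tab-separated table
#'
#' @param profile a [residue_profile].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  tab <- data.frame(position = profile$positions, residue = profile$sequence,
                    p_d = profile$p_d, p_dd = profile$p_dd,
                    p_dp = profile$p_dp,
                    mbm_flag = as.integer(profile$mbm_flag))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single sequence from a FASTA file
#'
#' Minimal single-record FASTA reader returning the amino-acid string.
#'
#' @param path path to a FASTA file; the first record is used.
#' @return A single character string.
#' @export
read_fasta_sequence <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA header found in ", path)
  from <- hdr[1] + 1L
  to <- if (length(hdr) > 1L) hdr[2] - 1L else length(lines)
  if (from > to) stop("empty FASTA record in ", path)
  toupper(gsub("[[:space:]]", "", paste(lines[from:to], collapse = "")))
}

#' Residue window in full-protein numbering
#'
#' An inclusive residue window `[start, end]`, by default the MEF2D beta-domain
#' (residues 286-292 in UniProt Q14814 numbering).
#'
#' @param start,end 1-based residue indices, inclusive on both ends.
#' @return An object of class `domain_window`.
#' @export
domain_window <- function(start = 286L, end = 292L) {
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("window start must be <= end")
  structure(list(start = start, end = end), class = "domain_window")
}

#' @export
print.domain_window <- function(x, ...) {
  cat("domain_window: residues", x$start, "-", x$end, "\n")
  invisible(x)
}

#' Map between full-protein and peptide-local numbering
#'
#' The NMR/MD peptides cover MEF2D residues 265-301; full-protein residue 265
#' is peptide residue 1. Converts indices (or a [domain_window]) between the
#' two frames.
#'
#' @param x integer positions or a [domain_window].
#' @param direction `"full_to_peptide"` or `"peptide_to_full"`.
#' @param peptide_start full-protein index of peptide residue 1 (default 265).
#' @return Same type as `x`, renumbered.
#' @export
map_numbering <- function(x, direction = c("full_to_peptide",
                                           "peptide_to_full"),
                          peptide_start = 265L) {
  direction <- match.arg(direction)
  off <- as.integer(peptide_start) - 1L
  shift <- if (direction == "full_to_peptide") -off else off
  if (inherits(x, "domain_window"))
    domain_window(x$start + shift, x$end + shift)
  else as.integer(x) + shift
}

window_index <- function(profile, window) {
  idx <- which(profile$positions >= window$start &
                 profile$positions <= window$end)
  if (length(idx) != window$end - window$start + 1L)
    stop("window ", window$start, "-", window$end,
         " is not fully covered by the profile (positions ",
         profile$positions[1], "-",
         profile$positions[length(profile$positions)], ")")
  idx
}
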