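#' Construct a binding dataset
#'
#' A binding dataset is a data frame of peptide binding records (columns
#' \code{allele}, \code{peptide}, \code{ic50_nM}, \code{ln_ic50} and
#' optionally \code{subset}) with uniform peptide length, tagged with the
#' MHC class the geometry implies (9-mers are class I, 15-mers class II).
#'
#' @param allele character vector of allele identifiers.
#' @param peptide character vector of peptide sequences (uniform length,
#'   standard residues only).
#' @param ic50_nM positive numeric, nanomolar.
#' @param subset optional per-record subset tag.
#' @return data frame of class \code{binding_dataset} with attributes
#'   \code{peptide_length} and \code{mhc_class}.
#' @export
binding_dataset <- function(allele, peptide, ic50_nM, subset = NULL) {
  n <- length(peptide)
  stopifnot(length(allele) %in% c(1L, n), length(ic50_nM) == n)
  allele <- rep_len(as.character(allele), n)
  peptide <- toupper(as.character(peptide))
  lens <- nchar(peptide)
  if (length(unique(lens)) != 1L) {
    stop("mixed peptide lengths: rows ",
         paste(head(which(lens != lens[1]), 5L), collapse = ", "))
  }
  bad <- grep(sprintf("[^%s]", paste(AA_CODES, collapse = "")), peptide)
  if (length(bad)) {
    stop("non-standard residues in rows ",
         paste(head(bad, 5L), collapse = ", "))
  }
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("ic50 must be positive and finite; rows ",
         paste(head(which(!is.finite(ic50_nM) | ic50_nM <= 0), 5L),
               collapse = ", "))
  }
  df <- data.frame(allele = allele, peptide = peptide,
                   ic50_nM = ic50_nM, ln_ic50 = log(ic50_nM),
                   stringsAsFactors = FALSE)
  if (!is.null(subset)) df$subset <- rep_len(as.character(subset), n)
  L <- lens[1]
  attr(df, "peptide_length") <- L
  attr(df, "mhc_class") <- if (L == 9L) "I" else if (L == 15L) "II"
                           else NA_character_
  class(df) <- c("binding_dataset", "data.frame")
  df
}

#' Read a peptide binding table from TSV
#'
#' Expects tab-separated columns \code{allele}, \code{peptide},
#' \code{ic50_nM}; lines starting with '#' are ignored. Duplicate
#' (allele, peptide) pairs are retained with a warning.
#'
#' @param path TSV path.
#' @return a \code{\link{binding_dataset}}.
#' @export
read_binding_table <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  req <- c("allele", "peptide", "ic50_nM")
  if (!all(req %in% names(df))) {
    stop("binding table needs columns: ", paste(req, collapse = ", "))
  }
  ic50 <- suppressWarnings(as.numeric(df$ic50_nM))
  if (anyNA(ic50)) {
    stop("malformed ic50 at line(s) ",
         paste(head(which(is.na(ic50)) + 1L, 5L), collapse = ", "))
  }
  dup <- duplicated(df[, c("allele", "peptide")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (allele, peptide) pair(s) retained")
  }
  binding_dataset(df$allele, df$peptide, ic50,
                  subset = if ("subset" %in% names(df)) df$subset)
}

#' Write a binding dataset to TSV
#'
#' ic50 values are written at full double precision so that reading the
#' file back reproduces the dataset exactly.
#'
#' @param ds a \code{binding_dataset}.
#' @param path output path.
#' @export
write_binding_table <- function(ds, path) {
  out <- data.frame(allele = ds$allele, peptide = ds$peptide,
                    ic50_nM = sprintf("%.17g", ds$ic50_nM))
  if ("subset" %in% names(ds)) out$subset <- ds$subset
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and terminal '*' stop symbols stripped. In
#' strict mode (default) records containing residues outside the 20
#' standard codes are skipped with a warning; in lenient mode they are
#' kept.
#'
#' @param path FASTA path (wrapped lines fine).
#' @param strict logical; skip records with non-standard residues.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, strict = TRUE) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  out <- toupper(as.character(seqs))
  out <- sub("^\\*+", "", sub("\\*+$", "", out))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (strict) {
    ok <- !grepl(sprintf("[^%s]", paste(AA_CODES, collapse = "")), out)
    if (any(!ok)) {
      warning("skipped ", sum(!ok),
              " record(s) with non-standard residues: ",
              paste(head(names(out)[!ok], 5L), collapse = ", "))
      out <- out[ok]
    }
  }
  out
}

#' Sample random k-mers from a proteome
#'
#' Draws \code{n} windows uniformly, without replacement, over all
#' (sequence, offset) windows of width k that contain only standard
#' residues. Duplicate peptide strings arising from different windows are
#' allowed (proteomes repeat motifs). Used to build random test sets,
#' e.g. 1000 15-mers from a bacterial proteome.
#'
#' @param proteome named character vector of sequences (as from
#'   \code{\link{read_fasta}}).
#' @param k window width (default 15).
#' @param n number of windows (default 1000).
#' @param seed integer seed.
#' @return data frame with columns \code{peptide}, \code{source},
#'   \code{start} (1-based offset).
#' @export
sample_kmers <- function(proteome, k = 15, n = 1000, seed = 1) {
  nm <- names(proteome)
  proteome <- as.character(proteome)
  names(proteome) <- if (is.null(nm)) paste0("seq", seq_along(proteome))
                     else nm
  if (!any(nchar(proteome) >= k)) {
    stop("no sequence of length >= ", k)
  }
  windows <- do.call(rbind, lapply(seq_along(proteome), function(i) {
    s <- proteome[i]
    L <- nchar(s)
    if (L < k) return(NULL)
    valid <- strsplit(s, "")[[1]] %in% AA_CODES
    bad_cum <- cumsum(!valid)
    starts <- seq_len(L - k + 1L)
    ok <- (bad_cum[starts + k - 1L] -
             c(0, bad_cum)[starts]) == 0L
    if (!any(ok)) return(NULL)
    data.frame(seq = i, start = starts[ok])
  }))
  if (is.null(windows) || nrow(windows) == 0L) {
    stop("no eligible windows of width ", k)
  }
  if (nrow(windows) < n) {
    warning("only ", nrow(windows), " eligible windows; returning all")
    pick <- seq_len(nrow(windows))
  } else {
    pick <- with_seed(seed, sort(sample.int(nrow(windows), n)))
  }
  sel <- windows[pick, , drop = FALSE]
  data.frame(peptide = substring(proteome[sel$seq], sel$start,
                                 sel$start + k - 1L),
             source = names(proteome)[sel$seq],
             start = sel$start, row.names = NULL,
             stringsAsFactors = FALSE)
}
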