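#' Binding-groove position labels
#'
#' Maps residue index to the standard MHC groove nomenclature: class I
#' 9-mers occupy pocket zones P1..P9; class II 15-mers place the 9-mer
#' core at P1..P9 with three peptide-flanking residues on each side
#' (N-3, N-2, N-1 before P1 and C+1, C+2, C+3 after P9).
#'
#' @param length peptide length: 9 (class I) or 15 (class II).
#' @param mhc_class "I" or "II".
#' @return character vector of \code{length} labels.
#' @export
position_labels <- function(length, mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  if (mhc_class == "I" && length == 9L) {
    paste0("P", 1:9)
  } else if (mhc_class == "II" && length == 15L) {
    c("N-3", "N-2", "N-1", paste0("P", 1:9), "C+1", "C+2", "C+3")
  } else {
    stop(sprintf("unsupported geometry: length %d for MHC class %s",
                 length, mhc_class))
  }
}

#' Encode a peptide as a z-scale descriptor vector
#'
#' Each residue contributes its (z1, z2, z3, ...) scores in sequence
#' order, so an L-mer becomes a flat vector of 3L descriptors (27 for a
#' 9-mer, 45 for a 15-mer with the default three-component table).
#'
#' @param peptide character scalar of one-letter codes.
#' @param zt a \code{zscale_table} (default \code{\link{canonical_zscales}()}).
#' @return named numeric vector of length \code{nchar(peptide) * ncol(zt$z)};
#'   names are \code{<position>.z<k>} with positions labelled by groove
#'   convention when the length is 9 or 15, else \code{pos<i>}.
#' @export
encode_peptide <- function(peptide, zt = canonical_zscales()) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  if (nchar(peptide) == 0L) stop("empty peptide sequence")
  res <- strsplit(toupper(peptide), "")[[1]]
  bad <- which(!res %in% zt$amino_acids)
  if (length(bad)) {
    stop(sprintf("non-standard residue '%s' at position %d",
                 res[bad[1]], bad[1]))
  }
  zrows <- zt$z[res, , drop = FALSE]
  v <- as.vector(t(zrows))
  labs <- descriptor_labels(length(res), ncol(zt$z))
  names(v) <- labs
  v
}

descriptor_labels <- function(L, ncomp) {
  pos <- if (L == 9L) {
    position_labels(9L, "I")
  } else if (L == 15L) {
    position_labels(15L, "II")
  } else {
    paste0("pos", seq_len(L))
  }
  as.vector(t(outer(pos, paste0("z", seq_len(ncomp)), paste, sep = ".")))
}

#' Encode a binding dataset as a descriptor matrix and response vector
#'
#' @param records a \code{binding_dataset} or data frame with columns
#'   \code{allele}, \code{peptide}, \code{ic50_nM}.
#' @param zt a \code{zscale_table}.
#' @return list with \code{X} (n x 3L descriptor matrix, row order
#'   preserved), \code{y} (n responses, \code{ln(ic50_nM)}),
#'   \code{position_labels}.
#' @export
encode_dataset <- function(records, zt = canonical_zscales()) {
  records <- as.data.frame(records)
  req <- c("allele", "peptide", "ic50_nM")
  if (!all(req %in% names(records))) {
    stop("records need columns: ", paste(req, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("no records to encode")
  lens <- nchar(records$peptide)
  if (length(unique(lens)) != 1L) {
    stop("mixed peptide lengths: rows ",
         paste(head(which(lens != lens[1]), 5), collapse = ", "))
  }
  if (length(unique(records$allele)) != 1L) {
    stop("records span multiple alleles; encode one allele at a time")
  }
  if (anyNA(records$ic50_nM)) {
    stop("missing ic50 for rows ",
         paste(head(which(is.na(records$ic50_nM)), 5), collapse = ", "))
  }
  if (any(records$ic50_nM <= 0)) {
    stop("non-positive ic50 for rows ",
         paste(head(which(records$ic50_nM <= 0), 5), collapse = ", "))
  }
  X <- t(vapply(records$peptide, encode_peptide,
                numeric(lens[1] * ncol(zt$z)), zt = zt))
  rownames(X) <- NULL
  L <- lens[1]
  pos <- if (L == 9L) position_labels(9L, "I")
         else if (L == 15L) position_labels(15L, "II")
         else paste0("pos", seq_len(L))
  list(X = X, y = log(records$ic50_nM), position_labels = pos)
}
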