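#' @importFrom stats cor prcomp sd var predict rnorm runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Canonical residue order used everywhere in the package.
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid physicochemical property matrix
#'
#' Constructs a validated 20-row matrix of raw physicochemical property
#' measurements, one row per standard amino acid (canonical alphabetical
#' order \code{ACDEFGHIKLMNPQRSTVWY}), one column per property scale.
#'
#' @param values numeric matrix or data frame, 20 rows x P columns (P >= 3).
#' @param amino_acids character vector of 20 one-letter codes matching the
#'   rows of \code{values} (any order; rows are re-sorted canonically).
#' @param property_names optional character vector of P column identifiers;
#'   defaults to the column names of \code{values}.
#' @return an object of class \code{property_matrix}: a numeric matrix with
#'   amino-acid row names in canonical order.
#' @export
property_matrix <- function(values, amino_acids = rownames(values),
                            property_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(amino_acids)) {
    stop("amino-acid row identifiers are required")
  }
  amino_acids <- toupper(as.character(amino_acids))
  if (length(amino_acids) != nrow(values)) {
    stop("length of 'amino_acids' does not match rows of 'values'")
  }
  dup <- amino_acids[duplicated(amino_acids)]
  if (length(dup)) {
    stop("duplicate amino-acid row(s): ", paste(unique(dup), collapse = ", "))
  }
  missing <- setdiff(AA_CODES, amino_acids)
  if (length(missing)) {
    stop("missing amino acid(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(amino_acids, AA_CODES)
  if (length(extra)) {
    stop("unrecognized amino-acid code(s): ", paste(extra, collapse = ", "))
  }
  if (ncol(values) < 3) {
    stop("at least 3 property columns are required, got ", ncol(values))
  }
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(suppressWarnings(matrix(as.numeric(values),
                                                    nrow(values)))),
                 arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                   amino_acids[bad[1, 1]],
                   if (is.null(property_names)) bad[1, 2] else
                     property_names[bad[1, 2]]))
    }
    stop("property values must be finite numeric")
  }
  if (is.null(property_names)) {
    property_names <- paste0("prop", seq_len(ncol(values)))
  }
  rownames(values) <- amino_acids
  colnames(values) <- property_names
  values <- values[AA_CODES, , drop = FALSE]
  structure(values, class = c("property_matrix", "matrix"))
}

#' Load an amino-acid property table from TSV
#'
#' Reads a tab-separated table whose first column holds one-letter
#' amino-acid codes and whose remaining columns are numeric property
#' scales (header row of property names). Rows may appear in any order;
#' the result is always in canonical order.
#'
#' @param path path to the TSV file.
#' @return a \code{\link{property_matrix}}.
#' @export
load_property_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) {
    stop("property table needs an amino-acid column plus >= 3 property columns")
  }
  aa <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   aa[i], names(vals)[j]))
    }
    vals[[j]] <- v
  }
  property_matrix(as.matrix(vals), amino_acids = aa,
                  property_names = names(vals))
}

new_zscale_table <- function(z, variance_explained, provenance) {
  stopifnot(nrow(z) == 20L)
  rownames(z) <- AA_CODES
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  structure(list(amino_acids = AA_CODES, z = z,
                 variance_explained = variance_explained,
                 provenance = provenance),
            class = "zscale_table")
}

#' @export
print.zscale_table <- function(x, ...) {
  cat(sprintf("z-scale table (%s), %d components\n",
              x$provenance, ncol(x$z)))
  if (!all(is.na(x$variance_explained))) {
    cat("variance explained:",
        paste(sprintf("%.3f", x$variance_explained), collapse = ", "), "\n")
  }
  print(round(x$z, 3))
  invisible(x)
}

#' Derive z-scales by correlation-matrix PCA
#'
#' Standardizes every property column to mean 0 / variance 1 over the 20
#' amino acids and extracts principal components of the resulting
#' correlation structure. The z-scores are the amino-acid projections onto
#' the unit eigenvectors (so they carry eigenvalue weighting: components
#' that explain more property variance span a wider score range). Signs
#' are fixed deterministically: PC1 is oriented so z1(F) > 0 (hydrophobic
#' phenylalanine positive), PC2 so z2(G) > 0, PC3 so z3(P) > 0; any
#' further component is oriented so its largest-magnitude score is
#' positive.
#'
#' @param props a \code{\link{property_matrix}}.
#' @param n_components number of components to retain (default 3).
#' @return a \code{zscale_table} with \code{provenance = "derived"} and
#'   \code{variance_explained} the eigenvalue proportions.
#' @export
compute_zscales <- function(props, n_components = 3) {
  if (!inherits(props, "property_matrix")) {
    props <- property_matrix(props)
  }
  P <- ncol(props)
  if (n_components < 1 || n_components > min(20L, P)) {
    stop("n_components must be between 1 and min(20, P)")
  }
  sds <- apply(props, 2, sd)
  if (any(sds == 0)) {
    stop("constant property column (zero variance): ",
         paste(colnames(props)[sds == 0], collapse = ", "))
  }
  Xs <- scale(unclass(props), center = TRUE, scale = TRUE)
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  prop_var <- ev / sum(ev)
  z <- pc$x[, seq_len(n_components), drop = FALSE]
  anchors <- c("F", "G", "P")
  for (k in seq_len(n_components)) {
    s <- if (k <= 3L) {
      sign(z[anchors[k], k])
    } else {
      sign(z[which.max(abs(z[, k])), k])
    }
    if (s < 0) z[, k] <- -z[, k]
  }
  new_zscale_table(z, prop_var[seq_len(n_components)], "derived")
}

#' Canonical three-component z-scale table
#'
#' Returns the reference z-scales shipped with the package: the published
#' first three principal components of a 31-scale amino-acid property
#' compendium (z1 tracks polarity/hydrophobicity, z2 molecular size,
#' z3 electronic character). The first three components of the source
#' property set account for approximately 90 percent of its variance;
#' the per-component proportions are not part of the published table, so
#' \code{variance_explained} is \code{NA}.
#'
#' @return a \code{zscale_table} with \code{provenance =
#'   "canonical_table1"}.
#' @export
canonical_zscales <- function() {
  path <- system.file("extdata", "zscales_canonical.tsv",
                      package = "mhcqsar", mustWork = TRUE)
  zt <- read_zscale_table(path)
  zt$provenance <- "canonical_table1"
  zt
}

#' Read a z-scale table from TSV
#'
#' @param path TSV with columns \code{aa}, \code{z1}, \code{z2}, \code{z3},
#'   (optionally more components).
#' @return a \code{zscale_table} with \code{provenance = "derived"}.
#' @export
read_zscale_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (names(df)[1] != "aa") stop("first column must be 'aa'")
  z <- as.matrix(df[, -1, drop = FALSE])
  rownames(z) <- df$aa
  missing <- setdiff(AA_CODES, df$aa)
  if (length(missing)) {
    stop("missing amino acid(s): ", paste(missing, collapse = ", "))
  }
  z <- z[AA_CODES, , drop = FALSE]
  new_zscale_table(z, rep(NA_real_, ncol(z)), "derived")
}

#' Write a z-scale table to TSV
#'
#' Values are written at 6 decimal places, which round-trips the canonical
#' table losslessly.
#'
#' @param zt a \code{zscale_table}.
#' @param path output path.
#' @export
write_zscale_table <- function(zt, path) {
  df <- data.frame(aa = zt$amino_acids,
                   round(zt$z, 6), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
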