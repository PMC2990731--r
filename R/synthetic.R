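#' Configuration for the synthetic binding-data generator
#'
#' The defaults emulate the documented structure of public MHC-II
#' benchmark datasets: two overlapping peptide subsets of 232 and 167
#' records whose ln(ic50) means differ by 2.2 (the smaller subset having
#' the higher affinity, i.e. an e^2.2-fold mean ratio), plus censoring
#' spikes at the assay limits 1 nM (low) and 20,000 / 78,125 nM (high)
#' with snap fractions approximating the observed spike loads.
#'
#' @param n_peptides integer vector, peptides per subset.
#' @param subset_mean_offsets baseline ln(ic50) per subset, same length.
#' @param true_effect either a K-vector of coefficients over the z-scale
#'   descriptors (see \code{\link{generate_linear_truth}}) or a planted
#'   network (list with \code{input_weights} H x (K+1) and
#'   \code{output_weights} H+1) evaluated by a logistic-hidden forward
#'   pass; \code{NULL} means no sequence effect.
#' @param noise_sd Gaussian noise SD on the ln scale (default 1).
#' @param censor_points_nM assay limits; the smallest acts as the low
#'   (left) limit, the others as high (right) limits.
#' @param censor_fractions per-limit probability that a value beyond the
#'   limit is snapped to it.
#' @param peptide_length 9 or 15.
#' @param allele allele tag written on the records.
#' @param composition residue sampling weights (named, defaults uniform
#'   over the 20 standard amino acids).
#' @param seed integer seed.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_peptides = c(232L, 167L),
                             subset_mean_offsets = c(8.0, 5.8),
                             true_effect = NULL,
                             noise_sd = 1,
                             censor_points_nM = c(1, 20000, 78125),
                             censor_fractions = c(0.75, 0.88, 0.86),
                             peptide_length = 15L,
                             allele = "SYN-DRB1*0101",
                             composition = NULL,
                             seed = 1L) {
  stopifnot(length(n_peptides) == length(subset_mean_offsets),
            all(n_peptides > 0), noise_sd >= 0,
            peptide_length %in% c(9L, 15L),
            length(censor_points_nM) == length(censor_fractions),
            all(censor_points_nM > 0),
            all(censor_fractions >= 0 & censor_fractions <= 1))
  if (is.null(composition)) {
    composition <- setNames(rep(1 / 20, 20), AA_CODES)
  }
  stopifnot(all(names(composition) %in% AA_CODES),
            all(composition >= 0), sum(composition) > 0)
  structure(list(n_peptides = as.integer(n_peptides),
                 subset_mean_offsets = subset_mean_offsets,
                 true_effect = true_effect, noise_sd = noise_sd,
                 censor_points_nM = censor_points_nM,
                 censor_fractions = censor_fractions,
                 peptide_length = as.integer(peptide_length),
                 allele = allele, composition = composition,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Planted sparse linear effect over z-scale descriptors
#'
#' Draws a coefficient vector with \code{sparsity} nonzero entries at
#' seed-chosen descriptor slots. \code{effect_scale} is a standardized
#' effect size: the nonzero coefficients are uniform in [0.5, 1.5] x
#' \code{effect_scale} with random sign, expressed per SD of the
#' corresponding z-scale descriptor (the raw coefficient is divided by
#' that SD under uniform residue composition). Planted slots therefore
#' contribute comparable signal variance regardless of which principal
#' component they sit on — z1 spans a much wider numeric range than z3,
#' and an unstandardized coefficient on z3 would be a much weaker
#' effect. The chosen slots are recorded in the \code{positions}
#' attribute for recovery checks (e.g. that planted positions receive
#' VIP > 1 after a PLS fit).
#'
#' @param length peptide length, 9 or 15 (K = 3 x length).
#' @param sparsity number of nonzero coefficients (<= K).
#' @param effect_scale standardized magnitude scale (ln units per
#'   descriptor SD).
#' @param seed integer seed.
#' @param zt z-scale table defining the descriptor SDs.
#' @return numeric K-vector with attribute \code{positions}.
#' @export
generate_linear_truth <- function(length, sparsity, effect_scale = 1,
                                  seed = 1, zt = canonical_zscales()) {
  K <- 3L * as.integer(length)
  if (sparsity > K) stop("sparsity exceeds descriptor count ", K)
  # population SD of each component over the 20 residues, recycled
  # across positions (uniform composition)
  comp_sd <- sqrt(colMeans(scale(zt$z, scale = FALSE)^2))
  slot_sd <- rep_len(comp_sd, K)
  with_seed(seed, {
    pos <- sort(sample.int(K, sparsity))
    beta <- numeric(K)
    beta[pos] <- effect_scale * runif(sparsity, 0.5, 1.5) *
      sample(c(-1, 1), sparsity, replace = TRUE) / slot_sd[pos]
    structure(beta, positions = pos)
  })
}

planted_signal <- function(X, truth) {
  if (is.null(truth)) return(numeric(nrow(X)))
  if (is.numeric(truth)) {
    if (length(truth) != ncol(X)) stop("effect vector length mismatch")
    return(as.vector(X %*% truth))
  }
  if (is.list(truth) && !is.null(truth$input_weights)) {
    act <- cbind(1, X) %*% t(truth$input_weights)
    hid <- 1 / (1 + exp(-act))
    return(as.vector(cbind(1, hid) %*% truth$output_weights))
  }
  stop("unrecognized true_effect specification")
}

#' Generate a synthetic binding dataset
#'
#' Peptides are drawn residue-wise from the configured composition; the
#' true ln(ic50) of each record is its subset baseline plus the planted
#' sequence effect plus Gaussian noise. Censoring then emulates assay
#' limits: each value below the lowest censor point is snapped to that
#' point with the configured probability, and each value above a high
#' censor point is snapped (with its probability) to the largest limit it
#' exceeds — reproducing the spike-at-the-limit histograms of real
#' datasets. Uncensored ground truth is kept in the \code{truth}
#' attribute, never in the standard columns models see.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param zt z-scale table used to evaluate the planted effect.
#' @return a \code{\link{binding_dataset}} with attribute \code{truth}
#'   (data frame: \code{ln_true}, \code{censored}, \code{subset}) and
#'   attribute \code{true_effect}.
#' @export
generate_dataset <- function(cfg, zt = canonical_zscales()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    n_total <- sum(cfg$n_peptides)
    subset_id <- rep(seq_along(cfg$n_peptides), cfg$n_peptides)
    aa <- names(cfg$composition)
    pep <- vapply(seq_len(n_total), function(i)
      paste(sample(aa, cfg$peptide_length, replace = TRUE,
                   prob = cfg$composition), collapse = ""),
      character(1))
    X <- t(vapply(pep, encode_peptide,
                  numeric(cfg$peptide_length * ncol(zt$z)), zt = zt))
    ln_true <- cfg$subset_mean_offsets[subset_id] +
      planted_signal(X, cfg$true_effect) +
      rnorm(n_total, 0, cfg$noise_sd)
    ln_obs <- ln_true
    censored <- rep("none", n_total)
    pts <- cfg$censor_points_nM
    frs <- cfg$censor_fractions
    ord <- order(pts)
    low_pt <- pts[ord[1]]; low_fr <- frs[ord[1]]
    ln_low <- log(low_pt)
    is_low <- ln_obs < ln_low
    snap <- is_low & runif(n_total) < low_fr
    ln_obs[snap] <- ln_low
    censored[snap] <- paste0("low:", low_pt)
    if (length(pts) > 1L) {
      hi_pts <- pts[ord[-1]]; hi_frs <- frs[ord[-1]]
      # assign each value to the largest limit it exceeds
      for (j in rev(seq_along(hi_pts))) {
        ln_pt <- log(hi_pts[j])
        beyond <- ln_obs > ln_pt & censored == "none"
        if (j < length(hi_pts)) {
          beyond <- beyond & ln_obs <= log(hi_pts[j + 1L])
        }
        snap <- beyond & runif(n_total) < hi_frs[j]
        ln_obs[snap] <- ln_pt
        censored[snap] <- paste0("high:", hi_pts[j])
      }
    }
    ds <- binding_dataset(cfg$allele, pep, exp(ln_obs),
                          subset = paste0("S", subset_id))
    attr(ds, "truth") <- data.frame(ln_true = ln_true,
                                    censored = censored,
                                    subset = paste0("S", subset_id),
                                    stringsAsFactors = FALSE)
    attr(ds, "true_effect") <- cfg$true_effect
    ds
  })
}
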