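# Shared fixtures, all generated in code.

# Random peptides of a given length (uniform residues).
random_peptides <- function(n, length, seed) {
  with_seed_local(seed, vapply(seq_len(n), function(i)
    paste(sample(mhcqsar:::AA_CODES, length, replace = TRUE),
          collapse = ""), character(1)))
}

# Local seed scoping for test code (mirrors the package-internal helper
# without reaching into it for control flow).
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Encoded synthetic linear-response problem: X from random peptides,
# y = X beta + noise at a chosen signal-to-noise.
linear_problem <- function(n, length, sparsity, effect_scale, r2_target,
                           seed, beta = NULL) {
  if (is.null(beta)) {
    beta <- generate_linear_truth(length, sparsity, effect_scale,
                                  seed = seed)
  }
  peps <- random_peptides(n, length, seed + 1)
  X <- t(vapply(peps, encode_peptide, numeric(3 * length)))
  signal <- as.vector(X %*% beta)
  sigma <- sqrt(var(signal) * (1 / r2_target - 1))
  y <- signal + with_seed_local(seed + 2, rnorm(n, 0, sigma))
  list(X = X, y = y, beta = beta, sigma = sigma, peptides = peps)
}

# Write a 20 x P property TSV (optionally shuffled / corrupted) and
# return its path.
write_property_tsv <- function(values, aa = rownames(values),
                               path = tempfile(fileext = ".tsv")) {
  df <- data.frame(aa = aa, values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A 20 x P property matrix driven by a few latent factors.
latent_property_values <- function(P, n_latent, noise_sd, seed) {
  with_seed_local(seed, {
    fac <- matrix(rnorm(20 * n_latent), 20, n_latent)
    load <- matrix(rnorm(n_latent * P, sd = 2), n_latent, P)
    vals <- fac %*% load + matrix(rnorm(20 * P, sd = noise_sd), 20, P)
    rownames(vals) <- mhcqsar:::AA_CODES
    colnames(vals) <- paste0("prop", seq_len(P))
    vals
  })
}
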