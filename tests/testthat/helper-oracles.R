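# Independent brute-force oracles and tiny fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# naive O(n*m) motif scan; N never matches
naive_find_sites <- function(seq, motif) {
  n <- nchar(seq)
  m <- nchar(motif)
  hits <- integer(0)
  if (n < m) return(hits)
  for (i in seq_len(n - m + 1L)) {
    if (substring(seq, i, i + m - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# unbiased expected heterozygosity from a dosage vector, textbook formula
he_brute <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  p <- sum(g) / (2 * n)
  (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
}

# Pearson correlation written out longhand
pearson_brute <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# diploid genotype likelihoods as a direct per-observation product in log
# space, normalised
lik_brute <- function(obs, ref, alt, e) {
  pb <- function(b, a) if (b == a) 1 - e else e / 3
  ll <- vapply(list(c(ref, ref), c(ref, alt), c(alt, alt)), function(g) {
    sum(vapply(obs, function(b)
      log(0.5 * pb(b, g[1]) + 0.5 * pb(b, g[2])), numeric(1)))
  }, numeric(1))
  lik <- exp(ll - max(ll))
  lik / sum(lik)
}

# small genotype matrix with explicit entries
toy_gm <- function(geno, positions = NULL, subpop = NULL) {
  n_s <- nrow(geno)
  n_l <- ncol(geno)
  if (is.null(positions)) positions <- seq_len(n_l) * 1000L
  samples <- data.frame(sample = sprintf("S%02d", seq_len(n_s)),
                        stringsAsFactors = FALSE)
  if (!is.null(subpop)) samples$subpop <- subpop
  genotype_matrix(geno,
                  data.frame(contig = "chr1", pos = positions,
                             ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  samples)
}

# deterministic small simulated pipeline shared by alignment/genotyper
# tests (built once per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- simulate_reference(n_contigs = 2, lengths = c(4e5, 1e5),
                                seed = 91)
      pop <- simulate_population(ref,
                                 population_model(n_cultivated = 8L,
                                                  n_wild = 6L),
                                 seed = 92)
      lib <- simulate_library(pop, library_model(error_rate = 0),
                              seed = 93)
      cache <<- list(ref = ref, pop = pop, lib = lib)
    }
    cache
  }
})
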