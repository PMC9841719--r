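# Small programmatic fixtures shared across tests.

# Compact two-class cohort for smoke tests (cheap to generate and fit).
tiny_cohort <- function(seed = 1L, n_per_class = 20L, p_genes = 40L,
                        block_size = 8L, n_shift_genes = 0L, shift = 2) {
  generate_cohort(n_per_class = n_per_class, p_genes = p_genes,
                  block_size = block_size, n_shift_genes = n_shift_genes,
                  shift = shift, seed = seed)
}

# Annotation frame for bare matrices.
make_ann <- function(sample_ids, classes) {
  data.frame(sample_id = sample_ids, class = classes, stringsAsFactors = FALSE)
}

# Seeded logistic test instance for solver checks.
solver_instance <- function(seed, n, p, q_range = c(0.5, 3)) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("g%03d", seq_len(p))))
  beta <- c(rep(1.5, min(3, p)), rep(0, p - min(3, p)))
  y <- stats::rbinom(n, 1, stats::plogis(drop(X %*% beta)))
  if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
  q <- stats::runif(p, q_range[1], q_range[2])
  list(X = X, y = y, q = q)
}
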