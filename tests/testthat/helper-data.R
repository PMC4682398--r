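# Shared in-code fixtures for the tests: tiny sequences, windows and a
# small planted benchmark that exercises every module quickly.

make_window <- function(..., n = NULL) {
  w <- paste0(...)
  stopifnot(nchar(w) %% 2 == 1)
  w
}

random_protein <- function(L, seed) {
  neddly:::with_local_seed(seed, paste(
    sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V"), L, replace = TRUE),
    collapse = ""
  ))
}

tiny_fixture_config <- function(seed = 42, signal = 1) {
  fixture_config(
    n_proteins = 5, length_range = c(120, 180), n_positive = 8,
    signal = signal, seed = seed
  )
}

# Small separable toy for SVM-level tests: two informative columns.
toy_classification <- function(n = 60, seed = 9, separation = 3) {
  neddly:::with_local_seed(seed, {
    y <- rep(c("positive", "negative"), length.out = n)
    X <- matrix(stats::rnorm(2 * n), n, 2,
                dimnames = list(NULL, c("f1", "f2")))
    X[y == "positive", 1] <- X[y == "positive", 1] + separation
    list(X = X, y = y)
  })
}
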