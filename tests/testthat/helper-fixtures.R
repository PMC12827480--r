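# Shared fixtures, built in code and memoised per test run.

.fixture_env <- new.env()

# small motif-planted transcriptome reused across files
small_sim <- function(seed = 11, n_genes = 40, ...) {
  key <- paste0("sim_", seed, "_", n_genes)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_transcriptome(
      n_genes = n_genes, utr_length_range = c(300, 700), seed = seed, ...)
  }
  .fixture_env[[key]]
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# regex oracle for pentamer classes (independent of the scanner)
regex_scan_oracle <- function(sequence, motif_class) {
  pat <- c(RRACH = "(?=[AG][AG]AC[ACT])", WWAWW = "(?=[AT][AT]A[AT][AT])",
           CRACH = "(?=C[AG]AC[ACT])")[[motif_class]]
  s <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# feature table with a planted composite-cluster signal: the c2 indicator
# implies the unstable class with probability p_signal; modules are mildly
# informative; remaining features are noise
planted_feature_table <- function(n = 400, p_signal = 0.8, seed = 1,
                                  decoy = FALSE) {
  set.seed(seed)
  c2 <- rbinom(n, 1, 0.4)
  p_unstable <- ifelse(c2 == 1, p_signal, 1 - p_signal)
  lab <- factor(ifelse(runif(n) < p_unstable, "unstable", "stable"),
                levels = c("unstable", "stable"))
  module <- ifelse(runif(n) < ifelse(lab == "unstable", 0.6, 0.4),
                   sample(c("C", "D", "F"), n, replace = TRUE),
                   sample(c("A", "B", "E", "G"), n, replace = TRUE))
  tab <- data.frame(
    c1 = rbinom(n, 1, 0.25), c2 = c2, c3 = rbinom(n, 1, 0.25),
    c4 = rbinom(n, 1, 0.25),
    ci = rbinom(n, 1, 0.3), cii = rbinom(n, 1, 0.3),
    state = factor(sample(c("noAct", "Day1", "Day5"), n, replace = TRUE)),
    module = factor(module),
    rrach_freq = rnorm(n, 10, 2), are_freq = rnorm(n, 15, 3),
    label = lab)
  if (decoy) {
    # correlated with c2 but conditionally independent of the label
    flip <- rbinom(n, 1, 0.15)
    tab$decoy <- ifelse(flip == 1, 1 - c2, c2)
    tab <- tab[, c(setdiff(names(tab), "label"), "label")]
  }
  tab
}
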