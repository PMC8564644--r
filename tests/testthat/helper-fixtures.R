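# Shared fixtures and independent oracles, built in code at test time.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# A repertoire from a count vector, with auto-generated distinct sequences.
make_rep <- function(counts, aa = NULL, nt = NULL, productive = TRUE,
                     sample_id = "s1", patient_id = "p1",
                     timepoint = "baseline") {
  n <- length(counts)
  i <- seq_len(n)
  if (is.null(nt)) nt <- paste0("TGT", strrep("A", i), "TTC")
  if (is.null(aa)) {
    aa <- paste0("CASS", AA20[(i - 1) %% 20 + 1],
                 AA20[(i - 1) %/% 20 %% 20 + 1], "F")
  }
  repertoire(data.frame(nt_seq = nt, aa_seq = aa, count = counts,
                        productive = productive),
             sample_id = sample_id, patient_id = patient_id,
             timepoint = timepoint)
}

rand_nt <- function(n, min_len = 12, max_len = 36) {
  vapply(sample(min_len:max_len, n, replace = TRUE), function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

rand_aa <- function(n, min_len = 8, max_len = 18) {
  vapply(sample(min_len:max_len, n, replace = TRUE), function(l)
    paste(c("C", sample(AA20, l - 2, replace = TRUE), "F"), collapse = ""),
    character(1))
}

random_repertoire <- function(n = 20, ...) {
  nt <- unique(rand_nt(2 * n))[seq_len(n)]
  aa <- rand_aa(n)
  make_rep(counts = stats::rgeom(n, 0.05) + 1, aa = aa, nt = nt, ...)
}

# Independent brute-force Levenshtein oracle: full dynamic-programming table,
# no shortcuts, no shared code with the package's distance or neighbor search.
lev_dp <- function(a, b) {
  s <- strsplit(a, "")[[1]]
  t <- strsplit(b, "")[[1]]
  m <- length(s)
  n <- length(t)
  if (m == 0) return(n)
  if (n == 0) return(m)
  prev <- 0:n
  for (i in seq_len(m)) {
    cur <- c(i, integer(n))
    for (j in seq_len(n)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + as.integer(s[i] != t[j]))
    }
    prev <- cur
  }
  prev[n + 1]
}

# Independent Renyi oracle: literal evaluation of the defining formula.
renyi_oracle <- function(counts, alpha) {
  p <- counts[counts > 0] / sum(counts)
  if (alpha == 0) return(log(length(p)))
  if (alpha == 1) return(-sum(p * log(p)))
  if (is.infinite(alpha)) return(-log(max(p)))
  log(sum(p^alpha)) / (1 - alpha)
}
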