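# Independent brute-force oracles used by unit and acceptance tests.

# O(n^2) union-find over the "spaced < x_nt" graph; returns the positions
# that belong to any component of size >= 2
oracle_cluster_members <- function(pos, x_nt) {
  n <- length(pos)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && abs(pos[i] - pos[j]) < x_nt) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  sort(pos[roots %in% roots[duplicated(roots)]])
}

# exhaustive gap placement by string surgery, counting mismatches
# character by character
oracle_alignments <- function(anc, der) {
  n_a <- nchar(anc); n_d <- nchar(der)
  L <- abs(n_a - n_d)
  long <- if (n_a > n_d) anc else der
  short <- if (n_a > n_d) der else anc
  sols <- 0L
  offsets <- integer(0)
  for (g in 1:(nchar(long) - L + 1L)) {
    reduced <- paste0(substring(long, 1, g - 1L),
                      substring(long, g + L, nchar(long)))
    mm <- which(strsplit(reduced, "")[[1]] != strsplit(short, "")[[1]])
    if (length(mm) == 1L) {
      sols <- sols + 1L
      offsets <- c(offsets, if (mm >= g) mm - g + 1L else mm - g)
    }
  }
  list(n = sols, offsets = sort(offsets))
}
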