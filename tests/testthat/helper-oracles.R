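# Independent brute-force oracles used to cross-check the closed-form
# implementations. These deliberately use naive explicit loops.

# Index of association by exhaustive enumeration of all individual pairs.
brute_ia <- function(incidence, a, b) {
  x <- incidence[, a]; y <- incidence[, b]
  n <- length(x)
  da <- db <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    da <- c(da, as.numeric(x[i] != x[j]))
    db <- c(db, as.numeric(y[i] != y[j]))
  }
  N <- length(da)
  va <- mean(da^2) - mean(da)^2
  vb <- mean(db^2) - mean(db)^2
  cab <- mean(da * db) - mean(da) * mean(db)
  2 * cab / (va + vb)
}

# Nei-Gojobori codon difference counts by exhaustive recursive pathway
# enumeration (all orderings; stop-free pathways only, with all-path
# fallback), independent of the package's iterative walker.
brute_codon_diffs <- function(c1, c2) {
  code <- as.list(as.character(Biostrings::GENETIC_CODE))
  names(code) <- names(Biostrings::GENETIC_CODE)
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diff_pos) == 0) return(c(syn = 0, nonsyn = 0))
  results <- list()
  recurse <- function(cur, remaining, syn, nonsyn, through_stop) {
    if (length(remaining) == 0) {
      results[[length(results) + 1]] <<-
        list(syn = syn, nonsyn = nonsyn, ok = !through_stop)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      is_syn <- code[[cur]] == code[[nxt]] && code[[nxt]] != "*"
      recurse(nxt, setdiff(remaining, pos),
              syn + is_syn, nonsyn + !is_syn,
              through_stop || code[[nxt]] == "*")
    }
  }
  recurse(c1, diff_pos, 0, 0, FALSE)
  ok <- Filter(function(r) r$ok, results)
  if (length(ok) == 0) ok <- results
  c(syn = mean(sapply(ok, `[[`, "syn")),
    nonsyn = mean(sapply(ok, `[[`, "nonsyn")))
}

# Proportion of differing positions, averaged over all sequence pairs,
# computed position by position (oracle for nucleotide diversity).
brute_pi <- function(seqs) {
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(chars[[i]] != chars[[j]])
    np <- np + 1
  }
  tot / np
}

# Do two cluster label vectors describe the same partition?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# Tiny fixed catalog used across data-model tests.
toy_catalog <- function() {
  allele_catalog(c(a1 = "AAATTT", a2 = "AAATTC", a3 = "AATTTC"))
}

toy_dataset <- function() {
  mhc_dataset(
    toy_catalog(),
    data.frame(
      individual = c("i1", "i1", "i2", "i2", "i3", "i3", "i4", "i4"),
      site = c("X", "X", "X", "X", "Y", "Y", "Y", "Y"),
      allele = c("a1", "a2", "a1", "a3", "a2", "a3", "a1", "a2")))
}
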