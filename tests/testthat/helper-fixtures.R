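# Shared fixtures and small independent oracles used across test files.

table2 <- function() read.csv(herbqc_example("table2.csv"))

table2_design <- function() {
  d <- table2()
  attr(d, "factors") <- extraction_factors()
  d
}

table3 <- function() {
  read.csv(herbqc_example("table3.csv"), stringsAsFactors = FALSE,
           colClasses = c(calc_mz_printed = "character"))
}

table4 <- function() {
  read.csv(herbqc_example("table4.csv"), stringsAsFactors = FALSE,
           colClasses = c(calc_mz_printed = "character"))
}

# decimal places of a printed numeric string
printed_decimals <- function(s) {
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}

# small parent panel used where full plasma panel would be overkill
toy_parents <- function() {
  list("apigenin" = "C15H10O5",
       "formononetin" = "C16H12O4",
       "calycosin-7-O-beta-d-glucoside" = "C22H22O10")
}

# independent enumeration oracle for the annotator: loops over all
# ordered modification sequences (deduplicated to multisets) and adducts,
# computing masses with its own atomic-mass table
oracle_annotate <- function(mz, mode, parents, tol_ppm = 10,
                            max_depth = 3) {
  am <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
          S = 31.97207117, Cl = 34.96885268)
  counts <- function(s) {
    parts <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
    el <- sub("[0-9]*$", "", parts)
    n <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", parts)))
    n[is.na(n)] <- 1L
    v <- setNames(rep(0L, length(am)), names(am))
    for (i in seq_along(el)) v[el[i]] <- v[el[i]] + n[i]
    v
  }
  deltas <- list(
    glucuronidation = c(C = 6, H = 8, O = 6),
    sulfation = c(S = 1, O = 3),
    demethylation = c(C = -1, H = -2),
    hydroxylation = c(O = 1),
    hydrogenation = c(H = 2),
    deglycosylation = c(C = -6, H = -10, O = -5))
  offs <- if (mode == "+") c("[M+H]+" = 1.0072765) else
    c("[M-H]-" = -1.0072765,
      "[M+FA-H]-" = 46.0054793 - 1.0072765,
      "[M+Cl]-" = 34.96885268 + 0.0005486)
  hits <- character(0)
  seqs <- list(character(0))
  for (d in seq_len(max_depth)) {
    new <- list()
    for (s in seqs[lengths(seqs) == d - 1])
      for (r in names(deltas)) new[[length(new) + 1L]] <- c(s, r)
    seqs <- c(seqs, new)
  }
  for (p in names(parents)) {
    base <- counts(parents[[p]])
    for (s in seqs) {
      v <- base
      for (r in s) {
        dl <- deltas[[r]]
        v[names(dl)] <- v[names(dl)] + dl
      }
      if (any(v < 0)) next
      m <- sum(am * v)
      for (a in names(offs)) {
        ppm <- (mz - (m + offs[[a]])) / (m + offs[[a]]) * 1e6
        if (abs(ppm) <= tol_ppm)
          hits <- c(hits, paste(p, paste(sort(s), collapse = "+"), a))
      }
    }
  }
  sort(unique(hits))
}
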