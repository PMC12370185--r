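# Fixtures are generated in code; no data files. Sequences come from a
# seeded generator so every test is reproducible.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_nps <- function(id = "nps", seed = 1) {
  set.seed(seed)
  nps_record(id, rand_seq(191))
}

# a scrubbed backbone free of the whole demo panel
clean_nps <- function(id = "nps", seed = 1) {
  set.seed(seed)
  synthetic_nps(id)
}

# inject k substitutions into a sequence at distinct positions
inject_subs <- function(seq, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (k == 0) return(seq)
  pos <- sample.int(nchar(seq), k)
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  seq
}

# inject k substitutions at distinct positions within [lo, hi]
inject_subs_in_range <- function(seq, k, lo, hi) {
  pos <- sample(lo:hi, k)
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  seq
}

# brute-force motif scan: slide the site (and its reverse complement) over
# every position; independent of the package scanner
brute_scan <- function(seq, site) {
  L <- nchar(site)
  n <- nchar(seq)
  out <- list()
  if (L <= n) {
    starts <- 1:(n - L + 1)
    winds <- substring(seq, starts, starts + L - 1)
    for (target in c(site, revcomp(site))) {
      strand <- if (target == site) "+" else "-"
      hit <- starts[winds == target]
      if (length(hit)) {
        out[[strand]] <- data.frame(start = hit, strand = strand)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), strand = character(0)))
  }
  d <- do.call(rbind, out)
  # a palindromic site matches both strands at the same start
  d[order(d$start, d$strand), , drop = FALSE]
}
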