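# Independent oracles and tiny fixture builders, written in plain base R so
# they share no code path with the package internals they check.

# The five published 21-bp Zur operator sites (C. glutamicum).
published_sites <- function() {
  c("TAATGATAACGGTTATCATTT", "AAATGATAACCGTTATCATTA",
    "TATTGAAAATGATTCCCAAAA", "TAATGGAAATTGTTTTCAATA",
    "TGTTGACATCCTTTTTCAATA")
}

# base-R reverse complement, independent of Biostrings
rc_chr <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

# brute-force PWM: symmetrised counts -> centred log-count weights
brute_weights <- function(sites, palindromic = TRUE, pc = 0.5) {
  all <- if (palindromic) c(sites, rc_chr(sites)) else sites
  W <- nchar(sites[1])
  N <- matrix(0, 4, W, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (s in all) {
    v <- strsplit(s, "")[[1]]
    for (k in seq_len(W)) N[v[k], k] <- N[v[k], k] + 1
  }
  wts <- log(N + pc)
  sweep(wts, 2, colMeans(wts))
}

# brute-force Z-score of one W-mer (sum of positional weights; palindromic
# models average the two readings)
brute_score <- function(wts, s, palindromic = TRUE) {
  one <- function(x) {
    v <- strsplit(x, "")[[1]]
    if (any(!v %in% rownames(wts))) return(-Inf)
    sum(vapply(seq_along(v), function(k) wts[v[k], k], 0.0))
  }
  if (palindromic) (one(s) + one(rc_chr(s))) / 2 else one(s)
}

# brute-force scan: enumerate every window on both strands via substring
brute_scan <- function(wts, seq, threshold, palindromic = TRUE) {
  W <- ncol(wts)
  n <- nchar(seq) - W + 1
  hits <- list()
  for (p in seq_len(n)) {
    win <- substr(seq, p, p + W - 1)
    zf <- brute_score(wts, win, palindromic)
    if (zf >= threshold) {
      hits[[length(hits) + 1]] <- data.frame(position = p - 1, strand = "+", z = zf)
    }
    if (!palindromic) {
      zr <- brute_score(wts, rc_chr(win), palindromic)
      if (zr >= threshold) {
        hits[[length(hits) + 1]] <- data.frame(position = p - 1, strand = "-", z = zr)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(), strand = character(), z = double()))
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# small linear genome with explicit genes
toy_genome <- function(sequence, genes, genome_id = "toy", circular = FALSE) {
  new_genome(genome_id, sequence, genes, circular = circular)
}
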