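# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the package's own code paths.

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
}

count_occurrences <- function(pattern, text) {
  hits <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (hits[1] == -1) 0L else length(hits)
}

# exhaustive maximal-unique-match enumeration (forward strand)
oracle_mums <- function(ref, qry, minlen) {
  n <- nchar(ref); m <- nchar(qry)
  rc <- strsplit(ref, "")[[1]]; qc <- strsplit(qry, "")[[1]]
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # left-maximal start?
      if (i > 1 && j > 1 && rc[i - 1] == qc[j - 1] && rc[i - 1] != "N") next
      len <- 0
      while (i + len <= n && j + len <= m && rc[i + len] == qc[j + len] &&
             rc[i + len] != "N") len <- len + 1
      if (len < minlen) next
      sub <- substr(ref, i, i + len - 1)
      if (count_occurrences(sub, ref) == 1 && count_occurrences(sub, qry) == 1)
        out[[length(out) + 1]] <- c(ref_start = i - 1, qry_start = j - 1,
                                    length = len)
    }
  }
  if (!length(out)) return(data.frame(ref_start = integer(0),
                                      qry_start = integer(0),
                                      length = integer(0)))
  df <- unique(as.data.frame(do.call(rbind, out)))
  df[order(df$ref_start), , drop = FALSE]
}

# brute-force repeat coverage: positions inside any off-diagonal exact
# self-match of length >= minlen (forward or reverse complement)
oracle_repeat_mask <- function(seq, minlen) {
  n <- nchar(seq)
  masked <- logical(n)
  rc <- revcomp_chr(seq)
  for (i in seq_len(n - minlen + 1)) {
    w <- substr(seq, i, i + minlen - 1)
    if (grepl("N", w, fixed = TRUE)) next
    nf <- count_occurrences(w, seq)
    nr <- count_occurrences(w, rc)
    if (nf + nr >= 2) masked[i:(i + minlen - 1)] <- TRUE
  }
  masked
}

# independent Nei-Gojobori implementation: explicit site counting and
# recursive pathway enumeration
oracle_ng86 <- function(a, b, code) {
  translate1 <- function(codon) unname(code[codon])
  syn_sites <- function(codon) {
    aa <- translate1(codon)
    s <- 0
    for (p in 1:3) for (nb in setdiff(c("A", "C", "G", "T"),
                                      substr(codon, p, p))) {
      mut <- codon; substr(mut, p, p) <- nb
      if (translate1(mut) == aa) s <- s + 1 / 3
    }
    s
  }
  paths <- function(x, y) {
    dp <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (!length(dp)) return(list(sd = 0, nd = 0, k = 1))
    tot_s <- 0; tot_n <- 0; k <- 0
    recur <- function(cur, remaining, s, nmis) {
      if (!length(remaining)) {
        tot_s <<- tot_s + s; tot_n <<- tot_n + nmis; k <<- k + 1
        return(invisible())
      }
      for (p in remaining) {
        nxt <- cur; substr(nxt, p, p) <- substr(y, p, p)
        syn <- translate1(cur) == translate1(nxt)
        recur(nxt, setdiff(remaining, p), s + syn, nmis + !syn)
      }
    }
    recur(x, dp, 0, 0)
    list(sd = tot_s / k, nd = tot_n / k, k = k)
  }
  nc <- nchar(a) %/% 3
  ca <- substring(a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cb <- substring(b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  S <- (sum(vapply(ca, syn_sites, 0)) + sum(vapply(cb, syn_sites, 0))) / 2
  N <- 3 * nc - S
  Sd <- 0; Nd <- 0
  for (i in seq_len(nc)) {
    pr <- paths(ca[i], cb[i])
    Sd <- Sd + pr$sd; Nd <- Nd + pr$nd
  }
  jc <- function(p) if (!is.finite(p) || p >= 0.75) NA_real_
                    else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       dS = jc(Sd / S), dN = jc(Nd / N))
}

# one small clade shared by several test files
sim_small_clade <- function(seed = 7, L = 30000, n = 5, bl = 0.005, ...) {
  corephylo::simulateClade(corephylo::simConfig(
    nTaxa = n, genomeLength = L, branchLength = bl, seed = seed, ...))
}
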