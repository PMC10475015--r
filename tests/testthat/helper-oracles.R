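# Independent oracles used to cross-check the compiled implementations.

# brute-force K-string interval histogram by direct enumeration
grm_brute <- function(seq, K, max_length = Inf) {
  n <- nchar(seq)
  empty <- data.frame(length = numeric(0), count = numeric(0))
  if (n < K) return(empty)
  wins <- substring(seq, 1:(n - K + 1), K:n)
  valid <- !grepl("[^ACGT]", wins)
  pos <- which(valid)
  if (!length(pos)) return(empty)
  tab <- split(pos, wins[valid])
  d <- unlist(lapply(tab, diff), use.names = FALSE)
  d <- d[d <= max_length]
  if (!length(d)) return(empty)
  t <- table(d)
  data.frame(length = as.numeric(names(t)), count = as.numeric(t))
}

# quadratic-DP semi-global end-distance profile (N never matches)
brute_end_dists <- function(text, pat) {
  tb <- strsplit(text, "")[[1]]
  pb <- strsplit(pat, "")[[1]]
  m <- length(pb)
  n <- length(tb)
  prev <- 0:m
  out <- integer(n)
  for (j in 1:n) {
    cur <- integer(m + 1)
    for (i in 1:m) {
      cost <- if (tb[j] != "N" && pb[i] != "N" && tb[j] == pb[i]) 0L else 1L
      cur[i + 1] <- min(prev[i] + cost, prev[i + 1] + 1L, cur[i] + 1L)
    }
    out[j] <- cur[m + 1]
    prev <- cur
  }
  out
}

# random unit whose cyclic k-mers are all distinct (clean tandem period)
distinct_cyclic_unit <- function(len = 50, k = 10) {
  repeat {
    u <- random_dna(len)
    kk <- substring(paste0(u, u), 1:len, k:(len + k - 1))
    if (!anyDuplicated(kk)) return(u)
  }
}

plant_at <- function(bg, insert, at) {
  paste0(substr(bg, 1, at), insert, substr(bg, at + 1, nchar(bg)))
}
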