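# Independent brute-force enumerators used as oracles for the frame engine,
# written as direct set enumeration + filtering (no shared code with R/).

label_set <- function(strategies) {
  if (nrow(strategies) == 0L) return(character(0))
  sort(paste(strategies$label, strategies$category))
}

oracle_deletion_skips <- function(t, f, l) {
  n <- nrow(t)
  len <- t$coding_length
  pool <- c(f - 2L, f - 1L, l + 1L, l + 2L)
  sets <- c(as.list(pool), utils::combn(pool, 2L, simplify = FALSE))
  out <- character(0)
  for (T in sets) {
    T <- sort(unique(T))
    if (any(T < 2L | T > n - 1L)) next
    excl <- sort(unique(c(f:l, T)))
    if (!identical(excl, seq(min(excl), max(excl)))) next  # contiguous run
    if (sum(len[excl]) %% 3L != 0L) next
    lab <- paste(paste(T, collapse = " & "),
                 if (length(T) == 1L) "single" else "double")
    out <- c(out, lab)
  }
  sort(unique(out))
}

oracle_small_lesion_skips <- function(t, e, site,
                                      convention = "own_exon") {
  n <- nrow(t)
  len <- t$coding_length
  if (site == "intra") {
    if (len[e] %% 3L == 0L) {
      if (e >= 2L && e <= n - 1L) return(paste(e, "single"))
      return(character(0))
    }
    out <- character(0)
    for (p in list(c(e - 1L, e), c(e, e + 1L)))
      if (all(p >= 2L & p <= n - 1L) && sum(len[p]) %% 3L == 0L)
        out <- c(out, paste(paste(p, collapse = " & "), "double"))
    return(sort(out))
  }
  lost <- if (convention == "own_exon") e
          else if (site == "donor") e + 1L else e - 1L
  if (lost < 1L || lost > n) return(character(0))
  if (len[lost] %% 3L == 0L) return("(none) none")
  oracle_deletion_skips(t, lost, lost)
}

oracle_duplication_skips <- function(t, f, l) {
  n <- nrow(t)
  len <- t$coding_length
  seg <- sum(len[f:l])
  sets <- as.list(f:l)
  if (l > f) sets <- c(sets, lapply(f:(l - 1L), function(e) c(e, e + 1L)))
  out <- character(0)
  for (S in sets) {
    if (any(S < 2L | S > n - 1L)) next
    if ((seg - sum(len[S])) %% 3L != 0L) next
    out <- c(out, paste(paste(S, collapse = " & "),
                        if (length(S) == 1L) "single" else "double"))
  }
  if (f == l)
    for (g in c(f - 1L, f + 1L))
      if (g >= 2L && g <= n - 1L && (len[f] + len[g]) %% 3L == 0L)
        out <- c(out, paste(g, "single"))
  sort(unique(out))
}

random_transcript <- function(n_exons = sample(5:15, 1L),
                              max_len = 300L) {
  transcript_model(sample.int(max_len, n_exons, replace = TRUE))
}

# a tiny hand-built transcript used across unit tests
toy_transcript <- function() transcript_model(c(10L, 21L, 14L, 30L, 16L, 9L))
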