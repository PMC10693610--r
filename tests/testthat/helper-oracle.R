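# Independent brute-force NG86 implementation used only as an oracle.
# Deliberately written as plain string manipulation with explicit pathway
# recursion, sharing no code with the package's table-driven engine.

.bf_code <- Biostrings::GENETIC_CODE

bf_translate <- function(codon) .bf_code[[codon]]

bf_is_stop <- function(codon) identical(bf_translate(codon), "*")

# fractional site counts of one codon
bf_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == nt) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (!bf_is_stop(mut) && bf_translate(mut) == bf_translate(codon)) {
        s <- s + 1 / 3
      }
    }
  }
  c(n = 3 - s, s = s)
}

# all orderings of a vector
bf_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in bf_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# pathway-averaged (nd, sd) between two non-stop codons
bf_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0L) return(c(nd = 0, sd = 0))
  nds <- c(); sds <- c(); valid <- c()
  for (ord in bf_perms(pos)) {
    cur <- a; nd <- 0; sd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (bf_is_stop(nxt) && nxt != b) ok <- FALSE
      if (!bf_is_stop(cur) && !bf_is_stop(nxt) &&
          bf_translate(cur) == bf_translate(nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    nds <- c(nds, nd); sds <- c(sds, sd); valid <- c(valid, ok)
  }
  if (!any(valid)) valid <- rep(TRUE, length(valid))
  c(nd = mean(nds[valid]), sd = mean(sds[valid]))
}

bf_jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)

# full NG86 Ka/Ks for an aligned pair of codon strings
bf_kaks <- function(sa, sb) {
  ca <- substring(sa, seq(1, nchar(sa), 3), seq(3, nchar(sa), 3))
  cb <- substring(sb, seq(1, nchar(sb), 3), seq(3, nchar(sb), 3))
  N <- 0; S <- 0; Nd <- 0; Sd <- 0; used <- 0L
  for (i in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    if (bf_is_stop(ca[i]) || bf_is_stop(cb[i])) next
    used <- used + 1L
    sa_i <- bf_sites(ca[i]); sb_i <- bf_sites(cb[i])
    N <- N + (sa_i["n"] + sb_i["n"]) / 2
    S <- S + (sa_i["s"] + sb_i["s"]) / 2
    d <- bf_diffs(ca[i], cb[i])
    Nd <- Nd + d["nd"]; Sd <- Sd + d["sd"]
  }
  list(n_sites = unname(N), s_sites = unname(S), nd = unname(Nd),
       sd = unname(Sd), used = used,
       ka = bf_jc(unname(Nd / N)), ks = bf_jc(unname(Sd / S)))
}

# random in-frame codon-string pair (may contain stops; both implementations
# must skip them identically)
random_codon_pair <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  a <- paste(sample(bases, 3 * n_codons, replace = TRUE), collapse = "")
  b <- strsplit(a, "")[[1]]
  nmut <- rpois(1, 0.25 * length(b))
  if (nmut > 0) {
    pos <- sample(length(b), min(nmut, length(b)))
    b[pos] <- sample(bases, length(pos), replace = TRUE)
  }
  c(a, paste(b, collapse = ""))
}
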