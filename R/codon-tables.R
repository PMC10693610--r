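# Internal codon lookup tables for the NG86 engine and the codon simulator.
# Built once per session from the standard genetic code and cached.

.allopolykit_cache <- new.env(parent = emptyenv())

.codonTables <- function() {
  tab <- .allopolykit_cache$codon_tables
  if (!is.null(tab)) return(tab)

  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  is_stop <- aa == "*"
  bases <- c("A", "C", "G", "T")
  idx <- seq_along(codons)
  names(idx) <- codons

  # neighbor[c, p, a]: codon reached from codon c by replacing position p
  # with the a-th alternative base (alphabetical order, current base excluded)
  neighbor <- array(0L, dim = c(64L, 3L, 3L))
  syn <- array(FALSE, dim = c(64L, 3L, 3L))      # synonymous, non-stop change
  to_stop <- array(FALSE, dim = c(64L, 3L, 3L))  # change creates a stop codon
  split_codons <- strsplit(codons, "", fixed = TRUE)
  for (ci in idx) {
    nts <- split_codons[[ci]]
    for (p in 1:3) {
      alts <- bases[bases != nts[p]]
      for (a in 1:3) {
        mut <- nts
        mut[p] <- alts[a]
        mi <- idx[[paste(mut, collapse = "")]]
        neighbor[ci, p, a] <- mi
        to_stop[ci, p, a] <- is_stop[mi]
        syn[ci, p, a] <- !is_stop[ci] && !is_stop[mi] && aa[mi] == aa[ci]
      }
    }
  }

  # NG86 fractional site counts: a codon's synonymous sites are one third of
  # its synonymous single-nucleotide neighbors; mutations to stop codons count
  # as nonsynonymous. Stop codons themselves are never counted.
  s_sites <- apply(syn, 1L, sum) / 3
  s_sites[is_stop] <- NA_real_
  n_sites <- 3 - s_sites

  # Pathway-averaged difference counts for every ordered codon pair.
  nd_mat <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
  sd_mat <- nd_mat
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  for (i in idx) {
    if (is_stop[i]) next
    for (j in idx) {
      if (is_stop[j]) next
      diffs <- which(split_codons[[i]] != split_codons[[j]])
      k <- length(diffs)
      if (k == 0L) {
        nd_mat[i, j] <- 0
        sd_mat[i, j] <- 0
        next
      }
      path_nd <- numeric(0)
      path_sd <- numeric(0)
      ok <- logical(0)
      for (ord in perms[[k]]) {
        cur <- split_codons[[i]]
        nd <- 0
        sd <- 0
        valid <- TRUE
        for (step in diffs[ord]) {
          nxt <- cur
          nxt[step] <- split_codons[[j]][step]
          from <- idx[[paste(cur, collapse = "")]]
          to <- idx[[paste(nxt, collapse = "")]]
          # pathways through intermediate stop codons are discarded
          if (is_stop[to] && to != j) valid <- FALSE
          if (!is_stop[from] && !is_stop[to] && aa[from] == aa[to]) {
            sd <- sd + 1
          } else {
            nd <- nd + 1
          }
          cur <- nxt
        }
        path_nd <- c(path_nd, nd)
        path_sd <- c(path_sd, sd)
        ok <- c(ok, valid)
      }
      if (!any(ok)) ok <- rep(TRUE, length(ok))  # all pathways blocked: keep all
      nd_mat[i, j] <- mean(path_nd[ok])
      sd_mat[i, j] <- mean(path_sd[ok])
    }
  }

  tab <- list(
    codons = codons, aa = aa, is_stop = is_stop, index = idx,
    neighbor = neighbor, syn = syn, to_stop = to_stop,
    # flattened copies for the simulator's event loop
    neighbor_flat = as.integer(neighbor),
    syn_flat = as.logical(syn),
    to_stop_flat = as.logical(to_stop),
    s_sites = s_sites, n_sites = n_sites,
    nd = nd_mat, sd = sd_mat
  )
  assign("codon_tables", tab, envir = .allopolykit_cache)
  tab
}

# Jukes-Cantor multiple-hit correction; NA (saturated) for p >= 3/4.
.jcCorrect <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

# Split an uppercase nucleotide string into codon triplets.
.toCodons <- function(x) {
  x <- toupper(as.character(x))
  if (nchar(x) %% 3L != 0L) {
    stop("sequence length ", nchar(x), " is not a multiple of 3")
  }
  substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
}

.validNucleotides <- function(x) {
  !grepl("[^ACGTN-]", x)
}
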