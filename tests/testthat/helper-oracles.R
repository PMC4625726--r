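# Independent oracles and fixture builders shared across the test files.
# Each oracle is a deliberately naive re-implementation (loops, enumeration)
# kept free of the package's own code paths.

# --- circular extraction by explicit rotation -------------------------------
oracle_extract <- function(sequence, start, end, strand = "H") {
  chars <- strsplit(sequence, "")[[1L]]
  L <- length(chars)
  out <- character(0)
  p <- start
  while (p <= end) {
    out <- c(out, chars[((p - 1L) %% L) + 1L])
    p <- p + 1L
  }
  s <- paste(out, collapse = "")
  if (strand == "L") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    s <- paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
  }
  s
}

# --- Spearman p-value by full permutation enumeration -----------------------
oracle_spearman <- function(x, y) {
  rho <- function(a, b) stats::cor(rank(a), rank(b))
  obs <- rho(x, y)
  perms <- combinat_permutations(length(y))
  stats <- apply(perms, 1L, function(idx) rho(x, y[idx]))
  list(rho = obs, p_value = mean(abs(stats) >= abs(obs) - 1e-12))
}

combinat_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- combinat_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# --- brute-force re-statement of the variant criteria -----------------------
# Accepts a parsed pileup; returns a data.frame of accepted (position, alt).
oracle_calls <- function(pileup, params) {
  obs <- pileup$obs
  gated <- obs[obs$base %in% c("A", "C", "G", "T") &
                 obs$qual >= params$min_base_quality &
                 (is.na(obs$mapq) | obs$mapq >= params$min_mapping_quality), ]
  acc <- list()
  for (p in sort(unique(gated$pos))) {
    col <- gated[gated$pos == p, ]
    ref <- col$ref[1L]
    if (nrow(col) < params$min_coverage) next                    # coverage
    altbases <- unique(col$base[col$base != ref])
    if (length(altbases) == 0L) next
    counts <- vapply(altbases, function(b) sum(col$base == b), integer(1))
    presence <- min(2L, max(1L, params$min_alt_reads))
    if (sum(counts >= presence) >= 2L) next                      # one alt only
    alt <- altbases[which.max(counts)]
    clean <- integer(0)
    for (k in which(col$base == alt)) {
      d5 <- col$dist5[k]; d3 <- col$dist3[k]
      if (!is.na(d5) && !is.na(d3) &&
          min(d5, d3) < params$min_read_end_distance) next       # read ends
      rid <- col$read_id[k]
      w <- params$neighborhood_window
      flank <- obs[obs$read_id == rid & obs$pos != p &
                     abs(obs$pos - p) <= w, ]
      if (nrow(flank) && any(flank$base != flank$ref)) next      # clean flanks
      clean <- c(clean, k)
    }
    if (length(clean) < params$min_alt_reads) next               # >= 2 reads
    st <- col$strand[clean]
    if (params$require_both_strands &&
        !(any(st == "+", na.rm = TRUE) && any(st == "-", na.rm = TRUE)))
      next                                                       # both strands
    acc[[length(acc) + 1L]] <- data.frame(position = p, alt = alt,
                                          stringsAsFactors = FALSE)
  }
  if (length(acc)) do.call(rbind, acc) else
    data.frame(position = integer(), alt = character())
}

# --- builders for hand-made pileup columns ---------------------------------
# n_ref reference observations split between strands, plus alt observations
# described by a data frame (base, strand, qual, dist5, dist3).
make_column <- function(pos, ref, n_ref, alts = NULL, qual_ref = 40L,
                        dist5 = 20L, dist3 = 20L) {
  n_fwd <- ceiling(n_ref / 2); n_rev <- n_ref - n_fwd
  obs <- data.frame(
    pos = pos, ref = ref,
    read_id = paste0("ref", seq_len(n_ref)),
    base = ref, strand = c(rep("+", n_fwd), rep("-", n_rev)),
    qual = qual_ref, mapq = 60L, dist5 = dist5, dist3 = dist3,
    stringsAsFactors = FALSE)
  if (!is.null(alts) && nrow(alts)) {
    alts$pos <- pos; alts$ref <- ref
    alts$read_id <- paste0("alt", seq_len(nrow(alts)))
    if (is.null(alts$qual)) alts$qual <- 40L
    if (is.null(alts$mapq)) alts$mapq <- 60L
    if (is.null(alts$dist5)) alts$dist5 <- 20L
    if (is.null(alts$dist3)) alts$dist3 <- 20L
    obs <- rbind(obs, alts[names(obs)])
  }
  obs
}

# A toy synthetic genome reused across tests (fixed seed).
toy_genome <- function(seed = 11L, genome_length = 1200L, cr_dup = 20L) {
  generate_genome(genome_spec(layout = toy_layout(genome_length),
                              genome_length = genome_length,
                              cr_dup_length = cr_dup, seed = seed))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
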