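# Shared fixture builders. Everything is generated in code; nothing binary.

write_fixture_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# small raw-intensity expression table fixture
toy_expression_file <- function() {
  write_fixture_tsv(c(
    "gene_id\ts1\ts2",
    "g1\t64\t128",
    "g2\t16\t32",
    "g3\t256\t1024"
  ))
}

toy_matrix <- function(nr = 3, nc = 4, seed = 1, prefix = "g") {
  set.seed(seed)
  m <- matrix(2^stats::rnorm(nr * nc, mean = 8), nr, nc,
              dimnames = list(sprintf("%s%d", prefix, seq_len(nr)),
                              sprintf("s%d", seq_len(nc))))
  m
}

# paired log2 dataset straight from the generator, small dims
toy_paired <- function(p = 6, m = 8, n_edges = 2, seed = 1, rho = 0.6,
                       shift = TRUE, noise_sd = 0.25) {
  truth <- synthetic_ground_truth(
    p_mirna = p, m_mrna = m, n_edges = n_edges, rho = rho,
    mirna_shift = if (shift) -1 else 0, mrna_shift = if (shift) 1 else 0,
    noise_sd = noise_sd, seed = seed)
  generate_paired_dataset(truth = truth)
}

# brute-force BH step-up oracle, written independently of the implementation:
# for each i, q_i = min over j with p_(j) >= p_i of p_(j) * M / rank_j
bh_oracle <- function(p) {
  M <- length(p)
  ord <- order(p)
  ranks <- integer(M)
  ranks[ord] <- seq_len(M)
  vapply(seq_len(M), function(i) {
    candidates <- vapply(seq_len(M), function(j) {
      if (ranks[j] >= ranks[i]) min(1, p[j] * M / ranks[j]) else Inf
    }, numeric(1))
    min(candidates)
  }, numeric(1))
}

# all 9 derangements of 1..4, by enumeration
derangements4 <- function() {
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  perms <- perms[apply(perms, 1, function(r) all(r != 1:4)), ]
  apply(perms, 1, paste, collapse = "")
}
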