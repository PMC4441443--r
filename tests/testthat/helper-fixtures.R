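# Fixture builders and independent brute-force oracles. The oracles work
# directly on flattened residues and never touch bin_counts/energy code, so
# they stay an independent check of the aggregated path.

make_chain <- function(id, temperature, aa, alpha,
                       max_asa = default_max_asa()) {
  chain_record(id, "A", temperature,
               data.frame(aa = aa, mean_area = alpha * unname(max_asa[aa]),
                          exposure = alpha, stringsAsFactors = FALSE))
}

# exposure identical across residue types: every type carries the same
# multiset of alpha values, so all type-vs-background contrasts are null
make_null_chains <- function(temps = c(278, 293, 298, 302, 320),
                             alphas = c(0.03, 0.2, 0.5, 0.9)) {
  lapply(seq_along(temps), function(i) {
    make_chain(sprintf("NUL%02d", i), temps[i],
               rep(amino_acids(), each = length(alphas)),
               rep(alphas, times = 20))
  })
}

# brute-force per-residue recount of all four estimators
oracle_energy <- function(chains, entity, method, q = 4, cutoff = 0.07,
                          max_asa = default_max_asa()) {
  aa <- unlist(lapply(chains, function(ch) ch$residues$aa))
  al <- unlist(lapply(chains, function(ch) ch$residues$exposure))
  pool <- aa %in% entity_types(entity)
  N <- length(aa)
  switch(method,
    contact = {
      caw <- sum(q * al[pool])
      W <- sum(q * al)
      omega <- sum(pool) * q * W / (q * N + W)
      -log(caw / omega)
    },
    surface = {
      b <- al < cutoff
      log((sum(b & pool) / sum(!b & pool)) / (sum(b) / sum(!b)))
    },
    area = -log((N / sum(pool)) * sum(al[pool]) / sum(al)),
    scaled_area = {
      ca <- -log((N / sum(pool)) * sum(al[pool]) / sum(al))
      ca * mean(unname(max_asa[aa[pool]]))
    }
  )
}

oracle_corrected <- function(chains, entity, method, ...) {
  oracle_energy(chains, entity, method, ...) -
    oracle_energy(chains, "reference", method, ...)
}

# a small heterogeneous chain set with a fixed seed
make_test_chains <- function(n = 10, seed = 7, len = 40, temps = NULL) {
  set.seed(seed)
  if (is.null(temps)) temps <- runif(n, 270, 330)
  lapply(seq_len(n), function(i) {
    aa <- sample(amino_acids(), len, replace = TRUE)
    make_chain(sprintf("TST%02d", i), temps[i], aa,
               round(runif(len), 3))
  })
}

# swap buried/non-buried labels in a bin_counts object
swap_burial <- function(bc) {
  sw <- bc
  sw$buried <- bc$n - bc$buried
  sw$N_b <- bc$N - bc$N_b
  sw$N_nb <- bc$N - bc$N_nb
  sw
}
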