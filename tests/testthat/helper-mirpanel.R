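# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# Small Ct matrix with explicit values; rows named A, B, C, ... and samples s1..sn.
toy_ct <- function(values, n_probes, n_samples) {
  m <- matrix(values, n_probes, n_samples, byrow = TRUE)
  dimnames(m) <- list(LETTERS[seq_len(n_probes)],
                      paste0("s", seq_len(n_samples)))
  m
}

toy_ann <- function(sample_ids, groups) {
  data.frame(sample_id = sample_ids, group = groups, stringsAsFactors = FALSE)
}

# Balanced annotation with case_* / control_* ids (the generator's layout).
balanced_ann <- function(n_case, n_control) {
  toy_ann(c(sprintf("case_%02d", seq_len(n_case)),
            sprintf("control_%02d", seq_len(n_control))),
          c(rep("case", n_case), rep("control", n_control)))
}

# Named feature vector with case/control means mu1/mu0 and unit-ish sd.
toy_feature <- function(ann, mu_case, mu_control, sd = 1, seed = 1) {
  set.seed(seed)
  x <- ifelse(ann$group == "case", rnorm(nrow(ann), mu_case, sd),
              rnorm(nrow(ann), mu_control, sd))
  stats::setNames(x, ann$sample_id)
}

# Generator config for experiments where the planted controls must be
# identifiable by IQR ranking: loading shifts must not dominate probe noise
# (see the methods vignette for the identifiability analysis).
recovery_config <- function(...) {
  sim_config(sample_shift_sd = 0.05, control_var = 1e-3, ...)
}

# Random collection of n_tables prediction tables over a small universe,
# for consensus-vote tests.
toy_prediction_tables <- function(n_tables = 12, n_pairs = 50, seed = 1,
                                  n_mirna = 6, n_tx = 25) {
  set.seed(seed)
  universe <- expand.grid(
    mirna_id = paste0("miR-", seq_len(n_mirna)),
    transcript_id = paste0("TX", seq_len(n_tx)),
    stringsAsFactors = FALSE
  )
  tabs <- lapply(seq_len(n_tables), function(i) {
    universe[sample(nrow(universe), n_pairs), , drop = FALSE]
  })
  names(tabs) <- paste0("db", seq_len(n_tables))
  tabs
}

# Brute-force vote count: for each pair in the union, count the tables
# containing it by direct membership tests.
brute_force_votes <- function(tables) {
  keys <- lapply(tables, function(tab) {
    unique(paste(tab$mirna_id, tab$transcript_id, sep = "\r"))
  })
  all_keys <- sort(unique(unlist(keys)))
  votes <- vapply(all_keys, function(k) {
    sum(vapply(keys, function(tk) k %in% tk, logical(1)))
  }, integer(1))
  data.frame(key = all_keys, votes = as.integer(votes),
             stringsAsFactors = FALSE)
}

# Brute-force BH step-up straight from the definition.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Pairwise-enumeration AUC: loop over all case-control pairs.
enumerate_auc <- function(scores, y) {
  cs <- scores[y == 1]; ct <- scores[y == 0]
  total <- 0
  for (a in cs) for (b in ct) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(cs) * length(ct))
}
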