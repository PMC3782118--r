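# -- tiny hand-built datasets -------------------------------------------------

tiny_dataset <- function() {
  ddi_dataset(
    drugs = data.frame(
      drug_id = c("SYN00001", "SYN00002", "SYN00003"),
      name = c("Alphaxine", "Betazole", "Gammadol"),
      indication = c("For the treatment of schizophrenia.",
                     "For hypertension.",
                     "For seasonal allergies.")),
    interactions = data.frame(
      drug_id = c("SYN00001", "SYN00002"),
      partner_id = c("SYN00002", "SYN00001"),
      description = c("Increased sedation.", "Increased sedation.")),
    atc_codes = list(SYN00001 = c("N05AH02", "A02BC01"),
                     SYN00002 = "C07AB02")
  )
}

# small generated dataset for property tests
small_dataset <- function(seed, ...) {
  cfg <- synthetic_config(
    seed = seed, n_drugs = 120L, n_cohort = 8L, typical_fraction = 0.5,
    degree_model = list(family = "poisson", lambda = 8),
    n_background_edges = 150L,
    keyword_plant = list(non_interacting = 2L, decoys = 2L,
                         keyword_only = 3L), ...)
  generate_dataset(cfg)
}

# Deterministic dataset with the reference subnetwork shape: 28 cohort drugs,
# 241 partners, 43 intra-cohort and 948 cohort-partner interactions.
shape_fixture_dataset <- function() {
  cohort <- sprintf("C%02d", 1:28)
  partners <- sprintf("P%03d", 1:241)

  # every partner interacts at least once; remaining inter edges fill a
  # deterministic enumeration of unused (cohort, partner) pairs
  first <- data.frame(a = cohort[((seq_len(241) - 1L) %% 28L) + 1L],
                      b = partners)
  grid <- expand.grid(a = cohort, b = partners, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  used <- paste(first$a, first$b)
  rest <- grid[!(paste(grid$a, grid$b) %in% used), ][seq_len(948L - 241L), ]
  inter <- rbind(first, rest)

  intra_pairs <- utils::combn(cohort[1:16], 2L)[, 1:43]
  interactions <- data.frame(
    drug_id = c(inter$a, intra_pairs[1L, ]),
    partner_id = c(inter$b, intra_pairs[2L, ]),
    description = "synthetic reference-shaped interaction")

  ddi_dataset(
    drugs = data.frame(drug_id = c(cohort, partners),
                       name = c(cohort, partners),
                       indication = c(rep("For the treatment of schizophrenia.", 28),
                                      rep("Other indication.", 241))),
    interactions = interactions)
}

# -- independent oracles ------------------------------------------------------

# two-sided Fisher p by explicit enumeration of all 2x2 tables with the
# observed margins; probabilities from the closed-form hypergeometric mass
# written with lchoose (independent of stats::dhyper)
brute_fisher <- function(n, N, r, R) {
  K <- n + r
  s <- max(0, K - R):min(K, N)
  logp <- lchoose(N, s) + lchoose(R, K - s) - lchoose(N + R, K)
  probs <- exp(logp)
  p_obs <- probs[s == n]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# exact rank-sum p by enumeration of all C(n1+n2, n1) assignments of the
# pooled ranks to the first sample
brute_ranksum <- function(x, y, alternative = "two.sided") {
  n1 <- length(x)
  n <- n1 + length(y)
  rk <- rank(c(x, y))
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  # untied ranks are a permutation of 1..n, so the null U distribution is
  # given by all n1-subsets of {1..n}
  subsets <- utils::combn(n, n1)
  u_all <- colSums(subsets) - n1 * (n1 + 1) / 2
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}
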