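#' Configuration for the synthetic DrugBank-like generator
#'
#' The generator emulates the statistical structure the pipeline assumes: a
#' pool of drugs with hierarchical ATC annotations over the 14 anatomical
#' main groups, a designated disease cohort split typical/atypical whose
#' members carry antipsychotic (N05A) codes and a disease keyword in their
#' indication, heterogeneous interaction degrees, a screening funnel with
#' keyword-only hits and manually excludable decoys, and optional planted
#' category-enrichment effects acting on typical drugs' partner selection.
#'
#' Defaults mirror the bundled reference antipsychotic cohort's shape: a 28-drug
#' cohort (18 typical / 10 atypical), Poisson partner counts with mean
#' 948/28, intra-cohort edge probability 43/choose(28,2), ~9940 background
#' edges over ~1087 interacting drugs, and first-level category weights
#' proportional to the observed sizes of the 14 ATC groups.
#'
#' @param seed integer random seed; the dataset is fully reproducible
#'   given the seed.
#' @param n_drugs number of interaction-eligible drugs (cohort included).
#' @param n_cohort cohort size; must not exceed `n_drugs`.
#' @param typical_fraction fraction of the cohort labeled typical.
#' @param atc_level1_weights named 14-vector of first-level category
#'   weights (normalized internally).
#' @param multi_code_prob probability an annotated non-cohort drug carries a
#'   second ATC code.
#' @param unannotated_prob probability a non-cohort drug has no ATC code.
#' @param partner_unannotated_prob probability a cohort interaction picks an
#'   unannotated partner.
#' @param degree_model list: `list(family = "poisson", lambda = )` or
#'   `list(family = "powerlaw", alpha = , k_min = )` for per-cohort-drug
#'   partner counts.
#' @param intra_edge_prob probability each cohort pair interacts.
#' @param planted_effects named numeric vector, first-level category ->
#'   odds multiplier applied to *typical* drugs' partner-category selection
#'   (atypical drugs stay at baseline). Empty = null dataset.
#' @param keyword_plant list with counts `non_interacting` (cohort-like
#'   drugs with the keyword in the indication but no interactions),
#'   `decoys` (indication keyword hits unrelated to the disease, listed as
#'   exclusion overrides in the truth), and `keyword_only` (drugs hit only
#'   through an interaction-description mention).
#' @param n_background_edges number of interactions among non-cohort drugs.
#' @param n_degree_boost background-propensity multiplier for drugs with a
#'   nervous-system (N) code, reproducing their higher connectivity.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_drugs = 1087L,
                             n_cohort = 28L,
                             typical_fraction = 18 / 28,
                             atc_level1_weights = NULL,
                             multi_code_prob = 0.08,
                             unannotated_prob = 0.075,
                             partner_unannotated_prob = 0.055,
                             degree_model = list(family = "poisson",
                                                 lambda = 948 / 28),
                             intra_edge_prob = 43 / choose(28, 2),
                             planted_effects = numeric(),
                             keyword_plant = list(non_interacting = 5L,
                                                  decoys = 5L,
                                                  keyword_only = 8L),
                             n_background_edges = 9940L,
                             n_degree_boost = 1.6) {
  if (is.null(atc_level1_weights)) {
    # proportional to the observed sizes of the 14 first-level groups in a
    # large adverse-DDI compilation
    atc_level1_weights <- c(A = 119, B = 45, C = 153, D = 56, G = 61, H = 21,
                            J = 143, L = 118, M = 56, N = 219, P = 20,
                            R = 75, S = 85, V = 22)
  }
  if (!setequal(names(atc_level1_weights), ATC_LEVEL1))
    stop("atc_level1_weights must be named by the 14 first-level letters")
  atc_level1_weights <- atc_level1_weights[ATC_LEVEL1]
  if (any(atc_level1_weights < 0)) stop("weights must be non-negative")
  atc_level1_weights <- atc_level1_weights / sum(atc_level1_weights)

  probs <- c(typical_fraction, multi_code_prob, unannotated_prob,
             partner_unannotated_prob, intra_edge_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  n_drugs <- as.integer(n_drugs); n_cohort <- as.integer(n_cohort)
  if (n_cohort < 1L || n_cohort > n_drugs)
    stop("need 1 <= n_cohort <= n_drugs")
  stopifnot(is.list(degree_model),
            degree_model$family %in% c("poisson", "powerlaw"))
  if (degree_model$family == "poisson") stopifnot(degree_model$lambda >= 0)
  if (degree_model$family == "powerlaw")
    stopifnot(degree_model$alpha > 1, degree_model$k_min >= 1)
  if (length(planted_effects) > 0L) {
    if (is.null(names(planted_effects)) ||
        any(!names(planted_effects) %in% ATC_LEVEL1))
      stop("planted_effects must be named by first-level letters")
    if (any(planted_effects <= 0)) stop("planted effects must be positive")
  }
  kp <- keyword_plant
  for (f in c("non_interacting", "decoys", "keyword_only"))
    if (is.null(kp[[f]]) || kp[[f]] < 0) stop("invalid keyword_plant$", f)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")

  structure(
    list(seed = seed, n_drugs = n_drugs, n_cohort = n_cohort,
         typical_fraction = typical_fraction,
         atc_level1_weights = atc_level1_weights,
         multi_code_prob = multi_code_prob,
         unannotated_prob = unannotated_prob,
         partner_unannotated_prob = partner_unannotated_prob,
         degree_model = degree_model, intra_edge_prob = intra_edge_prob,
         planted_effects = planted_effects, keyword_plant = kp,
         n_background_edges = as.integer(n_background_edges),
         n_degree_boost = n_degree_boost),
    class = "synthetic_config"
  )
}

# random full ATC codes under given first-level letters
random_atc <- function(letters1) {
  n <- length(letters1)
  paste0(letters1,
         sprintf("%02d", sample.int(16L, n, replace = TRUE)),
         sample(LETTERS, n, replace = TRUE),
         sample(LETTERS, n, replace = TRUE),
         sprintf("%02d", sample.int(30L, n, replace = TRUE)))
}

#' Generate a synthetic drug-interaction dataset with known truth
#'
#' See [synthetic_config()] for the generative model. The emitted dataset
#' always passes [validate_ddi_dataset()] with zero dangling references and
#' zero self-loops, and is byte-identical across runs with the same config.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `dataset` (a [ddi_dataset()]) and `truth`
#'   (class `synthetic_truth`): the planted cohort and typology, screening
#'   funnel ids (`decoy_ids` doubling as exclusion overrides,
#'   `keyword_only_ids`, `non_interacting_ids`), per-subgroup expected
#'   partner-category probabilities, the planted effects, and the config.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  stage_seed <- sample.int(2147483646L, 6L)

  n <- config$n_drugs
  kp <- config$keyword_plant
  n_extra <- kp$non_interacting + kp$decoys
  ids <- sprintf("SYN%05d", seq_len(n + n_extra))
  cohort <- ids[seq_len(config$n_cohort)]
  noncoh <- ids[(config$n_cohort + 1L):n]     # interaction-eligible non-cohort
  extra <- if (n_extra > 0L) ids[(n + 1L):(n + n_extra)] else character()
  non_interacting <- if (kp$non_interacting > 0L)
    extra[seq_len(kp$non_interacting)] else character()
  decoys <- setdiff(extra, non_interacting)

  n_typ <- round(config$typical_fraction * config$n_cohort)
  typology <- stats::setNames(
    rep(c("typical", "atypical"), c(n_typ, config$n_cohort - n_typ)), cohort)

  ## --- ATC annotation -----------------------------------------------------
  set.seed(stage_seed[1L])
  atc <- vector("list", length(ids)); names(atc) <- ids
  typ4 <- c("A", "B", "C", "D", "F")   # classic antipsychotic subgroups
  atyp4 <- c("E", "H", "L", "X")
  atc[cohort] <- as.list(paste0(
    "N05A", ifelse(typology == "typical",
                   sample(typ4, config$n_cohort, replace = TRUE),
                   sample(atyp4, config$n_cohort, replace = TRUE)),
    sprintf("%02d", sample.int(30L, config$n_cohort, replace = TRUE))))
  atc[non_interacting] <- as.list(
    random_atc(rep("N", length(non_interacting))))

  w <- config$atc_level1_weights
  annotated <- noncoh[stats::runif(length(noncoh)) >= config$unannotated_prob]
  if (length(annotated) > 0L) {
    l1 <- sample(names(w), length(annotated), replace = TRUE, prob = w)
    codes <- random_atc(l1)
    second <- stats::runif(length(annotated)) < config$multi_code_prob
    atc[annotated] <- as.list(codes)
    if (any(second)) {
      l1b <- sample(names(w), sum(second), replace = TRUE, prob = w)
      atc[annotated[second]] <- Map(c, codes[second], random_atc(l1b))
    }
  }
  unannotated_pool <- setdiff(noncoh, annotated)
  letter_of <- lapply(atc[annotated], function(cs) unique(substr(cs, 1L, 1L)))
  pool_ids <- rep(annotated, lengths(letter_of))
  pool_letter <- unlist(letter_of, use.names = FALSE)
  pools <- split(pool_ids, pool_letter)

  ## --- cohort-partner interactions ----------------------------------------
  set.seed(stage_seed[2L])
  dm <- config$degree_model
  k <- if (dm$family == "poisson") {
    stats::rpois(config$n_cohort, dm$lambda)
  } else {
    u <- stats::runif(config$n_cohort)
    pmin(round(dm$k_min * u^(-1 / (dm$alpha - 1))), length(noncoh))
  }

  # heavy-tailed partner popularity: a minority of drugs (enzyme inhibitors,
  # QT-prolongers, ...) interact with many cohort drugs
  popularity <- stats::setNames(pmin(stats::runif(length(noncoh))^(-1), 200),
                                noncoh)

  pu <- config$partner_unannotated_prob
  cat_probs <- function(subgroup) {
    wt <- w
    if (subgroup == "typical" && length(config$planted_effects) > 0L) {
      wt[names(config$planted_effects)] <-
        wt[names(config$planted_effects)] * config$planted_effects
      wt <- wt / sum(wt)
    }
    c(wt * (1 - pu), UNANN = pu)
  }
  probs_by_group <- list(typical = cat_probs("typical"),
                         atypical = cat_probs("atypical"))

  from <- character(0); to <- character(0)
  for (i in seq_len(config$n_cohort)) {
    if (k[i] == 0L) next
    p <- probs_by_group[[typology[i]]]
    cats <- sample(names(p), k[i], replace = TRUE, prob = p)
    tab <- table(cats)
    partners <- character(0)
    for (cc in names(tab)) {
      pool <- if (cc == "UNANN") unannotated_pool else pools[[cc]]
      m <- min(tab[[cc]], length(pool))
      if (m > 0L)
        partners <- c(partners, sample(pool, m, prob = popularity[pool]))
    }
    from <- c(from, rep(cohort[i], length(partners)))
    to <- c(to, partners)
  }
  inter <- data.frame(
    drug_id = from, partner_id = to,
    description = "Increased risk of adverse effects when coadministered.")

  ## --- intra-cohort interactions ------------------------------------------
  set.seed(stage_seed[3L])
  intra <- data.frame(drug_id = character(), partner_id = character(),
                      description = character())
  if (config$n_cohort >= 2L && config$intra_edge_prob > 0) {
    prs <- utils::combn(cohort, 2L)
    hit <- stats::runif(ncol(prs)) < config$intra_edge_prob
    if (any(hit))
      intra <- data.frame(
        drug_id = prs[1L, hit], partner_id = prs[2L, hit],
        description = "Increased risk of cardiotoxicity and arrhythmias.")
  }

  ## --- background interactions among non-cohort drugs ---------------------
  set.seed(stage_seed[4L])
  bg <- data.frame(drug_id = character(), partner_id = character(),
                   description = character())
  m_bg <- min(config$n_background_edges, choose(length(noncoh), 2L))
  if (m_bg > 0L && length(noncoh) >= 2L) {
    prop <- stats::runif(length(noncoh))^(-0.45)       # heavy-tailed propensity
    has_n <- vapply(atc[noncoh], function(cs)
      !is.null(cs) && any(substr(cs, 1L, 1L) == "N"), logical(1))
    prop[has_n] <- prop[has_n] * config$n_degree_boost
    keys <- character(0); ea <- character(0); eb <- character(0)
    while (length(ea) < m_bg) {
      need <- m_bg - length(ea)
      cand_a <- sample(noncoh, ceiling(need * 1.4), replace = TRUE, prob = prop)
      cand_b <- sample(noncoh, ceiling(need * 1.4), replace = TRUE, prob = prop)
      ok <- cand_a != cand_b
      a <- pmin(cand_a[ok], cand_b[ok]); b <- pmax(cand_a[ok], cand_b[ok])
      kk <- paste(a, b, sep = "\r")
      fresh <- !duplicated(kk) & !(kk %in% keys)
      ea <- c(ea, a[fresh]); eb <- c(eb, b[fresh]); keys <- c(keys, kk[fresh])
      if (length(ea) > m_bg) {
        ea <- ea[seq_len(m_bg)]; eb <- eb[seq_len(m_bg)]
      }
    }
    bg <- data.frame(drug_id = ea, partner_id = eb,
                     description = "Combination may alter drug plasma levels.")
  }

  ## --- screening funnel plants --------------------------------------------
  set.seed(stage_seed[5L])
  kw_only <- character()
  kw_decl <- NULL
  if (kp$keyword_only > 0L && length(noncoh) > kp$keyword_only) {
    kw_only <- sample(setdiff(noncoh, unique(inter$partner_id)),
                      kp$keyword_only)
    kw_partner <- sample(setdiff(noncoh, kw_only), kp$keyword_only,
                         replace = FALSE)
    kw_decl <- data.frame(
      drug_id = kw_only, partner_id = kw_partner,
      description = paste("Case reports of augmented sedation in",
                          "schizophrenic patients."))
  }

  indication <- rep("For the management of hypertension and angina.",
                    length(ids))
  names(indication) <- ids
  alt <- c("For the treatment of bacterial infections.",
           "For the relief of chronic pain.",
           "For the treatment of major depressive disorder.",
           "For the management of type 2 diabetes.",
           "For symptomatic relief of seasonal allergies.")
  indication[noncoh] <- sample(alt, length(noncoh), replace = TRUE)
  indication[cohort] <-
    "For the treatment of schizophrenia and related psychotic disorders."
  indication[non_interacting] <-
    "For the treatment of schizophrenia in patients unresponsive to first-line therapy."
  indication[decoys] <-
    "For sedation; historically investigated in schizophrenia trials without efficacy."

  drugs <- data.frame(drug_id = ids,
                      name = paste0("Syntheticin-", sub("^SYN", "", ids)),
                      indication = unname(indication[ids]))
  interactions <- rbind(inter, intra, bg, kw_decl)
  rownames(interactions) <- NULL

  dataset <- ddi_dataset(
    drugs, interactions, atc_codes = atc[lengths(atc) > 0L],
    provenance = paste0("sczddi synthetic generator, seed=", config$seed))

  truth <- structure(
    list(cohort = data.frame(drug_id = cohort,
                             typology = unname(typology[cohort])),
         typology = typology,
         decoy_ids = decoys,
         non_interacting_ids = non_interacting,
         keyword_only_ids = kw_only,
         planted_effects = config$planted_effects,
         category_probs = probs_by_group,
         realized = list(n_inter_declared = nrow(inter),
                         n_intra_edges = nrow(intra),
                         n_background_edges = nrow(bg)),
         config = config),
    class = "synthetic_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth (seed ", x$config$seed, ")\n", sep = "")
  cat("  cohort: ", nrow(x$cohort), " (",
      sum(x$cohort$typology == "typical"), " typical / ",
      sum(x$cohort$typology == "atypical"), " atypical)\n", sep = "")
  if (length(x$planted_effects) > 0L) {
    cat("  planted effects:",
        paste(names(x$planted_effects), x$planted_effects,
              sep = "=", collapse = ", "), "\n")
  } else cat("  planted effects: none (null dataset)\n")
  invisible(x)
}
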